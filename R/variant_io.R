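#' Read a VCF into a genotype or haplotype matrix
#'
#' Multiallelic and non-SNP records are dropped (a message reports the
#' count). With `phased = TRUE` every genotype must use the phased `|`
#' separator (missing calls are allowed) and a [hap_matrix()] is returned;
#' otherwise genotypes are collapsed to dosages in a [geno_matrix()].
#'
#' @param path VCF v4.x file (plain or gzipped).
#' @param phased logical; require phased genotypes and return haplotypes.
#' @return A [geno_matrix()] or [hap_matrix()], sites ordered by
#'   (chrom, pos).
#' @export
read_vcf <- function(path, phased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::tibble(
    chrom = vcfR::getCHROM(v),
    pos = as.integer(vcfR::getPOS(v)),
    ref = vcfR::getREF(v),
    alt = vcfR::getALT(v)
  )
  snp <- !is.na(fix$alt) & nchar(fix$ref) == 1L & nchar(fix$alt) == 1L &
    !grepl(",", fix$alt, fixed = TRUE)
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message(sprintf("read_vcf: dropped %d multiallelic/non-SNP record(s)", n_drop))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ord <- order(fix$chrom, fix$pos)
  fix <- fix[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  samples <- colnames(gt)

  # decode genotype strings through a small lookup over the distinct values
  codes <- unique(as.vector(gt))
  codes[is.na(codes)] <- "."
  gtv <- as.vector(gt)
  gtv[is.na(gtv)] <- "."
  parse1 <- function(code) {
    if (code %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_, 0L))
    phased_sep <- grepl("|", code, fixed = TRUE)
    parts <- strsplit(code, "[/|]")[[1]]
    if (length(parts) != 2L || !all(parts %in% c("0", "1", ".")))
      stop("read_vcf: unsupported genotype '", code, "'", call. = FALSE)
    a <- ifelse(parts == ".", NA_integer_, as.integer(parts))
    c(a, as.integer(phased_sep))
  }
  tab <- vapply(codes, parse1, integer(3))
  if (phased) {
    called <- !codes %in% c(".", "./.", ".|.")
    if (any(called & tab[3, ] == 0L))
      stop("read_vcf: unphased genotype under phased = TRUE", call. = FALSE)
  }
  idx <- match(gtv, codes)
  a1 <- matrix(tab[1, idx], nrow = nrow(gt))
  a2 <- matrix(tab[2, idx], nrow = nrow(gt))
  sites <- fix
  if (phased) {
    n <- length(samples)
    alleles <- matrix(0L, nrow = 2L * n, ncol = nrow(sites))
    alleles[seq(1L, 2L * n, 2L), ] <- t(a1)
    alleles[seq(2L, 2L * n, 2L), ] <- t(a2)
    hap_matrix(alleles, sites, samples)
  } else {
    geno_matrix(t(a1 + a2), sites, samples)
  }
}

#' Write a haplotype matrix as plain VCF v4.2
#'
#' Phased `0|1`-style genotypes, one contig header line, 1-based positions.
#' A logical `missing` mask (samples x sites) marks calls written as `./.`.
#'
#' @param haps a [hap_matrix()].
#' @param path output file.
#' @param contig_length contig length for the `##contig` header.
#' @param missing optional logical matrix, samples x sites.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(haps, path, contig_length = max(haps$sites$pos),
                      missing = NULL) {
  stopifnot(inherits(haps, "hap_matrix"))
  n <- length(haps$samples)
  L <- ncol(haps$alleles)
  a1 <- haps$alleles[seq(1L, 2L * n, 2L), , drop = FALSE]
  a2 <- haps$alleles[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow = n)
  if (!is.null(missing)) gt[missing] <- "./."
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", haps$sites$chrom[1],
            as.integer(contig_length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", haps$samples), collapse = "\t")
  )
  body <- paste(
    haps$sites$chrom, haps$sites$pos, ".", haps$sites$ref, haps$sites$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write gene annotation as BED4
#'
#' @param genes tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `gene_id`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(genes, path) {
  writeLines(paste(genes$chrom, genes$start, genes$end, genes$gene_id,
                   sep = "\t"), path)
  invisible(path)
}

#' Read gene annotation (BED4 or GFF3 gene lines)
#'
#' BED intervals are kept 0-based half-open as stored; GFF3 1-based closed
#' intervals are converted to 0-based half-open here, the package's single
#' interval convention.
#'
#' @param path annotation file; format chosen by extension (`.bed` vs
#'   `.gff`/`.gff3`) unless `format` is given.
#' @param format `"bed"` or `"gff"`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff" else "bed"
  if (format == "bed") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(x) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
    tibble::tibble(
      gene_id = if (ncol(x) >= 4L) as.character(x[[4]])
                else sprintf("gene%03d", seq_len(nrow(x))),
      chrom = as.character(x[[1]]),
      start = as.integer(x[[2]]),
      end = as.integer(x[[3]]),
      strand = if (ncol(x) >= 6L) as.character(x[[6]]) else "."
    )
  } else {
    x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
    x <- x[x[[3]] == "gene", , drop = FALSE]
    if (nrow(x) == 0L) stop("no gene records in GFF", call. = FALSE)
    id <- sub(".*ID=([^;]+).*", "\\1", x[[9]])
    tibble::tibble(
      gene_id = id,
      chrom = as.character(x[[1]]),
      start = as.integer(x[[4]]) - 1L,
      end = as.integer(x[[5]]),
      strand = as.character(x[[7]])
    )
  }
}

#' Read a population map
#'
#' @param path TSV with header `sample`, `population`, `phenotype`, `clade`.
#' @return Tibble with those columns; phenotypes must be
#'   `resident`/`migrant`.
#' @export
read_popmap <- function(path) {
  x <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           stringsAsFactors = FALSE))
  need <- c("sample", "population", "phenotype", "clade")
  if (!all(need %in% names(x)))
    stop("popmap must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(x$phenotype %in% c("resident", "migrant")))
    stop("phenotype must be 'resident' or 'migrant'", call. = FALSE)
  x[, need]
}

#' Filter sites on minor allele frequency and missingness
#'
#' Retains sites whose overall minor-allele frequency (computed on called
#' alleles) is at least `maf_min` and whose fraction of missing calls is at
#' most `max_missing_fraction`. Order is preserved and the operation is
#' idempotent. The per-site drop reasons are attached as attribute
#' `"report"` (tibble `chrom`, `pos`, `reason`).
#'
#' @param geno a [geno_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing_fraction maximum fraction of missing calls (default
#'   0.25, i.e. a site must be called in 75% of samples).
#' @return The filtered [geno_matrix()].
#' @export
filter_sites <- function(geno, maf_min = 0.05, max_missing_fraction = 0.25) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosages
  n_called <- colSums(!is.na(d))
  miss_frac <- 1 - n_called / nrow(d)
  alt <- colSums(d, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf < maf_min
  fail_miss <- miss_frac > max_missing_fraction
  keep <- !(fail_maf | fail_miss)
  reason <- dplyr::case_when(
    fail_maf & fail_miss ~ "maf+missingness",
    fail_maf ~ "maf",
    fail_miss ~ "missingness",
    TRUE ~ NA_character_
  )
  report <- tibble::tibble(chrom = geno$sites$chrom, pos = geno$sites$pos,
                           reason = reason)[!keep, ]
  out <- geno_matrix(d[, keep, drop = FALSE], geno$sites[keep, , drop = FALSE],
                     geno$samples)
  attr(out, "report") <- report
  out
}

#' Per-population allele counts and frequencies
#'
#' Counts use called alleles only; pooled population sets are merged before
#' counting (count-weighted pooling, not a mean of frequencies). A group
#' with zero called alleles at a site gets `freq = NA` and `undefined =
#' TRUE`, never 0.
#'
#' @param geno a [geno_matrix()].
#' @param popmap tibble with `sample`, `population`.
#' @param groups named list; each element is a character vector of population
#'   labels pooled into one group. A bare character vector is treated as
#'   one-group-per-population.
#' @return Tibble `chrom`, `pos`, `group`, `alt_count`, `called`, `freq`,
#'   `undefined`.
#' @export
allele_frequencies <- function(geno, popmap, groups) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (!is.list(groups)) groups <- stats::setNames(as.list(groups), groups)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named", call. = FALSE)
  purrr::map_dfr(names(groups), function(g) {
    pops <- groups[[g]]
    if (!all(pops %in% popmap$population))
      stop("unknown population(s) in group ", g, call. = FALSE)
    samp <- popmap$sample[popmap$population %in% pops]
    rows <- match(samp, geno$samples)
    if (anyNA(rows)) stop("popmap sample absent from genotypes", call. = FALSE)
    d <- geno$dosages[rows, , drop = FALSE]
    alt <- colSums(d, na.rm = TRUE)
    called <- 2L * colSums(!is.na(d))
    tibble::tibble(
      chrom = geno$sites$chrom, pos = geno$sites$pos, group = g,
      alt_count = as.integer(alt), called = as.integer(called),
      freq = ifelse(called > 0, alt / called, NA_real_),
      undefined = called == 0L
    )
  })
}
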