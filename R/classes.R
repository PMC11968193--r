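#' Haplotype and genotype matrix containers
#'
#' `hap_matrix()` wraps a phased 0/1 allele matrix (rows = haplotypes, two per
#' diploid sample; columns = sites) together with site coordinates and the
#' haplotype-to-sample index. `geno_matrix()` wraps the per-sample allele
#' dosage view (0/1/2, `NA` = missing call) of the same sites. Both carry a
#' `sites` tibble with 1-based VCF-style positions; all interval arithmetic
#' elsewhere in the package is 0-based half-open, and conversions happen at
#' the I/O boundary only.
#'
#' @param alleles integer matrix of 0/1 alleles, `2 * n_samples` rows.
#' @param dosages integer matrix of 0/1/2 dosages (`NA` missing), samples in rows.
#' @param sites tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   rows ordered strictly increasing by (chrom, pos).
#' @param samples character vector of sample identifiers.
#' @return An object of class `hap_matrix` or `geno_matrix`.
#' @export
hap_matrix <- function(alleles, sites, samples) {
  alleles <- as.matrix(alleles)
  stopifnot(nrow(alleles) == 2L * length(samples),
            ncol(alleles) == nrow(sites))
  check_site_order(sites)
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  structure(
    list(alleles = alleles, sites = tibble::as_tibble(sites),
         samples = samples,
         hap_sample = rep(samples, each = 2L)),
    class = "hap_matrix"
  )
}

#' @rdname hap_matrix
#' @export
geno_matrix <- function(dosages, sites, samples) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(samples), ncol(dosages) == nrow(sites))
  check_site_order(sites)
  storage.mode(dosages) <- "integer"
  rownames(dosages) <- samples
  structure(
    list(dosages = dosages, sites = tibble::as_tibble(sites), samples = samples),
    class = "geno_matrix"
  )
}

check_site_order <- function(sites) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  key <- order(sites$chrom, sites$pos)
  if (!identical(key, seq_len(nrow(sites))))
    stop("sites must be ordered by (chrom, pos)", call. = FALSE)
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) stop("duplicate site positions", call. = FALSE)
  invisible(TRUE)
}

#' Collapse phased haplotypes to dosages
#'
#' @param haps a [hap_matrix()].
#' @return A [geno_matrix()] whose dosages are the sum of each sample's two
#'   haplotypes; consistency of this view with a genotype matrix read from the
#'   same VCF is an invariant of the I/O layer.
#' @export
as_genotypes <- function(haps) {
  stopifnot(inherits(haps, "hap_matrix"))
  a <- haps$alleles
  n <- length(haps$samples)
  d <- a[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       a[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  geno_matrix(d, haps$sites, haps$samples)
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d haplotypes (%d samples) x %d sites on %s\n",
              nrow(x$alleles), length(x$samples), ncol(x$alleles),
              paste(unique(x$sites$chrom), collapse = ",")))
  invisible(x)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d sites on %s (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$sites$chrom), collapse = ","),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
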