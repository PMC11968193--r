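# All intervals in this module are 0-based half-open tibbles with columns
# chrom, start, end; a site is a length-1 interval [pos - 1, pos).
# IRanges/GenomicRanges (1-based closed) do the heavy lifting behind a
# conversion at this boundary; min.gapwidth = 0 preserves half-open
# semantics (adjacent intervals do not merge, a shared base is required to
# overlap).

iv_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

gr_to_iv <- function(gr) {
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
}

#' Convert site positions to length-1 intervals
#'
#' @param x tibble with `chrom` and 1-based `pos`.
#' @return Interval tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
sites_as_intervals <- function(x) {
  tibble::tibble(chrom = x$chrom, start = x$pos - 1L, end = x$pos)
}

#' Merge overlapping intervals
#'
#' Standard union with half-open semantics: `[0,10)` and `[10,20)` share no
#' base and do not merge.
#'
#' @param intervals interval tibble (`chrom`, `start`, `end`).
#' @return Sorted, non-overlapping interval tibble.
#' @export
merge_overlapping <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(iv_to_gr(intervals), min.gapwidth = 0L)
  dplyr::arrange(gr_to_iv(gr), .data$chrom, .data$start)
}

#' Exclude case outliers that replicate in control comparisons
#'
#' Removes every case item overlapping (sharing at least one base with) any
#' control item. With site-level items overlap degenerates to identical
#' position. This is the step that strips differentiation driven by shared
#' demography — anything a migrant-migrant or resident-resident contrast
#' also flags — from the case outlier sets.
#'
#' @param case interval tibble of case outliers (extra columns preserved).
#' @param controls a single interval tibble or a list of them.
#' @return The case tibble with overlapping rows removed; output is always a
#'   subset of the input.
#' @export
exclude_control_outliers <- function(case, controls) {
  if (is.data.frame(controls)) controls <- list(controls)
  controls <- purrr::keep(controls, ~ nrow(.x) > 0L)
  if (nrow(case) == 0L || length(controls) == 0L) return(case)
  ctrl <- dplyr::bind_rows(lapply(controls, function(x)
    x[, c("chrom", "start", "end")]))
  hits <- GenomicRanges::findOverlaps(iv_to_gr(case), iv_to_gr(ctrl),
                                      minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0L) case else case[-drop, , drop = FALSE]
}

#' Intersect outlier sets across comparisons
#'
#' Merges the union of all comparisons' items and assigns each merged item
#' the set of comparisons whose outliers overlap it, yielding the exclusive
#' regions of the Venn diagram (7 regions for three comparisons).
#'
#' @param sets named list of interval tibbles, one per comparison.
#' @return Tibble `chrom`, `start`, `end`, one logical column per
#'   comparison, `n_comparisons`, `region` (e.g. `"A&C"`).
#' @export
intersect_across <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  merged <- merge_overlapping(dplyr::bind_rows(lapply(sets, function(x)
    x[, c("chrom", "start", "end")])))
  if (nrow(merged) == 0L) {
    out <- merged
    for (nm in names(sets)) out[[nm]] <- logical(0)
    out$n_comparisons <- integer(0)
    out$region <- character(0)
    return(out)
  }
  gr <- iv_to_gr(merged)
  memb <- vapply(sets, function(x) {
    if (nrow(x) == 0L) return(rep(FALSE, nrow(merged)))
    GenomicRanges::countOverlaps(gr, iv_to_gr(x), minoverlap = 1L) > 0L
  }, logical(nrow(merged)))
  memb <- matrix(memb, nrow = nrow(merged),
                 dimnames = list(NULL, names(sets)))
  out <- dplyr::bind_cols(merged, tibble::as_tibble(memb))
  out$n_comparisons <- rowSums(memb)
  out$region <- apply(memb, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  out
}

#' Genes within a distance of outlier items
#'
#' A gene is hit when the minimum distance between the item interval and the
#' gene interval is at most `max_dist_bp` (0 when they overlap); the
#' boundary is inclusive, so a site exactly `max_dist_bp` from a gene edge
#' counts. One item may hit several genes. Items on chromosomes absent from
#' the annotation yield no hits.
#'
#' @param items interval tibble; a `comparison` column, if present, is
#'   carried into the hits.
#' @param genes gene annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param max_dist_bp proximity threshold (default 25 kb).
#' @return Tibble of hits: item coordinates, `gene_id`, `distance_bp`.
#' @export
genes_near <- function(items, genes, max_dist_bp = 25000L) {
  stopifnot(nrow(genes) > 0L)
  if (nrow(items) == 0L)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), gene_id = character(),
                          distance_bp = integer()))
  gi <- iv_to_gr(items)
  gg <- iv_to_gr(genes)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gi, gg, maxgap = as.integer(max_dist_bp)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- suppressWarnings(
    GenomicRanges::distance(gi[qh], gg[sh]))
  out <- tibble::tibble(
    chrom = items$chrom[qh], start = items$start[qh], end = items$end[qh],
    gene_id = genes$gene_id[sh], distance_bp = as.integer(dist)
  )
  if ("comparison" %in% names(items))
    out <- dplyr::mutate(out, comparison = items$comparison[qh], .before = 1)
  out
}

#' Classify parallelism across replicated comparisons
#'
#' Builds the membership of every item (gene identifier or merged genomic
#' interval) across comparisons and the exclusive Venn region counts. Items
#' present in two or more comparisons are the parallel candidates; the union
#' minus those is the convergent remainder.
#'
#' @param sets named list, one element per comparison: character vectors of
#'   gene ids (`level = "gene"`) or interval tibbles (`level = "snp"`).
#' @param level `"gene"` or `"snp"`.
#' @return Object of class `parallelism_report`: `level`, `membership`
#'   (tibble `item` + one logical column per comparison + `n_comparisons` +
#'   `region`), `venn` (tibble `region`, `count`, exclusive regions),
#'   `union_size`, `shared_multi` (items in >= 2 comparisons),
#'   `shared_all`.
#' @export
classify_parallelism <- function(sets, level = c("gene", "snp")) {
  level <- match.arg(level)
  stopifnot(!is.null(names(sets)), length(sets) >= 2L)
  if (level == "gene") {
    items <- sort(unique(unlist(sets)))
    memb <- vapply(sets, function(s) items %in% s, logical(length(items)))
    memb <- matrix(memb, nrow = length(items),
                   dimnames = list(NULL, names(sets)))
    membership <- dplyr::bind_cols(tibble::tibble(item = items),
                                   tibble::as_tibble(memb))
    membership$n_comparisons <- rowSums(memb)
    membership$region <- apply(memb, 1L, function(r)
      paste(names(sets)[r], collapse = "&"))
  } else {
    membership <- intersect_across(sets)
    membership <- dplyr::mutate(
      membership,
      item = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
      .before = 1
    )
    memb <- as.matrix(membership[, names(sets)])
  }
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  venn <- tibble::tibble(
    region = unlist(combos),
    count = vapply(combos, function(r) sum(membership$region == r),
                   integer(1), USE.NAMES = FALSE)
  )
  report <- structure(list(
    level = level,
    membership = membership,
    venn = venn,
    union_size = nrow(membership),
    shared_multi = sum(membership$n_comparisons >= 2L),
    shared_all = sum(membership$n_comparisons == length(sets))
  ), class = "parallelism_report")
  stopifnot(sum(venn$count) == report$union_size,
            report$shared_all <= report$shared_multi,
            report$shared_multi <= report$union_size)
  report
}

#' @export
print.parallelism_report <- function(x, ...) {
  cat(sprintf(
    "<parallelism_report> level=%s union=%d shared>=2=%d shared-all=%d\n",
    x$level, x$union_size, x$shared_multi, x$shared_all))
  print(x$venn)
  invisible(x)
}

#' @rdname classify_parallelism
#' @param x a `parallelism_report`.
#' @param ... unused.
#' @method tidy parallelism_report
#' @export
tidy.parallelism_report <- function(x, ...) x$membership

#' @rdname classify_parallelism
#' @method glance parallelism_report
#' @export
glance.parallelism_report <- function(x, ...) {
  tibble::tibble(level = x$level, union_size = x$union_size,
                 shared_multi = x$shared_multi, shared_all = x$shared_all)
}

#' Count shared versus comparison-specific genes by functional category
#'
#' Joins a gene-category table (e.g. timing / energetics / morphology) onto
#' a gene-level parallelism report and counts, per category, genes found in
#' two or more comparisons versus exactly one.
#'
#' @param report a gene-level `parallelism_report`.
#' @param categories tibble `gene`, `category`.
#' @return Tibble `category`, `shared_multi`, `single`, `total`.
#' @export
category_sharing <- function(report, categories) {
  stopifnot(inherits(report, "parallelism_report"), report$level == "gene")
  m <- dplyr::inner_join(report$membership,
                         dplyr::rename(categories, item = "gene"),
                         by = "item")
  dplyr::summarise(
    dplyr::group_by(m, .data$category),
    shared_multi = sum(.data$n_comparisons >= 2L),
    single = sum(.data$n_comparisons == 1L),
    total = dplyr::n(),
    .groups = "drop"
  )
}

#' Directionality concordance of shared outliers
#'
#' For every shared item, takes in each sharing comparison the sign of the
#' standardized XP-EHH score at the item's best significant site (largest
#' |score| among significant sites overlapping the item). An item is
#' concordant when all determined signs agree — all positive meaning
#' selection in the resident populations. Items with an undetermined sign in
#' any sharing comparison are excluded from the fraction's denominator.
#'
#' @param items interval tibble of shared items with an `item` identifier
#'   column and one logical membership column per comparison.
#' @param xpehh_results named list of [xpehh()] tibbles, names matching the
#'   membership columns.
#' @return Tibble `item`, `signs` (list of named signs), `determined`,
#'   `concordant`; the concordant fraction (concordant / determined) is in
#'   attribute `"fraction"` (NA when no item is determined).
#' @export
directionality_concordance <- function(items, xpehh_results) {
  comps <- names(xpehh_results)
  stopifnot(all(comps %in% names(items)))
  if (nrow(items) == 0L) {
    rows <- tibble::tibble(item = character(), signs = list(),
                           determined = logical(), concordant = logical())
    attr(rows, "fraction") <- NA_real_
    return(rows)
  }
  rows <- purrr::map_dfr(seq_len(nrow(items)), function(i) {
    sharing <- comps[vapply(comps, function(cc) isTRUE(items[[cc]][i]),
                            logical(1))]
    signs <- vapply(sharing, function(cc) {
      xr <- xpehh_results[[cc]]
      inside <- xr$chrom == items$chrom[i] &
        (xr$pos - 1L) >= items$start[i] & (xr$pos - 1L) < items$end[i] &
        xr$significant
      if (!any(inside)) return(NA_real_)
      best <- which.max(abs(xr$std[inside]))
      sign(xr$std[inside][best])
    }, numeric(1))
    det <- length(signs) > 0L && !anyNA(signs)
    conc <- det && length(unique(signs)) == 1L
    tibble::tibble(item = items$item[i], signs = list(signs),
                   determined = det, concordant = conc)
  })
  det <- sum(rows$determined)
  attr(rows, "fraction") <- if (det > 0) sum(rows$concordant) / det else NA_real_
  rows
}

#' Simplified functional categorization of outlier items
#'
#' `genic` items overlap a gene interval; `proximal-regulatory` items lie
#' within `max_dist_bp` of a gene without overlapping it; everything else is
#' `intergenic`.
#'
#' @param items interval tibble.
#' @param genes gene annotation tibble.
#' @param max_dist_bp regulatory proximity threshold (default 25 kb).
#' @return The items tibble with a `category` column.
#' @export
functional_categorize <- function(items, genes, max_dist_bp = 25000L) {
  if (nrow(items) == 0L) {
    items$category <- character(0)
    return(items)
  }
  gi <- iv_to_gr(items)
  gg <- iv_to_gr(genes)
  genic <- suppressWarnings(
    GenomicRanges::countOverlaps(gi, gg, minoverlap = 1L)) > 0L
  near <- suppressWarnings(
    GenomicRanges::countOverlaps(gi, gg, maxgap = as.integer(max_dist_bp))) > 0L
  items$category <- dplyr::case_when(
    genic ~ "genic",
    near ~ "proximal-regulatory",
    TRUE ~ "intergenic"
  )
  items
}
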