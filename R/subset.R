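#' Subset samples of a genotype or haplotype matrix
#'
#' @param x a [geno_matrix()] or [hap_matrix()].
#' @param samples character vector of sample names to keep (order respected).
#' @return The subsetted object.
#' @export
subset_samples <- function(x, samples) {
  if (inherits(x, "geno_matrix")) {
    rows <- match(samples, x$samples)
    if (anyNA(rows)) stop("unknown sample(s)", call. = FALSE)
    geno_matrix(x$dosages[rows, , drop = FALSE], x$sites, samples)
  } else if (inherits(x, "hap_matrix")) {
    idx <- match(samples, x$samples)
    if (anyNA(idx)) stop("unknown sample(s)", call. = FALSE)
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap_matrix(x$alleles[rows, , drop = FALSE], x$sites, samples)
  } else stop("unsupported class", call. = FALSE)
}

#' Subset sites of a genotype or haplotype matrix
#'
#' @param x a [geno_matrix()] or [hap_matrix()].
#' @param keep logical or integer index over sites.
#' @return The subsetted object.
#' @export
subset_sites <- function(x, keep) {
  if (inherits(x, "geno_matrix")) {
    geno_matrix(x$dosages[, keep, drop = FALSE], x$sites[keep, , drop = FALSE],
                x$samples)
  } else if (inherits(x, "hap_matrix")) {
    hap_matrix(x$alleles[, keep, drop = FALSE], x$sites[keep, , drop = FALSE],
               x$samples)
  } else stop("unsupported class", call. = FALSE)
}
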