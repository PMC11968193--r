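#' Single-read-sampling genetic covariance
#'
#' For every sample and site, one of the sample's two alleles is drawn
#' uniformly — a genotype-level proxy for sampling a single sequencing read,
#' which removes depth-dependent bias in covariance/PCA on low-coverage data.
#' The sampled allele is coded 0/1, centered by the site's sampled-allele
#' frequency and scaled by `sqrt(p * (1 - p))`; the covariance of a sample
#' pair is the mean of the product over sites where both are called. Sites
#' monomorphic in the sampled draw are excluded.
#'
#' @param geno a [geno_matrix()] with at least two samples.
#' @param seed integer seed; the draw is deterministic under it.
#' @return Object of class `srs_cov`: `cov` (samples x samples symmetric
#'   matrix), `n_pairs` (sites used per pair), `call_rate` (per sample),
#'   `n_sites_used`.
#' @export
srs_covariance <- function(geno, seed) {
  stopifnot(inherits(geno, "geno_matrix"), nrow(geno$dosages) >= 2L)
  d <- geno$dosages
  a <- with_seed(seed, {
    het <- !is.na(d) & d == 1L
    out <- matrix(NA_integer_, nrow(d), ncol(d))
    out[!is.na(d) & d == 0L] <- 0L
    out[!is.na(d) & d == 2L] <- 1L
    out[het] <- stats::rbinom(sum(het), 1L, 0.5)
    out
  })
  called <- !is.na(a)
  n_called <- colSums(called)
  p <- ifelse(n_called > 0, colSums(a, na.rm = TRUE) / n_called, NA_real_)
  keep <- !is.na(p) & p > 0 & p < 1
  a <- a[, keep, drop = FALSE]
  called <- called[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(a, 2L, p, `-`) / rep(sqrt(p * (1 - p)), each = nrow(a))
  x[!called] <- 0
  cc <- tcrossprod(x)
  np <- tcrossprod(called * 1L)
  cov <- cc / pmax(np, 1L)
  cov[np == 0L] <- NA_real_
  dimnames(cov) <- list(geno$samples, geno$samples)
  structure(list(cov = cov, n_pairs = np,
                 call_rate = rowMeans(!is.na(d)),
                 n_sites_used = sum(keep),
                 samples = geno$samples),
            class = "srs_cov")
}

#' @export
print.srs_cov <- function(x, ...) {
  cat(sprintf("<srs_cov> %d samples, %d sites used\n",
              length(x$samples), x$n_sites_used))
  invisible(x)
}

#' Drop related samples by covariance threshold
#'
#' Builds a graph with an edge for every sample pair whose covariance is at
#' least `threshold`; within each connected component (a related pair or
#' cluster) the single sample with the highest call rate is kept — ties break
#' to the lexicographically first name — and the rest are dropped.
#'
#' @param cov an `srs_cov` or a plain symmetric covariance matrix with sample
#'   dimnames.
#' @param threshold covariance at or above which a pair counts as related
#'   (default 0.3).
#' @param call_rate optional named per-sample call rate (taken from the
#'   `srs_cov` when available; defaults to 1 otherwise).
#' @return List: `retained` (character vector, input order), `dropped`
#'   (character vector), `pairs` (tibble `sample_a`, `sample_b`,
#'   `covariance` of the flagged pairs).
#' @export
relatedness_filter <- function(cov, threshold = 0.3, call_rate = NULL) {
  m <- if (inherits(cov, "srs_cov")) cov$cov else as.matrix(cov)
  samples <- rownames(m)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(m)))
  if (is.null(call_rate)) {
    call_rate <- if (inherits(cov, "srs_cov")) cov$call_rate
                 else stats::setNames(rep(1, length(samples)), samples)
  }
  ut <- upper.tri(m)
  hit <- which(ut & !is.na(m) & m >= threshold, arr.ind = TRUE)
  pairs <- tibble::tibble(
    sample_a = samples[hit[, 1]],
    sample_b = samples[hit[, 2]],
    covariance = m[hit]
  )
  if (nrow(pairs) == 0L)
    return(list(retained = samples, dropped = character(), pairs = pairs))
  g <- igraph::graph_from_data_frame(pairs[, 1:2], directed = FALSE)
  comp <- igraph::components(g)$membership
  dropped <- unlist(lapply(split(names(comp), comp), function(members) {
    members <- sort(members)  # lexicographic tie-break
    keep <- members[order(-call_rate[members], members)][1]
    setdiff(members, keep)
  }), use.names = FALSE)
  list(retained = setdiff(samples, dropped), dropped = dropped, pairs = pairs)
}

#' Principal component analysis of genetic covariance
#'
#' Eigendecomposition of the (single-read-sampling or genotype) covariance
#' matrix. Scores are eigenvectors ordered by descending eigenvalue, with the
#' sign convention that the largest-magnitude loading of each component is
#' positive.
#'
#' @param x an `srs_cov`, a [geno_matrix()] (standardized dosage covariance,
#'   missing calls mean-imputed per site), or a plain symmetric matrix.
#' @param k number of components to return (must not exceed the matrix rank).
#' @return Object of class `migscan_pca`: `scores` tibble (`sample`,
#'   `PC1..PCk`), `eigenvalues` (all, descending), `k`.
#' @export
pca_structure <- function(x, k = 2L) {
  k <- as.integer(k)
  m <- if (inherits(x, "srs_cov")) x$cov
       else if (inherits(x, "geno_matrix")) {
         z <- standardize_dosages(x)
         tcrossprod(z) / ncol(z)
       } else as.matrix(x)
  samples <- rownames(m)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(m)))
  m[is.na(m)] <- 0
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (k > rank) stop("k = ", k, " exceeds matrix rank (", rank, ")", call. = FALSE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PC", seq_len(k))
  scores <- tibble::as_tibble(vec)
  scores <- dplyr::bind_cols(tibble::tibble(sample = samples), scores)
  structure(list(scores = scores, eigenvalues = e$values, k = k),
            class = "migscan_pca")
}

# mean-impute missing dosages per site, center, scale by sqrt(2 p (1-p))
standardize_dosages <- function(geno, drop_monomorphic = TRUE) {
  d <- geno$dosages
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  z <- sweep(d, 2L, 2 * p, `-`)
  z[is.na(z)] <- 0
  denom <- sqrt(2 * p * (1 - p))
  poly <- denom > 0
  z <- sweep(z, 2L, ifelse(poly, denom, 1), `/`)
  if (drop_monomorphic) z <- z[, poly, drop = FALSE]
  attr(z, "polymorphic") <- poly
  z
}

#' @export
print.migscan_pca <- function(x, ...) {
  ve <- x$eigenvalues[seq_len(x$k)] / sum(pmax(x$eigenvalues, 0))
  cat(sprintf("<migscan_pca> %d samples, %d components (%s%% variance)\n",
              nrow(x$scores), x$k,
              paste(sprintf("%.1f", 100 * ve), collapse = "/")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname pca_structure
#' @param x a `migscan_pca`.
#' @param ... unused.
#' @method tidy migscan_pca
#' @export
tidy.migscan_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample", names_to = "component",
                      values_to = "score")
}

#' @rdname pca_structure
#' @method glance migscan_pca
#' @export
glance.migscan_pca <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(
    n_samples = nrow(x$scores),
    k = x$k,
    total_variance = sum(ev),
    prop_variance_k = sum(ev[seq_len(x$k)]) / sum(pmax(ev, 0)),
    leading_eigenvalue_ratio = ev[1] / mean(ev[ev > 0])
  )
}

#' Windowed nucleotide diversity
#'
#' Per site, `pi = 2 * c_ref * c_alt / (n * (n - 1))` with called-allele
#' counts; a window's diversity is the sum of its sites' values divided by
#' the window length in bp, so positions absent from the VCF count as
#' invariant. Windows tile each chromosome from 0 in non-overlapping
#' `window_bp` steps; the final partial window uses its true length.
#'
#' @param geno a [geno_matrix()] of variant (optionally plus invariant) sites,
#'   with no MAF filter applied.
#' @param popmap tibble `sample`, `population`.
#' @param populations character vector of population labels pooled into the
#'   analysed set.
#' @param window_bp window length (default 10 kb).
#' @param chrom_length named vector of chromosome lengths; defaults to the
#'   last site position per chromosome.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `n_sites`,
#'   `pi` (per bp), with the length-weighted mean diversity in attribute
#'   `"mean_pi"`.
#' @export
windowed_pi <- function(geno, popmap, populations, window_bp = 10000L,
                        chrom_length = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  samp <- popmap$sample[popmap$population %in% populations]
  if (length(samp) == 0L) stop("empty population set", call. = FALSE)
  rows <- match(samp, geno$samples)
  if (anyNA(rows)) stop("popmap sample absent from genotypes", call. = FALSE)
  d <- geno$dosages[rows, , drop = FALSE]
  alt <- colSums(d, na.rm = TRUE)
  n <- 2 * colSums(!is.na(d))
  ref <- n - alt
  pi_site <- ifelse(n >= 2, 2 * ref * alt / (n * (n - 1)), 0)

  out <- purrr::map_dfr(unique(geno$sites$chrom), function(ch) {
    sel <- geno$sites$chrom == ch
    pos <- geno$sites$pos[sel]
    ps <- pi_site[sel]
    len <- if (!is.null(chrom_length) && ch %in% names(chrom_length))
      as.integer(chrom_length[[ch]]) else max(pos)
    starts <- seq.int(0L, len - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    win <- findInterval(pos - 1L, starts)  # pos is 1-based; windows 0-based
    sums <- tapply(ps, factor(win, levels = seq_along(starts)), sum)
    cnts <- tapply(ps, factor(win, levels = seq_along(starts)), length)
    sums[is.na(sums)] <- 0
    cnts[is.na(cnts)] <- 0L
    tibble::tibble(chrom = ch, start = starts, end = ends,
                   n_sites = as.integer(cnts),
                   pi = as.numeric(sums) / (ends - starts))
  })
  attr(out, "mean_pi") <-
    sum(out$pi * (out$end - out$start)) / sum(out$end - out$start)
  out
}
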