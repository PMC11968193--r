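#' Hudson-style site F_ST components
#'
#' Numerator and denominator of the Hudson estimator in the
#' ratio-of-averages form, robust to unequal sample sizes:
#' `num = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`,
#' `den = p1 (1 - p2) + p2 (1 - p1)`, with `n` counted in called alleles.
#' Negative site values are retained (they average out in windows); a site
#' is undefined when the denominator is 0 (both populations fixed for the
#' same allele) or when either population has fewer than 2 called alleles.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 called-allele counts.
#' @return Tibble `num`, `den`, `fst` (NA when undefined).
#' @export
fst_site <- function(p1, n1, p2, n2) {
  ok <- n1 >= 2 & n2 >= 2 & !is.na(p1) & !is.na(p2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  tibble::tibble(num = num, den = den,
                 fst = ifelse(!is.na(den) & den > 0, num / den, NA_real_))
}

#' Site-wise F_ST scan between two population groups
#'
#' @param geno a [geno_matrix()].
#' @param popmap tibble `sample`, `population`.
#' @param group_a,group_b character vectors of population labels; pooled
#'   before counting. By convention group A is the resident side, so that
#'   positive downstream statistics point at selection in residents.
#' @param label comparison label carried through to outlier calling.
#' @return Tibble `chrom`, `pos`, `comparison`, `num`, `den`, `fst`.
#' @export
fst_scan <- function(geno, popmap, group_a, group_b, label = "A_vs_B") {
  af <- allele_frequencies(geno, popmap, list(A = group_a, B = group_b))
  wide <- tidyr::pivot_wider(af, id_cols = c("chrom", "pos"),
                             names_from = "group",
                             values_from = c("freq", "called"))
  fs <- fst_site(wide$freq_A, wide$called_A, wide$freq_B, wide$called_B)
  dplyr::bind_cols(
    tibble::tibble(chrom = wide$chrom, pos = wide$pos, comparison = label),
    fs
  )
}

#' Sliding-window F_ST (ratio of sums)
#'
#' Windows of `window_bp` advance by `step_bp` from position 0 on each
#' chromosome, up to the last window containing a site. A window's F_ST is
#' the ratio of summed site numerators to summed site denominators over its
#' defined sites; windows with no defined site are omitted. With one site in
#' a window the window value equals the site value.
#'
#' @param fst_sites tibble from [fst_scan()] (needs `chrom`, `pos`, `num`,
#'   `den`; `comparison` carried through if present).
#' @param window_bp window span (default 50 kb).
#' @param step_bp step between window starts (default 25 kb); must not
#'   exceed `window_bp`.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `n_sites`,
#'   `fst`.
#' @export
fst_windows <- function(fst_sites, window_bp = 50000L, step_bp = 25000L) {
  if (step_bp > window_bp) stop("step_bp must not exceed window_bp", call. = FALSE)
  x <- fst_sites[!is.na(fst_sites$den), , drop = FALSE]
  lab <- if ("comparison" %in% names(fst_sites) && nrow(fst_sites) > 0)
    fst_sites$comparison[1] else NULL
  k_max <- as.integer(ceiling(window_bp / step_bp))  # windows per site
  out <- purrr::map_dfr(unique(x$chrom), function(ch) {
    s <- x[x$chrom == ch, ]
    if (nrow(s) == 0L) return(NULL)
    pos0 <- s$pos - 1L  # 0-based
    # site in window w (start = w * step) iff w*step <= pos0 < w*step + window
    w_hi <- pos0 %/% step_bp
    acc <- list()
    for (j in seq_len(k_max) - 1L) {
      w <- w_hi - j
      ok <- w >= 0L & pos0 < w * step_bp + window_bp
      acc[[j + 1L]] <- data.frame(w = w[ok], num = s$num[ok], den = s$den[ok])
    }
    a <- do.call(rbind, acc)
    agg <- rowsum(cbind(a$num, a$den, 1), a$w)
    w <- as.integer(rownames(agg))
    ord <- order(w)
    tibble::tibble(chrom = ch,
                   start = w[ord] * step_bp,
                   end = w[ord] * step_bp + as.integer(window_bp),
                   n_sites = as.integer(unname(agg[ord, 3])),
                   fst = unname(agg[ord, 1] / agg[ord, 2]))
  })
  if (!is.null(lab) && nrow(out) > 0)
    out <- dplyr::mutate(out, comparison = lab, .before = 1)
  out
}

#' Flag values above an empirical percentile
#'
#' Flags values strictly greater than the linear-interpolation empirical
#' `q`-quantile; ties at the threshold are not flagged. With all values
#' equal nothing exceeds the quantile and nothing is flagged.
#'
#' @param values numeric vector.
#' @param q quantile (default 0.99, the scan's outlier percentile).
#' @return Logical vector with the threshold in attribute `"threshold"`.
#'   With fewer than `1 / (1 - q)` values a warning is raised and nothing is
#'   flagged.
#' @export
percentile_outliers <- function(values, q = 0.99) {
  values <- as.numeric(values)
  ok <- !is.na(values)
  if (sum(ok) < 1 / (1 - q)) {
    warning("fewer values than the percentile can resolve; nothing flagged")
    out <- rep(FALSE, length(values))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- stats::quantile(values[ok], q, names = FALSE, type = 7)
  out <- ok & values > thr
  attr(out, "threshold") <- thr
  out
}

#' PCA-based per-SNP selection statistic
#'
#' Dosages are standardized per site (missing calls mean-imputed, centered,
#' scaled by `sqrt(2 p (1 - p))`). For the k-th principal component with
#' unit sample-eigenvector `v` and eigenvalue `lambda`, the per-site
#' statistic measures the squared correlation between the standardized
#' dosage and the component, normalized by the eigenvalue so that the
#' genome-wide mean stays at its null value (the eigenvalue absorbs the
#' optimism of estimating `v` from the same data). Its exact null law at
#' `n` samples is Beta(1/2, (n-2)/2); the statistic is mapped to the
#' equivalent chi-squared(1 df) deviate, so `p` is the conventional
#' chi-squared conversion and is calibrated at finite sample size (the two
#' coincide as n grows). Monomorphic sites are excluded.
#'
#' @param geno a [geno_matrix()], typically restricted to one clade's
#'   samples.
#' @param samples optional character vector restricting the scan.
#' @param k which principal component carries the resident-migrant axis
#'   (default 1).
#' @param alpha significance level for the `selected` flag (default 0.05).
#' @return Tibble `chrom`, `pos`, `stat`, `p`, `selected`.
#' @export
pca_selection_scan <- function(geno, samples = NULL, k = 1L, alpha = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (!is.null(samples)) {
    rows <- match(samples, geno$samples)
    if (anyNA(rows)) stop("unknown sample(s)", call. = FALSE)
    geno <- geno_matrix(geno$dosages[rows, , drop = FALSE], geno$sites, samples)
  }
  n <- length(geno$samples)
  if (k < 1L || k >= n) stop("k out of range", call. = FALSE)
  z <- standardize_dosages(geno)
  poly <- attr(z, "polymorphic")
  L <- ncol(z)
  S <- tcrossprod(z) / L
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, k]
  lambda <- e$values[k]
  loading <- as.numeric(crossprod(z, v))  # z_j' v per site
  r2 <- pmin((loading / sqrt(colSums(z^2)))^2 / lambda, 1)
  p <- stats::pbeta(r2, 1 / 2, (n - 2) / 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  stat <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  tibble::tibble(
    chrom = geno$sites$chrom[poly],
    pos = geno$sites$pos[poly],
    stat = stat, p = p, selected = p < alpha
  )
}

#' Extended haplotype homozygosity decay curve
#'
#' EHH at extension site `j` is the probability that two haplotypes drawn
#' from the carriers are identical over the inclusive span from the core to
#' `j`: `sum_g C(m_g, 2) / C(m, 2)` over groups of identical haplotypes.
#' EHH at the core is 1 (all carriers share the core allele) and the curve
#' is non-increasing outward since extending the span only refines the
#' partition.
#'
#' @param haps a [hap_matrix()] restricted to the carriers of one core
#'   allele (at least 2 haplotypes), or a plain 0/1 matrix.
#' @param core column index of the core site.
#' @param direction `"both"`, `"left"` or `"right"`.
#' @return Tibble `site` (column index), `pos`, `distance_bp` (signed),
#'   `ehh`.
#' @export
ehh <- function(haps, core, direction = c("both", "left", "right")) {
  direction <- match.arg(direction)
  a <- if (inherits(haps, "hap_matrix")) haps$alleles else as.matrix(haps)
  pos <- if (inherits(haps, "hap_matrix")) haps$sites$pos else seq_len(ncol(a))
  H <- nrow(a)
  if (H < 2L) stop("EHH undefined for fewer than 2 carrier haplotypes",
                   call. = FALSE)
  denom <- H * (H - 1) / 2
  one_side <- function(step) {
    grp <- rep(1L, H)
    js <- integer(0); es <- numeric(0)
    j <- core
    while (j >= 1L && j <= ncol(a)) {
      grp <- as.integer(interaction(grp, a[, j], drop = TRUE))
      cnt <- tabulate(grp)
      js <- c(js, j)
      es <- c(es, sum(cnt * (cnt - 1) / 2) / denom)
      j <- j + step
    }
    tibble::tibble(site = js, pos = pos[js],
                   distance_bp = pos[js] - pos[core], ehh = es)
  }
  out <- switch(direction,
    left = one_side(-1L),
    right = one_side(1L),
    both = dplyr::bind_rows(one_side(-1L)[-1, ], one_side(1L)) |>
      dplyr::arrange(.data$site)
  )
  out
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' For every core site, each population's iHH is the trapezoidal integral of
#' its pooled-haplotype EHH decay curve over physical distance, extended in
#' both directions and truncated where EHH drops below `cutoff`. The
#' unstandardized score is `ln(iHH_A / iHH_B)`; scores are standardized
#' genome-wide to mean 0 and unit standard deviation, and significance is
#' rank-based on |score| ([rank_pvalues()]). Large positive scores indicate
#' a sweep approaching fixation in population A (by convention the resident
#' side), negative scores in population B.
#'
#' @param haps_a,haps_b [hap_matrix()] objects over identical sites (phased).
#' @param cutoff EHH truncation level (default 0.05).
#' @param labels length-2 character: names reported in `selected_population`.
#' @param log_p significance threshold on `-log10(p)` (default 2).
#' @return Tibble `chrom`, `pos`, `ihh_a`, `ihh_b`, `raw`, `std`, `p`,
#'   `selected_population`, `significant`. Sites with a zero iHH on either
#'   side are dropped (a message reports the count).
#' @export
xpehh <- function(haps_a, haps_b, cutoff = 0.05, labels = c("A", "B"),
                  log_p = 2) {
  stopifnot(inherits(haps_a, "hap_matrix"), inherits(haps_b, "hap_matrix"))
  if (!identical(haps_a$sites[, c("chrom", "pos")],
                 haps_b$sites[, c("chrom", "pos")]))
    stop("haplotype matrices must cover identical sites", call. = FALSE)
  sites <- haps_a$sites
  res <- purrr::map_dfr(unique(sites$chrom), function(ch) {
    sel <- sites$chrom == ch
    pos <- as.numeric(sites$pos[sel])
    ia <- .ihh_all_cores(haps_a$alleles[, sel, drop = FALSE], pos, cutoff)
    ib <- .ihh_all_cores(haps_b$alleles[, sel, drop = FALSE], pos, cutoff)
    tibble::tibble(chrom = ch, pos = sites$pos[sel], ihh_a = ia, ihh_b = ib)
  })
  bad <- res$ihh_a <= 0 | res$ihh_b <= 0
  if (any(bad))
    message(sprintf("xpehh: skipped %d site(s) with undefined iHH", sum(bad)))
  res <- res[!bad, , drop = FALSE]
  res$raw <- log(res$ihh_a / res$ihh_b)
  mu <- mean(res$raw)
  sdv <- stats::sd(res$raw)
  res$std <- if (isTRUE(sdv > 0)) (res$raw - mu) / sdv else res$raw * 0
  res$p <- rank_pvalues(res$std)
  res$selected_population <- ifelse(res$std > 0, labels[1], labels[2])
  res$significant <- -log10(res$p) > log_p
  res
}

#' Rank-based p-values for selection scores
#'
#' `p_i = rank_i / L` with rank 1 assigned to the largest |score|; ties
#' share the mean rank. The conventional significance call is
#' `-log10(p) > 2` (strict), so with `L` distinct scores exactly
#' `ceiling(L / 100) - 1` sites are significant.
#'
#' @param scores numeric vector (signed; ranking uses the absolute value).
#' @return Numeric vector of p-values in (0, 1].
#' @export
rank_pvalues <- function(scores) {
  L <- length(scores)
  rank(-abs(scores), ties.method = "average") / L
}
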