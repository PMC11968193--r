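# Independent brute-force oracles. These deliberately avoid the package's
# optimized code paths: EHH by pairwise identity counting, interval algebra
# by per-base bitmaps and all-pairs scans.

# EHH over the inclusive column span [lo, hi]: fraction of haplotype pairs
# identical over the span
oracle_ehh_span <- function(a, lo, hi) {
  H <- nrow(a)
  same <- 0L
  for (i in seq_len(H - 1L)) {
    for (j in seq.int(i + 1L, H)) {
      if (all(a[i, lo:hi] == a[j, lo:hi])) same <- same + 1L
    }
  }
  same / (H * (H - 1L) / 2L)
}

# iHH at one core: trapezoidal integral of the EHH decay curve outward in
# both directions over physical distance, truncated at the first point
# below `cutoff` (that segment not added)
oracle_ihh <- function(a, pos, core, cutoff = 0.05) {
  total <- 0
  for (step in c(-1L, 1L)) {
    ehh_prev <- oracle_ehh_span(a, min(core, core), max(core, core))
    if (ehh_prev < cutoff) next
    pos_prev <- pos[core]
    j <- core + step
    while (j >= 1L && j <= ncol(a)) {
      lo <- min(core, j); hi <- max(core, j)
      e <- oracle_ehh_span(a, lo, hi)
      if (e < cutoff) break
      total <- total + 0.5 * (ehh_prev + e) * abs(pos[j] - pos_prev)
      ehh_prev <- e
      pos_prev <- pos[j]
      j <- j + step
    }
  }
  total
}

oracle_xpehh_raw <- function(a1, a2, pos, cutoff = 0.05) {
  vapply(seq_along(pos), function(core) {
    i1 <- oracle_ihh(a1, pos, core, cutoff)
    i2 <- oracle_ihh(a2, pos, core, cutoff)
    if (i1 > 0 && i2 > 0) log(i1 / i2) else NA_real_
  }, numeric(1))
}

# interval union on one chromosome via a bitmap at half-unit resolution,
# so book-ended half-open intervals ([0,10) + [10,20)) stay separate
oracle_merge <- function(iv, max_bp = 3000L) {
  hit <- rep(FALSE, 2L * max_bp)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i])
      hit[(2L * iv$start[i] + 2L):(2L * iv$end[i])] <- TRUE
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(chrom = iv$chrom[1],
                 start = as.integer(starts[r$values] %/% 2L),
                 end = as.integer((ends[r$values] + 1L) %/% 2L))
}

# gap in bases between two half-open intervals (0 when overlapping/adjacent)
oracle_gap <- function(s1, e1, s2, e2) max(0L, s2 - e1, s1 - e2)

# random interval set on one chromosome
random_intervals <- function(n, max_bp = 2000L, max_len = 200L) {
  start <- sample.int(max_bp - max_len, n)
  tibble::tibble(chrom = "chr1", start = start,
                 end = start + sample.int(max_len, n, replace = TRUE))
}

# small helper: geno_matrix from a dosage matrix with default site metadata
toy_geno <- function(d, pos = NULL, chrom = "chr1") {
  d <- as.matrix(d)
  if (is.null(pos)) pos <- seq_len(ncol(d))
  geno_matrix(d, tibble::tibble(chrom = chrom, pos = as.integer(pos),
                                ref = "A", alt = "T"),
              sprintf("S%02d", seq_len(nrow(d))))
}

toy_haps <- function(a, pos = NULL, chrom = "chr1") {
  a <- as.matrix(a)
  if (is.null(pos)) pos <- seq_len(ncol(a))
  hap_matrix(a, tibble::tibble(chrom = chrom, pos = as.integer(pos),
                               ref = "A", alt = "T"),
             sprintf("S%02d", seq_len(nrow(a) / 2)))
}

# small default-shaped simulation for end-to-end tests
small_sim_config <- function(seed, ...) {
  default_sim_config(seed = seed, n_diploids = 8L, l_sites = 3000L,
                     chrom_length_bp = 3e6, n_genes = 12L, n_sweep_genes = 3L,
                     n_clade_sweeps = 1L, sweep_radius_bp = 30000L, ...)
}
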