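#' Configure a structured-population simulation
#'
#' Builds and validates the scenario description consumed by
#' [simulate_cohort()]. The generative model is hierarchical Balding-Nichols:
#' an ancestral allele frequency per site, a clade frequency drawn around it
#' with drift `f_clade`, and a population frequency drawn around the clade
#' value with drift `f_pop`, so that the expected Hudson F_ST between two
#' populations of one clade is `2 * f_pop / (expectation of the denominator)`
#' — numerically `f_pop` for the ratio-of-sums estimator. Haplotypes are
#' founder mosaics with a constant per-adjacent-site switch probability, which
#' yields distance-decaying linkage disequilibrium; hard sweeps are planted by
#' haplotype replacement at designated genes.
#'
#' @param populations tibble with columns `population`, `clade`,
#'   `phenotype` (`"resident"` or `"migrant"`), `n_diploids`.
#' @param ancestral_maf_range ancestral allele frequencies are drawn uniformly
#'   from this interval; both ends in (0, 0.5].
#' @param f_clade,f_pop Balding-Nichols drift parameters in [0, 1):
#'   clade-versus-root and population-versus-clade.
#' @param l_sites number of segregating sites to simulate.
#' @param chrom_length_bp chromosome length; site positions are sampled
#'   uniformly without replacement from `1:chrom_length_bp`.
#' @param recomb_switch_prob probability of switching founder between adjacent
#'   sites when building each mosaic haplotype.
#' @param n_genes number of non-overlapping gene intervals to annotate.
#' @param gene_length_bp length of each gene interval.
#' @param n_sweep_genes number of genes receiving a hard sweep in a resident
#'   unit (see `resident_units`).
#' @param n_clade_sweeps number of genes receiving an independent-donor sweep
#'   in *every* population of one clade; these emulate shared demographic
#'   divergence that the control comparisons are designed to flag.
#' @param sweep_carrier_fraction fraction of a population's haplotypes replaced
#'   by the donor haplotype; the default 0.9 leaves the selected haplotype
#'   above the 80% frequency regime hard sweeps are called at.
#' @param sweep_radius_bp half-width of the replaced segment around the core.
#' @param resident_units list of character vectors grouping resident
#'   populations that share one sweep donor (e.g. two pooled resident
#'   populations analysed as a single case unit). Default: each resident
#'   population is its own unit.
#' @param founders_per_pop founder haplotypes per population (default
#'   `8 * n_diploids`, large enough that founder-pool resampling adds only
#'   O(1/founders) to between-population differentiation).
#' @param missing_rate fraction of genotype calls masked to missing when the
#'   cohort is exported; 0 by default.
#' @param chrom contig name.
#' @param seed integer seed; identical configs with identical seeds give
#'   byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(populations,
                       ancestral_maf_range = c(0.05, 0.5),
                       f_clade = 0.15,
                       f_pop = 0.02,
                       l_sites = 20000L,
                       chrom_length_bp = 1e8,
                       recomb_switch_prob = 0.05,
                       n_genes = 30L,
                       gene_length_bp = 10000L,
                       n_sweep_genes = 9L,
                       n_clade_sweeps = 1L,
                       sweep_carrier_fraction = 0.9,
                       sweep_radius_bp = 50000L,
                       resident_units = NULL,
                       founders_per_pop = NULL,
                       missing_rate = 0,
                       chrom = "chr1",
                       seed) {
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("population", "clade", "phenotype", "n_diploids") %in%
                  names(populations)))
  if (anyDuplicated(populations$population))
    stop("population labels must be unique", call. = FALSE)
  if (!all(populations$phenotype %in% c("resident", "migrant")))
    stop("phenotype must be 'resident' or 'migrant'", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(
    length(ancestral_maf_range) == 2L,
    ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
    ancestral_maf_range[1] < ancestral_maf_range[2],
    f_clade >= 0, f_clade < 1, f_pop >= 0, f_pop < 1,
    recomb_switch_prob >= 0, recomb_switch_prob <= 1,
    sweep_carrier_fraction >= 0, sweep_carrier_fraction <= 1,
    missing_rate >= 0, missing_rate < 1,
    l_sites >= 2, chrom_length_bp >= l_sites,
    n_sweep_genes + n_clade_sweeps <= n_genes,
    (n_genes == 0) || (n_genes * gene_length_bp <= chrom_length_bp)
  )
  if (is.null(resident_units)) {
    res <- populations$population[populations$phenotype == "resident"]
    resident_units <- as.list(res)
  }
  if (!all(unlist(resident_units) %in% populations$population))
    stop("resident_units refers to unknown populations", call. = FALSE)
  structure(list(
    populations = populations,
    ancestral_maf_range = ancestral_maf_range,
    f_clade = f_clade, f_pop = f_pop,
    l_sites = as.integer(l_sites),
    chrom_length_bp = as.integer(chrom_length_bp),
    recomb_switch_prob = recomb_switch_prob,
    n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    n_sweep_genes = as.integer(n_sweep_genes),
    n_clade_sweeps = as.integer(n_clade_sweeps),
    sweep_carrier_fraction = sweep_carrier_fraction,
    sweep_radius_bp = as.integer(sweep_radius_bp),
    resident_units = resident_units,
    founders_per_pop = founders_per_pop,
    missing_rate = missing_rate,
    chrom = chrom,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Study-shaped default scenario
#'
#' Two deeply diverged clades; in each clade two resident and two migrant
#' populations. The western residents are analysed as separate case units and
#' the eastern residents as one pooled unit, mirroring a replicated
#' resident-migrant design with three case comparisons and within-clade
#' migrant-migrant and resident-resident controls.
#'
#' @param seed integer seed.
#' @param n_diploids diploids per population.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed, n_diploids = 12L, ...) {
  pops <- tibble::tribble(
    ~population, ~clade, ~phenotype,
    "res_az", "west", "resident",
    "res_ca", "west", "resident",
    "mig_w1", "west", "migrant",
    "mig_w2", "west", "migrant",
    "res_fl", "east", "resident",
    "res_al", "east", "resident",
    "mig_e1", "east", "migrant",
    "mig_e2", "east", "migrant"
  )
  pops$n_diploids <- as.integer(n_diploids)
  sim_config(
    populations = pops,
    resident_units = list("res_az", "res_ca", c("res_fl", "res_al")),
    seed = seed,
    ...
  )
}

# Balding-Nichols draw around mean p with drift F; F = 0 is the identity.
# Draws are clipped away from 0/1 so sites stay polymorphic at the
# expected-frequency level (fixation may still occur by sampling).
rbn <- function(p, f, eps = 1e-6) {
  if (f == 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  pmin(pmax(stats::rbeta(length(p), a, b), eps), 1 - eps)
}

#' Simulate hierarchical population allele frequencies
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_freqs`: `sites` (tibble `chrom`, `pos`,
#'   `p_anc`), `pop_freq` (matrix sites x populations of expected
#'   frequencies), `genes` (tibble of annotated gene intervals, 0-based
#'   half-open, with empty `swept_pops`), and the config. Frequencies and
#'   gene intervals together form the truth table against which downstream
#'   statistics are validated.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed + 1L, {
    L <- cfg$l_sites
    pos <- sort(sample.int(cfg$chrom_length_bp, L))
    p_anc <- stats::runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
    clades <- unique(cfg$populations$clade)
    clade_freq <- vapply(clades, function(cl) rbn(p_anc, cfg$f_clade),
                         numeric(L))
    pop_freq <- vapply(seq_len(nrow(cfg$populations)), function(i) {
      cl <- cfg$populations$clade[i]
      rbn(clade_freq[, cl], cfg$f_pop)
    }, numeric(L))
    colnames(pop_freq) <- cfg$populations$population
    genes <- place_genes(cfg)
    structure(list(
      sites = tibble::tibble(chrom = cfg$chrom, pos = as.integer(pos),
                             p_anc = p_anc),
      clade_freq = clade_freq,
      pop_freq = pop_freq,
      genes = genes,
      config = cfg
    ), class = "sim_freqs")
  })
}

# one gene per equal-width slot at a random offset -> non-overlapping,
# approximately uniform placement
place_genes <- function(cfg) {
  if (cfg$n_genes == 0L)
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          swept_pops = list()))
  slot <- cfg$chrom_length_bp %/% cfg$n_genes
  off <- sample.int(slot - cfg$gene_length_bp + 1L, cfg$n_genes,
                    replace = TRUE) - 1L
  start <- (seq_len(cfg$n_genes) - 1L) * slot + off
  tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
    chrom = cfg$chrom,
    start = as.integer(start),
    end = as.integer(start + cfg$gene_length_bp),
    swept_pops = rep(list(character()), cfg$n_genes)
  )
}

#' Simulate phased haplotypes as founder mosaics
#'
#' Per population, `founders_per_pop` founder haplotypes are drawn site-wise
#' Bernoulli at the population's expected frequency; each sampled haplotype
#' copies from a founder and switches to a uniformly chosen founder with
#' probability `recomb_switch_prob` between adjacent sites, so linkage decays
#' with inter-site distance.
#'
#' @param freqs a `sim_freqs` from [simulate_frequencies()].
#' @param config the same [sim_config()] (defaults to the one stored in `freqs`).
#' @return A [hap_matrix()] with `2 * n_diploids` haplotypes per population;
#'   sample identifiers are `<population>_<index>`.
#' @export
simulate_haplotypes <- function(freqs, config = freqs$config) {
  stopifnot(inherits(freqs, "sim_freqs"))
  cfg <- config
  with_seed(cfg$seed + 2L, {
    L <- cfg$l_sites
    pops <- cfg$populations
    blocks <- lapply(seq_len(nrow(pops)), function(i) {
      p <- freqs$pop_freq[, pops$population[i]]
      nf <- if (is.null(cfg$founders_per_pop)) 8L * pops$n_diploids[i]
            else as.integer(cfg$founders_per_pop)
      founders <- matrix(stats::rbinom(nf * L, 1L, rep(p, each = nf)),
                         nrow = nf, ncol = L)
      nh <- 2L * pops$n_diploids[i]
      out <- matrix(0L, nrow = nh, ncol = L)
      for (h in seq_len(nh)) {
        if (cfg$recomb_switch_prob >= 1) {
          fid <- sample.int(nf, L, replace = TRUE)
        } else if (cfg$recomb_switch_prob <= 0) {
          fid <- rep(sample.int(nf, 1L), L)
        } else {
          sw <- stats::rbinom(L - 1L, 1L, cfg$recomb_switch_prob)
          seg <- cumsum(c(1L, sw))
          fid <- sample.int(nf, max(seg), replace = TRUE)[seg]
        }
        out[h, ] <- founders[cbind(fid, seq_len(L))]
      }
      out
    })
    samples <- unlist(lapply(seq_len(nrow(pops)), function(i)
      sprintf("%s_%02d", pops$population[i], seq_len(pops$n_diploids[i]))))
    sites <- freqs$sites[, c("chrom", "pos")]
    sites$ref <- "A"
    sites$alt <- "T"
    hap_matrix(do.call(rbind, blocks), sites, samples)
  })
}

#' Plant an instantaneous hard sweep
#'
#' Replaces a fraction of one population's haplotypes, at every site within
#' `radius_bp` of the core position, with copies of a single donor haplotype.
#' The result is the post-sweep signature the haplotype statistics are
#' designed to detect: one long haplotype at high frequency, confined to the
#' target population and the sweep radius.
#'
#' @param haps a [hap_matrix()].
#' @param population population label whose haplotypes are swept; the
#'   population is identified by the `<population>_` sample-name prefix.
#' @param popmap optional tibble (`sample`, `population`) used instead of the
#'   prefix convention.
#' @param core_bp 1-based core position (bp).
#' @param radius_bp sites with `|pos - core_bp| <= radius_bp` are replaced.
#' @param carrier_fraction fraction of the population's haplotypes replaced.
#' @param seed integer seed controlling donor and carrier choice.
#' @param donor optional 0/1 allele vector of length `n_sites` supplying the
#'   swept haplotype; by default one of the population's own haplotypes is
#'   chosen at random. A shared donor is how a parallel sweep from shared
#'   standing variation is planted across several populations.
#' @return The modified [hap_matrix()].
#' @export
plant_sweep <- function(haps, population, core_bp, radius_bp,
                        carrier_fraction, seed, donor = NULL, popmap = NULL) {
  stopifnot(inherits(haps, "hap_matrix"))
  if (carrier_fraction < 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in [0, 1]", call. = FALSE)
  pop_of <- if (is.null(popmap)) sub("_[0-9]+$", "", haps$hap_sample)
            else popmap$population[match(haps$hap_sample, popmap$sample)]
  rows <- which(pop_of == population)
  if (length(rows) == 0L) stop("unknown population: ", population, call. = FALSE)
  if (core_bp < 1 || core_bp > max(haps$sites$pos))
    stop("core position outside chromosome", call. = FALSE)
  cols <- which(abs(haps$sites$pos - core_bp) <= radius_bp)
  if (length(cols) == 0L) return(haps)
  with_seed(seed, {
    if (is.null(donor)) {
      donor_row <- rows[sample.int(length(rows), 1L)]
      donor_alleles <- haps$alleles[donor_row, cols]
    } else {
      stopifnot(length(donor) == ncol(haps$alleles))
      donor_alleles <- as.integer(donor[cols])
    }
    n_carriers <- round(carrier_fraction * length(rows))
    carriers <- rows[sample.int(length(rows), n_carriers)]
    haps$alleles[carriers, cols] <-
      matrix(donor_alleles, nrow = n_carriers, ncol = length(cols), byrow = TRUE)
  })
  haps
}

#' Simulate a complete cohort with planted sweeps and known truth
#'
#' Runs [simulate_frequencies()] and [simulate_haplotypes()], then plants
#' sweeps: `n_sweep_genes` genes receive a resident-unit sweep (one shared
#' donor haplotype across the unit's populations, cycling over
#' `resident_units`), and `n_clade_sweeps` genes receive an independent-donor
#' sweep in every population of one clade — background divergence the control
#' comparisons are designed to exclude. Sweep cores sit at gene midpoints.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort`: `haps` ([hap_matrix()]), `geno`
#'   (dosage view, with `missing_rate` applied), `genes` (annotation with
#'   `swept_pops` list-column and `sweep_kind` in
#'   `{"none","resident","clade"}`), `popmap` (tibble `sample`, `population`,
#'   `phenotype`, `clade`), `freqs`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  freqs <- simulate_frequencies(cfg)
  haps <- simulate_haplotypes(freqs, cfg)
  genes <- freqs$genes
  genes$sweep_kind <- "none"

  n_sw <- cfg$n_sweep_genes + cfg$n_clade_sweeps
  if (n_sw > 0L) {
    sel <- with_seed(cfg$seed + 3L, sample.int(cfg$n_genes, n_sw))
    res_idx <- sel[seq_len(cfg$n_sweep_genes)]
    clade_idx <- if (cfg$n_clade_sweeps > 0L)
      sel[cfg$n_sweep_genes + seq_len(cfg$n_clade_sweeps)] else integer()

    units <- cfg$resident_units
    clades <- unique(cfg$populations$clade)
    for (k in seq_along(res_idx)) {
      g <- res_idx[k]
      unit <- units[[(k - 1L) %% length(units) + 1L]]
      core <- as.integer((genes$start[g] + genes$end[g]) / 2) + 1L
      # shared donor drawn from the unit's first population
      donor_seed <- cfg$seed + 100L + g
      pop_of <- sub("_[0-9]+$", "", haps$hap_sample)
      rows1 <- which(pop_of == unit[1])
      donor <- with_seed(donor_seed,
                         haps$alleles[rows1[sample.int(length(rows1), 1L)], ])
      for (pp in unit) {
        haps <- plant_sweep(haps, pp, core_bp = core,
                            radius_bp = cfg$sweep_radius_bp,
                            carrier_fraction = cfg$sweep_carrier_fraction,
                            seed = donor_seed + match(pp, cfg$populations$population),
                            donor = donor)
      }
      genes$swept_pops[[g]] <- unit
      genes$sweep_kind[g] <- "resident"
    }
    for (k in seq_along(clade_idx)) {
      g <- clade_idx[k]
      cl <- clades[(k - 1L) %% length(clades) + 1L]
      core <- as.integer((genes$start[g] + genes$end[g]) / 2) + 1L
      pops_cl <- cfg$populations$population[cfg$populations$clade == cl]
      for (pp in pops_cl) {
        haps <- plant_sweep(haps, pp, core_bp = core,
                            radius_bp = cfg$sweep_radius_bp,
                            carrier_fraction = cfg$sweep_carrier_fraction,
                            seed = cfg$seed + 500L + g * 13L +
                              match(pp, cfg$populations$population))
      }
      genes$swept_pops[[g]] <- pops_cl
      genes$sweep_kind[g] <- "clade"
    }
  }
  genes$migration_linked <- genes$sweep_kind == "resident"

  geno <- as_genotypes(haps)
  if (cfg$missing_rate > 0) {
    geno$dosages <- with_seed(cfg$seed + 4L, {
      mask <- matrix(stats::runif(length(geno$dosages)) < cfg$missing_rate,
                     nrow = nrow(geno$dosages))
      d <- geno$dosages
      d[mask] <- NA_integer_
      d
    })
  }
  popmap <- tibble::tibble(
    sample = haps$samples,
    population = sub("_[0-9]+$", "", haps$samples)
  )
  popmap <- dplyr::left_join(popmap, cfg$populations[, c("population", "phenotype", "clade")],
                             by = "population")
  structure(list(haps = haps, geno = geno, genes = genes, popmap = popmap,
                 freqs = freqs, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort to standard formats
#'
#' Emits a plain-text VCF v4.2 with phased genotypes, a BED4 gene annotation
#' (0-based half-open), a population-map TSV and a per-gene truth TSV.
#' Reading the VCF back with [read_vcf()] reproduces the haplotype matrix
#' exactly.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the paths written
#'   (`vcf`, `bed`, `popmap`, `truth`).
#' @export
write_sim_outputs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    bed = file.path(dir, "genes.bed"),
    popmap = file.path(dir, "popmap.tsv"),
    truth = file.path(dir, "truth_genes.tsv")
  )
  write_vcf(cohort$haps, paths$vcf,
            contig_length = cohort$config$chrom_length_bp,
            missing = is.na(cohort$geno$dosages))
  write_bed(cohort$genes, paths$bed)
  utils::write.table(cohort$popmap, paths$popmap, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$genes
  truth$swept_pops <- vapply(truth$swept_pops, paste, "", collapse = ",")
  utils::write.table(truth, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
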