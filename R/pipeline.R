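#' Assemble a pipeline configuration
#'
#' One declarative object drives the full analysis: either paths to input
#' files (VCF, gene annotation, population map) or a simulation block, plus
#' the comparison design and every analysis threshold. All thresholds
#' default to the study's values; overrides are recorded in the run
#' manifest.
#'
#' @param seed integer; the single source of randomness, from which stage
#'   seeds are derived (simulation uses `seed`, the single-read-sampling
#'   draw `seed + 10`).
#' @param outdir output directory.
#' @param simulate `NULL`, or a list of [sim_config()] / [default_sim_config()]
#'   arguments (the simulation inherits `seed`).
#' @param inputs `NULL`, or `list(vcf =, genes =, popmap =)` file paths.
#' @param comparisons list of comparison specs, each
#'   `list(label =, a =, b =, role =, clade =)` with `a`/`b` character
#'   vectors of population labels (pooled), and `role` one of `"case"`,
#'   `"control-migrant-migrant"`, `"control-resident-resident"`. For case
#'   comparisons `a` must be the resident side. `NULL` selects the default
#'   study-shaped design (only valid with the default simulation).
#' @param thresholds named overrides of
#'   `maf` (0.05), `max_missing` (0.25), `window_bp` (50000),
#'   `step_bp` (25000), `percentile` (0.99), `gene_dist_bp` (25000),
#'   `xpehh_log_p` (2), `pca_p` (0.05), `relatedness` (0.3),
#'   `pi_window_bp` (10000), `ehh_cutoff` (0.05).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, outdir, simulate = NULL, inputs = NULL,
                            comparisons = NULL, thresholds = list()) {
  if (is.null(simulate) == is.null(inputs))
    stop("exactly one of `simulate` or `inputs` must be given", call. = FALSE)
  defaults <- list(maf = 0.05, max_missing = 0.25, window_bp = 50000L,
                   step_bp = 25000L, percentile = 0.99, gene_dist_bp = 25000L,
                   xpehh_log_p = 2, pca_p = 0.05, relatedness = 0.3,
                   pi_window_bp = 10000L, ehh_cutoff = 0.05)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  thr <- utils::modifyList(defaults, thresholds)
  if (is.null(comparisons)) comparisons <- default_comparisons()
  roles <- vapply(comparisons, `[[`, "", "role")
  if (!any(roles == "case"))
    stop("at least one case comparison is required", call. = FALSE)
  ok_roles <- c("case", "control-migrant-migrant", "control-resident-resident")
  if (!all(roles %in% ok_roles))
    stop("comparison role must be one of: ", paste(ok_roles, collapse = ", "),
         call. = FALSE)
  labs <- vapply(comparisons, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("comparison labels must be unique", call. = FALSE)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 simulate = simulate, inputs = inputs,
                 comparisons = comparisons, thresholds = thr),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file mapping onto the `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed", call. = FALSE)
  pipeline_config(seed = y$seed,
                  outdir = y$outdir %||% ".",
                  simulate = y$simulate,
                  inputs = y$inputs,
                  comparisons = y$comparisons,
                  thresholds = y$thresholds %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The study-shaped comparison design
#'
#' Three case comparisons (two western resident units against the pooled
#' western migrants, the pooled eastern residents against the pooled eastern
#' migrants) with within-clade migrant-migrant and resident-resident
#' controls; matches the populations of [default_sim_config()].
#'
#' @return A list of comparison specs for [pipeline_config()].
#' @export
default_comparisons <- function() {
  list(
    list(label = "az", a = "res_az", b = c("mig_w1", "mig_w2"),
         role = "case", clade = "west"),
    list(label = "ca", a = "res_ca", b = c("mig_w1", "mig_w2"),
         role = "case", clade = "west"),
    list(label = "east", a = c("res_fl", "res_al"), b = c("mig_e1", "mig_e2"),
         role = "case", clade = "east"),
    list(label = "ctrl_mig_w", a = "mig_w1", b = "mig_w2",
         role = "control-migrant-migrant", clade = "west"),
    list(label = "ctrl_res_w", a = "res_az", b = "res_ca",
         role = "control-resident-resident", clade = "west"),
    list(label = "ctrl_mig_e", a = "mig_e1", b = "mig_e2",
         role = "control-migrant-migrant", clade = "east"),
    list(label = "ctrl_res_e", a = "res_fl", b = "res_al",
         role = "control-resident-resident", clade = "east")
  )
}

#' Run the replicated selection-scan pipeline
#'
#' Executes simulate/load, site filtering, relatedness filtering, population
#' structure (PCA, windowed diversity), the three selection statistics per
#' comparison, control-comparison exclusion, gene-proximity annotation, and
#' parallelism classification; writes every stage's table plus a run
#' manifest into `config$outdir`. Identical config and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param write logical; write output tables (default TRUE).
#' @param with_xpehh logical; set `FALSE` to skip the haplotype scans (and
#'   the directionality table that depends on them), e.g. for frequency-only
#'   calibration runs.
#' @return Invisibly, a list with all stage results (`cohort` or input data,
#'   `geno`, `retained`, `pca`, `pi`, `fst`, `outliers`, `xpehh`,
#'   `pca_scan`, `gene_sets`, `reports`, `manifest`).
#' @export
run_pipeline <- function(config, write = TRUE, with_xpehh = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  log_lines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  ## ---- stage: data ----
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    cfg <- if (isTRUE(sim_args$preset == "default") || is.null(sim_args$populations)) {
      sim_args$preset <- NULL
      do.call(default_sim_config, sim_args)
    } else do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cfg)
    haps <- cohort$haps; geno <- cohort$geno
    genes <- cohort$genes; popmap <- cohort$popmap
    note("simulated %d samples x %d sites, %d genes",
         length(geno$samples), ncol(geno$dosages), nrow(genes))
  } else {
    haps <- read_vcf(config$inputs$vcf, phased = TRUE)
    geno <- as_genotypes(haps)
    genes <- read_genes(config$inputs$genes)
    popmap <- read_popmap(config$inputs$popmap)
    cohort <- NULL
    note("loaded %d samples x %d sites, %d genes",
         length(geno$samples), ncol(geno$dosages), nrow(genes))
  }
  validate_comparisons(config$comparisons, popmap)
  n_sites_in <- ncol(geno$dosages)

  ## ---- stage: site filters ----
  geno_f <- filter_sites(geno, maf_min = thr$maf,
                         max_missing_fraction = thr$max_missing)
  filter_report <- attr(geno_f, "report")
  keep_key <- paste(geno_f$sites$chrom, geno_f$sites$pos)
  haps_f <- subset_sites(haps, paste(haps$sites$chrom, haps$sites$pos) %in% keep_key)
  note("site filter: %d -> %d sites", n_sites_in, ncol(geno_f$dosages))

  ## ---- stage: relatedness ----
  cov <- srs_covariance(geno_f, seed = config$seed + 10L)
  rel <- relatedness_filter(cov, threshold = thr$relatedness)
  note("relatedness: dropped %d of %d samples", length(rel$dropped),
       length(geno$samples))
  geno_f <- subset_samples(geno_f, rel$retained)
  haps_f <- subset_samples(haps_f, rel$retained)
  geno_all <- subset_samples(geno, rel$retained)  # unfiltered sites, for pi
  popmap <- popmap[popmap$sample %in% rel$retained, , drop = FALSE]

  ## ---- stage: structure ----
  clades <- unique(popmap$clade)
  pca <- lapply(stats::setNames(clades, clades), function(cl) {
    samp <- popmap$sample[popmap$clade == cl]
    pca_structure(srs_covariance(subset_samples(geno_f, samp),
                                 seed = config$seed + 10L), k = 2L)
  })
  chrom_len <- chrom_lengths(config, geno)
  pops <- unique(popmap$population)
  pi <- purrr::map_dfr(pops, function(pp) {
    w <- windowed_pi(geno_all, popmap, pp, window_bp = thr$pi_window_bp,
                     chrom_length = chrom_len)
    dplyr::mutate(w, population = pp, .before = 1)
  })
  pi_summary <- dplyr::summarise(
    dplyr::group_by(pi, .data$population),
    mean_pi = sum(.data$pi * (.data$end - .data$start)) /
      sum(.data$end - .data$start),
    .groups = "drop")

  ## ---- stage: F_ST scans + outliers ----
  comps <- config$comparisons
  names(comps) <- vapply(comps, `[[`, "", "label")
  fst <- lapply(comps, function(cc) {
    s <- fst_scan(geno_f, popmap, cc$a, cc$b, label = cc$label)
    list(sites = s, windows = fst_windows(s, thr$window_bp, thr$step_bp))
  })
  outliers <- lapply(comps, function(cc) {
    f <- fst[[cc$label]]
    def <- !is.na(f$sites$fst)
    so <- percentile_outliers(f$sites$fst[def], q = thr$percentile)
    wo <- percentile_outliers(f$windows$fst, q = thr$percentile)
    list(
      sites = sites_as_intervals(f$sites[def, ][so, ]),
      windows = f$windows[wo, c("chrom", "start", "end")]
    )
  })
  for (cc in comps)
    note("%s [%s]: %d outlier sites, %d outlier windows", cc$label, cc$role,
         nrow(outliers[[cc$label]]$sites), nrow(outliers[[cc$label]]$windows))

  ## ---- stage: control exclusion + merge ----
  case_labels <- names(comps)[vapply(comps, `[[`, "", "role") == "case"]
  # site-level case outliers are excluded by control outliers at both
  # levels (exact-position site hits and whole control windows, which
  # interval overlap composes); window-level case outliers by control
  # windows
  excluded <- lapply(stats::setNames(case_labels, case_labels), function(lb) {
    cl <- comps[[lb]]$clade
    ctrl_lb <- names(comps)[vapply(comps, `[[`, "", "role") != "case" &
                              vapply(comps, `[[`, "", "clade") == cl]
    ctrl_sites <- lapply(ctrl_lb, function(x) outliers[[x]]$sites)
    ctrl_windows <- lapply(ctrl_lb, function(x) outliers[[x]]$windows)
    list(
      sites = exclude_control_outliers(outliers[[lb]]$sites,
                                       c(ctrl_sites, ctrl_windows)),
      windows = merge_overlapping(exclude_control_outliers(
        outliers[[lb]]$windows, ctrl_windows))
    )
  })
  for (lb in case_labels)
    note("%s: %d sites / %d windows after control exclusion", lb,
         nrow(excluded[[lb]]$sites), nrow(excluded[[lb]]$windows))

  ## ---- stage: XP-EHH and PCA scans ----
  xp <- if (with_xpehh) {
    lapply(stats::setNames(case_labels, case_labels), function(lb) {
      cc <- comps[[lb]]
      ha <- subset_samples(haps_f, popmap$sample[popmap$population %in% cc$a])
      hb <- subset_samples(haps_f, popmap$sample[popmap$population %in% cc$b])
      xpehh(ha, hb, cutoff = thr$ehh_cutoff,
            labels = c("resident", "migrant"), log_p = thr$xpehh_log_p)
    })
  } else list()
  pca_scan <- lapply(stats::setNames(clades, clades), function(cl) {
    pca_selection_scan(geno_f, samples = popmap$sample[popmap$clade == cl],
                       k = 1L, alpha = thr$pca_p)
  })

  ## ---- stage: genes + parallelism ----
  gene_sets <- lapply(excluded, function(ex)
    sort(unique(genes_near(ex$sites, genes, thr$gene_dist_bp)$gene_id)))
  report_gene <- classify_parallelism(gene_sets, level = "gene")
  report_snp <- classify_parallelism(lapply(excluded, `[[`, "sites"),
                                     level = "snp")
  shared_genes <- report_gene$membership[report_gene$membership$n_comparisons >= 2L, ]
  shared_items <- dplyr::inner_join(
    dplyr::rename(genes[, c("gene_id", "chrom", "start", "end")],
                  item = "gene_id"),
    shared_genes, by = "item")
  concord <- if (with_xpehh) directionality_concordance(shared_items, xp)
             else tibble::tibble(item = character(), signs = list(),
                                 determined = logical(), concordant = logical())
  fun_cat <- purrr::map_dfr(case_labels, function(lb)
    dplyr::mutate(functional_categorize(excluded[[lb]]$sites, genes,
                                        thr$gene_dist_bp),
                  comparison = lb, .before = 1))

  manifest <- list(
    package_version = as.character(utils::packageVersion("migscan")),
    seed = config$seed,
    thresholds = thr,
    counts = list(
      samples_in = length(geno$samples),
      samples_retained = length(rel$retained),
      sites_in = n_sites_in,
      sites_filtered = ncol(geno_f$dosages),
      outlier_sites = lapply(outliers, function(o) nrow(o$sites)),
      outlier_sites_post_exclusion = lapply(excluded, function(o) nrow(o$sites)),
      genes_per_comparison = lapply(gene_sets, length),
      gene_union = report_gene$union_size,
      gene_shared_multi = report_gene$shared_multi,
      gene_shared_all = report_gene$shared_all
    )
  )
  res <- list(cohort = cohort, geno = geno_f, haps = haps_f, genes = genes,
              popmap = popmap, cov = cov, relatedness = rel, pca = pca,
              pi = pi, pi_summary = pi_summary, fst = fst,
              outliers = outliers, excluded = excluded, xpehh = xp,
              pca_scan = pca_scan, gene_sets = gene_sets,
              report_gene = report_gene, report_snp = report_snp,
              concordance = concord, functional = fun_cat,
              filter_report = filter_report, manifest = manifest,
              log = log_lines)
  if (write) write_pipeline_outputs(res, config)
  invisible(res)
}

chrom_lengths <- function(config, geno) {
  if (!is.null(config$simulate)) {
    len <- config$simulate$chrom_length_bp %||%
      formals(sim_config)$chrom_length_bp
    stats::setNames(as.integer(len), unique(geno$sites$chrom))
  } else {
    tapply(geno$sites$pos, geno$sites$chrom, max)
  }
}

validate_comparisons <- function(comparisons, popmap) {
  pheno <- stats::setNames(popmap$phenotype, popmap$population)
  clade <- stats::setNames(popmap$clade, popmap$population)
  for (cc in comparisons) {
    pops <- c(cc$a, cc$b)
    missing <- setdiff(pops, popmap$population)
    if (length(missing))
      stop("comparison ", cc$label, ": unknown population(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (length(unique(clade[pops])) != 1L)
      stop("comparison ", cc$label, " spans clades", call. = FALSE)
    if (cc$role == "case" &&
        !(all(pheno[cc$a] == "resident") && all(pheno[cc$b] == "migrant")))
      stop("case comparison ", cc$label,
           " must pair a resident set (a) against a migrant set (b)",
           call. = FALSE)
  }
  invisible(TRUE)
}

write_tsv_file <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) if (is.list(x[[j]]))
    x[[j]] <- vapply(x[[j]], paste, "", collapse = ",")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  utils::write.table(res$cov$cov, out("covariance.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  writeLines(res$relatedness$retained, out("retained_samples.txt"))
  write_tsv_file(res$filter_report, out("filtered_sites.tsv"))
  write_tsv_file(res$pi, out("pi_windows.tsv"))
  write_tsv_file(res$pi_summary, out("pi_summary.tsv"))
  for (lb in names(res$fst)) {
    write_tsv_file(res$fst[[lb]]$sites, out(sprintf("fst_sites_%s.tsv", lb)))
    write_tsv_file(res$fst[[lb]]$windows, out(sprintf("fst_windows_%s.tsv", lb)))
  }
  for (lb in names(res$excluded)) {
    write_tsv_file(res$excluded[[lb]]$sites,
                   out(sprintf("outlier_sites_%s.tsv", lb)))
    write_tsv_file(res$excluded[[lb]]$windows,
                   out(sprintf("outlier_windows_%s.tsv", lb)))
    if (lb %in% names(res$xpehh))
      write_tsv_file(res$xpehh[[lb]], out(sprintf("xpehh_%s.tsv", lb)))
  }
  for (cl in names(res$pca_scan))
    write_tsv_file(res$pca_scan[[cl]], out(sprintf("pca_scan_%s.tsv", cl)))
  write_tsv_file(res$report_gene$venn, out("venn_regions.tsv"))
  write_tsv_file(res$report_gene$membership, out("gene_membership.tsv"))
  write_tsv_file(res$report_snp$membership, out("snp_membership.tsv"))
  write_tsv_file(dplyr::mutate(res$concordance,
                               signs = vapply(res$concordance$signs, function(s)
                                 paste(sprintf("%s:%+d", names(s), as.integer(s)),
                                       collapse = ","), "")),
                 out("directionality.tsv"))
  write_tsv_file(res$functional, out("functional_categories.tsv"))
  yaml::write_yaml(res$manifest, out("manifest.yaml"))
  writeLines(res$log, out("run.log"))
  invisible(config$outdir)
}
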