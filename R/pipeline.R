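RUN_CONFIG_KEYS <- c(
  "species", "seed", "alignment", "sites", "snv_table", "snv_table_t0",
  "outdir",
  # simulator
  "sim_kind", "N", "n_sample", "L_sites", "mu", "rho", "mean_frag_sites",
  "generations", "strains_per_host", "mu_t", "gamma_t",
  # detection
  "emission", "window_bp", "n_bins", "d_star", "fc_star", "max_divergence",
  "min_snvs", "merge_gap_bp",
  # stats / sharing
  "bandwidth", "n_draws_per_event", "pairing", "window_syn_sites",
  # within-host
  "depth_min", "f_low", "f_high", "min_sites", "min_sweep_bp")

#' Assemble a validated run configuration
#'
#' Merges user settings (a YAML file or a named list) over the package
#' defaults; unknown keys are rejected so typos fail loudly.  The seed is
#' recorded in every output header.
#'
#' @param config path to a YAML file, a named list, or `NULL` for defaults.
#' @param ... individual overrides (highest precedence).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  defaults <- list(
    species = "unknown", seed = 1L, outdir = ".",
    sim_kind = "population", N = 200L, n_sample = 20L, L_sites = 20000L,
    mu = 5e-5, rho = 0, mean_frag_sites = 300, generations = NULL,
    strains_per_host = 1L, mu_t = 5e-5, gamma_t = 10,
    emission = "pooled", window_bp = 1000L, n_bins = 12L,
    d_star = 1e-4, fc_star = 0.2, max_divergence = 0.02,
    min_snvs = 2L, merge_gap_bp = 100L,
    bandwidth = 0.25, n_draws_per_event = 10L,
    pairing = "between_host_within_clade", window_syn_sites = "auto",
    depth_min = 10L, f_low = 0.2, f_high = 0.8, min_sites = 100L,
    min_sweep_bp = 10000L)
  user <- list()
  if (is.character(config)) user <- yaml::read_yaml(config)
  else if (is.list(config)) user <- config
  over <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, user), over)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}

prepare_outdir <- function(outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory ", outdir, " exists and is non-empty; use force")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  invisible(outdir)
}

write_manifest <- function(cfg, outdir, inputs = character(0)) {
  mf <- list(package = "corerecomb",
             version = as.character(utils::packageVersion("corerecomb")),
             seed = cfg$seed,
             config = unclass(cfg),
             input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  yaml::write_yaml(mf, file.path(outdir, "manifest.yaml"))
}

#' Pipeline commands
#'
#' Thin orchestration entry points mirroring the `corerecomb` command-line
#' interface.  Each writes its tables plus a `manifest.yaml` (package version,
#' parameters, seed, input checksums) into `outdir`.
#'
#' `cmd_simulate` runs the neutral simulator (population Moran model, or a
#' single pair when `sim_kind = "pair"`) and writes a FASTA alignment, a
#' site-annotation TSV and a truth TSV.  `cmd_detect` estimates the emission
#' distribution, decodes every between-host pair, selects close pairs, flags
#' duplicates and writes events and decodings.  `cmd_stats` computes the trend
#' curve, apparent rates, length summary and donor-divergence K-S test from a
#' detect output directory.  `cmd_sharing` computes identity runs and the
#' sharing landscape.  `cmd_withinhost` runs dual-colonization and sweep
#' detection on a sample SNV table.
#'
#' @param cfg a [run_config()] (or anything accepted by it).
#' @param outdir output directory.
#' @param force overwrite a non-empty output directory.
#' @return Invisibly, a list of the main results.
#' @export
cmd_simulate <- function(cfg, outdir = cfg$outdir, force = FALSE) {
  cfg <- run_config(cfg)
  prepare_outdir(outdir, force)
  set.seed(cfg$seed)
  if (identical(cfg$sim_kind, "pair")) {
    sim <- simulate_pair(pair_sim_config(L_sites = cfg$L_sites, mu_t = cfg$mu_t,
                                         gamma_t = cfg$gamma_t,
                                         mean_frag_sites = cfg$mean_frag_sites))
    write_tsv(data.frame(site = seq_along(sim$profile$diff),
                         pos_bp = sim$profile$site_pos,
                         diff = sim$profile$diff),
              file.path(outdir, "pair_profile.tsv"),
              comment = paste0("seed=", cfg$seed))
    write_tsv(sim$truth, file.path(outdir, "truth.tsv"),
              comment = paste0("seed=", cfg$seed))
    write_manifest(cfg, outdir)
    return(invisible(sim))
  }
  gens <- if (is.null(cfg$generations)) 10L * cfg$N else cfg$generations
  sim <- simulate_population(pop_sim_config(
    N = cfg$N, n_sample = cfg$n_sample, L_sites = cfg$L_sites, mu = cfg$mu,
    rho = cfg$rho, mean_frag_sites = cfg$mean_frag_sites, generations = gens,
    strains_per_host = cfg$strains_per_host))
  write_core_alignment(sim$genomes, file.path(outdir, "alignment.fa"),
                       file.path(outdir, "sites.tsv"))
  write_tsv(data.frame(steps = sim$truth$steps, N = cfg$N, mu = cfg$mu,
                       rho = cfg$rho, seed = cfg$seed),
            file.path(outdir, "truth.tsv"),
            comment = paste0("seed=", cfg$seed))
  write_manifest(cfg, outdir)
  invisible(sim)
}

#' @rdname cmd_simulate
#' @export
cmd_detect <- function(cfg, outdir = cfg$outdir, force = FALSE) {
  cfg <- run_config(cfg)
  for (p in c(cfg$alignment, cfg$sites))
    if (!file.exists(p)) stop("missing input: ", p)
  prepare_outdir(outdir, force)
  set.seed(cfg$seed)
  genomes <- load_core_alignment(cfg$alignment, cfg$sites,
                                 species_name = cfg$species)
  emissions <- estimate_empirical_divergence(
    genomes, window_bp = cfg$window_bp,
    clade_pairing = cfg$emission, n_bins = cfg$n_bins)
  res <- decode_pair_cohort(genomes, emissions,
                            max_divergence = cfg$max_divergence,
                            min_snvs = cfg$min_snvs,
                            merge_gap_bp = cfg$merge_gap_bp)
  sel <- select_close_pairs(res$decodings, d_star = cfg$d_star,
                            fc_star = cfg$fc_star)
  kept_pairs <- vapply(sel$kept, function(d) paste(d$pair, collapse = "\r"),
                       character(1))
  events <- res$events
  if (!is.null(events)) {
    events <- events[paste(events$strain_a, events$strain_b, sep = "\r") %in%
                       kept_pairs, , drop = FALSE]
    if (nrow(events)) events <- flag_duplicate_transfers(events)
  }
  write_events_tsv(events, file.path(outdir, "events.tsv"), cfg$species)
  write_decodings_tsv(res$decodings, file.path(outdir, "decodings.tsv"),
                      cfg$species)
  write_tsv(sel$excluded, file.path(outdir, "excluded_pairs.tsv"),
            comment = paste0("seed=", cfg$seed))
  write_manifest(cfg, outdir, c(cfg$alignment, cfg$sites))
  invisible(list(decodings = res$decodings, close_pairs = sel$kept,
                 events = events, genomes = genomes, emissions = emissions))
}

#' @rdname cmd_simulate
#' @param detect a result of [cmd_detect()] (or its output directory is
#'   re-read via `cfg`).
#' @export
cmd_stats <- function(cfg, detect, outdir = cfg$outdir, force = FALSE) {
  cfg <- run_config(cfg)
  prepare_outdir(outdir, force)
  set.seed(cfg$seed)
  genomes <- detect$genomes
  events <- detect$events
  L_bp <- genomes$L_bp
  empty_note <- paste0("seed=", cfg$seed)
  if (is.null(events) || !nrow(events)) {
    write_tsv(data.frame(d_c = numeric(0), mean = numeric(0), spread = numeric(0)),
              file.path(outdir, "trend.tsv"), comment = empty_note)
    write_tsv(data.frame(d_c = numeric(0), rate = numeric(0)),
              file.path(outdir, "rates.tsv"), comment = empty_note)
    write_tsv(data.frame(length_bp = numeric(0)),
              file.path(outdir, "lengths.tsv"), comment = empty_note)
    write_tsv(data.frame(ks_distance = numeric(0), p_value = numeric(0)),
              file.path(outdir, "ks.tsv"), comment = empty_note)
    write_manifest(cfg, outdir)
    return(invisible(NULL))
  }
  out <- list()
  trend <- tryCatch(transfer_trend(detect$close_pairs, bandwidth = cfg$bandwidth),
                    error = function(e) NULL)
  if (!is.null(trend)) {
    write_tsv(data.frame(d_c = trend$x, mean = trend$mean, spread = trend$spread),
              file.path(outdir, "trend.tsv"), comment = empty_note)
    rates <- apparent_rate(trend, L_bp)
  } else {
    rates <- apparent_rate(detect$close_pairs, L_bp)
  }
  write_tsv(rates, file.path(outdir, "rates.tsv"), comment = empty_note)
  len <- transfer_length_summary(events)
  write_tsv(data.frame(length_bp = len$lengths),
            file.path(outdir, "lengths.tsv"), comment = empty_note)
  dd <- donor_divergence_null(genomes, events[!events$is_duplicate, ],
                              n_draws_per_event = cfg$n_draws_per_event)
  write_tsv(data.frame(ks_distance = dd$ks_distance, p_value = dd$p_value),
            file.path(outdir, "ks.tsv"), comment = empty_note)
  write_manifest(cfg, outdir)
  invisible(list(trend = trend, rates = rates, lengths = len, ks = dd))
}

#' @rdname cmd_simulate
#' @export
cmd_sharing <- function(cfg, outdir = cfg$outdir, force = FALSE) {
  cfg <- run_config(cfg)
  for (p in c(cfg$alignment, cfg$sites))
    if (!file.exists(p)) stop("missing input: ", p)
  prepare_outdir(outdir, force)
  set.seed(cfg$seed)
  genomes <- load_core_alignment(cfg$alignment, cfg$sites,
                                 species_name = cfg$species)
  ls <- sharing_landscape(genomes, pairing = cfg$pairing,
                          window_syn_sites = cfg$window_syn_sites)
  write_landscape_tsv(ls, file.path(outdir, "landscape.tsv"))
  meta <- genomes$strain_meta
  pr <- all_pairs(meta$strain_id)
  pr <- pr[meta$host_id[pr[, 1]] != meta$host_id[pr[, 2]], , drop = FALSE]
  runs <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
    prof <- pair_difference_profile(genomes, meta$strain_id[pr[i, 1]],
                                    meta$strain_id[pr[i, 2]])
    rs <- identical_runs(prof)
    cbind(strain_a = prof$pair[1], strain_b = prof$pair[2],
          rs$runs[rs$runs$length_sites > 0, , drop = FALSE])
  }))
  write_tsv(runs, file.path(outdir, "runs.tsv"),
            comment = paste0("seed=", cfg$seed))
  write_manifest(cfg, outdir, c(cfg$alignment, cfg$sites))
  invisible(list(landscape = ls, cv = landscape_cv(ls)))
}

#' @rdname cmd_simulate
#' @export
cmd_withinhost <- function(cfg, outdir = cfg$outdir, force = FALSE) {
  cfg <- run_config(cfg)
  if (!file.exists(cfg$snv_table)) stop("missing input: ", cfg$snv_table)
  prepare_outdir(outdir, force)
  tab <- read_sample_snv_table(cfg$snv_table, depth_min = cfg$depth_min)
  tab0 <- if (!is.null(cfg$snv_table_t0) && nzchar(cfg$snv_table_t0))
    read_sample_snv_table(cfg$snv_table_t0, depth_min = cfg$depth_min) else NULL
  dual <- detect_dual_colonization(tab, f_low = cfg$f_low, f_high = cfg$f_high,
                                   min_sites = cfg$min_sites)
  calls <- if (dual$is_dual)
    detect_sweep_regions(tab, tab0, f_low = cfg$f_low, f_high = cfg$f_high,
                         min_sweep_bp = cfg$min_sweep_bp)
  else data.frame(contig = character(0), start_bp = numeric(0),
                  end_bp = numeric(0), length_bp = numeric(0),
                  coverage_ratio = numeric(0), mode = character(0))
  write_sweeps_tsv(calls, file.path(outdir, "sweeps.tsv"),
                   sample_id = basename(cfg$snv_table))
  write_tsv(data.frame(is_dual = dual$is_dual, strain_freq = dual$strain_freq,
                       n_intermediate = dual$n_intermediate),
            file.path(outdir, "dual_colonization.tsv"),
            comment = paste0("seed=", cfg$seed))
  write_manifest(cfg, outdir, cfg$snv_table)
  invisible(list(dual = dual, sweeps = calls))
}
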