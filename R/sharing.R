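#' Maximal runs of identity (shared ancestry) in a pair profile
#'
#' Maximal stretches of compared sites with zero differences, flanked by SNVs
#' or by the profile ends.  Long runs indicate recent common ancestry or a
#' recent transfer.
#'
#' @param profile a `diff_profile`.
#' @return A `run_set`: `runs` (data.frame with site and bp bounds and
#'   `length_sites`), `longest_run` (sites), and the pair ids.
#' @export
identical_runs <- function(profile) {
  d <- profile$diff
  n <- length(d)
  hits <- which(d == 1L)
  starts <- c(1L, hits + 1L)
  ends <- c(hits - 1L, n)
  len <- ends - starts + 1L
  keep <- len >= 0L
  runs <- data.frame(start_site = starts[keep], end_site = ends[keep],
                     length_sites = pmax(len[keep], 0L))
  nz <- runs$length_sites > 0L
  runs$start_bp <- NA_real_; runs$end_bp <- NA_real_
  runs$start_bp[nz] <- profile$site_pos[runs$start_site[nz]]
  runs$end_bp[nz] <- profile$site_pos[runs$end_site[nz]]
  structure(list(pair = profile$pair, runs = runs,
                 longest_run = max(runs$length_sites, 0L),
                 n_sites = n, n_snvs = length(hits)),
            class = "run_set")
}

#' Total length of identity runs exceeding a threshold
#'
#' @param run_set a `run_set` from [identical_runs()].
#' @param ell length threshold in synonymous sites.
#' @return Total sites in runs of length >= `ell`.
#' @export
total_run_length_above <- function(run_set, ell) {
  sum(run_set$runs$length_sites[run_set$runs$length_sites >= ell])
}

#' Null distribution of the longest identity run under random scatter
#'
#' Scatters `n_snvs` SNVs uniformly over `L_sites` sites (distinct positions)
#' and records the longest zero-SNV gap, repeated `reps` times.  This is the
#' null for "is this run longer than random mutation placement would give".
#'
#' @param n_snvs number of SNVs.
#' @param L_sites genome length in sites.
#' @param reps replicates.
#' @param seed integer seed or `NULL`.
#' @return list with `null` (longest runs) and `p_value(obs)` giving the
#'   upper-tail permutation p-value `(1 + #{null >= obs}) / (reps + 1)`.
#' @export
runs_null_random_scatter <- function(n_snvs, L_sites, reps = 1000, seed = NULL) {
  stopifnot(n_snvs <= L_sites)
  if (!is.null(seed)) set.seed(seed)
  null <- if (n_snvs == 0) rep(L_sites, reps)
  else if (n_snvs == L_sites) rep(0L, reps)
  else vapply(seq_len(reps), function(i) {
    pos <- sort.int(sample.int(L_sites, n_snvs))
    max(diff(c(0L, pos, L_sites + 1L))) - 1L
  }, numeric(1))
  list(null = null,
       p_value = function(obs) (1 + sum(null >= obs)) / (reps + 1))
}

#' Compare within-host and between-host longest runs (one-sided K-S)
#'
#' Tests whether within-host longest identity runs stochastically dominate the
#' between-host distribution (enrichment of long runs in co-colonizing
#' strains).  A `total_above` variant compares total run length above a
#' threshold instead of the longest run.
#'
#' @param within_runs longest runs (or totals) for co-colonizing pairs, one
#'   per host.
#' @param between_runs the same statistic for pairs from unrelated hosts.
#' @param variant `"longest"` or `"total_above"` (label only; supply the
#'   matching statistic).
#' @param method `"permutation"` (default; one-sided K-S distance with a
#'   label-permutation p-value, exactly calibrated at these sample sizes and
#'   robust to ties) or `"asymptotic"` (classical one-sided two-sample K-S
#'   p-value).
#' @param perm_reps permutations for `method = "permutation"`.
#' @param seed integer seed for the permutation null, or `NULL`.
#' @return list with `p_value`, `ks_distance`, `variant`, `low_power`
#'   (TRUE when either sample has fewer than 5 observations).
#' @export
compare_within_between_runs <- function(within_runs, between_runs,
                                        variant = c("longest", "total_above"),
                                        method = c("permutation", "asymptotic"),
                                        perm_reps = 999, seed = NULL) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  low_power <- length(within_runs) < 5 || length(between_runs) < 5
  n <- length(within_runs); m <- length(between_runs)
  # one-sided D: how far the within-host ECDF falls *below* the between-host
  # ECDF, i.e. within-host runs stochastically larger
  d_stat <- function(w_idx) {
    z <- c(within_runs, between_runs)
    isw <- seq_along(z) %in% w_idx
    o <- order(z)
    zw <- isw[o]
    fw <- cumsum(zw) / n
    fb <- cumsum(!zw) / m
    zs <- z[o]
    last_of_tie <- c(zs[-1] != zs[-length(zs)], TRUE)
    max((fb - fw)[last_of_tie])
  }
  obs <- d_stat(seq_len(n))
  if (method == "asymptotic") {
    kt <- suppressWarnings(ks.test(within_runs, between_runs, alternative = "less"))
    return(list(p_value = kt$p.value, ks_distance = unname(kt$statistic),
                variant = variant, low_power = low_power,
                n_within = n, n_between = m))
  }
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(perm_reps), function(i)
    d_stat(sample.int(n + m, n)), numeric(1))
  list(p_value = (1 + sum(null >= obs)) / (perm_reps + 1),
       ks_distance = obs, variant = variant, low_power = low_power,
       n_within = n, n_between = m)
}

#' Genome-wide haplotype sharing landscape
#'
#' For every core position at which a full window of `window_syn_sites`
#' synonymous sites fits, the fraction of eligible strain pairs whose
#' haplotypes are identical across the window ("identical" = zero mismatches
#' on non-missing sites, with at least 90% of window sites observed in both
#' strains).  The automatic window is `ceil(15 / d_bar)` synonymous sites --
#' long enough (`l * d_bar >> 1`) that typical pairs essentially never match,
#' so sharing isolates recent transfers and recent common ancestry.
#'
#' @param genomes a [core_genome_set()].
#' @param pairing `"between_host_within_clade"`, `"between_host_between_clade"`
#'   or `"within_host"` (one pair per dual-colonized host, the two strains of
#'   that host).
#' @param window_syn_sites window size in synonymous sites, or `"auto"`.
#' @param min_pairs minimum number of eligible pairs.
#' @param min_obs_frac minimum fraction of window sites observed in both
#'   strains.
#' @return A `sharing_landscape`: `site_idx` (synonymous-site index of window
#'   centers), `pos_bp`, `p_share`, `window`, `pairing`, `n_pairs`, `d_bar`.
#' @export
sharing_landscape <- function(genomes,
                              pairing = c("between_host_within_clade",
                                          "between_host_between_clade",
                                          "within_host"),
                              window_syn_sites = "auto",
                              min_pairs = 10, min_obs_frac = 0.9) {
  pairing <- match.arg(pairing)
  meta <- genomes$strain_meta
  syn <- which(genomes$sites$is_synonymous)
  hap <- genomes$haplotypes[, syn, drop = FALSE]
  n_syn <- ncol(hap)

  pr <- all_pairs(meta$strain_id)
  same_host <- meta$host_id[pr[, 1]] == meta$host_id[pr[, 2]]
  clade <- meta$clade_id
  same_clade <- is.na(clade[pr[, 1]]) | is.na(clade[pr[, 2]]) |
    clade[pr[, 1]] == clade[pr[, 2]]
  keep <- switch(pairing,
                 between_host_within_clade = !same_host & same_clade,
                 between_host_between_clade = !same_host & !same_clade,
                 within_host = same_host)
  pr <- pr[keep, , drop = FALSE]
  if (pairing == "within_host" && nrow(pr)) {
    # one pair per co-colonized host to avoid pseudo-replication
    hosts <- meta$host_id[pr[, 1]]
    pr <- pr[!duplicated(hosts), , drop = FALSE]
  }
  if (nrow(pr) < min_pairs)
    stop("only ", nrow(pr), " eligible pairs for pairing '", pairing,
         "' (need >= ", min_pairs, ")")

  # pass 1: pair divergences (for the automatic window)
  mism_list <- vector("list", nrow(pr))
  obs_list <- vector("list", nrow(pr))
  divs <- numeric(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    a <- hap[pr[i, 1], ]; b <- hap[pr[i, 2], ]
    obs <- !is.na(a) & !is.na(b)
    mism <- obs & (a != b)
    mism[is.na(mism)] <- FALSE
    mism_list[[i]] <- mism
    obs_list[[i]] <- obs
    divs[i] <- sum(mism) / max(sum(obs), 1)
  }
  d_bar <- mean(divs)
  w <- if (identical(window_syn_sites, "auto")) {
    if (d_bar <= 0) stop("cannot auto-size window: mean divergence is zero")
    as.integer(ceiling(15 / d_bar))
  } else as.integer(window_syn_sites)
  if (w >= n_syn)
    stop("window (", w, " sites) does not fit in the genome (", n_syn, " sites)")

  h <- w %/% 2L
  centers <- (h + 1L):(n_syn - h)
  need_obs <- min_obs_frac * (2L * h + 1L)
  acc <- numeric(length(centers))
  for (i in seq_len(nrow(pr))) {
    cm <- c(0, cumsum(mism_list[[i]]))
    co <- c(0, cumsum(obs_list[[i]]))
    nm <- cm[centers + h + 1L] - cm[centers - h]
    no <- co[centers + h + 1L] - co[centers - h]
    acc <- acc + as.numeric(nm == 0 & no >= need_obs)
  }
  structure(list(site_idx = centers,
                 pos_bp = genomes$sites$pos_bp[syn][centers],
                 p_share = acc / nrow(pr),
                 window = w, pairing = pairing, n_pairs = nrow(pr),
                 d_bar = d_bar),
            class = "sharing_landscape")
}

#' Coefficient of variation of the sharing landscape
#'
#' SD/mean of the per-position sharing probability; the genome-wide summary
#' separating heterogeneous (selection-driven) landscapes from the tight
#' neutral band.
#'
#' @param landscape a `sharing_landscape`.
#' @param min_positions minimum evaluated positions (default 100).
#' @return The CV, or `NA` (with a warning) when the landscape mean is zero.
#' @export
landscape_cv <- function(landscape, min_positions = 100) {
  p <- landscape$p_share
  if (length(p) < min_positions)
    stop("landscape has ", length(p), " evaluated positions (need >= ",
         min_positions, ")")
  m <- mean(p)
  if (m == 0) {
    warning("landscape mean is zero; CV undefined")
    return(NA_real_)
  }
  sd(p) / m
}

#' Expected number of shared fragments longer than a threshold
#'
#' Neutral closed-form scaling for a random strain pair: the expected number
#' of maximal identity tracts longer than `ell` scales as
#' `L / (d_bar * ell^2 * (1 + r_over_mu)^2)`.  The multiplicative constant is
#' calibrated once against the neutral Moran simulator (N = 200,
#' d_bar = 0.02, r/mu = 1, ell = 10/d_bar); the scaling exponents are exact.
#'
#' @param L_sites genome length in synonymous sites.
#' @param d_bar typical pairwise synonymous divergence.
#' @param r_over_mu ratio of recombination initiation to mutation rate.
#' @param ell tract length threshold in sites.
#' @param calibration multiplicative constant.
#' @return Expected fragment count per pair.
#' @export
expected_shared_fragments <- function(L_sites, d_bar, r_over_mu, ell,
                                      calibration = 2.5) {
  stopifnot(L_sites > 0, d_bar > 0, r_over_mu >= 0, all(ell > 0))
  calibration * L_sites / (d_bar * ell^2 * (1 + r_over_mu)^2)
}

#' Pooled identity-tract length census for a cohort
#'
#' Convenience helper: lengths (in synonymous sites) of all maximal identity
#' runs over all between-host pairs, used for shared-fragment counting.
#'
#' @param genomes a [core_genome_set()].
#' @return Integer vector of run lengths pooled over pairs.
#' @export
cohort_run_lengths <- function(genomes) {
  meta <- genomes$strain_meta
  pr <- all_pairs(meta$strain_id)
  pr <- pr[meta$host_id[pr[, 1]] != meta$host_id[pr[, 2]], , drop = FALSE]
  unlist(lapply(seq_len(nrow(pr)), function(i) {
    prof <- pair_difference_profile(genomes, meta$strain_id[pr[i, 1]],
                                    meta$strain_id[pr[i, 2]])
    identical_runs(prof)$runs$length_sites
  }))
}

#' Rotation permutation test for hotspot concordance between two landscapes
#'
#' Statistic: Spearman rank correlation (or top-k overlap) between the two
#' landscapes.  The null is formed by cyclically rotating one landscape by a
#' uniform random offset, which preserves its spatial autocorrelation
#' (site-wise shuffles would be anti-conservative).  `"concordance"` reports
#' the fraction of rotations with statistic >= observed (are the hotspots in
#' the *same* places?); `"discordance"` the fraction with statistic <=
#' observed (are they in *different* places beyond chance?).
#'
#' @param landscape_a,landscape_b `sharing_landscape` objects or plain numeric
#'   vectors on the same coordinate grid.
#' @param reps number of random rotations (>= 1000 recommended).
#' @param statistic `"spearman"` or `"topk"`.
#' @param top_frac fraction of positions considered hotspots for `"topk"`.
#' @param alternative `"discordance"` (default) or `"concordance"`.
#' @param seed integer seed or `NULL`.
#' @return list with `p_value`, `observed`, `statistic`, `alternative`,
#'   `reps`.
#' @export
hotspot_permutation_test <- function(landscape_a, landscape_b, reps = 1000,
                                     statistic = c("spearman", "topk"),
                                     top_frac = 0.02,
                                     alternative = c("discordance", "concordance"),
                                     seed = NULL) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  a <- if (inherits(landscape_a, "sharing_landscape")) landscape_a$p_share else landscape_a
  b <- if (inherits(landscape_b, "sharing_landscape")) landscape_b$p_share else landscape_b
  if (length(a) != length(b))
    stop("landscapes have different lengths (", length(a), " vs ", length(b), ")")
  n <- length(a)
  stat <- if (statistic == "spearman") {
    ra <- rank(a)
    function(bb) cor(ra, rank(bb))
  } else {
    k <- max(1L, round(top_frac * n))
    top_a <- order(a, decreasing = TRUE)[seq_len(k)]
    function(bb) length(intersect(top_a, order(bb, decreasing = TRUE)[seq_len(k)]))
  }
  observed <- stat(b)
  offsets <- sample.int(n - 1L, reps, replace = TRUE)
  null <- vapply(offsets, function(off)
    stat(c(b[(off + 1L):n], b[seq_len(off)])), numeric(1))
  p <- if (alternative == "concordance") (1 + sum(null >= observed)) / (reps + 1)
  else (1 + sum(null <= observed)) / (reps + 1)
  list(p_value = p, observed = observed, statistic = statistic,
       alternative = alternative, reps = reps)
}

#' Write a sharing landscape as TSV
#'
#' @param landscape a `sharing_landscape`.
#' @param path output path.
#' @param contig contig label for the output rows.
#' @return The path, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path, contig = "core") {
  write_tsv(data.frame(contig = contig, pos_bp = landscape$pos_bp,
                       p_share = landscape$p_share,
                       pairing = landscape$pairing,
                       window = landscape$window),
            path,
            comment = sprintf("sharing landscape; pairing=%s window=%d n_pairs=%d",
                              landscape$pairing, landscape$window,
                              landscape$n_pairs))
}
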