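#' Empirical distribution of local divergence
#'
#' Discretizes a sample of local (window) divergences into log-spaced bins.
#' The binned distribution parameterizes the recombined macro-state of the
#' pair HMM: one Bernoulli sub-state per bin, entered with probability
#' proportional to the bin mass.  Zero-divergence windows carry no information
#' about imported-fragment divergence and are dropped before binning.
#'
#' @param values positive local divergences (e.g. sliding-window values
#'   pooled over typically diverged pairs, or donor divergences).
#' @param n_bins number of log-spaced bins (default 12).
#' @param source provenance label: `"within_clade"`, `"between_clade"` or
#'   `"pooled"`.
#' @param window_bp window width the values were computed with (metadata).
#' @return An `empirical_div_dist` with `bin_edges`, per-bin mean divergence
#'   `bin_div` and probabilities `bin_probs` (summing to 1).
#' @export
empirical_div_dist <- function(values, n_bins = 12, source = "pooled",
                               window_bp = NA) {
  values <- values[is.finite(values) & values > 0]
  if (length(values) < 10)
    stop("need >= 10 positive divergence values to build an empirical ",
         "distribution; consider a parametric (gamma) emission instead")
  values <- pmin(values, 0.499)
  lo <- min(values); hi <- max(values) * (1 + 1e-9)
  edges <- if (lo == hi) c(lo * 0.9, hi * 1.1) else
    exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), length(edges) - 1L)
  tab <- tapply(values, bin, length)
  mid <- tapply(values, bin, mean)
  keep <- !is.na(tab)
  probs <- as.numeric(tab[keep]); probs <- probs / sum(probs)
  structure(list(bin_edges = edges, bin_div = as.numeric(mid[keep]),
                 bin_probs = probs, source = source, window_bp = window_bp,
                 n_values = length(values)),
            class = "empirical_div_dist")
}

#' @export
print.empirical_div_dist <- function(x, ...) {
  cat("empirical_div_dist (", x$source, "): ", length(x$bin_div),
      " bins over [", signif(min(x$bin_div), 3), ", ",
      signif(max(x$bin_div), 3), "], n = ", x$n_values, "\n", sep = "")
  invisible(x)
}

#' Estimate the empirical local-divergence distribution of a species
#'
#' Pools sliding-window divergences from typically diverged strain pairs
#' (those near the species' modal divergence; close pairs are excluded so the
#' clonal backbone does not contaminate the distribution) into the binned
#' emission distribution used by [fit_decode_pair()].
#'
#' @param genomes a [core_genome_set()].
#' @param window_bp sliding-window width in bp (default 1000).
#' @param clade_pairing `"within"`, `"between"` or `"pooled"`: which pairs to
#'   pool, relative to the clade annotation.
#' @param n_bins number of emission bins.
#' @param max_pairs cap on the number of pairs scanned (subsampled at random).
#' @param min_pairs minimum number of typically diverged pairs required.
#' @return An [empirical_div_dist()].
#' @export
estimate_empirical_divergence <- function(genomes, window_bp = 1000,
                                          clade_pairing = c("pooled", "within", "between"),
                                          n_bins = 12, max_pairs = 60,
                                          min_pairs = 10) {
  clade_pairing <- match.arg(clade_pairing)
  meta <- genomes$strain_meta
  pr <- all_pairs(meta$strain_id)
  keep <- meta$host_id[pr[, 1]] != meta$host_id[pr[, 2]]
  if (clade_pairing != "pooled") {
    if (all(is.na(meta$clade_id)))
      stop("clade_pairing='", clade_pairing, "' requires clade annotations")
    same <- meta$clade_id[pr[, 1]] == meta$clade_id[pr[, 2]]
    keep <- keep & if (clade_pairing == "within") same else !same
  }
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) > max_pairs) pr <- pr[sample.int(nrow(pr), max_pairs), , drop = FALSE]
  profs <- lapply(seq_len(nrow(pr)), function(i)
    pair_difference_profile(genomes, meta$strain_id[pr[i, 1]],
                            meta$strain_id[pr[i, 2]]))
  # exclude close (partially clonal) pairs: their identical-block fraction is
  # high, whereas typically diverged pairs have essentially no identical
  # blocks; this keeps within-clade pairs of structured species in the pool
  f_id <- vapply(profs, function(p) {
    bs <- min(1000L, max(10L, p$n_sites %/% 10L))
    fraction_identical_blocks(partition_blocks(p, bs))
  }, numeric(1))
  typical <- f_id < 0.25 & vapply(profs, function(p) p$divergence > 0, logical(1))
  if (sum(typical, na.rm = TRUE) < min_pairs)
    stop("only ", sum(typical, na.rm = TRUE), " typically diverged pairs ",
         "available (need >= ", min_pairs, "); fall back to a parametric ",
         "gamma emission built with empirical_div_dist()")
  vals <- unlist(lapply(profs[which(typical)], function(p)
    sliding_divergence(p, window_bp = window_bp)$divergence))
  src <- c(pooled = "pooled", within = "within_clade",
           between = "between_clade")[clade_pairing]
  empirical_div_dist(vals[!is.na(vals)], n_bins = n_bins, source = src,
                     window_bp = window_bp)
}

all_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(idx[, "row"], idx[, "col"])
}

#' Decode one close pair into clonal and recombined segments (CP-HMM)
#'
#' Fits the two-macro-state pair HMM by Baum-Welch (re-estimating the clonal
#' divergence and the enter/exit transition rates, with the empirical
#' emission bins held fixed) and segments the profile by Viterbi.  Decoded
#' recombined segments separated by fewer than `merge_gap_bp` of clonal path
#' are merged, and segments supported by fewer than `min_snvs` differences are
#' discarded (they are indistinguishable from chance mutation pairs; this is
#' the method's sensitivity floor).  Each event's local divergence is
#' recomputed from the data inside the event.
#'
#' @param profile a `diff_profile` for a candidate close pair.
#' @param emissions an [empirical_div_dist()].
#' @param init optional named list overriding the moment-matched
#'   initialization (`d_clonal`, `t_enter`, `t_exit`).
#' @param max_iters,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param min_snvs minimum SNV support per event (default 2).
#' @param merge_gap_bp clonal micro-gaps below this width are merged.
#' @param max_divergence genome-wide divergence above which the pair is
#'   rejected as outside the close-pair regime (default 0.02, near the typical
#'   pairwise divergence of prevalent gut species; final close-pair selection
#'   happens downstream via [select_close_pairs()]).
#' @param separation_factor emission bins below `separation_factor` times the
#'   initial clonal divergence are dropped (clonal/recombined separability).
#' @return A `pair_decoding`: `d_clonal_hat`, `clonal_fraction`, `events`
#'   (data.frame of transfer events), `loglik`, `n_em_iters`, `converged`,
#'   `status`, and the posterior mean recombined occupancy `post_recomb_mean`.
#' @export
fit_decode_pair <- function(profile, emissions, init = NULL,
                            max_iters = 50, tol = 1e-4,
                            min_snvs = 2, merge_gap_bp = 100,
                            max_divergence = 0.02,
                            separation_factor = 3) {
  stopifnot(inherits(profile, "diff_profile"),
            inherits(emissions, "empirical_div_dist"))
  empty_events <- data.frame(start_site = integer(0), end_site = integer(0),
                             start_bp = numeric(0), end_bp = numeric(0),
                             length_sites = integer(0), length_bp = numeric(0),
                             n_snvs = integer(0), local_div = numeric(0),
                             clade_label = character(0), is_duplicate = logical(0))
  base <- list(pair = profile$pair, d_clonal_hat = NA_real_,
               clonal_fraction = NA_real_, events = empty_events,
               loglik = NA_real_, n_em_iters = 0L, converged = FALSE,
               t_enter = NA_real_, t_exit = NA_real_,
               post_recomb_mean = NA_real_, n_sites = profile$n_sites,
               status = "ok")
  if (is.na(profile$divergence) || profile$divergence > max_divergence) {
    base$status <- sprintf(
      "rejected: genome-wide divergence %.3g above close-pair threshold %.3g",
      profile$divergence, max_divergence)
    return(structure(base, class = "pair_decoding"))
  }

  x <- profile$diff
  n <- length(x)
  if (sum(x) == 0) {
    base$d_clonal_hat <- 0; base$clonal_fraction <- 1
    base$converged <- TRUE; base$loglik <- 0
    base$post_recomb_mean <- 0
    base$status <- "ok (zero differences)"
    return(structure(base, class = "pair_decoding"))
  }

  # moment-matched initialization from identical-block statistics
  bs <- min(1000L, max(10L, n %/% 10L))
  blocks <- partition_blocks(profile, bs)
  f_id <- fraction_identical_blocks(blocks)
  lowb <- blocks$snv_count_per_block <= 2L
  d0 <- if (any(lowb)) sum(blocks$snv_count_per_block[lowb]) / (sum(lowb) * bs)
        else profile$divergence / 2
  d0 <- max(d0, 0.25 / n)
  c0 <- min(1, max(f_id * exp(bs * d0), 0.05))
  tx0 <- 1 / 2000
  te0 <- max((1 - c0) * tx0, 1e-8)
  if (!is.null(init)) {
    if (!is.null(init$d_clonal)) d0 <- init$d_clonal
    if (!is.null(init$t_enter)) te0 <- init$t_enter
    if (!is.null(init$t_exit)) tx0 <- init$t_exit
  }

  bin_div <- emissions$bin_div
  bin_probs <- emissions$bin_probs
  keep <- bin_div > max(separation_factor * d0, 1e-4)
  if (!any(keep))
    stop("no emission bins above the clonal divergence scale; ",
         "emission distribution unusable for this pair")
  bin_div <- bin_div[keep]
  bin_probs <- bin_probs[keep] / sum(bin_probs[keep])
  d_max <- min(bin_div) / 2

  fit <- cphmm_em_cpp(x, d0, te0, tx0, bin_div, bin_probs,
                      as.integer(max_iters), tol, d_max)

  # Viterbi path -> visible segments
  rec <- fit$path > 0L
  ev <- segments_from_logical(rec)
  if (nrow(ev) > 1 && merge_gap_bp > 0) {
    gap_bp <- profile$site_pos[ev$start[-1]] -
      profile$site_pos[ev$end[-nrow(ev)]]
    same_ctg <- profile$contig[ev$start[-1]] == profile$contig[ev$end[-nrow(ev)]]
    merge <- gap_bp < merge_gap_bp & same_ctg
    grp <- cumsum(c(TRUE, !merge))
    ev <- data.frame(start = tapply(ev$start, grp, min),
                     end = tapply(ev$end, grp, max))
  }
  if (nrow(ev)) {
    cd <- c(0, cumsum(x))
    nsnv <- cd[ev$end + 1] - cd[ev$start]
    ev <- ev[nsnv >= min_snvs, , drop = FALSE]
  }
  events <- empty_events
  if (nrow(ev)) {
    cd <- c(0, cumsum(x))
    nsnv <- as.integer(cd[ev$end + 1] - cd[ev$start])
    len_sites <- ev$end - ev$start + 1L
    # bp bounds extended half-way to the flanking compared sites, so that
    # length_bp reflects the local density of synonymous sites
    sp <- profile$site_pos
    start_bp <- sp[ev$start]
    has_prev <- ev$start > 1
    start_bp[has_prev] <- (sp[ev$start[has_prev] - 1] + sp[ev$start[has_prev]]) / 2
    end_bp <- sp[ev$end]
    has_next <- ev$end < n
    end_bp[has_next] <- (sp[ev$end[has_next]] + sp[ev$end[has_next] + 1]) / 2
    events <- data.frame(start_site = as.integer(ev$start),
                         end_site = as.integer(ev$end),
                         start_bp = start_bp, end_bp = end_bp,
                         length_sites = as.integer(len_sites),
                         length_bp = end_bp - start_bp,
                         n_snvs = nsnv,
                         local_div = nsnv / len_sites,
                         clade_label = NA_character_,
                         is_duplicate = FALSE)
  }

  base$d_clonal_hat <- fit$d_clonal
  base$clonal_fraction <- 1 - sum(events$length_sites) / n
  base$events <- events
  base$loglik <- fit$loglik
  base$n_em_iters <- fit$n_iters
  base$converged <- fit$converged
  base$t_enter <- fit$t_enter
  base$t_exit <- fit$t_exit
  base$post_recomb_mean <- mean(fit$post_recomb)
  base$loglik_trace <- fit$loglik_trace
  structure(base, class = "pair_decoding")
}

segments_from_logical <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start[r$values], end = end[r$values])
}

#' @export
print.pair_decoding <- function(x, ...) {
  cat("pair_decoding", paste(x$pair, collapse = " vs "), "\n",
      " status:", x$status, "\n",
      " d_clonal_hat =", signif(x$d_clonal_hat, 3),
      " clonal_fraction =", signif(x$clonal_fraction, 3),
      " events =", nrow(x$events),
      " converged =", x$converged, "\n")
  invisible(x)
}

#' Classify a transfer as within- or between-clade
#'
#' Labels an event `"between"` when its local divergence exceeds the
#' geometric midpoint `sqrt(within_div * between_div)` of the two clade
#' divergence scales (divergences are log-spread, so the geometric mean is the
#' natural decision boundary), `"within"` otherwise, and `NA` when the species
#' has no clade structure.
#'
#' @param local_div local synonymous divergence of the event (scalar or
#'   vector).
#' @param within_div,between_div characteristic within-/between-clade
#'   divergences; `NA` for species without clade structure.
#' @return Character vector of `"within"` / `"between"` / `NA`.
#' @export
classify_transfer_clade <- function(local_div, within_div, between_div) {
  if (is.na(within_div) || is.na(between_div))
    return(rep(NA_character_, length(local_div)))
  if (within_div >= between_div)
    stop("within_div must be smaller than between_div")
  midpoint <- sqrt(within_div * between_div)
  ifelse(local_div > midpoint, "between", "within")
}

#' Select close pairs by clonal divergence and clonal fraction
#'
#' Keeps decodings with `d_clonal_hat <= d_star` and
#' `clonal_fraction >= fc_star`; everything else is reported with the reason
#' for exclusion.  Defaults follow the generic thresholds used when no
#' species-specific values are supplied.
#'
#' @param decodings list of `pair_decoding` objects.
#' @param d_star clonal divergence threshold (default 1e-4).
#' @param fc_star clonal fraction threshold (default 0.2).
#' @return list with `kept` (decodings) and `excluded` (data.frame of pair,
#'   `d_clonal_hat`, `clonal_fraction`, `reason`).
#' @export
select_close_pairs <- function(decodings, d_star = 1e-4, fc_star = 0.2) {
  reason <- vapply(decodings, function(d) {
    if (d$status != "ok" && !startsWith(d$status, "ok")) "rejected"
    else if (is.na(d$d_clonal_hat)) "rejected"
    else if (d$d_clonal_hat > d_star) "d_clonal above d_star"
    else if (d$clonal_fraction < fc_star) "clonal fraction below fc_star"
    else "kept"
  }, character(1))
  excluded <- data.frame(
    strain_a = vapply(decodings, function(d) d$pair[1], character(1)),
    strain_b = vapply(decodings, function(d) d$pair[2], character(1)),
    d_clonal_hat = vapply(decodings, function(d) d$d_clonal_hat, numeric(1)),
    clonal_fraction = vapply(decodings, function(d) d$clonal_fraction, numeric(1)),
    reason = reason)[reason != "kept", ]
  list(kept = decodings[reason == "kept"], excluded = excluded)
}

#' Flag duplicate transfer events across pairs
#'
#' Two events are duplicates when their pairs share a strain, their reciprocal
#' bp overlap is at least `overlap_frac`, and their local divergences agree
#' within relative tolerance `div_tol` (the same ancestral transfer seen
#' through two different partners).  Within each duplicate cluster all but one
#' event are flagged `is_duplicate = TRUE`.
#'
#' @param events data.frame with columns `strain_a`, `strain_b`, `start_bp`,
#'   `end_bp`, `local_div` (one row per event, as produced by
#'   [decode_pair_cohort()]).
#' @param overlap_frac reciprocal overlap threshold (default 0.8).
#' @param div_tol relative local-divergence tolerance (default 0.3).
#' @return The events data.frame with `is_duplicate` filled in.
#' @export
flag_duplicate_transfers <- function(events, overlap_frac = 0.8, div_tol = 0.3) {
  n <- nrow(events)
  events$is_duplicate <- rep(FALSE, n)
  if (n < 2) return(events)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      share <- length(intersect(c(events$strain_a[i], events$strain_b[i]),
                                c(events$strain_a[j], events$strain_b[j]))) > 0
      if (!share) next
      ov <- min(events$end_bp[i], events$end_bp[j]) -
        max(events$start_bp[i], events$start_bp[j])
      if (ov <= 0) next
      li <- events$end_bp[i] - events$start_bp[i]
      lj <- events$end_bp[j] - events$start_bp[j]
      if (ov / li < overlap_frac || ov / lj < overlap_frac) next
      dmax <- max(events$local_div[i], events$local_div[j])
      if (dmax > 0 &&
          abs(events$local_div[i] - events$local_div[j]) / dmax > div_tol) next
      parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  first_of_root <- !duplicated(root)
  events$is_duplicate <- !first_of_root
  events
}

#' Decode all candidate pairs of a cohort
#'
#' Convenience driver: computes difference profiles and runs
#' [fit_decode_pair()] for every between-host strain pair (or a supplied list
#' of pairs), returning the decodings and a combined events table.
#'
#' @param genomes a [core_genome_set()].
#' @param emissions an [empirical_div_dist()].
#' @param pairs optional 2-column matrix/data.frame of strain ids.
#' @param ... passed to [fit_decode_pair()].
#' @return list with `decodings` (list) and `events` (data.frame with
#'   `strain_a`/`strain_b` columns prepended).
#' @export
decode_pair_cohort <- function(genomes, emissions, pairs = NULL, ...) {
  meta <- genomes$strain_meta
  if (is.null(pairs)) {
    pr <- all_pairs(meta$strain_id)
    pr <- pr[meta$host_id[pr[, 1]] != meta$host_id[pr[, 2]], , drop = FALSE]
    pairs <- cbind(meta$strain_id[pr[, 1]], meta$strain_id[pr[, 2]])
  }
  pairs <- as.matrix(pairs)
  decs <- vector("list", nrow(pairs))
  evs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    prof <- pair_difference_profile(genomes, pairs[i, 1], pairs[i, 2])
    d <- fit_decode_pair(prof, emissions, ...)
    decs[[i]] <- d
    if (nrow(d$events))
      evs[[i]] <- cbind(strain_a = pairs[i, 1], strain_b = pairs[i, 2],
                        d$events)
  }
  events <- if (length(ev <- evs[!vapply(evs, is.null, logical(1))]))
    do.call(rbind, ev) else NULL
  list(decodings = decs, events = events)
}

#' Write transfer events and pair decodings as TSV
#'
#' @param events events data.frame (with `strain_a`/`strain_b`).
#' @param decodings list of `pair_decoding`.
#' @param path output path.
#' @param species species label written into every row.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(events, path, species = "unknown") {
  df <- if (is.null(events) || !nrow(events))
    data.frame(species = character(0), strain_a = character(0),
               strain_b = character(0), between_clade = character(0),
               divergence = numeric(0), start_bp = numeric(0),
               end_bp = numeric(0), length_bp = numeric(0),
               n_snvs = integer(0), is_duplicate = logical(0))
  else data.frame(species = species, strain_a = events$strain_a,
                  strain_b = events$strain_b,
                  between_clade = ifelse(is.na(events$clade_label), "NA",
                                         ifelse(events$clade_label == "between", "Y", "N")),
                  divergence = events$local_div,
                  start_bp = events$start_bp, end_bp = events$end_bp,
                  length_bp = events$length_bp, n_snvs = events$n_snvs,
                  is_duplicate = events$is_duplicate)
  write_tsv(df, path, comment = paste0("transfer events; species=", species))
}

#' @rdname write_events_tsv
#' @export
write_decodings_tsv <- function(decodings, path, species = "unknown") {
  df <- data.frame(
    species = species,
    strain_a = vapply(decodings, function(d) d$pair[1], character(1)),
    strain_b = vapply(decodings, function(d) d$pair[2], character(1)),
    d_clonal_hat = vapply(decodings, function(d) d$d_clonal_hat, numeric(1)),
    clonal_fraction = vapply(decodings, function(d) d$clonal_fraction, numeric(1)),
    n_events = vapply(decodings, function(d) nrow(d$events), integer(1)),
    loglik = vapply(decodings, function(d) d$loglik, numeric(1)),
    converged = vapply(decodings, function(d) d$converged, logical(1)),
    status = vapply(decodings, function(d) d$status, character(1)))
  write_tsv(df, path, comment = paste0("pair decodings; species=", species))
}
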