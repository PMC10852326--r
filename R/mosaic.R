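#' Accumulated-transfers (mosaic) model parameters
#'
#' The model treats a pair's genome as a clonal backbone progressively
#' overwritten by transfers: with clonal divergence `d_cl` the surviving
#' clonal fraction is `c = exp(-kappa * d_cl)` and the overwritten remainder
#' carries the typical divergence `d_bar_r` of the donor pool.  `kappa` is the
#' recombination-to-mutation overwrite ratio per unit clonal divergence (for a
#' transfer rate of R events per unit clonal divergence and mean tract length
#' l_r over a genome of L sites, `kappa = R * l_r / L`).
#'
#' @param kappa overwrite ratio (>= 0).
#' @param d_bar_r mean divergence of recombined sequence (> 0).
#' @param block_size synonymous sites per identity block (default 1000).
#' @return A `mosaic_params` list.
#' @export
mosaic_params <- function(kappa, d_bar_r, block_size = 1000) {
  stopifnot(kappa >= 0, d_bar_r > 0)
  structure(list(kappa = kappa, d_bar_r = d_bar_r, block_size = block_size),
            class = "mosaic_params")
}

#' Expected genome-wide divergence at a given clonal fraction
#'
#' Inverts `c = exp(-kappa * d_cl)` to `d_cl = -log(c)/kappa` and returns
#' `d(c) = c * d_cl + (1 - c) * d_bar_r`: the clonal backbone contributes its
#' own divergence, the overwritten fraction contributes the donor-pool
#' divergence.  `c = 1` gives 0 (no time elapsed) and `c -> 0` gives
#' `d_bar_r` (fully overwritten).
#'
#' @param c clonal fraction(s) in \[0, 1\].
#' @param params a [mosaic_params()].
#' @return Expected divergence, same length as `c`.
#' @export
mosaic_expected_divergence <- function(c, params) {
  stopifnot(all(c >= 0 & c <= 1))
  if (params$kappa == 0) {
    if (any(c < 1))
      stop("kappa = 0 (no recombination) cannot produce clonal fraction < 1")
    return(rep(0, length(c)))
  }
  out <- ifelse(c == 0, params$d_bar_r,
                c * (-log(c) / params$kappa) + (1 - c) * params$d_bar_r)
  out[c == 1] <- 0
  out
}

#' Expected fraction of identical blocks
#'
#' A block of `block_size` synonymous sites is identical iff it is clonal and
#' mutation-free: `f_id = c * exp(-block_size * d_cl)` (edge effects ignored;
#' recombined blocks carry typical divergence with `d_bar_r * B >> 1` and so
#' are essentially never identical).
#'
#' @param c clonal fraction in \[0, 1\].
#' @param d_cl clonal divergence per site.
#' @param block_size sites per block.
#' @return Expected identical-block fraction.
#' @export
identical_fraction_expected <- function(c, d_cl, block_size = 1000) {
  stopifnot(all(c >= 0 & c <= 1), all(d_cl >= 0))
  c * exp(-block_size * d_cl)
}

#' Fit the mosaic model to an (identical-block fraction, divergence) cloud
#'
#' Weighted least squares of observed genome-wide divergence against the
#' mosaic expectation.  For a trial `kappa` each pair's latent clonal
#' divergence is recovered jointly from its identical-block fraction by
#' inverting `f_id = exp(-(kappa + B) * d_cl)` (clonal fraction and
#' mutation-free probability together), avoiding the bias of a two-step
#' plug-in when `d_cl` is non-negligible; `d_bar_r` then has a closed-form
#' weighted solution and `kappa` is profiled by 1-D optimization on a log
#' scale.  Default weights are the inverse local density of points along the
#' `f_id` axis, so dense near-clonal pairs do not dominate the fit.
#'
#' @param f_id per-pair identical-block fractions.
#' @param d per-pair genome-wide synonymous divergences.
#' @param block_size sites per block used for `f_id`.
#' @param weights optional per-pair weights (default: inverse `f_id` density).
#' @param kappa_range log10 search interval for kappa.
#' @return A `mosaic_fit`: `params`, `weighted_var_explained`, `n_pairs`,
#'   `identifiable` (FALSE when kappa runs into the search boundary or the
#'   cloud is degenerate).
#' @export
fit_mosaic <- function(f_id, d, block_size = 1000, weights = NULL,
                       kappa_range = c(0, 6)) {
  ok <- is.finite(f_id) & is.finite(d) & f_id > 0 & f_id <= 1
  f_id <- f_id[ok]; d <- d[ok]
  if (length(f_id) < 10)
    stop("need >= 10 pairs with positive identical-block fraction")
  if (diff(range(f_id)) < 1e-6) {
    return(structure(list(params = mosaic_params(0, max(mean(d), 1e-8), block_size),
                          weighted_var_explained = NA_real_,
                          n_pairs = length(f_id), identifiable = FALSE),
                     class = "mosaic_fit"))
  }
  if (is.null(weights)) {
    dens <- density(f_id, bw = "nrd0")
    w <- 1 / pmax(stats::approx(dens$x, dens$y, xout = f_id, rule = 2)$y, 1e-8)
    w <- w / mean(w)
  } else w <- weights

  sse_for <- function(log10_kappa) {
    kappa <- 10^log10_kappa
    d_cl <- -log(f_id) / (kappa + block_size)
    cc <- exp(-kappa * d_cl)
    y <- d - cc * d_cl
    z <- 1 - cc
    dbar <- max(sum(w * z * y) / max(sum(w * z^2), 1e-12), 1e-8)
    pred <- cc * d_cl + z * dbar
    list(sse = sum(w * (d - pred)^2), dbar = dbar)
  }
  opt <- optimize(function(lk) sse_for(lk)$sse,
                  interval = kappa_range, tol = 1e-4)
  kappa <- 10^opt$minimum
  sol <- sse_for(opt$minimum)
  wmean <- sum(w * d) / sum(w)
  sstot <- sum(w * (d - wmean)^2)
  ve <- 1 - sol$sse / sstot
  at_boundary <- opt$minimum < kappa_range[1] + 0.05 ||
    opt$minimum > kappa_range[2] - 0.05
  # ridge check: if the no-recombination boundary fits essentially as well,
  # kappa is not identified (pure-mutation cohorts land here)
  sse_clonal <- sse_for(kappa_range[1])$sse
  flat_ridge <- (sse_clonal - sol$sse) < 0.01 * sstot
  structure(list(params = mosaic_params(kappa, sol$dbar, block_size),
                 weighted_var_explained = ve, n_pairs = length(f_id),
                 identifiable = !at_boundary && !flat_ridge),
            class = "mosaic_fit")
}

#' @export
print.mosaic_fit <- function(x, ...) {
  cat("mosaic_fit: kappa =", signif(x$params$kappa, 4),
      " d_bar_r =", signif(x$params$d_bar_r, 4),
      " T_mrca/T_mosaic =", signif(x$params$kappa * x$params$d_bar_r, 3),
      "\n weighted var explained =", signif(x$weighted_var_explained, 3),
      " n_pairs =", x$n_pairs,
      if (!x$identifiable) " [NOT identifiable]" else "", "\n")
  invisible(x)
}

#' Ratio of coalescence time to mosaic (full-overwrite) time
#'
#' In clonal-divergence units the mosaic time is `1/kappa` (clonal fraction
#' decayed to 1/e) and the typical pair coalescence time is proxied by
#' `d_bar_r` (the divergence recombined regions carry reflects typical
#' coalescence), so the ratio is `kappa * d_bar_r`.  Values much greater than
#' one mean typical genomes are completely overwritten by recombination.
#'
#' @param fit a `mosaic_fit`.
#' @return The ratio `T_mrca / T_mosaic`.
#' @export
tmrca_over_tmosaic <- function(fit) {
  stopifnot(inherits(fit, "mosaic_fit"))
  if (!fit$identifiable)
    stop("mosaic fit is not identifiable; ratio undefined")
  fit$params$kappa * fit$params$d_bar_r
}

#' Neutral expectation for the fraction of partially recombined pairs
#'
#' Under a neutral coalescent, a pair is "partially recombined" (close) when
#' its coalescence time is below the mosaic time.  With pair times
#' standardized to Exp(1), that probability is `P(Exp(1) < ratio)` with
#' `ratio = T_mosaic / T_mrca`; this routine estimates it by Monte Carlo over
#' samples of `choose(n_sample, 2)` pair times and reports a CI over
#' replicates.
#'
#' @param ratio_mosaic_over_mrca positive ratio `T_mosaic / T_mrca`.
#' @param n_sample number of strains per replicate sample.
#' @param reps Monte Carlo replicates (>= 100).
#' @param seed integer seed or `NULL`.
#' @return list with `estimate`, `ci` (2.5/97.5 percentiles over replicates)
#'   and `reps`.
#' @export
neutral_close_pair_fraction <- function(ratio_mosaic_over_mrca, n_sample = 30,
                                        reps = 1000, seed = NULL) {
  stopifnot(ratio_mosaic_over_mrca > 0, reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- choose(n_sample, 2)
  fr <- vapply(seq_len(reps), function(i)
    mean(rexp(n_pairs) < ratio_mosaic_over_mrca), numeric(1))
  list(estimate = mean(fr),
       ci = unname(quantile(fr, c(0.025, 0.975))), reps = reps)
}
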