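#' Local-regression trend of transfer accumulation versus clonal divergence
#'
#' Nadaraya-Watson kernel regression (Gaussian kernel in log10 clonal
#' divergence, default bandwidth 0.25 decades) of a per-pair response --
#' number of detected transfers or cumulative recombined length -- against the
#' pair's clonal divergence, with a local weighted-SD spread band.
#'
#' @param decodings list of `pair_decoding` objects (close pairs).
#' @param bandwidth kernel bandwidth in decades of clonal divergence.
#' @param response `"count"` (number of events) or `"cumulative_length"`
#'   (total recombined bp).
#' @param grid_n number of grid points.
#' @param min_pairs minimum number of pairs required (default 20).
#' @return A `trend_curve`: `x` (clonal divergence grid), `mean`, `spread`
#'   (local SD), `bandwidth`, `n_pairs`.
#' @export
transfer_trend <- function(decodings, bandwidth = 0.25,
                           response = c("count", "cumulative_length"),
                           grid_n = 50, min_pairs = 20) {
  response <- match.arg(response)
  x <- vapply(decodings, function(d) d$d_clonal_hat, numeric(1))
  y <- vapply(decodings, function(d) {
    ev <- d$events[!d$events$is_duplicate, , drop = FALSE]
    if (response == "count") nrow(ev) else sum(ev$length_bp)
  }, numeric(1))
  ok <- is.finite(x) & x > 0 & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_pairs)
    stop("need >= ", min_pairs, " close pairs with positive clonal divergence")
  lx <- log10(x)
  if (bandwidth > diff(range(lx)))
    stop("bandwidth (", bandwidth, " decades) exceeds the clonal divergence ",
         "range of the data (", signif(diff(range(lx)), 3), " decades)")
  grid <- seq(min(lx), max(lx), length.out = grid_n)
  mean_y <- numeric(grid_n); sd_y <- numeric(grid_n)
  for (i in seq_len(grid_n)) {
    w <- exp(-0.5 * ((lx - grid[i]) / bandwidth)^2)
    sw <- sum(w)
    m <- sum(w * y) / sw
    mean_y[i] <- m
    sd_y[i] <- sqrt(max(sum(w * (y - m)^2) / sw, 0))
  }
  structure(list(x = 10^grid, mean = mean_y, spread = sd_y,
                 bandwidth = bandwidth, response = response,
                 n_pairs = length(x)),
            class = "trend_curve")
}

#' Evaluate a trend curve at given clonal divergences
#'
#' Linear interpolation on the log-divergence axis; values outside the trend
#' support are `NA`.
#'
#' @param trend a `trend_curve`.
#' @param d_c clonal divergence(s).
#' @return Interpolated mean response.
#' @export
eval_trend <- function(trend, d_c) {
  stats::approx(log10(trend$x), trend$mean, xout = log10(d_c), rule = 1)$y
}

#' Apparent recombination rate
#'
#' Number of transfers per unit clonal divergence per bp of core genome,
#' `rate = n_transfers / (d_c * L_bp)`.  In `trend` mode (recommended for
#' species with > 100 close pairs) the transfer count is the trend-curve value
#' at each reference divergence `d_c` (default 2.5, 5, 7.5, 10 x 1e-5).  In
#' `per_pair` mode the rate is computed for every pair from its own
#' `d_clonal_hat` and the distribution is returned.
#'
#' @param x a `trend_curve` (trend mode) or list of `pair_decoding`
#'   (per-pair mode).
#' @param L_bp core genome length in bp.
#' @param d_c reference clonal divergences (trend mode).
#' @return data.frame `d_c`, `rate` (trend mode; `NA` outside support), or
#'   data.frame `strain_a`, `strain_b`, `d_c`, `rate` (per-pair mode).
#' @export
apparent_rate <- function(x, L_bp, d_c = c(2.5, 5, 7.5, 10) * 1e-5) {
  stopifnot(all(d_c > 0), L_bp > 0)
  if (inherits(x, "trend_curve")) {
    n_at <- eval_trend(x, d_c)
    return(data.frame(d_c = d_c, rate = n_at / (d_c * L_bp)))
  }
  stopifnot(is.list(x))
  dd <- vapply(x, function(d) d$d_clonal_hat, numeric(1))
  nn <- vapply(x, function(d) sum(!d$events$is_duplicate), numeric(1))
  pa <- vapply(x, function(d) d$pair[1], character(1))
  pb <- vapply(x, function(d) d$pair[2], character(1))
  ok <- is.finite(dd) & dd > 0
  data.frame(strain_a = pa[ok], strain_b = pb[ok], d_c = dd[ok],
             rate = nn[ok] / (dd[ok] * L_bp))
}

#' Transfer length summary
#'
#' Median, interquartile range and full sample of event lengths in bp,
#' excluding events flagged as duplicates.
#'
#' @param events events data.frame (needs `length_bp`, `is_duplicate`).
#' @return list with `median`, `iqr` (lower/upper quartiles), `n`, `lengths`.
#' @export
transfer_length_summary <- function(events) {
  ev <- events[!events$is_duplicate, , drop = FALSE]
  if (!nrow(ev)) stop("no non-duplicate events")
  q <- unname(quantile(ev$length_bp, c(0.25, 0.5, 0.75)))
  list(median = q[2], iqr = q[c(1, 3)], n = nrow(ev), lengths = ev$length_bp)
}

#' Donor-divergence distribution of detected transfers versus a random null
#'
#' For each detected event, draws `n_draws_per_event` segments of the same
#' length at uniform positions from uniformly chosen strains (excluding the
#' focal pair, whose genomes define the clonal background) and computes their
#' synonymous divergence to the recipient strain.  The pooled null is compared
#' with the observed transfer divergences by a one-sided two-sample
#' Kolmogorov-Smirnov test oriented to detect a *deficit* of high-divergence
#' transfers (observed shifted low), the signature of genetically isolated
#' clades.
#'
#' @param genomes a [core_genome_set()].
#' @param events events data.frame with `strain_a`, `strain_b`, `start_site`,
#'   `end_site` (site indices into the synonymous-site profile), `length_sites`
#'   and `local_div`.
#' @param n_draws_per_event null segments per event (default 10).
#' @param seed integer seed or `NULL`.
#' @return A `divergence_distributions` list: `observed`, `null`,
#'   `ks_distance`, `p_value`.
#' @export
donor_divergence_null <- function(genomes, events, n_draws_per_event = 10,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(events) >= 1)
  syn <- which(genomes$sites$is_synonymous)
  hap <- genomes$haplotypes[, syn, drop = FALSE]
  n_syn <- ncol(hap)
  strains <- rownames(hap)
  if (length(strains) < 3) stop("need >= 3 strains to draw null segments")
  if (any(events$length_sites > n_syn))
    stop("event longer than the synonymous-site genome")
  null_div <- numeric(0)
  for (i in seq_len(nrow(events))) {
    len <- events$length_sites[i]
    recipient <- events$strain_a[i]
    others <- setdiff(strains, c(events$strain_a[i], events$strain_b[i]))
    donors <- sample(others, n_draws_per_event, replace = TRUE)
    starts <- sample.int(n_syn - len + 1L, n_draws_per_event, replace = TRUE)
    for (j in seq_len(n_draws_per_event)) {
      sel <- starts[j]:(starts[j] + len - 1L)
      a <- hap[recipient, sel]; b <- hap[donors[j], sel]
      obs <- !is.na(a) & !is.na(b)
      null_div <- c(null_div, mean(a[obs] != b[obs]))
    }
  }
  observed <- events$local_div
  # two-sided distance summarises the difference; the p-value is one-sided
  # for a deficit of high-divergence transfers (observed shifted low)
  kt2 <- suppressWarnings(ks.test(observed, null_div))
  kt1 <- suppressWarnings(ks.test(observed, null_div, alternative = "greater"))
  structure(list(observed = observed, null = null_div,
                 ks_distance = unname(kt2$statistic),
                 p_value = kt1$p.value),
            class = "divergence_distributions")
}
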