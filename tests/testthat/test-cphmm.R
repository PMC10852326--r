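test_that("empirical divergence distribution reflects the population structure", {
  set.seed(21)
  # uniform ~1% population -> mass concentrated at 0.01
  g <- simulate_star_population(n = 12, L_sites = 5e4, d_bar = 0.01)
  em <- estimate_empirical_divergence(g, window_bp = 2000, max_pairs = 30)
  m <- sum(em$bin_div * em$bin_probs)
  expect_lt(abs(m - 0.01), 0.004)

  # two clades (1% within, 10% between)
  g2 <- simulate_two_clade_population(n_per_clade = 8, L_sites = 5e4)
  em_b <- estimate_empirical_divergence(g2, window_bp = 2000,
                                        clade_pairing = "between")
  expect_lt(abs(sum(em_b$bin_div * em_b$bin_probs) - 0.10), 0.03)
  em_w <- estimate_empirical_divergence(g2, window_bp = 2000,
                                        clade_pairing = "within")
  expect_lt(abs(sum(em_w$bin_div * em_w$bin_probs) - 0.01), 0.005)

  # pooled: bimodal, with mass near both modes
  em_p <- estimate_empirical_divergence(g2, window_bp = 2000, max_pairs = 60)
  lo <- sum(em_p$bin_probs[em_p$bin_div < 0.03])
  hi <- sum(em_p$bin_probs[em_p$bin_div > 0.05])
  expect_gt(lo, 0.15); expect_gt(hi, 0.15)

  # too few typically diverged pairs -> instructive error
  g3 <- simulate_star_population(n = 3, L_sites = 1e4, d_bar = 0.01)
  expect_error(estimate_empirical_divergence(g3), "parametric")
})

test_that("decoding a zero-difference profile is the trivial fixed point", {
  em <- two_mode_emissions()
  dec <- fit_decode_pair(profile_from_diff(integer(2e4)), em)
  expect_equal(dec$d_clonal_hat, 0)
  expect_equal(dec$clonal_fraction, 1)
  expect_equal(nrow(dec$events), 0)
  expect_true(dec$converged)
})

test_that("a single planted transfer is recovered with >= 90% reciprocal overlap", {
  em <- two_mode_emissions()
  set.seed(22)
  sim <- simulate_pair(pair_sim_config(L_sites = 2e5, mu_t = 5e-5, gamma_t = 1,
                                       mean_frag_sites = 2e4,
                                       donor_div_dist = div_dist_constant(0.01),
                                       constant_frag = TRUE))
  stopifnot(nrow(sim$truth) == 1)
  dec <- fit_decode_pair(sim$profile, em)
  expect_equal(nrow(dec$events), 1)
  ov <- min(dec$events$end_site, sim$truth$end_site) -
    max(dec$events$start_site, sim$truth$start_site) + 1
  expect_gte(ov / sim$truth$length_sites, 0.9)
  expect_gte(ov / dec$events$length_sites, 0.9)

  # EM log-likelihood is non-decreasing
  expect_true(all(diff(dec$loglik_trace) > -1e-6 * abs(dec$loglik)))

  # bookkeeping identity: f_c + recombined/total = 1
  expect_equal(dec$clonal_fraction + sum(dec$events$length_sites) / 2e5, 1)
})

test_that("decoding is invariant under coordinate reversal", {
  em <- two_mode_emissions()
  set.seed(23)
  sim <- simulate_pair(pair_sim_config(L_sites = 2e5, mu_t = 5e-5, gamma_t = 4,
                                       mean_frag_sites = 1e4,
                                       donor_div_dist = div_dist_constant(0.02)))
  d1 <- fit_decode_pair(sim$profile, em)
  d2 <- fit_decode_pair(reverse_profile(sim$profile), em)
  expect_equal(nrow(d1$events), nrow(d2$events))
  expect_equal(d1$clonal_fraction, d2$clonal_fraction, tolerance = 1e-8)
  n <- length(sim$profile$diff)
  expect_equal(sort(n - d1$events$end_site + 1L),
               sort(d2$events$start_site))
})

test_that("clonal-only pairs yield (almost) no false events", {
  em <- two_mode_emissions()
  set.seed(24)
  n_ev <- replicate(40, {
    prof <- profile_from_diff(rbinom(1e5, 1, 5e-5))
    nrow(fit_decode_pair(prof, em)$events)
  })
  expect_lte(mean(n_ev), 0.05)
})

test_that("pairs outside the close-pair regime are rejected with a diagnostic", {
  em <- two_mode_emissions()
  set.seed(25)
  prof <- profile_from_diff(rbinom(5e4, 1, 0.03))
  dec <- fit_decode_pair(prof, em)
  expect_match(dec$status, "rejected")
  expect_true(is.na(dec$d_clonal_hat))
})

test_that("clade classification uses the geometric midpoint", {
  expect_equal(classify_transfer_clade(0.009, 0.01, 0.10), "within")
  expect_equal(classify_transfer_clade(0.09, 0.01, 0.10), "between")
  # midpoint sqrt(0.001) ~ 0.0316
  expect_equal(classify_transfer_clade(c(0.03, 0.033), 0.01, 0.10),
               c("within", "between"))
  expect_true(is.na(classify_transfer_clade(0.05, NA, NA)))
  expect_error(classify_transfer_clade(0.05, 0.1, 0.01), "smaller")
})

test_that("close-pair selection equals brute-force thresholding", {
  mk <- function(d, fc) structure(list(pair = c("a", "b"), d_clonal_hat = d,
                                       clonal_fraction = fc,
                                       events = data.frame(), status = "ok"),
                                  class = "pair_decoding")
  set.seed(26)
  ds <- 10^runif(30, -5, -3); fcs <- runif(30)
  decs <- mapply(mk, ds, fcs, SIMPLIFY = FALSE)
  sel <- select_close_pairs(decs, d_star = 1e-4, fc_star = 0.2)
  expect_equal(length(sel$kept), sum(ds <= 1e-4 & fcs >= 0.2))
  expect_true(all(sel$excluded$reason != "kept"))
  # single-threshold cases
  expect_equal(length(select_close_pairs(list(mk(2e-4, 0.9)))$kept), 0)
  expect_equal(length(select_close_pairs(list(mk(5e-5, 0.05)))$kept), 0)
})

test_that("duplicate flagging requires a shared strain, overlap and matching divergence", {
  ev <- data.frame(strain_a = c("A", "A", "D"), strain_b = c("B", "C", "E"),
                   start_bp = c(100, 100, 100), end_bp = c(2100, 2100, 2100),
                   local_div = c(0.01, 0.0105, 0.01), is_duplicate = FALSE)
  out <- flag_duplicate_transfers(ev)
  expect_equal(out$is_duplicate, c(FALSE, TRUE, FALSE))  # (D,E) shares no strain

  # 60% overlap below the 0.8 threshold -> not duplicates
  ev2 <- data.frame(strain_a = c("A", "A"), strain_b = c("B", "C"),
                    start_bp = c(0, 800), end_bp = c(2000, 2800),
                    local_div = c(0.01, 0.01), is_duplicate = FALSE)
  expect_equal(flag_duplicate_transfers(ev2, overlap_frac = 0.8)$is_duplicate,
               c(FALSE, FALSE))

  # divergence mismatch blocks the flag
  ev3 <- ev[1:2, ]; ev3$local_div <- c(0.01, 0.05)
  expect_equal(flag_duplicate_transfers(ev3)$is_duplicate, c(FALSE, FALSE))
})
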