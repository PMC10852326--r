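test_that("identity runs partition the genome and bound the bookkeeping", {
  rs0 <- identical_runs(profile_from_diff(integer(1e4)))
  expect_equal(nrow(rs0$runs), 1)
  expect_equal(rs0$longest_run, 1e4)

  rs1 <- identical_runs(profile_from_diff(rep(1L, 50)))
  expect_equal(rs1$longest_run, 0)

  set.seed(51)
  d <- rbinom(5e4, 1, 0.005)
  rs <- identical_runs(profile_from_diff(d))
  # sum of run lengths + number of SNVs = total compared sites
  expect_equal(sum(rs$runs$length_sites) + rs$n_snvs, 5e4)
  expect_equal(total_run_length_above(rs, 0), sum(rs$runs$length_sites))
  expect_gte(total_run_length_above(rs, 500),
             max(rs$runs$length_sites) * (rs$longest_run >= 500))
})

test_that("longest gap matches the order-statistics oracle ln(n)/d", {
  set.seed(52)
  d <- 0.01; L <- 1e5
  obs <- replicate(40, identical_runs(profile_from_diff(
    rbinom(L, 1, d)))$longest_run)
  # Monte-Carlo scatter oracle at the same SNV count
  null <- runs_null_random_scatter(round(L * d), L, reps = 200)$null
  expect_lt(abs(mean(obs) - mean(null)) / mean(null), 0.1)
  expect_lt(abs(mean(obs) - log(L * d) / d) / (log(L * d) / d), 0.25)
})

test_that("random-scatter null covers the degenerate cases and flags planted tracts", {
  n0 <- runs_null_random_scatter(0, 1000, reps = 10, seed = 53)
  expect_true(all(n0$null == 1000))
  nL <- runs_null_random_scatter(1000, 1000, reps = 10, seed = 53)
  expect_true(all(nL$null == 0))

  # planted 3e4-site identical tract on a 1% background
  set.seed(54)
  d <- rbinom(3e5, 1, 0.01)
  d[100001:130000] <- 0L
  rs <- identical_runs(profile_from_diff(d))
  null <- runs_null_random_scatter(sum(d), 3e5, reps = 999, seed = 55)
  expect_lte(null$p_value(rs$longest_run), 1e-3)
})

test_that("within/between longest-run comparison is correctly oriented", {
  set.seed(56)
  longest <- function(d) identical_runs(profile_from_diff(
    rbinom(5e4, 1, d)))$longest_run
  w_same <- replicate(20, longest(0.01))
  b_same <- replicate(40, longest(0.01))
  r <- compare_within_between_runs(w_same, b_same, seed = 57)
  expect_gt(r$p_value, 0.05)  # no signal from a common generator

  # between dominates within -> one-sided p near 1
  w_small <- replicate(20, longest(0.02))
  b_big <- replicate(40, longest(0.005))
  r2 <- compare_within_between_runs(w_small, b_big, seed = 58)
  expect_gt(r2$p_value, 0.9)

  # within dominates strongly -> significant
  w_big <- replicate(20, longest(0.004))
  r3 <- compare_within_between_runs(w_big, b_same, seed = 59)
  expect_lt(r3$p_value, 0.01)
  expect_true(compare_within_between_runs(w_same[1:3], b_same)$low_power)
})

test_that("sharing landscape matches counting oracles and its exchange identity", {
  # all strains identical -> p == 1 everywhere
  hap <- matrix(1L, nrow = 12, ncol = 3000)
  g <- core_genome_set(hap, data.frame(contig = "c", pos_bp = 1:3000,
                                       is_synonymous = TRUE),
                       data.frame(strain_id = sprintf("s%02d", 1:12),
                                  host_id = sprintf("h%02d", 1:12)))
  ls <- sharing_landscape(g, window_syn_sites = 500)
  expect_true(all(ls$p_share == 1))

  # independent scatters at d with window 15/d -> essentially zero sharing
  set.seed(60)
  g2 <- simulate_star_population(n = 12, L_sites = 2e4, d_bar = 0.02)
  ls2 <- sharing_landscape(g2, window_syn_sites = ceiling(15 / 0.02))
  expect_lt(mean(ls2$p_share), 1e-3)

  # exchange of summation order: mean_i p_i equals the mean per-pair
  # fraction of identical windows
  set.seed(61)
  g3 <- simulate_star_population(n = 8, L_sites = 5e3, d_bar = 0.005)
  w <- 401
  ls3 <- sharing_landscape(g3, window_syn_sites = w)
  meta <- g3$strain_meta
  pr <- corerecomb:::all_pairs(meta$strain_id)
  h <- w %/% 2
  per_pair <- sapply(seq_len(nrow(pr)), function(i) {
    dif <- g3$haplotypes[pr[i, 1], ] != g3$haplotypes[pr[i, 2], ]
    cm <- c(0, cumsum(dif))
    centers <- (h + 1):(5e3 - h)
    mean(cm[centers + h + 1] - cm[centers - h] == 0)
  })
  expect_equal(mean(ls3$p_share), mean(per_pair), tolerance = 1e-12)
})

test_that("landscape CV matches direct arithmetic and flags a zero mean", {
  ls <- structure(list(p_share = rep(0.2, 200)), class = "sharing_landscape")
  expect_equal(landscape_cv(ls), 0)
  p <- c(rep(0.01, 990), rep(0.5, 10))
  ls2 <- structure(list(p_share = p), class = "sharing_landscape")
  expect_equal(landscape_cv(ls2), sd(p) / mean(p))
  expect_gt(landscape_cv(ls2), 3)  # direct arithmetic oracle ~ 3.3
  ls0 <- structure(list(p_share = rep(0, 200)), class = "sharing_landscape")
  expect_warning(cv0 <- landscape_cv(ls0), "undefined")
  expect_true(is.na(cv0))
  expect_error(landscape_cv(structure(list(p_share = rep(0.1, 10)),
                                      class = "sharing_landscape")),
               "positions")
})

test_that("shared-fragment formula has the exact scaling exponents", {
  base <- expected_shared_fragments(1e6, 0.01, 0, 1000)
  expect_equal(expected_shared_fragments(1e6, 0.01, 0, 2000) / base, 1 / 4)
  expect_equal(expected_shared_fragments(1e6, 0.01, 1, 1000) / base, 1 / 4)
  expect_equal(expected_shared_fragments(2e6, 0.01, 0, 1000) / base, 2)
  expect_equal(expected_shared_fragments(1e6, 0.02, 0, 1000) / base, 1 / 2)
})

test_that("rotation permutation test orients concordance and discordance", {
  set.seed(62)
  # identical landscapes: concordant at the resolution of the null
  a <- stats::filter(rnorm(2000), rep(1, 50), circular = TRUE)
  pt <- hotspot_permutation_test(as.numeric(a), as.numeric(a), reps = 500,
                                 alternative = "concordance", seed = 63)
  expect_lte(pt$p_value, 2 / 500)
  pt2 <- hotspot_permutation_test(as.numeric(a), as.numeric(a), reps = 500,
                                  alternative = "discordance", seed = 63)
  expect_gt(pt2$p_value, 0.9)

  # independent landscapes: no signal either way
  b <- stats::filter(rnorm(2000), rep(1, 50), circular = TRUE)
  pt3 <- hotspot_permutation_test(as.numeric(a), as.numeric(b), reps = 500,
                                  alternative = "discordance", seed = 64)
  expect_gt(pt3$p_value, 0.02)
  expect_lt(pt3$p_value, 0.98)

  expect_error(hotspot_permutation_test(1:10, 1:9), "different lengths")
})
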