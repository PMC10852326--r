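test_that("pair simulator honours degenerate configs and analytic means", {
  sim0 <- simulate_pair(pair_sim_config(L_sites = 1e4, mu_t = 0, gamma_t = 0,
                                        seed = 1))
  expect_equal(sum(sim0$profile$diff), 0)
  expect_equal(nrow(sim0$truth), 0)

  # Bernoulli-sum oracle: mean SNV count = L * mu_t
  sim1 <- simulate_pair(pair_sim_config(L_sites = 1e6, mu_t = 5e-5,
                                        gamma_t = 0, seed = 2))
  expect_lt(abs(sum(sim1$profile$diff) - 50), 5 * sqrt(50))

  # coverage-process oracle: recombined fraction ~ 1 - exp(-gamma*frag/L)
  set.seed(3)
  fr <- replicate(60, simulate_pair(pair_sim_config(
    L_sites = 1e5, mu_t = 0, gamma_t = 10, mean_frag_sites = 2e3,
    donor_div_dist = div_dist_constant(0.01)))$recombined_fraction)
  expect_lt(abs(mean(fr) - (1 - exp(-0.2))), 4 * sd(fr) / sqrt(60) + 0.005)
})

test_that("pair simulator divergence decomposes into clonal and donor parts", {
  # E[d] = (1 - f_r) mu_t + f_r E[donor], with f_r the realized fraction
  set.seed(4)
  mu_t <- 1e-4; ddonor <- 0.02
  res <- t(replicate(100, {
    s <- simulate_pair(pair_sim_config(L_sites = 5e4, mu_t = mu_t,
                                       gamma_t = 5, mean_frag_sites = 2e3,
                                       donor_div_dist = div_dist_constant(ddonor)))
    c(d = s$profile$divergence, fr = s$recombined_fraction)
  }))
  pred <- (1 - res[, "fr"]) * mu_t + res[, "fr"] * ddonor
  err <- res[, "d"] - pred
  expect_lt(abs(mean(err)), 4 * sd(err) / sqrt(nrow(res)) + 1e-5)
})

test_that("truth records visible post-overlap segments inside bounds", {
  set.seed(5)
  sim <- simulate_pair(pair_sim_config(L_sites = 5e4, mu_t = 0, gamma_t = 30,
                                       mean_frag_sites = 5e3,
                                       donor_div_dist = div_dist_constant(0.05)))
  tr <- sim$truth
  expect_true(all(tr$start_site >= 1 & tr$end_site <= 5e4))
  expect_true(all(tr$end_site >= tr$start_site))
  # visible segments never overlap
  if (nrow(tr) > 1)
    expect_true(all(tr$start_site[-1] > tr$end_site[-nrow(tr)]))
  # SNV counts inside segments match the profile
  for (j in seq_len(nrow(tr)))
    expect_equal(sum(sim$profile$diff[tr$start_site[j]:tr$end_site[j]]),
                 tr$n_snvs[j])
})

test_that("seeded simulations are bit-reproducible", {
  a <- simulate_pair(pair_sim_config(L_sites = 1e4, seed = 11))
  b <- simulate_pair(pair_sim_config(L_sites = 1e4, seed = 11))
  expect_identical(a$profile$diff, b$profile$diff)
  expect_identical(a$truth, b$truth)

  p1 <- simulate_population(pop_sim_config(N = 30, n_sample = 5,
                                           L_sites = 2e3, seed = 12))
  p2 <- simulate_population(pop_sim_config(N = 30, n_sample = 5,
                                           L_sites = 2e3, seed = 12))
  expect_identical(p1$genomes$haplotypes, p2$genomes$haplotypes)
})

test_that("Moran model reduces to the clonal limit and matches pair-coalescence theory", {
  # mu = 0: all haplotypes identical
  s0 <- simulate_population(pop_sim_config(N = 30, n_sample = 10,
                                           L_sites = 2e3, mu = 0, seed = 13))
  expect_equal(length(unique(apply(s0$genomes$haplotypes, 1, paste,
                                   collapse = ""))), 1)

  # rho = 0: mean pairwise divergence ~ N * mu (pair TMRCA ~ N^2/2 events),
  # and per-pair identical-block fractions follow the exp(-B d) gray line
  set.seed(14)
  divs <- c(); fid_dev <- c()
  for (r in 1:6) {
    sim <- simulate_population(pop_sim_config(N = 60, n_sample = 12,
                                              L_sites = 2e4, mu = 2e-4, rho = 0))
    g <- sim$genomes
    pr <- corerecomb:::all_pairs(g$strain_meta$strain_id)
    for (i in seq_len(nrow(pr))) {
      p <- pair_difference_profile(g, g$strain_meta$strain_id[pr[i, 1]],
                                   g$strain_meta$strain_id[pr[i, 2]])
      divs <- c(divs, p$divergence)
      f <- fraction_identical_blocks(partition_blocks(p, 500))
      fid_dev <- c(fid_dev, f - exp(-500 * p$divergence))
    }
  }
  expect_lt(abs(mean(divs) - 60 * 2e-4), 0.25 * 60 * 2e-4)
  expect_lt(abs(mean(fid_dev)), 0.02)
})

test_that("sweep injection copies donor haplotypes as specified", {
  set.seed(15)
  g <- simulate_star_population(n = 20, L_sites = 5e3, d_bar = 0.02)
  region <- c(1000, 2000)

  # hard sweep, carrier fraction 1 -> region monomorphic
  g1 <- inject_sweep(g, region, mode = "hard", carrier_fraction = 1)
  reg <- g1$haplotypes[, region[1]:region[2]]
  expect_equal(nrow(unique(reg)), 1)

  # carrier fraction 0.5, n = 20 -> exactly 10 strains share the donor region
  g2 <- inject_sweep(g, region, mode = "hard", carrier_fraction = 0.5)
  carriers <- attr(g2, "carriers")[[1]]
  expect_equal(length(carriers), 10)
  donor_row <- g2$haplotypes[carriers[1], region[1]:region[2]]
  share <- apply(g2$haplotypes[, region[1]:region[2]], 1,
                 function(r) all(r == donor_row))
  expect_equal(sum(share), 10)

  # soft sweep with k = 3 -> at least 3 distinct haplotypes among carriers
  g3 <- inject_sweep(g, region, mode = "soft", k = 3, carrier_fraction = 0.6)
  cr <- unlist(attr(g3, "carriers"))
  haps <- apply(g3$haplotypes[cr, region[1]:region[2]], 1, paste, collapse = "")
  expect_gte(length(unique(haps)), 3)

  expect_error(inject_sweep(g, c(10, 5)), "region")
})

test_that("planted close pairs carry within-clade donor fragments only", {
  set.seed(16)
  g <- simulate_two_clade_population(n_per_clade = 6, L_sites = 3e4,
                                     d_within = 0.01, d_between = 0.10)
  pl <- plant_close_pairs(g, n_pairs = 3, d_clonal = 1e-4, gamma_t = 6,
                          mean_frag_sites = 2e3, donor_pool = "within")
  expect_equal(nrow(pl$genomes$haplotypes), 15)
  for (i in 1:3) {
    p <- pair_difference_profile(pl$genomes, pl$pairs[i, 1], pl$pairs[i, 2])
    # fragments come from ~1% donors, never the 10% clade -> divergence stays low
    expect_lt(p$divergence, 0.01)
  }
})
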