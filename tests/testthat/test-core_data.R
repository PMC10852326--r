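test_that("FASTA + annotation round trip preserves alleles, ids and masking", {
  g <- tiny_genomes()
  expect_equal(nrow(g$haplotypes), 3)
  expect_equal(ncol(g$haplotypes), 12)
  expect_equal(sum(g$sites$is_synonymous), 4)
  expect_true(is.na(g$haplotypes["b", 5]))  # 'N' masked

  fa <- tempfile(fileext = ".fa"); ts <- tempfile(fileext = ".tsv")
  write_core_alignment(g, fa, ts)
  g2 <- load_core_alignment(fa, ts, species_name = "tiny")
  expect_equal(g2$haplotypes, g$haplotypes)
  expect_equal(g2$strain_meta$strain_id, g$strain_meta$strain_id)
  expect_equal(g2$strain_meta$host_id, g$strain_meta$host_id)
  expect_equal(g2$sites$pos_bp, g$sites$pos_bp)
})

test_that("loader validates record lengths and annotation coverage", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1|h1", "ACGT", ">s2|h2", "ACG"), fa)
  ts <- tempfile(fileext = ".tsv")
  write.table(data.frame(contig = "c", pos_bp = 1:4, is_synonymous = 1),
              ts, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_core_alignment(fa, ts), "unequal lengths.*s2")

  writeLines(c(">s1|h1", "ACGT", ">s2|h2", "AGGT"), fa)
  ts2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(contig = "c", pos_bp = 1:3, is_synonymous = 1),
              ts2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_core_alignment(fa, ts2), "annotation covers 3 sites")

  ts3 <- tempfile(fileext = ".tsv")
  write.table(data.frame(contig = "c", pos_bp = 1:4), ts3, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_core_alignment(fa, ts3), "is_synonymous")

  empty <- tempfile(fileext = ".fa"); file.create(empty)
  expect_error(load_core_alignment(empty, ts), "empty FASTA")
})

test_that("difference profiles: divergence, masking arithmetic, symmetry", {
  g <- tiny_genomes()
  # identical strain against itself
  p_aa <- pair_difference_profile(g, "a", "a")
  expect_equal(sum(p_aa$diff), 0)
  expect_equal(p_aa$divergence, 0)

  # a vs b: synonymous sites are columns 1:4; column 5 is non-synonymous
  p_ab <- pair_difference_profile(g, "a", "b")
  expect_equal(p_ab$n_sites, 4)
  expect_equal(sum(p_ab$diff), 0)

  # all sites: the N at column 5 is masked from numerator and denominator
  p_all <- pair_difference_profile(g, "a", "b", synonymous_only = FALSE)
  expect_equal(p_all$n_missing, 1)
  expect_equal(p_all$n_sites, 11)
  expect_equal(p_all$divergence, 1 / 11)  # one real mismatch at column 12

  # symmetry
  p_ba <- pair_difference_profile(g, "b", "a", synonymous_only = FALSE)
  expect_equal(p_ba$diff, p_all$diff)
  expect_equal(p_ba$divergence, p_all$divergence)

  expect_error(pair_difference_profile(g, "a", "zz"), "unknown strain")
})

test_that("complementary haplotypes give divergence 1; masking reduces the denominator", {
  hap <- rbind(rep(0L, 100), rep(2L, 100))
  sites <- data.frame(contig = "c", pos_bp = 1:100, is_synonymous = TRUE)
  meta <- data.frame(strain_id = c("x", "y"), host_id = c("h1", "h2"))
  g <- core_genome_set(hap, sites, meta)
  expect_equal(pair_difference_profile(g, "x", "y")$divergence, 1)

  # one site missing in x, one mismatch among the remaining 99
  hap2 <- rbind(c(NA, rep(0L, 99)), c(0L, 1L, rep(0L, 98)))
  g2 <- core_genome_set(hap2, sites, meta)
  p <- pair_difference_profile(g2, "x", "y")
  expect_equal(p$n_sites, 99)
  expect_equal(p$divergence, 1 / 99)
})

test_that("block partition conserves counts, drops partial blocks, breaks at contigs", {
  d <- integer(3000); d[c(1, 1001)] <- 1L
  prof <- profile_from_diff(d)
  b <- partition_blocks(prof, 1000)
  expect_equal(length(b$snv_count_per_block), 3)
  expect_equal(b$snv_count_per_block, c(1L, 1L, 0L))

  set.seed(1)
  d2 <- rbinom(3500, 1, 0.01)
  prof2 <- profile_from_diff(d2)
  b2 <- partition_blocks(prof2, 1000)
  expect_equal(length(b2$snv_count_per_block), 3)  # trailing 500 dropped
  expect_equal(sum(b2$snv_count_per_block), sum(d2[1:3000]))  # conservation

  expect_error(partition_blocks(profile_from_diff(integer(10)), 1000),
               "shorter than one block")

  # contig boundary: 2 contigs of 1500 sites -> 1 block each, not 3
  prof3 <- profile_from_diff(integer(3000))
  prof3$contig <- rep(c("c1", "c2"), each = 1500)
  b3 <- partition_blocks(prof3, 1000)
  expect_equal(length(b3$snv_count_per_block), 2)
})

test_that("identical-block fraction matches the random-scatter closed form", {
  b0 <- partition_blocks(profile_from_diff(integer(3000)), 1000)
  expect_equal(fraction_identical_blocks(b0), 1)
  ball <- partition_blocks(profile_from_diff(rep(c(1, rep(0, 9)), 300)), 1000)
  expect_equal(fraction_identical_blocks(ball), 0)

  # Poisson-scattered SNVs at d = 1e-3, blocks of 1000 -> f_id ~ exp(-1)
  set.seed(7)
  f <- replicate(50, {
    fraction_identical_blocks(
      partition_blocks(profile_from_diff(rbinom(2e4, 1, 1e-3)), 1000))
  })
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - exp(-1)), 4 * se + 0.01)
})

test_that("sliding divergence tracks local structure", {
  prof <- profile_from_diff(integer(5000))
  sw <- sliding_divergence(prof, window_bp = 500)
  expect_true(all(sw$divergence == 0))

  set.seed(8)
  prof2 <- profile_from_diff(rbinom(5e4, 1, 0.01))
  sw2 <- sliding_divergence(prof2, window_bp = 1000)
  expect_lt(abs(mean(sw2$divergence) - 0.01), 0.002)
  # binomial sampling oracle: window values spread ~ sqrt(p(1-p)/n)
  expect_lt(sd(sw2$divergence), 3 * sqrt(0.01 * 0.99 / 1000))

  # single 2 kb fragment at 2% inside 50 kb of zeros -> one plateau
  set.seed(9)
  d3 <- integer(5e4)
  d3[20001:22000] <- rbinom(2000, 1, 0.02)
  sw3 <- sliding_divergence(profile_from_diff(d3), window_bp = 1000)
  inside <- sw3$mid_bp > 20500 & sw3$mid_bp < 21500
  outside <- sw3$mid_bp < 19000 | sw3$mid_bp > 23500
  expect_lt(abs(mean(sw3$divergence[inside]) - 0.02), 0.01)
  expect_equal(max(sw3$divergence[outside]), 0)
})
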