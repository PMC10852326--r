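#' Donor-divergence distributions for the pair simulator
#'
#' Three families are supported: a constant per-site divergence, a two-mode
#' lognormal mixture (emulating within- vs between-clade donors), and an
#' empirical sample to be resampled.  All draws are truncated to (5e-4, 0.45).
#'
#' @param value constant per-site donor divergence.
#' @return An object of class `div_dist` with a `$draw(n)` sampler.
#' @export
div_dist_constant <- function(value) {
  stopifnot(value > 0, value < 0.5)
  structure(list(type = "constant", value = value,
                 draw = function(n) rep(value, n)),
            class = "div_dist")
}

#' @rdname div_dist_constant
#' @param mode1,mode2 modes of the two mixture components (per-site divergence).
#' @param w1 weight of the first component.
#' @param sdlog1,sdlog2 lognormal spreads of the two components.
#' @export
div_dist_two_mode <- function(mode1 = 0.01, mode2 = 0.10, w1 = 0.7,
                              sdlog1 = 0.3, sdlog2 = 0.2) {
  draw <- function(n) {
    pick <- runif(n) < w1
    v <- ifelse(pick,
                stats::rlnorm(n, log(mode1), sdlog1),
                stats::rlnorm(n, log(mode2), sdlog2))
    pmin(pmax(v, 5e-4), 0.45)
  }
  structure(list(type = "two_mode", mode1 = mode1, mode2 = mode2, w1 = w1,
                 draw = draw), class = "div_dist")
}

#' @rdname div_dist_constant
#' @param values numeric vector of observed local divergences to resample.
#' @export
div_dist_sample <- function(values) {
  values <- values[is.finite(values) & values > 0 & values < 0.5]
  stopifnot(length(values) >= 1)
  structure(list(type = "sample", values = values,
                 draw = function(n) sample(values, n, replace = TRUE)),
            class = "div_dist")
}

#' Configuration for the neutral pair simulator
#'
#' Defaults reflect the close-pair regime in which individual transfers are
#' resolvable: a clonal backbone at divergence `mu_t = 5e-5`, ten transfers of
#' geometric mean length 2e4 sites over a genome of 1e6 synonymous sites, and
#' a two-mode donor-divergence mixture (a ~1% within-clade mode and a ~10x
#' more diverged between-clade mode, as seen in species with two subspecies).
#'
#' @param L_sites number of synonymous sites.
#' @param mu_t expected clonal divergence per site (2 mu T).
#' @param gamma_t expected number of transfers over the pair's history.
#' @param mean_frag_sites mean transfer length in sites (geometric lengths;
#'   set `constant_frag = TRUE` for fixed lengths in unit tests).
#' @param donor_div_dist a [div_dist_constant()]-family object.
#' @param clade_frac_between fraction of transfers drawn from a second, more
#'   diverged clade via `donor_div_dist_between`.
#' @param donor_div_dist_between donor distribution for between-clade
#'   transfers (required if `clade_frac_between > 0`).
#' @param bp_per_site genomic spacing of consecutive synonymous sites.
#' @param constant_frag use fixed instead of geometric fragment lengths.
#' @param seed integer seed or `NULL` to use the current RNG state.
#' @return A `pair_sim_config`.
#' @export
pair_sim_config <- function(L_sites = 1e6, mu_t = 5e-5, gamma_t = 10,
                            mean_frag_sites = 2e4,
                            donor_div_dist = div_dist_two_mode(),
                            clade_frac_between = 0,
                            donor_div_dist_between = NULL,
                            bp_per_site = 1, constant_frag = FALSE,
                            seed = NULL) {
  stopifnot(L_sites >= 1, mu_t >= 0, gamma_t >= 0, mean_frag_sites >= 1,
            clade_frac_between >= 0, clade_frac_between <= 1)
  if (clade_frac_between > 0 && is.null(donor_div_dist_between))
    stop("clade_frac_between > 0 requires donor_div_dist_between")
  structure(list(L_sites = as.integer(L_sites), mu_t = mu_t, gamma_t = gamma_t,
                 mean_frag_sites = mean_frag_sites,
                 donor_div_dist = donor_div_dist,
                 clade_frac_between = clade_frac_between,
                 donor_div_dist_between = donor_div_dist_between,
                 bp_per_site = bp_per_site, constant_frag = constant_frag,
                 seed = seed),
            class = "pair_sim_config")
}

#' Simulate one pair of genomes with known recombination events
#'
#' Generates the binary difference profile of a strain pair: a clonal
#' backbone with Bernoulli(`mu_t`) differences, overwritten by
#' Poisson(`gamma_t`) transfers placed uniformly with geometric lengths, whose
#' interiors are Bernoulli(donor divergence).  Overlapping transfers are
#' resolved last-writer-wins and the recorded truth is the set of *visible*
#' (post-overlap) segments -- what any detector could possibly recover.
#'
#' @param cfg a [pair_sim_config()].
#' @return list with `profile` (a `diff_profile`) and `truth` (data.frame of
#'   visible segments: site/bp bounds, donor divergence, realized SNV count,
#'   clade label) plus the realized recombined fraction.
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "pair_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$L_sites
  diff <- rbinom(L, 1L, cfg$mu_t)

  n_tr <- rpois(1, cfg$gamma_t)
  truth <- data.frame(start_site = integer(0), end_site = integer(0),
                      length_sites = integer(0), donor_div = numeric(0),
                      n_snvs = integer(0), clade = character(0))
  if (n_tr > 0) {
    starts <- sample.int(L, n_tr, replace = TRUE)
    lens <- if (cfg$constant_frag) rep(ceiling(cfg$mean_frag_sites), n_tr) else
      1L + rgeom(n_tr, 1 / cfg$mean_frag_sites)
    between <- runif(n_tr) < cfg$clade_frac_between
    divs <- numeric(n_tr)
    if (any(!between)) divs[!between] <- cfg$donor_div_dist$draw(sum(!between))
    if (any(between)) divs[between] <- cfg$donor_div_dist_between$draw(sum(between))
    ends <- pmin(starts + lens - 1L, L)

    owner <- integer(L) # 0 = clonal; transfers applied in order, last wins
    for (j in seq_len(n_tr)) owner[starts[j]:ends[j]] <- j
    r <- rle(owner)
    seg_end <- cumsum(r$lengths)
    seg_start <- seg_end - r$lengths + 1L
    vis <- which(r$values > 0L)
    if (length(vis)) {
      sj <- seg_start[vis]; ej <- seg_end[vis]; oj <- r$values[vis]
      nsnv <- integer(length(vis))
      for (i in seq_along(vis)) {
        seg <- sj[i]:ej[i]
        diff[seg] <- rbinom(length(seg), 1L, divs[oj[i]])
        nsnv[i] <- sum(diff[seg])
      }
      truth <- data.frame(start_site = sj, end_site = ej,
                          length_sites = ej - sj + 1L,
                          donor_div = divs[oj], n_snvs = nsnv,
                          clade = ifelse(between[oj], "between", "within"))
    }
  }
  site_pos <- as.integer(round(seq_len(L) * cfg$bp_per_site))
  profile <- new_diff_profile(pair = c("sim_a", "sim_b"),
                              site_pos = site_pos,
                              site_idx = seq_len(L),
                              contig = rep("sim", L),
                              diff = diff, n_missing = 0L)
  f_r <- sum(truth$length_sites) / L
  list(profile = profile, truth = truth, recombined_fraction = f_r,
       clonal_divergence = cfg$mu_t)
}

#' Configuration for the forward-time Moran population simulator
#'
#' Each Moran event replaces one individual by the offspring of another; the
#' offspring acquires Poisson(`mu * L`) point mutations and Poisson(`rho * L`)
#' gene conversions that copy geometric-length fragments from random donors.
#' With both birth and death uniform, a pair of lineages coalesces at rate
#' 2/N^2 per event, so expected pairwise synonymous divergence is `N * mu`.
#' `generations` are Moran generations (N events each); the default burn-in of
#' 10N generations is ~20x the mean pair coalescence time, ample for the
#' pairwise statistics used here.
#'
#' @param N population size.
#' @param n_sample number of sampled haplotypes.
#' @param L_sites genome length in synonymous sites.
#' @param mu mutation rate per site per generation.
#' @param rho recombination (gene-conversion initiation) rate per site per
#'   generation.
#' @param mean_frag_sites mean conversion tract length in sites.
#' @param generations run length in Moran generations.
#' @param hotspot optional `list(start =, end =, mult =)` site range with a
#'   multiplied conversion initiation rate.
#' @param strains_per_host 1 (default) or 2; with 2, consecutive sampled
#'   strains share a host id, emulating dual-colonized hosts.
#' @param bp_per_site genomic spacing of consecutive synonymous sites.
#' @param seed integer seed or `NULL`.
#' @return A `pop_sim_config`.
#' @export
pop_sim_config <- function(N = 200, n_sample = 20, L_sites = 2e4,
                           mu = 5e-5, rho = 0, mean_frag_sites = 300,
                           generations = 10 * N, hotspot = NULL,
                           strains_per_host = 1, bp_per_site = 1,
                           seed = NULL) {
  stopifnot(N >= n_sample, n_sample >= 2, generations >= 1,
            mu >= 0, rho >= 0, mean_frag_sites >= 1,
            strains_per_host %in% c(1, 2))
  if (!is.null(hotspot))
    stopifnot(hotspot$start >= 1, hotspot$end <= L_sites,
              hotspot$start <= hotspot$end, hotspot$mult > 0)
  structure(list(N = as.integer(N), n_sample = as.integer(n_sample),
                 L_sites = as.integer(L_sites), mu = mu, rho = rho,
                 mean_frag_sites = mean_frag_sites,
                 generations = as.integer(generations), hotspot = hotspot,
                 strains_per_host = strains_per_host,
                 bp_per_site = bp_per_site, seed = seed),
            class = "pop_sim_config")
}

#' Simulate a recombining population under the neutral Moran model
#'
#' @param cfg a [pop_sim_config()].
#' @return list with `genomes` (a [core_genome_set()] of the sampled
#'   haplotypes) and `truth` (run bookkeeping: configuration and step count).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  steps <- cfg$generations * cfg$N
  hs <- if (is.null(cfg$hotspot)) c(-1L, -2L, 1) else
    c(cfg$hotspot$start - 1L, cfg$hotspot$end - 1L, cfg$hotspot$mult)
  idx <- sample.int(cfg$N, cfg$n_sample)
  hap <- moran_sim_cpp(cfg$N, cfg$L_sites, cfg$mu, cfg$rho,
                       cfg$mean_frag_sites, steps,
                       as.integer(hs[1]), as.integer(hs[2]), hs[3], idx)
  n <- cfg$n_sample
  strain_id <- sprintf("s%03d", seq_len(n))
  host_id <- if (cfg$strains_per_host == 2)
    sprintf("h%03d", (seq_len(n) + 1L) %/% 2L) else sprintf("h%03d", seq_len(n))
  rownames(hap) <- strain_id
  sites <- data.frame(contig = "sim",
                      pos_bp = as.integer(round(seq_len(cfg$L_sites) * cfg$bp_per_site)),
                      is_synonymous = TRUE, gene_id = NA_character_)
  genomes <- core_genome_set(hap, sites,
                             data.frame(strain_id = strain_id, host_id = host_id),
                             species_name = "moran_sim")
  list(genomes = genomes,
       truth = list(config = cfg, steps = steps, sampled = idx))
}

#' Star-genealogy control population at fixed pairwise divergence
#'
#' Every strain descends independently from a common ancestor so that all
#' pairwise difference profiles are independent Bernoulli scatters at
#' divergence ~`d_bar` (the "mutations randomly distributed" limit).  Used as
#' the clonal-limit null for block and sharing statistics.
#'
#' @param n number of strains.
#' @param L_sites genome length in synonymous sites.
#' @param d_bar target pairwise synonymous divergence.
#' @param bp_per_site genomic spacing of sites.
#' @param seed integer seed or `NULL`.
#' @return A [core_genome_set()].
#' @export
simulate_star_population <- function(n, L_sites, d_bar, bp_per_site = 1,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- d_bar / 2
  hap <- matrix(0L, nrow = n, ncol = L_sites)
  for (i in seq_len(n)) {
    mut <- which(rbinom(L_sites, 1L, p) == 1L)
    hap[i, mut] <- 1L + (sample.int(3L, length(mut), replace = TRUE) - 1L)
  }
  strain_id <- sprintf("s%03d", seq_len(n))
  rownames(hap) <- strain_id
  sites <- data.frame(contig = "sim",
                      pos_bp = as.integer(round(seq_len(L_sites) * bp_per_site)),
                      is_synonymous = TRUE, gene_id = NA_character_)
  core_genome_set(hap, sites,
                  data.frame(strain_id = strain_id,
                             host_id = sprintf("h%03d", seq_len(n))),
                  species_name = "star_sim")
}

#' Two-clade control population
#'
#' Two star-shaped clades whose ancestors differ at divergence `d_between`;
#' strains within each clade sit at ~`d_within` from each other.  Emulates
#' species with two subspecies (within-clade divergence ~10-fold smaller than
#' between clades).
#'
#' @param n_per_clade strains per clade.
#' @param L_sites genome length in synonymous sites.
#' @param d_within,d_between pairwise divergence within / between clades.
#' @param bp_per_site genomic spacing of sites.
#' @param seed integer seed or `NULL`.
#' @return A [core_genome_set()] with `clade_id` set to "c1"/"c2".
#' @export
simulate_two_clade_population <- function(n_per_clade, L_sites,
                                          d_within = 0.01, d_between = 0.10,
                                          bp_per_site = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc1 <- integer(L_sites)
  flip <- which(rbinom(L_sites, 1L, d_between) == 1L)
  anc2 <- anc1
  anc2[flip] <- 1L + (sample.int(3L, length(flip), replace = TRUE) - 1L)
  n <- 2L * n_per_clade
  hap <- matrix(0L, nrow = n, ncol = L_sites)
  p <- d_within / 2
  for (i in seq_len(n)) {
    base <- if (i <= n_per_clade) anc1 else anc2
    mut <- which(rbinom(L_sites, 1L, p) == 1L)
    row <- base
    row[mut] <- (row[mut] + sample.int(3L, length(mut), replace = TRUE)) %% 4L
    hap[i, ] <- row
  }
  strain_id <- sprintf("s%03d", seq_len(n))
  rownames(hap) <- strain_id
  sites <- data.frame(contig = "sim",
                      pos_bp = as.integer(round(seq_len(L_sites) * bp_per_site)),
                      is_synonymous = TRUE, gene_id = NA_character_)
  core_genome_set(hap, sites,
                  data.frame(strain_id = strain_id,
                             host_id = sprintf("h%03d", seq_len(n)),
                             clade_id = rep(c("c1", "c2"), each = n_per_clade)),
                  species_name = "two_clade_sim")
}

#' Inject a selective sweep of a transferred haplotype
#'
#' Copies a donor haplotype's region into a fraction of strains.  In `hard`
#' mode a single donor haplotype expands; in `soft` mode `k` distinct donors
#' each seed `carrier_fraction / k` of the strains.
#'
#' @param genomes a [core_genome_set()].
#' @param region length-2 site-index range `c(start, end)`.
#' @param mode `"hard"` or `"soft"`.
#' @param donor donor strain id(s); default: sampled.  For `soft`, either `k`
#'   distinct ids or `NULL` to sample them.
#' @param carrier_fraction fraction of strains that end up carrying a donor
#'   haplotype over the region (donors count as carriers of their own
#'   haplotype).
#' @param k number of distinct donor haplotypes for `soft` mode.
#' @param seed integer seed or `NULL`.
#' @return The modified [core_genome_set()]; carriers are recorded in
#'   `attr(, "carriers")` (per-donor list) for bookkeeping.
#' @export
inject_sweep <- function(genomes, region, mode = c("hard", "soft"),
                         donor = NULL, carrier_fraction = 0.5, k = 3,
                         seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(region) == 2, region[1] >= 1,
            region[2] <= ncol(genomes$haplotypes), region[1] <= region[2],
            carrier_fraction > 0, carrier_fraction <= 1)
  sel <- region[1]:region[2]
  strains <- rownames(genomes$haplotypes)
  n <- length(strains)
  n_donors <- if (mode == "hard") 1L else as.integer(k)
  if (is.null(donor)) donor <- sample(strains, n_donors) else
    stopifnot(length(donor) == n_donors, all(donor %in% strains))
  n_carriers <- round(carrier_fraction * n)
  if (n_carriers < n_donors)
    stop("carrier_fraction too small for ", n_donors, " donor haplotypes")
  recruits <- sample(setdiff(strains, donor), n_carriers - n_donors)
  groups <- split(recruits, rep(seq_len(n_donors), length.out = length(recruits)))
  carriers <- vector("list", n_donors)
  for (j in seq_len(n_donors)) {
    members <- if (j <= length(groups)) groups[[j]] else character(0)
    for (s in members)
      genomes$haplotypes[s, sel] <- genomes$haplotypes[donor[j], sel]
    carriers[[j]] <- c(donor[j], members)
  }
  names(carriers) <- donor
  attr(genomes, "carriers") <- carriers
  genomes
}

#' Plant close-pair partners into a population
#'
#' For each of `n_pairs` base strains, adds a new strain derived from it by a
#' clonal backbone (Bernoulli(`d_clonal`) point differences) plus
#' Poisson(`gamma_t`) homologous transfers of geometric mean length
#' `mean_frag_sites`, each copied verbatim from a randomly chosen donor strain
#' (restricted to the base strain's clade when `donor_pool = "within"`).
#' Unlike [simulate_pair()], the imported fragments carry *real* donor
#' haplotypes, so their local divergence follows the population's actual
#' divergence structure -- the construction used to study clade-specific
#' recombination barriers.
#'
#' @param genomes a [core_genome_set()].
#' @param n_pairs number of close pairs to plant (partners of strains
#'   1..n_pairs).
#' @param d_clonal clonal backbone divergence.
#' @param gamma_t expected transfers per partner.
#' @param mean_frag_sites mean transfer length in sites.
#' @param donor_pool `"within"` (same-clade donors only; emulates suppressed
#'   between-clade recombination) or `"all"`.
#' @param seed integer seed or `NULL`.
#' @return list with `genomes` (augmented set; partners named `cp<i>` on hosts
#'   `hostcp<i>`) and `pairs` (2-column matrix of base/partner strain ids).
#' @export
plant_close_pairs <- function(genomes, n_pairs, d_clonal = 5e-5,
                              gamma_t = 10, mean_frag_sites = 1e4,
                              donor_pool = c("within", "all"), seed = NULL) {
  donor_pool <- match.arg(donor_pool)
  if (!is.null(seed)) set.seed(seed)
  hap <- genomes$haplotypes
  meta <- genomes$strain_meta
  L <- ncol(hap)
  stopifnot(n_pairs <= nrow(hap))
  new_rows <- vector("list", n_pairs)
  new_meta <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    base_id <- meta$strain_id[k]
    partner <- hap[base_id, ]
    mut <- which(rbinom(L, 1L, d_clonal) == 1L)
    partner[mut] <- (partner[mut] + sample.int(3L, length(mut), replace = TRUE)) %% 4L
    cands <- meta$strain_id[meta$strain_id != base_id]
    if (donor_pool == "within" && !all(is.na(meta$clade_id)))
      cands <- meta$strain_id[meta$strain_id != base_id &
                                meta$clade_id == meta$clade_id[k]]
    n_tr <- rpois(1, gamma_t)
    if (n_tr > 0) {
      donors <- sample(cands, n_tr, replace = TRUE)
      starts <- sample.int(L, n_tr, replace = TRUE)
      lens <- 1L + rgeom(n_tr, 1 / mean_frag_sites)
      for (j in seq_len(n_tr)) {
        sel <- starts[j]:min(starts[j] + lens[j] - 1L, L)
        partner[sel] <- hap[donors[j], sel]
      }
    }
    new_rows[[k]] <- partner
    new_meta[[k]] <- data.frame(strain_id = paste0("cp", k),
                                host_id = paste0("hostcp", k),
                                clade_id = meta$clade_id[k])
  }
  hap2 <- rbind(hap, do.call(rbind, lapply(new_rows, matrix, nrow = 1)))
  meta2 <- rbind(meta, do.call(rbind, new_meta))
  rownames(hap2) <- meta2$strain_id
  out <- core_genome_set(hap2, genomes$sites, meta2,
                         species_name = genomes$species_name,
                         L_bp = genomes$L_bp)
  list(genomes = out,
       pairs = cbind(meta$strain_id[seq_len(n_pairs)],
                     paste0("cp", seq_len(n_pairs))))
}
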