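# Small hand-built and simulated fixtures shared across test files.

# three strains x 12 sites, 4 synonymous columns, one 'N' in strain b
tiny_genomes <- function() {
  seqs <- c("ACGTACGTACGT",
            "ACGTNCGTACGA",
            "ACCTACGTACGA")
  hap <- do.call(rbind, strsplit(seqs, ""))
  sites <- data.frame(contig = "c1", pos_bp = seq(10, 120, by = 10),
                      is_synonymous = rep(c(TRUE, FALSE, FALSE), each = 4),
                      gene_id = "g1")
  meta <- data.frame(strain_id = c("a", "b", "c"),
                     host_id = c("h1", "h2", "h3"))
  core_genome_set(hap, sites, meta, species_name = "tiny")
}

# a diff_profile built directly from a 0/1 vector on unit spacing
profile_from_diff <- function(diff, bp_per_site = 1) {
  corerecomb:::new_diff_profile(
    pair = c("x", "y"),
    site_pos = as.integer(round(seq_along(diff) * bp_per_site)),
    site_idx = seq_along(diff),
    contig = rep("sim", length(diff)),
    diff = as.integer(diff), n_missing = 0L)
}

# reverse a profile's coordinate system (for symmetry checks)
reverse_profile <- function(profile) {
  n <- length(profile$diff)
  tot <- profile$site_pos[n] + profile$site_pos[1]
  corerecomb:::new_diff_profile(
    pair = profile$pair,
    site_pos = tot - rev(profile$site_pos),
    site_idx = seq_len(n),
    contig = rev(profile$contig),
    diff = rev(profile$diff), n_missing = profile$n_missing)
}

# emission distribution matching the default two-mode donor mixture
two_mode_emissions <- function(seed = 99, n = 5000) {
  set.seed(seed)
  empirical_div_dist(div_dist_two_mode()$draw(n), n_bins = 12)
}

# SNV table for a dual-colonized sample: intermediate SNVs every `spacing` bp
# at alt frequency `freq`, depth `depth`, with optional zero-SNV gap
dual_snv_table <- function(L_bp = 1e5, spacing = 500, freq = 0.7, depth = 60,
                           gap = NULL, gap_depth_factor = 1) {
  pos <- seq(spacing, L_bp, by = spacing)
  keep <- rep(TRUE, length(pos))
  if (!is.null(gap)) keep <- !(pos > gap[1] & pos < gap[2])
  pos <- pos[keep]
  dep <- rep(depth, length(pos))
  df <- data.frame(contig = "c1", pos_bp = pos, ref_allele = "A",
                   alt_allele = "G", alt_count = round(freq * dep), depth = dep)
  if (!is.null(gap)) {
    # coverage probes inside the gap so the region coverage ratio is defined
    probe <- seq(gap[1] + 100, gap[2] - 100, by = spacing)
    df <- rbind(df, data.frame(contig = "c1", pos_bp = probe, ref_allele = "A",
                               alt_allele = "G", alt_count = 0,
                               depth = round(depth * gap_depth_factor)))
  }
  sample_snv_table(df[order(df$pos_bp), ])
}
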