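#' Read a per-sample SNV frequency/coverage table
#'
#' Flat TSV dialect with columns `contig`, `pos_bp`, `ref_allele`,
#' `alt_allele`, `alt_count`, `depth` ('#' comment lines allowed).  Alt-allele
#' frequencies are defined only where depth is at least `depth_min`; shallower
#' sites are masked.
#'
#' @param path TSV path.
#' @param depth_min minimum depth for a site to be usable (default 10).
#' @return A `sample_snv_table`: the data plus `alt_freq` (NA below
#'   `depth_min`) and the genome-wide median depth.
#' @export
read_sample_snv_table <- function(path, depth_min = 10) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("contig", "pos_bp", "ref_allele", "alt_allele", "alt_count", "depth")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("SNV table missing column(s): ", paste(miss, collapse = ", "))
  sample_snv_table(df, depth_min = depth_min)
}

#' @rdname read_sample_snv_table
#' @param df data.frame with the columns above.
#' @export
sample_snv_table <- function(df, depth_min = 10) {
  stopifnot(all(df$depth >= 0), all(df$alt_count >= 0),
            all(df$alt_count <= df$depth))
  df <- df[order(df$contig, df$pos_bp), ]
  df$alt_freq <- ifelse(df$depth >= depth_min, df$alt_count / df$depth, NA_real_)
  structure(list(snvs = df, depth_min = depth_min,
                 genome_wide_median_depth = median(df$depth)),
            class = "sample_snv_table")
}

#' Detect dual colonization from intermediate-frequency SNVs
#'
#' A sample is called dual-colonized when at least `min_sites` usable SNVs
#' have alt-allele frequency strictly inside (`f_low`, `f_high`): two diverged
#' strains at intermediate frequencies put most of their distinguishing SNVs
#' in that band.  The dominant-strain frequency is estimated as the mode of
#' the major-allele (folded) frequencies of those intermediate sites.
#'
#' @param table a `sample_snv_table`.
#' @param f_low,f_high intermediate-frequency band (defaults 0.2, 0.8).
#' @param min_sites minimum number of intermediate-frequency SNVs.
#' @return list with `is_dual`, `strain_freq` (NA unless dual),
#'   `n_intermediate`, `indeterminate` (TRUE when too few usable sites to
#'   decide).
#' @export
detect_dual_colonization <- function(table, f_low = 0.2, f_high = 0.8,
                                     min_sites = 100) {
  f <- table$snvs$alt_freq
  usable <- !is.na(f)
  if (sum(usable) < min_sites)
    return(list(is_dual = FALSE, strain_freq = NA_real_,
                n_intermediate = sum(f[usable] > f_low & f[usable] < f_high),
                indeterminate = TRUE))
  inter <- usable & f > f_low & f < f_high
  n_int <- sum(inter)
  if (n_int < min_sites)
    return(list(is_dual = FALSE, strain_freq = NA_real_,
                n_intermediate = n_int, indeterminate = FALSE))
  major <- pmax(f[inter], 1 - f[inter])
  dens <- density(major, bw = 0.02, from = 0.5, to = 1)
  list(is_dual = TRUE, strain_freq = dens$x[which.max(dens$y)],
       n_intermediate = n_int, indeterminate = FALSE)
}

#' Quasi-phase the dominant strain's haplotype
#'
#' Where the major allele exceeds `threshold` the dominant strain is assigned
#' that allele; sites with more even frequencies (or insufficient depth) are
#' masked.  This reconstructs the dominant strain's core genome from a
#' metagenomic frequency table when one strain exceeds ~80% frequency.
#'
#' @param table a `sample_snv_table`.
#' @param threshold major-allele frequency threshold (default 0.8).
#' @return data.frame `contig`, `pos_bp`, `allele` (character, NA = masked).
#' @export
quasi_phase_dominant <- function(table, threshold = 0.8) {
  df <- table$snvs
  f <- df$alt_freq
  allele <- rep(NA_character_, nrow(df))
  take_alt <- !is.na(f) & f > threshold
  take_ref <- !is.na(f) & (1 - f) > threshold
  allele[take_alt] <- df$alt_allele[take_alt]
  allele[take_ref] <- df$ref_allele[take_ref]
  data.frame(contig = df$contig, pos_bp = df$pos_bp, allele = allele)
}

#' Detect gene-specific sweep regions in a dual-colonized sample
#'
#' Scans for maximal regions of at least `min_sweep_bp` with zero
#' intermediate-frequency SNVs whose flanks remain polymorphic (at least one
#' intermediate SNV per 2 kb on each 10 kb flank, distinguishing a local sweep
#' from a region where the two strains happen to be identical) and whose
#' median coverage is close to the genome-wide median (`cov_band`), ruling out
#' deletions.  With a second timepoint the region must additionally have been
#' polymorphic at T0 and swept at T1 (strictly more conservative).
#'
#' @param table a `sample_snv_table` (single timepoint, or T1 in longitudinal
#'   mode).
#' @param table_t0 optional earlier-timepoint `sample_snv_table`.
#' @param f_low,f_high intermediate-frequency band.
#' @param min_sweep_bp minimum swept-region length (default 10000).
#' @param cov_band admissible region/genome median-coverage ratio (default
#'   (0.6, 1.5), the "copy number close to one" criterion).
#' @param flank_bp,flank_density_bp flank width and required SNV spacing:
#'   each `flank_bp` flank needs >= `flank_bp / flank_density_bp`
#'   intermediate SNVs.
#' @return data.frame of sweep calls: `contig`, `start_bp`, `end_bp`,
#'   `length_bp`, `coverage_ratio`, `mode`; zero rows if none.
#' @export
detect_sweep_regions <- function(table, table_t0 = NULL,
                                 f_low = 0.2, f_high = 0.8,
                                 min_sweep_bp = 10000,
                                 cov_band = c(0.6, 1.5),
                                 flank_bp = 10000, flank_density_bp = 2000) {
  df <- table$snvs
  empty <- data.frame(contig = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), length_bp = numeric(0),
                      coverage_ratio = numeric(0), mode = character(0))
  calls <- empty
  mode <- if (is.null(table_t0)) "single_timepoint" else "longitudinal"
  gw_med <- table$genome_wide_median_depth
  for (ctg in unique(df$contig)) {
    sub <- df[df$contig == ctg, ]
    f <- sub$alt_freq
    inter <- !is.na(f) & f > f_low & f < f_high
    if (!any(inter)) next
    ipos <- sub$pos_bp[inter]
    gaps <- data.frame(start_bp = head(ipos, -1), end_bp = tail(ipos, -1))
    gaps$length_bp <- gaps$end_bp - gaps$start_bp
    gaps <- gaps[gaps$length_bp >= min_sweep_bp, , drop = FALSE]
    if (!nrow(gaps)) next
    need <- flank_bp / flank_density_bp
    for (g in seq_len(nrow(gaps))) {
      s <- gaps$start_bp[g]; e <- gaps$end_bp[g]
      left <- sum(ipos >= s - flank_bp & ipos <= s)
      right <- sum(ipos >= e & ipos <= e + flank_bp)
      if (left < need || right < need) next
      in_reg <- sub$pos_bp > s & sub$pos_bp < e
      if (!any(in_reg)) next
      cov_ratio <- median(sub$depth[in_reg]) / gw_med
      if (cov_ratio < cov_band[1] || cov_ratio > cov_band[2]) next
      if (!is.null(table_t0)) {
        df0 <- table_t0$snvs
        sub0 <- df0[df0$contig == ctg, ]
        f0 <- sub0$alt_freq
        i0 <- !is.na(f0) & f0 > f_low & f0 < f_high & sub0$pos_bp > s &
          sub0$pos_bp < e
        # longitudinal: region must have been polymorphic before the sweep
        if (sum(i0) < (e - s) / flank_density_bp / 2) next
      }
      calls <- rbind(calls, data.frame(contig = ctg, start_bp = s, end_bp = e,
                                       length_bp = e - s,
                                       coverage_ratio = cov_ratio, mode = mode))
    }
  }
  calls
}

#' Write sweep calls as TSV
#'
#' @param calls data.frame from [detect_sweep_regions()].
#' @param path output path.
#' @param sample_id sample label.
#' @return The path, invisibly.
#' @export
write_sweeps_tsv <- function(calls, path, sample_id = "sample") {
  df <- cbind(sample = if (nrow(calls)) sample_id else character(0), calls)
  write_tsv(df, path, comment = paste0("sweep calls; sample=", sample_id))
}
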