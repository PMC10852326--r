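#' @useDynLib corerecomb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rpois rgeom rexp runif median quantile sd var
#'   density optimize ks.test cor setNames complete.cases ecdf
#' @importFrom utils read.delim write.table head tail
NULL

ALLELE_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

code_to_allele <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- names(ALLELE_CODES)[x[ok] + 1L]
  out[!ok] <- "N"
  out
}

#' Construct a core-genome haplotype set
#'
#' The central container for all analyses: an alignment of core-genome
#' haplotypes (one row per strain) with per-site annotations (genomic
#' coordinates and synonymous flags) and per-strain metadata (host and
#' optional clade labels).
#'
#' @param haplotypes integer matrix, strains x sites, allele codes 0..3
#'   (A,C,G,T) with `NA` for missing; or a character matrix of A/C/G/T/N.
#' @param sites data.frame with columns `contig`, `pos_bp` (1-based),
#'   `is_synonymous` (logical or 0/1) and optionally `gene_id`.
#' @param strain_meta data.frame with columns `strain_id`, `host_id` and
#'   optionally `clade_id`.
#' @param species_name species label carried into output tables.
#' @param L_bp total core-genome length in bp; defaults to the largest
#'   annotated position per contig summed over contigs.
#' @return An object of class `core_genome_set`.
#' @export
core_genome_set <- function(haplotypes, sites, strain_meta,
                            species_name = "unknown", L_bp = NULL) {
  if (is.character(haplotypes)) {
    codes <- ALLELE_CODES[haplotypes]
    haplotypes <- matrix(unname(codes), nrow = nrow(haplotypes),
                         dimnames = dimnames(haplotypes))
  }
  storage.mode(haplotypes) <- "integer"
  sites <- as.data.frame(sites)
  if (is.null(sites$gene_id)) sites$gene_id <- NA_character_
  sites$is_synonymous <- as.logical(sites$is_synonymous)
  strain_meta <- as.data.frame(strain_meta)
  if (is.null(strain_meta$clade_id)) strain_meta$clade_id <- NA_character_

  if (ncol(haplotypes) != nrow(sites))
    stop("haplotype matrix has ", ncol(haplotypes), " columns but ",
         nrow(sites), " annotated sites")
  if (anyDuplicated(strain_meta$strain_id))
    stop("strain_id values must be unique")
  if (nrow(haplotypes) != nrow(strain_meta))
    stop("haplotype rows and strain_meta rows differ")
  for (ctg in unique(sites$contig)) {
    p <- sites$pos_bp[sites$contig == ctg]
    if (any(p < 1)) stop("pos_bp must be >= 1")
    if (is.unsorted(p, strictly = TRUE))
      stop("site positions must be strictly increasing within contig ", ctg)
  }
  rownames(haplotypes) <- strain_meta$strain_id
  if (is.null(L_bp)) {
    L_bp <- sum(vapply(split(sites$pos_bp, sites$contig), max, numeric(1)))
  }
  structure(list(species_name = species_name, sites = sites,
                 haplotypes = haplotypes, strain_meta = strain_meta,
                 L_bp = as.numeric(L_bp)),
            class = "core_genome_set")
}

#' @export
print.core_genome_set <- function(x, ...) {
  cat("core_genome_set:", x$species_name, "\n",
      nrow(x$haplotypes), "strains x", ncol(x$haplotypes), "sites (",
      sum(x$sites$is_synonymous), "synonymous ), L_bp =", x$L_bp, "\n")
  invisible(x)
}

#' Load an aligned core genome from FASTA plus a site-annotation table
#'
#' FASTA records must all have the same length (one alignment column per
#' annotated site) and ids of the form `strain_id|host_id` or
#' `strain_id|host_id|clade_id`.  The annotation TSV needs columns `contig`,
#' `pos_bp`, `is_synonymous` and optionally `gene_id`, one row per column.
#' Characters other than A/C/G/T are treated as missing.
#'
#' @param path path to the aligned FASTA.
#' @param site_annotation path to the site-annotation TSV.
#' @param species_name species label.
#' @return A [core_genome_set()].
#' @export
load_core_alignment <- function(path, site_annotation, species_name = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1) {
    bad <- names(seqs)[widths != widths[1]][1]
    stop("FASTA records have unequal lengths (e.g. record '", bad, "')")
  }
  ann <- read.delim(site_annotation, comment.char = "#",
                    stringsAsFactors = FALSE)
  req <- c("contig", "pos_bp", "is_synonymous")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("site annotation missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(ann) != widths[1])
    stop("annotation covers ", nrow(ann), " sites but alignment has ",
         widths[1], " columns; first uncovered column: ",
         min(nrow(ann), widths[1]) + 1)

  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  codes <- ALLELE_CODES[mat]
  hap <- matrix(unname(codes), nrow = length(seqs))

  meta_parts <- strsplit(names(seqs), "|", fixed = TRUE)
  strain_meta <- data.frame(
    strain_id = vapply(meta_parts, `[`, "", 1),
    host_id = vapply(meta_parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""),
    clade_id = vapply(meta_parts, function(p) if (length(p) >= 3) p[3] else NA_character_, ""),
    stringsAsFactors = FALSE)
  if (is.null(species_name))
    species_name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  core_genome_set(hap, ann, strain_meta, species_name = species_name)
}

#' Write a core genome set as FASTA plus site-annotation TSV
#'
#' @param genomes a [core_genome_set()].
#' @param fasta_path,sites_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_core_alignment <- function(genomes, fasta_path, sites_path) {
  hap <- genomes$haplotypes
  seq_chr <- apply(hap, 1, function(r) paste(code_to_allele(r), collapse = ""))
  meta <- genomes$strain_meta
  ids <- paste(meta$strain_id, meta$host_id, sep = "|")
  has_clade <- !is.na(meta$clade_id)
  ids[has_clade] <- paste(ids[has_clade], meta$clade_id[has_clade], sep = "|")
  ss <- Biostrings::BStringSet(setNames(seq_chr, ids))
  Biostrings::writeXStringSet(ss, fasta_path)
  write_tsv(data.frame(contig = genomes$sites$contig,
                       pos_bp = genomes$sites$pos_bp,
                       is_synonymous = as.integer(genomes$sites$is_synonymous),
                       gene_id = genomes$sites$gene_id),
            sites_path,
            comment = paste0("species=", genomes$species_name))
  invisible(c(fasta_path, sites_path))
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise difference profile between two strains
#'
#' Compares two haplotypes site by site.  Sites missing in either strain are
#' excluded from both the numerator and the denominator of divergence and are
#' only reported through `n_missing`.
#'
#' @param genomes a [core_genome_set()].
#' @param a,b strain ids.
#' @param synonymous_only restrict to annotated synonymous sites (default).
#' @return A `diff_profile`: pair ids, retained site coordinates (bp and
#'   column index), the binary difference vector, divergence and the count of
#'   masked sites.
#' @export
pair_difference_profile <- function(genomes, a, b, synonymous_only = TRUE) {
  hap <- genomes$haplotypes
  for (s in c(a, b)) if (!s %in% rownames(hap)) stop("unknown strain: ", s)
  keep <- if (synonymous_only) which(genomes$sites$is_synonymous) else
    seq_len(ncol(hap))
  va <- hap[a, keep]
  vb <- hap[b, keep]
  obs <- !is.na(va) & !is.na(vb)
  diff <- as.integer(va[obs] != vb[obs])
  new_diff_profile(pair = c(a, b),
                   site_pos = genomes$sites$pos_bp[keep][obs],
                   site_idx = keep[obs],
                   contig = genomes$sites$contig[keep][obs],
                   diff = diff,
                   n_missing = sum(!obs))
}

new_diff_profile <- function(pair, site_pos, site_idx, contig, diff, n_missing) {
  structure(list(pair = pair, site_pos = site_pos, site_idx = site_idx,
                 contig = contig, diff = diff, n_missing = n_missing,
                 n_sites = length(diff),
                 divergence = if (length(diff)) mean(diff) else NA_real_),
            class = "diff_profile")
}

#' @export
print.diff_profile <- function(x, ...) {
  cat("diff_profile", paste(x$pair, collapse = " vs "), ":", x$n_sites,
      "sites,", sum(x$diff), "differences (d =",
      signif(x$divergence, 3), "),", x$n_missing, "masked\n")
  invisible(x)
}

#' Partition a difference profile into fixed-size blocks of synonymous sites
#'
#' Consecutive non-overlapping blocks of `block_size_sites` compared sites;
#' blocks do not span contig boundaries and a trailing partial block on each
#' contig is dropped.
#'
#' @param profile a `diff_profile`.
#' @param block_size_sites sites per block (default 1000).
#' @return A `block_series` with per-block SNV counts and site-index bounds.
#' @export
partition_blocks <- function(profile, block_size_sites = 1000) {
  stopifnot(block_size_sites >= 1)
  counts <- integer(0)
  bounds <- list()
  for (ctg in unique(profile$contig)) {
    idx <- which(profile$contig == ctg)
    nb <- length(idx) %/% block_size_sites
    if (nb == 0) next
    d <- profile$diff[idx[seq_len(nb * block_size_sites)]]
    cnt <- as.integer(tapply(d, rep(seq_len(nb), each = block_size_sites), sum))
    counts <- c(counts, cnt)
    starts <- idx[(seq_len(nb) - 1) * block_size_sites + 1]
    ends <- idx[seq_len(nb) * block_size_sites]
    bounds[[ctg]] <- data.frame(contig = ctg, start = starts, end = ends)
  }
  if (!length(counts))
    stop("profile shorter than one block (", block_size_sites, " sites)")
  structure(list(block_size_sites = block_size_sites,
                 snv_count_per_block = counts,
                 block_bounds = do.call(rbind, bounds)),
            class = "block_series")
}

#' Fraction of blocks with zero SNV differences
#'
#' The per-pair summary used as a proxy for clonal ancestry: the share of
#' fixed-size synonymous blocks that contain no differences.
#'
#' @param blocks a `block_series` from [partition_blocks()].
#' @return Fraction in \[0, 1\].
#' @export
fraction_identical_blocks <- function(blocks) {
  stopifnot(inherits(blocks, "block_series"),
            length(blocks$snv_count_per_block) >= 1)
  mean(blocks$snv_count_per_block == 0L)
}

#' Local divergence in sliding genomic windows
#'
#' Divergence (differences / compared sites) in windows of fixed bp width
#' stepped along each contig; windows are indexed by their genomic midpoint
#' and windows containing no compared site are reported as `NA`.
#'
#' @param profile a `diff_profile`.
#' @param window_bp window width in bp.
#' @param step_bp step between window starts in bp (default: window width).
#' @return data.frame with `contig`, `mid_bp`, `n_sites`, `n_diff`,
#'   `divergence`.
#' @export
sliding_divergence <- function(profile, window_bp = 1000, step_bp = window_bp) {
  stopifnot(window_bp >= 1, step_bp >= 1)
  out <- lapply(unique(profile$contig), function(ctg) {
    sel <- profile$contig == ctg
    pos <- profile$site_pos[sel]
    dif <- profile$diff[sel]
    lo <- min(pos); hi <- max(pos)
    starts <- seq(lo, max(lo, hi - window_bp + 1), by = step_bp)
    cd <- c(0, cumsum(dif))
    # windows are [start, start + window_bp)
    i0 <- findInterval(starts - 0.5, pos)
    i1 <- findInterval(starts + window_bp - 0.5, pos)
    n_sites <- i1 - i0
    n_diff <- cd[i1 + 1] - cd[i0 + 1]
    data.frame(contig = ctg, mid_bp = starts + window_bp / 2,
               n_sites = n_sites, n_diff = n_diff,
               divergence = ifelse(n_sites > 0, n_diff / n_sites, NA_real_))
  })
  do.call(rbind, out)
}
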