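#' Orient the stream allele at every SNP
#'
#' The stream allele is the nucleotide relatively more frequent in the most
#' distant stream sample than in the most distant lake sample.  Ties (equal
#' frequencies) are broken deterministically toward the alphabetically first
#' allele nucleotide and flagged.  Applying the orientation twice is a no-op.
#'
#' @param snps A `snp_table` (see [discover_snps()]).
#' @param lake_site,stream_site Reference site ids (defaults `"L1"`, `"S7"`).
#' @return The `snp_table` with added columns `stream_allele` (nucleotide),
#'   `freq_stream` (per-row frequency of the stream allele) and `tie`
#'   (logical).  SNPs missing (NA frequency) in either reference sample are
#'   dropped with a message.
#' @export
orient_stream_allele <- function(snps, lake_site = "L1", stream_site = "S7") {
  drop_cols <- intersect(c("stream_allele", "tie", "freq_stream"), names(snps))
  if (length(drop_cols)) {  # re-orientation is idempotent
    snps <- copy(snps)[, (drop_cols) := NULL]
    setattr(snps, "class", c("snp_table", class(data.table())))
  }
  ref <- dcast(snps[site_id %in% c(lake_site, stream_site)],
               chrom + pos + allele1 + allele2 ~ site_id, value.var = "freq")
  if (!all(c(lake_site, stream_site) %in% names(ref)))
    stop("reference site not genotyped: need ", lake_site, " and ", stream_site)
  fl <- ref[[lake_site]]
  fs <- ref[[stream_site]]
  drop <- is.na(fl) | is.na(fs)
  if (any(drop))
    message(sum(drop), " SNP(s) missing in a reference sample; dropped")
  ref <- ref[!drop]
  fl <- fl[!drop]; fs <- fs[!drop]
  ## freq is the frequency of allele2; stream allele = allele with higher
  ## frequency at the stream reference than at the lake reference
  a2_is_stream <- fs > fl
  tie_rows <- fs == fl
  first_allele <- pmin(ref$allele1, ref$allele2)  # lexicographic
  ref[, stream_allele := fifelse(tie_rows, first_allele,
                                 fifelse(a2_is_stream, allele2, allele1))]
  ref[, tie := tie_rows]
  out <- merge(snps, ref[, .(chrom, pos, allele1, allele2, stream_allele, tie)],
               by = c("chrom", "pos", "allele1", "allele2"))
  out[, freq_stream := fifelse(stream_allele == allele2, freq, 1 - freq)]
  setkey(out, chrom, pos, site_id)
  setattr(out, "class", c("snp_table", class(data.table())))
  out[]
}

## cluster ids by single-linkage chaining: any gap < spacing merges
chain_clusters <- function(dt, spacing_bp) {
  setorder(dt, chrom, pos)
  dt[, cluster_id := {
    gap_new <- c(TRUE, diff(pos) >= spacing_bp)
    cumsum(gap_new)
  }, by = chrom]
  dt[, cluster_id := paste(chrom, cluster_id, sep = "_")]
  dt
}

#' Ascertain the panel of selected SNPs
#'
#' Candidates are autosomal SNPs whose endpoint AFD (in `profile`) reaches
#' `threshold`.  Candidates closer than `spacing_bp` are chained into
#' clusters by single linkage (a gap below the threshold anywhere merges),
#' and one member per cluster is drawn uniformly at random, ensuring
#' statistical independence among panel members.
#'
#' @param profile A `pair_profile` of the endpoint comparison (e.g. L1-S7).
#' @param layout Genome layout; sex chromosomes are excluded.
#' @param threshold Minimum endpoint AFD (default 0.97).
#' @param spacing_bp Independence spacing (default 50 kb).
#' @param seed Integer seed for the per-cluster draw.
#' @return A `snp_panel`: data.table (`chrom`, `pos`, `endpoint_afd`,
#'   `cluster_id`) with attributes `category = "selected"`, `threshold`,
#'   `spacing_bp`, `seed`, `n_candidates`.  Empty (with a warning) if no SNP
#'   qualifies.
#' @export
pick_selected_panel <- function(profile, layout, threshold = 0.97,
                                spacing_bp = 50000, seed = 1L) {
  layout <- validate_layout(layout)
  auto <- layout[is_sex == FALSE, chrom]
  cand <- as.data.table(profile)[chrom %in% auto & afd >= threshold,
                                 .(chrom, pos, endpoint_afd = afd)]
  if (nrow(cand) == 0L) {
    warning("no candidate SNP reaches AFD >= ", threshold)
    panel <- cand[, cluster_id := character(0)]
  } else {
    cand <- chain_clusters(cand, spacing_bp)
    setorder(cand, chrom, pos)   # input-order invariance
    panel <- withr::with_seed(seed,
      cand[, .SD[sample.int(.N, 1L)], by = cluster_id])
    setcolorder(panel, c("chrom", "pos", "endpoint_afd", "cluster_id"))
    setorder(panel, chrom, pos)
  }
  structure_panel(panel, "selected", threshold = threshold,
                  spacing_bp = spacing_bp, seed = seed,
                  n_candidates = nrow(cand))
}

#' Ascertain an AFD-matched background panel (neutral or loDiff)
#'
#' Candidates are autosomal SNPs whose endpoint AFD deviates from
#' `target_afd` by at most `tolerance` (absolute AFD units).  `n` members are
#' drawn at random in a random order, greedily rejecting any draw closer than
#' `spacing_bp` to an already accepted member on the same chromosome.
#'
#' @inheritParams pick_selected_panel
#' @param target_afd Target AFD (e.g. the genome-wide median, or half of it).
#' @param tolerance Absolute deviation allowed (default 0.001, i.e. 0.1
#'   AFD percentage points).
#' @param n Panel size (default 500).  If fewer admissible SNPs exist, all
#'   are returned with a warning.
#' @param category Panel label (`"neutral"` or `"loDiff"`).
#' @return A `snp_panel` (see [pick_selected_panel()]).
#' @export
pick_matched_panel <- function(profile, layout, target_afd,
                               tolerance = 0.001, n = 500L,
                               spacing_bp = 50000, seed = 1L,
                               category = "neutral") {
  stop_if_not_prob(target_afd, "target_afd")
  layout <- validate_layout(layout)
  auto <- layout[is_sex == FALSE, chrom]
  cand <- as.data.table(profile)[chrom %in% auto &
                                   abs(afd - target_afd) <= tolerance,
                                 .(chrom, pos, endpoint_afd = afd)]
  setorder(cand, chrom, pos)     # input-order invariance
  picked <- integer(0)
  if (nrow(cand)) {
    ord <- withr::with_seed(seed, sample.int(nrow(cand)))
    ## greedy rejection sampling against accepted members
    acc <- list()
    for (i in ord) {
      ch <- cand$chrom[i]; p <- cand$pos[i]
      prev <- acc[[ch]]
      if (is.null(prev) || all(abs(prev - p) >= spacing_bp)) {
        acc[[ch]] <- c(prev, p)
        picked <- c(picked, i)
        if (length(picked) >= n) break
      }
    }
  }
  if (length(picked) < n)
    warning("only ", length(picked), " admissible SNPs for target AFD ",
            target_afd, " (requested ", n, ")")
  panel <- cand[sort(picked)]
  panel[, cluster_id := NA_character_]
  structure_panel(panel, category, target_afd = target_afd,
                  tolerance = tolerance, spacing_bp = spacing_bp,
                  seed = seed, n_candidates = nrow(cand))
}

structure_panel <- function(panel, category, ...) {
  setattr(panel, "category", category)
  meta <- list(...)
  for (nm in names(meta)) setattr(panel, nm, meta[[nm]])
  setattr(panel, "class", c("snp_panel", class(data.table())))
  panel[]
}

#' Write a panel TSV
#' @param panel A `snp_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  out <- copy(as.data.table(panel))
  out[, category := attr(panel, "category")]
  out[, seed := attr(panel, "seed")]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Generic interval-overlap helper
#'
#' Returns, for each query interval, the features (e.g. genes) overlapping
#' it.  Provided as a convenience stub for annotation lookups around panel
#' SNPs; not validated against any specific annotation.
#'
#' @param features data.table with `chrom`, `start`, `end` (1-based,
#'   half-open) plus arbitrary columns.
#' @param queries data.table with `chrom`, `start`, `end`.
#' @return data.table of overlapping (query, feature) pairs.
#' @export
interval_overlaps <- function(features, queries) {
  f <- as.data.table(features)
  q <- as.data.table(queries)
  out <- f[q, on = .(chrom, start < end, end > start), nomatch = NULL,
           .(chrom, q_start = i.start, q_end = i.end,
             f_start = x.start, f_end = x.end)]
  out
}
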