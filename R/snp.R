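#' Absolute allele frequency difference (AFD)
#'
#' For biallelic loci AFD reduces to `|p1 - p2|` of the shared oriented
#' allele; it is 1 iff the populations are fixed for alternative alleles and
#' 0 iff frequencies are equal.
#'
#' @param p1,p2 Frequencies of the same oriented allele in two populations,
#'   in `[0, 1]` (vectorized).
#' @return AFD in `[0, 1]`.
#' @export
afd <- function(p1, p2) {
  stop_if_not_prob(p1[!is.na(p1)], "p1")
  stop_if_not_prob(p2[!is.na(p2)], "p2")
  abs(p1 - p2)
}

#' Fst from two allele frequencies
#'
#' Nei/Hudson-style estimator on pool frequencies:
#' `(Ht - Hs) / Ht` with `Ht = 2 p.bar (1 - p.bar)`, `p.bar = (p1 + p2)/2`,
#' and `Hs` the mean of the within-population heterozygosities
#' `2 p_i (1 - p_i)`.  Returns 0 where `Ht = 0` (both populations fixed for
#' the same allele).
#'
#' @inheritParams afd
#' @return Fst in `[0, 1]`.
#' @export
fst <- function(p1, p2) {
  stop_if_not_prob(p1[!is.na(p1)], "p1")
  stop_if_not_prob(p2[!is.na(p2)], "p2")
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  out <- ifelse(ht > 0, (ht - hs) / ht, 0)
  pmin(pmax(out, 0), 1)
}

#' Discover SNPs from pooled nucleotide counts
#'
#' Counts are summed within a discovery pool A (e.g. the two lake sites) and
#' pool B (the two most distant stream sites).  A position qualifies as a SNP
#' iff (i) total read depth lies within `[depth_min, depth_max]` in each pool
#' separately (excludes poorly sequenced and repeated regions) and (ii) the
#' minor allele frequency on the two most frequent nucleotides of the
#' combined pools is at least `maf_min` (information content).  Retained
#' positions are then genotyped in every sample separately: the per-sample
#' frequency of allele 2 is computed from that sample's counts of the two SNP
#' alleles (reads of a third nucleotide are ignored, i.e. frequencies are
#' renormalized over the two SNP alleles).
#'
#' @param counts A `count_table` covering all samples.
#' @param pool_a_sites,pool_b_sites Disjoint, non-empty site-id vectors.
#' @param depth_min,depth_max Per-pool depth window (defaults 50 / 400).
#' @param maf_min Combined-pool minor allele frequency threshold (default
#'   0.25).
#' @return A `snp_table`: long data.table with one row per SNP per sample
#'   (`chrom`, `pos`, `allele1`, `allele2`, `site_id`, `n1`, `n2`, `depth`,
#'   `freq`), where `freq` is the frequency of `allele2` and `depth` the
#'   total (four-nucleotide) read depth in that sample.  `allele1`/`allele2`
#'   are the major/minor nucleotide of the combined discovery pools; ties are
#'   broken by nucleotide order A < C < G < T.
#' @export
discover_snps <- function(counts, pool_a_sites, pool_b_sites,
                          depth_min = 50, depth_max = 400, maf_min = 0.25) {
  counts <- as_count_table(counts)
  if (length(pool_a_sites) == 0L || length(pool_b_sites) == 0L)
    stop("discovery pools must be non-empty")
  if (length(intersect(pool_a_sites, pool_b_sites)))
    stop("discovery pools must be disjoint")
  unknown <- setdiff(c(pool_a_sites, pool_b_sites), unique(counts$site_id))
  if (length(unknown)) stop("unknown site IDs: ", paste(unknown, collapse = ", "))

  pool_sum <- function(ids)
    counts[site_id %in% ids,
           .(A = sum(A), C = sum(C), G = sum(G), T = sum(T)),
           by = .(chrom, pos)]
  pa <- pool_sum(pool_a_sites)
  pb <- pool_sum(pool_b_sites)
  m <- merge(pa, pb, by = c("chrom", "pos"), suffixes = c("_a", "_b"))

  da <- m$A_a + m$C_a + m$G_a + m$T_a
  db <- m$A_b + m$C_b + m$G_b + m$T_b
  keep_depth <- da >= depth_min & da <= depth_max &
                db >= depth_min & db <= depth_max
  comb <- cbind(A = m$A_a + m$A_b, C = m$C_a + m$C_b,
                G = m$G_a + m$G_b, T = m$T_a + m$T_b)
  ## two most frequent nucleotides of the combined counts; stable order
  ## breaks ties A < C < G < T
  ord <- t(apply(comb, 1L, order, decreasing = TRUE))  # ties: first index wins
  top1 <- comb[cbind(seq_len(nrow(comb)), ord[, 1L])]
  top2 <- comb[cbind(seq_len(nrow(comb)), ord[, 2L])]
  maf <- ifelse(top1 + top2 > 0, top2 / (top1 + top2), 0)
  keep <- keep_depth & maf >= maf_min

  snp_loci <- data.table(chrom = m$chrom[keep], pos = m$pos[keep],
                         allele1 = NUCS[ord[keep, 1L]],
                         allele2 = NUCS[ord[keep, 2L]])
  genotype_snps(counts, snp_loci)
}

#' Genotype a set of biallelic loci in every sample of a count table
#'
#' @param counts A `count_table`.
#' @param loci data.table with `chrom`, `pos`, `allele1`, `allele2`.
#' @return A `snp_table` (see [discover_snps()]).
#' @export
genotype_snps <- function(counts, loci) {
  counts <- as_count_table(counts)
  loci <- as.data.table(loci)[, .(chrom, pos, allele1, allele2)]
  g <- merge(counts, loci, by = c("chrom", "pos"))
  cnt <- as.matrix(g[, .(A, C, G, T)])
  idx1 <- match(g$allele1, NUCS)
  idx2 <- match(g$allele2, NUCS)
  g[, n1 := cnt[cbind(seq_len(.N), idx1)]]
  g[, n2 := cnt[cbind(seq_len(.N), idx2)]]
  g[, depth := A + C + G + T]
  g[, freq := fifelse(n1 + n2 > 0, n2 / (n1 + n2), NA_real_)]
  out <- g[, .(chrom, pos, allele1, allele2, site_id, n1, n2, depth, freq)]
  setkey(out, chrom, pos, site_id)
  setattr(out, "class", c("snp_table", class(data.table())))
  out[]
}

#' Per-SNP differentiation profile between two samples
#'
#' AFD (and Fst) at every SNP where *both* samples pass the per-sample read
#' depth window; SNPs failing the filter in either sample are absent from the
#' profile (missing, never imputed as zero).
#'
#' @param snps A `snp_table`.
#' @param site_a,site_b Site ids.
#' @param depth_min,depth_max Per-sample total-depth window (defaults 50 /
#'   200).
#' @return A `pair_profile`: data.table (`chrom`, `pos`, `afd`, `fst`,
#'   `depth_a`, `depth_b`), sorted by position, with attributes `site_a`,
#'   `site_b`.  A profile with zero passing SNPs is returned empty with a
#'   warning.
#' @export
pairwise_profile <- function(snps, site_a, site_b,
                             depth_min = 50, depth_max = 200) {
  a <- snps[site_id == site_a]
  b <- snps[site_id == site_b]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("site not genotyped: ", if (nrow(a) == 0L) site_a else site_b)
  m <- merge(a, b, by = c("chrom", "pos", "allele1", "allele2"),
             suffixes = c("_a", "_b"))
  ok <- m$depth_a >= depth_min & m$depth_a <= depth_max &
        m$depth_b >= depth_min & m$depth_b <= depth_max &
        !is.na(m$freq_a) & !is.na(m$freq_b)
  prof <- m[ok, .(chrom, pos, afd = afd(freq_a, freq_b),
                  fst = fst(freq_a, freq_b),
                  depth_a, depth_b)]
  setorder(prof, chrom, pos)
  if (nrow(prof) == 0L)
    warning("no SNP passes the depth filter for ", site_a, "-", site_b)
  setattr(prof, "site_a", site_a)
  setattr(prof, "site_b", site_b)
  setattr(prof, "class", c("pair_profile", class(data.table())))
  prof[]
}

#' Sliding-window mean AFD
#'
#' Windows are half-open `[start, start + window_bp)` on a 1-based coordinate
#' system, laid on a fixed grid with starts `1, 1 + step_bp, 1 + 2 step_bp,
#' ...` per chromosome.  Windows containing fewer than `min_snps` profile
#' SNPs are dropped.
#'
#' @param profile A `pair_profile` (or data.table with `chrom`, `pos`,
#'   `afd`).
#' @param window_bp Window size (default 10 kb).
#' @param step_bp Step between window starts (default 5 kb, i.e. 50%
#'   overlap); must divide `window_bp`.
#' @param min_snps Minimum SNPs per window (default 5).
#' @return data.table (`chrom`, `start`, `end`, `n_snps`, `mean_afd`), keyed
#'   by (chrom, start); `end = start + window_bp` (exclusive).
#' @export
window_mean_afd <- function(profile, window_bp = 10000, step_bp = 5000,
                            min_snps = 5L) {
  if (window_bp <= 0 || step_bp <= 0) stop("window_bp and step_bp must be > 0")
  if (window_bp %% step_bp != 0)
    stop("step_bp must divide window_bp")
  r <- window_bp %/% step_bp
  p <- as.data.table(profile)[, .(chrom, pos, afd)]
  ## replicate each SNP into the r windows covering it
  reps <- rbindlist(lapply(seq_len(r) - 1L, function(j) {
    k <- (p$pos - 1L) %/% step_bp - j          # window index
    data.table(chrom = p$chrom, start = k * step_bp + 1, afd = p$afd)
  }))
  reps <- reps[start >= 1 & !is.na(afd)]
  out <- reps[, .(n_snps = .N, mean_afd = mean(afd)), by = .(chrom, start)]
  out <- out[n_snps >= min_snps]
  out[, end := start + window_bp]
  setcolorder(out, c("chrom", "start", "end", "n_snps", "mean_afd"))
  setkey(out, chrom, start)
  out[]
}

#' Smooth a differentiation profile along a chromosome
#'
#' Cubic smoothing spline (`stats::smooth.spline`) evaluated at the input
#' positions.
#'
#' @param positions Base-pair positions (>= 4 points).
#' @param values Values to smooth (e.g. per-SNP AFD).
#' @param spar Smoothing parameter passed to `smooth.spline` (default 0.1).
#' @return Numeric vector of smoothed values at `positions`.
#' @export
smooth_profile <- function(positions, values, spar = 0.1) {
  ok <- is.finite(positions) & is.finite(values)
  if (sum(ok) < 4L) stop("need at least 4 finite points to smooth")
  fit <- smooth.spline(positions[ok], values[ok], spar = spar)
  out <- rep(NA_real_, length(positions))
  out[ok] <- predict(fit, positions[ok])$y
  out
}
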