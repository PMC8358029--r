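#' Select population-distinctive SNPs for the flood analysis
#'
#' Keeps SNPs that are (i) highly differentiated between the lake pool
#' (counts of the lake sites summed) and the stream pool (AFD >=
#' `afd_min`), and (ii) sequenced to at least `depth_min` in each of the
#' temporal marsh samples.  The stream allele is oriented by the pool
#' comparison (the allele more frequent in the stream pool).
#'
#' @param snps A `snp_table` genotyped in the pool sites and all temporal
#'   samples.
#' @param lake_pool,stream_pool Site-id vectors (defaults `c("L1","L2")`,
#'   `c("S6","S7")`).
#' @param temporal_samples The three temporal site ids, in time order
#'   (before, during, after).
#' @param afd_min Pool AFD threshold (default 0.75).
#' @param depth_min Per-temporal-sample depth minimum (default 50).
#' @return Object of class `flood_snps`: list with `loci` (data.table incl.
#'   pool frequencies and pool AFD), `freq` (data.table: chrom, pos, one
#'   stream-allele frequency column per temporal sample) and
#'   `temporal_samples`.
#' @export
select_flood_snps <- function(snps, lake_pool = c("L1", "L2"),
                              stream_pool = c("S6", "S7"),
                              temporal_samples,
                              afd_min = 0.75, depth_min = 50) {
  have <- unique(snps$site_id)
  missing_ts <- setdiff(temporal_samples, have)
  if (length(missing_ts))
    stop("missing temporal sample(s): ", paste(missing_ts, collapse = ", "))
  if (length(setdiff(c(lake_pool, stream_pool), have)))
    stop("missing pool sample(s)")
  if (length(temporal_samples) < 2L)
    stop("need the temporal samples in time order")

  pool_freq <- function(ids) {
    snps[site_id %in% ids,
         .(n1 = sum(n1), n2 = sum(n2)), by = .(chrom, pos, allele1, allele2)][
           , .(chrom, pos, allele1, allele2,
               freq = fifelse(n1 + n2 > 0, n2 / (n1 + n2), NA_real_))]
  }
  pl <- pool_freq(lake_pool)
  ps <- pool_freq(stream_pool)
  loci <- merge(pl, ps, by = c("chrom", "pos", "allele1", "allele2"),
                suffixes = c("_lake", "_stream"))
  loci <- loci[!is.na(freq_lake) & !is.na(freq_stream) &
                 abs(freq_lake - freq_stream) >= afd_min]
  ## stream allele: more frequent in the stream pool; ties cannot pass afd_min
  loci[, stream_allele := fifelse(freq_stream > freq_lake, allele2, allele1)]
  loci[, `:=`(p_lake = fifelse(stream_allele == allele2, freq_lake, 1 - freq_lake),
              p_stream = fifelse(stream_allele == allele2, freq_stream,
                                 1 - freq_stream))]

  tmp <- snps[site_id %in% temporal_samples &
                depth >= depth_min & !is.na(freq)]
  wide <- dcast(tmp, chrom + pos + allele1 + allele2 ~ site_id,
                value.var = "freq")
  present <- intersect(temporal_samples, names(wide))
  wide <- wide[stats::complete.cases(wide[, ..present])]
  out <- merge(loci, wide, by = c("chrom", "pos", "allele1", "allele2"))
  if (nrow(out) == 0L) stop("no SNP passes the flood filters")
  for (ts in temporal_samples)
    out[, (ts) := fifelse(stream_allele == allele2, get(ts), 1 - get(ts))]
  freq <- out[, c("chrom", "pos", temporal_samples), with = FALSE]
  structure(list(loci = out[], freq = freq[],
                 temporal_samples = temporal_samples,
                 afd_min = afd_min, depth_min = depth_min),
            class = "flood_snps")
}

#' Per-time-point summaries of the flood SNP set
#'
#' Median and mean stream-allele frequency, the count of SNPs monomorphic
#' for the lake allele (observed stream-allele frequency exactly 0), and —
#' when the samples are (before, during, after) — the percent decline in
#' that count from during to after:
#' `100 * (count_during - count_after) / count_during`.
#'
#' @param fs A `flood_snps` object.
#' @return List with `summary` (data.table: sample, n, median, mean,
#'   n_monomorphic_lake) and `monomorphic_decline_pct` (NA when undefined).
#' @export
temporal_summaries <- function(fs) {
  stopifnot(inherits(fs, "flood_snps"))
  sm <- rbindlist(lapply(fs$temporal_samples, function(ts) {
    v <- fs$freq[[ts]]
    data.table(sample = ts, n = length(v), median = median(v),
               mean = mean(v), n_monomorphic_lake = sum(v == 0))
  }))
  decline <- NA_real_
  if (length(fs$temporal_samples) >= 3L) {
    nd <- sm$n_monomorphic_lake[2L]
    na_ <- sm$n_monomorphic_lake[3L]
    if (nd > 0) decline <- 100 * (nd - na_) / nd
  }
  list(summary = sm[], monomorphic_decline_pct = decline)
}

#' Mixture of before-flood and lake allele-frequency distributions
#'
#' `p_mix = lambda * p_lake + (1 - lambda) * p_before` per SNP, for each
#' lambda on the grid.
#'
#' @param p_before,p_lake Per-SNP stream-allele frequencies (matched order).
#' @param lambda_grid Mixing proportions (default `seq(0.1, 1, by = 0.1)`).
#' @return Matrix SNPs x lambdas of mixed frequencies (columns named by
#'   lambda).
#' @export
mix_distributions <- function(p_before, p_lake,
                              lambda_grid = seq(0.1, 1, by = 0.1)) {
  if (length(p_before) != length(p_lake)) stop("mismatched SNP sets")
  stop_if_not_prob(p_before, "p_before")
  stop_if_not_prob(p_lake, "p_lake")
  stop_if_not_prob(lambda_grid, "lambda_grid")
  out <- vapply(lambda_grid,
                function(l) l * p_lake + (1 - l) * p_before,
                numeric(length(p_before)))
  out <- matrix(out, nrow = length(p_before),
                dimnames = list(NULL, format(lambda_grid)))
  out
}

flood_summaries <- function(freq, depth, low_thresh = 0.05) {
  k <- round(freq * depth)
  c(mean = mean(freq), median = median(freq),
    frac_zero = mean(k == 0), frac_low = mean(freq < low_thresh))
}

#' Rejection-ABC estimate of the lake-migrant proportion during the flood
#'
#' Draws `n_sims` values of lambda from a uniform prior, simulates the
#' during-flood sample by mixing `p_before` and `p_lake` and binomially
#' resampling read counts at the observed depths, and accepts the
#' `accept_fraction` of draws whose summary statistics are closest
#' (Euclidean distance on summaries standardized by their simulation SD).
#' Summaries: mean, median, fraction of SNPs with stream-allele count 0,
#' fraction with frequency < 0.05 — the features of the frequency
#' distribution the temporal comparison reports.
#'
#' @param observed_during data.frame/list with `freq` (observed during-flood
#'   stream-allele frequencies) and `depth` (read depths), or a
#'   `flood_snps` plus `depths`.
#' @param p_before,p_lake Per-SNP stream-allele frequencies (matched).
#' @param prior Lower/upper bound of the uniform prior (default `c(0, 1)`).
#' @param n_sims Number of prior draws (default 1e5; scale down with the
#'   SNP count).
#' @param accept_fraction Fraction of draws accepted (default 0.001).
#' @param seed Integer seed.
#' @return Object of class `mixture_estimate`: list with `posterior`
#'   (accepted lambdas), `median`, `ci` (2.5/97.5 percentiles),
#'   `p_ge_0.9`, `n_accepted`, `observed` and `prior`.
#' @export
abc_lake_proportion <- function(observed_during, p_before, p_lake,
                                prior = c(0, 1), n_sims = 1e5,
                                accept_fraction = 0.001, seed = 1L) {
  if (length(p_before) != length(p_lake)) stop("mismatched SNP sets")
  f_obs <- observed_during$freq
  d_obs <- as.integer(observed_during$depth)
  if (length(f_obs) != length(p_before) || length(d_obs) != length(p_before))
    stop("observed_during must carry freq and depth per SNP")
  if (any(d_obs < 1L)) stop("observed depths must be >= 1")
  obs <- flood_summaries(f_obs, d_obs)

  sims <- withr::with_seed(seed, {
    lam <- runif(n_sims, prior[1], prior[2])
    list(lambda = lam,
         stats = abc_sim_summaries_cpp(p_before, p_lake, d_obs, lam, 0.05))
  })
  sdv <- apply(sims$stats, 2L, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sims$stats, 2L, obs, "-")
  z <- sweep(z, 2L, sdv, "/")
  dist <- sqrt(rowSums(z^2))
  n_acc <- max(1L, ceiling(accept_fraction * n_sims))
  keep <- order(dist)[seq_len(n_acc)]
  post <- sims$lambda[keep]
  structure(list(posterior = post, median = median(post),
                 ci = unname(quantile(post, c(0.025, 0.975))),
                 p_ge_0.9 = mean(post >= 0.9),
                 n_accepted = n_acc, n_sims = n_sims,
                 observed = obs, prior = prior, seed = seed),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("<mixture_estimate> lambda = %.3f [%.3f, %.3f], P(lambda >= 0.9) = %.2f (%d accepted / %g sims)\n",
              x$median, x$ci[1], x$ci[2], x$p_ge_0.9, x$n_accepted, x$n_sims))
  invisible(x)
}
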