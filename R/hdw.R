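#' Per-window AFD contrast between a target and a baseline comparison
#'
#' Subtracts the baseline window mean AFD (e.g. the within-lake L1-L2
#' comparison) from the target window mean AFD (e.g. L1-S1) on the shared
#' window grid.  Windows present in only one input are dropped.
#'
#' @param win_target,win_baseline Window tables from [window_mean_afd()] on
#'   identical grids.
#' @return data.table (`chrom`, `start`, `end`, `delta`) keyed by
#'   (chrom, start).
#' @export
delta_windows <- function(win_target, win_baseline) {
  m <- merge(as.data.table(win_target), as.data.table(win_baseline),
             by = c("chrom", "start", "end"), suffixes = c("_t", "_b"))
  if (nrow(m) == 0L) stop("disjoint window sets")
  out <- m[, .(chrom, start, end, delta = mean_afd_t - mean_afd_b)]
  setkey(out, chrom, start)
  out[]
}

#' Pick high-differentiation windows and an equal-size random control set
#'
#' HDW are the most differentiated `top_fraction` of windows by `delta`
#' (ties at the cut broken deterministically by smallest genomic
#' coordinate); controls are drawn uniformly without replacement from the
#' remaining windows.
#'
#' @param deltas Output of [delta_windows()].
#' @param top_fraction Fraction of windows taken as HDW (default 0.005).
#' @param seed Integer seed for the control draw.
#' @return List with `hdw` and `control` (equal-size data.tables).
#' @export
pick_hdw_and_controls <- function(deltas, top_fraction = 0.005, seed = 1L) {
  d <- as.data.table(deltas)
  n_hdw <- max(1L, round(nrow(d) * top_fraction))
  if (nrow(d) < 2L * n_hdw) stop("too few windows")
  setorder(d, -delta, chrom, start)      # ties: smallest coordinate first
  hdw <- d[seq_len(n_hdw)]
  rest <- d[-seq_len(n_hdw)]
  ctrl <- withr::with_seed(seed, rest[sample.int(.N, n_hdw)])
  setkey(hdw, chrom, start); setkey(ctrl, chrom, start)
  list(hdw = hdw[], control = ctrl[])
}

boot_median_diff <- function(x, y, n_boot, seed) {
  point <- median(x) - median(y)
  if (length(x) < 2L || length(y) < 2L) {
    warning("degenerate bootstrap: a set has fewer than 2 elements")
    return(list(point = point, ci = c(point, point)))
  }
  bm <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      median(sample(x, replace = TRUE)) - median(sample(y, replace = TRUE)),
      0)
  })
  list(point = point, ci = unname(quantile(bm, c(0.025, 0.975))))
}

#' Empirical deltaAFD between HDW and control windows in a focal comparison
#'
#' Difference in median window-mean AFD (focal comparison, e.g. L1-S7)
#' between the HDW and control sets, with a percentile 95% CI from
#' bootstrapping windows within each set.
#'
#' @param hdw,controls Window sets from [pick_hdw_and_controls()].
#' @param win_focal Window table of the focal comparison on the same grid.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return Object of class `delta_afd_result`: list with `source =
#'   "empirical"`, `delta_afd`, `ci`, `n`, `median_hdw`, `median_control`.
#' @export
empirical_delta_afd <- function(hdw, controls, win_focal, n_boot = 10000L,
                                seed = 1L) {
  if (nrow(hdw) == 0L || nrow(controls) == 0L) stop("empty window set")
  wf <- as.data.table(win_focal)
  vh <- merge(as.data.table(hdw), wf, by = c("chrom", "start", "end"))$mean_afd
  vc <- merge(as.data.table(controls), wf, by = c("chrom", "start", "end"))$mean_afd
  if (length(vh) == 0L || length(vc) == 0L)
    stop("window sets have no mean AFD in the focal comparison")
  b <- boot_median_diff(vh, vc, n_boot, seed)
  structure(list(source = "empirical", delta_afd = b$point, ci = b$ci,
                 n = c(hdw = length(vh), control = length(vc)),
                 median_hdw = median(vh), median_control = median(vc),
                 n_boot = n_boot),
            class = "delta_afd_result")
}

#' @export
print.delta_afd_result <- function(x, ...) {
  cat(sprintf("<delta_afd_result %s> deltaAFD = %.4f [%.4f, %.4f]\n",
              x$source, x$delta_afd, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Simulate haploid neutral drift of unlinked loci
#'
#' Individual-based haploid Wright-Fisher population: `n` haplotypes carrying
#' `n_loci` biallelic unlinked loci.  Each generation, offspring are drawn at
#' random with replacement from the parents; random assortment is realized by
#' swapping alleles, per locus independently with probability 1/2, between
#' the haplotypes within consecutive offspring pairs.  Initial allele
#' frequencies are realized exactly (rounded to the nearest achievable count
#' of `n`).
#'
#' @param init_freq Per-locus initial stream-allele frequencies.
#' @param n Haploid population size.
#' @param g Generations.
#' @return List with `freq_before` (realized) and `freq_after`.
#' @export
drift_sim_haploid <- function(init_freq, n = 200L, g = 1000L) {
  stop_if_not_prob(init_freq, "init_freq")
  if (n < 1L || g < 0L) stop("n >= 1 and g >= 0 required")
  L <- length(init_freq)
  k0 <- round(init_freq * n)
  ## exact realization: k0 ones per locus, shuffled among haplotypes
  state <- vapply(k0, function(k) {
    v <- rep(c(1L, 0L), c(k, n - k))
    v[sample.int(n)]
  }, integer(n))
  freq_before <- colMeans(state)
  half <- n %/% 2L
  for (gen in seq_len(g)) {
    state <- state[sample.int(n, n, replace = TRUE), , drop = FALSE]
    if (half > 0L) {
      i1 <- seq_len(half) * 2L - 1L
      i2 <- i1 + 1L
      swap <- matrix(runif(half * L) < 0.5, nrow = half)
      a <- state[i1, , drop = FALSE]
      b <- state[i2, , drop = FALSE]
      tmp <- a
      a[swap] <- b[swap]
      b[swap] <- tmp[swap]
      state[i1, ] <- a
      state[i2, ] <- b
    }
  }
  list(freq_before = freq_before, freq_after = colMeans(state))
}

#' Neutral drift benchmark for the HDW contrast
#'
#' Simulates, per replicate, a haploid population of size `n` with two sets
#' of `n_loci` unlinked loci: non-HDL with initial stream-allele frequencies
#' drawn uniformly from `init_range` (the stream allele is always the minor
#' allele), and HDL with the same draw shifted up by `hdl_increment`
#' (the observed HDW vs non-HDW difference in the ascertainment comparison).
#' After `g` generations of neutral drift, per-locus AFD is
#' `|freq_after - freq_before|`, and the replicate's deltaAFD is the
#' difference of the median AFD between HDL and non-HDL.  The reported point
#' estimate is the median across replicates, with a percentile bootstrap CI
#' over replicates.
#'
#' @param n Haploid population size (default 200).
#' @param g Generations (default 1000).
#' @param n_loci Loci per set (default 178).
#' @param init_range Uniform support of the initial minor-allele frequency
#'   (default `c(0.05, 0.5)`).
#' @param hdl_increment Initial-frequency increment of the HDL set (default
#'   0.1).
#' @param reps Replicates (default 25).
#' @param n_boot Bootstrap resamples over replicates (default 10000).
#' @param seed Integer seed.
#' @return A `delta_afd_result` with `source = "simulated"` and the
#'   per-replicate `deltas`.
#' @export
drift_benchmark <- function(n = 200L, g = 1000L, n_loci = 178L,
                            init_range = c(0.05, 0.5), hdl_increment = 0.1,
                            reps = 25L, n_boot = 10000L, seed = 1L) {
  if (init_range[1] < 0 || init_range[2] + hdl_increment > 1 ||
      init_range[1] >= init_range[2])
    stop("invalid init_range / hdl_increment")
  deltas <- vapply(seq_len(reps), function(r) {
    withr::with_seed(child_seed(seed, r), {
      p_non <- runif(n_loci, init_range[1], init_range[2])
      p_hdl <- runif(n_loci, init_range[1], init_range[2]) + hdl_increment
      sim <- drift_sim_haploid(c(p_non, p_hdl), n = n, g = g)
      a <- abs(sim$freq_after - sim$freq_before)
      median(a[seq_len(n_loci) + n_loci]) - median(a[seq_len(n_loci)])
    })
  }, 0)
  point <- median(deltas)
  bm <- withr::with_seed(child_seed(seed, 0), {
    vapply(seq_len(n_boot),
           function(i) median(sample(deltas, replace = TRUE)), 0)
  })
  structure(list(source = "simulated", delta_afd = point,
                 ci = unname(quantile(bm, c(0.025, 0.975))),
                 n = c(hdl = n_loci, non_hdl = n_loci), reps = reps,
                 n_boot = n_boot, deltas = deltas,
                 params = list(n = n, g = g, init_range = init_range,
                               hdl_increment = hdl_increment)),
            class = "delta_afd_result")
}
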