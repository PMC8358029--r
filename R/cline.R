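#' Geographic cline model: tanh center with exponential tails
#'
#' The scaled cline is `Phi(x) = (1 + tanh(2 (x - c) / w)) / 2` on the
#' central segment `[c - delta_L, c + delta_R]`.  Outside, the Szymura-Barton
#' exponential tails apply: for `x < c - delta_L`,
#' `Phi(x) = Phi_L * exp(4 tau_L (x - (c - delta_L)) / (w (1 + exp(-4 delta_L / w))))`
#' with `Phi_L = Phi(c - delta_L)`, mirrored on the right.  The expected
#' frequency is `p(x) = pmin + (pmax - pmin) Phi(x)`.  The width `w` is the
#' inverse of the maximum slope of the scaled cline; `tau` in `[0, 1]` is the
#' tail/center slope ratio (0 = flat tail, 1 = no slope change).  The model
#' is continuous and monotone non-decreasing in `x` by construction.
#'
#' @param params List or named vector with `c`, `w` (> 0), `pmin`, `pmax`
#'   (`0 <= pmin <= pmax <= 1`), `delta_L`, `tau_L`, `delta_R`, `tau_R`
#'   (deltas >= 0, taus in `[0, 1]`).  Missing tail entries default to
#'   `Inf`/1 (no tails).
#' @param x Positions along the gradient (meters).
#' @return Expected stream-allele frequency at `x`.
#' @export
cline_predict <- function(params, x) {
  p <- as.list(params)
  cc <- p$c; w <- p$w
  pmin_ <- p$pmin %||% 0; pmax_ <- p$pmax %||% 1
  dL <- p$delta_L %||% Inf; tL <- p$tau_L %||% 1
  dR <- p$delta_R %||% Inf; tR <- p$tau_R %||% 1
  if (!is.finite(cc) || !is.finite(w) || w <= 0) stop("invalid c or w")
  if (pmin_ < 0 || pmax_ > 1 || pmin_ > pmax_) stop("invalid pmin/pmax")
  if (dL < 0 || dR < 0 || tL < 0 || tL > 1 || tR < 0 || tR > 1)
    stop("invalid tail parameters")

  phi_c <- function(z) (1 + tanh(2 * (z - cc) / w)) / 2
  phi <- phi_c(x)
  if (is.finite(dL)) {
    xl <- cc - dL
    left <- x < xl
    if (any(left)) {
      denom <- w * (1 + exp(-4 * dL / w))
      phi[left] <- phi_c(xl) * exp(4 * tL * (x[left] - xl) / denom)
    }
  }
  if (is.finite(dR)) {
    xr <- cc + dR
    right <- x > xr
    if (any(right)) {
      denom <- w * (1 + exp(-4 * dR / w))
      phi[right] <- 1 - (1 - phi_c(xr)) * exp(-4 * tR * (x[right] - xr) / denom)
    }
  }
  pmin_ + (pmax_ - pmin_) * phi
}

cline_loglik <- function(params, k, n, x, p_clamp = 1e-6) {
  p <- cline_predict(params, x)
  p <- pmin(pmax(p, p_clamp), 1 - p_clamp)
  sum(k * log(p) + (n - k) * log(1 - p))
}

#' Fit a geographic cline to site frequencies by maximum likelihood
#'
#' Binomial likelihood on the stream-allele read counts:
#' `sum(k log p(x) + (n - k) log(1 - p(x)))`, with `p` clamped to
#' `[p_clamp, 1 - p_clamp]` so fixed sites keep a finite likelihood.
#' `pmin`/`pmax` are fixed at the observed extreme frequencies.  Optimization
#' is multi-start Nelder-Mead on a transformed unconstrained scale
#' (`log w`, `log delta`, logit `tau`); each of `n_replicates` restarts draws
#' its start from the seed, and the reported parameters are the element-wise
#' medians across converged replicates.
#'
#' @param freqs Per-site stream-allele frequency.
#' @param counts Per-site total allele counts underlying `freqs`.
#' @param distances Site positions (meters).
#' @param n_replicates Number of random restarts (default 10).
#' @param exclude_sites Optional indices or logical mask of sites to drop
#'   (e.g. the endpoint sites used for ascertainment).
#' @param model `"two_tail"` (default) or `"none"` (pure tanh cline).
#' @param p_clamp Frequency clamp (default 1e-6).
#' @param seed Integer seed.
#' @return Object of class `cline_fit`: list with `params` (named vector),
#'   `log_lik`, `replicates` (data.table of per-replicate estimates),
#'   `n_converged`, `model`.
#' @export
fit_cline <- function(freqs, counts, distances, n_replicates = 10L,
                      exclude_sites = NULL, model = c("two_tail", "none"),
                      p_clamp = 1e-6, seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(freqs) == length(counts),
            length(freqs) == length(distances))
  keep <- rep(TRUE, length(freqs))
  if (!is.null(exclude_sites)) {
    if (is.logical(exclude_sites)) keep <- !exclude_sites
    else keep[exclude_sites] <- FALSE
  }
  x <- distances[keep]; f <- freqs[keep]; n <- counts[keep]
  if (length(x) < 4L) stop("need at least 4 sites after exclusions")
  k <- round(f * n)
  pmin_ <- min(f); pmax_ <- max(f)
  span <- diff(range(x))
  if (span <= 0) stop("sites must span a positive distance")

  two_tail <- model == "two_tail"
  unpack <- function(th) {
    out <- list(c = th[1], w = exp(th[2]), pmin = pmin_, pmax = pmax_)
    if (two_tail) {
      out$delta_L <- exp(th[3]); out$tau_L <- stats::plogis(th[4])
      out$delta_R <- exp(th[5]); out$tau_R <- stats::plogis(th[6])
    }
    out
  }
  negll <- function(th) {
    pr <- unpack(th)
    ## soft box keeps the center near the sampled transect
    if (pr$c < min(x) - span || pr$c > max(x) + span) return(1e10)
    if (pr$w > 20 * span || pr$w < 1e-3) return(1e10)
    ll <- tryCatch(cline_loglik(pr, k, n, x, p_clamp), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  reps <- withr::with_seed(seed, {
    rbindlist(lapply(seq_len(n_replicates), function(r) {
      th0 <- c(runif(1, min(x), max(x)),
               log(runif(1, 0.02, 1.5) * span))
      if (two_tail)
        th0 <- c(th0, log(runif(1, 0.05, 1) * span), stats::qlogis(runif(1, .2, .8)),
                 log(runif(1, 0.05, 1) * span), stats::qlogis(runif(1, .2, .8)))
      opt <- tryCatch(
        optim(th0, negll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(opt)) return(NULL)
      pr <- unpack(opt$par)
      data.table(rep = r, c = pr$c, w = pr$w,
                 delta_L = pr$delta_L %||% Inf, tau_L = pr$tau_L %||% 1,
                 delta_R = pr$delta_R %||% Inf, tau_R = pr$tau_R %||% 1,
                 log_lik = -opt$value, converged = opt$convergence == 0)
    }))
  })
  conv <- reps[converged == TRUE]
  if (nrow(conv) == 0L) {
    if (nrow(reps) == 0L) stop("all cline replicates failed")
    warning("no replicate converged; using best non-converged estimate")
    conv <- reps[which.max(log_lik)]
  }
  ## keep replicates within 2 log-lik units of the best: Nelder-Mead restarts
  ## that stalled in a poor local optimum should not drag the median
  best <- max(conv$log_lik)
  good <- conv[log_lik >= best - 2]
  params <- c(c = median(good$c), w = median(good$w),
              pmin = pmin_, pmax = pmax_,
              delta_L = median(good$delta_L), tau_L = median(good$tau_L),
              delta_R = median(good$delta_R), tau_R = median(good$tau_R))
  structure(list(params = params, log_lik = best, replicates = reps,
                 n_converged = nrow(conv), model = model,
                 data = data.table(distance_m = x, freq = f, total = n)),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("<cline_fit %s> center = %.1f m, width = %.1f m (logLik %.2f, %d/%d converged)\n",
              x$model, x$params["c"], x$params["w"], x$log_lik,
              x$n_converged, nrow(x$replicates)))
  invisible(x)
}

#' Summarize cline fits across a SNP panel
#'
#' Medians of cline center and width across per-SNP fits, with percentile
#' 95% bootstrap compatibility intervals obtained by resampling SNPs (fits),
#' not sites.
#'
#' @param fits List of `cline_fit` objects (>= 2).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return List with `center` and `width`, each `c(median, lower, upper)`,
#'   plus `n_snps` and the per-SNP estimates.
#' @export
summarize_panel_clines <- function(fits, n_boot = 10000L, seed = 1L) {
  if (length(fits) < 2L) stop("need at least 2 fits to summarize")
  cs <- vapply(fits, function(f) unname(f$params["c"]), 0)
  ws <- vapply(fits, function(f) unname(f$params["w"]), 0)
  boot_ci <- function(v) {
    bm <- withr::with_seed(seed, {
      idx <- matrix(sample.int(length(v), length(v) * n_boot, replace = TRUE),
                    ncol = n_boot)
      matrixStats_colMedians(matrix(v[idx], ncol = n_boot))
    })
    c(median = median(v), lower = unname(quantile(bm, 0.025)),
      upper = unname(quantile(bm, 0.975)))
  }
  list(center = boot_ci(cs), width = boot_ci(ws),
       n_snps = length(fits),
       estimates = data.table(c = cs, w = ws))
}

## column medians without extra deps
matrixStats_colMedians <- function(m) apply(m, 2L, median)

#' Cline-width estimation artifact experiment
#'
#' Generates, for each AFD level, SNPs whose true site frequencies follow the
#' *same* abrupt break shape (step at `break_m`) scaled to that endpoint AFD,
#' adds two-stage pool-seq sampling noise, fits clines, and reports per-level
#' medians and inter-quartile spreads of fitted center and width.  With
#' identically abrupt breaks, lower AFD levels yield wider fitted clines and
#' larger spread — the estimation artifact this experiment quantifies.
#'
#' @param afd_levels Endpoint AFD levels (default `c(0.97, 0.35, 0.175)`).
#' @param sites Site table (default [default_sites()]).
#' @param n_snps_per_level SNPs per level (default 50).
#' @param mean_depth Mean read depth (default 103).
#' @param break_m Break location (default 1071 m).
#' @param n_replicates Restarts per fit (default 10).
#' @param model Cline model passed to [fit_cline()].
#' @param seed Integer seed.
#' @return List with `summary` (data.table: level, median/IQR of c and w) and
#'   `fits` (data.table of all per-SNP estimates).
#' @export
cline_artifact_experiment <- function(afd_levels = c(0.97, 0.35, 0.175),
                                      sites = default_sites(),
                                      n_snps_per_level = 50L,
                                      mean_depth = 103, break_m = 1071,
                                      n_replicates = 10L,
                                      model = "two_tail", seed = 1L) {
  if (any(afd_levels <= 0 | afd_levels > 1))
    stop("afd_levels must lie in (0, 1]")
  sites <- validate_sites(sites)
  layout <- default_layout()
  res <- rbindlist(lapply(seq_along(afd_levels), function(li) {
    a <- afd_levels[li]
    s1 <- child_seed(seed, li)
    truth <- make_gradient_truth(layout, sites, n_selected = n_snps_per_level,
                                 n_background = 0L, break_m = break_m,
                                 endpoint_afd_selected = a, seed = s1)
    counts <- simulate_pool_counts(truth, sites, mean_depth = mean_depth,
                                   seed = child_seed(seed, 1000 + li))
    al <- attr(counts, "alleles")
    snps <- genotype_snps(counts, data.table(chrom = al$chrom, pos = al$pos,
                                             allele1 = al$lake_allele,
                                             allele2 = al$stream_allele))
    rbindlist(lapply(seq_len(nrow(al)), function(i) {
      g <- snps[chrom == al$chrom[i] & pos == al$pos[i]]
      g <- g[match(sites$site_id, site_id)]
      fit <- fit_cline(g$freq, g$n1 + g$n2, sites$distance_m,
                       n_replicates = n_replicates, model = model,
                       seed = child_seed(seed, 2000 + li * n_snps_per_level + i))
      data.table(level = a, snp = i,
                 c = unname(fit$params["c"]), w = unname(fit$params["w"]))
    }))
  }))
  summary <- res[, .(median_c = median(c), iqr_c = stats::IQR(c),
                     median_w = median(w), iqr_w = stats::IQR(w)),
                 by = level]
  list(summary = summary[], fits = res[])
}
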