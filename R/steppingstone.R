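#' Parameters of the stepping-stone divergence simulator
#'
#' Defaults describe the standard model: nine demes in a linear array, the
#' first (lake) deme of 2000 diploids and eight stream demes of 200 each;
#' 100 biallelic unlinked loci under divergent selection (the stream allele
#' favored everywhere except the lake deme); additive fitness
#' `max(0, 1 - s * k)` with `k` the number of locally maladaptive allele
#' copies, rescaled within demes; both alleles start at frequency 0.5 in all
#' demes; 1000 discrete generations of migrate-then-reproduce.
#'
#' @param deme_sizes Integer vector of deme sizes (first = lake).
#' @param L Number of selected loci.
#' @param s Selection coefficient per maladaptive allele copy (scalar, or
#'   the mean of the exponential when `s_distribution = "exponential"`).
#' @param m Migration fraction per adjacent neighbor per generation.
#' @param generations Number of generations.
#' @param fitness_mode `"additive"` or `"multiplicative"`.
#' @param linkage `"unlinked"` or `"single_chromosome"`.
#' @param crossover `"one"` (exactly one crossover, uniform position) or
#'   `"poisson"` (Poisson(1) crossovers), used only with
#'   `single_chromosome`.
#' @param s_distribution `"constant"` or `"exponential"` (locus-specific
#'   coefficients drawn once per replicate with rate `1/s`).
#' @param p0 Initial allele frequency (default 0.5).
#' @param allow_selfing Hermaphrodites may self (default TRUE).
#' @param record_every Record per-deme median frequencies every this many
#'   generations (0 = final state only).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(deme_sizes = c(2000L, rep(200L, 8L)),
                       L = 100L, s = 0.005, m = 0.01,
                       generations = 1000L,
                       fitness_mode = c("additive", "multiplicative"),
                       linkage = c("unlinked", "single_chromosome"),
                       crossover = c("one", "poisson"),
                       s_distribution = c("constant", "exponential"),
                       p0 = 0.5, allow_selfing = TRUE,
                       record_every = 0L) {
  fitness_mode <- match.arg(fitness_mode)
  linkage <- match.arg(linkage)
  crossover <- match.arg(crossover)
  s_distribution <- match.arg(s_distribution)
  stopifnot(all(deme_sizes >= 1L), L >= 1L, s >= 0, m >= 0, 2 * m <= 1,
            generations >= 0L, p0 >= 0, p0 <= 1)
  structure(list(deme_sizes = as.integer(deme_sizes), L = as.integer(L),
                 s = s, m = m, generations = as.integer(generations),
                 fitness_mode = fitness_mode, linkage = linkage,
                 crossover = crossover, s_distribution = s_distribution,
                 p0 = p0, allow_selfing = allow_selfing,
                 record_every = as.integer(record_every)),
            class = "sim_params")
}

locus_s <- function(params) {
  if (params$s_distribution == "exponential")
    pmin(stats::rexp(params$L, rate = 1 / params$s), 0.999)
  else rep(params$s, params$L)
}

#' Run one replicate of the stepping-stone simulation
#'
#' Generation loop = migration (a fraction `m` of each deme moves to each
#' adjacent neighbor, `round(m * N)` individuals drawn without replacement,
#' simultaneously across demes) followed by fitness-weighted reproduction
#' that restores every deme to its target size.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return List with `freq` (deme x locus stream-allele frequencies at the
#'   final generation), `median_freq` (per-deme median across loci), `traj`
#'   (matrix of recorded per-deme medians, if `record_every > 0`),
#'   `traj_generation`, `params`, `seed`.
#' @export
run_simulation <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  res <- withr::with_seed(seed, {
    sv <- locus_s(params)
    ss_run_cpp(params$deme_sizes, params$L, sv, params$m,
               params$generations,
               match(params$fitness_mode, c("additive", "multiplicative")) - 1L,
               match(params$linkage, c("unlinked", "single_chromosome")) - 1L,
               match(params$crossover, c("one", "poisson")) - 1L,
               params$p0, !params$allow_selfing, params$record_every)
  })
  res$params <- params
  res$seed <- seed
  res
}

#' Run a migration/selection parameter grid
#'
#' For every `(m, s)` combination, runs `reps` replicates and averages the
#' per-deme median stream-allele frequency at the final generation across
#' replicates.  Per-cell seeds are derived deterministically from `seed` and
#' the cell/replicate indices.
#'
#' @param m_values,s_values Grid values.
#' @param reps Replicates per cell (default 20).
#' @param base_params Template [sim_params()]; its `m` and `s` are
#'   overridden cell by cell.
#' @param seed Integer master seed.
#' @return data.table with one row per (m, s, deme): columns `m`, `s`,
#'   `deme`, `mean_median_freq` (mean over reps), `min_median_freq`,
#'   plus attribute `replicates` (long data.table incl. the per-rep values).
#' @export
run_parameter_grid <- function(m_values, s_values, reps = 20L,
                               base_params = sim_params(), seed = 1L) {
  if (length(m_values) == 0L || length(s_values) == 0L)
    stop("empty parameter grid")
  cells <- CJ(m = m_values, s = s_values)
  long <- rbindlist(lapply(seq_len(nrow(cells)), function(ci) {
    p <- base_params
    p$m <- cells$m[ci]
    p$s <- cells$s[ci]
    rbindlist(lapply(seq_len(reps), function(r) {
      res <- run_simulation(p, seed = child_seed(seed, (ci - 1L) * reps + r))
      data.table(m = p$m, s = p$s, rep = r,
                 deme = seq_along(res$median_freq),
                 median_freq = res$median_freq)
    }))
  }))
  out <- long[, .(mean_median_freq = mean(median_freq),
                  min_median_freq = min(median_freq)),
              by = .(m, s, deme)]
  setattr(out, "replicates", long)
  out[]
}

#' Build an explicit deme-array state (for phase-level testing)
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return List of class `deme_state` with `h1`, `h2` (individual x locus
#'   0/1 haplotype matrices), `deme` (1-based deme index per individual) and
#'   `params`.
#' @export
init_deme_state <- function(params, seed = 1L) {
  n <- sum(params$deme_sizes)
  withr::with_seed(seed, {
    h1 <- matrix(as.integer(runif(n * params$L) < params$p0), n, params$L)
    h2 <- matrix(as.integer(runif(n * params$L) < params$p0), n, params$L)
  })
  structure(list(h1 = h1, h2 = h2,
                 deme = rep(seq_along(params$deme_sizes), params$deme_sizes),
                 params = params),
            class = "deme_state")
}

#' Migration phase on an explicit state
#' @param state A `deme_state`.
#' @param m Migration fraction per neighbor.
#' @param seed Optional integer seed.
#' @return The state with updated deme assignments (genotypes untouched).
#' @export
migrate <- function(state, m, seed = NULL) {
  run <- function() ss_migrate_cpp(state$deme - 1L,
                                   length(state$params$deme_sizes), m) + 1L
  state$deme <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  state
}

#' Selection + reproduction phase on an explicit state
#' @param state A `deme_state`.
#' @param seed Optional integer seed.
#' @return The state after one round of fitness-weighted reproduction; deme
#'   sizes equal `params$deme_sizes` again.
#' @export
select_and_reproduce <- function(state, seed = NULL) {
  p <- state$params
  run <- function() {
    sv <- locus_s(p)
    ss_reproduce_cpp(state$h1, state$h2, state$deme - 1L, p$deme_sizes, sv,
                     match(p$fitness_mode, c("additive", "multiplicative")) - 1L,
                     match(p$linkage, c("unlinked", "single_chromosome")) - 1L,
                     match(p$crossover, c("one", "poisson")) - 1L,
                     !p$allow_selfing)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  state$h1 <- res$h1
  state$h2 <- res$h2
  state$deme <- res$deme + 1L
  state
}

#' Per-deme allele frequencies of an explicit state
#' @param state A `deme_state`.
#' @return Matrix deme x locus of stream-allele frequencies.
#' @export
state_freqs <- function(state) {
  g <- state$h1 + state$h2
  D <- length(state$params$deme_sizes)
  t(vapply(seq_len(D), function(d)
    colMeans(g[state$deme == d, , drop = FALSE]) / 2,
    numeric(state$params$L)))
}

#' Smallest selection coefficient fixing all stream demes at every migration rate
#'
#' Runs the simulator over the (m, s) grid and reports the smallest `s` for
#' which, at *every* migration rate, all stream demes end with a median
#' stream-allele frequency of exactly 1 across the selected loci in every
#' replicate.  Migration rates are visited in descending order within each
#' `s` and the scan short-circuits on the first failing rate, since higher
#' gene flow is the binding constraint.
#'
#' @param m_values Migration rates (default `c(0.005, 0.01, 0.025, 0.05,
#'   0.1)`).
#' @param s_values Selection coefficients in ascending order (default
#'   `c(0.0005, 0.001, 0.0025, 0.005, 0.0075)`).
#' @param reps Replicates per cell (default 20; analyses under time
#'   constraints use 5).
#' @param base_params Template [sim_params()].
#' @param seed Integer master seed.
#' @return List with `s_min` (NA if no grid value suffices) and `detail`
#'   (data.table: s, m, fixed flag; unexamined cells absent).
#' @export
smallest_sufficient_s <- function(m_values = c(0.005, 0.01, 0.025, 0.05, 0.1),
                                  s_values = c(0.0005, 0.001, 0.0025, 0.005,
                                               0.0075),
                                  reps = 20L, base_params = sim_params(),
                                  seed = 1L) {
  s_values <- sort(s_values)
  detail <- list()
  s_min <- NA_real_
  for (si in seq_along(s_values)) {
    all_fixed <- TRUE
    for (mv in sort(m_values, decreasing = TRUE)) {
      p <- base_params
      p$s <- s_values[si]
      p$m <- mv
      fixed <- TRUE
      for (r in seq_len(reps)) {
        res <- run_simulation(p, seed = child_seed(seed,
                                                   si * 10000 + which(m_values == mv) * 100 + r))
        if (any(res$median_freq[-1L] < 1)) { fixed <- FALSE; break }
      }
      detail[[length(detail) + 1L]] <- data.table(s = p$s, m = mv, fixed = fixed)
      if (!fixed) { all_fixed <- FALSE; break }
    }
    if (all_fixed) { s_min <- s_values[si]; break }
  }
  list(s_min = s_min, detail = rbindlist(detail))
}
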