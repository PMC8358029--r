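test_that("sim_params validates its arguments", {
  expect_error(sim_params(m = 0.6), "2 \\* m")
  expect_error(sim_params(s = -0.1), "s >= 0")
  expect_s3_class(sim_params(), "sim_params")
})

test_that("migration relabels round(m*N) individuals per neighbor", {
  p <- sim_params(deme_sizes = c(100L, 50L, 30L), L = 4L, generations = 1L)
  st <- init_deme_state(p, seed = 1)
  g_before <- st$h1 + st$h2
  st2 <- migrate(st, m = 0.1, seed = 2)
  # genotypes untouched: allele counts conserved exactly
  expect_identical(st2$h1 + st2$h2, g_before)
  # sizes: d1 100-10+5, d2 50-10+10+3, d3 30-3+5
  expect_equal(as.vector(table(st2$deme)), c(95, 53, 32))
  # m = 0 is the identity
  st0 <- migrate(st, m = 0, seed = 3)
  expect_identical(st0$deme, st$deme)
  expect_error(migrate(st, m = 0.7), "2m")
})

test_that("interior emigrant sets are disjoint (each migrates once)", {
  p <- sim_params(deme_sizes = c(50L, 200L, 50L), L = 2L)
  st <- init_deme_state(p, seed = 4)
  st2 <- migrate(st, m = 0.1, seed = 5)
  moved <- which(st2$deme != st$deme)
  expect_equal(length(moved), 5L + 20L + 20L + 5L)
})

test_that("reproduction restores target sizes and drifts neutrally at s=0", {
  p <- sim_params(deme_sizes = c(80L, 40L), L = 30L, s = 0)
  st <- init_deme_state(p, seed = 6)
  st2 <- select_and_reproduce(st, seed = 7)
  expect_equal(as.vector(table(st2$deme)), c(80, 40))
  # E[dp] = 0 under neutrality: average change across 30 loci x reps
  deltas <- vapply(1:20, function(r) {
    s2 <- select_and_reproduce(st, seed = 100 + r)
    mean(state_freqs(s2) - state_freqs(st))
  }, 0)
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 4 * se + 1e-3)
})

test_that("one-generation selection matches the exact weighted oracle", {
  # lake deme (stream allele maladaptive), one locus, s = 0.01, N = 1e5:
  # E[p'] = sum(w_i g_i) / (2 sum(w_i)) with w_i = 1 - s g_i
  p <- sim_params(deme_sizes = 100000L, L = 1L, s = 0.01)
  st <- init_deme_state(p, seed = 8)
  g <- as.vector(st$h1 + st$h2)
  w <- 1 - 0.01 * g
  p_expect <- sum(w * g) / (2 * sum(w))
  st2 <- select_and_reproduce(st, seed = 9)
  p_obs <- mean(st2$h1 + st2$h2) / 2
  expect_equal(p_obs, p_expect, tolerance = 0.005)
  # and it differs measurably from the unselected frequency
  expect_lt(p_obs, mean(g) / 2 - 0.001)
})

test_that("all-zero fitness in a deme signals extinction", {
  p <- sim_params(deme_sizes = 10L, L = 2L, s = 0.9)
  st <- init_deme_state(p, seed = 10)
  st$h1[] <- 1L; st$h2[] <- 1L   # lake deme full of stream homozygotes
  expect_error(select_and_reproduce(st, seed = 11), "extinction")
})

test_that("neutral limit reproduces the Wright-Fisher variance", {
  # var(p_g) ~ p0(1-p0)(1 - (1 - 1/(2N))^g), N = 100, g = 100, 1000 loci
  p <- sim_params(deme_sizes = 100L, L = 1000L, s = 0, m = 0,
                  generations = 100L)
  r <- run_simulation(p, seed = 12)
  v <- var(as.vector(r$freq))
  expect_equal(v, 0.25 * (1 - (1 - 1 / 200)^100), tolerance = 0.15)
})

test_that("strong selection without gene flow fixes stream demes", {
  # diffusion oracle: P(fix) = (1 - exp(-4Ns p0)) / (1 - exp(-4Ns)),
  # N = 200, s = 0.0075, p0 = 0.5 -> 0.9526
  p <- sim_params(s = 0.0075, m = 0)
  r <- run_simulation(p, seed = 13)
  stream <- r$freq[-1, , drop = FALSE]
  frac_fixed <- mean(stream == 1)
  expect_equal(frac_fixed, (1 - exp(-3)) / (1 - exp(-6)), tolerance = 0.06)
  expect_true(all(r$median_freq[-1] == 1))
  # the lake deme fixes the lake allele analogously
  expect_equal(mean(r$freq[1, ] == 0), (1 - exp(-3)) / (1 - exp(-6)),
               tolerance = 0.06)
})

test_that("runs are seed-deterministic and grid cells match direct runs", {
  p <- sim_params(deme_sizes = c(200L, rep(50L, 3L)), L = 20L,
                  generations = 60L, s = 0.005, m = 0.05)
  a <- run_simulation(p, seed = 14)
  b <- run_simulation(p, seed = 14)
  expect_identical(a$freq, b$freq)
  g <- run_parameter_grid(0.05, 0.005, reps = 2, base_params = p, seed = 21)
  direct <- run_simulation(p, seed = child_seed(21, 1L))
  reps <- attr(g, "replicates")
  expect_equal(reps[rep == 1, median_freq], direct$median_freq)
})

test_that("robustness variants preserve lake-stream divergence", {
  variants <- list(
    sim_params(s = 0.0075, m = 0.01, generations = 400L,
               fitness_mode = "multiplicative"),
    sim_params(s = 0.0075, m = 0.01, generations = 400L, L = 10L),
    sim_params(s = 0.0075, m = 0.01, generations = 400L,
               linkage = "single_chromosome"),
    sim_params(s = 0.0075, m = 0.01, generations = 400L,
               s_distribution = "exponential"),
    sim_params(s = 0.0075, m = 0.01, generations = 400L,
               deme_sizes = c(10000L, rep(125L, 8L))))
  for (v in variants) {
    r <- run_simulation(v, seed = 15)
    # the distal stream deme diverges from the lake under every variant;
    # the high-gene-flow shape (first stream deme most constrained) is
    # exercised separately at m = 0.1 in the acceptance suite
    expect_gt(r$median_freq[9] - r$median_freq[1], 0.3)
  }
})

test_that("single-chromosome gametes are parental-haplotype mosaics", {
  p <- sim_params(deme_sizes = 2L, L = 12L, s = 0,
                  linkage = "single_chromosome")
  st <- init_deme_state(p, seed = 16)
  st$h1[] <- 1L; st$h2[] <- 0L  # heterozygous at every locus
  st2 <- select_and_reproduce(st, seed = 17)
  # exactly one crossover: each gamete has at most one 0/1 switch
  switches <- apply(st2$h1, 1, function(v) sum(diff(v) != 0))
  expect_true(all(switches <= 1))
})
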