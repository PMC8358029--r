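mk_windows <- function(n, delta, chrom = "chrI") {
  data.table::data.table(chrom = chrom, start = seq(1, by = 5000,
                                                    length.out = n),
                         end = seq(1, by = 5000, length.out = n) + 10000,
                         n_snps = 10L, mean_afd = delta)
}

test_that("delta windows subtract the baseline on the shared grid", {
  a <- mk_windows(10, 0.30)
  b <- mk_windows(10, 0.05)
  d <- delta_windows(a, b)
  expect_true(all(d$delta == 0.25))
  expect_true(all(delta_windows(a, a)$delta == 0))
  b2 <- data.table::copy(b)[, start := start + 1e6][, end := end + 1e6]
  expect_error(delta_windows(a, b2), "disjoint")
})

test_that("HDW selection takes the top fraction plus matched controls", {
  withr::with_seed(2, {
    d <- mk_windows(1000, runif(1000))
  })
  hc <- pick_hdw_and_controls(delta_windows(d, mk_windows(1000, 0)),
                              top_fraction = 0.005, seed = 3)
  expect_equal(nrow(hc$hdw), 5L)        # 0.5% of 1000
  expect_equal(nrow(hc$control), 5L)
  expect_gte(min(hc$hdw$delta), max(0, sort(d$mean_afd, TRUE)[6]))
  # no window in both sets
  expect_equal(nrow(merge(hc$hdw, hc$control, by = c("chrom", "start"))), 0L)
  # all-equal deltas: deterministic under seed, ties by coordinate
  deq <- delta_windows(mk_windows(1000, 0.3), mk_windows(1000, 0))
  h1 <- pick_hdw_and_controls(deq, seed = 9)
  h2 <- pick_hdw_and_controls(deq, seed = 9)
  expect_identical(h1$hdw$start, h2$hdw$start)
  expect_equal(h1$hdw$start, sort(deq$start)[1:5])  # smallest coordinates
  expect_error(pick_hdw_and_controls(deq[1:100], top_fraction = 0.6),
               "too few")
})

test_that("empirical deltaAFD behaves on identical, planted and tiny sets", {
  withr::with_seed(4, {
    focal <- mk_windows(400, rbeta(400, 2, 3))
  })
  hc <- list(hdw = focal[1:50, .(chrom, start, end)],
             control = focal[51:100, .(chrom, start, end)])
  same <- empirical_delta_afd(hc$hdw, hc$hdw, focal, n_boot = 500, seed = 1)
  expect_equal(same$delta_afd, 0)
  expect_lte(same$ci[1], 0); expect_gte(same$ci[2], 0)
  # planted +0.3 excess
  focal2 <- data.table::copy(focal)
  focal2[1:50, mean_afd := mean_afd + 0.3]
  up <- empirical_delta_afd(hc$hdw, hc$control, focal2, n_boot = 2000,
                            seed = 2)
  expect_gt(up$ci[1], 0)                # CI excludes 0
  expect_warning(
    empirical_delta_afd(focal[1, .(chrom, start, end)],
                        focal[2, .(chrom, start, end)], focal,
                        n_boot = 100, seed = 3),
    "degenerate")
})

test_that("haploid drift conserves nothing but matches WF variance", {
  # g = 0: no evolution
  s0 <- withr::with_seed(5, drift_sim_haploid(runif(50, .1, .5), n = 100,
                                              g = 0))
  expect_equal(s0$freq_before, s0$freq_after)
  # realized initial frequencies are exact
  expect_equal(s0$freq_before, round(s0$freq_before * 100) / 100)
  # variance decay ~ p0(1-p0)(1 - (1 - 1/n)^g), n = 50, g = 20
  withr::with_seed(6, {
    sim <- drift_sim_haploid(rep(0.3, 4000), n = 50, g = 20)
  })
  expect_equal(var(sim$freq_after), 0.21 * (1 - (1 - 1 / 50)^20),
               tolerance = 0.1)
})

test_that("pair-swap assortment is equivalent to independent binomial WF", {
  withr::with_seed(7, {
    sim <- drift_sim_haploid(rep(0.3, 1000), n = 200, g = 30)
    oracle <- wf_binomial_oracle(rep(0.3, 1000), n = 200, g = 30)
  })
  ks <- suppressWarnings(stats::ks.test(sim$freq_after, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("drift benchmark reports a small positive deltaAFD under drift", {
  bench <- drift_benchmark(n = 100, g = 50, n_loci = 60, reps = 8,
                           n_boot = 500, seed = 8)
  expect_s3_class(bench, "delta_afd_result")
  expect_equal(bench$source, "simulated")
  expect_lte(bench$ci[1], bench$delta_afd)
  expect_gte(bench$ci[2], bench$delta_afd)
  # under pure drift the HDL excess is far below a selection-driven excess
  expect_lt(abs(bench$delta_afd), 0.25)
  expect_error(drift_benchmark(init_range = c(0.4, 0.2)), "invalid")
})

test_that("bootstrap CI of equal-distribution sets covers 0 at ~95%", {
  withr::with_seed(9, {
    cover <- vapply(1:100, function(i) {
      x <- runif(178); y <- runif(178)
      b <- clinepool:::boot_median_diff(x, y, n_boot = 400, seed = i)
      b$ci[1] <= 0 && b$ci[2] >= 0
    }, TRUE)
  })
  expect_gte(mean(cover), 0.93)
})

test_that("planted selection exceeds the neutral drift benchmark", {
  # empirical deltaAFD with a +0.3 planted excess at HDW positions vs the
  # haploid drift benchmark near its stated size (25 -> 10 replicates)
  withr::with_seed(10, {
    focal <- mk_windows(600, rbeta(600, 2, 3) * 0.5)
  })
  focal[1:178, mean_afd := pmin(mean_afd + 0.3, 1)]
  emp <- empirical_delta_afd(focal[1:178, .(chrom, start, end)],
                             focal[201:378, .(chrom, start, end)],
                             focal, n_boot = 1000, seed = 11)
  bench <- drift_benchmark(n = 200, g = 1000, n_loci = 178, reps = 10,
                           n_boot = 1000, seed = 12)
  expect_gt(emp$delta_afd, bench$ci[2])
  expect_gt(emp$ci[1], bench$ci[2])
})
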