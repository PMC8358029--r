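test_that("afd and fst match their closed forms", {
  expect_equal(afd(1, 0), 1)          # fixed for alternative alleles
  expect_equal(afd(0.3, 0.3), 0)
  expect_equal(afd(0.9, 0.2), 0.7)
  expect_equal(fst(1, 0), 1)
  expect_equal(fst(0.4, 0.4), 0)
  expect_equal(fst(0.9, 0.2), 49 / 99)  # ((.495-.25)/.495), frozen
  expect_error(afd(1.2, 0), "\\[0, 1\\]")
  expect_error(fst(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("afd is symmetric and satisfies the triangle bound", {
  withr::with_seed(1, {
    for (i in 1:200) {
      p <- runif(3)
      expect_identical(afd(p[1], p[2]), afd(p[2], p[1]))
      expect_lte(afd(p[1], p[3]), afd(p[1], p[2]) + afd(p[2], p[3]) + 1e-12)
    }
  })
})

test_that("discover_snps applies the depth and MAF filters", {
  # MAF on the two most frequent nucleotides of the combined pools:
  # combined A:60/C:40 -> MAF 0.4 (retained); A:90/C:10 -> 0.10 (rejected)
  tbl <- manual_counts(list(
    count_row("La", pos = 100, A = 35L, C = 25L),   # pool A depth 60
    count_row("Sa", pos = 100, A = 25L, C = 15L),   # pool B depth 40 -> 40<50?
    count_row("La", pos = 200, A = 55L, C = 5L),    # combined 90/10
    count_row("Sa", pos = 200, A = 35L, C = 5L),
    count_row("La", pos = 300, A = 40L, C = 20L),   # retained: depths 60 + 55
    count_row("Sa", pos = 300, A = 30L, C = 25L)))
  # depth window 50..400: position 100 fails pool B depth (40 < 50)
  out <- discover_snps(tbl, "La", "Sa")
  expect_equal(unique(out$pos), 300)
  expect_equal(out[out$site_id == "La", ]$freq, 20 / 60)
  # with the depth floor relaxed, position 100 passes on MAF = 0.4
  out2 <- discover_snps(tbl, "La", "Sa", depth_min = 40)
  expect_setequal(unique(out2$pos), c(100, 300))
  # position 200 is always rejected: MAF 0.10 < 0.25
  expect_false(200 %in% out2$pos)
  expect_error(discover_snps(tbl, "La", "Nope"), "unknown site")
  expect_error(discover_snps(tbl, "La", "La"), "disjoint")
})

test_that("genotyping renormalizes over the two SNP alleles", {
  tbl <- manual_counts(list(
    count_row("X", pos = 10, A = 60L, C = 30L, G = 10L)))
  g <- genotype_snps(tbl, data.table::data.table(
    chrom = "chrI", pos = 10, allele1 = "A", allele2 = "C"))
  expect_equal(g$freq, 30 / 90)   # third-allele reads ignored
  expect_equal(g$depth, 100L)     # but depth counts all four nucleotides
})

test_that("discover_snps is invariant to input row order", {
  w <- tiny_world(n_selected = 5L, n_background = 60L, seed = 11)
  shuffled <- withr::with_seed(3, w$counts[sample(.N)])
  s1 <- discover_snps(w$counts, c("L1", "L2"), c("S6", "S7"))
  s2 <- discover_snps(as_count_table(shuffled), c("L1", "L2"), c("S6", "S7"))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("pairwise profiles respect the per-sample depth window", {
  tbl <- manual_counts(list(
    count_row("X", pos = 10, A = 150L, C = 60L),   # depth 210 at X -> dropped
    count_row("Y", pos = 10, A = 80L, C = 20L),
    count_row("X", pos = 20, A = 50L, C = 50L),
    count_row("Y", pos = 20, A = 50L, C = 50L)))
  loci <- data.table::data.table(chrom = "chrI", pos = c(10, 20),
                                 allele1 = "A", allele2 = "C")
  snps <- genotype_snps(tbl, loci)
  prof <- pairwise_profile(snps, "X", "Y")
  expect_equal(prof$pos, 20)
  expect_equal(prof$afd, 0)        # identical counts
  expect_warning(pairwise_profile(snps, "X", "Y", depth_min = 300),
                 "no SNP passes")
})

test_that("planted AFD-1 loci reach exactly 1 in the endpoint profile", {
  w <- tiny_world(n_selected = 8L, n_background = 50L, seed = 23)
  prof <- pairwise_profile(w$snps, "L1", "S7")
  sel <- w$truth$loci[class == "selected"]
  hit <- merge(prof, sel, by = c("chrom", "pos"))
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$afd == 1))
})

test_that("window means follow the stated window algebra", {
  # 5 SNPs with AFD .1...5 in one window -> mean 0.3; 4 SNPs -> dropped
  prof <- manual_profile("chrI", c(1000, 2000, 3000, 4000, 5000),
                         c(0.1, 0.2, 0.3, 0.4, 0.5))
  w <- window_mean_afd(prof, 10000, 5000, min_snps = 5)
  expect_equal(w[w$start == 1, ]$mean_afd, 0.3)
  expect_true(all(w$end - w$start == 10000))
  w4 <- window_mean_afd(manual_profile("chrI", c(1, 2, 3, 4) * 1000,
                                       rep(0.2, 4)), 10000, 5000, 5)
  expect_equal(nrow(w4), 0L)
  # constant AFD is conserved by window averaging
  pos <- sort(withr::with_seed(2, sample.int(1e5, 400)))
  wc <- window_mean_afd(manual_profile("chrI", pos, rep(0.37, 400)),
                        10000, 5000, 5)
  expect_true(all(abs(wc$mean_afd - 0.37) < 1e-12))
  expect_error(window_mean_afd(prof, -1, 5000), "> 0")
})

test_that("smoothing reproduces constants and lines, shrinks step noise", {
  x <- seq(1, 100) * 1000
  expect_equal(smooth_profile(x, rep(0.4, 100)), rep(0.4, 100),
               tolerance = 1e-8)
  lin <- 0.001 * seq_along(x) + 0.1
  expect_equal(smooth_profile(x, lin), lin, tolerance = 1e-6)
  step <- rep(c(0.1, 0.9), each = 50)
  noisy <- step + withr::with_seed(4, rnorm(100, 0, 0.1))
  sm <- smooth_profile(x, noisy, spar = 0.5)
  expect_lt(sum((sm - step)^2), sum((noisy - step)^2))
  expect_error(smooth_profile(x[1:3], noisy[1:3]), "at least 4")
})

test_that("median endpoint AFD converges to the planted background", {
  # depth 1e4 removes nearly all read-sampling noise; pool sampling remains
  sites <- default_sites(pool_n = 500L)[c(1, 11)]
  tr <- make_gradient_truth(default_layout(), sites, n_selected = 0L,
                            n_background = 800L,
                            endpoint_afd_background = 0.35, seed = 6)
  cnt <- simulate_pool_counts(tr, sites, mean_depth = 1e4, seed = 7)
  al <- attr(cnt, "alleles")
  snps <- genotype_snps(cnt, data.table::data.table(
    chrom = al$chrom, pos = al$pos, allele1 = al$lake_allele,
    allele2 = al$stream_allele))
  prof <- pairwise_profile(snps, "L1", "S7", depth_min = 50, depth_max = 2e4)
  expect_equal(median(prof$afd), 0.35, tolerance = 0.02)
})

test_that("stored SNP frequencies equal frequencies recomputed from counts", {
  w <- tiny_world(n_selected = 4L, n_background = 40L, seed = 31)
  s <- w$snps
  expect_equal(s$freq, s$n2 / (s$n1 + s$n2))
})
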