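test_that("default site template is a valid 11-site gradient", {
  s <- default_sites()
  expect_equal(nrow(s), 11L)
  expect_true(all(diff(s$distance_m) > 0))
  # marsh lies between the lake and stream blocks
  expect_equal(s$habitat, c(rep("lake", 2), rep("marsh", 2), rep("stream", 7)))
  expect_error(validate_sites(s[c(2, 1)]), "increasing")
  expect_error(validate_sites(s[0]), "empty")
})

test_that("gradient truth plants exact steps and validates inputs", {
  sites <- default_sites()
  layout <- default_layout()
  tr <- make_gradient_truth(layout, sites, n_selected = 25L,
                            n_background = 0L, break_m = 1071,
                            endpoint_afd_selected = 1.0, seed = 1)
  lakeside <- sites$distance_m < 1071
  expect_true(all(tr$freq[, lakeside] == 0))
  expect_true(all(tr$freq[, !lakeside] == 1))

  tr0 <- make_gradient_truth(layout, sites, n_selected = 0L,
                             n_background = 30L,
                             endpoint_afd_background = 0, seed = 2)
  expect_true(all(tr0$freq == tr0$freq[, 1]))  # identical across sites

  expect_error(make_gradient_truth(layout, sites[0], 5L, 5L), "empty")
  expect_error(make_gradient_truth(layout, sites, 5L, 5L,
                                   endpoint_afd_selected = 1.2), "\\[0, 1\\]")
  expect_error(make_gradient_truth(layout, sites, 5L, 5L, break_m = 5000),
               "span")
})

test_that("planted loci respect spacing and autosome restriction", {
  w <- make_gradient_truth(default_layout(), default_sites(),
                           n_selected = 40L, n_background = 400L, seed = 3)
  expect_false(any(w$loci$chrom == "chrXIX"))
  gaps <- w$loci[, diff(sort(pos)), by = chrom]$V1
  expect_true(all(gaps >= 1e5))
})

test_that("pool count simulation matches the two-stage sampling variance", {
  # frequency 0.5, pool of 56, mean depth 100: var(f) ~= p(1-p)(1/(2N) + 1/D)
  n_loc <- 20000L
  sites <- data.table::data.table(site_id = "P1", habitat = "lake",
                                  distance_m = 0, pool_n = 56L,
                                  time_point = NA_character_)
  truth <- structure(list(
    loci = data.table::data.table(locus_id = sprintf("l%05d", 1:n_loc),
                                  chrom = "chrI", pos = seq_len(n_loc) * 10,
                                  class = "neutral"),
    freq = matrix(0.5, n_loc, 1, dimnames = list(NULL, "P1")),
    sites = sites, layout = default_layout(), break_m = 0),
    class = "gradient_truth")
  cnt <- simulate_pool_counts(truth, sites, mean_depth = 100, seed = 42)
  al <- attr(cnt, "alleles")
  idx <- match(al$stream_allele, c("A", "C", "G", "T"))
  cntm <- as.matrix(cnt[, c("A", "C", "G", "T"), with = FALSE])
  f <- cntm[cbind(seq_len(n_loc), idx)] / rowSums(cntm)
  expect_equal(mean(f), 0.5, tolerance = 0.005)
  v_expect <- 0.25 * (1 / 112 + 1 / 100)
  expect_equal(var(f), v_expect, tolerance = 0.05)
})

test_that("fixed truth gives monomorphic reads; identical seeds reproduce", {
  sites <- default_sites()
  tr <- make_gradient_truth(default_layout(), sites, n_selected = 5L,
                            n_background = 0L, endpoint_afd_selected = 1,
                            seed = 5)
  c1 <- simulate_pool_counts(tr, sites, seed = 9)
  c2 <- simulate_pool_counts(tr, sites, seed = 9)
  c3 <- simulate_pool_counts(tr, sites, seed = 10)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
  # truth 0 on the lake side: every read carries the lake allele there
  al <- attr(c1, "alleles")
  lake_sites <- sites[sites$distance_m < tr$break_m, site_id]
  m <- merge(c1, al[, .(chrom, pos, stream_allele)], by = c("chrom", "pos"))
  cntm <- as.matrix(m[, c("A", "C", "G", "T"), with = FALSE])
  sidx <- match(m$stream_allele, c("A", "C", "G", "T"))
  stream_reads <- cntm[cbind(seq_len(nrow(m)), sidx)]
  expect_true(all(stream_reads[m$site_id %in% lake_sites] == 0))
})

test_that("count table IO round-trips and rejects malformed rows", {
  tbl <- manual_counts(list(
    count_row("L1", pos = 100, A = 30L, C = 20L),
    count_row("L1", pos = 200, G = 55L),
    count_row("S7", pos = 100, A = 5L, T = 45L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tbl, path)
  back <- read_count_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))

  bad <- data.table::copy(tbl)[2, A := -1L]
  expect_error(as_count_table(bad), "row")
  dup <- rbind(tbl, tbl[1])
  expect_error(as_count_table(dup), "duplicate")

  writeLines("site_id\tchrom\tpos\tA\tC\tG\tT", path)
  expect_equal(nrow(read_count_table(path)), 0L)
})

test_that("flood scenario mixes truth linearly", {
  sites <- default_sites()
  tr <- make_gradient_truth(default_layout(), sites, n_selected = 20L,
                            n_background = 0L, seed = 1)
  p_b <- runif(20, 0, 0.3)
  p_l <- runif(20, 0, 0.1)
  sc0 <- make_flood_scenario(tr, p_b, p_l, lambda_true = 0, seed = 2)
  expect_equal(unname(sc0$truth[, 2]), p_b)     # lambda 0: during == before
  sc1 <- make_flood_scenario(tr, p_b, p_l, lambda_true = 1, seed = 2)
  expect_equal(unname(sc1$truth[, 2]), p_l)     # lambda 1: during == lake
  sc <- make_flood_scenario(tr, p_b, p_l, lambda_true = 0.6, recovery = 1,
                            seed = 2)
  expect_equal(unname(sc$truth[, 2]), 0.6 * p_l + 0.4 * p_b)
  expect_equal(unname(sc$truth[, 3]), p_b)      # full recovery
  expect_error(make_flood_scenario(tr, p_b[-1], p_l, 0.5), "mismatch")
  expect_error(make_flood_scenario(tr, p_b, p_l, 1.5), "\\[0, 1\\]")
})

test_that("child_seed is deterministic and separates streams", {
  expect_identical(child_seed(1, 0), child_seed(1, 0))
  s <- vapply(0:200, function(i) child_seed(42, i), 1L)
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 1 & s < 2^31))
})
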