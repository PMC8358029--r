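# Shared fixture builders; everything is generated in code at test time.

# small synthetic world: default 11-site design, few loci, dense enough for
# panel and profile tests
tiny_world <- function(n_selected = 10L, n_background = 200L, seed = 7L,
                       mean_depth = 103, endpoint_afd_background = 0.35,
                       pool_n = 56L) {
  sites <- default_sites(pool_n = pool_n)
  layout <- default_layout()
  truth <- make_gradient_truth(layout, sites, n_selected = n_selected,
                               n_background = n_background,
                               endpoint_afd_background = endpoint_afd_background,
                               seed = seed)
  counts <- simulate_pool_counts(truth, sites, mean_depth = mean_depth,
                                 seed = seed + 1L)
  snps <- discover_snps(counts, c("L1", "L2"), c("S6", "S7"))
  snps <- orient_stream_allele(snps)
  list(sites = sites, layout = layout, truth = truth, counts = counts,
       snps = snps)
}

# hand-made count table: one site, explicit nucleotide counts
manual_counts <- function(rows) {
  as_count_table(data.table::rbindlist(rows))
}

count_row <- function(site, chrom = "chrI", pos, A = 0L, C = 0L, G = 0L,
                      T = 0L) {
  data.table::data.table(site_id = site, chrom = chrom, pos = pos,
                         A = A, C = C, G = G, T = T)
}

# profile built directly (positions + afd), bypassing genotyping
manual_profile <- function(chrom, pos, afd, site_a = "X", site_b = "Y") {
  p <- data.table::data.table(chrom = chrom, pos = pos, afd = afd,
                              fst = afd, depth_a = 100L, depth_b = 100L)
  data.table::setattr(p, "site_a", site_a)
  data.table::setattr(p, "site_b", site_b)
  data.table::setattr(p, "class",
                      c("pair_profile", class(data.table::data.table())))
  p[]
}

# independent binomial Wright-Fisher oracle (haploid), per locus
wf_binomial_oracle <- function(p0, n, g) {
  k <- round(p0 * n)
  for (i in seq_len(g)) k <- rbinom(length(k), n, k / n)
  k / n
}
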