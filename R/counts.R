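#' Count tables of pooled nucleotide counts
#'
#' The universal input of the pipeline: one row per (site, chromosome,
#' position) with counts of the four nucleotides observed in the pooled reads.
#'
#' @param x data.frame with columns `site_id`, `chrom`, `pos`, `A`, `C`, `G`,
#'   `T`.
#' @return A validated `count_table` (a keyed `data.table`).
#' @export
as_count_table <- function(x) {
  x <- as.data.table(x)
  need <- c("site_id", "chrom", "pos", "A", "C", "G", "T")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("count table missing columns: ",
                         paste(miss, collapse = ", "))
  cnt <- as.matrix(x[, .(A, C, G, T)])
  bad <- which(!stats::complete.cases(cnt) | apply(cnt < 0, 1L, any))
  if (length(bad))
    stop("negative or missing counts at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (any(x$pos < 1)) stop("positions must be >= 1 (1-based)")
  x[, pos := as.integer(pos)]
  dup <- duplicated(x, by = c("site_id", "chrom", "pos"))
  if (any(dup))
    stop("duplicate (site, chrom, pos) at row(s): ",
         paste(head(which(dup), 5L), collapse = ", "))
  setkey(x, site_id, chrom, pos)
  setattr(x, "class", c("count_table", class(data.table())))
  x[]
}

#' Read / write a count table TSV
#'
#' TSV with header `site_id chrom pos A C G T`; write-then-read is the
#' identity.  Malformed rows are rejected with their row number.
#'
#' @param path File path.
#' @return `read_count_table` returns a `count_table`.
#' @export
read_count_table <- function(path) {
  x <- fread(path, sep = "\t",
             colClasses = list(character = c("site_id", "chrom")))
  as_count_table(x)
}

#' @rdname read_count_table
#' @param counts A `count_table`.
#' @export
write_count_table <- function(counts, path) {
  fwrite(as_count_table(counts), path, sep = "\t")
  invisible(path)
}

#' Per-row read depth of a count table
#' @param counts A `count_table`.
#' @return Integer vector, `A + C + G + T` per row.
#' @export
count_depth <- function(counts) {
  counts$A + counts$C + counts$G + counts$T
}

#' Simulate pooled sequencing counts from planted truth
#'
#' Two-stage pool-seq sampling per locus and site: (1) the pool's realized
#' allele frequency is Binomial(2 * pool_n, p_true) / (2 * pool_n) — the
#' individuals that went into the pool; (2) read depth is Poisson around
#' `mean_depth` (floored at 1) and the stream-allele read count Binomial at
#' the realized pool frequency.  The resulting sampling variance of the read
#' frequency is p(1-p) (1/(2N) + 1/D), the classical pool-seq formula.
#' Each locus is assigned two distinct nucleotides; the second is the true
#' stream allele.
#'
#' @param truth A [make_gradient_truth()] object (or any list with `loci`,
#'   `freq`, `sites`).
#' @param sites Site table; defaults to `truth$sites`.  Must match the truth's
#'   site columns.
#' @param mean_depth Mean read depth per site (default 103, a realistic
#'   pool-seq median).
#' @param seed Integer seed.
#' @return A `count_table` covering all loci at all sites, with attribute
#'   `alleles` (data.table: locus_id, chrom, pos, lake_allele, stream_allele).
#' @export
simulate_pool_counts <- function(truth, sites = truth$sites,
                                 mean_depth = 103, seed = 1L) {
  sites <- validate_sites(sites)
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (!all(colnames(truth$freq) %in% sites$site_id) ||
      ncol(truth$freq) != nrow(sites))
    stop("truth/site mismatch: site sets differ")
  sites <- sites[match(colnames(truth$freq), sites$site_id)]

  n_loc <- nrow(truth$loci)
  n_site <- nrow(sites)

  withr::with_seed(seed, {
    ## two distinct nucleotides per locus; second one carries the truth
    ## frequency.  The coding is taken from the truth object when present so
    ## that repeated simulations (e.g. temporal replicates) stay consistent.
    pair <- if (!is.null(truth$alleles))
      as.matrix(truth$alleles[, c("lake_allele", "stream_allele")])
    else t(vapply(seq_len(n_loc), function(i) sample(NUCS, 2L),
                  character(2L)))
    p_true <- as.vector(truth$freq)                     # locus-major per site
    pool2n <- rep(2L * sites$pool_n, each = n_loc)
    k_pool <- rbinom(n_loc * n_site, pool2n, p_true)
    p_pool <- k_pool / pool2n
    depth <- pmax(1L, rpois(n_loc * n_site, mean_depth))
    n_stream <- rbinom(n_loc * n_site, depth, p_pool)
  })
  n_lake <- depth - n_stream

  dt <- data.table(
    site_id = rep(sites$site_id, each = n_loc),
    chrom = rep(truth$loci$chrom, n_site),
    pos = rep(truth$loci$pos, n_site),
    lake_allele = rep(pair[, 1L], n_site),
    stream_allele = rep(pair[, 2L], n_site),
    n_lake = n_lake, n_stream = n_stream
  )
  for (nuc in NUCS)
    dt[, (nuc) := fifelse(lake_allele == nuc, n_lake, 0L) +
                  fifelse(stream_allele == nuc, n_stream, 0L)]
  out <- as_count_table(dt[, .(site_id, chrom, pos, A, C, G, T)])
  alleles <- data.table(locus_id = truth$loci$locus_id,
                        chrom = truth$loci$chrom, pos = truth$loci$pos,
                        lake_allele = pair[, 1L], stream_allele = pair[, 2L],
                        class = truth$loci$class)
  setattr(out, "alleles", alleles)
  out
}

#' Simulate the three temporal marsh samples around a flood
#'
#' True during-flood frequencies are the linear mixture
#' `lambda_true * truth_lake + (1 - lambda_true) * truth_before`; after-flood
#' frequencies move back toward the before state by `recovery` (1 = full
#' recovery).  Counts are sampled exactly as in [simulate_pool_counts()].
#'
#' @param truth A `gradient_truth` whose loci define positions and alleles.
#' @param truth_before,truth_lake Per-locus true stream-allele frequencies of
#'   the marsh (before flood) and of the lake source population.
#' @param lambda_true Proportion of lake migrants during the flood, in [0,1].
#' @param recovery Fraction of the flood perturbation reverted one year later.
#' @param site_id Marsh site identifier (temporal samples get suffixes
#'   `_before`, `_during`, `_after`).
#' @param pool_n Individuals per temporal pool.
#' @param mean_depth Mean read depth.
#' @param seed Integer seed.
#' @return A list with `counts` (one `count_table` with the three temporal
#'   site ids), `truth` (matrix loci x 3 of true frequencies) and
#'   `site_ids`.
#' @export
make_flood_scenario <- function(truth, truth_before, truth_lake,
                                lambda_true, recovery = 0.5,
                                site_id = "M1", pool_n = 56L,
                                mean_depth = 103, seed = 1L) {
  stop_if_not_prob(lambda_true, "lambda_true")
  stop_if_not_prob(truth_before, "truth_before")
  stop_if_not_prob(truth_lake, "truth_lake")
  n_loc <- nrow(truth$loci)
  if (length(truth_before) != n_loc || length(truth_lake) != n_loc)
    stop("mismatched locus sets: truth_before/truth_lake must have one entry per locus")

  p_during <- lambda_true * truth_lake + (1 - lambda_true) * truth_before
  p_after <- p_during + recovery * (truth_before - p_during)

  ids <- paste0(site_id, c("_before", "_during", "_after"))
  fmat <- cbind(p_during * 0 + truth_before, p_during, p_after)
  colnames(fmat) <- ids
  sites3 <- data.table(site_id = ids, habitat = "marsh",
                       distance_m = c(0, 1, 2), pool_n = as.integer(pool_n),
                       time_point = c("before", "during", "after"))
  t3 <- structure(list(loci = truth$loci, freq = fmat,
                       alleles = truth$alleles, sites = sites3,
                       layout = truth$layout, break_m = truth$break_m),
                  class = "gradient_truth")
  counts <- simulate_pool_counts(t3, sites3, mean_depth = mean_depth,
                                 seed = seed)
  list(counts = counts, truth = fmat, site_ids = ids)
}
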