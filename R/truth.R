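#' Plant ground-truth allele-frequency clines along the gradient
#'
#' Builds the "stated world" for synthetic data: a set of loci with known
#' stream-allele frequencies at every sampling site.  `selected` loci follow a
#' step at `break_m` (low frequency on the lake side, `low + endpoint_afd` on
#' the stream side), emulating loci under strong divergent selection.
#' Background loci (`neutral` and optionally `loDiff`) follow the same step
#' shape but scaled to a drift-level endpoint difference around a per-locus
#' random base frequency — fine-scale clinal data show background markers
#' tracking the same habitat transition as selected ones, only much more
#' weakly.
#'
#' @param layout Genome layout (see [default_layout()]).
#' @param sites Site table (see [default_sites()]), ordered by distance.
#' @param n_selected,n_background,n_lodiff Number of loci per class.
#' @param break_m Gradient position of the frequency break (meters); must lie
#'   within the span of `sites$distance_m`.
#' @param endpoint_afd_selected Endpoint allele-frequency difference of
#'   selected loci, in `[0, 1]`.
#' @param endpoint_afd_background,endpoint_afd_lodiff Endpoint AFD of the two
#'   background classes.
#' @param min_spacing_bp Minimum distance between planted loci (keeps panels
#'   statistically independent under the 50 kb ascertainment spacing).
#' @param autosomes_only Plant loci on autosomes only (default TRUE; sex
#'   chromosomes are excluded from all panel analyses anyway).
#' @param seed Integer seed.
#' @return Object of class `gradient_truth`: a list with `loci` (data.table:
#'   `locus_id`, `chrom`, `pos`, `class`), `freq` (matrix loci x sites of true
#'   stream-allele frequencies), `sites`, `layout`.
#' @export
make_gradient_truth <- function(layout, sites,
                                n_selected = 50L,
                                n_background = 1000L,
                                n_lodiff = 0L,
                                break_m = 1071,
                                endpoint_afd_selected = 1.0,
                                endpoint_afd_background = 0.35,
                                endpoint_afd_lodiff = 0.175,
                                min_spacing_bp = 1e5,
                                autosomes_only = TRUE,
                                seed = 1L) {
  sites <- validate_sites(sites)
  layout <- validate_layout(layout)
  stop_if_not_prob(endpoint_afd_selected, "endpoint_afd_selected")
  stop_if_not_prob(endpoint_afd_background, "endpoint_afd_background")
  stop_if_not_prob(endpoint_afd_lodiff, "endpoint_afd_lodiff")
  if (break_m < min(sites$distance_m) || break_m > max(sites$distance_m))
    stop("break_m must lie within the gradient span")

  n_tot <- n_selected + n_background + n_lodiff
  if (n_tot < 1L) stop("no loci requested")
  cls <- rep(c("selected", "neutral", "loDiff"),
             c(n_selected, n_background, n_lodiff))

  chroms <- if (autosomes_only) layout[is_sex == FALSE] else layout
  if (nrow(chroms) == 0L) stop("no eligible chromosomes in layout")

  withr::with_seed(seed, {
    loci <- draw_spaced_positions(chroms, n_tot, min_spacing_bp)
    loci[, locus_id := sprintf("locus_%04d", .I)]
    ## positions come back sorted: assign classes at random so locus class
    ## is independent of genomic location
    cls <- sample(cls)
    loci[, class := cls]

    ## fixed nucleotide coding per locus, so every count table simulated
    ## from this truth (including temporal replicates) is consistent
    pair <- t(vapply(seq_len(n_tot), function(i) sample(NUCS, 2L),
                     character(2L)))
    alleles <- data.table(locus_id = loci$locus_id, chrom = loci$chrom,
                          pos = loci$pos, lake_allele = pair[, 1L],
                          stream_allele = pair[, 2L], class = cls)

    on_stream_side <- sites$distance_m >= break_m
    freq <- matrix(NA_real_, nrow = n_tot, ncol = nrow(sites),
                   dimnames = list(loci$locus_id, sites$site_id))
    step01 <- as.numeric(on_stream_side)

    fill_class <- function(rows, afd) {
      k <- length(rows)
      if (k == 0L) return()
      ## per-locus base frequency keeps endpoints inside [0,1]
      base <- if (afd >= 1) rep(0.5, k) else runif(k, afd / 2, 1 - afd / 2)
      lo <- base - afd / 2
      freq[rows, ] <<- outer(lo, rep(1, ncol(freq))) +
        afd * matrix(step01, nrow = k, ncol = ncol(freq), byrow = TRUE)
    }
    fill_class(which(cls == "selected"), endpoint_afd_selected)
    fill_class(which(cls == "neutral"), endpoint_afd_background)
    fill_class(which(cls == "loDiff"), endpoint_afd_lodiff)
  })

  stopifnot(all(freq >= 0 & freq <= 1))
  structure(list(loci = loci[], freq = freq, alleles = alleles[],
                 sites = sites, layout = layout, break_m = break_m),
            class = "gradient_truth")
}

## Draw n positions on the given chromosomes, no two closer than spacing on
## the same chromosome.  Loci are allotted to chromosomes proportionally to
## length (capped at capacity), then placed uniformly within each chromosome
## by the order-statistics construction: sorted uniforms on the slack
## interval plus a cumulative spacing shift, which yields exactly uniform
## spaced points and works at any admissible density.
draw_spaced_positions <- function(chroms, n, spacing) {
  caps <- floor(chroms$length_bp / spacing)
  if (n > sum(caps))
    stop("cannot place ", n, " loci with spacing ", spacing, " bp")
  alloc <- as.vector(stats::rmultinom(1, n, prob = chroms$length_bp))
  while (any(alloc > caps)) {
    excess <- sum(pmax(alloc - caps, 0))
    alloc <- pmin(alloc, caps)
    slack <- caps - alloc
    for (i in order(slack, decreasing = TRUE)) {
      take <- min(excess, slack[i])
      alloc[i] <- alloc[i] + take
      excess <- excess - take
      if (excess == 0) break
    }
  }
  out <- rbindlist(lapply(which(alloc > 0L), function(i) {
    k <- alloc[i]
    room <- chroms$length_bp[i] - k * spacing
    u <- sort(runif(k, 0, max(room, 0)))
    data.table(chrom = chroms$chrom[i],
               pos = as.integer(floor(u + (seq_len(k) - 1) * spacing)) + 1L)
  }))
  setorder(out, chrom, pos)
  out
}

#' @export
print.gradient_truth <- function(x, ...) {
  cat("<gradient_truth> ", nrow(x$loci), " loci (",
      paste(sprintf("%s: %d", names(table(x$loci$class)),
                    as.integer(table(x$loci$class))), collapse = ", "),
      ") at ", ncol(x$freq), " sites; break at ", x$break_m, " m\n", sep = "")
  invisible(x)
}

#' Write a truth table as TSV (long format, for test introspection)
#' @param truth A `gradient_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  long <- data.table(
    locus_id = rep(rownames(truth$freq), ncol(truth$freq)),
    site_id = rep(colnames(truth$freq), each = nrow(truth$freq)),
    true_freq = as.vector(truth$freq)
  )
  long <- merge(long, truth$loci, by = "locus_id", sort = FALSE)
  fwrite(long, path, sep = "\t")
  invisible(path)
}
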