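#' Classify positions into chromosome center vs periphery
#'
#' The outer `margin_bp` on either chromosome end is the high-recombination
#' periphery; the remainder is the low-recombination center.  Chromosomes not
#' longer than `2 * margin_bp` have no center; every position is periphery
#' (such chromosomes are excluded from CCBD ratios).
#'
#' @param position_bp 1-based position(s).
#' @param chrom_length_bp Chromosome length(s), recycled.
#' @param margin_bp Periphery size per side (default 5 Mb).
#' @return Character vector `"center"`/`"periphery"`.
#' @export
classify_center_periphery <- function(position_bp, chrom_length_bp,
                                      margin_bp = 5e6) {
  if (any(position_bp < 1 | position_bp > chrom_length_bp))
    stop("position outside chromosome")
  periph <- position_bp <= margin_bp |
    position_bp > chrom_length_bp - margin_bp
  ifelse(periph, "periphery", "center")
}

#' Chromosome-center-biased differentiation for one site pair
#'
#' For each chromosome, the ratio of the median AFD across central SNPs to
#' the median AFD across peripheral SNPs; CCBD is the median of these
#' per-chromosome ratios (not a pooled ratio).  Chromosomes lacking SNPs in
#' either zone, chromosomes with no center (length <= 2 margins), and
#' chromosomes with a zero peripheral median are skipped with a warning.
#'
#' @param profile A `pair_profile` (per-SNP AFD with positions).
#' @param layout Genome layout; sex chromosomes are excluded.
#' @param margin_bp Periphery size per side (default 5 Mb).
#' @param metric `"afd"` (default) or `"fst"` (untested convention).
#' @return Object of class `ccbd_result`: list with `ccbd`, `ratios`
#'   (data.table chrom/center_median/periphery_median/ratio),
#'   `n_chromosomes_used`, `site_a`, `site_b`.
#' @export
ccbd_for_pair <- function(profile, layout, margin_bp = 5e6, metric = "afd") {
  layout <- validate_layout(layout)
  p <- as.data.table(profile)
  p <- p[chrom %in% layout[is_sex == FALSE, chrom]]
  p <- merge(p, layout[, .(chrom, length_bp)], by = "chrom")
  if (nrow(p) == 0L) stop("no usable chromosome in profile")
  no_center <- unique(p$chrom[p$length_bp <= 2 * margin_bp])
  if (length(no_center)) {
    warning("chromosome(s) without center excluded: ",
            paste(no_center, collapse = ", "))
    p <- p[!chrom %in% no_center]
  }
  if (nrow(p) == 0L) stop("no usable chromosome in profile")
  p[, zone := classify_center_periphery(pos, length_bp, margin_bp)]
  v <- if (metric == "fst") p$fst else p$afd
  p[, value := v]
  ratios <- p[, .(center_median = median(value[zone == "center"]),
                  periphery_median = median(value[zone == "periphery"]),
                  n_center = sum(zone == "center"),
                  n_periphery = sum(zone == "periphery")),
              by = chrom]
  usable <- ratios[n_center > 0 & n_periphery > 0 & periphery_median > 0]
  dropped <- nrow(ratios) - nrow(usable)
  if (dropped > 0)
    warning(dropped, " chromosome(s) dropped (empty zone or zero peripheral median)")
  if (nrow(usable) == 0L) stop("no chromosome with both zones populated")
  usable[, ratio := center_median / periphery_median]
  structure(list(ccbd = median(usable$ratio), ratios = usable[],
                 n_chromosomes_used = nrow(usable),
                 site_a = attr(profile, "site_a"),
                 site_b = attr(profile, "site_b")),
            class = "ccbd_result")
}

#' @export
print.ccbd_result <- function(x, ...) {
  cat(sprintf("<ccbd_result> %s-%s: CCBD = %.3f (%d chromosomes)\n",
              x$site_a %||% "?", x$site_b %||% "?", x$ccbd,
              x$n_chromosomes_used))
  invisible(x)
}

#' CCBD along the gradient
#'
#' Computes CCBD for successive site pairs: `mode = "neighbors"` pairs each
#' site with the next one along the gradient (10 pairs for 11 sites), using
#' the midpoint of the two distances as gradient location;
#' `mode = "anchored_to_first"` pairs every later site with the first site.
#'
#' @param snps A `snp_table` genotyped at all sites.
#' @param sites Site table ordered by distance.
#' @param layout Genome layout.
#' @param mode `"neighbors"` or `"anchored_to_first"`.
#' @param depth_min,depth_max Per-sample depth window for the underlying
#'   pairwise profiles (defaults 50 / 200).
#' @param margin_bp Periphery size (default 5 Mb).
#' @return data.table (`site_a`, `site_b`, `midpoint_m`, `ccbd`,
#'   `n_chromosomes_used`) with one row per pair, plus attribute `results`
#'   (list of `ccbd_result`).
#' @export
ccbd_along_gradient <- function(snps, sites, layout,
                                mode = c("neighbors", "anchored_to_first"),
                                depth_min = 50, depth_max = 200,
                                margin_bp = 5e6) {
  mode <- match.arg(mode)
  sites <- validate_sites(sites)
  if (nrow(sites) < 2L) stop("need at least 2 sites")
  pairs <- if (mode == "neighbors")
    data.table(a = sites$site_id[-nrow(sites)], b = sites$site_id[-1L],
               mid = (sites$distance_m[-nrow(sites)] + sites$distance_m[-1L]) / 2)
  else
    data.table(a = sites$site_id[1L], b = sites$site_id[-1L],
               mid = (sites$distance_m[1L] + sites$distance_m[-1L]) / 2)
  results <- lapply(seq_len(nrow(pairs)), function(i) {
    prof <- pairwise_profile(snps, pairs$a[i], pairs$b[i],
                             depth_min = depth_min, depth_max = depth_max)
    ccbd_for_pair(prof, layout, margin_bp = margin_bp)
  })
  out <- data.table(site_a = pairs$a, site_b = pairs$b,
                    midpoint_m = pairs$mid,
                    ccbd = vapply(results, `[[`, 0, "ccbd"),
                    n_chromosomes_used = vapply(results, `[[`, 0L,
                                                "n_chromosomes_used"))
  setattr(out, "results", results)
  out[]
}
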