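#' Default clinal sampling design
#'
#' Eleven sampling sites along a ~2 km lake-marsh-stream gradient: two lake
#' sites, two marsh sites and seven stream sites, each a pool of 56 diploid
#' individuals.  Distances are synthetic defaults (meters of swimming path
#' from the first lake site); the habitat boundaries are lake/marsh at 600 m
#' and marsh/stream at 1045 m.  Override any column when real site metadata
#' are available.
#'
#' @param pool_n Number of diploid individuals per pool (recycled).
#' @return A `data.table` with columns `site_id`, `habitat`, `distance_m`,
#'   `pool_n`, `time_point` (NA except for temporal replicates).
#' @export
default_sites <- function(pool_n = 56L) {
  s <- data.table(
    site_id = c("L1", "L2", "M1", "M2", "S1", "S2", "S3", "S4", "S5", "S6", "S7"),
    habitat = c("lake", "lake", "marsh", "marsh", rep("stream", 7L)),
    distance_m = c(0, 350, 700, 900, 1050, 1120, 1180, 1250, 1450, 1700, 1950),
    pool_n = as.integer(pool_n),
    time_point = NA_character_
  )
  validate_sites(s)
  s
}

#' Validate a site metadata table
#'
#' @param sites data.frame with at least `site_id`, `habitat`, `distance_m`,
#'   `pool_n`.
#' @return The table, invisibly, as a `data.table`.
#' @export
validate_sites <- function(sites) {
  sites <- as.data.table(sites)
  need <- c("site_id", "habitat", "distance_m", "pool_n")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(sites) == 0L) stop("empty site list")
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id")
  if (any(sites$distance_m < 0)) stop("distance_m must be >= 0")
  if (is.unsorted(sites$distance_m, strictly = TRUE))
    stop("distance_m must be strictly increasing along the gradient order")
  if (any(sites$pool_n < 1L)) stop("pool_n must be >= 1")
  invisible(sites)
}

#' Default synthetic genome layout
#'
#' Twenty-one chromosomes of 28 Mb each; chromosome XIX is flagged as the sex
#' chromosome and excluded from autosomal analyses.  28 Mb keeps the 5 Mb
#' chromosome peripheries used by CCBD meaningful (center = 18 Mb).
#'
#' @param n_chrom Number of chromosomes.
#' @param length_bp Length of every chromosome, in bp.
#' @param sex_chrom Names of sex chromosomes.
#' @return `data.table` with columns `chrom`, `length_bp`, `is_sex`.
#' @export
default_layout <- function(n_chrom = 21L, length_bp = 28e6,
                           sex_chrom = "chrXIX") {
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
             "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
             "XIX", "XX", "XXI")
  nm <- if (n_chrom <= 21L) paste0("chr", roman[seq_len(n_chrom)])
        else paste0("chr", seq_len(n_chrom))
  layout <- data.table(chrom = nm,
                       length_bp = as.numeric(length_bp),
                       is_sex = nm %in% sex_chrom)
  validate_layout(layout)
  layout
}

#' Validate a genome layout
#' @param layout data.frame with `chrom`, `length_bp`, and optional `is_sex`.
#' @return The layout, invisibly, as a `data.table`.
#' @export
validate_layout <- function(layout) {
  layout <- as.data.table(layout)
  if (!all(c("chrom", "length_bp") %in% names(layout)))
    stop("layout needs columns chrom, length_bp")
  if (!"is_sex" %in% names(layout)) layout[, is_sex := FALSE]
  if (any(layout$length_bp <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(layout$chrom)) stop("duplicate chromosome names")
  invisible(layout)
}

#' Read / write site metadata TSV
#' @param path File path.
#' @return `read_sites` returns a validated `data.table`.
#' @export
read_sites <- function(path) {
  s <- fread(path, sep = "\t", colClasses = list(character = "time_point"))
  validate_sites(s)
  as.data.table(s)
}

#' @rdname read_sites
#' @param sites Site table to write.
#' @export
write_sites <- function(sites, path) {
  fwrite(validate_sites(sites), path, sep = "\t")
  invisible(path)
}
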