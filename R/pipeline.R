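#' Default pipeline configuration
#'
#' All filter thresholds default to the pipeline's canonical values: SNP
#' discovery depth 50-400x per pool and combined MAF >= 0.25; pairwise
#' profile depth 50-200x per sample; selected-panel AFD >= 0.97 with 50 kb
#' spacing; matched panels of 500 at the genome-wide median AFD (and half
#' of it) with 0.001 tolerance; 10 kb windows with 5 kb step and >= 5 SNPs;
#' 5 Mb CCBD periphery; HDW top 0.5%; flood filters AFD >= 0.75 / depth >=
#' 50.  The synthetic-data block describes the generated world; set
#' `counts_path`/`sites_path`/`layout_path` instead to run on real data.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides of individual entries (partial lists are merged).
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "clinepool_out", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    counts_path = NULL, sites_path = NULL, layout_path = NULL,
    ## default synthetic world: a 5-chromosome genome dense enough for the
    ## 10 kb window scan (~0.5 SNPs/kb) while keeping runtime desk-scale;
    ## the 21 x 28 Mb layout of make_gradient_truth remains available by
    ## overriding n_chrom / chrom_length_bp
    synthetic = list(n_selected = 50L, n_background = 60000L,
                     break_m = 1071, endpoint_afd_selected = 1.0,
                     endpoint_afd_background = 0.35,
                     mean_depth = 103, min_spacing_bp = 1000,
                     n_chrom = 5L, chrom_length_bp = 28e6,
                     sex_chrom = "chrV"),
    discovery = list(pool_a = c("L1", "L2"), pool_b = c("S6", "S7"),
                     depth_min = 50, depth_max = 400, maf_min = 0.25),
    profile = list(depth_min = 50, depth_max = 200),
    panels = list(selected_threshold = 0.97, spacing_bp = 50000,
                  matched_n = 500L, matched_tolerance = 0.001),
    windows = list(window_bp = 10000, step_bp = 5000, min_snps = 5L),
    ccbd = list(margin_bp = 5e6),
    hdw = list(top_fraction = 0.005, n_boot = 1000L),
    clines = list(n_replicates = 10L, n_snps = 10L, model = "two_tail"),
    ## synthetic-input only: simulate the three temporal marsh samples and
    ## estimate the admixture pulse back by mixture ABC
    ## before_stream_frac: pre-flood marsh composition, a lake-dominated
    ## genomic mix with a modest stream component (contact-zone hybridization)
    flood = list(enabled = TRUE, lambda_true = 0.9, recovery = 0.5,
                 before_stream_frac = 0.15, afd_min = 0.75, depth_min = 50,
                 n_sims = 4000, accept_fraction = 0.025),
    ## optional stepping-stone grid: list(m_values=..., s_values=..., reps=...)
    grid = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline config as JSON
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(list(out_dir = raw$out_dir %||% "clinepool_out",
                                  seed = raw$seed %||% 1L),
                             raw[setdiff(names(raw), c("out_dir", "seed"))]))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the clinal pipeline end to end
#'
#' Stages, in dependency order: load-or-simulate counts; SNP discovery;
#' stream-allele orientation; endpoint profile; panels (selected, neutral,
#' loDiff); per-panel cline fits; CCBD along the gradient; HDW scan with
#' empirical deltaAFD.  Every stage writes its TSV/JSON output under
#' `out_dir`, and a run manifest records the package version, seed and
#' config.  Re-running with the same config and seed reproduces all outputs
#' bit-identically.  Stage failures abort with the failing stage named.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res <- list()
  res$config <- config

  stage("input", {
    if (!is.null(config$counts_path)) {
      if (is.null(config$sites_path) || is.null(config$layout_path))
        stop("counts_path requires sites_path and layout_path")
      res$sites <- read_sites(config$sites_path)
      lay <- fread(config$layout_path)
      res$layout <- validate_layout(lay)
      res$counts <- read_count_table(config$counts_path)
    } else {
      res$sites <- default_sites()
      sy <- config$synthetic
      res$layout <- default_layout(n_chrom = sy$n_chrom,
                                   length_bp = sy$chrom_length_bp,
                                   sex_chrom = sy$sex_chrom)
      res$truth <- make_gradient_truth(
        res$layout, res$sites, n_selected = sy$n_selected,
        n_background = sy$n_background, break_m = sy$break_m,
        endpoint_afd_selected = sy$endpoint_afd_selected,
        endpoint_afd_background = sy$endpoint_afd_background,
        min_spacing_bp = sy$min_spacing_bp,
        seed = child_seed(config$seed, 1))
      res$counts <- simulate_pool_counts(res$truth, res$sites,
                                         mean_depth = sy$mean_depth,
                                         seed = child_seed(config$seed, 2))
      write_truth(res$truth, file.path(config$out_dir, "truth.tsv"))
    }
    write_sites(res$sites, file.path(config$out_dir, "sites.tsv"))
  })

  stage("discover", {
    dc <- config$discovery
    res$snps <- discover_snps(res$counts, dc$pool_a, dc$pool_b,
                              depth_min = dc$depth_min,
                              depth_max = dc$depth_max, maf_min = dc$maf_min)
    res$snps <- orient_stream_allele(res$snps, lake_site = dc$pool_a[1],
                                     stream_site = dc$pool_b[length(dc$pool_b)])
  })

  endpoint_a <- res$sites$site_id[1L]
  endpoint_b <- res$sites$site_id[nrow(res$sites)]
  stage("profile", {
    pf <- config$profile
    res$endpoint_profile <- pairwise_profile(res$snps, endpoint_a, endpoint_b,
                                             depth_min = pf$depth_min,
                                             depth_max = pf$depth_max)
    fwrite(res$endpoint_profile,
           file.path(config$out_dir, "endpoint_profile.tsv"), sep = "\t")
  })

  stage("panels", {
    pn <- config$panels
    res$panel_selected <- pick_selected_panel(
      res$endpoint_profile, res$layout, threshold = pn$selected_threshold,
      spacing_bp = pn$spacing_bp, seed = child_seed(config$seed, 3))
    med <- median(res$endpoint_profile$afd)
    res$median_afd <- med
    res$panel_neutral <- pick_matched_panel(
      res$endpoint_profile, res$layout, target_afd = med,
      tolerance = pn$matched_tolerance, n = pn$matched_n,
      spacing_bp = pn$spacing_bp, seed = child_seed(config$seed, 4),
      category = "neutral")
    res$panel_lodiff <- pick_matched_panel(
      res$endpoint_profile, res$layout, target_afd = med / 2,
      tolerance = pn$matched_tolerance, n = pn$matched_n,
      spacing_bp = pn$spacing_bp, seed = child_seed(config$seed, 5),
      category = "loDiff")
    write_panel(res$panel_selected, file.path(config$out_dir, "panel_selected.tsv"))
    write_panel(res$panel_neutral, file.path(config$out_dir, "panel_neutral.tsv"))
    write_panel(res$panel_lodiff, file.path(config$out_dir, "panel_lodiff.tsv"))
  })

  stage("clines", {
    cl <- config$clines
    pan <- as.data.table(res$panel_selected)
    n_fit <- min(nrow(pan), cl$n_snps)
    if (n_fit >= 2L) {
      fits <- lapply(seq_len(n_fit), function(i) {
        g <- res$snps[chrom == pan$chrom[i] & pos == pan$pos[i]]
        g <- g[match(res$sites$site_id, site_id)]
        fit_cline(g$freq_stream, g$n1 + g$n2, res$sites$distance_m,
                  n_replicates = cl$n_replicates, model = cl$model,
                  seed = child_seed(config$seed, 100 + i))
      })
      res$cline_fits <- fits
      res$cline_summary <- summarize_panel_clines(
        fits, n_boot = 1000L, seed = child_seed(config$seed, 6))
      est <- rbindlist(lapply(seq_along(fits), function(i)
        data.table(snp = i, center = fits[[i]]$params["c"],
                   width = fits[[i]]$params["w"],
                   loglik = fits[[i]]$log_lik,
                   n_converged = fits[[i]]$n_converged)))
      fwrite(est, file.path(config$out_dir, "cline_fits.tsv"), sep = "\t")
    }
  })

  stage("ccbd", {
    res$ccbd <- ccbd_along_gradient(res$snps, res$sites, res$layout,
                                    mode = "neighbors",
                                    depth_min = config$profile$depth_min,
                                    depth_max = config$profile$depth_max,
                                    margin_bp = config$ccbd$margin_bp)
    fwrite(res$ccbd, file.path(config$out_dir, "ccbd.tsv"), sep = "\t")
  })

  stage("hdw", {
    w <- config$windows
    s <- res$sites$site_id
    prof <- function(a, b) pairwise_profile(res$snps, a, b,
                                            depth_min = config$profile$depth_min,
                                            depth_max = config$profile$depth_max)
    win <- function(p) window_mean_afd(p, w$window_bp, w$step_bp, w$min_snps)
    ## target: first site vs first stream site; baseline: within first habitat
    first_stream <- res$sites[habitat == "stream", site_id][1L]
    d <- delta_windows(win(prof(s[1], first_stream)), win(prof(s[1], s[2])))
    hc <- pick_hdw_and_controls(d, top_fraction = config$hdw$top_fraction,
                                seed = child_seed(config$seed, 7))
    res$hdw <- hc
    res$delta_afd <- empirical_delta_afd(
      hc$hdw, hc$control, win(res$endpoint_profile),
      n_boot = config$hdw$n_boot, seed = child_seed(config$seed, 8))
    fwrite(d, file.path(config$out_dir, "delta_windows.tsv"), sep = "\t")
    jsonlite::write_json(
      res$delta_afd[c("source", "delta_afd", "ci", "n")],
      file.path(config$out_dir, "delta_afd.json"), auto_unbox = TRUE,
      digits = NA)
  })

  if (isTRUE(config$flood$enabled) && !is.null(res$truth)) stage("flood", {
    fl <- config$flood
    tf <- res$truth$freq
    n_sites <- ncol(tf)
    before <- fl$before_stream_frac * tf[, n_sites] +
      (1 - fl$before_stream_frac) * tf[, "M1"]
    sc <- make_flood_scenario(res$truth,
                              truth_before = before,
                              truth_lake = tf[, "L2"],
                              lambda_true = fl$lambda_true,
                              recovery = fl$recovery,
                              mean_depth = config$synthetic$mean_depth,
                              seed = child_seed(config$seed, 9))
    loci <- unique(as.data.table(res$snps)[, .(chrom, pos, allele1, allele2)])
    all_counts <- as_count_table(rbind(as.data.table(res$counts),
                                       as.data.table(sc$counts)))
    snps_all <- genotype_snps(all_counts, loci)
    res$flood_snps <- select_flood_snps(snps_all,
                                        temporal_samples = sc$site_ids,
                                        afd_min = fl$afd_min,
                                        depth_min = fl$depth_min)
    res$flood_summary <- temporal_summaries(res$flood_snps)
    fwrite(res$flood_summary$summary,
           file.path(config$out_dir, "flood_summary.tsv"), sep = "\t")
    during <- sc$site_ids[2L]
    fsl <- res$flood_snps$loci
    dsub <- snps_all[site_id == during]
    dsub <- dsub[res$flood_snps$freq[, .(chrom, pos)], on = c("chrom", "pos")]
    res$flood_abc <- abc_lake_proportion(
      list(freq = res$flood_snps$freq[[during]], depth = dsub$depth),
      p_before = res$flood_snps$freq[[sc$site_ids[1L]]],
      p_lake = fsl$p_lake,
      n_sims = fl$n_sims, accept_fraction = fl$accept_fraction,
      seed = child_seed(config$seed, 10))
    jsonlite::write_json(
      list(lambda_true = fl$lambda_true,
           posterior_median = res$flood_abc$median,
           ci = res$flood_abc$ci, p_ge_0.9 = res$flood_abc$p_ge_0.9,
           n_snps = nrow(res$flood_snps$freq)),
      file.path(config$out_dir, "flood_abc.json"), auto_unbox = TRUE,
      digits = NA)
  })

  if (!is.null(config$grid)) stage("simulations", {
    g <- run_parameter_grid(config$grid$m_values, config$grid$s_values,
                            reps = config$grid$reps %||% 20L,
                            seed = child_seed(config$seed, 11))
    res$grid <- g
    fwrite(g, file.path(config$out_dir, "grid_summary.tsv"), sep = "\t")
  })

  res$manifest <- list(
    package = "clinepool",
    version = as.character(utils::packageVersion("clinepool")),
    seed = config$seed,
    timestamp = NULL,   # deterministic outputs: no timestamps
    n_snps = length(unique(paste(res$snps$chrom, res$snps$pos))),
    config = unclass(config))
  jsonlite::write_json(res$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}
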