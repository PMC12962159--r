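#' Configuration of a full analysis run
#'
#' Bundles the inputs and tunables of the end-to-end analysis: the
#' human-footprint and ecosystem-quality stacks, the driver layers, the
#' four-quadrant significance rule, the CCD parameters, the screening
#' settings, the structural model and the regions to fit, plus the output
#' directory and the global seed from which every stage seed is derived.
#'
#' @param hfi,eqi `aligned_stack`s sharing epochs and geometry.
#' @param drivers named list of `raster_grid` driver layers aligned with
#'   the stacks.
#' @param sigma_fraction four-quadrant significance fraction (default 0.1).
#' @param quadrant_rule `"or"` or `"and"` (see [classify_quadrant()]).
#' @param ccd a [ccd_params()] object.
#' @param pls a [path_model_spec()]; `NULL` builds the default model over
#'   whatever drivers survive screening.
#' @param regions quadrant classes to analyse (default all four).
#' @param vif_threshold,n_trees,n_permutations,alpha screening settings.
#' @param sample_max cap on driver-table rows (default `Inf`).
#' @param bootstrap_B bootstrap resamples for path inference; 0 disables.
#' @param min_region_rows minimum rows for a region to be fitted
#'   (default 100).
#' @param out_dir output directory; `NULL` disables file output.
#' @param seed global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(hfi, eqi, drivers,
                       sigma_fraction = 0.1,
                       quadrant_rule = c("or", "and"),
                       ccd = ccd_params(),
                       pls = NULL,
                       regions = c("coordination", "good_for_nature",
                                   "degradation", "conflict"),
                       vif_threshold = 6, n_trees = 500,
                       n_permutations = 100, alpha = 0.05,
                       sample_max = Inf, bootstrap_B = 0L,
                       min_region_rows = 100L,
                       out_dir = NULL, seed = 1L) {
  stopifnot(inherits(hfi, "aligned_stack"), inherits(eqi, "aligned_stack"))
  if (!identical(hfi$epochs, eqi$epochs))
    stop("HFI and EQI stacks must share epochs")
  assert_aligned(hfi$grids[[1]], eqi$grids[[1]])
  for (nm in names(drivers))
    if (!same_geometry(hfi$grids[[1]], drivers[[nm]]))
      stop(sprintf("driver layer '%s' is not aligned with the index stacks", nm))
  stopifnot(all(regions %in% names(QUADRANT_CLASSES)))
  structure(list(hfi = hfi, eqi = eqi, drivers = drivers,
                 sigma_fraction = sigma_fraction,
                 quadrant_rule = match.arg(quadrant_rule),
                 ccd = ccd, pls = pls, regions = regions,
                 vif_threshold = vif_threshold, n_trees = n_trees,
                 n_permutations = n_permutations, alpha = alpha,
                 sample_max = sample_max, bootstrap_B = as.integer(bootstrap_B),
                 min_region_rows = as.integer(min_region_rows),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Expects top-level keys `epochs`, `hfi` and `eqi` (lists of ASCII-grid
#' paths, one per epoch), `drivers` (named map of paths), and optionally
#' any scalar setting of [run_config()] (`sigma_fraction`, `seed`,
#' `out_dir`, ...). Relative paths resolve against the YAML file's
#' directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  epochs <- as.numeric(y$epochs)
  load_stack <- function(paths) aligned_stack(
    mapply(function(p, e) read_ascii_grid(resolve(p), epoch = e),
           paths, epochs, SIMPLIFY = FALSE), epochs)
  drivers <- lapply(y$drivers, function(p) read_ascii_grid(resolve(p)))
  extra <- y[setdiff(names(y), c("epochs", "hfi", "eqi", "drivers", "ccd"))]
  args <- c(list(hfi = load_stack(unlist(y$hfi)),
                 eqi = load_stack(unlist(y$eqi)),
                 drivers = drivers), extra)
  if (!is.null(y$ccd))
    args$ccd <- do.call(ccd_params, y$ccd)
  do.call(run_config, args)
}

#' Run the full human-nature coupling analysis
#'
#' Executes, in order: (1) index summaries and pooled natural-breaks
#' classification of HFI and EQI; (2) four-quadrant change classification
#' over the full period with area proportions; (3) CCD computation per
#' epoch with five-level classification; (4) assembly of the per-cell
#' driver table with the union-period quadrant map as region labels;
#' (5) per-region driver screening (VIF intersect permutation importance);
#' (6) per-region PLS path model fits on the surviving drivers, with
#' effect decomposition and optional bootstrap inference. Identical
#' config + seed gives identical outputs; when `out_dir` is set, rasters
#' (.asc), tables (.csv) and a JSON report are written there.
#'
#' @param config a [run_config()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  epochs <- config$hfi$epochs
  say("stage indices: %d epochs, %d x %d cells, %d unmasked",
      length(epochs), nrow(config$hfi$grids[[1]]$values),
      ncol(config$hfi$grids[[1]]$values),
      length(grid_values(config$hfi$grids[[1]])))

  index_means <- data.frame(
    epoch = epochs,
    hfi_mean = vapply(config$hfi$grids, function(g) mean(grid_values(g)), 0),
    eqi_mean = vapply(config$eqi$grids, function(g) mean(grid_values(g)), 0))
  hfi_classes <- classify_natural_breaks(config$hfi, k = 5)
  eqi_classes <- classify_natural_breaks(config$eqi, k = 5)

  # stage 2: four-quadrant classification over the union period
  t0 <- epochs[1]; t1 <- epochs[length(epochs)]
  chg <- period_change(config$hfi, config$eqi, t0, t1)
  qmap <- classify_quadrant(chg, sigma_fraction = config$sigma_fraction,
                            rule = config$quadrant_rule)
  qprop <- area_proportions(qmap)
  say("stage quadrant: %s-%s, sigma thresholds %.4g / %.4g", t0, t1,
      config$sigma_fraction * chg$sigma_d_hfi,
      config$sigma_fraction * chg$sigma_d_eqi)

  # stage 3: CCD per epoch on pooled 0-1 rescaled indices
  hfi01 <- minmax_normalize(config$hfi, 0, 1, domain = "pooled")
  eqi01 <- minmax_normalize(config$eqi, 0, 1, domain = "pooled")
  ccd_by_epoch <- lapply(seq_along(epochs), function(k) {
    res <- ccd_pipeline(hfi01$grids[[k]], eqi01$grids[[k]], config$ccd)
    cls <- classify_ccd(res$CCD)
    list(epoch = epochs[k], result = res, levels = cls$level,
         proportions = cls$proportions)
  })
  names(ccd_by_epoch) <- as.character(epochs)
  say("stage coupling: CCD computed for %d epochs (variant %s)",
      length(epochs), config$ccd$variant)

  # stage 4: driver table labelled by the union-period quadrant map
  last_ccd <- ccd_by_epoch[[length(epochs)]]$result$CCD
  table_seed <- config$seed + 1000L
  dtab <- build_driver_table(config$drivers, last_ccd, qmap,
                             sample_max = config$sample_max,
                             seed = table_seed)
  say("stage driver_table: %d rows across %d region classes",
      nrow(dtab), length(unique(dtab$region)))

  # stages 5-6: per-region screening and PLS fits
  region_results <- list()
  for (i in seq_along(config$regions)) {
    reg <- config$regions[i]
    rows <- dtab[dtab$region == reg, , drop = FALSE]
    if (nrow(rows) < config$min_region_rows) {
      say("region %s: skipped (%d rows < %d required)", reg, nrow(rows),
          config$min_region_rows)
      region_results[[reg]] <- list(region = reg, skipped = TRUE,
                                    cause = "insufficient rows",
                                    n_rows = nrow(rows))
      next
    }
    scr <- screen_drivers(rows,
                          vif_threshold = config$vif_threshold,
                          n_trees = config$n_trees,
                          n_permutations = config$n_permutations,
                          alpha = config$alpha,
                          seed = config$seed + 2000L + i)
    pls_res <- fit_region_pls(rows, scr$selected, config, i)
    say("region %s: %d rows, %d drivers selected, %s", reg, nrow(rows),
        length(scr$selected),
        if (is.null(pls_res)) "PLS skipped"
        else sprintf("GOF %.3f", pls_res$fit$gof))
    region_results[[reg]] <- list(region = reg, skipped = FALSE,
                                  n_rows = nrow(rows), screening = scr,
                                  pls = pls_res)
  }

  report <- structure(list(
    index_means = index_means,
    hfi_breaks = hfi_classes$breaks, eqi_breaks = eqi_classes$breaks,
    change = chg, quadrant_map = qmap, quadrant_proportions = qprop,
    ccd_by_epoch = ccd_by_epoch,
    driver_table = dtab, regions = region_results,
    seed = config$seed, log = log_lines,
    outputs = character(0)), class = "run_report")
  if (!is.null(config$out_dir))
    report <- write_run_outputs(report, config)
  report
}

# Fit the structural model for one region on its selected drivers.
fit_region_pls <- function(rows, selected, config, i) {
  spec <- config$pls
  if (is.null(spec)) {
    blocks <- list(Ter = c("ELE", "SLO"), Hum = c("NL", "PD", "GDP"),
                   Clm = c("PRE", "TEM", "ET"), Veg = c("NPP", "FVC", "kNDVI"),
                   CCD = "CCD")
    blocks <- lapply(blocks, function(b)
      b[b %in% c(selected, "CCD") & b %in% names(rows)])
    empty <- names(blocks)[lengths(blocks) == 0L]
    if (length(empty)) {
      warning(sprintf("latent(s) dropped (no surviving indicator): %s",
                      paste(empty, collapse = ", ")))
      blocks <- blocks[lengths(blocks) > 0L]
    }
    if (length(blocks) < 2L || !"CCD" %in% names(blocks)) return(NULL)
    paths <- data.frame(
      from = c("Ter", "Ter", "Ter", "Hum", "Hum", "Hum", "Clm", "Clm", "Veg"),
      to   = c("Hum", "Veg", "CCD", "Clm", "Veg", "CCD", "Veg", "CCD", "CCD"))
    paths <- paths[paths$from %in% names(blocks) & paths$to %in% names(blocks), ]
    if (!nrow(paths)) return(NULL)
    spec <- path_model_spec(names(blocks), blocks, paths)
  }
  fit <- tryCatch(fit_pls_pm(rows, spec), error = function(e) {
    warning(sprintf("PLS fit failed: %s", conditionMessage(e)))
    NULL
  })
  if (is.null(fit)) return(NULL)
  boot <- NULL
  if (config$bootstrap_B >= 100L)
    boot <- bootstrap_inference(rows, spec, B = config$bootstrap_B,
                                seed = config$seed + 3000L + i)
  list(fit = fit, effects = effects(fit), bootstrap = boot,
       gof = gof(fit))
}

# Serialize-and-checksum provenance hash of the settings (not the data).
config_hash <- function(config) {
  settings <- config[setdiff(names(config), c("hfi", "eqi", "drivers"))]
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(settings, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

write_run_outputs <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  files <- character(0)
  wcsv <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE)
    files <<- c(files, name)
  }
  wcsv(report$index_means, "index_means.csv")
  wcsv(report$quadrant_proportions, "quadrant_proportions.csv")
  lvl <- do.call(rbind, lapply(report$ccd_by_epoch, function(e)
    cbind(epoch = e$epoch, e$proportions)))
  rownames(lvl) <- NULL
  wcsv(lvl, "ccd_level_proportions.csv")
  write_ascii_grid(report$quadrant_map, out("quadrant_map.asc"))
  files <- c(files, "quadrant_map.asc")
  for (e in report$ccd_by_epoch) {
    nm <- sprintf("ccd_%s.asc", e$epoch)
    write_ascii_grid(e$result$CCD, out(nm))
    files <- c(files, nm)
  }
  for (reg in names(report$regions)) {
    rr <- report$regions[[reg]]
    if (isTRUE(rr$skipped) || is.null(rr$pls)) next
    wcsv(rr$pls$fit$path_coefficients,
         sprintf("paths_%s.csv", reg))
    wcsv(as.data.frame(rr$pls$effects), sprintf("effects_%s.csv", reg))
    if (!is.null(rr$pls$bootstrap))
      wcsv(rr$pls$bootstrap$paths, sprintf("bootstrap_%s.csv", reg))
  }
  summary <- list(
    seed = report$seed,
    config_hash = config_hash(config),
    r_version = as.character(getRversion()),
    outputs = files,
    quadrant_percent = stats::setNames(
      as.list(report$quadrant_proportions$percent),
      report$quadrant_proportions$class),
    gof = lapply(report$regions, function(rr)
      if (isTRUE(rr$skipped) || is.null(rr$pls)) NULL else rr$pls$fit$gof),
    log = report$log)
  jsonlite::write_json(summary, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(report$log, out("run.log"))
  report$outputs <- c(files, "report.json", "run.log")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  epochs:", paste(x$index_means$epoch, collapse = ", "), "\n")
  cat(sprintf("  quadrant shares: %s\n",
              paste(sprintf("%s %.1f%%", x$quadrant_proportions$class,
                            x$quadrant_proportions$percent),
                    collapse = ", ")))
  for (reg in names(x$regions)) {
    rr <- x$regions[[reg]]
    if (isTRUE(rr$skipped)) {
      cat(sprintf("  region %s: skipped (%s)\n", reg, rr$cause))
    } else if (!is.null(rr$pls)) {
      cat(sprintf("  region %s: %d rows, GOF %.3f (%s)\n", reg, rr$n_rows,
                  rr$pls$gof$gof, rr$pls$gof$label))
    }
  }
  invisible(x)
}
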