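#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R²_j), where R²_j comes from the ordinary
#' least-squares regression (with intercept) of predictor j on all other
#' predictors. Computed as the diagonal of the inverse correlation matrix;
#' exactly collinear predictors are reported as `Inf` rather than raising
#' an error.
#'
#' @param table data frame of observations.
#' @param predictors character vector of predictor columns (default: all
#'   numeric columns except `CCD`, `region` and `year`).
#' @return Named numeric vector of VIFs (all >= 1, possibly `Inf`).
#' @export
vif <- function(table, predictors = NULL) {
  predictors <- screen_predictors(table, predictors)
  if (length(predictors) < 2L) stop("need at least two predictors")
  X <- as.matrix(table[predictors])
  if (nrow(X) <= length(predictors))
    stop("need more rows than predictors")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant predictor: %s",
                 paste(predictors[sds == 0], collapse = ", ")))
  R <- stats::cor(X)
  out <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out)) || any(out < 1 - 1e-8)) {
    # singular or ill-conditioned: fall back per predictor, flag exact
    # linear dependence as +Inf
    out <- vapply(seq_along(predictors), function(j) {
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
      if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
    }, 0)
  }
  out <- pmax(out, 1)
  stats::setNames(as.numeric(out), predictors)
}

screen_predictors <- function(table, predictors) {
  if (!is.null(predictors)) return(predictors)
  drop <- c("CCD", "region", "year")
  num <- vapply(table, is.numeric, TRUE)
  setdiff(names(table)[num], drop)
}

#' Collinearity filter on VIF
#'
#' One-shot mode (default) excludes every predictor whose VIF exceeds the
#' threshold in a single pass. Iterative mode repeatedly drops the single
#' highest-VIF offender and recomputes until all survivors pass.
#'
#' @param table data frame of observations.
#' @param threshold VIF cutoff (default 6).
#' @param predictors predictor columns (default: see [vif()]).
#' @param mode `"one-shot"` (default) or `"iterative"`.
#' @return A list with `pass` (surviving predictor names, original order),
#'   `vif` (their VIFs in the final fit), `excluded`, and `all_vif` (the
#'   initial VIFs).
#' @export
vif_filter <- function(table, threshold = 6, predictors = NULL,
                       mode = c("one-shot", "iterative")) {
  mode <- match.arg(mode)
  predictors <- screen_predictors(table, predictors)
  v0 <- vif(table, predictors)
  if (mode == "one-shot") {
    pass <- predictors[v0 <= threshold]
    vfin <- v0[pass]
  } else {
    pass <- predictors
    vfin <- v0
    while (length(pass) >= 2L && max(vfin) > threshold) {
      worst <- pass[which.max(vfin)]
      pass <- setdiff(pass, worst)
      vfin <- if (length(pass) >= 2L) vif(table, pass)
              else stats::setNames(1, pass)
    }
  }
  if (length(pass) == 0L)
    warning("all predictors excluded by the VIF filter")
  list(pass = pass, vif = vfin, excluded = setdiff(predictors, pass),
       all_vif = v0)
}

#' Default random-forest regressor for importance screening
#'
#' The regressor contract behind [importance_filter()]: a function taking
#' `(x, y, seed)` and returning a list with `oob_mse` (out-of-bag mean
#' squared error) and `importance` (named permutation importance: mean
#' increase in out-of-bag MSE when one predictor is shuffled). This default
#' wraps a `ranger` regression forest.
#'
#' @param n_trees number of trees (default 500).
#' @param ... further arguments passed to [ranger::ranger()].
#' @return A regressor function.
#' @export
forest_regressor <- function(n_trees = 500, ...) {
  force(n_trees)
  dots <- list(...)
  function(x, y, seed) {
    df <- as.data.frame(x)
    df$.response <- y
    fit <- do.call(ranger::ranger, c(list(
      dependent.variable.name = ".response", data = df,
      num.trees = n_trees, importance = "permutation",
      seed = seed, num.threads = 1L, verbose = FALSE), dots))
    list(oob_mse = fit$prediction.error,
         importance = fit$variable.importance)
  }
}

#' Permutation-importance filter with a permutation-null significance test
#'
#' Fits an ensemble regression forest of the coupling coordination degree
#' on the candidate drivers and scores each driver by %IncMSE: the
#' out-of-bag permutation importance expressed as a percentage of the
#' out-of-bag MSE. Significance is assessed against a response-permutation
#' null: the response is permuted `n_permutations` times, the forest refit
#' and the importance recomputed each time, and the p-value for driver j is
#' `(1 + #{null >= observed}) / (n_permutations + 1)`. Drivers with
#' `p < alpha` pass.
#'
#' @param table data frame with driver columns and the response.
#' @param response response column name (default `"CCD"`).
#' @param predictors predictor columns (default: see [vif()]).
#' @param n_trees trees in the ensemble (default 500).
#' @param n_permutations null resamples (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed driving both the forest and the null draws.
#' @param regressor a regressor contract (default [forest_regressor()]).
#' @return A list with `pass`, `scores` (%IncMSE), `p_values`, and the
#'   settings used.
#' @export
importance_filter <- function(table, response = "CCD", predictors = NULL,
                              n_trees = 500, n_permutations = 100,
                              alpha = 0.05, seed = 1L,
                              regressor = forest_regressor(n_trees)) {
  predictors <- screen_predictors(table, predictors)
  if (!response %in% names(table)) stop("response column missing")
  if (nrow(table) < 100L) stop("need at least 100 rows for importance screening")
  X <- as.matrix(table[predictors])
  y <- table[[response]]
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in the screening table")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  base <- regressor(X, y, seed = sample.int(.Machine$integer.max, 1))
  obs <- 100 * base$importance[predictors] / base$oob_mse
  obs[apply(X, 2, stats::sd) == 0] <- 0   # permuting a constant is a no-op
  null <- matrix(0, n_permutations, length(predictors),
                 dimnames = list(NULL, predictors))
  for (b in seq_len(n_permutations)) {
    yb <- y[sample.int(length(y))]
    fb <- regressor(X, yb, seed = sample.int(.Machine$integer.max, 1))
    null[b, ] <- 100 * fb$importance[predictors] / fb$oob_mse
  }
  p <- vapply(predictors, function(j)
    (1 + sum(null[, j] >= obs[[j]])) / (n_permutations + 1), 0)
  list(pass = predictors[p < alpha],
       scores = obs, p_values = p,
       n_trees = n_trees, n_permutations = n_permutations, alpha = alpha)
}

#' Intersection of the two screening filters
#'
#' @param vif_pass,importance_pass character vectors of surviving drivers.
#' @param order reference ordering for the result (default: order of
#'   `vif_pass`).
#' @return Character vector of drivers passing both filters, in stable
#'   original order; warns when empty.
#' @export
intersect_screen <- function(vif_pass, importance_pass, order = vif_pass) {
  sel <- order[order %in% vif_pass & order %in% importance_pass]
  if (length(sel) == 0L) warning("screening selected no drivers")
  sel
}

#' Full driver screening for one table
#'
#' Runs the collinearity filter and the importance filter on the same
#' table and intersects the survivors.
#'
#' @inheritParams importance_filter
#' @param vif_threshold VIF cutoff (default 6).
#' @param vif_mode `"one-shot"` (default) or `"iterative"`.
#' @return An object of class `screening_report`: `vif`, `importance`
#'   (scores and p-values), `vif_pass`, `importance_pass`, `selected`,
#'   `n_rows`.
#' @export
screen_drivers <- function(table, response = "CCD", predictors = NULL,
                           vif_threshold = 6,
                           vif_mode = c("one-shot", "iterative"),
                           n_trees = 500, n_permutations = 100,
                           alpha = 0.05, seed = 1L) {
  predictors <- screen_predictors(table, predictors)
  vf <- vif_filter(table, threshold = vif_threshold,
                   predictors = predictors, mode = match.arg(vif_mode))
  im <- importance_filter(table, response = response,
                          predictors = predictors, n_trees = n_trees,
                          n_permutations = n_permutations, alpha = alpha,
                          seed = seed)
  structure(list(vif = vf$all_vif, importance = im,
                 vif_pass = vf$pass, importance_pass = im$pass,
                 selected = intersect_screen(vf$pass, im$pass,
                                             order = predictors),
                 n_rows = nrow(table)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d rows\n", x$n_rows))
  cat("  VIF pass:        ", paste(x$vif_pass, collapse = ", "), "\n")
  cat("  importance pass: ", paste(x$importance_pass, collapse = ", "), "\n")
  cat("  selected:        ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a per-cell driver table
#'
#' Joins aligned driver layers, a CCD layer and a quadrant (region) map
#' into the tabular form used by screening and path modeling: one row per
#' unmasked cell with driver values, the CCD response and the region
#' label. Insignificant cells are dropped (they belong to no region).
#'
#' @param drivers named list of aligned `raster_grid` layers.
#' @param ccd_grid aligned `raster_grid` of CCD values.
#' @param quadrant_map aligned quadrant map from [classify_quadrant()].
#' @param sample_max optional cap on rows; a seeded uniform subsample is
#'   taken when exceeded.
#' @param seed seed for the subsample (default 1).
#' @return Data frame with driver columns, `CCD` and `region`.
#' @export
build_driver_table <- function(drivers, ccd_grid, quadrant_map,
                               sample_max = Inf, seed = 1L) {
  stopifnot(length(drivers) >= 1L, !is.null(names(drivers)))
  ref <- drivers[[1]]
  for (d in drivers) if (!same_geometry(ref, d)) stop("driver layers misaligned")
  if (!same_geometry(ref, ccd_grid) || !same_geometry(ref, quadrant_map))
    stop("CCD or quadrant layer misaligned with drivers")
  masks <- c(lapply(drivers, function(g) g$mask),
             list(ccd_grid$mask, quadrant_map$mask))
  bad <- Reduce(`|`, masks)
  keep <- !bad & !is.na(quadrant_map$values) &
    quadrant_map$values != QUADRANT_CLASSES[["insignificant"]]
  df <- as.data.frame(lapply(drivers, function(g) g$values[keep]))
  names(df) <- names(drivers)
  df$CCD <- ccd_grid$values[keep]
  code <- quadrant_map$values[keep]
  df$region <- names(QUADRANT_CLASSES)[match(code, QUADRANT_CLASSES)]
  if (nrow(df) > sample_max) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    df <- df[sort(sample.int(nrow(df), sample_max)), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
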