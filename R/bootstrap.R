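#' Bootstrap inference for PLS path coefficients
#'
#' Nonparametric bootstrap over observations: rows are resampled with
#' replacement `B` times, the full PLS-PM estimator is re-run on each
#' resample, and each bootstrap fit is sign-aligned to the base fit (per
#' block, the latent orientation with the positive inner product of outer
#' weights is kept) before aggregation. Per-path standard errors are the
#' SDs of the bootstrap distribution; two-sided p-values use the normal
#' approximation z = estimate / SE, starred at 0.05 / 0.01 / 0.001;
#' percentile confidence intervals are also reported. Resamples whose fit
#' fails (e.g. a constant indicator after resampling) are dropped and
#' counted; more than 10% failures aborts the inference.
#'
#' @param data data frame with all indicator columns.
#' @param spec a [path_model_spec()].
#' @param B number of bootstrap resamples (default 999, minimum 100).
#' @param seed integer seed.
#' @param conf_level confidence level for the percentile intervals
#'   (default 0.95).
#' @param resample_fn function `(n, b) -> integer indices` drawing the
#'   b-th resample; the default draws `n` rows with replacement.
#'   Replaceable for diagnostics (e.g. a degenerate identity resampler).
#' @return An object of class `pls_boot`: data frame `paths` with columns
#'   `from`, `to`, `estimate`, `se`, `z`, `p_value`, `stars`, `ci_lo`,
#'   `ci_hi`, plus `fit` (the base fit), `B`, `n_failed`.
#' @export
bootstrap_inference <- function(data, spec, B = 999L, seed = 1L,
                                conf_level = 0.95,
                                resample_fn = NULL) {
  stopifnot(inherits(spec, "path_model_spec"))
  if (B < 100L) stop("B must be at least 100")
  base <- fit_pls_pm(data, spec)
  inds <- unlist(spec$blocks, use.names = FALSE)
  X <- as.matrix(data[inds])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  cs <- compile_spec(spec, colnames(X))
  edges <- which(spec$adj, arr.ind = TRUE)
  if (is.null(resample_fn))
    resample_fn <- function(n, b) sample.int(n, replace = TRUE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  est <- matrix(NA_real_, B, nrow(edges))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- resample_fn(n, b)
    fit_b <- tryCatch({
      Xb <- X[idx, , drop = FALSE]
      if (any(apply(Xb, 2, stats::sd) == 0)) stop("constant column")
      pls_core(scale(Xb), cs)
    }, error = function(e) NULL)
    if (is.null(fit_b)) { n_failed <- n_failed + 1L; next }
    pm <- align_signs(fit_b, base, spec)
    est[b, ] <- pm[edges]
  }
  if (n_failed > 0.1 * B)
    stop(sprintf("bootstrap inference failed: %d of %d resamples unusable",
                 n_failed, B))
  est <- est[stats::complete.cases(est), , drop = FALSE]
  se <- apply(est, 2, stats::sd)
  point <- base$path_matrix[edges]
  z <- ifelse(se > 0, point / se, ifelse(point == 0, 0, Inf * sign(point)))
  p <- 2 * stats::pnorm(-abs(z))
  alpha2 <- (1 - conf_level) / 2
  ci <- apply(est, 2, stats::quantile, probs = c(alpha2, 1 - alpha2),
              names = FALSE)
  paths <- data.frame(
    from = spec$latent_names[edges[, "col"]],
    to = spec$latent_names[edges[, "row"]],
    estimate = point, se = se, z = z, p_value = p,
    stars = significance_stars(p),
    ci_lo = ci[1, ], ci_hi = ci[2, ])
  ord <- order(match(paths$from, spec$latent_names),
               match(paths$to, spec$latent_names))
  paths <- paths[ord, ]; rownames(paths) <- NULL
  structure(list(paths = paths, fit = base, B = B, n_failed = n_failed,
                 conf_level = conf_level),
            class = "pls_boot")
}

# Flip bootstrap latent orientations to match the base fit and return the
# sign-adjusted path matrix.
align_signs <- function(fit_b, base, spec) {
  q <- length(spec$latent_names)
  s <- vapply(seq_len(q), function(j) {
    d <- sum(fit_b$weights[[j]] * base$outer_weights[[j]])
    if (d < 0) -1 else 1
  }, 0)
  fit_b$path_matrix * outer(s, s)
}

#' Significance stars at the conventional thresholds
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.pls_boot <- function(x, ...) {
  cat(sprintf("<pls_boot> B = %d resamples (%d failed), %.0f%% CIs\n",
              x$B, x$n_failed, 100 * x$conf_level))
  print(x$paths, digits = 3)
  invisible(x)
}
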