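# Shared fixtures and independent oracles used across the test files.

# quick grid from a matrix
g_ <- function(m, ...) raster_grid(as.matrix(m), ...)

# two-epoch stacks from matrices
stack2 <- function(m0, m1, epochs = c(2000, 2020)) {
  aligned_stack(list(g_(m0, epoch = epochs[1]), g_(m1, epoch = epochs[2])),
                epochs)
}

# --- Jenks oracle: exhaustive search over contiguous k-partitions ----------
partition_sse <- function(x, starts) {
  # starts: 1-based start index of each class (first is 1), x sorted
  ends <- c(starts[-1] - 1L, length(x))
  sum(vapply(seq_along(starts), function(i) {
    seg <- x[starts[i]:ends[i]]
    sum((seg - mean(seg))^2)
  }, 0))
}

exhaustive_jenks_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  if (k == 1L) return(partition_sse(x, 1L))
  cuts <- utils::combn(2:n, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    sse <- partition_sse(x, c(1L, cuts[, j]))
    if (sse < best) best <- sse
  }
  best
}

jenks_sse <- function(x, breaks) {
  x <- sort(x)
  cls <- findInterval(x, breaks, left.open = TRUE) + 1L
  sum(tapply(x, cls, function(s) sum((s - mean(s))^2)))
}

# --- VIF oracle: per-predictor OLS via the full normal equations ------------
brute_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    A <- cbind(1, X[, -j, drop = FALSE])
    b <- solve(crossprod(A), crossprod(A, X[, j]))
    res <- X[, j] - A %*% b
    r2 <- 1 - sum(res^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, 0)
}

# --- chained standardized OLS oracle for single-indicator path models -------
chained_ols_paths <- function(data, spec) {
  q <- length(spec$latent_names)
  Z <- sapply(spec$latent_names, function(l) {
    as.numeric(scale(data[[spec$blocks[[l]]]]))
  })
  out <- matrix(0, q, q, dimnames = list(spec$latent_names, spec$latent_names))
  for (j in seq_len(q)) {
    pred <- which(spec$adj[j, ])
    if (!length(pred)) next
    fit <- stats::lm.fit(cbind(1, Z[, pred, drop = FALSE]), Z[, j])
    out[j, pred] <- fit$coefficients[-1]
  }
  out
}

# --- calibrated quadrant fixture: large-trend blocks fix the change-SD so
# the small blocks sit at exactly 3x the 10%-of-SD significance threshold ---
three_sigma_spec <- function(seed, shape = c(40, 40), s = 10, sigma = 0.4) {
  m <- 3 * 0.1 * s
  M <- sqrt(1.91 * s^2 - 4 * sigma^2)
  rs <- shape[1] %/% 2L; qc <- shape[2] %/% 4L
  cls <- c("coordination", "good_for_nature", "degradation", "conflict")
  sgn_h <- c(1, -1, -1, 1); sgn_e <- c(1, 1, -1, -1)
  lay <- rbind(
    data.frame(row0 = 1L, row1 = rs, col0 = seq(1L, by = qc, length.out = 4),
               col1 = seq(qc, by = qc, length.out = 4), class = cls,
               d_hfi = sgn_h * M, d_eqi = sgn_e * M),
    data.frame(row0 = rs + 1L, row1 = shape[1],
               col0 = seq(1L, by = qc, length.out = 4),
               col1 = seq(qc, by = qc, length.out = 4), class = cls,
               d_hfi = sgn_h * m, d_eqi = sgn_e * m))
  synthetic_raster_spec(shape, c(2000, 2020), lay, base_hfi = 45,
                        base_eqi = 50, noise_sd = sigma,
                        nodata_fraction = 0, seed = seed)
}

# --- random feasible path draws on the default 5-latent hypothesis graph ---
rand_default_paths <- function(seed, range = c(-0.6, 0.6)) {
  set.seed(seed)
  keys <- c("Ter->Hum", "Ter->Veg", "Ter->CCD", "Hum->Clm", "Hum->Veg",
            "Hum->CCD", "Clm->Veg", "Clm->CCD", "Veg->CCD")
  pv <- stats::setNames(stats::runif(length(keys), range[1], range[2]), keys)
  # keep the unit-variance construction feasible: shrink a latent's
  # incoming coefficients while its implied explained variance is >= 0.85
  repeat {
    ok <- tryCatch({
      generate_sem_table(default_latent_model(pv, n = 130, seed = 1))
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      ex <- max_explained(pv)
      if (ex < 0.85) break
    }
    pv <- pv * 0.9
  }
  pv
}

max_explained <- function(pv) {
  ls <- default_latent_model(pv, n = 130, seed = 1)
  tb <- generate_sem_table(ls)
  R <- tb$truth$latent_correlation
  B <- tb$truth$path_matrix
  mx <- 0
  for (j in seq_len(nrow(B))) {
    pred <- which(B[j, ] != 0)
    if (!length(pred)) next
    mx <- max(mx, drop(t(B[j, pred]) %*% R[pred, pred] %*% B[j, pred]))
  }
  mx
}
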