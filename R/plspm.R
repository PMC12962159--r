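#' Specify a PLS path model
#'
#' Defines the measurement model (reflective indicator blocks per latent)
#' and the structural model (directed paths among latents) for the partial
#' least squares path modeling estimator. Latents must be ordered so that
#' every path runs from an earlier to a later latent (strictly
#' lower-triangular adjacency, hence acyclic).
#'
#' @param latent_names ordered character vector of latent names.
#' @param blocks named list: latent -> character vector of indicator
#'   columns (reflective, Mode A).
#' @param paths two-column data frame (`from`, `to`) of structural edges,
#'   or a logical adjacency matrix `adj[to, from]`.
#' @param scheme inner weighting scheme: `"path"` (default), `"centroid"`
#'   or `"factorial"`.
#' @param max_iter maximum outer-weight iterations (default 300).
#' @param tol convergence tolerance on the maximum absolute outer-weight
#'   change (default 1e-6).
#' @return An object of class `path_model_spec`.
#' @export
path_model_spec <- function(latent_names, blocks, paths,
                            scheme = c("path", "centroid", "factorial"),
                            max_iter = 300L, tol = 1e-6) {
  scheme <- match.arg(scheme)
  q <- length(latent_names)
  if (!setequal(names(blocks), latent_names))
    stop("blocks must be named by the latents")
  inds <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(inds))
    stop("every indicator must belong to exactly one block")
  if (is.data.frame(paths)) {
    adj <- matrix(FALSE, q, q, dimnames = list(latent_names, latent_names))
    for (i in seq_len(nrow(paths))) {
      f <- paths$from[i]; t_ <- paths$to[i]
      if (!f %in% latent_names || !t_ %in% latent_names)
        stop("path endpoint is not a declared latent")
      adj[t_, f] <- TRUE
    }
  } else {
    adj <- as.matrix(paths)
    dimnames(adj) <- list(latent_names, latent_names)
  }
  if (any(adj[upper.tri(adj, diag = TRUE)]))
    stop("paths must respect the latent ordering (acyclic, lower-triangular)")
  structure(list(latent_names = latent_names, blocks = blocks[latent_names],
                 adj = adj, scheme = scheme,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "path_model_spec")
}

#' Default structural model for CCD driving mechanisms
#'
#' Five latents in causal order -- terrain (Ter), human activity (Hum),
#' climate (Clm), vegetation (Veg) and the coupling coordination degree
#' (CCD) -- wired with the four standard hypotheses: all four driver
#' latents influence CCD directly; terrain acts indirectly through human
#' activity and vegetation; human activity acts indirectly through climate
#' and vegetation; climate acts indirectly through vegetation.
#'
#' @param blocks named list of indicator columns per latent; the default
#'   uses the canonical driver blocks (Ter = ELE, SLO; Hum = NL, PD, GDP;
#'   Clm = PRE, TEM, ET; Veg = NPP, FVC, kNDVI; CCD = CCD).
#' @param ... passed on to [path_model_spec()].
#' @return A `path_model_spec`.
#' @export
default_path_model <- function(blocks = NULL, ...) {
  if (is.null(blocks))
    blocks <- list(Ter = c("ELE", "SLO"),
                   Hum = c("NL", "PD", "GDP"),
                   Clm = c("PRE", "TEM", "ET"),
                   Veg = c("NPP", "FVC", "kNDVI"),
                   CCD = "CCD")
  paths <- data.frame(
    from = c("Ter", "Ter", "Ter", "Hum", "Hum", "Hum", "Clm", "Clm", "Veg"),
    to   = c("Hum", "Veg", "CCD", "Clm", "Veg", "CCD", "Veg", "CCD", "CCD"))
  path_model_spec(names(blocks), blocks, paths, ...)
}

# Compile a spec against a data matrix: resolve indicator columns.
compile_spec <- function(spec, cols) {
  idx <- lapply(spec$blocks, function(b) {
    i <- match(b, cols)
    if (anyNA(i)) stop(sprintf("indicator(s) missing from data: %s",
                               paste(b[is.na(i)], collapse = ", ")))
    i
  })
  list(latent_names = spec$latent_names, block_idx = idx, adj = spec$adj,
       scheme = spec$scheme, max_iter = spec$max_iter, tol = spec$tol)
}

# Core Lohmoeller PLS-PM estimator on a standardized matrix. Mode A outer
# estimation; centroid/factorial/path inner schemes; sign fixed per block
# so the sum of loadings is non-negative.
pls_core <- function(Xs, cs) {
  n <- nrow(Xs)
  q <- length(cs$latent_names)
  adj <- cs$adj
  nbr <- adj | t(adj)                      # adjacency, either direction
  W <- lapply(cs$block_idx, function(idx) rep(1, length(idx)))
  LV <- matrix(0, n, q, dimnames = list(NULL, cs$latent_names))
  norm_lv <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("degenerate latent: zero variance")
    (v - mean(v)) / s
  }
  for (j in 1:q) {
    raw <- Xs[, cs$block_idx[[j]], drop = FALSE] %*% W[[j]]
    s <- stats::sd(raw); W[[j]] <- W[[j]] / s
    LV[, j] <- norm_lv(raw)
  }
  converged <- FALSE
  iter <- 0L
  while (iter < cs$max_iter) {
    iter <- iter + 1L
    R <- stats::cor(LV)
    E <- matrix(0, q, q)
    for (j in 1:q) {
      if (cs$scheme == "centroid") {
        E[j, nbr[j, ]] <- sign(R[j, nbr[j, ]])
      } else if (cs$scheme == "factorial") {
        E[j, nbr[j, ]] <- R[j, nbr[j, ]]
      } else {                              # path scheme
        pred <- which(adj[j, ])
        succ <- which(adj[, j])
        if (length(pred)) {
          b <- solve(R[pred, pred, drop = FALSE], R[pred, j])
          E[j, pred] <- b
        }
        if (length(succ)) E[j, succ] <- R[j, succ]
      }
    }
    Z <- LV %*% t(E)                        # inner proxies
    W_new <- W
    delta <- 0
    for (j in 1:q) {
      idx <- cs$block_idx[[j]]
      if (all(Z[, j] == 0)) next            # isolated latent: keep weights
      w <- drop(crossprod(Xs[, idx, drop = FALSE], Z[, j])) / (n - 1)
      raw <- Xs[, idx, drop = FALSE] %*% w
      s <- stats::sd(raw)
      if (s == 0) stop("degenerate latent: zero variance")
      w <- w / s
      lv <- norm_lv(Xs[, idx, drop = FALSE] %*% w)
      # orient so the block's summed loading is non-negative
      if (sum(stats::cor(Xs[, idx, drop = FALSE], lv)) < 0) {
        w <- -w; lv <- -lv
      }
      delta <- max(delta, max(abs(w - W[[j]])))
      W_new[[j]] <- w
      LV[, j] <- lv
    }
    W <- W_new
    if (delta < cs$tol) { converged <- TRUE; break }
  }
  # measurement model
  loadings <- stats::setNames(
    unlist(lapply(1:q, function(j)
      drop(stats::cor(Xs[, cs$block_idx[[j]], drop = FALSE], LV[, j])))),
    colnames(Xs)[unlist(cs$block_idx)])
  communality <- loadings^2
  # structural model: OLS of each endogenous latent on its predecessors
  pathm <- matrix(0, q, q, dimnames = dimnames(adj))
  r2 <- stats::setNames(rep(NA_real_, q), cs$latent_names)
  Rlv <- stats::cor(LV)
  for (j in 1:q) {
    pred <- which(adj[j, ])
    if (!length(pred)) next
    b <- solve(Rlv[pred, pred, drop = FALSE], Rlv[pred, j])
    pathm[j, pred] <- b
    r2[j] <- drop(crossprod(b, Rlv[pred, j]))
  }
  list(weights = W, scores = LV, loadings = loadings,
       communality = communality, path_matrix = pathm, r2 = r2,
       n_iterations = iter, converged = converged)
}

#' Fit a PLS path model
#'
#' Estimates latent variable scores and structural coefficients by the
#' iterative PLS-PM algorithm: indicators are standardized; outer weights
#' (initialised equal within block) define latent scores as standardized
#' weighted sums of their block; inner proxies are built from adjacent
#' latents under the chosen scheme; Mode A updates each weight vector as
#' the covariance of the block with its inner proxy; iteration stops when
#' the largest absolute weight change falls below `tol`. Loadings are
#' indicator-latent correlations, structural coefficients come from
#' ordinary least squares of each endogenous latent score on its
#' predecessors' scores, and GOF = sqrt(mean communality x mean R-squared).
#' Latent score signs are oriented so each block's summed loading is
#' non-negative.
#'
#' @param data data frame containing every indicator column; rows with
#'   missing indicator values are dropped (listwise deletion).
#' @param spec a [path_model_spec()].
#' @return An object of class `pls_fit`: `outer_weights`, `loadings`,
#'   `scores`, `path_matrix` (coefficient of column latent on row latent),
#'   `path_coefficients` (edge-wise data frame), `r2`, `communality`,
#'   `block_communality`, `gof`, `n`, `n_iterations`, `converged`, `spec`.
#' @export
fit_pls_pm <- function(data, spec) {
  stopifnot(inherits(spec, "path_model_spec"))
  inds <- unlist(spec$blocks, use.names = FALSE)
  missing_cols <- setdiff(inds, names(data))
  if (length(missing_cols))
    stop(sprintf("indicator(s) missing from data: %s",
                 paste(missing_cols, collapse = ", ")))
  X <- as.matrix(data[inds])
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) <= length(inds))
    stop("need more rows than indicators")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant indicator: %s",
                 paste(inds[sds == 0], collapse = ", ")))
  Xs <- scale(X)
  cs <- compile_spec(spec, colnames(Xs))
  core <- pls_core(Xs, cs)
  if (!core$converged)
    warning(sprintf("PLS-PM did not converge in %d iterations", cs$max_iter))
  finish_fit(core, cs, spec, nrow(Xs))
}

finish_fit <- function(core, cs, spec, n) {
  block_comm <- vapply(seq_along(spec$blocks), function(j)
    mean(core$communality[spec$blocks[[j]]]), 0)
  names(block_comm) <- spec$latent_names
  endo <- !is.na(core$r2)
  g <- sqrt(mean(core$communality) * mean(core$r2[endo]))
  edges <- which(spec$adj, arr.ind = TRUE)
  pc <- data.frame(from = spec$latent_names[edges[, "col"]],
                   to = spec$latent_names[edges[, "row"]],
                   coefficient = core$path_matrix[edges])
  pc <- pc[order(match(pc$from, spec$latent_names),
                 match(pc$to, spec$latent_names)), ]
  rownames(pc) <- NULL
  structure(list(outer_weights = core$weights, loadings = core$loadings,
                 scores = core$scores, path_matrix = core$path_matrix,
                 path_coefficients = pc, r2 = core$r2,
                 communality = core$communality,
                 block_communality = block_comm, gof = g, n = n,
                 n_iterations = core$n_iterations,
                 converged = core$converged, spec = spec),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d obs, %d latents, %s in %d iteration(s)\n",
              x$n, length(x$spec$latent_names),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  GOF %.4f (%s)\n", x$gof, gof_label(x$gof)))
  print(x$path_coefficients, digits = 3)
  invisible(x)
}

#' Goodness of fit of a PLS path model
#'
#' GOF = sqrt(mean indicator communality x mean R-squared over endogenous
#' latents), labelled weak / medium / strong at the 0.10 / 0.25 / 0.36
#' thresholds (boundaries closed upwards: a GOF of exactly 0.36 is
#' strong).
#'
#' @param fit a `pls_fit`.
#' @param include_single include single-indicator blocks (communality 1)
#'   in the communality mean (default `TRUE`).
#' @return A list with `gof` and `label`.
#' @export
gof <- function(fit, include_single = TRUE) {
  stopifnot(inherits(fit, "pls_fit"))
  comm <- fit$communality
  if (!include_single) {
    single <- names(which(lengths(fit$spec$blocks) == 1L))
    drop_ind <- unlist(fit$spec$blocks[single], use.names = FALSE)
    comm <- comm[setdiff(names(comm), drop_ind)]
  }
  endo <- !is.na(fit$r2)
  g <- sqrt(mean(comm) * mean(fit$r2[endo]))
  list(gof = g, label = gof_label(g))
}

#' @rdname gof
#' @param g numeric GOF value in \[0, 1\].
#' @export
gof_label <- function(g) {
  if (g >= 0.36) "strong" else if (g >= 0.25) "medium"
  else if (g >= 0.10) "weak" else "poor"
}
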