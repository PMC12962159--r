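#' Canonical driver names
#'
#' The eleven candidate drivers of the coupling coordination degree used
#' throughout: precipitation (PRE), temperature (TEM), evapotranspiration
#' (ET), elevation (ELE), slope (SLO), nighttime light (NL), population
#' density (PD), gross domestic product (GDP), net primary productivity
#' (NPP), fractional vegetation cover (FVC) and kernel NDVI (kNDVI).
#' @export
DRIVER_NAMES <- c("PRE", "TEM", "ET", "ELE", "SLO", "NL", "PD", "GDP",
                  "NPP", "FVC", "kNDVI")

#' Specification of a planted-change raster pair
#'
#' Describes a synthetic experiment: grid shape, epochs, a block layout
#' that tiles the grid with rectangles each planted with one quadrant
#' class, per-class signed trends for the human (HFI-like) and nature
#' (EQI-like) index, cell noise and a nodata fraction. The defaults emulate
#' an urbanising region over 2000-2020: HFI rising from about 36 to 46 on
#' the 0-100 scale while EQI declines from about 50 to 47, with spatially
#' clustered coordination / good-for-nature / degradation / conflict
#' blocks.
#'
#' @param shape integer `c(rows, cols)`, at least 2 x 2.
#' @param epochs strictly increasing numeric epoch labels, at least two.
#' @param block_layout data frame with columns `row0, row1, col0, col1`
#'   (1-based inclusive bounds), `class` (a [QUADRANT_CLASSES] name),
#'   `d_hfi`, `d_eqi` (signed total change over the full period, index
#'   units). `NULL` for the default quadrant layout built by
#'   [quadrant_block_layout()].
#' @param base_hfi,base_eqi baseline levels at the first epoch.
#' @param noise_sd non-negative iid cell/epoch noise SD (index units).
#' @param nodata_fraction fraction of cells masked (identically across
#'   epochs and both indices), in \[0, 1).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return An object of class `synthetic_raster_spec`.
#' @export
synthetic_raster_spec <- function(shape = c(60, 60),
                                  epochs = c(2000, 2010, 2020),
                                  block_layout = NULL,
                                  base_hfi = 35.72, base_eqi = 50.39,
                                  noise_sd = 1, nodata_fraction = 0.02,
                                  seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L))
    stop("degenerate shape: need at least 2 x 2 cells")
  if (length(epochs) < 2L || any(diff(epochs) <= 0))
    stop("need at least two strictly increasing epochs")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (nodata_fraction < 0 || nodata_fraction >= 1)
    stop("nodata_fraction must be in [0, 1)")
  if (is.null(block_layout))
    block_layout <- quadrant_block_layout(shape)
  validate_block_layout(block_layout, shape)
  structure(list(shape = shape, epochs = as.numeric(epochs),
                 block_layout = block_layout,
                 base_hfi = base_hfi, base_eqi = base_eqi,
                 noise_sd = noise_sd, nodata_fraction = nodata_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_raster_spec")
}

#' Default four-quadrant block layout
#'
#' Splits the grid into four equal rectangles, planted (clockwise from the
#' top-left) as coordination, good_for_nature, conflict and degradation.
#' Each block's total change is the regional mean trend plus a
#' class-consistent deviation, so the grid as a whole reproduces the
#' emulated 2000-2020 shifts (HFI rising by about +10.4 on the 0-100
#' scale while EQI declines by about -3.2) while every quadrant class is
#' still present with the correct change signs.
#'
#' @param shape integer `c(rows, cols)`.
#' @param mean_d_hfi,mean_d_eqi regional mean total changes (index units).
#' @param amp_hfi,amp_eqi block deviation amplitudes; must exceed the
#'   absolute mean trends so that both signs occur.
#' @return A block-layout data frame (see [synthetic_raster_spec()]).
#' @export
quadrant_block_layout <- function(shape, mean_d_hfi = 10.4,
                                  mean_d_eqi = -3.2,
                                  amp_hfi = 20, amp_eqi = 10) {
  if (amp_hfi <= abs(mean_d_hfi) || amp_eqi <= abs(mean_d_eqi))
    stop("deviation amplitudes must exceed the absolute mean trends")
  rs <- shape[1] %/% 2L; cs <- shape[2] %/% 2L
  data.frame(
    row0 = c(1L, 1L, rs + 1L, rs + 1L),
    row1 = c(rs, rs, shape[1], shape[1]),
    col0 = c(1L, cs + 1L, 1L, cs + 1L),
    col1 = c(cs, shape[2], cs, shape[2]),
    class = c("coordination", "good_for_nature", "conflict", "degradation"),
    d_hfi = mean_d_hfi + c(amp_hfi, -amp_hfi, amp_hfi, -amp_hfi),
    d_eqi = mean_d_eqi + c(amp_eqi, amp_eqi, -amp_eqi, -amp_eqi))
}

validate_block_layout <- function(layout, shape) {
  need <- c("row0", "row1", "col0", "col1", "class", "d_hfi", "d_eqi")
  if (!all(need %in% names(layout))) stop("block layout missing columns")
  if (!all(layout$class %in% names(QUADRANT_CLASSES)))
    stop("unknown quadrant class in block layout")
  cover <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(layout))) {
    b <- layout[i, ]
    if (b$row0 < 1 || b$col0 < 1 || b$row1 > shape[1] || b$col1 > shape[2] ||
        b$row0 > b$row1 || b$col0 > b$col1)
      stop("block outside the grid or inverted")
    cover[b$row0:b$row1, b$col0:b$col1] <-
      cover[b$row0:b$row1, b$col0:b$col1] + 1L
  }
  if (any(cover > 1L)) stop("blocks overlap")
  if (any(cover < 1L)) stop("blocks do not tile the grid")
  invisible(TRUE)
}

#' Planted class-label grid of a spec
#'
#' @param spec a `synthetic_raster_spec`.
#' @return Integer matrix of [QUADRANT_CLASSES] codes.
#' @export
planted_classes <- function(spec) {
  lab <- matrix(NA_integer_, spec$shape[1], spec$shape[2])
  for (i in seq_len(nrow(spec$block_layout))) {
    b <- spec$block_layout[i, ]
    lab[b$row0:b$row1, b$col0:b$col1] <- QUADRANT_CLASSES[[b$class]]
  }
  lab
}

#' Generate coupled HFI-like and EQI-like raster time series
#'
#' Builds two aligned multi-epoch stacks with the planted block trends:
#' each cell follows a linear trajectory from its baseline to baseline +
#' planted total change, with iid Gaussian noise per cell and epoch, values
#' clamped to the 0-100 index scale, and one common nodata mask drawn once
#' and applied to every epoch of both stacks. Bit-identical output for an
#' identical spec (the RNG state is restored afterwards).
#'
#' @param spec a [synthetic_raster_spec()].
#' @return A list with `hfi` and `eqi` (`aligned_stack`s), `classes` (the
#'   planted label matrix) and `spec`.
#' @export
generate_coupled_stacks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_raster_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  ne <- length(spec$epochs)
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)

  dh <- de <- matrix(0, nr, nc)
  for (i in seq_len(nrow(spec$block_layout))) {
    b <- spec$block_layout[i, ]
    dh[b$row0:b$row1, b$col0:b$col1] <- b$d_hfi
    de[b$row0:b$row1, b$col0:b$col1] <- b$d_eqi
  }
  mask <- matrix(FALSE, nr, nc)
  if (spec$nodata_fraction > 0) {
    n_bad <- floor(spec$nodata_fraction * nr * nc)
    mask[sample.int(nr * nc, n_bad)] <- TRUE
  }
  frac <- (spec$epochs - spec$epochs[1]) /
    (spec$epochs[ne] - spec$epochs[1])
  make_stack <- function(base, delta) {
    grids <- lapply(seq_len(ne), function(k) {
      v <- base + frac[k] * delta
      if (spec$noise_sd > 0)
        v <- v + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      v <- pmin(pmax(v, 0), 100)   # argument order keeps the dim attribute
      v[mask] <- NA_real_
      raster_grid(v, mask = mask, transform = c(0, nr, 1),
                  crs = "synthetic", epoch = spec$epochs[k])
    })
    aligned_stack(grids, spec$epochs)
  }
  hfi <- make_stack(spec$base_hfi, dh)
  eqi <- make_stack(spec$base_eqi, de)
  list(hfi = hfi, eqi = eqi, classes = planted_classes(spec), spec = spec)
}

# Seed the RNG locally; returns a restorer function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- latent path model generator -------------------------------------------

#' Specification of a latent path model generator
#'
#' A recursive (acyclic, lower-triangular) structural model over latent
#' variables with reflective indicator blocks, used to simulate driver
#' tables whose true standardized path coefficients and loadings are known.
#' By default noise terms are auto-calibrated so every latent and indicator
#' has unit population variance, making the planted `path_matrix` and
#' `loadings` themselves the standardized truth. Explicit noise SDs are
#' honoured; the implied standardized truth is then computed analytically
#' from the model's covariance recursion.
#'
#' @param latent_names ordered latent names; the order fixes the causal
#'   ordering (edges only from earlier to later).
#' @param path_matrix square strictly lower-triangular numeric matrix of
#'   structural coefficients, `path_matrix[j, i]` = effect of latent i on
#'   latent j.
#' @param blocks named list mapping each latent to its indicator names;
#'   every indicator belongs to exactly one block.
#' @param loadings named numeric vector, one loading in (0, 1\] per
#'   indicator.
#' @param structural_noise_sd `NULL` (auto: unit latent variance) or named
#'   vector per endogenous latent.
#' @param measurement_noise_sd `NULL` (auto: unit indicator variance) or
#'   named vector per indicator.
#' @param n sample size, at least 10 rows per indicator.
#' @param seed integer seed.
#' @return An object of class `latent_model_spec`.
#' @export
latent_model_spec <- function(latent_names, path_matrix, blocks, loadings,
                              structural_noise_sd = NULL,
                              measurement_noise_sd = NULL,
                              n = 1000L, seed = 1L) {
  p <- length(latent_names)
  path_matrix <- as.matrix(path_matrix)
  if (!identical(dim(path_matrix), c(p, p)))
    stop("path_matrix must be square over the latents")
  if (any(path_matrix[upper.tri(path_matrix, diag = TRUE)] != 0))
    stop("path_matrix must be strictly lower-triangular (acyclic ordering)")
  dimnames(path_matrix) <- list(latent_names, latent_names)
  if (!setequal(names(blocks), latent_names))
    stop("blocks must be named by the latents")
  inds <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(inds))
    stop("every indicator must belong to exactly one block")
  if (!setequal(names(loadings), inds))
    stop("one loading per indicator required")
  if (any(loadings <= 0 | loadings > 1))
    stop("loadings must lie in (0, 1]")
  if (n < 10L * length(inds))
    stop("n must be at least 10 rows per indicator")
  structure(list(latent_names = latent_names, path_matrix = path_matrix,
                 blocks = blocks[latent_names], loadings = loadings,
                 structural_noise_sd = structural_noise_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "latent_model_spec")
}

# Population covariance of the latents under the recursion
# eta_j = sum_i B[j,i] eta_i + zeta_j, Var(zeta_j) = s2[j].
latent_covariance <- function(B, s2) {
  p <- nrow(B)
  S <- matrix(0, p, p, dimnames = dimnames(B))
  for (j in 1:p) {
    b <- B[j, seq_len(j - 1L), drop = TRUE]
    if (j > 1L) {
      Sp <- S[seq_len(j - 1L), seq_len(j - 1L), drop = FALSE]
      S[j, j] <- drop(t(b) %*% Sp %*% b) + s2[j]
      cov_j <- drop(Sp %*% b)
      S[j, seq_len(j - 1L)] <- cov_j
      S[seq_len(j - 1L), j] <- cov_j
    } else S[j, j] <- s2[j]
  }
  S
}

# Analytic population quantities of a latent_model_spec: structural noise
# variances, latent covariance/correlation, standardized paths/loadings and
# per-indicator measurement noise SDs.
latent_truth <- function(spec) {
  p <- length(spec$latent_names)
  B <- spec$path_matrix
  explained <- function(j, S) {
    b <- B[j, seq_len(j - 1L)]
    if (j == 1L) 0
    else drop(t(b) %*% S[seq_len(j - 1L), seq_len(j - 1L)] %*% b)
  }
  s2 <- numeric(p); names(s2) <- spec$latent_names
  S <- matrix(0, p, p)
  if (is.null(spec$structural_noise_sd)) {
    for (j in 1:p) {
      ex <- explained(j, S)
      if (ex >= 1) stop("planted paths imply explained variance >= 1; infeasible")
      s2[j] <- 1 - ex
      S <- latent_covariance(B, s2)
    }
  } else {
    sds <- spec$structural_noise_sd
    for (j in 1:p) {
      nm <- spec$latent_names[j]
      s2[j] <- if (nm %in% names(sds)) sds[[nm]]^2 else 1
    }
    S <- latent_covariance(B, s2)
  }
  sd_lat <- sqrt(diag(S))
  B_std <- B * outer(1 / sd_lat, sd_lat)
  R_lat <- S / outer(sd_lat, sd_lat)
  dimnames(R_lat) <- dimnames(B)
  inds <- unlist(spec$blocks, use.names = FALSE)
  lam <- spec$loadings[inds]
  m_sd <- vapply(seq_along(inds), function(k) {
    if (is.null(spec$measurement_noise_sd)) sqrt(1 - lam[k]^2)
    else if (inds[k] %in% names(spec$measurement_noise_sd))
      spec$measurement_noise_sd[[inds[k]]]
    else 0
  }, 0)
  lam_std <- stats::setNames(lam / sqrt(lam^2 + m_sd^2), inds)
  list(s2 = s2, S = S, sd_lat = sd_lat, B_std = B_std, R_lat = R_lat,
       indicators = inds, lam = lam, m_sd = m_sd, lam_std = lam_std,
       owner = rep(names(spec$blocks), lengths(spec$blocks)))
}

#' Simulate an indicator table from a latent path model
#'
#' Latents are drawn recursively along the structural matrix; indicators
#' are `loading x latent + measurement noise`. Exported data are
#' standardized (sample mean 0, SD 1) per column; the true standardized
#' path coefficients and loadings are returned alongside for recovery
#' tests.
#'
#' @param spec a [latent_model_spec()].
#' @return A list with `data` (data frame, n rows, standardized indicator
#'   columns), `latents` (matrix of true latent scores), and `truth` (list
#'   with standardized `path_matrix`, `loadings`, and the latent
#'   correlation matrix).
#' @export
generate_sem_table <- function(spec) {
  stopifnot(inherits(spec, "latent_model_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)
  p <- length(spec$latent_names)
  B <- spec$path_matrix
  n <- spec$n
  tr <- latent_truth(spec)

  # draw latents recursively, then standardize by their population SDs
  L <- matrix(0, n, p, dimnames = list(NULL, spec$latent_names))
  for (j in 1:p) {
    mu <- if (j > 1L) L[, seq_len(j - 1L), drop = FALSE] %*% B[j, seq_len(j - 1L)]
          else rep(0, n)
    L[, j] <- mu + stats::rnorm(n, 0, sqrt(tr$s2[j]))
  }
  Lstd <- sweep(L, 2, tr$sd_lat, "/")

  X <- matrix(0, n, length(tr$indicators),
              dimnames = list(NULL, tr$indicators))
  for (k in seq_along(tr$indicators))
    X[, k] <- tr$lam[k] * Lstd[, tr$owner[k]] +
      stats::rnorm(n, 0, tr$m_sd[k])
  X <- scale(X)                      # sample standardization for export
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  list(data = as.data.frame(X), latents = Lstd,
       truth = list(path_matrix = tr$B_std, loadings = tr$lam_std,
                    latent_correlation = tr$R_lat))
}

#' Default latent driver model for the CCD
#'
#' The five-latent model in causal order Ter, Hum, Clm, Veg, CCD with the
#' canonical driver blocks (Ter = ELE, SLO; Hum = NL, PD, GDP; Clm = PRE,
#' TEM, ET; Veg = NPP, FVC, kNDVI; CCD single-indicator) and all nine
#' structural edges of the standard hypotheses.
#'
#' @param path_values named numeric vector of structural coefficients
#'   keyed `"from->to"` (e.g. `c("Veg->CCD" = 0.6)`); unnamed edges are 0.
#' @param loadings single value or named vector of indicator loadings
#'   (default 0.9; the CCD indicator always loads 1).
#' @param n,seed passed to [latent_model_spec()].
#' @return A `latent_model_spec`.
#' @export
default_latent_model <- function(path_values = c("Ter->Hum" = -0.4,
                                                 "Ter->Veg" = 0.4,
                                                 "Ter->CCD" = -0.3,
                                                 "Hum->Clm" = 0.4,
                                                 "Hum->Veg" = -0.25,
                                                 "Hum->CCD" = 0.5,
                                                 "Clm->Veg" = 0.25,
                                                 "Clm->CCD" = 0.3,
                                                 "Veg->CCD" = 0.6),
                                 loadings = 0.9, n = 2000L, seed = 1L) {
  lat <- c("Ter", "Hum", "Clm", "Veg", "CCD")
  blocks <- list(Ter = c("ELE", "SLO"), Hum = c("NL", "PD", "GDP"),
                 Clm = c("PRE", "TEM", "ET"), Veg = c("NPP", "FVC", "kNDVI"),
                 CCD = "CCD")
  B <- matrix(0, 5, 5, dimnames = list(lat, lat))
  for (nm in names(path_values)) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (length(ft) != 2L || !all(ft %in% lat)) stop("bad path key: ", nm)
    B[ft[2], ft[1]] <- path_values[[nm]]
  }
  inds <- unlist(blocks, use.names = FALSE)
  lo <- if (length(loadings) == 1L && is.null(names(loadings)))
    stats::setNames(rep(loadings, length(inds)), inds) else loadings
  lo["CCD"] <- 1
  latent_model_spec(lat, B, blocks, lo, n = n, seed = seed)
}

#' Generate a complete synthetic analysis bundle
#'
#' Builds every input of the end-to-end pipeline with known ground truth:
#' coupled HFI/EQI stacks with planted quadrant blocks, and driver rasters
#' simulated from a latent path model *conditionally on the realised CCD
#' raster*, stratified by the quadrant region. Within each region the CCD
#' values are converted to normal scores, the four upstream latents are
#' drawn from their exact conditional Gaussian distribution given the CCD
#' latent, and indicators are built with the standardized loadings -- so
#' inside every region the joint driver/CCD distribution follows the
#' planted standardized model, and region-stratified path modeling has an
#' exact target.
#'
#' @param raster_spec a [synthetic_raster_spec()].
#' @param latent_spec a [latent_model_spec()] whose last latent is the
#'   single-indicator CCD block (default [default_latent_model()]); its
#'   `n` is ignored (one row per cell).
#' @param sigma_fraction,rule quadrant settings used to form the region
#'   strata (must match the pipeline settings).
#' @param params [ccd_params()] used to realise the CCD raster.
#' @return A list with `hfi`, `eqi` (stacks), `drivers` (named raster
#'   list), `ccd_grid`, `quadrant_map`, `classes` (planted labels), and
#'   `truth` (standardized paths, loadings, latent correlation).
#' @export
generate_analysis_bundle <- function(raster_spec,
                                     latent_spec = default_latent_model(),
                                     sigma_fraction = 0.1, rule = "or",
                                     params = ccd_params()) {
  stopifnot(inherits(latent_spec, "latent_model_spec"))
  q <- length(latent_spec$latent_names)
  ccd_name <- latent_spec$latent_names[q]
  if (length(latent_spec$blocks[[ccd_name]]) != 1L)
    stop("the last latent must be the single-indicator CCD block")
  stacks <- generate_coupled_stacks(raster_spec)
  epochs <- stacks$hfi$epochs
  chg <- period_change(stacks$hfi, stacks$eqi, epochs[1], epochs[length(epochs)])
  qmap <- classify_quadrant(chg, sigma_fraction = sigma_fraction, rule = rule)
  hfi01 <- minmax_normalize(stacks$hfi, 0, 1, domain = "pooled")
  eqi01 <- minmax_normalize(stacks$eqi, 0, 1, domain = "pooled")
  k <- length(epochs)
  ccd_grid <- ccd_pipeline(hfi01$grids[[k]], eqi01$grids[[k]], params)$CCD

  tr <- latent_truth(latent_spec)
  R <- tr$R_lat
  syc <- R[seq_len(q - 1L), q]
  Syy <- R[seq_len(q - 1L), seq_len(q - 1L)] - tcrossprod(syc)
  Lc <- chol(Syy)
  drv_ind <- tr$indicators[tr$owner != ccd_name]

  rng <- local_rng(raster_spec$seed + 1L)
  on.exit(rng(), add = TRUE)
  shape <- raster_spec$shape
  vals <- lapply(drv_ind, function(i) matrix(NA_real_, shape[1], shape[2]))
  names(vals) <- drv_ind
  cells_ok <- !qmap$mask & !is.na(qmap$values)
  for (code in unique(qmap$values[cells_ok])) {
    sel <- which(cells_ok & qmap$values == code)
    m <- length(sel)
    if (m < 3L) next
    z <- stats::qnorm((rank(ccd_grid$values[sel],
                            ties.method = "average") - 0.5) / m)
    eps <- matrix(stats::rnorm(m * (q - 1L)), m, q - 1L) %*% Lc
    Lat <- outer(z, syc) + eps            # conditional latents given CCD
    colnames(Lat) <- latent_spec$latent_names[seq_len(q - 1L)]
    for (ki in seq_along(drv_ind)) {
      nm <- drv_ind[ki]
      lam <- tr$lam_std[nm]
      own <- tr$owner[match(nm, tr$indicators)]
      vals[[nm]][sel] <- lam * Lat[, own] +
        stats::rnorm(m, 0, sqrt(1 - lam^2))
    }
  }
  drivers <- lapply(vals, function(v) {
    v[qmap$mask] <- NA_real_
    raster_grid(v, mask = is.na(v), transform = qmap$transform,
                crs = "synthetic")
  })
  list(hfi = stacks$hfi, eqi = stacks$eqi, drivers = drivers,
       ccd_grid = ccd_grid, quadrant_map = qmap, classes = stacks$classes,
       truth = list(path_matrix = tr$B_std, loadings = tr$lam_std,
                    latent_correlation = tr$R_lat))
}

#' Generate correlated driver raster layers
#'
#' Draws standard-normal driver layers with a requested pairwise
#' correlation structure via a Gaussian copula (eigen square root of the
#' target correlation matrix). Deterministic for a seed.
#'
#' @param shape integer `c(rows, cols)`.
#' @param collinearity_pairs data frame with columns `a`, `b` (driver
#'   names) and `r` (target correlation in (-1, 1)); `NULL` for mutually
#'   independent drivers.
#' @param seed integer seed.
#' @param names driver layer names (default [DRIVER_NAMES]).
#' @return Named list of `raster_grid` layers.
#' @export
generate_driver_rasters <- function(shape, collinearity_pairs = NULL,
                                    seed = 1L, names = DRIVER_NAMES) {
  p <- length(names)
  R <- diag(p); dimnames(R) <- list(names, names)
  if (!is.null(collinearity_pairs)) {
    for (i in seq_len(nrow(collinearity_pairs))) {
      pr <- collinearity_pairs[i, ]
      if (abs(pr$r) >= 1) stop("requested correlations must lie in (-1, 1)")
      R[pr$a, pr$b] <- R[pr$b, pr$a] <- pr$r
    }
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("requested correlation matrix is not positive semi-definite")
  sq <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- prod(shape)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% sq
  out <- lapply(seq_len(p), function(k)
    raster_grid(matrix(Z[, k], shape[1], shape[2]),
                transform = c(0, shape[1], 1), crs = "synthetic"))
  stats::setNames(out, names)
}
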