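#' Bare-soil and full-vegetation EVI reference values
#'
#' Percentile proxies for the enhanced vegetation index of bare soil and of
#' fully vegetated cover, taken over the unmasked cells of an EVI layer.
#' The 5th and 95th percentiles are the defaults; percentiles use the
#' linear-interpolation definition (type 7).
#'
#' @param evi a `raster_grid` of EVI values.
#' @param p_soil,p_veg percentiles in \[0, 100\], `p_soil < p_veg`.
#' @return Named numeric vector `c(evi_soil, evi_veg)`.
#' @export
evi_proxies <- function(evi, p_soil = 5, p_veg = 95) {
  stopifnot(inherits(evi, "raster_grid"), p_soil < p_veg)
  v <- grid_values(evi)
  if (length(v) < 2L) stop("need at least two unmasked cells")
  q <- stats::quantile(v, c(p_soil, p_veg) / 100, names = FALSE, type = 7)
  if (q[1] >= q[2])
    stop("degenerate EVI layer: soil and vegetation percentiles coincide")
  c(evi_soil = q[1], evi_veg = q[2])
}

#' Fractional vegetation cover from EVI
#'
#' FVC = (EVI - EVI_soil) / (EVI_veg - EVI_soil), clamped to \[0, 1\], so
#' cells at or below the bare-soil reference get 0 and cells at or above
#' the full-vegetation reference get 1.
#'
#' @param evi a `raster_grid` of EVI values.
#' @param evi_soil,evi_veg reference EVI values, `evi_soil < evi_veg`
#'   (typically from [evi_proxies()]).
#' @return A `raster_grid` of FVC in \[0, 1\].
#' @export
compute_fvc <- function(evi, evi_soil, evi_veg) {
  if (evi_soil >= evi_veg) stop("`evi_soil` must be below `evi_veg`")
  grid_map(evi, function(v)
    pmin(pmax((v - evi_soil) / (evi_veg - evi_soil), 0), 1))
}

#' Ecosystem quality index
#'
#' EQI = 100 * (LAI + GPP + FVC) / 3, the equally weighted mean of three
#' vegetation indicators each pre-normalised to \[0, 1\], scaled to the
#' 0-100 range. The output mask is the union of the input masks.
#'
#' @param lai,gpp,fvc aligned `raster_grid` layers with values in \[0, 1\].
#' @return A `raster_grid` of EQI in \[0, 100\].
#' @export
compute_eqi <- function(lai, gpp, fvc) {
  assert_aligned(lai, gpp, fvc)
  for (g in list(lai, gpp, fvc)) {
    v <- grid_values(g)
    if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
      stop("EQI inputs must be normalised to [0, 1]")
  }
  m <- union_mask(lai, gpp, fvc)
  v <- 100 * (lai$values + gpp$values + fvc$values) / 3
  v[m] <- NA_real_
  raster_grid(v, mask = m, transform = lai$transform, crs = lai$crs,
              epoch = lai$epoch)
}

#' Min-max normalisation of vectors, grids and stacks
#'
#' Affine map of the observed \[min, max\] onto `[target_lo, target_hi]`.
#' For an `aligned_stack` the domain is either `"pooled"` (one min-max over
#' all epochs, preserving cross-epoch comparability -- the default used
#' when index levels are compared across years) or `"per-epoch"`.
#'
#' @param x numeric vector, `raster_grid`, or `aligned_stack`.
#' @param target_lo,target_hi target range (defaults 0 and 1).
#' @param domain `"pooled"` or `"per-epoch"` (stacks only).
#' @return Object of the same type, rescaled.
#' @export
minmax_normalize <- function(x, target_lo = 0, target_hi = 1,
                             domain = c("pooled", "per-epoch")) {
  domain <- match.arg(domain)
  stopifnot(target_lo < target_hi)
  rescale <- function(v, lo, hi) {
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
      stop("degenerate layer: constant over the normalisation domain")
    target_lo + (v - lo) * (target_hi - target_lo) / (hi - lo)
  }
  if (is.numeric(x)) {
    return(rescale(x, min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  }
  if (inherits(x, "raster_grid")) {
    v <- grid_values(x)
    if (length(v) < 2L) stop("need at least two unmasked cells")
    return(grid_map(x, function(m) rescale(m, min(v), max(v))))
  }
  if (inherits(x, "aligned_stack")) {
    if (domain == "per-epoch") {
      grids <- lapply(x$grids, minmax_normalize,
                      target_lo = target_lo, target_hi = target_hi)
    } else {
      all_v <- unlist(lapply(x$grids, grid_values))
      lo <- min(all_v); hi <- max(all_v)
      grids <- lapply(x$grids, grid_map, f = function(m) rescale(m, lo, hi))
    }
    return(aligned_stack(grids, x$epochs))
  }
  stop("unsupported input type")
}

#' Fisher-Jenks natural breaks
#'
#' Optimal contiguous partition of a 1-D sample into `k` classes minimising
#' the total within-class sum of squared deviations, by dynamic programming
#' over the sorted values (exact, not the heuristic "jenks" refinement).
#' Returns the k-1 interior break values, taken as the maximum of each
#' lower class; classification assigns `value <= break` to the lower class.
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes, `1 <= k <= ` number of distinct values.
#' @return Numeric vector of k-1 interior breaks (empty for k = 1).
#' @export
jenks_breaks <- function(values, k) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (k < 1L) stop("k must be >= 1")
  if (length(unique(x)) < k)
    stop("k exceeds the number of distinct values")
  if (k == 1L) return(numeric(0))
  # prefix sums for O(1) within-class SSE of x[i..j]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {                 # 1-based inclusive
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  # D[m, j]: minimal cost of splitting x[1..j] into m classes
  D <- matrix(Inf, nrow = k, ncol = n)
  B <- matrix(0L, nrow = k, ncol = n)     # index of last class start
  for (j in 1:n) { D[1, j] <- sse(1L, j); B[1, j] <- 1L }
  cs0 <- c(0, cs); cs20 <- c(0, cs2)      # shifted prefixes for vector form
  for (m in 2:k) {
    for (j in m:n) {
      s <- m:j                            # candidate starts of class m
      sse_sj <- (cs2[j] - cs20[s]) - (cs[j] - cs0[s])^2 / (j - s + 1L)
      cost <- D[m - 1L, s - 1L] + sse_sj
      arg <- which.min(cost)
      D[m, j] <- cost[arg]; B[m, j] <- s[arg]
    }
  }
  # backtrack class boundaries
  breaks <- numeric(k - 1L)
  j <- n
  for (m in k:2) {
    s <- B[m, j]
    breaks[m - 1L] <- x[s - 1L]           # max of the class below
    j <- s - 1L
  }
  breaks
}

#' Classify a grid or stack into natural-breaks categories
#'
#' Computes Fisher-Jenks breaks on the (optionally subsampled) pooled
#' unmasked values and maps every cell to its class, so that class ranges
#' are identical across epochs. Values at a break go to the lower class.
#'
#' @param x a `raster_grid` or `aligned_stack`.
#' @param k number of classes (default 5).
#' @param sample_max cap on the number of values used to locate the breaks
#'   (deterministic thinning of the sorted pool, which preserves the
#'   quantile structure the optimal partition depends on); `Inf` to use
#'   all values.
#' @return A list with `breaks` (k-1 interior breaks) and `classes`
#'   (a `raster_grid` of integer codes 1..k, or a list of them per epoch).
#' @export
classify_natural_breaks <- function(x, k = 5, sample_max = 2000) {
  grids <- if (inherits(x, "aligned_stack")) x$grids else list(x)
  pool <- sort(unlist(lapply(grids, grid_values)))
  if (length(pool) > sample_max) {
    idx <- unique(round(seq(1, length(pool), length.out = sample_max)))
    pool <- pool[idx]
  }
  brks <- jenks_breaks(pool, k)
  cut_codes <- function(g) {
    v <- g$values
    # left.open: a value equal to a break joins the lower class
    code <- findInterval(v, brks, left.open = TRUE) + 1L
    cm <- matrix(as.numeric(code), nrow = nrow(v))
    cm[g$mask] <- NA_real_
    raster_grid(cm, mask = g$mask, transform = g$transform, crs = g$crs,
                epoch = g$epoch)
  }
  classes <- lapply(grids, cut_codes)
  if (inherits(x, "raster_grid")) classes <- classes[[1]]
  list(breaks = brks, classes = classes)
}
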