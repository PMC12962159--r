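#' CCD level labels and bounds
#'
#' Five coordination levels on the CCD scale: \[0,0.2) severely disordered,
#' \[0.2,0.4) nearly disordered, \[0.4,0.6) primarily coordinated,
#' \[0.6,0.8) moderately coordinated, \[0.8,1\] highly coordinated.
#' Intervals are half-open with the top interval closed, so every CCD value
#' maps to exactly one level.
#' @export
CCD_LEVELS <- data.frame(
  level = c("severely_disordered", "nearly_disordered",
            "primarily_coordinated", "moderately_coordinated",
            "highly_coordinated"),
  lo = c(0, 0.2, 0.4, 0.6, 0.8),
  hi = c(0.2, 0.4, 0.6, 0.8, 1))

#' Coupling coordination parameters
#'
#' Subsystem weights `a` (human) and `b` (nature) with `a + b = 1`, both
#' 0.5 by default (the two systems treated as equally important), and the
#' formula variant: `"canonical"` uses C = 2*sqrt(HFI*EQI)/(HFI+EQI) and
#' CCD = sqrt(C*T), the standard coupling-coordination form in which
#' balanced subsystems give C = 1; `"literal"` uses C = 2*HFI*EQI/(HFI+EQI)
#' and CCD = C*T, retained for sensitivity checks.
#'
#' @param a,b non-negative weights summing to 1.
#' @param variant `"canonical"` (default) or `"literal"`.
#' @return An object of class `ccd_params`.
#' @export
ccd_params <- function(a = 0.5, b = 0.5, variant = c("canonical", "literal")) {
  variant <- match.arg(variant)
  if (a < 0 || b < 0 || abs(a + b - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  structure(list(a = a, b = b, variant = variant), class = "ccd_params")
}

as_values <- function(x) if (inherits(x, "raster_grid")) x$values else x

rewrap <- function(template, v) {
  if (!inherits(template, "raster_grid")) return(v)
  v[template$mask] <- NA_real_
  raster_grid(v, mask = template$mask, transform = template$transform,
              crs = template$crs, epoch = template$epoch)
}

check_unit <- function(x, what) {
  v <- as_values(x)
  v <- v[!is.na(v)]
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    stop(sprintf("%s must lie in [0, 1]; rescale with minmax_normalize()", what))
}

#' Coupling degree between two unit-scaled subsystems
#'
#' Canonical form C = 2*sqrt(HFI*EQI)/(HFI+EQI): 1 when the two levels are
#' equal (and positive), falling towards 0 as they diverge, and 0 when
#' either level is 0. Where both levels are 0 the 0/0 form is defined as
#' C = 0 (no coupling without activity or quality). The literal variant
#' C = 2*HFI*EQI/(HFI+EQI) (the harmonic mean) is also available.
#'
#' @param hfi01,eqi01 aligned `raster_grid`s or numeric arrays in \[0, 1\].
#' @param variant `"canonical"` (default) or `"literal"`.
#' @return Same type as the inputs, C in \[0, 1\].
#' @export
coupling_degree <- function(hfi01, eqi01, variant = c("canonical", "literal")) {
  variant <- match.arg(variant)
  if (inherits(hfi01, "raster_grid")) assert_aligned(hfi01, eqi01)
  check_unit(hfi01, "HFI"); check_unit(eqi01, "EQI")
  h <- as_values(hfi01); e <- as_values(eqi01)
  s <- h + e
  num <- if (variant == "canonical") 2 * sqrt(h * e) else 2 * h * e
  C <- ifelse(s > 0, num / s, 0)
  C <- pmin(pmax(C, 0), 1)   # argument order keeps the dim attribute
  rewrap(hfi01, C)
}

#' Comprehensive development index
#'
#' T = a*HFI + b*EQI, the weighted mean of the two unit-scaled subsystem
#' levels.
#'
#' @inheritParams coupling_degree
#' @param params a [ccd_params()] object.
#' @return Same type as the inputs, T in \[0, 1\].
#' @export
comprehensive_index <- function(hfi01, eqi01, params = ccd_params()) {
  stopifnot(inherits(params, "ccd_params"))
  if (params$a < 0 || params$b < 0 || abs(params$a + params$b - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  if (inherits(hfi01, "raster_grid")) assert_aligned(hfi01, eqi01)
  check_unit(hfi01, "HFI"); check_unit(eqi01, "EQI")
  rewrap(hfi01, params$a * as_values(hfi01) + params$b * as_values(eqi01))
}

#' Coupling coordination degree
#'
#' CCD = sqrt(C * T) (canonical) or C * T (literal): the geometric
#' combination of how balanced the two subsystems are (C) and their joint
#' level (T). Monotone non-decreasing in both arguments.
#'
#' @param C,T_ coupling degree and comprehensive index, in \[0, 1\].
#' @param variant `"canonical"` (default) or `"literal"`.
#' @return Same type as the inputs, CCD in \[0, 1\].
#' @export
ccd <- function(C, T_, variant = c("canonical", "literal")) {
  variant <- match.arg(variant)
  if (inherits(C, "raster_grid")) assert_aligned(C, T_)
  check_unit(C, "C"); check_unit(T_, "T")
  p <- as_values(C) * as_values(T_)
  rewrap(C, if (variant == "canonical") sqrt(p) else p)
}

#' Full CCD computation from unit-scaled HFI and EQI
#'
#' Convenience wrapper chaining [coupling_degree()],
#' [comprehensive_index()] and [ccd()].
#'
#' @inheritParams comprehensive_index
#' @return A list with `C`, `T`, `CCD` (same type as the inputs) and
#'   `params`.
#' @export
ccd_pipeline <- function(hfi01, eqi01, params = ccd_params()) {
  C <- coupling_degree(hfi01, eqi01, variant = params$variant)
  T_ <- comprehensive_index(hfi01, eqi01, params)
  list(C = C, T = T_, CCD = ccd(C, T_, variant = params$variant),
       params = params)
}

#' Classify CCD into the five coordination levels
#'
#' @param x a `raster_grid` or numeric vector of CCD values in \[0, 1\].
#' @return A list with `level` (integer codes 1..5, same container as the
#'   input; labels in [CCD_LEVELS]) and `proportions` (data frame of class
#'   shares in percent over unmasked values).
#' @export
classify_ccd <- function(x) {
  check_unit(x, "CCD")
  v <- as_values(x)
  # half-open [lo, hi); top closed: 1 falls in the last class
  code <- findInterval(v, CCD_LEVELS$lo, left.open = FALSE)
  code[!is.na(v) & v >= 1] <- nrow(CCD_LEVELS)
  vals <- code[!is.na(code)]
  counts <- vapply(seq_len(nrow(CCD_LEVELS)),
                   function(k) sum(vals == k), integer(1))
  props <- data.frame(level = CCD_LEVELS$level,
                      count = as.integer(counts),
                      percent = 100 * counts / max(1L, sum(counts)))
  lvl <- if (inherits(x, "raster_grid")) {
    cm <- matrix(as.numeric(code), nrow = nrow(v))
    rewrap(x, cm)
  } else code
  list(level = lvl, proportions = props)
}
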