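#' Quadrant class codes
#'
#' Integer coding shared by the quadrant classifier and its outputs:
#' 1 coordination (+,+), 2 good_for_nature (-,+), 3 degradation (-,-),
#' 4 conflict (+,-), 5 insignificant.
#' @export
QUADRANT_CLASSES <- c(coordination = 1L, good_for_nature = 2L,
                      degradation = 3L, conflict = 4L, insignificant = 5L)

#' Paired index change between two epochs
#'
#' Cellwise differences HFI(t1) - HFI(t0) and EQI(t1) - EQI(t0), together
#' with the standard deviations of the unmasked change values -- the
#' reference scale for the significance rule of the four-quadrant model.
#'
#' @param hfi,eqi `aligned_stack` objects containing both epochs.
#' @param t0,t1 epoch labels, `t0` before `t1`.
#' @return An object of class `period_change` with elements `d_hfi`,
#'   `d_eqi` (raster grids), `sigma_d_hfi`, `sigma_d_eqi`, `t0`, `t1`.
#' @export
period_change <- function(hfi, eqi, t0, t1) {
  h0 <- stack_epoch(hfi, t0); h1 <- stack_epoch(hfi, t1)
  e0 <- stack_epoch(eqi, t0); e1 <- stack_epoch(eqi, t1)
  assert_aligned(h0, e0)
  diff_grid <- function(a, b) {
    m <- union_mask(a, b)
    v <- b$values - a$values
    v[m] <- NA_real_
    raster_grid(v, mask = m, transform = a$transform, crs = a$crs,
                epoch = sprintf("%s-%s", t0, t1))
  }
  dh <- diff_grid(h0, h1)
  de <- diff_grid(e0, e1)
  pop_sd <- function(g) {
    v <- grid_values(g)
    if (length(v) < 2L) return(0)
    stats::sd(v)
  }
  structure(list(d_hfi = dh, d_eqi = de,
                 sigma_d_hfi = pop_sd(dh), sigma_d_eqi = pop_sd(de),
                 t0 = t0, t1 = t1),
            class = "period_change")
}

#' Four-quadrant classification with a significance rule
#'
#' Classifies each cell's paired change into coordination (+,+),
#' good_for_nature (-,+), degradation (-,-) or conflict (+,-). Changes
#' smaller in magnitude than `sigma_fraction` times the standard deviation
#' of the respective change raster are treated as no-change; under the
#' default `"or"` rule a cell must change significantly on *both* axes to
#' receive a quadrant, otherwise it is insignificant (under `"and"`, only
#' cells insignificant on both axes are). A change exactly equal to the
#' threshold counts as significant.
#'
#' @param change a `period_change`.
#' @param sigma_fraction positive multiplier of the change-SD (default 0.1).
#' @param rule `"or"` (default) or `"and"` -- how per-axis insignificance
#'   combines into cell insignificance.
#' @return A `raster_grid` of codes per [QUADRANT_CLASSES], with attribute
#'   `"classes"`.
#' @export
classify_quadrant <- function(change, sigma_fraction = 0.1,
                              rule = c("or", "and")) {
  stopifnot(inherits(change, "period_change"), sigma_fraction > 0)
  rule <- match.arg(rule)
  dh <- change$d_hfi$values
  de <- change$d_eqi$values
  thr_h <- sigma_fraction * change$sigma_d_hfi
  thr_e <- sigma_fraction * change$sigma_d_eqi
  insig_h <- abs(dh) < thr_h
  insig_e <- abs(de) < thr_e
  insig <- if (rule == "or") insig_h | insig_e else insig_h & insig_e
  code <- matrix(NA_real_, nrow = nrow(dh), ncol = ncol(dh))
  code[dh >= 0 & de >= 0] <- QUADRANT_CLASSES[["coordination"]]
  code[dh < 0 & de >= 0] <- QUADRANT_CLASSES[["good_for_nature"]]
  code[dh < 0 & de < 0] <- QUADRANT_CLASSES[["degradation"]]
  code[dh >= 0 & de < 0] <- QUADRANT_CLASSES[["conflict"]]
  code[insig] <- QUADRANT_CLASSES[["insignificant"]]
  m <- union_mask(change$d_hfi, change$d_eqi)
  code[m] <- NA_real_
  out <- raster_grid(code, mask = m, transform = change$d_hfi$transform,
                     crs = change$d_hfi$crs, epoch = change$d_hfi$epoch)
  attr(out, "classes") <- QUADRANT_CLASSES
  attr(out, "sigma_fraction") <- sigma_fraction
  out
}

#' Area shares of quadrant classes
#'
#' Percentage of unmasked cells per quadrant class, optionally restricted
#' to a region mask. Every class is reported (zero share when absent);
#' percentages sum to 100.
#'
#' @param map a quadrant map from [classify_quadrant()].
#' @param region_mask optional logical matrix, `TRUE` = cell included.
#' @return Data frame with columns `class`, `count`, `percent`.
#' @export
area_proportions <- function(map, region_mask = NULL) {
  stopifnot(inherits(map, "raster_grid"))
  keep <- !map$mask
  if (!is.null(region_mask)) {
    stopifnot(identical(dim(region_mask), dim(map$values)))
    keep <- keep & region_mask
  }
  if (!any(keep)) stop("no unmasked cells in the requested region")
  codes <- map$values[keep]
  counts <- vapply(QUADRANT_CLASSES,
                   function(k) sum(codes == k), integer(1))
  data.frame(class = names(QUADRANT_CLASSES),
             count = as.integer(counts),
             percent = 100 * counts / sum(counts),
             row.names = NULL)
}
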