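#' Construct a raster grid
#'
#' The basic spatial container of the package: one single-band, north-up,
#' row-major 2-D layer with a nodata mask and a minimal affine transform
#' (origin and square cell size). All spatial inputs and outputs of the
#' analysis -- human footprint index (HFI), vegetation indicators, the
#' ecosystem quality index (EQI), driver layers, categorical maps -- travel
#' as `raster_grid` objects.
#'
#' Masked cells are stored as `NA` in `values`; `mask` is `TRUE` where a
#' cell carries no data. Unmasked cells must be finite.
#'
#' @param values numeric matrix (rows = north to south).
#' @param mask logical matrix of the same shape, `TRUE` = nodata. Defaults
#'   to `is.na(values)`.
#' @param transform numeric length-3 vector `c(origin_x, origin_y,
#'   cell_size)`: coordinates of the upper-left corner and the (square)
#'   cell size.
#' @param crs character identifier of the coordinate reference system
#'   (free-form; the package never reprojects).
#' @param epoch optional label (e.g. a year) identifying the time slice.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, mask = NULL,
                        transform = c(0, nrow(values), 1),
                        crs = "local", epoch = NA) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  if (!is.logical(mask)) stop("`mask` must be logical")
  if (!identical(dim(mask), dim(values)))
    stop("mask shape must equal values shape")
  values[mask] <- NA_real_
  if (any(!is.finite(values[!mask])))
    stop("unmasked cells must be finite")
  if (length(transform) != 3L || transform[3] <= 0)
    stop("`transform` must be c(origin_x, origin_y, cell_size) with cell_size > 0")
  structure(list(values = values, mask = mask,
                 transform = as.numeric(transform),
                 crs = as.character(crs), epoch = epoch),
            class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- grid_values(x)
  cat(sprintf("<raster_grid> %d x %d cells, %d unmasked", d[1], d[2], length(v)))
  if (!is.na(x$epoch)) cat(sprintf(", epoch %s", x$epoch))
  if (length(v))
    cat(sprintf("\n  range [%.4g, %.4g], mean %.4g", min(v), max(v), mean(v)))
  cat("\n")
  invisible(x)
}

#' Unmasked cell values of a raster grid
#'
#' @param grid a `raster_grid`.
#' @return Numeric vector of values at unmasked cells (column-major order).
#' @export
grid_values <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  grid$values[!grid$mask]
}

#' Apply a cellwise function, preserving mask and georeferencing
#'
#' @param grid a `raster_grid`.
#' @param f vectorised function applied to the value matrix.
#' @param epoch optional new epoch label (default: keep).
#' @return A `raster_grid` of the same shape.
#' @export
grid_map <- function(grid, f, epoch = grid$epoch) {
  v <- f(grid$values)
  v[grid$mask] <- NA_real_
  raster_grid(v, mask = grid$mask, transform = grid$transform,
              crs = grid$crs, epoch = epoch)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$transform, b$transform)) &&
    identical(a$crs, b$crs)
}

#' Assert that raster grids are mutually aligned
#'
#' Grids are aligned when they share shape, affine transform and CRS.
#' Masks may differ; operations combining grids mask the union.
#'
#' @param ... `raster_grid` objects.
#' @return Invisibly `TRUE`; otherwise an error naming the offender.
#' @export
assert_aligned <- function(...) {
  grids <- list(...)
  nm <- vapply(substitute(list(...))[-1], deparse, "")
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    if (!inherits(grids[[i]], "raster_grid"))
      stop(sprintf("'%s' is not a raster_grid", nm[i]))
    if (!same_geometry(ref, grids[[i]]))
      stop(sprintf("raster '%s' is not aligned with '%s'", nm[i], nm[1]))
  }
  invisible(TRUE)
}

union_mask <- function(...) {
  masks <- lapply(list(...), function(g) g$mask)
  Reduce(`|`, masks)
}

#' Construct an aligned multi-epoch stack
#'
#' An ordered list of mutually aligned `raster_grid` layers, one per epoch,
#' sharing a common nodata mask: only cells observed in every epoch are
#' analysed, so a cell masked in any layer is masked in all.
#'
#' @param grids list of `raster_grid` objects.
#' @param epochs numeric epoch labels, strictly increasing; defaults to the
#'   grids' own epoch labels.
#' @return An object of class `aligned_stack`.
#' @export
aligned_stack <- function(grids, epochs = NULL) {
  stopifnot(is.list(grids), length(grids) >= 1L)
  if (is.null(epochs))
    epochs <- vapply(grids, function(g) as.numeric(g$epoch), 0)
  epochs <- as.numeric(epochs)
  if (length(epochs) != length(grids)) stop("one epoch label per grid")
  if (any(is.na(epochs)) || any(diff(epochs) <= 0))
    stop("epochs must be strictly increasing")
  ref <- grids[[1]]
  for (g in grids) {
    if (!inherits(g, "raster_grid")) stop("all elements must be raster_grid")
    if (!same_geometry(ref, g)) stop("all grids in a stack must be aligned")
  }
  common <- Reduce(`|`, lapply(grids, function(g) g$mask))
  grids <- mapply(function(g, e) {
    v <- g$values; v[common] <- NA_real_
    raster_grid(v, mask = common, transform = g$transform, crs = g$crs,
                epoch = e)
  }, grids, epochs, SIMPLIFY = FALSE)
  structure(list(grids = grids, epochs = epochs), class = "aligned_stack")
}

#' @export
print.aligned_stack <- function(x, ...) {
  cat(sprintf("<aligned_stack> %d epochs (%s), %d x %d cells\n",
              length(x$epochs), paste(x$epochs, collapse = ", "),
              nrow(x$grids[[1]]$values), ncol(x$grids[[1]]$values)))
  invisible(x)
}

#' @export
length.aligned_stack <- function(x) length(x$grids)

#' Extract one epoch from a stack
#'
#' @param stack an `aligned_stack`.
#' @param epoch epoch label present in the stack.
#' @return The `raster_grid` for that epoch.
#' @export
stack_epoch <- function(stack, epoch) {
  stopifnot(inherits(stack, "aligned_stack"))
  i <- match(as.numeric(epoch), stack$epochs)
  if (is.na(i)) stop(sprintf("epoch %s not present in stack", epoch))
  stack$grids[[i]]
}

# ---- plain-text grid interchange (ESRI ASCII grid) -------------------------

#' Write a raster grid as an ESRI ASCII grid (.asc)
#'
#' Plain-text single-band raster interchange: a six-line header (ncols,
#' nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' whitespace-separated rows, north to south.
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @param nodata numeric sentinel written at masked cells.
#' @param digits significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  tr <- grid$transform
  yll <- tr[2] - nr * tr[3]    # origin_y is the top edge
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", tr[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", tr[3]),
           sprintf("NODATA_value %.10g", nodata))
  v[grid$mask] <- nodata
  rows <- apply(format(v, digits = digits, trim = TRUE, scientific = FALSE),
                1L, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @param crs,epoch metadata attached to the result (not stored in .asc).
#' @return A `raster_grid`.
#' @export
read_ascii_grid <- function(path, crs = "local", epoch = NA) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(body) != nr * nc) stop("ASCII grid body size mismatch")
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  raster_grid(v, transform = c(xll, yll + nr * hdr$cellsize, hdr$cellsize),
              crs = crs, epoch = epoch)
}

#' Per-zone summary statistics of a raster grid
#'
#' Mean, standard deviation and cell count of `grid` within each category
#' of an aligned zone grid, over cells unmasked in both layers.
#'
#' @param grid a `raster_grid` of values.
#' @param zones an aligned `raster_grid` whose values are zone codes.
#' @return A data frame with columns `zone`, `mean`, `sd`, `count`.
#' @export
zonal_summary <- function(grid, zones) {
  assert_aligned(grid, zones)
  keep <- !(grid$mask | zones$mask)
  if (!any(keep)) {
    warning("no overlapping unmasked cells between grid and zones")
    return(data.frame(zone = numeric(0), mean = numeric(0),
                      sd = numeric(0), count = integer(0)))
  }
  v <- grid$values[keep]
  z <- zones$values[keep]
  out <- do.call(rbind, lapply(split(v, z), function(x)
    data.frame(mean = mean(x), sd = stats::sd(x), count = length(x))))
  data.frame(zone = as.numeric(rownames(out)), out, row.names = NULL)
}
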