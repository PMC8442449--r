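#' Grid geometry of a planar raster
#'
#' Describes the regular square-cell lattice shared by all geomagnetic cue
#' grids. The origin is the CENTRE of the top-left cell (row 1, column 1);
#' row index increases with decreasing y (raster convention); all coordinates
#' are planar metres in a projected coordinate system.
#'
#' @param origin_x,origin_y coordinates (m) of the centre of cell (1, 1).
#' @param cell_size cell edge length in metres (> 0). The daily magnetic
#'   model grids this package emulates are conventionally resampled to 5 km.
#' @param n_rows,n_cols grid dimensions (each >= 2).
#' @param crs_label free-text metadata describing the projection (never used
#'   in computation; the package does not reproject).
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                          crs_label = "") {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 2, n_cols >= 2)
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 crs_label = as.character(crs_label)),
            class = "grid_geometry")
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("<grid_geometry %d x %d cells of %.0f m, origin (%.0f, %.0f)>",
          x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y)
}

#' @export
print.grid_geometry <- function(x, ...) cat(format(x), "\n")

#' @keywords internal
same_geometry <- function(a, b, tol = 1e-6) {
  abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

# x coordinates of all column centres / y of all row centres
#' @keywords internal
col_x <- function(g) g$origin_x + (seq_len(g$n_cols) - 1) * g$cell_size
#' @keywords internal
row_y <- function(g) g$origin_y - (seq_len(g$n_rows) - 1) * g$cell_size

# Outer bounds (cell edges, not centres)
#' @keywords internal
grid_bounds <- function(g) {
  h <- g$cell_size / 2
  list(xmin = g$origin_x - h,
       xmax = g$origin_x + (g$n_cols - 1) * g$cell_size + h,
       ymin = g$origin_y - (g$n_rows - 1) * g$cell_size - h,
       ymax = g$origin_y + h)
}

#' @keywords internal
in_bounds <- function(g, x, y) {
  b <- grid_bounds(g)
  x >= b$xmin & x <= b$xmax & y >= b$ymin & y <= b$ymax
}

#' A dated grid of one geomagnetic cue
#'
#' Holds a single day's values of one geomagnetic quantity on a planar grid:
#' total intensity F (nT), inclination I (degrees, dip angle of the field
#' lines; -90 to 90) or horizontal component H (nT, the projection of the
#' field vector onto the horizontal plane, H = F cos I).
#'
#' @param cue one of `"F"`, `"I"`, `"H"`.
#' @param date a `Date` (calendar day of the daily magnetic model grid).
#' @param geometry a [grid_geometry()].
#' @param values numeric matrix `n_rows x n_cols`; nT for F/H, degrees for I.
#' @return an object of class `field_grid`.
#' @export
field_grid <- function(cue, date, geometry, values) {
  cue <- match.arg(cue, c("F", "I", "H"))
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_rows || ncol(values) != geometry$n_cols)
    stop("values matrix does not match geometry (",
         geometry$n_rows, " x ", geometry$n_cols, ")")
  if (!all(is.finite(values)))
    stop("field grid contains non-finite values")
  if (cue == "I" && (min(values) < -90 || max(values) > 90))
    stop("inclination values outside [-90, 90]: range [",
         signif(min(values), 6), ", ", signif(max(values), 6), "]")
  if (cue %in% c("F", "H") && min(values) < 0)
    stop(cue, " values must be >= 0; minimum is ", signif(min(values), 6))
  structure(list(cue = cue, date = as.Date(date), geometry = geometry,
                 values = values),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid %s %s, %s, range [%.6g, %.6g]>\n",
              x$cue, format(x$date), format(x$geometry),
              min(x$values), max(x$values)))
}

#' One day's F, I and H grids on a shared geometry
#'
#' @param F_grid,I_grid,H_grid `field_grid` objects for cues F, I, H on the
#'   same date and geometry. If `H_grid` is `NULL` it is derived as
#'   H = F cos I via [derive_horizontal()].
#' @param check_h verify |H - F cos I| <= 1e-6 F cellwise (set `FALSE` for
#'   independently measured H grids).
#' @return an object of class `field_stack`: list with elements `F`, `I`,
#'   `H`, `date`, `geometry`.
#' @export
field_stack <- function(F_grid, I_grid, H_grid = NULL, check_h = TRUE) {
  stopifnot(F_grid$cue == "F", I_grid$cue == "I")
  if (!same_geometry(F_grid$geometry, I_grid$geometry))
    stop("F and I grids have mismatched geometry")
  if (F_grid$date != I_grid$date) stop("F and I grids have different dates")
  if (is.null(H_grid)) {
    H_grid <- derive_horizontal(F_grid, I_grid)
  } else {
    stopifnot(H_grid$cue == "H")
    if (!same_geometry(F_grid$geometry, H_grid$geometry))
      stop("H grid has mismatched geometry")
    if (H_grid$date != F_grid$date) stop("H grid has a different date")
    if (check_h) {
      dev <- abs(H_grid$values - F_grid$values * cos(deg2rad(I_grid$values)))
      if (any(dev > 1e-6 * pmax(F_grid$values, 1)))
        stop("H grid is inconsistent with F cos I (max deviation ",
             signif(max(dev), 4), " nT)")
    }
  }
  structure(list(F = F_grid, I = I_grid, H = H_grid,
                 date = F_grid$date, geometry = F_grid$geometry),
            class = "field_stack")
}

#' Derive the horizontal component H = F cos I
#'
#' The horizontal component is the projection of the geomagnetic field
#' vector onto the local horizontal (north-east) plane.
#'
#' @param F_grid intensity grid (cue F, nT).
#' @param I_grid inclination grid (cue I, degrees).
#' @return a `field_grid` with cue H on the shared geometry and date.
#' @export
derive_horizontal <- function(F_grid, I_grid) {
  stopifnot(F_grid$cue == "F", I_grid$cue == "I")
  if (!same_geometry(F_grid$geometry, I_grid$geometry))
    stop("geometry mismatch between F and I grids")
  if (F_grid$date != I_grid$date)
    stop("date mismatch between F and I grids")
  h <- F_grid$values * cos(deg2rad(I_grid$values))
  h[h < 0] <- 0   # numerical guard at |I| = 90
  field_grid("H", F_grid$date, F_grid$geometry, h)
}

#' Query a field grid at planar coordinates
#'
#' Bilinear interpolation of the four surrounding cell centres (default), or
#' nearest-cell lookup for exact reproduction of cell-sampled behaviour.
#' Points in the outer half-cell margin (inside the grid bounds but outside
#' the lattice of centres) use constant extrapolation from the edge centres.
#'
#' @param grid a `field_grid`.
#' @param x,y planar coordinates (m); vectors of equal length.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return numeric vector of cue values.
#' @export
value_at <- function(grid, x, y, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  g <- grid$geometry
  if (!all(in_bounds(g, x, y))) {
    bad <- which(!in_bounds(g, x, y))[1]
    b <- grid_bounds(g)
    stop(sprintf(
      "query point (%.1f, %.1f) outside grid bounds x:[%.1f, %.1f] y:[%.1f, %.1f]",
      x[bad], y[bad], b$xmin, b$xmax, b$ymin, b$ymax))
  }
  # fractional (row, col), 1-based, at cell centres
  fc <- (x - g$origin_x) / g$cell_size + 1
  fr <- (g$origin_y - y) / g$cell_size + 1
  v <- grid$values
  if (method == "nearest") {
    r <- pmin(pmax(round(fr), 1), g$n_rows)
    c_ <- pmin(pmax(round(fc), 1), g$n_cols)
    return(v[cbind(r, c_)])
  }
  r0 <- pmin(pmax(floor(fr), 1), g$n_rows)
  c0 <- pmin(pmax(floor(fc), 1), g$n_cols)
  r1 <- pmin(r0 + 1, g$n_rows)
  c1 <- pmin(c0 + 1, g$n_cols)
  tr <- pmin(pmax(fr - r0, 0), 1)
  tc <- pmin(pmax(fc - c0, 0), 1)
  v00 <- v[cbind(r0, c0)]; v01 <- v[cbind(r0, c1)]
  v10 <- v[cbind(r1, c0)]; v11 <- v[cbind(r1, c1)]
  (1 - tr) * ((1 - tc) * v00 + tc * v01) + tr * ((1 - tc) * v10 + tc * v11)
}

#' Locate the global extremum of a grid
#'
#' Returns the cell-centre coordinates attaining the grid minimum or maximum.
#' Ties are broken by the smallest (row, column) in row-major order, which
#' makes the result deterministic on flat or symmetric fields.
#'
#' @param grid a `field_grid`.
#' @param which `"min"` or `"max"`.
#' @return list with elements `x`, `y`, `value`, `row`, `col`.
#' @export
extremum_location <- function(grid, which = c("min", "max")) {
  which <- match.arg(which)
  v <- grid$values
  target <- if (which == "min") min(v) else max(v)
  hits <- which(v == target, arr.ind = TRUE)   # arr.ind: row, col
  # row-major tie-break: smallest row, then smallest col
  ord <- order(hits[, 1], hits[, 2])
  r <- unname(hits[ord[1], 1]); c_ <- unname(hits[ord[1], 2])
  g <- grid$geometry
  list(x = g$origin_x + (c_ - 1) * g$cell_size,
       y = g$origin_y - (r - 1) * g$cell_size,
       value = target, row = r, col = c_)
}

# ---- raster file I/O -------------------------------------------------------

# World-file (.tfw) sidecar: the standard six-line plain-text georeferencing
# companion for TIFF rasters. Lines: x cell size, rotation, rotation,
# negative y cell size, x of the CENTRE of the top-left cell, y of same.
#' @keywords internal
world_file_path <- function(path) sub("\\.tiff?$", ".tfw", path)

#' Read a dated geomagnetic cue grid from a single-band raster
#'
#' Reads a single-band float TIFF (as written by [write_field_grid()] or any
#' GIS exporting a square-cell raster with a world-file sidecar). Grid
#' geometry is taken from the `.tfw` world file next to the raster; the
#' world-file coordinates refer to the centre of the top-left cell.
#'
#' @param path path to the `.tif` file; `<path>.tfw` must exist beside it.
#' @param cue one of `"F"`, `"I"`, `"H"`; cue-specific value invariants are
#'   validated (I in [-90, 90]; F, H >= 0).
#' @param date calendar day of the grid (`Date` or ISO string).
#' @param crs_label optional projection metadata carried through unchanged.
#' @return a `field_grid`.
#' @export
read_field_grid <- function(path, cue, date, crs_label = "") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  wf <- world_file_path(path)
  if (!file.exists(wf))
    stop("world file not found: ", wf,
         " (georeferencing sidecar is required)")
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3) {
    if (dim(v)[3] != 1) stop("raster must be single-band: ", path)
    v <- v[, , 1]
  }
  w <- as.numeric(readLines(wf, n = 6))
  if (length(w) < 6 || any(!is.finite(w)))
    stop("malformed world file: ", wf)
  if (abs(w[2]) > 1e-9 || abs(w[3]) > 1e-9)
    stop("rotated grids are not supported: ", wf)
  if (abs(w[1] + w[4]) > 1e-6 * abs(w[1]))
    stop("non-square cells (", w[1], " x ", -w[4], " m) in ", wf)
  g <- grid_geometry(origin_x = w[5], origin_y = w[6], cell_size = w[1],
                     n_rows = nrow(v), n_cols = ncol(v),
                     crs_label = crs_label)
  field_grid(cue, date, g, v)
}

#' Write a field grid as a float32 single-band TIFF plus world file
#'
#' Writes an uncompressed single-strip 32-bit IEEE float grey TIFF (readable
#' by any libtiff-based tool) and the `.tfw` world-file sidecar used by
#' [read_field_grid()]. File naming convention for daily cue stacks is
#' `<cue>_<YYYY-MM-DD>.tif`.
#'
#' @param grid a `field_grid`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_field_grid <- function(grid, path) {
  write_float_tiff(grid$values, path)
  g <- grid$geometry
  writeLines(c(format(g$cell_size, digits = 15), "0", "0",
               format(-g$cell_size, digits = 15),
               format(g$origin_x, digits = 15),
               format(g$origin_y, digits = 15)),
             world_file_path(path))
  invisible(path)
}

# Minimal float32 TIFF writer (little-endian, single strip, no compression).
# The tiff package reads float rasters but only writes clamped [0,1] images,
# so raw nT / degree values are written here directly.
#' @keywords internal
write_float_tiff <- function(m, path) {
  m <- as.matrix(m)
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, IFD offset (after 8-byte header + pixel data)
  writeBin(charToRaw("II"), con)
  w2(42)
  w4(8 + 4 * n)
  # pixel data row-major from offset 8
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  # IFD: 10 tags
  tag <- function(code, type, count, value) {
    w2(code); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0) } else w4(value)   # 3 = SHORT, 4 = LONG
  }
  w2(10)
  tag(256, 4, 1, nc)        # ImageWidth
  tag(257, 4, 1, nr)        # ImageLength
  tag(258, 3, 1, 32)        # BitsPerSample
  tag(259, 3, 1, 1)         # Compression: none
  tag(262, 3, 1, 1)         # Photometric: BlackIsZero
  tag(273, 4, 1, 8)         # StripOffsets
  tag(277, 3, 1, 1)         # SamplesPerPixel
  tag(278, 4, 1, nr)        # RowsPerStrip
  tag(279, 4, 1, 4 * n)     # StripByteCounts
  tag(339, 3, 1, 3)         # SampleFormat: IEEE float
  w4(0)                     # next IFD
  invisible(path)
}

#' Read one day's F/I/H stack from a directory of cue rasters
#'
#' Expects files named `<cue>_<YYYY-MM-DD>.tif` (with `.tfw` sidecars) in
#' `dir`. If the H file is absent, H is derived as F cos I.
#'
#' @param dir directory containing the rasters.
#' @param date calendar day.
#' @param crs_label optional projection metadata.
#' @return a `field_stack`.
#' @export
read_field_stack <- function(dir, date, crs_label = "") {
  date <- as.Date(date)
  p <- function(cue) file.path(dir, sprintf("%s_%s.tif", cue, format(date)))
  Fg <- read_field_grid(p("F"), "F", date, crs_label)
  Ig <- read_field_grid(p("I"), "I", date, crs_label)
  Hg <- if (file.exists(p("H"))) read_field_grid(p("H"), "H", date, crs_label)
        else NULL
  field_stack(Fg, Ig, Hg, check_h = FALSE)
}
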