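#' Construct a land-use raster
#'
#' A regular rectangular grid of integer land-use class codes on a planar
#' metric projection. Row 1 of `codes` is the northernmost row (as in the
#' plain-text grid format written by [write_raster()]).
#'
#' @param codes Integer matrix of class codes (`nrows x ncols`).
#' @param xll,yll Coordinates (meters) of the lower-left corner of the grid.
#' @param cell_size Cell edge length in meters, `> 0`.
#' @return A `lur_raster` object.
#' @export
lur_raster <- function(codes, xll, yll, cell_size) {
  stopifnot(is.matrix(codes), cell_size > 0)
  structure(list(codes = codes, xll = as.numeric(xll), yll = as.numeric(yll),
                 cell_size = as.numeric(cell_size)),
            class = "lur_raster")
}

#' @export
print.lur_raster <- function(x, ...) {
  cat(sprintf("land-use raster: %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$codes), ncol(x$codes), x$cell_size, x$xll, x$yll))
  invisible(x)
}

# cell-center coordinates; row i counts from the top (north)
raster_cell_centers <- function(raster, rows, cols) {
  nr <- nrow(raster$codes)
  list(x = raster$xll + (cols - 0.5) * raster$cell_size,
       y = raster$yll + (nr - rows + 0.5) * raster$cell_size)
}

#' Land-use class area inside a circular buffer
#'
#' Counts raster cells whose center lies inside the closed disc and whose
#' class code is in `classes`, times the cell area. Cell-center inclusion is
#' used rather than polygon clipping; the discretization bias vanishes as
#' `cell_size / radius` shrinks.
#'
#' @param raster A [lur_raster()].
#' @param center Numeric `c(x, y)`, meters.
#' @param radius Buffer radius in meters, `> 0`.
#' @param classes Integer class codes to sum; empty set gives 0.
#' @return Area in square meters. A disc entirely outside the raster extent
#'   yields 0 with a warning.
#' @export
raster_class_area_in_disc <- function(raster, center, radius, classes) {
  stopifnot(radius > 0)
  if (!length(classes)) return(0)
  nr <- nrow(raster$codes); nc <- ncol(raster$codes); cs <- raster$cell_size
  xmax <- raster$xll + nc * cs
  ymax <- raster$yll + nr * cs
  if (center[1L] + radius < raster$xll || center[1L] - radius > xmax ||
      center[2L] + radius < raster$yll || center[2L] - radius > ymax) {
    warning("buffer disc entirely outside raster extent; returning 0")
    return(0)
  }
  # restrict to the bounding box of the disc
  c1 <- max(1L, floor((center[1L] - radius - raster$xll) / cs) + 1L)
  c2 <- min(nc, ceiling((center[1L] + radius - raster$xll) / cs))
  r_top <- max(1L, floor((ymax - (center[2L] + radius)) / cs) + 1L)
  r_bot <- min(nr, ceiling((ymax - (center[2L] - radius)) / cs))
  if (c1 > c2 || r_top > r_bot) return(0)
  rows <- r_top:r_bot; cols <- c1:c2
  cx <- raster$xll + (cols - 0.5) * cs
  cy <- raster$yll + (nr - rows + 0.5) * cs
  dx2 <- outer(rows * 0, (cx - center[1L])^2, `+`)
  dy2 <- matrix((cy - center[2L])^2, nrow = length(rows), ncol = length(cols))
  inside <- (dx2 + dy2) <= radius * radius
  sub <- raster$codes[rows, cols, drop = FALSE]
  sum(inside & matrix(sub %in% classes, nrow = length(rows))) * cs * cs
}

#' Read / write a plain-text land-use grid
#'
#' The format is the 6-line-header ASCII grid (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`, then one row of integer codes per
#' line, north first).
#'
#' @param raster A [lur_raster()].
#' @param path File path.
#' @return `read_raster()` returns a `lur_raster`; `write_raster()` its path,
#'   invisibly.
#' @export
write_raster <- function(raster, path) {
  h <- c(sprintf("ncols %d", ncol(raster$codes)),
         sprintf("nrows %d", nrow(raster$codes)),
         sprintf("xllcorner %.10g", raster$xll),
         sprintf("yllcorner %.10g", raster$yll),
         sprintf("cellsize %.10g", raster$cell_size),
         "NODATA_value -9999")
  body <- apply(raster$codes, 1L, paste, collapse = " ")
  writeLines(c(h, body), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2L]), 0),
                          tolower(vapply(hdr, `[`, "", 1L)))
  codes <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1L]])))
  if (nrow(codes) != vals[["nrows"]] || ncol(codes) != vals[["ncols"]])
    stop_data("raster '%s': grid does not match header dimensions", path)
  lur_raster(codes, vals[["xllcorner"]], vals[["yllcorner"]],
             vals[["cellsize"]])
}
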