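#' Geographic grid definition
#'
#' A plain geographic (longitude/latitude) raster georeference: cell registry
#' is lower-left corner (`xll`, `yll`), square cells of `cellsize` degrees,
#' `nrow` rows and `ncol` columns. Values attached to a grid are stored as an
#' `nrow x ncol` matrix whose first row is the NORTHERNMOST row, matching the
#' ESRI ASCII grid convention.
#'
#' @param nrow,ncol grid dimensions (positive integers).
#' @param xll,yll longitude/latitude of the lower-left corner, degrees.
#' @param cellsize cell edge, degrees (default 5 arc-minutes).
#' @return an object of class `trait_grid`.
#' @export
trait_grid <- function(nrow, ncol, xll, yll, cellsize = 5 / 60) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xll = xll, yll = yll, cellsize = cellsize),
    class = "trait_grid"
  )
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("<trait_grid> %d x %d cells, %.4f deg, origin (%.3f, %.3f)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  invisible(x)
}

grid_same <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Cell centre coordinates of every cell
#'
#' @param grid a [trait_grid()].
#' @return data.frame with `row`, `col`, `lon`, `lat` (row 1 = north).
#' @export
grid_centers <- function(grid) {
  col <- rep(seq_len(grid$ncol), times = grid$nrow)
  row <- rep(seq_len(grid$nrow), each = grid$ncol)
  lon <- grid$xll + (col - 0.5) * grid$cellsize
  lat <- grid$yll + (grid$nrow - row + 0.5) * grid$cellsize
  data.frame(row = row, col = col, lon = lon, lat = lat)
}

#' Locate the cell containing a point
#'
#' Cells are half-open, `[west, east) x [south, north)`: a point exactly on a
#' shared edge belongs to the cell to its east/north, so every in-extent point
#' maps to exactly one cell.
#'
#' @param grid a [trait_grid()].
#' @param lon,lat point coordinates (vectorized).
#' @return data.frame with `row`, `col` (NA outside the grid extent).
#' @export
cell_index <- function(grid, lon, lat) {
  i <- floor((lon - grid$xll) / grid$cellsize)       # 0-based from west
  j <- floor((lat - grid$yll) / grid$cellsize)       # 0-based from south
  inside <- i >= 0 & i < grid$ncol & j >= 0 & j < grid$nrow
  col <- ifelse(inside, i + 1L, NA_integer_)
  row <- ifelse(inside, grid$nrow - j, NA_integer_)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values `nrow x ncol` matrix, first row = north.
#' @param grid a [trait_grid()] describing the georeference.
#' @param path output file.
#' @param nodata value standing in for NA cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid$nrow,
            ncol(values) == grid$ncol)
  values[is.na(values)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(values, 1L, function(r) paste(format(r, trim = TRUE,
                                                     digits = 10),
                                              collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return list with `grid` (a [trait_grid()]) and `values` matrix (NA where
#'   the file holds its NODATA value).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) in ", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(grid = trait_grid(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                         hdr$cellsize),
       values = m)
}

# Separable Gaussian blur of a matrix; sigma in cells. Edges are renormalized
# (kernel mass falling off the grid is dropped), so a constant field maps to
# itself.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  smooth1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(v[lo:hi] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2L, smooth1)
  t(apply(m, 1L, smooth1))
}

# Smooth unit-variance Gaussian random field on a grid: white noise blurred
# with a Gaussian kernel, then standardized.
smooth_field <- function(nrow, ncol, sigma_cells) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  z <- gaussian_smooth(z, sigma_cells)
  (z - mean(z)) / stats::sd(z)
}

#' Synthetic digital elevation model
#'
#' A smooth, strictly positive elevation surface: a broad ridge running
#' through the grid plus smoothed random relief. Deterministic given the
#' current RNG state.
#'
#' @param grid a [trait_grid()].
#' @param base_elev mean elevation, metres.
#' @param relief approximate elevation range, metres.
#' @return matrix of elevations (m), first row = north.
#' @export
synthetic_dem <- function(grid, base_elev = 400, relief = 900) {
  cc <- grid_centers(grid)
  lon0 <- grid$xll + grid$ncol * grid$cellsize * 0.35
  width <- grid$ncol * grid$cellsize * 0.25
  ridge <- exp(-((cc$lon - lon0) / width)^2)
  dem <- base_elev + relief * matrix(ridge, grid$nrow, grid$ncol,
                                     byrow = TRUE)
  dem <- dem + 0.15 * relief * smooth_field(grid$nrow, grid$ncol, 2)
  pmax(dem, 1)
}
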