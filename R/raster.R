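#' Gridded seascape domain
#'
#' A `sea_grid` describes a regular raster grid with a constant land/sea mask.
#' Coordinates are either planar (km, origin at the lower-left corner) or
#' geographic (origin = lon/lat of the lower-left corner, cell size in
#' decimal degrees). Row 1 is the northernmost row, matching the way a matrix
#' prints as a map; `y` (or latitude) therefore decreases with the row index.
#'
#' @param nrow,ncol grid dimensions (each >= 2).
#' @param cellsize cell edge length; km for planar grids, degrees for
#'   geographic grids.
#' @param origin numeric length-2, x/y (or lon/lat) of the lower-left corner.
#' @param mask logical `nrow x ncol` matrix, `TRUE` for sea pixels. Default
#'   all sea.
#' @param geographic if `TRUE` coordinates are lon/lat and great-circle
#'   distances are used where distances matter.
#' @return an object of class `sea_grid`.
#' @export
sea_grid <- function(nrow, ncol, cellsize, origin = c(0, 0), mask = NULL,
                     geographic = FALSE) {
  if (nrow < 2 || ncol < 2) stop("degenerate grid: need at least 2x2 pixels")
  if (is.null(mask)) mask <- matrix(TRUE, nrow, ncol)
  stopifnot(is.logical(mask), all(dim(mask) == c(nrow, ncol)))
  structure(list(nrow = nrow, ncol = ncol, cellsize = cellsize,
                 origin = as.numeric(origin), mask = mask,
                 geographic = isTRUE(geographic)),
            class = "sea_grid")
}

#' @exportS3Method base::print
print.sea_grid <- function(x, ...) {
  cat(sprintf("<sea_grid> %d x %d, cellsize %g %s, %d sea / %d pixels\n",
              x$nrow, x$ncol, x$cellsize,
              if (x$geographic) "deg (geographic)" else "km (planar)",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Pixel-center coordinates
#'
#' @param grid a [sea_grid()].
#' @param sea_only keep sea pixels only.
#' @return data frame with `row`, `col`, `x`, `y` (lon/lat for geographic
#'   grids).
#' @export
cell_centers <- function(grid, sea_only = FALSE) {
  rc <- expand.grid(row = seq_len(grid$nrow), col = seq_len(grid$ncol))
  out <- data.frame(
    row = rc$row, col = rc$col,
    x = grid$origin[1] + (rc$col - 0.5) * grid$cellsize,
    y = grid$origin[2] + (grid$nrow - rc$row + 0.5) * grid$cellsize)
  if (sea_only) out <- out[grid$mask[cbind(out$row, out$col)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance between two sets of points on a grid
#'
#' Planar grids use Euclidean distance in km; geographic grids use the
#' haversine great-circle distance (returned in km).
#'
#' @param grid a [sea_grid()].
#' @param a,b data frames with `x`, `y` columns.
#' @return matrix `nrow(a) x nrow(b)` of distances in km.
#' @export
grid_distance <- function(grid, a, b) {
  if (grid$geographic) {
    geosphere::distm(cbind(a$x, a$y), cbind(b$x, b$y),
                     fun = geosphere::distHaversine) / 1000
  } else {
    sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  }
}

#' Time-stamped raster series
#'
#' Container for a daily or monthly gridded series over a [sea_grid()].
#' Values are stored as a `time x nrow x ncol` array; land pixels are `NA` on
#' every time slice (the mask is constant over time).
#'
#' @param grid a [sea_grid()].
#' @param dates `Date` vector, strictly increasing; daily series are
#'   consecutive days, monthly series first-of-month stamps.
#' @param values numeric array `length(dates) x nrow x ncol`.
#' @param freq `"daily"` or `"monthly"`; inferred from `dates` when missing.
#' @return an object of class `raster_series`.
#' @export
raster_series <- function(grid, dates, values, freq = NULL) {
  stopifnot(inherits(grid, "sea_grid"), inherits(dates, "Date"))
  values <- as.array(values)
  if (length(dim(values)) != 3 ||
      !all(dim(values) == c(length(dates), grid$nrow, grid$ncol)))
    stop("values must be a time x nrow x ncol array matching grid and dates")
  if (length(dates) > 1 && any(diff(as.numeric(dates)) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(freq)) {
    freq <- if (length(dates) > 1 && all(diff(as.numeric(dates)) == 1))
      "daily" else "monthly"
  }
  freq <- match.arg(freq, c("daily", "monthly"))
  land <- which(!grid$mask)
  if (length(land)) {
    # enforce mask on every slice
    for (idx in land) {
      r <- (idx - 1) %% grid$nrow + 1
      cc <- (idx - 1) %/% grid$nrow + 1
      values[, r, cc] <- NA_real_
    }
  }
  structure(list(grid = grid, dates = dates, values = values, freq = freq),
            class = "raster_series")
}

#' @exportS3Method base::print
print.raster_series <- function(x, ...) {
  cat(sprintf("<raster_series> %s, %d steps (%s .. %s), grid %d x %d\n",
              x$freq, length(x$dates), min(x$dates), max(x$dates),
              x$grid$nrow, x$grid$ncol))
  invisible(x)
}

#' Flatten a raster series to a time x pixel matrix
#'
#' Pixels are ordered column-major over `(row, col)`, i.e.
#' `pixel = (col - 1) * nrow + row`.
#'
#' @param series a [raster_series()].
#' @return numeric matrix, one column per pixel (land pixels all-`NA`).
#' @export
series_matrix <- function(series) {
  d <- dim(series$values)
  matrix(series$values, nrow = d[1], ncol = d[2] * d[3])
}

#' Single static raster layer
#'
#' @param grid a [sea_grid()].
#' @param values numeric `nrow x ncol` matrix.
#' @return object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values) {
  stopifnot(inherits(grid, "sea_grid"),
            all(dim(values) == c(grid$nrow, grid$ncol)))
  values[!grid$mask] <- NA_real_
  structure(list(grid = grid, values = values), class = "raster_layer")
}

#' Write / read a raster series as long-format CSV
#'
#' Plain-text interchange format: one line per (date, row, col) sea pixel.
#'
#' @param series a [raster_series()].
#' @param path file path.
#' @export
write_series_csv <- function(series, path) {
  cc <- cell_centers(series$grid, sea_only = TRUE)
  m <- series_matrix(series)
  pix <- (cc$col - 1) * series$grid$nrow + cc$row
  df <- data.frame(
    date = rep(as.character(series$dates), times = nrow(cc)),
    row = rep(cc$row, each = length(series$dates)),
    col = rep(cc$col, each = length(series$dates)),
    value = as.vector(m[, pix]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param grid the [sea_grid()] the file was written from.
#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, grid) {
  df <- utils::read.csv(path)
  dates <- sort(unique(as.Date(df$date)))
  arr <- array(NA_real_, c(length(dates), grid$nrow, grid$ncol))
  ti <- match(as.Date(df$date), dates)
  arr[cbind(ti, df$row, df$col)] <- df$value
  raster_series(grid, dates, arr)
}

#' Bilinear resampling of a raster layer to a finer grid
#'
#' Continuous fields are interpolated bilinearly between source pixel
#' centers; the target land mask is re-applied afterwards, so interpolated
#' values never leak onto land.
#'
#' @param layer a [raster_layer()].
#' @param target a [sea_grid()] covering the same extent.
#' @return a [raster_layer()] on `target`.
#' @export
resample_bilinear <- function(layer, target) {
  src <- layer$grid
  tc <- cell_centers(target)
  # fractional source pixel coordinates of each target center
  fx <- (tc$x - src$origin[1]) / src$cellsize + 0.5
  fy <- (src$origin[2] + src$nrow * src$cellsize - tc$y) / src$cellsize + 0.5
  x0 <- pmin(pmax(floor(fx), 1), src$ncol - 1); x1 <- x0 + 1
  y0 <- pmin(pmax(floor(fy), 1), src$nrow - 1); y1 <- y0 + 1
  wx <- pmin(pmax(fx - x0, 0), 1); wy <- pmin(pmax(fy - y0, 0), 1)
  v <- layer$values
  val <- (1 - wy) * ((1 - wx) * v[cbind(y0, x0)] + wx * v[cbind(y0, x1)]) +
    wy * ((1 - wx) * v[cbind(y1, x0)] + wx * v[cbind(y1, x1)])
  out <- matrix(NA_real_, target$nrow, target$ncol)
  out[cbind(tc$row, tc$col)] <- val
  raster_layer(target, out)
}
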