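#' Per-pixel summary statistics of a raster series
#'
#' For any series: the overall average (`AVG`), and the highest (`HM`) and
#' lowest (`LM`) calendar-month climatological means. For daily series
#' additionally three standard deviations: the SD of all daily values
#' (`SD.AVG`) and the SDs of the daily values falling in the highest- and
#' lowest-mean calendar months (`SD.HM`, `SD.LM`). Calendar months are
#' pooled across years (climatology); partial months at the series edges
#' contribute to their month. All statistics are per pixel; all-missing
#' pixels yield missing outputs.
#'
#' @param series a [raster_series()].
#' @return named list of `nrow x ncol` matrices: `AVG`, `HM`, `LM` and, for
#'   daily series, `SD.AVG`, `SD.HM`, `SD.LM`.
#' @export
summary_stats <- function(series) {
  mon <- as.integer(format(series$dates, "%m"))
  if (length(unique(paste(format(series$dates, "%Y-%m")))) < 1)
    stop("need at least one full month of data")
  V <- series_matrix(series)            # time x pixel
  months <- sort(unique(mon))
  P <- ncol(V)
  mmeans <- matrix(NA_real_, length(months), P)
  for (i in seq_along(months))
    mmeans[i, ] <- colMeans(V[mon == months[i], , drop = FALSE], na.rm = TRUE)
  mmeans[is.nan(mmeans)] <- NA_real_
  avg <- colMeans(V, na.rm = TRUE); avg[is.nan(avg)] <- NA_real_
  hm_i <- apply(mmeans, 2, function(x) if (all(is.na(x))) NA_integer_
                else which.max(x))
  lm_i <- apply(mmeans, 2, function(x) if (all(is.na(x))) NA_integer_
                else which.min(x))
  pick <- function(idx) ifelse(is.na(idx), NA_real_,
                               mmeans[cbind(idx, seq_len(P))])
  shape <- function(x) matrix(x, series$grid$nrow, series$grid$ncol)
  out <- list(AVG = shape(avg), HM = shape(pick(hm_i)),
              LM = shape(pick(lm_i)))
  if (series$freq == "daily") {
    sd_all <- apply(V, 2, stats::sd, na.rm = TRUE)
    msd <- matrix(NA_real_, length(months), P)
    for (i in seq_along(months))
      msd[i, ] <- apply(V[mon == months[i], , drop = FALSE], 2,
                        stats::sd, na.rm = TRUE)
    out$SD.AVG <- shape(sd_all)
    out$SD.HM <- shape(ifelse(is.na(hm_i), NA_real_,
                              msd[cbind(hm_i, seq_len(P))]))
    out$SD.LM <- shape(ifelse(is.na(lm_i), NA_real_,
                              msd[cbind(lm_i, seq_len(P))]))
  }
  out
}

#' Default alkalinity polynomial coefficients
#'
#' External reference values: the Lee et al. (2006, Geophys. Res. Lett.)
#' subtropical-zone fit of total alkalinity to sea-surface salinity and
#' temperature, shipped in `inst/extdata/alkalinity_coeffs.csv`.
#'
#' @return named list with `intercept`, `s1`, `s2`, `t1`, `t2`, `s0`, `t0`.
#' @export
alkalinity_coeffs <- function() {
  path <- system.file("extdata", "alkalinity_coeffs.csv",
                      package = "reefscape")
  df <- utils::read.csv(path)
  as.list(stats::setNames(df$value, df$term))
}

#' Seawater alkalinity from SST and salinity
#'
#' Pointwise polynomial `intercept + s1*(SSS - s0) + s2*(SSS - s0)^2 +
#' t1*(SST - t0) + t2*(SST - t0)^2`, evaluated day by day on co-registered
#' series. Missing in either input propagates.
#'
#' @param sst,sss co-registered daily [raster_series()].
#' @param coeffs coefficient list as from [alkalinity_coeffs()].
#' @return a daily [raster_series()] in umol/kg.
#' @export
alkalinity <- function(sst, sss, coeffs = alkalinity_coeffs()) {
  stopifnot(identical(sst$dates, sss$dates),
            identical(dim(sst$values), dim(sss$values)))
  ds <- sss$values - coeffs$s0
  dt <- sst$values - coeffs$t0
  at <- coeffs$intercept + coeffs$s1 * ds + coeffs$s2 * ds^2 +
    coeffs$t1 * dt + coeffs$t2 * dt^2
  raster_series(sst$grid, sst$dates, at, "daily")
}

#' Maximum monthly mean climatology
#'
#' Per-pixel maximum of the calendar-month climatological means, the
#' baseline against which degree-heating hotspots are measured.
#'
#' @param sst_series daily [raster_series()].
#' @return a [raster_layer()].
#' @export
mmm_climatology <- function(sst_series) {
  raster_layer(sst_series$grid, summary_stats(sst_series)$HM)
}

#' Bleaching alert frequency
#'
#' Daily heat stress (hotspot) is the positive excess of SST over the
#' maximum monthly mean climatology (MMM). A day is under bleaching alert
#' when the hotspot accumulated over the trailing `window_days` window,
#' expressed in deg C-weeks (sum of daily hotspots / 7), reaches
#' `threshold`. BAF is the fraction of alerted days among days with a full
#' trailing window.
#'
#' @param sst_series daily [raster_series()].
#' @param climatology MMM [raster_layer()]; computed from the series itself
#'   when `NULL`.
#' @param window_days trailing accumulation window (days).
#' @param threshold alert threshold in deg C-weeks (`>=` comparison).
#' @param hotspot_floor minimum hotspot magnitude that accumulates (deg C);
#'   0 disables the floor.
#' @return a [raster_layer()] with values in `[0, 1]`.
#' @export
bleaching_alert_frequency <- function(sst_series, climatology = NULL,
                                      window_days = 14, threshold = 4,
                                      hotspot_floor = 0) {
  nd <- length(sst_series$dates)
  if (nd < window_days) stop("series shorter than the accumulation window")
  if (is.null(climatology)) climatology <- mmm_climatology(sst_series)
  V <- series_matrix(sst_series)
  mmm <- as.vector(climatology$values)
  hot <- pmax(sweep(V, 2, mmm, "-"), 0)
  if (hotspot_floor > 0) hot[hot < hotspot_floor] <- 0
  cs <- apply(hot, 2, cumsum)
  win <- (cs[window_days:nd, , drop = FALSE] -
          rbind(0, cs[seq_len(nd - window_days), , drop = FALSE])) / 7
  baf <- colMeans(win >= threshold)
  raster_layer(sst_series$grid,
               matrix(baf, sst_series$grid$nrow, sst_series$grid$ncol))
}

#' Mean of a static raster within a radius of each point
#'
#' Averages the pixels whose centers lie within `radius_km` of each point
#' (great-circle for geographic grids, Euclidean km for planar ones).
#'
#' @param layer a [raster_layer()].
#' @param points data frame with `x`, `y` (grid coordinates).
#' @param radius_km buffer radius in km.
#' @return numeric vector, one value per point; `NA` where the buffer holds
#'   no valued pixel.
#' @export
buffer_mean <- function(layer, points, radius_km = 50) {
  cc <- cell_centers(layer$grid)
  val <- layer$values[cbind(cc$row, cc$col)]
  D <- grid_distance(layer$grid, points, cc)
  out <- rep(NA_real_, nrow(points))
  for (i in seq_len(nrow(points))) {
    sel <- D[i, ] <= radius_km & !is.na(val)
    if (any(sel)) out[i] <- mean(val[sel])
  }
  out
}

#' Reef-cell grid
#'
#' Reef cells are sets of grid pixels with an id and an area in km2. Areas
#' default to `n_pixels * cellsize^2` but may be overridden per cell (cells
#' whose reef covers less than a full pixel carry their actual area).
#'
#' @param cells data frame with `cell` (id), `row`, `col`; one line per
#'   member pixel.
#' @param grid a [sea_grid()].
#' @param areas optional named vector of areas (km2) by cell id.
#' @return object of class `reef_grid`: data frame of pixels plus an `area`
#'   table attribute.
#' @export
reef_grid <- function(cells, grid, areas = NULL) {
  stopifnot(all(c("cell", "row", "col") %in% names(cells)))
  full <- tapply(rep(grid$cellsize^2, nrow(cells)), cells$cell, sum)
  area <- full
  if (!is.null(areas)) {
    stopifnot(all(names(areas) %in% names(full)),
              all(areas > 0), all(areas <= full[names(areas)] + 1e-9))
    area[names(areas)] <- areas
  }
  structure(cells, area = area, grid = grid,
            class = c("reef_grid", "data.frame"))
}

#' Zonal mean of a raster over reef cells
#'
#' @param layer a [raster_layer()].
#' @param reefs a [reef_grid()].
#' @return named numeric vector, one mean per reef cell (pixels with no
#'   value are ignored).
#' @export
zonal_mean <- function(layer, reefs) {
  v <- layer$values[cbind(reefs$row, reefs$col)]
  out <- tapply(v, reefs$cell, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  out[unique(reefs$cell)]
}

#' Nearest-pixel extraction at sample points
#'
#' @param layers named list of [raster_layer()]s.
#' @param points data frame with `row`, `col` (pixel of each sample point).
#' @return data frame, one column per layer. A point on a land pixel raises
#'   an error naming it.
#' @export
extract_at_points <- function(layers, points) {
  grid <- layers[[1]]$grid
  land <- !grid$mask[cbind(points$row, points$col)]
  if (any(land))
    stop("point(s) on land: ",
         paste(rownames(points)[land] %||% which(land), collapse = ", "))
  as.data.frame(lapply(layers, function(l)
    l$values[cbind(points$row, points$col)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the environmental descriptor table
#'
#' Applies the descriptor scheme to a set of variables and joins the
#' singleton descriptors: every daily variable contributes six statistics
#' (AVG, HM, LM and the three SDs), every monthly variable three (AVG, HM,
#' LM), plus one column each for the bleaching alert frequency (BAF), depth
#' (DEPTH) and human population density in a 50-km buffer (POPDENS). With
#' five daily variables (e.g. SST, SSS, CHL, current speed, alkalinity) and
#' two monthly ones (SPM, PAR) this is the standard 39-column scheme.
#'
#' @param daily named list of daily [raster_series()].
#' @param monthly named list of monthly [raster_series()].
#' @param baf BAF [raster_layer()], or `NULL` to compute from `daily$SST`.
#' @param depth static depth [raster_layer()] (or `NULL` to omit).
#' @param popdens static population-density [raster_layer()] (or `NULL`).
#' @param at either a points data frame (`row`, `col`) for nearest-pixel
#'   site extraction, or a [reef_grid()] for zonal means.
#' @param buffer_km buffer radius for POPDENS.
#' @param baf_window,baf_threshold forwarded to
#'   [bleaching_alert_frequency()].
#' @return data frame of descriptor columns (39 under the standard scheme),
#'   rownames = site ids or reef-cell ids.
#' @export
env_features <- function(daily, monthly = list(), baf = NULL, depth = NULL,
                         popdens = NULL, at, buffer_km = 50,
                         baf_window = 14, baf_threshold = 4) {
  layers <- list()
  add_stats <- function(name, series) {
    st <- summary_stats(series)
    for (s in names(st))
      layers[[paste(name, s, sep = ".")]] <<-
        raster_layer(series$grid, st[[s]])
  }
  for (nm in names(daily)) add_stats(nm, daily[[nm]])
  for (nm in names(monthly)) add_stats(nm, monthly[[nm]])
  if (is.null(baf) && "SST" %in% names(daily))
    baf <- bleaching_alert_frequency(daily$SST, window_days = baf_window,
                                     threshold = baf_threshold)
  if (!is.null(baf)) layers$BAF <- baf
  if (!is.null(depth)) layers$DEPTH <- depth
  is_reef <- inherits(at, "reef_grid")
  if (is_reef) {
    tab <- as.data.frame(lapply(layers, zonal_mean, reefs = at))
    rownames(tab) <- unique(at$cell)
    if (!is.null(popdens)) {
      grid <- attr(at, "grid")
      cc <- cell_centers(grid)
      key <- (at$col - 1) * grid$nrow + at$row
      cent <- data.frame(x = tapply(cc$x[key], at$cell, mean),
                         y = tapply(cc$y[key], at$cell, mean))
      cent <- cent[unique(at$cell), ]
      tab$POPDENS <- buffer_mean(popdens, cent, buffer_km)
    }
  } else {
    tab <- extract_at_points(layers, at)
    if (!is.null(rownames(at))) rownames(tab) <- rownames(at)
    if (!is.null(popdens)) {
      grid <- popdens$grid
      cc <- cell_centers(grid)
      key <- (at$col - 1) * grid$nrow + at$row
      tab$POPDENS <- buffer_mean(popdens,
                                 data.frame(x = cc$x[key], y = cc$y[key]),
                                 buffer_km)
    }
  }
  tab
}
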