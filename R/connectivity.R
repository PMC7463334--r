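# The eight neighbor directions. dr/dc are row/col offsets (row 1 = north);
# dx/dy are the unit direction vectors (east/north components).
direction_table <- function() {
  s <- 1 / sqrt(2)
  data.frame(
    dir = c("E", "NE", "N", "NW", "W", "SW", "S", "SE"),
    dr = c(0, -1, -1, -1, 0, 1, 1, 1),
    dc = c(1, 1, 0, -1, -1, -1, 0, 1),
    dx = c(1, s, 0, -s, -1, -s, 0, s),
    dy = c(0, s, 1, s, 0, -s, -1, -s))
}

#' Cumulative directional current speed
#'
#' Stacks the daily current field: each day and pixel, the current vector's
#' positive scalar projection onto each of the eight neighbor unit vectors
#' is added to that direction's accumulator (negative projections
#' contribute nothing).
#'
#' @param u_series,v_series co-registered daily [raster_series()] of the
#'   eastward (u) and northward (v) velocity components (m/s).
#' @return list with `acc` (pixels x 8 matrix of cumulative speeds, rows in
#'   pixel order `(col - 1) * nrow + row`, columns named by direction) and
#'   `grid`.
#' @export
accumulate_directional_speed <- function(u_series, v_series) {
  stopifnot(identical(dim(u_series$values), dim(v_series$values)))
  grid <- u_series$grid
  U <- series_matrix(u_series); V <- series_matrix(v_series)
  dirs <- direction_table()
  acc <- matrix(0, ncol(U), 8, dimnames = list(NULL, dirs$dir))
  for (d in seq_len(8)) {
    proj <- U * dirs$dx[d] + V * dirs$dy[d]
    proj[proj < 0] <- 0
    acc[, d] <- colSums(proj)
  }
  acc[as.vector(!grid$mask), ] <- NA_real_
  list(acc = acc, grid = grid)
}

#' Build the directed transition graph
#'
#' Per pixel, the conductance toward each of the eight directions is that
#' direction's cumulative speed divided by the pixel's total (normalization
#' uses all eight physical directions; edges pointing off-grid or into land
#' are removed only afterwards, without re-normalizing). The dispersal cost
#' of an edge is the inverse of its squared conductance. Directions with
#' zero cumulative speed carry no edge; a pixel with zero total speed has
#' no outgoing edges.
#'
#' @param accumulators result of [accumulate_directional_speed()].
#' @param diagonal_scale if `TRUE`, diagonal edge costs are scaled by
#'   sqrt(2) to account for the longer pixel traverse (off by default).
#' @return object of class `transition_graph`: list with `edges` (data
#'   frame `from`, `to` as pixel indices, `conductance`, `cost`), `grid`,
#'   `n_nodes`.
#' @export
build_transition_graph <- function(accumulators, diagonal_scale = FALSE) {
  grid <- accumulators$grid
  acc <- accumulators$acc
  stopifnot(all(acc >= 0, na.rm = TRUE))
  dirs <- direction_table()
  nr <- grid$nrow; ncg <- grid$ncol
  npix <- nr * ncg
  tot <- rowSums(acc)
  rows <- (seq_len(npix) - 1) %% nr + 1
  cols <- (seq_len(npix) - 1) %/% nr + 1
  sea <- as.vector(grid$mask)
  eds <- vector("list", 8)
  for (d in seq_len(8)) {
    cond <- acc[, d] / tot
    r2 <- rows + dirs$dr[d]; c2 <- cols + dirs$dc[d]
    valid <- sea & !is.na(cond) & cond > 0 &
      r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncg
    to <- (c2 - 1) * nr + r2
    valid[valid] <- sea[to[valid]]
    cost <- 1 / cond[valid]^2
    if (diagonal_scale && dirs$dr[d] != 0 && dirs$dc[d] != 0)
      cost <- cost * sqrt(2)
    eds[[d]] <- data.frame(from = which(valid), to = to[valid],
                           conductance = cond[valid], cost = cost)
  }
  structure(list(edges = do.call(rbind, eds), grid = grid, n_nodes = npix),
            class = "transition_graph")
}

#' @exportS3Method base::print
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph> %d sea pixels, %d directed edges\n",
              sum(x$grid$mask), nrow(x$edges)))
  invisible(x)
}

#' Map sites or reef cells to graph nodes
#'
#' Each location is mapped to the sea pixel nearest to it (itself when it
#' already is one); locations with no sea pixel within `max_cells` cells
#' are dropped with a warning.
#'
#' @param grid a [sea_grid()].
#' @param points data frame with `row`, `col`.
#' @param max_cells search radius in cells.
#' @return integer vector of pixel node indices (NA for dropped points).
#' @export
site_nodes <- function(grid, points, max_cells = 2) {
  sea <- which(grid$mask, arr.ind = TRUE)
  out <- rep(NA_integer_, nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (sea[, 1] - points$row[i])^2 + (sea[, 2] - points$col[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_cells)
      out[i] <- (sea[j, 2] - 1) * grid$nrow + sea[j, 1]
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " location(s) with no sea pixel within ",
            max_cells, " cells were dropped")
  out
}

#' Asymmetric least-cost sea distances
#'
#' Directed shortest-path cost (Dijkstra) from every origin to every
#' destination node over the transition graph. Unreachable pairs are
#' `+Inf` (with a warning); the diagonal is 0.
#'
#' @param graph a [build_transition_graph()] result.
#' @param origins,destinations pixel node indices (from [site_nodes()]).
#' @return `length(origins) x length(destinations)` matrix of least-cost
#'   distances.
#' @export
least_cost <- function(graph, origins, destinations) {
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = TRUE)
  g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
  D <- igraph::distances(g, v = origins, to = destinations, mode = "out",
                         weights = graph$edges$cost, algorithm = "dijkstra")
  dimnames(D) <- NULL
  if (any(is.infinite(D))) warning("unreachable origin-destination pair(s)")
  D
}

#' Fit the linear FST-by-distance connectivity model
#'
#' Ordinary least squares of pairwise FST on between-site distance. Since
#' FST is undirected while sea distances are directed, each pair's two
#' directed distances are collapsed by `pair_collapse` (default: the
#' minimum, i.e. the easier direction) before fitting. Model quality is
#' summarized by R-squared and the Gaussian-likelihood AIC (variance
#' counted as a parameter, the mainstream statistical convention).
#'
#' @param fst_table data frame from [pairwise_fst()].
#' @param distances directed site x site distance matrix with site names
#'   on both dimnames, or an already-collapsed symmetric matrix.
#' @param kind label stored with the model (`"least_cost"` or
#'   `"euclidean"`).
#' @param pair_collapse `"min"` or `"mean"` of the two directed distances.
#' @return object of class `connectivity_model`: list with `intercept`,
#'   `slope`, `r_squared`, `aic`, `n`, `kind`, `fit` (the `lm` object).
#' @export
fit_connectivity_model <- function(fst_table, distances,
                                   kind = "least_cost",
                                   pair_collapse = c("min", "mean")) {
  pair_collapse <- match.arg(pair_collapse)
  if (nrow(fst_table) < 3) stop("need at least 3 site pairs")
  i <- match(fst_table$site1, rownames(distances))
  j <- match(fst_table$site2, colnames(distances))
  if (anyNA(i) || anyNA(j))
    stop("sites of the FST table missing from the distance matrix")
  dij <- distances[cbind(i, j)]; dji <- distances[cbind(j, i)]
  d <- if (pair_collapse == "min") pmin(dij, dji) else (dij + dji) / 2
  if (stats::var(d) == 0) stop("zero-variance distances")
  fit <- stats::lm(fst_table$fst ~ d)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 aic = stats::AIC(fit), n = nrow(fst_table), kind = kind,
                 fit = fit),
            class = "connectivity_model")
}

#' @exportS3Method base::print
print.connectivity_model <- function(x, ...) {
  cat(sprintf("<connectivity_model %s> FST = %.4g + %.4g * distance  (n = %d, R2 = %.3f, AIC = %.2f)\n",
              x$kind, x$intercept, x$slope, x$n, x$r_squared, x$aic))
  invisible(x)
}

#' Predict directional genetic separation (dFST)
#'
#' Applies the fitted connectivity model elementwise to a directed distance
#' matrix: `dFST = intercept + slope * distance`, with the diagonal set to 0
#' by convention and negative predictions floored at 0.
#'
#' @param model a [fit_connectivity_model()] result.
#' @param distance_matrix directed distance matrix.
#' @return dFST matrix of the same dimension.
#' @export
predict_dfst <- function(model, distance_matrix) {
  out <- model$intercept + model$slope * distance_matrix
  out[out < 0] <- 0
  diag(out) <- 0
  out
}
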