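#' Pipeline run configuration
#'
#' Builds the full configuration for [run_pipeline()], with every tunable
#' of the analysis surfaced at its standard default: bleaching-alert window
#' 14 days and threshold 4 deg C-weeks, MAF 0.05, major-genotype 0.95,
#' missing 0.1, LD r2 0.3, q-value threshold 0.01, site sample-size rule
#' > 10, dFST threshold 0.02. Unknown keys are rejected.
#'
#' @param seascape a [seascape_config()] (or arguments for one, as a list).
#' @param ... overrides of the default tunables (see Details in the
#'   package vignette).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seascape = seascape_config(), ...) {
  cfg <- list(
    seascape = seascape,
    stages = c("simulate", "features", "genotypes", "gea",
               "connectivity", "indices"),
    baf_window = 14, baf_threshold = 4,
    maf = 0.05, major_geno = 0.95, miss = 0.1,
    ld_r2 = 0.3, ld_window = 50,
    covariate_k = 1,
    q_threshold = 0.01, qvalue_method = "storey",
    min_site_n = 10,
    dfst_threshold = 0.02,
    gea_env_vars = NULL)  # NULL = all feature columns
  extra <- list(...)
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(extra)] <- extra
  class(cfg) <- "pipeline_config"
  cfg
}

# Auxiliary synthetic environmental series so the standard 39-column
# descriptor scheme can be exercised end to end: daily salinity and
# chlorophyll, current speed from the simulated field, daily alkalinity
# derived from SST and SSS, and monthly suspended matter and radiation.
default_env_stack <- function(sim) {
  cfg <- sim$config; grid <- cfg$grid
  nd <- cfg$n_days
  dates <- cfg$start + seq_len(nd) - 1
  doy <- as.numeric(format(dates, "%j"))
  set.seed(substream_seed(cfg$seed, "aux_env"))
  mk_daily <- function(base, amp, grad, sdn) {
    arr <- array(0, c(nd, grid$nrow, grid$ncol))
    seasonal <- amp * cos(2 * pi * (doy - 227) / 365.25)
    for (r in seq_len(grid$nrow))
      arr[, r, ] <- base + seasonal + grad * (r - 1) +
        stats::rnorm(nd * grid$ncol, sd = sdn)
    raster_series(grid, dates, arr, "daily")
  }
  sss <- mk_daily(34.2, 0.4, 0.01, 0.05)
  chl <- mk_daily(0.35, 0.12, -0.004, 0.02)
  spd_arr <- sqrt(sim$currents$u$values^2 + sim$currents$v$values^2)
  spd <- raster_series(grid, dates, spd_arr, "daily")
  at <- alkalinity(sim$sst, sss)
  mstamp <- seq(as.Date(format(cfg$start, "%Y-%m-01")), by = "month",
                length.out = max(2, ceiling(nd / 30.44)))
  mk_monthly <- function(base, amp, sdn) {
    nm <- length(mstamp)
    mdoy <- as.numeric(format(mstamp, "%j"))
    arr <- array(0, c(nm, grid$nrow, grid$ncol))
    seasonal <- amp * cos(2 * pi * (mdoy - 227) / 365.25)
    for (r in seq_len(grid$nrow))
      arr[, r, ] <- base + seasonal + stats::rnorm(nm * grid$ncol, sd = sdn)
    raster_series(grid, mstamp, arr, "monthly")
  }
  list(daily = list(SST = sim$sst, SSS = sss, CHL = chl, SPD = spd,
                    AT = at),
       monthly = list(SPM = mk_monthly(2.5, 0.6, 0.1),
                      PAR = mk_monthly(40, 12, 1)))
}

# Static depth and population-density layers for the singleton descriptors.
default_static_layers <- function(cfg) {
  grid <- cfg$grid
  set.seed(substream_seed(cfg$seed, "static_layers"))
  rc <- expand.grid(row = seq_len(grid$nrow), col = seq_len(grid$ncol))
  land <- which(!grid$mask, arr.ind = TRUE)
  dist_land <- if (nrow(land)) {
    apply(rc, 1, function(p)
      sqrt(min((land[, 1] - p[1])^2 + (land[, 2] - p[2])^2)))
  } else rep(5, nrow(rc))
  depth <- raster_layer(grid, matrix(5 + 12 * dist_land, grid$nrow))
  # population clustered on coastal land: density decays with land distance
  pop <- matrix(stats::rpois(grid$nrow * grid$ncol,
                             800 * exp(-dist_land / 2)), grid$nrow)
  popdens <- structure(list(grid = sea_grid(grid$nrow, grid$ncol,
                                           grid$cellsize,
                                           grid$origin),
                            values = pop), class = "raster_layer")
  list(depth = depth, popdens = popdens)
}

# Reef-cell grid: sea pixels fringing land, one cell per pixel; every third
# cell carries a reduced actual area (reefs smaller than the nominal cell).
default_reef_cells <- function(grid) {
  sea <- which(grid$mask, arr.ind = TRUE)
  fringe <- apply(sea, 1, function(p) {
    nb <- expand.grid(r = p[1] + -1:1, c = p[2] + -1:1)
    nb <- nb[nb$r >= 1 & nb$r <= grid$nrow & nb$c >= 1 & nb$c <= grid$ncol, ]
    any(!grid$mask[cbind(nb$r, nb$c)])
  })
  px <- sea[fringe, , drop = FALSE]
  cells <- data.frame(cell = sprintf("R%03d", seq_len(nrow(px))),
                      row = px[, 1], col = px[, 2])
  small <- seq(3, nrow(cells), by = 3)
  areas <- stats::setNames(rep(grid$cellsize^2 * 0.4, length(small)),
                           cells$cell[small])
  reef_grid(cells, grid, areas)
}

#' Run the full seascape-genomics pipeline
#'
#' Orchestrates simulate -> environmental features -> genotype filtering ->
#' genotype-environment association -> connectivity -> conservation
#' indices, writing every artifact into one run directory:
#' `features.csv`, `reef_features.csv`, `models.csv`, `sgea.csv`, `pa.csv`,
#' `distances.csv`, `connectivity_model.json`, `dfst.csv`, `indices.csv`
#' and `run_log.yaml` (package version, seed and full configuration).
#' Disabling the `gea` stage drops `pa.csv` and leaves the API column of
#' `indices.csv` empty; the index stage only needs dFST (workflow
#' topology: genomics + environment give PA, genomics + currents give the
#' connectivity model and dFST, PA + dFST give API).
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; must not already contain a run).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(s) s %in% config$stages
  res <- list()

  sim <- simulate_seascape(config$seascape)
  res$sim <- sim
  sites <- config$seascape$sites

  if (on_stage("features")) {
    stack <- default_env_stack(sim)
    static <- default_static_layers(config$seascape)
    pts <- sites[, c("row", "col")]
    rownames(pts) <- sites$site
    feat_sites <- env_features(stack$daily, stack$monthly,
                               depth = static$depth,
                               popdens = static$popdens, at = pts,
                               baf_window = config$baf_window,
                               baf_threshold = config$baf_threshold)
    reefs <- default_reef_cells(config$seascape$grid)
    feat_reefs <- env_features(stack$daily, stack$monthly,
                               depth = static$depth,
                               popdens = static$popdens, at = reefs,
                               baf_window = config$baf_window,
                               baf_threshold = config$baf_threshold)
    utils::write.csv(cbind(site = rownames(feat_sites), feat_sites),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(cbind(cell = rownames(feat_reefs), feat_reefs),
                     file.path(out_dir, "reef_features.csv"),
                     row.names = FALSE)
    res$features <- feat_sites; res$reef_features <- feat_reefs
    res$reefs <- reefs
  }

  gm <- sim$genotypes
  if (on_stage("genotypes")) {
    gm <- filter_snps(gm, config$maf, config$major_geno, config$miss)
    gm <- ld_prune(gm, config$ld_r2, config$ld_window)
    res$covariate <- structure_covariate(gm, k = config$covariate_k)
    res$genotypes <- gm
  }

  if (on_stage("gea") && on_stage("features")) {
    site_of <- match(gm$ind$site, sites$site)
    fcols <- config$gea_env_vars %||% names(res$features)
    feats_ind <- res$features[site_of, fcols, drop = FALSE]
    usable <- vapply(feats_ind, function(x) stats::sd(x) > 0, logical(1))
    models <- gea_scan(gm, feats_ind[, usable, drop = FALSE],
                       covariates = res$covariate,
                       qvalue_method = config$qvalue_method)
    sgea <- select_sgea(models, config$q_threshold)
    utils::write.csv(models, file.path(out_dir, "models.csv"),
                     row.names = FALSE)
    utils::write.csv(sgea, file.path(out_dir, "sgea.csv"),
                     row.names = FALSE)
    res$models <- models; res$sgea <- sgea
    if (nrow(sgea)) {
      pa <- compute_pa(sgea, res$reef_features)
      utils::write.csv(pa, file.path(out_dir, "pa.csv"), row.names = FALSE)
      res$pa <- pa
    }
  }

  if (on_stage("connectivity")) {
    fst <- pairwise_fst(gm, min_n = config$min_site_n)
    D <- sim$sea_distance
    dimnames(D) <- list(sites$site, sites$site)
    cm_lcp <- fit_connectivity_model(fst, D, "least_cost")
    cc <- cell_centers(config$seascape$grid)
    key <- (sites$col - 1) * config$seascape$grid$nrow + sites$row
    E <- grid_distance(config$seascape$grid,
                       data.frame(x = cc$x[key], y = cc$y[key]),
                       data.frame(x = cc$x[key], y = cc$y[key]))
    dimnames(E) <- list(sites$site, sites$site)
    cm_euc <- fit_connectivity_model(fst, E, "euclidean")
    utils::write.csv(cbind(site = rownames(D), as.data.frame(D)),
                     file.path(out_dir, "distances.csv"),
                     row.names = FALSE)
    utils::write.csv(fst, file.path(out_dir, "fst.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(least_cost = cm_lcp[c("intercept", "slope", "r_squared",
                                 "aic", "n")],
           euclidean = cm_euc[c("intercept", "slope", "r_squared",
                                "aic", "n")]),
      file.path(out_dir, "connectivity_model.json"), auto_unbox = TRUE,
      digits = NA)
    res$fst <- fst; res$model_lcp <- cm_lcp; res$model_euc <- cm_euc
  }

  if (on_stage("indices") && on_stage("connectivity") &&
      on_stage("features")) {
    reefs <- res$reefs
    grid <- config$seascape$grid
    upx <- !duplicated(reefs$cell)
    nodes <- site_nodes(grid, data.frame(row = reefs$row[upx],
                                         col = reefs$col[upx]))
    Dr <- least_cost(sim$graph, nodes, nodes)
    dfst <- predict_dfst(res$model_lcp, Dr)
    cells <- reefs$cell[upx]
    dimnames(dfst) <- list(cells, cells)
    areas <- attr(reefs, "area")[cells]
    pa <- if (!is.null(res$pa)) res$pa$PA[match(cells, res$pa$cell)]
    idx <- index_table(dfst, areas, pa, T = config$dfst_threshold,
                       cells = cells)
    utils::write.csv(as.data.frame(dfst) |>
                       (\(d) cbind(cell = rownames(dfst), d))(),
                     file.path(out_dir, "dfst.csv"), row.names = FALSE)
    utils::write.csv(idx, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
    res$indices <- idx; res$dfst <- dfst
  }

  log <- list(package = "reefscape",
              version = as.character(utils::packageVersion("reefscape")),
              seed = config$seascape$seed,
              config = config_to_list(config))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(res)
}

# Serialize a pipeline_config (including the nested seascape_config) to
# plain lists for the run log.
config_to_list <- function(config) {
  cfg <- unclass(config)
  sc <- unclass(cfg$seascape)
  sc$grid <- list(nrow = sc$grid$nrow, ncol = sc$grid$ncol,
                  cellsize = sc$grid$cellsize,
                  sea_pixels = sum(sc$grid$mask))
  sc$sites <- lapply(split(sc$sites, seq_len(nrow(sc$sites))), as.list)
  sc$sst$events <- if (!is.null(sc$sst$events))
    lapply(split(sc$sst$events, seq_len(nrow(sc$sst$events))), as.list)
  sc$start <- as.character(sc$start)
  cfg$seascape <- sc
  cfg
}
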