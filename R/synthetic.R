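#' Synthetic seascape configuration
#'
#' Bundles every tunable of the synthetic study system: grid geometry and
#' land mask, the daily current field (a dominant directional flow plus
#' spatially smooth noise), the daily SST field (seasonal sinusoid, linear
#' spatial gradient, localized heatwave events), sampling sites, and the
#' genetic architecture (neutral loci under isolation-by-sea-distance,
#' adaptive loci under a logistic genotype-environment link).
#'
#' Defaults emulate an idealized island-chain seascape swept by a dominant
#' north-eastward boundary current: 12 sites of 15 colonies each, 2,000
#' neutral loci, 5 adaptive loci with logistic slope `b = 8` over an
#' environmental gradient rescaled to `[0, 1]`, and localized summer
#' heatwaves in the southern half of the domain.
#'
#' @param nrow,ncol grid dimensions.
#' @param cellsize_km cell edge (km).
#' @param land logical matrix (`TRUE` = sea) or `NULL` for the default
#'   island-chain mask.
#' @param n_days length of the daily series (>= 730 when a monthly
#'   climatology will be derived downstream).
#' @param start date of the first day.
#' @param current list: `direction` (unit vector, east/north components),
#'   `speed` (mean, m/s), `noise_sd` (m/s), `noise_scale` (pixels; spatial
#'   smoothing length of the noise).
#' @param sst list: `baseline` (deg C), `amplitude` (seasonal half-range,
#'   deg C), `gradient` (deg C per row, increasing southward), `events`
#'   data frame with `row`, `col`, `radius` (pixels), `start` (day index),
#'   `duration` (days), `intensity` (deg C).
#' @param sites data frame with `site`, `row`, `col`, `n` (colonies); `NULL`
#'   for 12 default sites along the chain.
#' @param loci list: `n_neutral`, `n_adaptive`, `a` and `b` (logistic
#'   intercept/slope, recycled across adaptive loci), `beta_sim` (target
#'   FST per unit sea distance; `NA` = scale to `fst_max` at the widest
#'   site pair), `fst_max` (target FST at the maximum distance when
#'   `beta_sim` is `NA`), `missing_rate`.
#' @param seed root seed; all stages draw from named substreams of it.
#' @return an object of class `seascape_config`.
#' @export
seascape_config <- function(nrow = 24, ncol = 40, cellsize_km = 10,
                            land = NULL, n_days = 1461,
                            start = as.Date("2008-01-01"),
                            current = list(direction = c(1, 1) / sqrt(2),
                                           speed = 0.5, noise_sd = 0.25,
                                           noise_scale = 3),
                            sst = list(baseline = 26, amplitude = 3,
                                       gradient = 0.08, events = NULL),
                            sites = NULL,
                            loci = list(n_neutral = 2000, n_adaptive = 5,
                                        a = -4, b = 8, beta_sim = NA,
                                        fst_max = 0.05, missing_rate = 0.02),
                            seed = 1L) {
  if (nrow < 2 || ncol < 2) stop("degenerate grid: need at least 2x2 pixels")
  if (is.null(land)) land <- default_land_mask(nrow, ncol)
  grid <- sea_grid(nrow, ncol, cellsize_km, mask = land)
  if (is.null(sst$events)) sst$events <- default_heatwaves(nrow, ncol, n_days)
  if (is.null(sites)) sites <- default_sites(grid)
  stopifnot(all(sites$n >= 1))
  bad <- !grid$mask[cbind(sites$row, sites$col)]
  if (any(bad)) stop("site pixels must be sea pixels: ",
                     paste(sites$site[bad], collapse = ", "))
  structure(list(grid = grid, n_days = n_days, start = start,
                 current = current, sst = sst, sites = sites, loci = loci,
                 seed = as.integer(seed)),
            class = "seascape_config")
}

# Island-chain mask: a diagonal chain of elliptical islands plus a western
# landmass, leaving a connected sea with real detours around land.
default_land_mask <- function(nrow, ncol) {
  mask <- matrix(TRUE, nrow, ncol)
  centers <- cbind(row = round(seq(nrow * 0.8, nrow * 0.2, length.out = 5)),
                   col = round(seq(ncol * 0.2, ncol * 0.85, length.out = 5)))
  rc <- expand.grid(row = seq_len(nrow), col = seq_len(ncol))
  for (k in seq_len(nrow(centers))) {
    d2 <- ((rc$row - centers[k, 1]) / 1.6)^2 + ((rc$col - centers[k, 2]) / 2.2)^2
    mask[cbind(rc$row, rc$col)[d2 <= 1, , drop = FALSE]] <- FALSE
  }
  mask[, 1] <- FALSE  # continental margin on the western edge
  mask
}

# Sites hug the island chain (adjacent sea pixels), 12 sites, 15 colonies.
default_sites <- function(grid) {
  centers <- cbind(row = round(seq(grid$nrow * 0.8, grid$nrow * 0.2,
                                   length.out = 5)),
                   col = round(seq(grid$ncol * 0.2, grid$ncol * 0.85,
                                   length.out = 5)))
  cand <- list()
  for (k in seq_len(nrow(centers))) {
    for (off in list(c(-3, 0), c(3, 0), c(0, -4), c(0, 4))) {
      r <- centers[k, 1] + off[1]; cc <- centers[k, 2] + off[2]
      if (r >= 1 && r <= grid$nrow && cc >= 1 && cc <= grid$ncol &&
          grid$mask[r, cc])
        cand[[length(cand) + 1]] <- c(r, cc)
    }
  }
  cand <- unique(do.call(rbind, cand))
  keep <- round(seq(1, nrow(cand), length.out = min(12, nrow(cand))))
  data.frame(site = sprintf("S%02d", seq_along(keep)),
             row = cand[keep, 1], col = cand[keep, 2], n = 15L)
}

# Two summer heatwaves in the south-west (upstream, high-stress) corner,
# each confined to one summer so the multi-year climatology is only mildly
# contaminated and the degree-heating excess stays detectable.
default_heatwaves <- function(nrow, ncol, n_days) {
  data.frame(
    row = c(round(nrow * 0.8), round(nrow * 0.65)),
    col = c(round(ncol * 0.25), round(ncol * 0.45)),
    radius = c(7, 6),
    start = pmin(c(565, 930), n_days),
    duration = c(45, 40),
    intensity = c(4, 3.5))
}

#' Named substream seed
#'
#' Derives a deterministic 32-bit seed for a named stage from the root seed,
#' so stages can be regenerated independently of each other.
#'
#' @param root integer root seed.
#' @param name substream name (e.g. "currents", "sst", "genotypes").
#' @return integer seed.
#' @export
substream_seed <- function(root, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483647L)
}

# Spatially smooth zero-mean noise field via moving-average smoothing of
# white noise, rescaled to unit sd before scaling by the requested sd.
smooth_noise <- function(nrow, ncol, scale) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (scale <= 1) return(z)
  k <- max(1L, as.integer(scale))
  pad <- function(m, k) {
    m2 <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), ]
    m2[, c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k))]
  }
  zp <- pad(z, k)
  out <- matrix(0, nrow, ncol)
  for (dr in -k:k) for (dc in -k:k)
    out <- out + zp[k + seq_len(nrow) + dr, k + seq_len(ncol) + dc]
  out / stats::sd(out)
}

#' Generate daily current fields
#'
#' Each day's vector field is the configured dominant vector plus spatially
#' smooth zero-mean Gaussian noise (independent across days); land pixels are
#' masked.
#'
#' @param config a [seascape_config()].
#' @return list of two [raster_series()]: `u` (eastward) and `v` (northward),
#'   m/s.
#' @export
generate_currents <- function(config) {
  if (config$n_days < 1) stop("n_days must be >= 1")
  grid <- config$grid
  set.seed(substream_seed(config$seed, "currents"))
  dom <- config$current$direction * config$current$speed
  nd <- config$n_days
  u <- array(dom[1], c(nd, grid$nrow, grid$ncol))
  v <- array(dom[2], c(nd, grid$nrow, grid$ncol))
  if (config$current$noise_sd > 0) {
    for (t in seq_len(nd)) {
      u[t, , ] <- u[t, , ] + config$current$noise_sd *
        smooth_noise(grid$nrow, grid$ncol, config$current$noise_scale)
      v[t, , ] <- v[t, , ] + config$current$noise_sd *
        smooth_noise(grid$nrow, grid$ncol, config$current$noise_scale)
    }
  }
  dates <- config$start + seq_len(nd) - 1
  list(u = raster_series(grid, dates, u, "daily"),
       v = raster_series(grid, dates, v, "daily"))
}

#' Generate a daily SST series
#'
#' SST = baseline + seasonal sinusoid (peak in late summer of a 365.25-day
#' year) + linear north-south gradient + heatwave boosts inside each event's
#' circular footprint and time window. Overlapping events sum.
#'
#' @param config a [seascape_config()].
#' @return a daily [raster_series()] in deg C.
#' @export
generate_sst <- function(config) {
  grid <- config$grid
  set.seed(substream_seed(config$seed, "sst"))
  nd <- config$n_days
  dates <- config$start + seq_len(nd) - 1
  doy <- as.numeric(format(dates, "%j"))
  seasonal <- config$sst$amplitude * cos(2 * pi * (doy - 227) / 365.25)
  rowgrad <- config$sst$gradient * (seq_len(grid$nrow) - 1)  # warmer south
  arr <- array(0, c(nd, grid$nrow, grid$ncol))
  for (r in seq_len(grid$nrow))
    arr[, r, ] <- config$sst$baseline + seasonal + rowgrad[r]
  ev <- config$sst$events
  if (!is.null(ev) && nrow(ev)) {
    rc <- expand.grid(row = seq_len(grid$nrow), col = seq_len(grid$ncol))
    for (k in seq_len(nrow(ev))) {
      inside <- (rc$row - ev$row[k])^2 + (rc$col - ev$col[k])^2 <=
        ev$radius[k]^2
      days <- seq(ev$start[k], min(nd, ev$start[k] + ev$duration[k] - 1))
      px <- rc[inside, , drop = FALSE]
      for (i in seq_len(nrow(px)))
        arr[days, px$row[i], px$col[i]] <-
          arr[days, px$row[i], px$col[i]] + ev$intensity[k]
    }
  }
  raster_series(grid, dates, arr, "daily")
}

# Classical MDS embedding treating d as SQUARED distances: returns X such
# that ||x_i - x_j||^2 approximates d_ij (exact when d is conditionally
# negative definite; least-cost matrices usually are not). The embedding is
# rescaled so the with-intercept least-squares slope of achieved on planted
# values equals 1: the drift-distance relation then increases at the
# planted rate, with any embedding distortion absorbed into a nonnegative
# offset (which surfaces as the intercept of the FST-distance relation).
mds_embed_sqdist <- function(d) {
  n <- nrow(d)
  d <- (d + t(d)) / 2
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% d %*% J
  eg <- eigen(B, symmetric = TRUE)
  k <- sum(eg$values > 1e-10 * max(abs(eg$values), 1e-300))
  k <- max(k, 1)
  X <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  ach <- as.matrix(stats::dist(X))^2
  ut <- upper.tri(d)
  if (isTRUE(stats::var(d[ut]) > 0)) {
    s <- unname(stats::coef(stats::lm(ach[ut] ~ d[ut]))[2])
    if (is.finite(s) && s > 0) X <- X / sqrt(s)
  }
  X
}

#' Generate genotypes with planted structure
#'
#' Neutral loci follow a Gaussian drift-field scheme: sites are embedded in
#' Euclidean space so squared embedding distances track the planted sea
#' distances (classical MDS with slope calibration), and for each locus an
#' ancestral frequency `p0 ~ U(0.3, 0.7)` is perturbed at each site by
#' zero-mean Gaussian deviates built on that embedding so that
#' `E[(p_i - p_j)^2] = 2 beta p0 (1 - p0) d_ij`, i.e. the expected pairwise
#' FST between sites i and j is `beta * d_ij` by construction (up to the
#' embedding distortion of non-embeddable least-cost matrices, which shows
#' up as a nonnegative intercept, not a slope change). Genotypes are
#' Hardy-Weinberg draws from the site frequencies. Adaptive loci plant a
#' per-individual Bernoulli presence of the homozygous-alternate genotype
#' with probability `plogis(a + b * env)`; absent individuals are assigned
#' heterozygous or homozygous-reference codes with equal probability.
#'
#' @param config a [seascape_config()].
#' @param sea_distance symmetric matrix of between-site sea distances (any
#'   positive cost unit), dimension `n_sites x n_sites`.
#' @param env numeric vector of the adaptive environmental variable at the
#'   sites (the planted logistic is evaluated on it as given).
#' @return a [genotype_matrix()] with a `truth` attribute: data frame with
#'   one row per locus (`locus`, `type`, `a`, `b`) plus attributes
#'   `beta_sim` and `site_freq` (neutral site frequency matrix).
#' @export
generate_genotypes <- function(config, sea_distance, env) {
  sites <- config$sites
  ns <- nrow(sites)
  stopifnot(all(dim(sea_distance) == c(ns, ns)), length(env) == ns)
  lo <- config$loci
  dmax <- max(sea_distance)
  beta <- lo$beta_sim
  if (is.na(beta) || is.null(beta)) beta <- lo$fst_max / dmax
  if (beta * dmax > 1)
    stop("beta_sim x max distance exceeds 1: FST target infeasible")
  set.seed(substream_seed(config$seed, "genotypes"))

  # Embed sites in Euclidean space so that squared embedding distances
  # reproduce the planted sea distances: classical MDS on d (treated as
  # squared distances), least-squares optimal when d is not exactly
  # embeddable (least-cost matrices are quasi-metrics), then rescaled so
  # the no-intercept regression of achieved on planted distances has
  # slope 1.
  L <- mds_embed_sqdist(sea_distance)

  e_base <- L %*% matrix(stats::rnorm(ncol(L) * (lo$n_neutral)),
                         ncol(L), lo$n_neutral)

  n_ind <- sum(sites$n)
  ind_site <- rep(seq_len(ns), sites$n)
  n_neu <- lo$n_neutral; n_ada <- lo$n_adaptive
  geno <- matrix(NA_integer_, n_ind, n_neu + n_ada)
  freq <- matrix(NA_real_, ns, n_neu)
  p0s <- stats::runif(n_neu, 0.3, 0.7)
  for (l in seq_len(n_neu)) {
    p0 <- p0s[l]
    # E[(p_i - p_j)^2] = 2 beta p0 q0 d_ij, i.e. expected FST = beta * d
    e <- e_base[, l] * sqrt(2 * beta * p0 * (1 - p0))
    p <- pmin(pmax(p0 + e, 0.005), 0.995)
    freq[, l] <- p
    geno[, l] <- stats::rbinom(n_ind, 2, p[ind_site])
  }
  a <- rep_len(lo$a, max(n_ada, 1)); b <- rep_len(lo$b, max(n_ada, 1))
  if (n_ada > 0) {
    for (l in seq_len(n_ada)) {
      pr <- stats::plogis(a[l] + b[l] * env[ind_site])
      z <- stats::rbinom(n_ind, 1, pr)
      geno[, n_neu + l] <- ifelse(z == 1, 2L,
                                  stats::rbinom(n_ind, 1, 0.5))
    }
  }
  if (lo$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < lo$missing_rate
    geno[miss] <- NA_integer_
  }
  nl <- ncol(geno)
  # interleave adaptive loci evenly along the genome (they are mutually
  # correlated through the shared environment, so adjacency would make
  # LD pruning collapse them onto one representative)
  if (n_ada > 0 && n_neu > 0) {
    slots <- round(seq(1, nl, length.out = n_ada + 2))[2:(n_ada + 1)]
    ord <- integer(nl)
    ord[slots] <- n_neu + seq_len(n_ada)
    ord[-slots] <- seq_len(n_neu)
    geno <- geno[, ord, drop = FALSE]
  } else ord <- seq_len(nl)
  type <- c(rep("neutral", n_neu), rep("adaptive", n_ada))[ord]
  aa <- c(rep(NA_real_, n_neu), a[seq_len(max(n_ada, 0))])[ord]
  bb <- c(rep(NA_real_, n_neu), b[seq_len(max(n_ada, 0))])[ord]
  scaffold <- sprintf("scf%03d", ceiling(seq_len(nl) / 100))
  pos <- ((seq_len(nl) - 1) %% 100) * 1000 + 500
  truth <- data.frame(
    locus = sprintf("%s:%d", scaffold, pos),
    type = type, a = aa, b = bb)
  attr(truth, "beta_sim") <- beta
  attr(truth, "site_freq") <- freq
  cc <- cell_centers(config$grid)
  key <- (sites$col - 1) * config$grid$nrow + sites$row
  ind <- data.frame(
    id = sprintf("ind%03d", seq_len(n_ind)),
    site = sites$site[ind_site],
    x = cc$x[key][ind_site], y = cc$y[key][ind_site])
  gm <- genotype_matrix(geno, ind,
                        data.frame(scaffold = scaffold, pos = pos,
                                   ref = "A", alt = "T"))
  attr(gm, "truth") <- truth
  gm
}

#' Simulate a complete seascape study system
#'
#' Convenience wrapper running currents, SST, the transition graph, site sea
#' distances, and genotypes in order, wiring the planted adaptive signal to
#' the (0-1 rescaled) bleaching alert frequency at the sites.
#'
#' @param config a [seascape_config()].
#' @return list with `config`, `currents`, `sst`, `graph`, `site_nodes`,
#'   `sea_distance` (directed site x site), `pair_distance` (min of the two
#'   directions), `env_sites` (rescaled BAF), `genotypes`.
#' @export
simulate_seascape <- function(config) {
  cur <- generate_currents(config)
  sst <- generate_sst(config)
  acc <- accumulate_directional_speed(cur$u, cur$v)
  graph <- build_transition_graph(acc)
  nodes <- site_nodes(config$grid, config$sites)
  D <- least_cost(graph, nodes, nodes)
  Dp <- pmin(D, t(D))
  baf <- bleaching_alert_frequency(sst)
  env <- baf$values[cbind(config$sites$row, config$sites$col)]
  env <- rescale01(env)
  gm <- generate_genotypes(config, Dp, env)
  list(config = config, currents = cur, sst = sst, graph = graph,
       site_nodes = nodes, sea_distance = D, pair_distance = Dp,
       env_sites = env, genotypes = gm)
}

#' Rescale a vector to the unit interval
#'
#' @param x numeric vector.
#' @return `(x - min) / (max - min)`; all-equal input maps to 0.
#' @export
rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}
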