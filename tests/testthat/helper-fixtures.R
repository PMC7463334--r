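# Shared fixture builders: everything is generated in code at test time.

tiny_grid <- function(nrow = 4, ncol = 4, mask = NULL, cellsize = 1) {
  sea_grid(nrow, ncol, cellsize, mask = mask)
}

# constant-valued daily series
const_series <- function(grid, value, n_days, start = as.Date("2001-01-01")) {
  raster_series(grid, start + seq_len(n_days) - 1,
                array(value, c(n_days, grid$nrow, grid$ncol)), "daily")
}

# daily series from a vector of per-day values (spatially constant)
ts_series <- function(grid, daily_values, start = as.Date("2001-01-01")) {
  nd <- length(daily_values)
  arr <- array(rep(daily_values, grid$nrow * grid$ncol),
               c(nd, grid$nrow, grid$ncol))
  raster_series(grid, start + seq_len(nd) - 1, arr, "daily")
}

# genotype matrix from a raw dosage matrix and per-individual site labels
toy_gm <- function(geno, sites, scaffold = NULL, pos = NULL) {
  n <- nrow(geno); L <- ncol(geno)
  genotype_matrix(geno,
                  data.frame(id = sprintf("i%03d", seq_len(n)),
                             site = sites),
                  data.frame(scaffold = scaffold %||% rep("s1", L),
                             pos = pos %||% (seq_len(L) * 100),
                             ref = "A", alt = "T"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# a small, fast seascape for pipeline-level tests; two single-summer
# heatwaves strong enough to stand out of the two-year climatology
small_seascape <- function(seed = 1, n_neutral = 150, n_adaptive = 2,
                           n_days = 730) {
  seascape_config(nrow = 14, ncol = 20, cellsize_km = 10,
                  n_days = n_days,
                  sst = list(baseline = 26, amplitude = 3, gradient = 0.08,
                             events = data.frame(
                               row = c(11, 9), col = c(5, 9),
                               radius = c(5, 4),
                               start = pmin(c(540, 580), n_days),
                               duration = c(45, 40),
                               intensity = c(5, 4.5))),
                  loci = list(n_neutral = n_neutral,
                              n_adaptive = n_adaptive,
                              a = -4, b = 8, beta_sim = NA,
                              fst_max = 0.12, missing_rate = 0.02),
                  seed = seed)
}

# accumulator structure for hand-built transition graphs
acc_fixture <- function(grid, acc) {
  stopifnot(nrow(acc) == grid$nrow * grid$ncol, ncol(acc) == 8)
  colnames(acc) <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")
  acc[as.vector(!grid$mask), ] <- NA_real_
  list(acc = acc, grid = grid)
}

# independent brute-force shortest path by exhaustive simple-path
# enumeration over an edge list (used as the Dijkstra oracle)
brute_force_shortest <- function(edges, n_nodes, from, to) {
  best <- Inf
  adj <- split(seq_len(nrow(edges)), edges$from)
  recurse <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == to) { best <<- cost; return() }
    for (ei in adj[[as.character(node)]]) {
      nxt <- edges$to[ei]
      if (!visited[nxt]) {
        visited[nxt] <- TRUE
        recurse(nxt, visited, cost + edges$cost[ei])
        visited[nxt] <- FALSE
      }
    }
  }
  v <- rep(FALSE, n_nodes); v[from] <- TRUE
  recurse(from, v, 0)
  best
}

# independent transcription of the Weir & Cockerham (1984) single-locus
# components, scalar code kept deliberately close to the published algebra
wc84_transcription <- function(geno_list) {
  # geno_list: list of dosage vectors, one per population (no NA)
  r <- length(geno_list)
  n <- vapply(geno_list, length, numeric(1))
  p <- vapply(geno_list, function(g) mean(g) / 2, numeric(1))
  h <- vapply(geno_list, function(g) mean(g == 1), numeric(1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# independent step-by-step transcription of Storey's q-value algorithm
storey_transcription <- function(p) {
  m <- length(p)
  lambda <- seq(0.05, 0.95, 0.05)
  pi0_l <- sapply(lambda, function(l) sum(p > l) / (m * (1 - l)))
  sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- min(max(stats::predict(sp, x = 0.95)$y, 1e-8), 1)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- min(pi0 * p[o[m]], 1)
  for (i in (m - 1):1)
    q[o[i]] <- min(pi0 * p[o[i]] * m / i, q[o[i + 1]])
  q
}
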