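test_that("summary statistics handle constant and two-month toy series", {
  g <- tiny_grid(2, 2)
  s <- const_series(g, 7, 90)
  st <- summary_stats(s)
  expect_true(all(st$AVG == 7) && all(st$HM == 7) && all(st$LM == 7))
  expect_true(all(st$SD.AVG == 0) && all(st$SD.HM == 0) &&
                all(st$SD.LM == 0))

  # Jan at 10, Feb at 20 (31 + 28 days, hand computation)
  vals <- c(rep(10, 31), rep(20, 28))
  s2 <- ts_series(g, vals)
  st2 <- summary_stats(s2)
  expect_equal(st2$HM[1, 1], 20)
  expect_equal(st2$LM[1, 1], 10)
  expect_equal(st2$AVG[1, 1], mean(vals))
  # SDs within each extreme month are 0 here
  expect_equal(st2$SD.HM[1, 1], 0)
})

test_that("monthly series get three statistics, daily series six", {
  g <- tiny_grid(2, 2)
  mon <- raster_series(g, as.Date(c("2001-01-01", "2001-02-01",
                                    "2001-03-01")),
                       array(1:12, c(3, 2, 2)), "monthly")
  expect_named(summary_stats(mon), c("AVG", "HM", "LM"))
  expect_named(summary_stats(const_series(g, 1, 40)),
               c("AVG", "HM", "LM", "SD.AVG", "SD.HM", "SD.LM"))
})

test_that("extreme-month means bracket the overall average everywhere", {
  g <- tiny_grid(3, 4)
  set.seed(2)
  nd <- 365
  arr <- array(rnorm(nd * 12, mean = 20), c(nd, 3, 4))
  st <- summary_stats(raster_series(g, as.Date("2001-01-01") + 0:(nd - 1),
                                    arr, "daily"))
  expect_true(all(st$LM <= st$AVG + 1e-12))
  expect_true(all(st$AVG <= st$HM + 1e-12))
})

test_that("alkalinity polynomial matches a hand expansion and its identities", {
  g <- tiny_grid(2, 2)
  co <- list(intercept = 2305, s1 = 58.66, s2 = 2.32, t1 = -1.41,
             t2 = 0.04, s0 = 35, t0 = 20)
  sst <- const_series(g, 27.3, 40)
  sss <- const_series(g, 34.1, 40)
  at <- alkalinity(sst, sss, co)
  hand <- 2305 + 58.66 * (34.1 - 35) + 2.32 * (34.1 - 35)^2 -
    1.41 * (27.3 - 20) + 0.04 * (27.3 - 20)^2
  expect_equal(at$values[1, 1, 1], hand, tolerance = 1e-9)
  # centering identity
  at0 <- alkalinity(const_series(g, 20, 10), const_series(g, 35, 10), co)
  expect_true(all(at0$values == 2305))
  # intercept-only
  co0 <- list(intercept = 5, s1 = 0, s2 = 0, t1 = 0, t2 = 0, s0 = 0, t0 = 0)
  expect_true(all(alkalinity(sst, sss, co0)$values == 5))
})

test_that("bleaching alert frequency matches hand counts and bounds", {
  g <- tiny_grid(2, 2)
  # two flat years -> MMM equals the constant, no stress
  s <- const_series(g, 26, 730)
  expect_true(all(bleaching_alert_frequency(s)$values == 0))

  # constant +2 above a supplied MMM: accumulation = 2*14/7 = 4 >= 4
  mmm <- raster_layer(g, matrix(24, 2, 2))
  baf <- bleaching_alert_frequency(s, climatology = mmm)
  expect_true(all(baf$values == 1))

  # hand-counted single heatwave: baseline 26, +3 for days 101..130
  vals <- rep(26, 365); vals[101:130] <- 29
  s2 <- ts_series(g, vals)
  mmm26 <- raster_layer(g, matrix(26, 2, 2))
  baf2 <- bleaching_alert_frequency(s2, climatology = mmm26)
  # window sums/7: day t alerted iff sum(hotspot[t-13..t])/7 >= 4
  # hotspot = 3 on days 101..130 -> need >= 28/3 = 9.33 event days in window
  hot <- pmax(vals - 26, 0)
  alerts <- sum(vapply(14:365, function(t)
    sum(hot[(t - 13):t]) / 7 >= 4, logical(1)))
  expect_equal(baf2$values[1, 1], alerts / (365 - 13))
  expect_gt(baf2$values[1, 1], 0)

  expect_error(bleaching_alert_frequency(const_series(g, 26, 10)),
               "shorter than")
})

test_that("BAF is monotone in added heat and higher at event centers", {
  cfg <- small_seascape(seed = 3)
  sst <- generate_sst(cfg)
  baf <- bleaching_alert_frequency(sst)
  ev <- cfg$sst$events[1, ]
  sea <- which(cfg$grid$mask, arr.ind = TRUE)
  d2 <- (sea[, 1] - ev$row)^2 + (sea[, 2] - ev$col)^2
  center <- sea[which.min(d2), ]           # nearest sea pixel to the center
  coolest <- which(baf$values == min(baf$values, na.rm = TRUE),
                   arr.ind = TRUE)[1, ]    # a pixel outside every event
  expect_gt(baf$values[center[1], center[2]],
            baf$values[coolest[1], coolest[2]])

  # adding a nonnegative field never decreases BAF (same climatology)
  mmm <- mmm_climatology(sst)
  bump <- sst
  bump$values <- sst$values + 0.5
  b1 <- bleaching_alert_frequency(sst, mmm)
  b2 <- bleaching_alert_frequency(bump, mmm)
  expect_true(all(b2$values >= b1$values, na.rm = TRUE))
})

test_that("buffer means equal brute-force enumeration", {
  g <- tiny_grid(10, 10, cellsize = 1)
  set.seed(4)
  vals <- matrix(runif(100), 10, 10)
  layer <- raster_layer(g, vals)
  pts <- data.frame(x = c(5, 2.3, 9.9), y = c(5, 7.1, 0.4))
  for (r in c(0.4, 2.5, 6)) {
    got <- buffer_mean(layer, pts, radius_km = r)
    cc <- cell_centers(g)
    want <- vapply(seq_len(nrow(pts)), function(i) {
      d <- sqrt((cc$x - pts$x[i])^2 + (cc$y - pts$y[i])^2)
      mean(vals[cbind(cc$row, cc$col)][d <= r])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # uniform raster returns the uniform value
  expect_equal(buffer_mean(raster_layer(g, matrix(3, 10, 10)), pts, 3),
               rep(3, 3))
  # radius below half a cell -> containing pixel
  one <- buffer_mean(layer, data.frame(x = 2.5, y = 2.5), 0.4)
  expect_equal(one, vals[8, 3])  # y=2.5 -> row 8 (row 1 is north), x -> col 3
})

test_that("zonal means equal brute-force enumeration over member pixels", {
  g <- tiny_grid(10, 10)
  set.seed(5)
  vals <- matrix(runif(100), 10, 10)
  layer <- raster_layer(g, vals)
  cells <- data.frame(cell = c("a", "b", "b", "b", "c", "c"),
                      row = c(1, 2, 2, 3, 9, 10),
                      col = c(1, 4, 5, 4, 9, 9))
  rg <- reef_grid(cells, g)
  got <- zonal_mean(layer, rg)
  expect_equal(unname(got["a"]), vals[1, 1])
  expect_equal(unname(got["b"]), mean(vals[cbind(c(2, 2, 3), c(4, 5, 4))]),
               tolerance = 1e-12)
  expect_equal(unname(got["c"]), mean(c(vals[9, 9], vals[10, 9])))
})

test_that("point extraction refuses land points by name", {
  m <- matrix(TRUE, 4, 4); m[2, 2] <- FALSE
  g <- tiny_grid(4, 4, mask = m)
  layer <- raster_layer(g, matrix(1:16, 4, 4))
  pts <- data.frame(row = c(1, 2), col = c(1, 2))
  rownames(pts) <- c("ok", "bad")
  expect_error(extract_at_points(list(X = layer), pts), "bad")
  ok <- extract_at_points(list(X = layer), pts[1, , drop = FALSE])
  expect_equal(ok$X, 1)
})

test_that("the standard scheme yields exactly 39 descriptor columns", {
  cfg <- small_seascape(seed = 2)
  sim <- simulate_seascape(cfg)
  stack <- reefscape:::default_env_stack(sim)
  static <- reefscape:::default_static_layers(cfg)
  pts <- cfg$sites[, c("row", "col")]
  rownames(pts) <- cfg$sites$site
  feats <- env_features(stack$daily, stack$monthly, depth = static$depth,
                        popdens = static$popdens, at = pts)
  # 5 daily x 6 + 2 monthly x 3 + BAF + DEPTH + POPDENS
  expect_identical(ncol(feats), 39L)
  expect_true(all(c("SST.AVG", "SST.SD.HM", "AT.LM", "SPM.AVG", "BAF",
                    "DEPTH", "POPDENS") %in% names(feats)))
  expect_true(all(feats$BAF >= 0 & feats$BAF <= 1))
})

test_that("reef-cell areas respect the actual-area override", {
  g <- tiny_grid(4, 4, cellsize = 5)
  cells <- data.frame(cell = c("r1", "r2"), row = c(1, 2), col = c(1, 2))
  rg <- reef_grid(cells, g, areas = c(r2 = 3.2))
  a <- attr(rg, "area")
  expect_equal(unname(a["r1"]), 25)
  expect_equal(unname(a["r2"]), 3.2)
  expect_error(reef_grid(cells, g, areas = c(r2 = 26)))
})

test_that("series CSV round-trips and bilinear resampling is exact on planes", {
  m <- matrix(TRUE, 3, 4); m[1, 1] <- FALSE
  g <- sea_grid(3, 4, 1, mask = m)
  set.seed(6)
  s <- raster_series(g, as.Date("2001-01-01") + 0:4,
                     array(rnorm(60), c(5, 3, 4)), "daily")
  path <- tempfile(fileext = ".csv")
  write_series_csv(s, path)
  s2 <- read_series_csv(path, g)
  expect_equal(s2$values, s$values)

  # a linear ramp is reproduced exactly by bilinear interpolation
  g1 <- sea_grid(4, 4, 2)
  ramp <- outer(seq(8, 2, length.out = 4), seq(1, 7, length.out = 4), "+")
  fine <- sea_grid(8, 8, 1)
  rs <- resample_bilinear(raster_layer(g1, ramp), fine)
  cc <- cell_centers(fine)
  # interior fine pixels lie inside the source pixel-center hull
  interior <- cc$x > 1 & cc$x < 7 & cc$y > 1 & cc$y < 7
  expected <- cc$x + cc$y + 1   # the plane through the source pixel centers
  got <- rs$values[cbind(cc$row, cc$col)]
  expect_equal(got[interior], expected[interior], tolerance = 1e-9)
})
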