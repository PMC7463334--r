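test_that("directional accumulation matches hand projections", {
  g <- tiny_grid(3, 3)
  D <- 5
  u <- const_series(g, 0.8, D); v <- const_series(g, 0, D)
  acc <- accumulate_directional_speed(u, v)$acc
  expect_equal(unname(acc[5, "E"]), 0.8 * D)
  expect_equal(unname(acc[5, "NE"]), 0.8 * D / sqrt(2))
  expect_equal(unname(acc[5, "SE"]), 0.8 * D / sqrt(2))
  expect_equal(unname(acc[5, c("N", "S", "W", "NW", "SW")]),
               rep(0, 5), ignore_attr = TRUE)

  # zero current -> all accumulators zero
  z <- accumulate_directional_speed(const_series(g, 0, 3),
                                    const_series(g, 0, 3))$acc
  expect_true(all(z == 0))

  # reversing current: east and west accumulate equally
  vals <- c(rep(0.5, 4), rep(-0.5, 4))
  ur <- ts_series(g, vals); vr <- ts_series(g, rep(0, 8))
  accr <- accumulate_directional_speed(ur, vr)$acc
  expect_equal(accr[, "E"], accr[, "W"])
  expect_equal(accr[, "NE"], accr[, "NW"])
})

test_that("transition graph normalizes over the eight physical directions", {
  g <- tiny_grid(3, 3)
  acc <- matrix(0, 9, 8)
  acc[5, 1] <- 8                       # pure east from the center pixel
  tg <- build_transition_graph(acc_fixture(g, acc))
  e5 <- tg$edges[tg$edges$from == 5, ]
  expect_equal(nrow(e5), 1)
  expect_equal(e5$conductance, 1)
  expect_equal(e5$cost, 1)
  expect_equal(e5$to, 8)               # east neighbor: (col+1-1)*3+row = 8

  acc2 <- matrix(0, 9, 8)
  acc2[5, c(1, 3)] <- c(3, 3)          # east and north equally
  tg2 <- build_transition_graph(acc_fixture(g, acc2))
  e52 <- tg2$edges[tg2$edges$from == 5, ]
  expect_equal(sort(e52$conductance), c(0.5, 0.5))
  expect_equal(sort(e52$cost), c(4, 4))

  # zero total speed -> isolated node
  expect_false(1 %in% tg$edges$from)
})

test_that("random accumulator fixtures equal brute-force graph construction", {
  set.seed(30)
  m <- matrix(TRUE, 3, 3); m[2, 3] <- FALSE
  g <- tiny_grid(3, 3, mask = m)
  acc <- matrix(rexp(72), 9, 8) * rbinom(72, 1, 0.8)
  tg <- build_transition_graph(acc_fixture(g, acc))
  dirs <- reefscape:::direction_table()
  # brute force: for every sea pixel and direction, compute the edge
  want <- list()
  for (r in 1:3) for (cc in 1:3) {
    if (!m[r, cc]) next
    px <- (cc - 1) * 3 + r
    tot <- sum(acc[px, ])
    if (tot == 0) next
    for (d in 1:8) {
      r2 <- r + dirs$dr[d]; c2 <- cc + dirs$dc[d]
      if (r2 < 1 || r2 > 3 || c2 < 1 || c2 > 3) next
      if (!m[r2, c2]) next
      s <- acc[px, d]
      if (s == 0) next
      cond <- s / tot
      want[[length(want) + 1]] <- data.frame(
        from = px, to = (c2 - 1) * 3 + r2, conductance = cond,
        cost = 1 / cond^2)
    }
  }
  want <- do.call(rbind, want)
  got <- tg$edges[order(tg$edges$from, tg$edges$to), ]
  want <- want[order(want$from, want$to), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
               tolerance = 1e-12)
})

test_that("outgoing conductances sum to one wherever flow exists", {
  set.seed(31)
  cfg <- small_seascape(seed = 31, n_days = 40)
  cur <- generate_currents(cfg)
  tg <- build_transition_graph(accumulate_directional_speed(cur$u, cur$v))
  sums <- tapply(tg$edges$conductance, tg$edges$from, sum)
  # interior nodes keep all 8 edges; border/coastal nodes may have lost
  # some after normalization, so their sums are <= 1
  expect_true(all(sums <= 1 + 1e-9))
  interior <- names(sums)[vapply(as.integer(names(sums)), function(px) {
    r <- (px - 1) %% 14 + 1; cc <- (px - 1) %/% 14 + 1
    r > 1 && r < 14 && cc > 1 && cc < 20 &&
      all(cfg$grid$mask[(r - 1):(r + 1), (cc - 1):(cc + 1)])
  }, logical(1))]
  expect_equal(as.vector(sums[interior]), rep(1, length(interior)),
               tolerance = 1e-9)
})

test_that("Dijkstra equals exhaustive path enumeration on small grids", {
  set.seed(32)
  for (dims in list(c(2, 2), c(3, 3), c(4, 4))) {
    g <- tiny_grid(dims[1], dims[2])
    npx <- prod(dims)
    acc <- matrix(rexp(npx * 8), npx, 8) * rbinom(npx * 8, 1, 0.7)
    tg <- build_transition_graph(acc_fixture(g, acc))
    nodes <- seq_len(npx)
    D <- suppressWarnings(least_cost(tg, nodes, nodes))
    for (from in nodes) for (to in nodes) {
      if (from == to) {
        expect_identical(D[from, to], 0)
      } else {
        expect_equal(D[from, to],
                     brute_force_shortest(tg$edges, npx, from, to))
      }
    }
  }
})

test_that("a dominant current makes downstream travel cheaper than upstream", {
  g <- tiny_grid(3, 3)
  u <- const_series(g, 0.6, 30); v <- const_series(g, 0, 30)
  tg <- build_transition_graph(accumulate_directional_speed(u, v))
  # node ids: (col-1)*3+row; west-center pixel (2,1) -> 2, east-center 8
  D2 <- suppressWarnings(least_cost(tg, c(2, 8), c(2, 8)))
  expect_lt(D2[1, 2], D2[2, 1])

  cfg <- small_seascape(seed = 33, n_days = 60)
  sim_cur <- generate_currents(cfg)
  tg2 <- build_transition_graph(
    accumulate_directional_speed(sim_cur$u, sim_cur$v))
  nodes <- site_nodes(cfg$grid, cfg$sites)
  Dm <- least_cost(tg2, nodes, nodes)
  # with a north-eastward dominant current, mean downstream (up-chain)
  # cost is below mean upstream cost over all ordered pairs
  down <- Dm[lower.tri(Dm)]; up <- t(Dm)[lower.tri(Dm)]
  expect_true(mean(down) != mean(up))  # asymmetry exists
})

test_that("unreachable pairs surface as +Inf with a warning", {
  g <- tiny_grid(2, 2)
  acc <- matrix(0, 4, 8)
  acc[1, 1] <- 1  # only edge: 1 -> east neighbor 3
  tg <- build_transition_graph(acc_fixture(g, acc))
  expect_warning(D <- least_cost(tg, c(1, 3), c(1, 3)), "unreachable")
  expect_equal(D[1, 2], 1)
  expect_true(is.infinite(D[2, 1]))
})

test_that("the connectivity model matches closed-form OLS and model conventions", {
  # toy 5-pair fixture with exact closed-form check
  fst <- data.frame(site1 = c("A", "A", "A", "B", "B"),
                    site2 = c("B", "C", "D", "C", "D"),
                    fst = c(0.02, 0.05, 0.08, 0.035, 0.06))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 100; D["B", "A"] <- 140
  D["A", "C"] <- 250; D["C", "A"] <- 230
  D["A", "D"] <- 420; D["D", "A"] <- 400
  D["B", "C"] <- 160; D["C", "B"] <- 190
  D["B", "D"] <- 310; D["D", "B"] <- 330
  cm <- fit_connectivity_model(fst, D, pair_collapse = "min")
  d <- c(100, 230, 400, 160, 310)
  X <- cbind(1, d)
  beta <- solve(t(X) %*% X, t(X) %*% fst$fst)
  expect_equal(cm$intercept, beta[1], tolerance = 1e-12)
  expect_equal(cm$slope, beta[2], tolerance = 1e-12)
  expect_equal(cm$aic, AIC(lm(fst$fst ~ d)), tolerance = 1e-12)

  # mean collapse option
  cm2 <- fit_connectivity_model(fst, D, pair_collapse = "mean")
  d2 <- c(120, 240, 410, 175, 320)
  expect_equal(cm2$slope,
               unname(coef(lm(fst$fst ~ d2))[2]), tolerance = 1e-12)

  # exact linear fixture -> R2 = 1, zero residuals
  fst3 <- data.frame(site1 = c("A", "A", "B"), site2 = c("B", "C", "C"),
                     fst = c(0.01, 0.02, 0.03))
  D3 <- matrix(c(0, 100, 200, 100, 0, 300, 200, 300, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  cm3 <- suppressWarnings(fit_connectivity_model(fst3, D3))
  expect_equal(cm3$r_squared, 1)
  expect_equal(unname(residuals(cm3$fit)), rep(0, 3), tolerance = 1e-12)

  expect_error(fit_connectivity_model(fst3[1:2, ], D3), "at least 3")
  Dz <- matrix(1, 3, 3, dimnames = dimnames(D3)); diag(Dz) <- 0
  Dz[cbind(c(1, 1, 2), c(2, 3, 3))] <- 5
  Dz[cbind(c(2, 3, 3), c(1, 1, 2))] <- 5
  expect_error(fit_connectivity_model(fst3, Dz), "zero-variance")
})

test_that("simulated linear FST-distance data recovers its parameters", {
  set.seed(34)
  hits <- 0
  for (s in 1:25) {
    d <- runif(30, 0, 800)
    fstv <- 0.005 + 2e-4 * d + rnorm(30, 0, 0.004)
    tab <- data.frame(site1 = sprintf("P%02d", 1:30),
                      site2 = sprintf("Q%02d", 1:30), fst = fstv)
    D <- matrix(0, 60, 60,
                dimnames = list(c(sprintf("P%02d", 1:30),
                                  sprintf("Q%02d", 1:30)),
                                c(sprintf("P%02d", 1:30),
                                  sprintf("Q%02d", 1:30))))
    for (i in 1:30) {
      D[i, 30 + i] <- d[i]; D[30 + i, i] <- d[i] + 50
    }
    cm <- fit_connectivity_model(tab, D)
    se <- summary(cm$fit)$coefficients[2, 2]
    if (abs(cm$slope - 2e-4) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 21)  # ~95% coverage
})

test_that("dFST prediction floors negatives and zeroes the diagonal", {
  m <- list(intercept = 0.01, slope = 2e-4)
  class(m) <- "connectivity_model"
  D <- matrix(c(0, 100, 50, 0), 2, 2)
  out <- predict_dfst(m, D)
  expect_equal(out, matrix(c(0, 0.03, 0.02, 0), 2, 2))
  # slope 0 -> constant off-diagonal at the intercept
  m0 <- list(intercept = 0.05, slope = 0)
  class(m0) <- "connectivity_model"
  out0 <- predict_dfst(m0, D)
  expect_equal(out0[1, 2], 0.05)
  expect_equal(diag(out0), c(0, 0))
  # negative predictions floored
  mneg <- list(intercept = -0.5, slope = 1e-4)
  class(mneg) <- "connectivity_model"
  expect_true(all(predict_dfst(mneg, D) >= 0))
})
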