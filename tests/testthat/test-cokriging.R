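# Index 2: semivariograms, LMC, ordinary co-kriging, surface and zonal
# summaries.

test_that("log transform of head counts is the natural log and monotone", {
  expect_equal(log_transform_heads(18), 2.8904, tolerance = 1e-4)
  expect_equal(log_transform_heads(64680), 11.0773, tolerance = 1e-4)
  h <- c(18, 250, 3500, 64680)
  expect_true(all(diff(log_transform_heads(h)) > 0))
  expect_error(log_transform_heads(0.5), ">= 1")
})

test_that("empirical semivariogram reproduces hand and all-pairs oracles", {
  # constant field: all gamma zero
  coords <- cbind(c(0, 100, 200, 300), c(0, 50, 0, 50))
  sv <- empirical_semivariogram(coords, rep(3, 4), n_lags = 3)
  expect_true(all(sv$gamma[sv$np > 0] == 0))

  # two points, values 0 and 4, one bin: gamma = 16 / 2 = 8
  sv2 <- empirical_semivariogram(cbind(c(0, 100), c(0, 0)), c(0, 4),
                                 n_lags = 3, lag_width = 50)
  expect_equal(sv2$gamma[sv2$np > 0], 8)
  expect_true(all(is.na(sv2$gamma[sv2$np == 0])))  # empty bins flagged

  set.seed(31)
  coords <- cbind(runif(30, 0, 5000), runif(30, 0, 5000))
  zu <- rnorm(30); zv <- zu * 0.5 + rnorm(30)
  for (pair in list(list(zu, zu), list(zv, zv), list(zu, zv))) {
    sv <- empirical_semivariogram(coords, pair[[1L]], pair[[2L]],
                                  n_lags = 8, lag_width = 600)
    or <- brute_semivariogram(coords, pair[[1L]], pair[[2L]], 8L, 600)
    expect_equal(sv$np, or$np)
    expect_equal(sv$gamma, or$gamma, tolerance = 1e-12)
  }
  expect_error(empirical_semivariogram(cbind(1, 1), 1), "at least 2")
})

test_that("WLS variogram fit recovers exact model parameters from clean bins", {
  truth <- variogram_model("spherical", nugget = 0.1, psill = 1.0, range = 5000)
  h <- seq(250, 12250, by = 500)
  cloud <- data.frame(lag = h, np = rep(1000L, length(h)),
                      gamma = predict(truth, h))
  class(cloud) <- c("semivariogram", "data.frame")
  fit <- fit_variogram(cloud, "spherical")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-6)
  expect_equal(fit$psill, 1.0, tolerance = 1e-6)
  expect_equal(fit$range, 5000, tolerance = 1e-6 * 5000)

  # pure nugget: flat cloud fits a flat model with c ~ 0
  flat <- data.frame(lag = h, np = rep(1000L, length(h)), gamma = rep(0.7, length(h)))
  class(flat) <- c("semivariogram", "data.frame")
  ffit <- fit_variogram(flat, "spherical")
  expect_equal(ffit$psill, 0, tolerance = 1e-8)
  expect_equal(ffit$nugget, 0.7, tolerance = 1e-8)

  zero <- data.frame(lag = h, np = rep(10L, length(h)), gamma = rep(0, length(h)))
  class(zero) <- c("semivariogram", "data.frame")
  expect_error(fit_variogram(zero), "degenerate")
})

test_that("LMC fit recovers clean coefficients, zeroes absent cross, stays PSD", {
  truth <- lmc_model(list(
    list(family = "nugget", B = matrix(c(0.2, 0.05, 0.05, 0.3), 2L)),
    list(family = "spherical", range = 4000,
         B = matrix(c(1.0, 0.4, 0.4, 0.5), 2L))))
  h <- seq(200, 9800, by = 400)
  mk <- function(u, v) {
    d <- data.frame(lag = h, np = rep(500L, length(h)),
                    gamma = predict(truth, h, u = u, v = v))
    class(d) <- c("semivariogram", "data.frame")
    d
  }
  clouds <- list(primary = mk(1, 1), secondary = mk(2, 2), cross = mk(1, 2))
  fit <- fit_lmc(clouds, structures = list(list(family = "nugget"),
                                           list(family = "spherical", range = 4000)))
  for (k in 1:2)
    expect_equal(fit$structures[[k]]$B, truth$structures[[k]]$B,
                 tolerance = 0.1)

  # identically zero cross component: zero cross sills in every structure
  z <- mk(1, 2); z$gamma <- 0
  fit0 <- fit_lmc(list(primary = mk(1, 1), secondary = mk(2, 2), cross = z),
                  structures = list(list(family = "nugget"),
                                    list(family = "spherical", range = 4000)))
  for (s in fit0$structures) expect_equal(s$B[1, 2], 0, tolerance = 1e-10)

  # deliberately inflated cross cloud: projection restores PSD
  infl <- mk(1, 2); infl$gamma <- infl$gamma * 10 + 2
  fit1 <- fit_lmc(list(primary = mk(1, 1), secondary = mk(2, 2), cross = infl),
                  structures = list(list(family = "nugget"),
                                    list(family = "spherical", range = 4000)))
  for (s in fit1$structures) {
    ev <- eigen(s$B, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_lte(abs(s$B[1, 2]), sqrt(s$B[1, 1] * s$B[2, 2]) + 1e-10)
  }
})

test_that("fitting a simulated Gaussian random field recovers the variogram", {
  truth <- variogram_model("spherical", nugget = 0.1, psill = 1.0, range = 5000)
  hits <- 0L
  n_seeds <- 15L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    # domain of 8x the range so the field holds independent range-scale
    # replicates; max lag ~ 0.44 of the domain side
    coords <- cbind(runif(400, 0, 40000), runif(400, 0, 40000))
    z <- simulate_grf(coords, truth)
    sv <- empirical_semivariogram(coords, z, n_lags = 14, lag_width = 1250)
    fit <- fit_variogram(sv, "spherical")
    sill_ok <- abs((fit$nugget + fit$psill) - 1.1) <= 0.25 * 1.1
    range_ok <- abs(fit$range - 5000) <= 0.4 * 5000
    hits <- hits + (sill_ok && range_ok)
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("co-kriging is exact at data sites and honours weight constraints", {
  model <- rand_lmc(1)
  # strip the nugget for the exact-interpolation property
  nofree <- lmc_model(list(list(family = "nugget", B = matrix(0, 2, 2)),
                           model$structures[[2L]]))
  set.seed(2)
  coords <- cbind(runif(12, 0, 8000), runif(12, 0, 8000))
  z1 <- rnorm(12); z2 <- rnorm(12)
  for (k in c(1L, 5L, 12L)) {
    r <- cokrige_point(coords[k, ], coords, z1, z2, nofree)
    expect_equal(r$pred, z1[k], tolerance = 1e-8)
    expect_equal(r$var, 0, tolerance = 1e-8)
  }
  # weight sums at off-data points, nugget present
  for (s in 1:25) {
    set.seed(s + 50)
    s0 <- runif(2, -1000, 9000)
    r <- cokrige_point(s0, coords, z1, z2, model)
    expect_equal(sum(r$lambda1), 1, tolerance = 1e-8)
    expect_equal(sum(r$lambda2), 0, tolerance = 1e-8)
    expect_gte(r$var, 0)
  }
})

test_that("pure-nugget co-kriging without cross-correlation averages z1", {
  model <- lmc_model(list(list(family = "nugget",
                               B = matrix(c(0.8, 0, 0, 0.5), 2L))))
  set.seed(3)
  coords <- cbind(runif(9, 0, 5000), runif(9, 0, 5000))
  z1 <- rnorm(9); z2 <- rnorm(9)
  r <- cokrige_point(c(2500, 2500), coords, z1, z2, model)
  expect_equal(r$pred, mean(z1), tolerance = 1e-8)
  expect_equal(max(abs(r$lambda2)), 0, tolerance = 1e-8)
})

test_that("co-kriging equals the dense-solver oracle on random configurations", {
  for (s in 1:30) {
    model <- rand_lmc(s)
    set.seed(s + 500)
    coords <- cbind(runif(8, 0, 10000), runif(8, 0, 10000))
    z1 <- rnorm(8, 8, 1); z2 <- rpois(8, 3)
    s0 <- runif(2, 0, 10000)
    got <- cokrige_point(s0, coords, z1, z2, model)$pred
    expect_equal(got, oracle_cokrige(s0, coords, z1, z2, model),
                 tolerance = 1e-8)
  }
})

test_that("zero secondary structure reduces co-kriging to ordinary kriging", {
  ok_krige <- function(s0, coords, z, model) {
    # independent one-variable ordinary kriging solver
    n <- nrow(coords)
    G <- oracle_gamma(model, as.matrix(dist(coords)), 1, 1)
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    d0 <- sqrt((coords[, 1] - s0[1])^2 + (coords[, 2] - s0[2])^2)
    b <- c(oracle_gamma(model, d0, 1, 1), 1)
    lam <- qr.solve(A, b)
    sum(lam[1:n] * z)
  }
  for (s in 1:10) {
    set.seed(s + 900)
    B1 <- matrix(c(0.3, 0, 0, 0), 2L)
    B2 <- matrix(c(1.2, 0, 0, 0), 2L)
    model <- lmc_model(list(list(family = "nugget", B = B1),
                            list(family = "spherical", range = 4500, B = B2)))
    coords <- cbind(runif(10, 0, 8000), runif(10, 0, 8000))
    z1 <- rnorm(10); z2 <- rnorm(10)
    s0 <- runif(2, 0, 8000)
    got <- suppressWarnings(cokrige_point(s0, coords, z1, z2, model)$pred)
    expect_equal(got, ok_krige(s0, coords, z1, model), tolerance = 1e-8)
  }
})

test_that("coincident duplicate data are averaged with a warning", {
  model <- rand_lmc(4)
  coords <- cbind(c(0, 0, 4000), c(0, 0, 3000))
  expect_warning(
    r <- cokrige_point(c(1000, 1000), coords, c(1, 3, 5), c(0, 2, 1), model),
    "coincident")
  r2 <- cokrige_point(c(1000, 1000), cbind(c(0, 4000), c(0, 3000)),
                      c(2, 5), c(1, 1), model)
  expect_equal(r$pred, r2$pred, tolerance = 1e-10)
})

test_that("surfaces are constant for constant data and nest under refinement", {
  tr <- make_grid_tracts(2, 2, 5000)
  set.seed(9)
  farms <- list(x = runif(15, 0, 10000), y = runif(15, 0, 10000))
  model <- rand_lmc(7)
  sconst <- predict_surface(farms, rep(4.2, 15), rep(2, 15), model, tr,
                            kriging_config(grid_cell = 2000))
  expect_equal(as.numeric(sconst$pred), rep(4.2, length(sconst$pred)),
               tolerance = 1e-8)

  z1 <- rnorm(15, 8); z2 <- rnorm(15, 2)
  coarse <- predict_surface(farms, z1, z2, model, tr, kriging_config(grid_cell = 2000))
  fine <- predict_surface(farms, z1, z2, model, tr, kriging_config(grid_cell = 1000))
  cx <- intersect(coarse$x, fine$x); cy <- intersect(coarse$y, fine$y)
  expect_gte(length(cx) * length(cy), 25L)
  expect_equal(coarse$pred[match(cx, coarse$x), match(cy, coarse$y)],
               fine$pred[match(cx, fine$x), match(cy, fine$y)],
               tolerance = 1e-10)

  # nugget-free model interpolates the data exactly at coincident cells
  nofree <- lmc_model(list(model$structures[[2L]]))
  cellpts <- cbind(c(2000, 4000), c(2000, 6000))  # exact cell centres
  s2 <- predict_surface(list(x = cellpts[, 1L], y = cellpts[, 2L]),
                        c(5, 9), c(1, 3), nofree, tr, kriging_config(grid_cell = 2000))
  for (k in 1:2) {
    i <- match(cellpts[k, 1L], s2$x); j <- match(cellpts[k, 2L], s2$y)
    expect_equal(s2$pred[i, j], c(5, 9)[k], tolerance = 1e-8)
  }
})

test_that("zonal maxima enumerate cells, with centroid fallback for slivers", {
  tr <- make_grid_tracts(2, 1, 6000)
  surf <- structure(list(x = seq(500, 11500, by = 1000),
                         y = seq(500, 5500, by = 1000),
                         pred = matrix(0, 12, 6), var = matrix(0, 12, 6),
                         cell = 1000), class = "cokriging_surface")
  surf$pred[] <- seq_len(72)
  zm <- zonal_max(surf, tr)
  in_t1 <- surf$x <= 6000
  expect_equal(unname(zm["T001"]), max(surf$pred[in_t1, ]))
  expect_equal(unname(zm["T002"]), max(surf$pred[!in_t1, ]))

  const <- surf; const$pred[] <- 7
  expect_equal(unname(zonal_max(const, tr)), c(7, 7))

  # sliver tract smaller than one cell: centroid fallback
  sliver <- tract_records(c("S1", "S2"),
                          list(square_ring(0, 0, 6000),
                               square_ring(6050, 5050, 300)))
  expect_warning(zf <- zonal_max(surf, sliver, fallback_predict = function(p) -99),
                 "centroid fallback")
  expect_equal(unname(zf["S2"]), -99)
})

test_that("percent-of-total normalization is exact and guards degeneracy", {
  p <- percent_of_total(c(A = 2, B = 3, C = 5))
  expect_equal(unname(p), c(20, 30, 50))
  expect_equal(unname(percent_of_total(c(X = 4))), 100)
  set.seed(12)
  v <- setNames(runif(200, 0.1, 9), paste0("T", 1:200))
  expect_lt(abs(sum(percent_of_total(v)) - 100), 1e-9)
  expect_error(percent_of_total(c(A = 0, B = 0)), "degenerate")
  expect_error(percent_of_total(c(A = 1, B = NA)), "finite")
})

test_that("idx2 chain produces normalized per-tract percentages", {
  reg <- generate_region(region_config(4, 4, tract_side = 3, seed = 21))
  farms <- generate_farms(reg$tracts, farm_gen_config(n_farms = 80, seed = 21))
  r <- idx2_per_tract(farms, reg$tracts, kriging_config(grid_cell = 1200))
  expect_equal(sum(r$percent), 100, tolerance = 1e-9)
  expect_length(r$percent, 16L)
  expect_true(all(r$raw_max > 0))
  # raw maxima live on the log-head scale spanned by the data
  expect_true(all(r$raw_max < log(64680) + 3))
})
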