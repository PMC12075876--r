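# Urban classification, Spearman machinery, stratified matrix, reporting
# filter and geometric map classes.

test_that("urban classification applies the inclusive 50% land-area rule", {
  tr <- make_grid_tracts(2, 1, 1000)
  # city fully covers T001; nothing of T002
  full <- classify_urban(tr, list(square_ring(-10, -10, 1100)))
  expect_identical(full$urban, c(TRUE, FALSE))
  # exactly half of T001 covered: inclusive >= 0.5 makes it urban
  half <- classify_urban(tr, list(square_ring(0, 0, 500)))
  half2 <- classify_urban(tr, list(cbind(c(0, 500, 500, 0), c(0, 0, 1000, 1000))))
  expect_true(half2$urban[1L])
  expect_equal(half2$urban_area_fraction[1L], 0.5, tolerance = 1e-12)
  expect_false(half$urban[1L])  # quarter coverage stays rural
})

test_that("clipped area fractions match a fine-grid rasterization oracle", {
  set.seed(14)
  tr <- make_grid_tracts(1, 1, 4000)
  for (k in 1:6) {
    x0 <- runif(1, -1000, 3000); y0 <- runif(1, -1000, 3000)
    w <- runif(1, 500, 4000); h <- runif(1, 500, 4000)
    city <- list(square_ring(x0, y0, 1) * 0 + cbind(c(x0, x0 + w, x0 + w, x0),
                                                    c(y0, y0, y0 + h, y0 + h)))
    got <- classify_urban(tr, city)$urban_area_fraction
    gx <- seq(5, 3995, by = 10); gy <- seq(5, 3995, by = 10)
    gridpts <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
    ras <- mean(point_in_polygon(gridpts, city[[1L]]))
    expect_lt(abs(got - ras), 0.005)
  }
})

test_that("non-convex city polygons fall back to quasi-Monte-Carlo fractions", {
  tr <- make_grid_tracts(1, 1, 1000)
  # L-shaped (non-convex) city covering 3/4 of the tract
  ell <- cbind(c(0, 1000, 1000, 500, 500, 0), c(0, 0, 500, 500, 1000, 1000))
  expect_message(cls <- classify_urban(tr, list(ell)), "quasi-Monte-Carlo")
  expect_true(cls$urban[1L])
  expect_lt(abs(cls$urban_area_fraction[1L] - 0.75), 0.01)
})

test_that("spearman handles monotone, antitone, tied and missing inputs", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1.0)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$rho, -1.0)
  # hand-computed average ranks: x -> 1, 2.5, 2.5, 4 ; y -> 1, 3, 2, 4
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  hand <- cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4))
  got <- spearman_cor(x, y)
  expect_equal(got$rho, hand)
  expect_equal(got$n_pairs, 4L)
  # agreement with the standard library estimator
  set.seed(3)
  a <- rpois(40, 4); b <- a + rpois(40, 6)
  expect_equal(spearman_cor(a, b)$rho, cor(a, b, method = "spearman"))
  # pairwise deletion
  a[c(2, 9)] <- NA; b[5] <- NA
  ok <- !is.na(a) & !is.na(b)
  expect_equal(spearman_cor(a, b)$n_pairs, sum(ok))
  expect_equal(spearman_cor(a, b)$rho, cor(a[ok], b[ok], method = "spearman"))
  # undefined results are flagged, never coerced to 0
  expect_false(spearman_cor(c(1, 2), c(3, 4))$defined)
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))$rho))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(60); y <- 0.6 * x + rnorm(60)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, rank(y))$rho, base)
  expect_equal(spearman_cor(-x, y)$rho, -base)
})

test_that("the correlation matrix is symmetric-complete per stratum", {
  reg <- generate_region(region_config(6, 6, urban_fraction = 0.25, seed = 31))
  tr <- generate_vulnerability(reg$tracts, vuln_gen_config(seed = 31))
  set.seed(31)
  n <- nrow(tr)
  exposure <- data.frame(tract_id = tr$tract_id,
                         idx1_count = rpois(n, 20),
                         idx2_percent = runif(n), idx3_density = rlnorm(n))
  cm <- correlation_matrix(exposure, tr)
  expect_setequal(unique(cm$stratum), c("all", "urban", "rural"))
  expect_equal(sum(cm$stratum == "all"), 10L)  # all unordered pairs
  expect_true(all(abs(cm$rho[!is.na(cm$rho)]) <= 1))
  # urban + rural complete cases partition the all-stratum complete cases
  for (k in which(cm$stratum == "all")) {
    u <- cm[cm$stratum == "urban" & cm$var_a == cm$var_a[k] &
              cm$var_b == cm$var_b[k], ]
    r <- cm[cm$stratum == "rural" & cm$var_a == cm$var_a[k] &
              cm$var_b == cm$var_b[k], ]
    expect_equal(u$n_pairs + r$n_pairs, cm$n_pairs[k])
  }
  # a perfectly rank-aligned pair gives rho = 1 in every stratum
  exposure$idx3_density <- exposure$idx1_count
  cm2 <- correlation_matrix(exposure, tr)
  sub <- cm2[cm2$var_a == "idx1" & cm2$var_b == "idx3", ]
  expect_equal(sub$rho, rep(1, 3), tolerance = 1e-12)
})

test_that("an empty stratum is omitted with a warning, others intact", {
  reg <- generate_region(region_config(3, 3, urban_fraction = 0, seed = 2))
  tr <- generate_vulnerability(reg$tracts, vuln_gen_config(seed = 2))
  exposure <- data.frame(tract_id = tr$tract_id, idx1_count = 1:9,
                         idx2_percent = runif(9), idx3_density = rnorm(9)^2)
  expect_warning(cm <- correlation_matrix(exposure, tr), "urban")
  expect_setequal(unique(cm$stratum), c("all", "rural"))
})

test_that("the reporting filter applies |rho| >= 0.1 and flags strata differences", {
  cm <- data.frame(stratum = rep(c("all", "urban", "rural"), each = 2),
                   var_a = rep(c("idx1", "idx2"), 3),
                   var_b = rep(c("idx3", "svi"), 3),
                   rho = c(0.05, 0.3, 0.82, 0.05, 0.9, 0.05),
                   rho_rounded = c(0.1, 0.3, 0.8, 0.1, 0.9, 0.1),
                   n_pairs = 50L)
  class(cm) <- c("correlation_matrix", "data.frame")
  rep <- filter_report(cm, threshold = 0.1)
  expect_equal(nrow(rep$reported), 3L)          # |rho| >= 0.1 retained
  expect_equal(nrow(rep$full), nrow(cm))        # full matrix intact
  expect_equal(rep$differs$var_a, "idx1")       # 0.8 urban vs 0.9 rural
  expect_equal(rep$differs$urban_rho, 0.8)
  expect_equal(rep$differs$rural_rho, 0.9)

  low <- cm; low$rho <- 0.05
  expect_equal(nrow(filter_report(low, 0.1)$reported), 0L)
  expect_equal(nrow(filter_report(low, 0)$reported), nrow(cm))
})

test_that("planted exposure coupling orders the correlations as expected", {
  # rural-concentrated farms drive both idx1 (addresses near farms) and
  # idx3 (head density); idx2 vs svi is much weaker by construction
  wins <- vapply(1:20, function(s) {
    reg <- generate_region(region_config(5, 5, tract_side = 3,
                                         urban_fraction = 0.2, seed = s))
    tr <- generate_vulnerability(reg$tracts, vuln_gen_config(seed = s))
    farms <- generate_farms(tr, farm_gen_config(n_farms = 120, seed = s))
    addresses <- generate_addresses(tr, address_gen_config(n_addresses = 900,
                                                           urban_share = 0.5,
                                                           seed = s))
    i1 <- idx1_per_tract(farms, addresses, tr)
    i3 <- idx3_per_tract(farms, tr)
    r13 <- spearman_cor(i1[sort(names(i1))], i3[sort(names(i3))])$rho
    m <- match(sort(names(i1)), tr$tract_id)
    r2s <- spearman_cor(i1[sort(names(i1))], tr$svi_rank[m])$rho
    r13 > r2s
  }, logical(1L))
  expect_gt(mean(wins), 0.5)  # majority of seeds
})

test_that("geometric intervals give multiplicative classes plus a zero class", {
  b <- geometric_breaks(c(0, 1, 10, 100), k = 2)
  expect_equal(b$breaks, 10)
  cls <- assign_classes(c(0, 1, 10, 100), b)
  expect_equal(cls, c(0L, 1L, 1L, 2L))  # upper-inclusive: 10 in (0, 10]

  same <- geometric_breaks(c(5, 5, 5), k = 4)
  expect_equal(assign_classes(c(5, 5, 5), same), c(1L, 1L, 1L))

  allz <- geometric_breaks(c(0, 0), k = 3)
  expect_equal(assign_classes(c(0, 0), allz), c(0L, 0L))

  set.seed(4)
  v <- c(rep(0, 7), rlnorm(200, 2, 1.5))
  k <- 5L
  br <- geometric_breaks(v, k)
  cls <- assign_classes(v, br)
  expect_equal(sum(cls == 0L), 7L)
  expect_equal(length(cls), length(v))
  # membership oracle: each positive value in exactly the interval it claims
  edges <- c(0, br$breaks, br$v_max)
  for (j in seq_len(k)) {
    sel <- cls == j
    expect_true(all(v[sel] > edges[j] & v[sel] <= edges[j + 1L] + 1e-12))
  }
  expect_equal(as.integer(table(factor(cls, levels = 0:k))), c(7L, as.integer(
    vapply(seq_len(k), function(j) sum(v > edges[j] & v <= edges[j + 1L]), 1L))))
  # breaks form a geometric progression
  expect_equal(diff(log(c(br$v_min, br$breaks, br$v_max))),
               rep(log(br$v_max / br$v_min) / k, k))
})
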