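# Index 2: ordinary co-kriging of log permitted head (primary) and manure
# lagoon count (secondary) under a linear model of coregionalization (LMC),
# grid prediction, per-tract zonal maximum and percent-of-total
# normalization.
#
# Semivariogram convention: gamma(0) = 0; the nugget is a discontinuity at
# the origin.  Exponential and gaussian families use the practical-range
# parameterisation (95% of the sill at h = range).

#' Kriging configuration
#'
#' @param n_lags number of semivariogram lag bins (>= 3)
#' @param lag_width bin width in metres; when NULL it is chosen at fit time
#'   as envelope diagonal / (2 * n_lags)
#' @param neighborhood max data points used per variable at each prediction
#'   point; 0 means all points (global neighbourhood)
#' @param grid_cell prediction grid cell size in metres
#' @param max_search_radius neighbourhood search cut-off in metres (Inf = none)
#' @return classed list
#' @export
kriging_config <- function(n_lags = 12L, lag_width = NULL, neighborhood = 0L,
                           grid_cell = 1000, max_search_radius = Inf) {
  stopifnot(n_lags >= 3, is.null(lag_width) || lag_width > 0, grid_cell > 0,
            neighborhood >= 0)
  structure(list(n_lags = as.integer(n_lags), lag_width = lag_width,
                 neighborhood = as.integer(neighborhood), grid_cell = grid_cell,
                 max_search_radius = max_search_radius),
            class = "kriging_config")
}

#' Log transform of permitted head counts
#'
#' Natural logarithm of the permitted head count, the primary co-kriging
#' variable.  The base only rescales the variable and cancels in the final
#' percent-of-total normalization.
#'
#' @param farms `farm_records` (or a numeric vector of head counts)
#' @return numeric vector of log head counts
#' @export
log_transform_heads <- function(farms) {
  h <- if (is.data.frame(farms)) farms$permitted_head else farms
  if (any(h < 1)) stop("permitted head counts must be >= 1 for the log transform")
  log(h)
}

# ---------------------------------------------------------------------------
# Empirical (cross-)semivariogram

#' Empirical direct or cross semivariogram
#'
#' Method-of-moments estimator on distance bins: for pairs (i, j) whose
#' separation falls in bin b,
#' `gamma_hat(b) = sum((zu_i - zu_j) * (zv_i - zv_j)) / (2 * N(b))`.
#' With `zv = zu` this is the classical direct semivariogram.  Empty bins
#' keep `np = 0` and `gamma = NA` (flagged, never fabricated).
#'
#' @param coords n x 2 matrix of planar coordinates (metres)
#' @param zu,zv numeric vectors of co-located values; `zv` defaults to `zu`
#' @param n_lags number of bins
#' @param lag_width bin width in metres; default spans the maximum pair
#'   distance across `n_lags` bins
#' @return data.frame of class `semivariogram` with columns `lag` (bin
#'   centre), `np` (pair count), `gamma`
#' @export
empirical_semivariogram <- function(coords, zu, zv = zu, n_lags = 12L,
                                    lag_width = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("semivariogram estimation needs at least 2 points")
  stopifnot(length(zu) == n, length(zv) == n)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1L]; j <- pr[, 2L]
  d <- sqrt((coords[i, 1L] - coords[j, 1L])^2 + (coords[i, 2L] - coords[j, 2L])^2)
  g <- (zu[i] - zu[j]) * (zv[i] - zv[j])
  if (is.null(lag_width)) lag_width <- max(d) / n_lags * (1 + 1e-9)
  bin <- ceiling(d / lag_width)
  bin[d == 0] <- 1L
  keep <- bin <= n_lags
  bin <- bin[keep]; g <- g[keep]
  np <- tabulate(bin, nbins = n_lags)
  gsum <- vapply(seq_len(n_lags), function(b) sum(g[bin == b]), numeric(1L))
  gamma <- ifelse(np > 0, gsum / (2 * np), NA_real_)
  out <- data.frame(lag = (seq_len(n_lags) - 0.5) * lag_width, np = np,
                    gamma = gamma)
  attr(out, "lag_width") <- lag_width
  class(out) <- c("semivariogram", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Variogram model

.vgm_curve <- function(family, h, a) {
  # unit-sill structure curves; gamma(0) = 0
  switch(family,
         spherical = ifelse(h >= a, 1, 1.5 * (h / a) - 0.5 * (h / a)^3),
         exponential = 1 - exp(-3 * h / a),
         gaussian = 1 - exp(-3 * (h / a)^2),
         nugget = (h > 0) * 1,  # *1 keeps matrix shape
         stop("unknown variogram family: ", family))
}

#' Variogram model object
#'
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`
#' @param nugget nugget variance c0 >= 0
#' @param psill partial sill c >= 0
#' @param range range parameter a > 0 (practical range for exponential and
#'   gaussian)
#' @return object of class `variogram_model`
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill, range = range),
            class = "variogram_model")
}

#' Evaluate a semivariogram model
#'
#' @param object a `variogram_model` or `lmc`
#' @param h distances in metres
#' @param ... for `lmc`: `u`, `v` in \{1, 2\} selecting the component
#' @return gamma(h)
#' @export
predict.variogram_model <- function(object, h, ...) {
  object$nugget * ((h > 0) * 1) +
    object$psill * .vgm_curve(object$family, h, object$range)
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram model: %s  nugget=%.6g  psill=%.6g  range=%.6g m\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

# Weighted least squares for (c0, c) given a fixed range; nonnegativity by
# clipped re-fit.  Returns list(c0, c, sse).
.wls_sills <- function(h, gamma, w, family, a) {
  g1 <- .vgm_curve(family, h, a)
  X <- cbind(1, g1)
  XtW <- t(X * w)
  beta <- tryCatch(solve(XtW %*% X, XtW %*% gamma),
                   error = function(e) c(mean(gamma), 0))
  c0 <- beta[1L]; cc <- beta[2L]
  if (c0 < 0) {
    c0 <- 0
    cc <- sum(w * g1 * gamma) / sum(w * g1^2)
  }
  if (cc < 0) {
    cc <- 0
    c0 <- sum(w * gamma) / sum(w)
    if (c0 < 0) c0 <- 0
  }
  res <- gamma - (c0 + cc * g1)
  list(c0 = c0, c = cc, sse = sum(w * res^2))
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with pair-count weights N(h) (Cressie-style),
#' minimised over nugget, partial sill and range.  Conditional on the range
#' the problem is linear in the sills, so the fit is a deterministic
#' multistart over a coarse range grid followed by golden-section refinement
#' of the range.
#'
#' @param cloud a `semivariogram` (direct component: gamma >= 0)
#' @param family model family, default spherical
#' @return `variogram_model`
#' @export
fit_variogram <- function(cloud, family = c("spherical", "exponential", "gaussian")) {
  family <- match.arg(family)
  ok <- cloud$np > 0 & !is.na(cloud$gamma)
  if (sum(ok) < 3L) stop("variogram fit needs at least 3 nonempty lag bins")
  h <- cloud$lag[ok]; g <- cloud$gamma[ok]; w <- cloud$np[ok]
  if (all(g == 0)) stop("degenerate fit: all semivariogram estimates are zero")
  a_grid <- seq(min(h), 2 * max(h), length.out = 48L)
  fits <- lapply(a_grid, function(a) .wls_sills(h, g, w, family, a))
  sse <- vapply(fits, `[[`, numeric(1L), "sse")
  k <- which.min(sse)
  lo <- a_grid[max(1L, k - 1L)]; hi <- a_grid[min(length(a_grid), k + 1L)]
  obj <- function(a) .wls_sills(h, g, w, family, a)$sse
  a_best <- if (hi > lo)
    stats::optimize(obj, c(lo, hi),
                    tol = max((hi - lo) * 1e-9, .Machine$double.eps^0.5))$minimum
  else a_grid[k]
  if (obj(a_grid[k]) < obj(a_best)) a_best <- a_grid[k]
  s <- .wls_sills(h, g, w, family, a_best)
  variogram_model(family, nugget = s$c0, psill = s$c, range = a_best)
}

# ---------------------------------------------------------------------------
# Linear model of coregionalization

.psd_project <- function(B, tol = 0) {
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  vals <- pmax(e$values, tol)
  B2 <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  (B2 + t(B2)) / 2
}

#' Fit a linear model of coregionalization
#'
#' Given the three empirical components (primary direct, secondary direct,
#' cross) on identical lag bins, estimates one 2 x 2 coefficient matrix per
#' structure by weighted least squares (pair-count weights), then projects
#' each matrix onto the positive-semidefinite cone by eigenvalue clipping
#' with re-symmetrization, which guarantees a valid co-kriging system and
#' `|b12| <= sqrt(b11 * b22)` per structure.
#'
#' @param clouds list with elements `primary`, `secondary`, `cross`, each a
#'   `semivariogram` on the same bins
#' @param structures list of structures; each is `list(family=, range=)`,
#'   with family `"nugget"` needing no range.  Default: nugget plus one
#'   spherical structure whose range is fitted from the primary direct
#'   component.
#' @return object of class `lmc`: list of structures each carrying its `B`
#'   matrix (rows/cols: primary, secondary)
#' @export
fit_lmc <- function(clouds, structures = NULL) {
  stopifnot(all(c("primary", "secondary", "cross") %in% names(clouds)))
  lag <- clouds$primary$lag
  if (!isTRUE(all.equal(lag, clouds$secondary$lag)) ||
      !isTRUE(all.equal(lag, clouds$cross$lag)))
    stop("LMC components must share identical lag bins")
  ok <- clouds$primary$np > 0 & !is.na(clouds$primary$gamma) &
    !is.na(clouds$secondary$gamma) & !is.na(clouds$cross$gamma)
  if (sum(ok) < 3L) stop("LMC fit needs at least 3 shared nonempty bins")
  if (is.null(structures)) {
    vm <- fit_variogram(clouds$primary, "spherical")
    structures <- list(list(family = "nugget"),
                       list(family = "spherical", range = vm$range))
  }
  h <- lag[ok]; w <- clouds$primary$np[ok]
  G <- vapply(structures, function(s)
    .vgm_curve(s$family, h, if (is.null(s$range)) 1 else s$range),
    numeric(length(h)))
  G <- matrix(G, nrow = length(h))
  GtW <- t(G * w)
  A <- GtW %*% G
  solve_b <- function(gamma) as.numeric(solve(A, GtW %*% gamma))
  b11 <- solve_b(clouds$primary$gamma[ok])
  b22 <- solve_b(clouds$secondary$gamma[ok])
  b12 <- solve_b(clouds$cross$gamma[ok])
  structs <- lapply(seq_along(structures), function(k) {
    B <- .psd_project(matrix(c(b11[k], b12[k], b12[k], b22[k]), 2L, 2L))
    c(structures[[k]], list(B = B))
  })
  structure(list(structures = structs), class = "lmc")
}

#' @rdname predict.variogram_model
#' @export
predict.lmc <- function(object, h, ...) {
  dots <- list(...)
  u <- if (is.null(dots$u)) 1L else dots$u
  v <- if (is.null(dots$v)) 1L else dots$v
  out <- 0
  for (s in object$structures)
    out <- out + s$B[u, v] * .vgm_curve(s$family, h,
                                        if (is.null(s$range)) 1 else s$range)
  out
}

#' @export
print.lmc <- function(x, ...) {
  cat("linear model of coregionalization:", length(x$structures), "structure(s)\n")
  for (s in x$structures) {
    cat(sprintf("  %s%s  B = [%.6g %.6g; %.6g %.6g]\n", s$family,
                if (is.null(s$range)) "" else sprintf(" (range %.6g m)", s$range),
                s$B[1, 1], s$B[1, 2], s$B[2, 1], s$B[2, 2]))
  }
  invisible(x)
}

#' Build an LMC directly from parameter values
#'
#' Convenience constructor for tests and simulation: supply per-structure
#' 2 x 2 coefficient matrices.
#'
#' @param structures list of `list(family=, range=, B=)`
#' @return `lmc`
#' @export
lmc_model <- function(structures) {
  for (s in structures) {
    stopifnot(is.matrix(s$B), all(dim(s$B) == 2L))
    if (min(eigen((s$B + t(s$B)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-10)
      stop("coefficient matrix not positive semidefinite")
  }
  structure(list(structures = structures), class = "lmc")
}

# ---------------------------------------------------------------------------
# Ordinary co-kriging

# Average coincident duplicate points (both variables); warns when any.
.dedupe_coords <- function(coords, z1, z2) {
  key <- paste(coords[, 1L], coords[, 2L], sep = "|")
  if (!anyDuplicated(key)) return(list(coords = coords, z1 = z1, z2 = z2))
  warning("coincident data points averaged before co-kriging")
  grp <- match(key, unique(key))
  agg <- function(z) as.numeric(tapply(z, grp, mean))
  xs <- as.numeric(tapply(coords[, 1L], grp, mean))
  ys <- as.numeric(tapply(coords[, 2L], grp, mean))
  list(coords = cbind(xs, ys), z1 = agg(z1), z2 = agg(z2))
}

# Assemble the ordinary co-kriging LHS for n co-located data points:
# [ G11  G12  1  0 ]
# [ G12' G22  0  1 ]
# [ 1'   0'   0  0 ]
# [ 0'   1'   0  0 ]
.ck_lhs <- function(coords, model) {
  n <- nrow(coords)
  D <- .cross_dist(coords, coords)
  G11 <- predict(model, D, u = 1L, v = 1L)
  G22 <- predict(model, D, u = 2L, v = 2L)
  G12 <- predict(model, D, u = 1L, v = 2L)
  m <- 2L * n + 2L
  A <- matrix(0, m, m)
  A[1:n, 1:n] <- G11
  A[1:n, (n + 1):(2 * n)] <- G12
  A[(n + 1):(2 * n), 1:n] <- t(G12)
  A[(n + 1):(2 * n), (n + 1):(2 * n)] <- G22
  A[1:n, 2 * n + 1] <- 1; A[2 * n + 1, 1:n] <- 1
  A[(n + 1):(2 * n), 2 * n + 2] <- 1; A[2 * n + 2, (n + 1):(2 * n)] <- 1
  A
}

# RHS columns for prediction points S0 (m x 2): gamma vectors + constraints.
.ck_rhs <- function(coords, S0, model) {
  n <- nrow(coords)
  D0 <- .cross_dist(coords, S0)            # n x npred
  R <- rbind(predict(model, D0, u = 1L, v = 1L),
             predict(model, D0, u = 1L, v = 2L),
             matrix(1, 1L, ncol(D0)),
             matrix(0, 1L, ncol(D0)))
  R
}

.ck_solve <- function(A, B, coords) {
  sol <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(sol)) {
    eps <- 1e-10 * mean(abs(A))
    A2 <- A
    diag(A2) <- diag(A2) + eps
    sol <- tryCatch(solve(A2, B), error = function(e) NULL)
    if (is.null(sol)) {
      key <- paste(round(coords[, 1L], 6), round(coords[, 2L], 6))
      dup <- unique(key[duplicated(key)])
      stop("singular co-kriging system",
           if (length(dup)) paste0("; coincident points at ",
                                   paste(dup, collapse = "; ")) else "")
    }
  }
  sol
}

# Batched ordinary co-kriging at prediction points S0 with a global
# neighbourhood: one LHS factorisation, all RHS columns solved together.
.cokrige_batch <- function(S0, coords, z1, z2, model) {
  n <- nrow(coords)
  A <- .ck_lhs(coords, model)
  B <- .ck_rhs(coords, S0, model)
  sol <- .ck_solve(A, B, coords)
  l1 <- sol[1:n, , drop = FALSE]
  l2 <- sol[(n + 1):(2 * n), , drop = FALSE]
  mu1 <- sol[2 * n + 1, ]
  pred <- as.numeric(crossprod(l1, z1) + crossprod(l2, z2))
  varc <- colSums(sol[1:(2 * n), , drop = FALSE] * B[1:(2 * n), , drop = FALSE]) + mu1
  varc[varc < 0 & varc > -1e-9] <- 0
  list(pred = pred, var = varc, lambda1 = l1, lambda2 = l2, mu = sol[2 * n + 1:2, , drop = FALSE])
}

#' Ordinary co-kriging prediction at one point
#'
#' Solves the ordinary co-kriging system for co-located primary (z1) and
#' secondary (z2) data under an LMC: semivariogram blocks for both variables
#' and their cross-component, with the two unbiasedness constraints (primary
#' weights sum to 1, secondary weights to 0) via Lagrange multipliers.  The
#' prediction is `sum(lambda1 * z1) + sum(lambda2 * z2)`; the variance is the
#' standard `sum(lambda1 * gamma11(s0)) + sum(lambda2 * gamma12(s0)) + mu1`
#' (clipped at -1e-9 to 0).
#'
#' @param s0 length-2 numeric prediction location
#' @param coords n x 2 matrix of data locations
#' @param z1,z2 primary and secondary values at `coords`
#' @param model an `lmc`
#' @param neighborhood use only this many nearest data points per variable
#'   (0 = all)
#' @return list with `pred`, `var`, `lambda1`, `lambda2`, `mu`
#' @export
cokrige_point <- function(s0, coords, z1, z2, model, neighborhood = 0L) {
  coords <- as.matrix(coords)
  dd <- .dedupe_coords(coords, z1, z2)
  coords <- dd$coords; z1 <- dd$z1; z2 <- dd$z2
  if (neighborhood > 0L && neighborhood < nrow(coords)) {
    d <- sqrt((coords[, 1L] - s0[1L])^2 + (coords[, 2L] - s0[2L])^2)
    keep <- order(d)[seq_len(neighborhood)]
    coords <- coords[keep, , drop = FALSE]
    z1 <- z1[keep]; z2 <- z2[keep]
  }
  if (nrow(coords) < 1L) stop("co-kriging needs at least one datum in the neighbourhood")
  r <- .cokrige_batch(matrix(s0, ncol = 2L), coords, z1, z2, model)
  list(pred = r$pred[1L], var = r$var[1L], lambda1 = as.numeric(r$lambda1),
       lambda2 = as.numeric(r$lambda2), mu = as.numeric(r$mu))
}

#' Co-kriged prediction surface
#'
#' Evaluates the co-kriging predictor at every cell centre of a regular grid
#' covering the tract envelope plus a one-cell margin.  With
#' `cfg$neighborhood = 0` the data system is factorised once and all grid
#' cells are solved as one batched right-hand side.
#'
#' @param farms `farm_records` (locations)
#' @param z1,z2 primary and secondary values at the farm locations
#' @param model an `lmc`
#' @param tracts `tract_records` defining the envelope
#' @param cfg a [kriging_config()]
#' @return object of class `cokriging_surface`: list with cell-centre
#'   coordinate vectors `x`, `y`, matrices `pred` and `var`
#'   (rows index x, columns index y), and `cell`
#' @export
predict_surface <- function(farms, z1, z2, model, tracts, cfg = kriging_config()) {
  stopifnot(inherits(cfg, "kriging_config"))
  coords <- cbind(farms$x, farms$y)
  dd <- .dedupe_coords(coords, z1, z2)
  bbs <- vapply(tracts$geometry, .mp_bbox, numeric(4L))
  env <- c(min(bbs[1L, ]), min(bbs[2L, ]), max(bbs[3L, ]), max(bbs[4L, ]))
  cell <- cfg$grid_cell
  # cell centres on the absolute lattice cell * Z, so halving the cell size
  # keeps every coarse centre as a fine centre (nesting property)
  xs <- seq(ceiling((env[1L] - cell) / cell), floor((env[3L] + cell) / cell)) * cell
  ys <- seq(ceiling((env[2L] - cell) / cell), floor((env[4L] + cell) / cell)) * cell
  S0 <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  if (cfg$neighborhood == 0L || cfg$neighborhood >= nrow(dd$coords)) {
    r <- .cokrige_batch(S0, dd$coords, dd$z1, dd$z2, model)
    pred <- r$pred; varc <- r$var
  } else {
    pred <- numeric(nrow(S0)); varc <- numeric(nrow(S0))
    for (i in seq_len(nrow(S0))) {
      ri <- cokrige_point(S0[i, ], dd$coords, dd$z1, dd$z2, model,
                          neighborhood = cfg$neighborhood)
      pred[i] <- ri$pred; varc[i] <- ri$var
    }
  }
  structure(list(x = xs, y = ys,
                 pred = matrix(pred, nrow = length(xs)),
                 var = matrix(varc, nrow = length(xs)),
                 cell = cell),
            class = "cokriging_surface")
}

#' @export
print.cokriging_surface <- function(x, ...) {
  cat(sprintf("co-kriging surface: %d x %d cells of %.6g m, prediction range [%.4g, %.4g]\n",
              length(x$x), length(x$y), x$cell, min(x$pred), max(x$pred)))
  invisible(x)
}

#' Per-tract zonal maximum of a surface
#'
#' Maximum of the cell values whose centres fall inside each tract (partition
#' convention of [assign_tracts()]).  A tract containing no cell centre falls
#' back to a single prediction at its centroid via `fallback_predict` when
#' supplied (NA with a warning otherwise).
#'
#' @param surface a `cokriging_surface`
#' @param tracts `tract_records`
#' @param fallback_predict optional `function(s0)` returning a prediction at
#'   a point, used for tracts smaller than a grid cell
#' @return named numeric vector of maxima ordered by `tract_id`
#' @export
zonal_max <- function(surface, tracts, fallback_predict = NULL) {
  centers <- cbind(rep(surface$x, times = length(surface$y)),
                   rep(surface$y, each = length(surface$x)))
  tid <- assign_tracts(centers, tracts)
  vals <- as.numeric(surface$pred)
  ids <- sort(tracts$tract_id)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  ok <- !is.na(tid)
  if (any(ok)) {
    mx <- tapply(vals[ok], tid[ok], max)
    out[names(mx)] <- as.numeric(mx)
  }
  empty <- names(out)[is.na(out)]
  for (id in empty) {
    if (is.null(fallback_predict)) {
      warning("tract ", id, " contains no grid cell centre and no fallback predictor")
    } else {
      ctr <- .mp_centroid(tracts$geometry[[match(id, tracts$tract_id)]])
      out[id] <- fallback_predict(ctr)
      warning("tract ", id, " contains no grid cell centre; centroid fallback used")
    }
  }
  out
}

#' Percent-of-total normalization of zonal maxima
#'
#' `p_i = 100 * m_i / sum(m)`; the output sums to 100 to within 1e-9.
#'
#' @param maxima named numeric vector of per-tract zonal maxima (finite)
#' @return named numeric vector of percentages
#' @export
percent_of_total <- function(maxima) {
  if (any(!is.finite(maxima))) stop("zonal maxima must all be finite")
  tot <- sum(maxima)
  if (tot <= 0) stop("degenerate input: total of zonal maxima is not positive")
  100 * maxima / tot
}

# ---------------------------------------------------------------------------
# Gaussian random field simulation (used by tests and calibration)

#' Simulate a Gaussian random field at given locations
#'
#' Cholesky simulation under a `variogram_model`: covariance
#' `C(h) = psill * (1 - curve(h)) + nugget * 1[h = 0]`.
#'
#' @param coords n x 2 matrix of locations
#' @param model a `variogram_model`
#' @param mean constant mean
#' @return numeric vector of length n (uses the current RNG state)
#' @export
simulate_grf <- function(coords, model, mean = 0) {
  coords <- as.matrix(coords)
  D <- .cross_dist(coords, coords)
  C <- model$psill * (1 - .vgm_curve(model$family, D, model$range))
  diag(C) <- model$psill + model$nugget
  L <- chol(C + diag(1e-10 * (model$psill + model$nugget), nrow(C)))
  mean + as.numeric(crossprod(L, stats::rnorm(nrow(C))))
}
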