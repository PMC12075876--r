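# Shared fixture builders and independent oracles, all generated in code.

square_ring <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

# nx x ny grid of square tracts with side `side` metres
make_grid_tracts <- function(nx, ny, side, urban = NA) {
  n <- nx * ny
  geom <- vector("list", n)
  k <- 0L
  for (cx in seq_len(nx)) for (cy in seq_len(ny)) {
    k <- k + 1L
    geom[[k]] <- list(list(square_ring((cx - 1L) * side, (cy - 1L) * side, side)))
  }
  tract_records(sprintf("T%03d", seq_len(n)), geom, urban = urban)
}

rand_farms <- function(n, extent, seed) {
  set.seed(seed)
  farm_records(sprintf("F%04d", seq_len(n)),
               runif(n, 0, extent), runif(n, 0, extent),
               sample(18:64680, n, replace = TRUE),
               sample(0:13, n, replace = TRUE))
}

rand_addresses <- function(n, extent, seed) {
  set.seed(seed)
  address_records(sprintf("A%05d", seq_len(n)),
                  runif(n, 0, extent), runif(n, 0, extent))
}

# --- independent oracles -------------------------------------------------

# shoelace-by-triangulation: fan from the first vertex
triangulation_area_m2 <- function(ring) {
  n <- nrow(ring)
  a <- 0
  for (i in 2:(n - 1L)) {
    v1 <- ring[i, ] - ring[1L, ]
    v2 <- ring[i + 1L, ] - ring[1L, ]
    a <- a + (v1[1L] * v2[2L] - v1[2L] * v2[1L]) / 2
  }
  abs(a)
}

# winding-number containment oracle (nonzero rule; convex/simple rings only,
# where it agrees with even-odd)
winding_inside <- function(p, ring) {
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[(i %% n) + 1L, ]
    is_left <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (p[1L] - a[1L]) * (b[2L] - a[2L])
    if (a[2L] <= p[2L]) {
      if (b[2L] > p[2L] && is_left > 0) wn <- wn + 1
    } else {
      if (b[2L] <= p[2L] && is_left < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# exhaustive O(F*A) buffer scan
brute_near_farm_ids <- function(farms, addresses, radius) {
  if (!nrow(farms) || !nrow(addresses)) return(character())
  hit <- vapply(seq_len(nrow(addresses)), function(i) {
    d2 <- (farms$x - addresses$x[i])^2 + (farms$y - addresses$y[i])^2
    any(d2 <= radius^2)
  }, logical(1L))
  sort(addresses$address_id[hit])
}

# all-pairs double-loop semivariogram oracle
brute_semivariogram <- function(coords, zu, zv, n_lags, lag_width) {
  n <- nrow(coords)
  sums <- numeric(n_lags); np <- integer(n_lags)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    b <- ceiling(d / lag_width)
    if (d == 0) b <- 1L
    if (b >= 1L && b <= n_lags) {
      sums[b] <- sums[b] + (zu[i] - zu[j]) * (zv[i] - zv[j])
      np[b] <- np[b] + 1L
    }
  }
  list(np = np, gamma = ifelse(np > 0, sums / (2 * np), NA_real_))
}

# spherical semivariogram evaluated from first principles (oracle side)
oracle_gamma <- function(lmc, h, u, v) {
  g <- 0
  for (s in lmc$structures) {
    base <- if (s$family == "nugget") as.numeric(h > 0)
    else if (s$family == "spherical") {
      hh <- pmin(h / s$range, 1)
      1.5 * hh - 0.5 * hh^3
    } else stop("oracle only knows nugget/spherical")
    g <- g + s$B[u, v] * base
  }
  g
}

# dense ordinary co-kriging oracle: full system assembled from first
# principles and solved by QR elimination
oracle_cokrige <- function(s0, coords, z1, z2, lmc) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  d0 <- sqrt((coords[, 1L] - s0[1L])^2 + (coords[, 2L] - s0[2L])^2)
  A <- matrix(0, 2 * n + 2, 2 * n + 2)
  A[1:n, 1:n] <- oracle_gamma(lmc, D, 1, 1)
  A[1:n, (n + 1):(2 * n)] <- oracle_gamma(lmc, D, 1, 2)
  A[(n + 1):(2 * n), 1:n] <- oracle_gamma(lmc, D, 2, 1)
  A[(n + 1):(2 * n), (n + 1):(2 * n)] <- oracle_gamma(lmc, D, 2, 2)
  A[1:n, 2 * n + 1] <- 1; A[2 * n + 1, 1:n] <- 1
  A[(n + 1):(2 * n), 2 * n + 2] <- 1; A[2 * n + 2, (n + 1):(2 * n)] <- 1
  b <- c(oracle_gamma(lmc, d0, 1, 1), oracle_gamma(lmc, d0, 1, 2), 1, 0)
  lam <- qr.solve(A, b)
  sum(lam[1:n] * z1) + sum(lam[(n + 1):(2 * n)] * z2)
}

# random valid two-structure LMC (nugget + spherical) via A %*% t(A)
rand_lmc <- function(seed, range = NULL) {
  set.seed(seed)
  if (is.null(range)) range <- runif(1, 2000, 10000)
  psd <- function() { A <- matrix(rnorm(4), 2L); A %*% t(A) }
  lmc_model(list(list(family = "nugget", B = psd() * 0.2),
                 list(family = "spherical", range = range, B = psd())))
}
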