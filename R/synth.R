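# Synthetic study-region generator.
#
# Emulates the statistical structure the analysis assumes: a rectangular
# partition of square tracts with a contiguous urban block covered by city
# limits, swine farms concentrated in rural tracts with log-normal permitted
# head counts and head-coupled lagoon counts, Thomas-style clustered address
# points, and latent-factor vulnerability rankings with plantable SVI-EJI
# rank correlation and missing values.

# One global seed expands to per-component seeds by a fixed affine rule so
# stages can be regenerated independently of each other.
.split_seed <- function(seed, component) {
  offs <- c(region = 1L, farms = 2L, addresses = 3L, vulnerability = 4L)
  k <- offs[[component]]
  as.integer((as.double(seed) %% 1048573) * 1009 + 7919 * k) %% 2147483647L
}

#' Synthetic-region configuration objects
#'
#' Constructors for the four generator configurations.  Defaults describe
#' the study conditions the generators emulate: a 10 x 10 grid of square
#' tracts with a contiguous urban block, ~2,000 farms with log-normal
#' permitted head (median 3,500, clipped to \[18, 64,680\]) concentrated in
#' rural tracts, clustered addresses mostly in urban tracts, and percentile
#' vulnerability rankings whose latent correlation yields a Spearman
#' SVI-EJI association near 0.5.
#'
#' @param n_tracts_x,n_tracts_y grid dimensions (>= 1)
#' @param tract_side tract side length in miles (> 0)
#' @param urban_fraction fraction of tracts labelled urban, in \[0, 1\]
#' @param seed integer seed
#' @return a classed list of validated parameters
#' @export
region_config <- function(n_tracts_x = 10L, n_tracts_y = 10L, tract_side = 4,
                          urban_fraction = 0.2, seed = 1L) {
  stopifnot(n_tracts_x >= 1, n_tracts_y >= 1, tract_side > 0,
            urban_fraction >= 0, urban_fraction <= 1)
  structure(list(n_tracts_x = as.integer(n_tracts_x),
                 n_tracts_y = as.integer(n_tracts_y),
                 tract_side = tract_side, urban_fraction = urban_fraction,
                 seed = as.integer(seed)),
            class = "region_config")
}

#' @rdname region_config
#' @param n_farms number of farms
#' @param head_log_mean,head_log_sd log-normal parameters of permitted head
#' @param head_min,head_max clip bounds on permitted head
#' @param lagoon_slope expected lagoons per unit log(head)
#' @param lagoon_max upper clip on lagoon count
#' @param rural_intensity_ratio farm-placement intensity rural : urban
#' @export
farm_gen_config <- function(n_farms = 2000L, head_log_mean = log(3500),
                            head_log_sd = 0.9, head_min = 18L, head_max = 64680L,
                            lagoon_slope = 0.3, lagoon_max = 13L,
                            rural_intensity_ratio = 4, seed = 1L) {
  stopifnot(n_farms >= 0, head_min >= 1, head_min < head_max,
            lagoon_max >= 0, rural_intensity_ratio > 0, head_log_sd > 0)
  structure(list(n_farms = as.integer(n_farms), head_log_mean = head_log_mean,
                 head_log_sd = head_log_sd, head_min = as.integer(head_min),
                 head_max = as.integer(head_max), lagoon_slope = lagoon_slope,
                 lagoon_max = as.integer(lagoon_max),
                 rural_intensity_ratio = rural_intensity_ratio,
                 seed = as.integer(seed)),
            class = "farm_gen_config")
}

#' @rdname region_config
#' @param n_addresses number of address points (>= 0)
#' @param cluster_count number of cluster centres per stratum
#' @param cluster_sd Gaussian scatter of points about centres, metres
#' @param urban_share fraction of addresses placed in urban tracts
#' @export
address_gen_config <- function(n_addresses = 8000L, cluster_count = 50L,
                               cluster_sd = 800, urban_share = 0.8, seed = 1L) {
  stopifnot(n_addresses >= 0, cluster_count >= 1, cluster_sd > 0,
            urban_share >= 0, urban_share <= 1)
  structure(list(n_addresses = as.integer(n_addresses),
                 cluster_count = as.integer(cluster_count),
                 cluster_sd = cluster_sd, urban_share = urban_share,
                 seed = as.integer(seed)),
            class = "address_gen_config")
}

#' @rdname region_config
#' @param rural_svi_shift additive effect of rurality on the SVI latent
#' @param svi_eji_latent_corr shared-factor loading in \[-1, 1\]; the SVI and
#'   EJI latents each load on one common Gaussian factor with this loading,
#'   so their Pearson correlation is the loading squared
#' @param missing_fraction fraction of tracts with a missing rank, in \[0, 1)
#' @export
vuln_gen_config <- function(rural_svi_shift = 0.5, svi_eji_latent_corr = 0.72,
                            missing_fraction = 0.01, seed = 1L) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1,
            abs(svi_eji_latent_corr) <= 1)
  structure(list(rural_svi_shift = rural_svi_shift,
                 svi_eji_latent_corr = svi_eji_latent_corr,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "vuln_gen_config")
}

#' Generate the synthetic study region
#'
#' Builds a rectangular grid of square tracts plus the city-limit polygons.
#' A contiguous column-major block of `round(urban_fraction * n)` tracts is
#' designated urban and each urban tract is fully covered by a city-limit
#' rectangle, so classifying tracts by the >= 50 percent land-area rule
#' reproduces the planted urban labels exactly.
#'
#' @param cfg a [region_config()]
#' @return list with elements `tracts` (a `tract_records` collection with
#'   `urban` set) and `city` (list of city-limit polygons)
#' @export
generate_region <- function(cfg = region_config()) {
  stopifnot(inherits(cfg, "region_config"))
  nx <- cfg$n_tracts_x; ny <- cfg$n_tracts_y
  n <- nx * ny
  side <- cfg$tract_side * METERS_PER_MILE
  # column-major order makes the first k tracts a contiguous block of columns
  col <- rep(seq_len(nx), each = ny)
  row <- rep(seq_len(ny), times = nx)
  ids <- sprintf("T%04d", seq_len(n))
  geom <- vector("list", n)
  for (i in seq_len(n)) {
    x0 <- (col[i] - 1L) * side; y0 <- (row[i] - 1L) * side
    ring <- cbind(c(x0, x0 + side, x0 + side, x0),
                  c(y0, y0, y0 + side, y0 + side))
    geom[[i]] <- list(list(ring))
  }
  k <- round(cfg$urban_fraction * n)
  urban <- seq_len(n) <= k
  tracts <- tract_records(ids, geom, urban = urban)
  city <- lapply(which(urban), function(i) tracts$geometry[[i]][[1L]])
  list(tracts = tracts, city = city)
}

.stratum_indices <- function(tracts, want_urban) {
  idx <- which(!is.na(tracts$urban) & tracts$urban == want_urban)
  if (!length(idx)) which(!is.na(tracts$urban) & tracts$urban == !want_urban)
  else idx
}

# Uniform point inside a tract: rejection from the bounding box.  Synthetic
# tracts are squares, so acceptance is immediate; the loop is a safety net
# for general geometries.
.runif_in_tract <- function(mp) {
  bb <- .mp_bbox(mp)
  for (it in 1:1000) {
    p <- c(stats::runif(1, bb["xmin"], bb["xmax"]),
           stats::runif(1, bb["ymin"], bb["ymax"]))
    if (point_in_multipolygon(p, mp)) return(p)
  }
  .mp_centroid(mp)
}

#' Generate synthetic swine farms
#'
#' Each farm picks a tract with probability proportional to the placement
#' intensity (`rural_intensity_ratio` for rural tracts, 1 for urban) and a
#' uniform location inside it.  Permitted head is a rounded log-normal
#' clipped to `[head_min, head_max]`; the lagoon count is a Poisson draw
#' with mean `lagoon_slope * log(head)` clipped to `lagoon_max`, which
#' plants the cross-correlation the co-kriging stage estimates.
#'
#' @param tracts tract collection from [generate_region()]
#' @param cfg a [farm_gen_config()]
#' @return `farm_records`
#' @export
generate_farms <- function(tracts, cfg = farm_gen_config()) {
  stopifnot(inherits(cfg, "farm_gen_config"))
  set.seed(.split_seed(cfg$seed, "farms"))
  n <- cfg$n_farms
  if (n == 0L)
    return(farm_records(character(), numeric(), numeric(), numeric(), numeric()))
  w <- ifelse(!is.na(tracts$urban) & !tracts$urban, cfg$rural_intensity_ratio, 1)
  ti <- sample.int(nrow(tracts), n, replace = TRUE, prob = w)
  xy <- t(vapply(ti, function(i) .runif_in_tract(tracts$geometry[[i]]),
                 numeric(2L)))
  head_raw <- stats::rlnorm(n, cfg$head_log_mean, cfg$head_log_sd)
  head <- pmin(pmax(round(head_raw), cfg$head_min), cfg$head_max)
  lag <- pmin(stats::rpois(n, cfg$lagoon_slope * log(head)), cfg$lagoon_max)
  farm_records(sprintf("F%05d", seq_len(n)), xy[, 1L], xy[, 2L], head, lag)
}

#' Generate synthetic address points
#'
#' Thomas-style clustered point process stratified by urbanicity: each
#' address draws its stratum (urban with probability `urban_share`), picks a
#' cluster centre of that stratum uniformly, and scatters about it with an
#' isotropic Gaussian of sd `cluster_sd`, resampling the offset until the
#' point lands inside its stratum so the expected urban share is exactly
#' `urban_share`.
#'
#' @param tracts tract collection with urban labels
#' @param cfg an [address_gen_config()]
#' @return `address_records`
#' @export
generate_addresses <- function(tracts, cfg = address_gen_config()) {
  stopifnot(inherits(cfg, "address_gen_config"))
  set.seed(.split_seed(cfg$seed, "addresses"))
  n <- cfg$n_addresses
  if (n == 0L) return(address_records(character(), numeric(), numeric()))
  strata <- list(urban = .stratum_indices(tracts, TRUE),
                 rural = .stratum_indices(tracts, FALSE))
  centers <- lapply(strata, function(idx) {
    t(vapply(seq_len(cfg$cluster_count), function(j) {
      i <- idx[1L + (j - 1L) %% length(idx)]
      .runif_in_tract(tracts$geometry[[i]])
    }, numeric(2L)))
  })
  tract_urban <- stats::setNames(tracts$urban, tracts$tract_id)
  want_urb <- stats::runif(n) < cfg$urban_share
  xs <- rep(NA_real_, n); ys <- rep(NA_real_, n)
  pending <- seq_len(n)
  for (round in 1:100) {
    if (!length(pending)) break
    st <- ifelse(want_urb[pending], "urban", "rural")
    px <- numeric(length(pending)); py <- numeric(length(pending))
    for (s in c("urban", "rural")) {
      sel <- which(st == s)
      if (!length(sel)) next
      ctr <- centers[[s]]
      ci <- sample.int(nrow(ctr), length(sel), replace = TRUE)
      px[sel] <- ctr[ci, 1L] + stats::rnorm(length(sel), 0, cfg$cluster_sd)
      py[sel] <- ctr[ci, 2L] + stats::rnorm(length(sel), 0, cfg$cluster_sd)
    }
    tid <- assign_tracts(cbind(px, py), tracts)
    u <- unname(tract_urban[tid])
    ok <- !is.na(tid) & !is.na(u) & (u == want_urb[pending])
    xs[pending[ok]] <- px[ok]; ys[pending[ok]] <- py[ok]
    pending <- pending[!ok]
  }
  for (i in pending) {  # safety net: uniform in a random tract of the stratum
    idx <- strata[[if (want_urb[i]) "urban" else "rural"]]
    p <- .runif_in_tract(tracts$geometry[[idx[sample.int(length(idx), 1L)]]])
    xs[i] <- p[1L]; ys[i] <- p[2L]
  }
  address_records(sprintf("A%06d", seq_len(n)), xs, ys)
}

#' Generate synthetic vulnerability rankings
#'
#' Per tract, a shared standard-Gaussian factor F and idiosyncratic noise
#' build two latents: `svi = loading*F + sqrt(1-loading^2)*e1 +
#' rural_svi_shift*1[rural]` and `eji = loading*F + sqrt(1-loading^2)*e2`.
#' Ranks are percentile transforms `(rank - 0.5)/n` with average-rank ties;
#' a `missing_fraction` of tracts (sampled independently per variable) gets
#' NA, mirroring the null tracts in the public rankings.
#'
#' @param tracts tract collection with urban labels
#' @param cfg a [vuln_gen_config()]
#' @return the tract collection with `svi_rank`, `eji_rank` filled
#' @export
generate_vulnerability <- function(tracts, cfg = vuln_gen_config()) {
  stopifnot(inherits(cfg, "vuln_gen_config"))
  set.seed(.split_seed(cfg$seed, "vulnerability"))
  n <- nrow(tracts)
  lam <- cfg$svi_eji_latent_corr
  f <- stats::rnorm(n)
  e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
  rural <- !is.na(tracts$urban) & !tracts$urban
  svi_lat <- lam * f + sqrt(1 - lam^2) * e1 + cfg$rural_svi_shift * rural
  eji_lat <- lam * f + sqrt(1 - lam^2) * e2
  pct <- function(z) (rank(z, ties.method = "average") - 0.5) / length(z)
  svi <- pct(svi_lat); eji <- pct(eji_lat)
  n_miss <- round(cfg$missing_fraction * n)
  if (n_miss > 0) {
    svi[sample.int(n, n_miss)] <- NA_real_
    eji[sample.int(n, n_miss)] <- NA_real_
  }
  tracts$svi_rank <- svi
  tracts$eji_rank <- eji
  tracts
}

#' Calibrate the latent loading for a target rank correlation
#'
#' Simulation oracle mapping the shared-factor loading to the expected
#' Spearman correlation between the two generated rankings, inverted by
#' monotone interpolation over a loading grid.  Used to choose
#' `svi_eji_latent_corr` so the synthetic SVI-EJI association matches a
#' target (the closed-form bivariate-normal relation rho_S =
#' (6/pi) asin(r/2) with r = loading^2 gives the same answer and is a handy
#' cross-check).
#'
#' @param target_rho desired Spearman correlation in (0, 1)
#' @param n tracts per simulated draw
#' @param n_draws Monte-Carlo draws per grid point
#' @param seed integer seed
#' @return the calibrated loading
#' @export
calibrate_latent_corr <- function(target_rho, n = 400L, n_draws = 40L, seed = 1L) {
  stopifnot(target_rho > 0, target_rho < 1)
  set.seed(as.integer(seed))
  grid <- seq(0.05, 0.999, length.out = 25L)
  mean_rho <- vapply(grid, function(lam) {
    mean(replicate(n_draws, {
      f <- stats::rnorm(n); e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
      a <- lam * f + sqrt(1 - lam^2) * e1
      b <- lam * f + sqrt(1 - lam^2) * e2
      stats::cor(rank(a), rank(b))
    }))
  }, numeric(1L))
  # monotone in the loading; invert by linear interpolation
  stats::approx(mean_rho, grid, xout = target_rho, rule = 2)$y
}
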