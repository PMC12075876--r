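# Urban/rural classification, Spearman correlation matrices among the three
# exposure indices and the vulnerability rankings, the >= 0.1 reporting
# filter, and geometric-interval map classes.

# ---------------------------------------------------------------------------
# Urban classification

.is_convex_ring <- function(ring) {
  m <- .ring_mat(ring)
  n <- nrow(m)
  if (n < 3L) return(FALSE)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- m[i, ]; b <- m[(i %% n) + 1L, ]; c <- m[((i + 1L) %% n) + 1L, ]
    cr <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
    if (cr != 0) {
      s <- sign(cr)
      if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
    }
  }
  TRUE
}

.ensure_ccw <- function(ring) {
  m <- .ring_mat(ring)
  if (.ring_area_signed(m) < 0) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
}

# Sutherland-Hodgman: clip a subject ring against one convex clip ring (CCW).
.clip_ring <- function(subject, clip) {
  out <- .ring_mat(subject)
  clip <- .ensure_ccw(clip)
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    a <- clip[e, ]; b <- clip[(e %% nc) + 1L, ]
    if (nrow(out) == 0L) return(out)
    input <- out
    out <- matrix(numeric(), ncol = 2L)
    n <- nrow(input)
    side <- (b[1L] - a[1L]) * (input[, 2L] - a[2L]) -
      (b[2L] - a[2L]) * (input[, 1L] - a[1L])
    for (i in seq_len(n)) {
      j <- (i %% n) + 1L
      p <- input[i, ]; q <- input[j, ]
      pin <- side[i] >= 0; qin <- side[j] >= 0
      if (pin) out <- rbind(out, p)
      if (pin != qin) {
        # intersection of segment pq with the (infinite) clip edge ab
        denom <- side[i] - side[j]
        t <- side[i] / denom
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  out
}

# Area (m^2) of the intersection of a subject ring with a convex clip ring.
.clip_area <- function(subject, clip) {
  res <- .clip_ring(subject, clip)
  if (nrow(res) < 3L) return(0)
  x <- res[, 1L]; y <- res[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y) / 2)
}

# Halton quasi-random sequence in [0, 1).
.halton <- function(n, base) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1; r <- 0; k <- i
    while (k > 0) {
      f <- f / base
      r <- r + f * (k %% base)
      k <- k %/% base
    }
    out[i] <- r
  }
  out
}

# Fraction of a tract's area inside the union of city polygons, by
# deterministic quasi-Monte-Carlo (Halton bases 2 and 3) over the tract bbox.
.mc_city_fraction <- function(mp, city, n_points = 10000L) {
  bb <- .mp_bbox(mp)
  px <- bb["xmin"] + .halton(n_points, 2L) * (bb["xmax"] - bb["xmin"])
  py <- bb["ymin"] + .halton(n_points, 3L) * (bb["ymax"] - bb["ymin"])
  pts <- cbind(px, py)
  inside <- point_in_multipolygon(pts, mp)
  if (!any(inside)) return(0)
  sub <- pts[inside, , drop = FALSE]
  incity <- logical(nrow(sub))
  for (poly in city) incity <- incity | point_in_polygon(sub, poly)
  sum(incity) / sum(inside)
}

#' Classify tracts as urban by city-limit coverage
#'
#' A tract is urban iff at least 50 percent of its land area lies within the
#' union of the city-limit polygons (inclusive at exactly 50 percent).  For
#' convex, non-overlapping city polygons the intersection areas are computed
#' exactly by Sutherland-Hodgman clipping and summed; holes in tract
#' geometry, or any non-convex city polygon, switch that tract to a
#' deterministic quasi-Monte-Carlo area fraction (10,000 Halton points, with
#' a message).
#'
#' @param tracts `tract_records`
#' @param city_polygons list of city-limit polygons (each a list of rings or
#'   a bare ring matrix)
#' @return the tract collection with the `urban` flag (and an
#'   `urban_area_fraction` column) set
#' @export
classify_urban <- function(tracts, city_polygons) {
  city <- lapply(city_polygons, function(p) if (is.matrix(p)) list(p) else p)
  city_rings <- lapply(city, function(p) p[[1L]])
  all_convex <- all(vapply(city_rings, .is_convex_ring, logical(1L)))
  if (!all_convex)
    message("non-convex city polygon: using quasi-Monte-Carlo area fractions")
  frac <- numeric(nrow(tracts))
  for (i in seq_len(nrow(tracts))) {
    mp <- tracts$geometry[[i]]
    has_holes <- any(vapply(mp, function(poly) length(poly) > 1L, logical(1L)))
    area_m2 <- multipolygon_area(mp) * SQMETERS_PER_SQMILE
    if (all_convex && !has_holes) {
      inter <- 0
      for (poly in mp)
        for (ring in city_rings)
          inter <- inter + .clip_area(poly[[1L]], ring)
      frac[i] <- inter / area_m2
    } else {
      frac[i] <- .mc_city_fraction(mp, city)
    }
  }
  tracts$urban <- frac >= 0.5
  tracts$urban_area_fraction <- frac
  tracts
}

# ---------------------------------------------------------------------------
# Spearman correlation with pairwise deletion

#' Spearman rank correlation with pairwise deletion
#'
#' Average ranks for ties; rho is the Pearson correlation of the two rank
#' vectors after removing pairs with a missing value in either argument.
#' Fewer than 3 complete pairs, or zero rank variance in either argument,
#' yields an undefined result (`rho = NA`, flagged), never 0.
#'
#' @param x,y numeric vectors of equal length, NA = missing
#' @return list with `rho`, `n_pairs`, `defined`
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(rho = NA_real_, n_pairs = n, defined = FALSE))
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, n_pairs = n, defined = FALSE))
  list(rho = stats::cor(rx, ry), n_pairs = n, defined = TRUE)
}

# round half away from zero, for display parity with printed matrices
.round_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Stratified Spearman correlation matrix
#'
#' All unordered pairs among `idx1`, `idx2`, `idx3`, `svi`, `eji`, computed
#' per stratum (`all`, `urban`, `rural`) with pairwise deletion of missing
#' values.  Values are stored at full precision with a display rounding to
#' one decimal (half away from zero).  Empty strata are omitted with a
#' warning.
#'
#' @param exposure exposure table with `tract_id`, `idx1_count`,
#'   `idx2_percent`, `idx3_density`
#' @param tracts `tract_records` with urban flags and rankings
#' @return data.frame of class `correlation_matrix` with columns `stratum`,
#'   `var_a`, `var_b`, `rho`, `rho_rounded`, `n_pairs`
#' @export
correlation_matrix <- function(exposure, tracts) {
  m <- match(tracts$tract_id, exposure$tract_id)
  if (anyNA(m)) stop("exposure table missing tracts: ",
                     paste(tracts$tract_id[is.na(m)], collapse = ", "))
  dat <- data.frame(idx1 = exposure$idx1_count[m],
                    idx2 = exposure$idx2_percent[m],
                    idx3 = exposure$idx3_density[m],
                    svi = tracts$svi_rank,
                    eji = tracts$eji_rank)
  strata <- list(all = rep(TRUE, nrow(dat)),
                 urban = !is.na(tracts$urban) & tracts$urban,
                 rural = !is.na(tracts$urban) & !tracts$urban)
  vars <- names(dat)
  pairs <- utils::combn(vars, 2L)
  rows <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    if (!any(sel)) {
      warning("stratum '", s, "' has no tracts; omitted")
      next
    }
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      r <- spearman_cor(dat[[a]][sel], dat[[b]][sel])
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = s, var_a = a, var_b = b, rho = r$rho,
                   rho_rounded = .round_away(r$rho), n_pairs = r$n_pairs,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_matrix", "data.frame")
  out
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman correlations (pairwise complete cases)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Narrative reporting filter for the correlation matrix
#'
#' Retains pairs with `|rho| >= threshold` in any stratum for the narrative
#' report (the full matrix is always kept alongside), and flags pairs whose
#' display-rounded rho differs between the urban and rural strata.
#'
#' @param matrix a `correlation_matrix`
#' @param threshold reporting threshold on `|rho|`, default 0.1
#' @return list with `reported` (filtered rows), `full` (input), and
#'   `differs` (data.frame of pairs with `urban_rho`, `rural_rho` whose
#'   rounded values differ between the two strata)
#' @export
filter_report <- function(matrix, threshold = 0.1) {
  keep <- !is.na(matrix$rho) & abs(matrix$rho) >= threshold
  reported <- matrix[keep, , drop = FALSE]
  u <- matrix[matrix$stratum == "urban", , drop = FALSE]
  r <- matrix[matrix$stratum == "rural", , drop = FALSE]
  key <- function(d) paste(d$var_a, d$var_b)
  common <- intersect(key(u), key(r))
  iu <- match(common, key(u)); ir <- match(common, key(r))
  diff_sel <- !is.na(u$rho_rounded[iu]) & !is.na(r$rho_rounded[ir]) &
    u$rho_rounded[iu] != r$rho_rounded[ir]
  differs <- data.frame(var_a = u$var_a[iu][diff_sel],
                        var_b = u$var_b[iu][diff_sel],
                        urban_rho = u$rho_rounded[iu][diff_sel],
                        rural_rho = r$rho_rounded[ir][diff_sel],
                        stringsAsFactors = FALSE)
  list(reported = reported, full = matrix, differs = differs)
}

# ---------------------------------------------------------------------------
# Geometric-interval map classes

#' Geometric-interval class breaks with a zero class
#'
#' Zeros get a dedicated class 0.  Positive values are classed by a
#' multiplicative progression: with `r = (v_max / v_min)^(1/k)`, the breaks
#' are `b_i = v_min * r^i` and class j covers `(b_(j-1), b_j]`
#' (upper-inclusive), so every positive value falls in exactly one of the
#' `k` classes.
#'
#' @param values numeric vector, nonnegative; at least one strictly positive
#'   value unless all are zero
#' @param k number of positive classes (>= 2)
#' @return object of class `class_breaks`: list with `k`, `breaks` (the
#'   interior breaks `b_1..b_(k-1)`), `v_min`, `v_max`, `zero_class`
#' @export
geometric_breaks <- function(values, k = 5L) {
  stopifnot(k >= 2L)
  if (any(values < 0)) stop("geometric intervals need nonnegative values")
  pos <- values[values > 0]
  if (!length(pos)) {
    return(structure(list(k = 0L, breaks = numeric(), v_min = NA_real_,
                          v_max = NA_real_, zero_class = TRUE),
                     class = "class_breaks"))
  }
  v_min <- min(pos); v_max <- max(pos)
  if (v_min == v_max) {
    return(structure(list(k = 1L, breaks = numeric(), v_min = v_min,
                          v_max = v_max, zero_class = any(values == 0)),
                     class = "class_breaks"))
  }
  r <- (v_max / v_min)^(1 / k)
  breaks <- v_min * r^seq_len(k - 1L)
  structure(list(k = as.integer(k), breaks = breaks, v_min = v_min,
                 v_max = v_max, zero_class = any(values == 0)),
            class = "class_breaks")
}

#' Assign geometric-interval classes
#'
#' @param values nonnegative numeric vector
#' @param breaks a `class_breaks` from [geometric_breaks()]
#' @return integer classes: 0 for zero values, 1..k for positive values
#' @export
assign_classes <- function(values, breaks) {
  stopifnot(inherits(breaks, "class_breaks"))
  out <- integer(length(values))
  pos <- values > 0
  if (breaks$k == 0L) {
    if (any(pos)) stop("positive values but zero-only class breaks")
    return(out)
  }
  if (any(pos)) {
    cls <- rep(1L, sum(pos))
    for (b in breaks$breaks) cls <- cls + (values[pos] > b)
    out[pos] <- pmin(cls, max(breaks$k, 1L))
  }
  out
}

#' @export
print.class_breaks <- function(x, ...) {
  if (x$k == 0L) cat("class breaks: zero class only\n")
  else cat(sprintf("class breaks: %d geometric classes on (%.6g, %.6g], zero class %s\n",
                   x$k, x$v_min, x$v_max, if (x$zero_class) "yes" else "no"))
  invisible(x)
}
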