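# Planar geometry primitives and GeoJSON/CSV interchange.
#
# All geometry is in a projected planar CRS in metres; the package performs
# no reprojection.  Polygons are lists of rings, each ring an n x 2 numeric
# matrix of vertices (closure implicit: the last vertex need not repeat the
# first).  The first ring is the exterior, further rings are holes.  A tract
# geometry is a multipolygon: a list of such polygons.

#' Unit constants
#'
#' One mile and one square mile in metric units, used everywhere a
#' mile-based quantity (buffer radius, tract side, density denominator)
#' meets the metre-based geometry.
#'
#' @format `METERS_PER_MILE` is 1609.344 exactly; `SQMETERS_PER_SQMILE` is
#'   2589988.110336 exactly.
#' @name units
#' @keywords internal
METERS_PER_MILE <- 1609.344
SQMETERS_PER_SQMILE <- 2589988.110336

.ring_mat <- function(ring) {
  m <- as.matrix(ring)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("ring must be an n x 2 matrix of vertices")
  # drop explicit closure so vertices are unique
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  m
}

.ring_area_signed <- function(ring) {
  m <- .ring_mat(ring)
  if (nrow(unique(m)) < 3L) stop("degenerate ring: fewer than 3 distinct vertices")
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Planar polygon area in square miles
#'
#' Shoelace area of the exterior ring minus any interior rings, converted
#' from square metres (1 sq mile = 2,589,988.110336 m^2).  For a
#' multipolygon pass a list of polygons to [multipolygon_area()].
#'
#' @param poly a polygon: list of rings, each an n x 2 matrix in metres;
#'   the first ring is the exterior.  A bare matrix is taken as a single
#'   exterior ring.
#' @return area in square miles (> 0 for a valid polygon).
#' @examples
#' sq <- cbind(c(0, 1609.344, 1609.344, 0), c(0, 0, 1609.344, 1609.344))
#' polygon_area(list(sq))  # 1 square mile
#' @export
polygon_area <- function(poly) {
  if (is.matrix(poly)) poly <- list(poly)
  areas <- vapply(poly, function(r) abs(.ring_area_signed(r)), numeric(1L))
  a <- if (length(areas) == 1L) areas else areas[1L] - sum(areas[-1L])
  if (a <= 0) stop("polygon has non-positive area")
  a / SQMETERS_PER_SQMILE
}

#' @rdname polygon_area
#' @param mp a multipolygon: list of polygons.
#' @export
multipolygon_area <- function(mp) {
  sum(vapply(mp, polygon_area, numeric(1L)))
}

#' Euclidean planar distance
#'
#' @param a,b length-2 numeric vectors (x, y) in metres.
#' @return distance in metres.
#' @export
point_distance <- function(a, b) {
  sqrt((a[1L] - b[1L])^2 + (a[2L] - b[2L])^2)
}

# All pairwise distances between rows of two coordinate matrices.  Uses
# coordinate differences (not the a^2 + b^2 - 2ab expansion) so identical
# points get an exactly zero distance — the nugget discontinuity at h = 0
# must never fire at a data point's own location.
.cross_dist <- function(A, B) {
  sqrt(outer(A[, 1L], B[, 1L], "-")^2 + outer(A[, 2L], B[, 2L], "-")^2)
}

# Vectorised even-odd test of many points against one ring.
# Returns list(inside = parity result excluding boundary, on = on-boundary).
.pip_ring <- function(px, py, ring) {
  m <- .ring_mat(ring)
  nv <- nrow(m)
  inside <- logical(length(px))
  on <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- m[i, 1L]; yi <- m[i, 2L]
    xj <- m[j, 1L]; yj <- m[j, 2L]
    # boundary: zero cross product and within the segment's bounding box
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg <- cr == 0 &
      px >= pmin(xi, xj) & px <= pmax(xi, xj) &
      py >= pmin(yi, yj) & py <= pmax(yi, yj)
    on <- on | seg
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  list(inside = inside, on = on)
}

#' Point-in-polygon test
#'
#' Even-odd ray casting over all rings of a polygon (so holes exclude),
#' with the documented convention that points exactly on any boundary edge
#' count as inside.
#'
#' @param p length-2 numeric (x, y), or an n x 2 matrix of points.
#' @param poly polygon (list of rings) or a bare ring matrix.
#' @return logical, one value per point.
#' @export
point_in_polygon <- function(p, poly) {
  if (is.matrix(poly)) poly <- list(poly)
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 2L)
  px <- pm[, 1L]; py <- pm[, 2L]
  parity <- logical(length(px))
  on <- logical(length(px))
  for (ring in poly) {
    r <- .pip_ring(px, py, ring)
    parity <- xor(parity, r$inside)
    on <- on | r$on
  }
  parity | on
}

#' @rdname point_in_polygon
#' @param mp multipolygon (list of polygons); a point in any part is in.
#' @export
point_in_multipolygon <- function(p, mp) {
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 2L)
  res <- logical(nrow(pm))
  for (poly in mp) res <- res | point_in_polygon(pm, poly)
  res
}

.mp_bbox <- function(mp) {
  xs <- unlist(lapply(mp, function(poly) lapply(poly, function(r) .ring_mat(r)[, 1L])))
  ys <- unlist(lapply(mp, function(poly) lapply(poly, function(r) .ring_mat(r)[, 2L])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

.mp_centroid <- function(mp) {
  # area-weighted centroid of exterior rings (sufficient for fallback points)
  cx <- 0; cy <- 0; atot <- 0
  for (poly in mp) {
    m <- .ring_mat(poly[[1L]])
    x <- m[, 1L]; y <- m[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cr <- x * yn - xn * y
    a <- sum(cr) / 2
    if (a == 0) next
    cx <- cx + sum((x + xn) * cr) / 6
    cy <- cy + sum((y + yn) * cr) / 6
    atot <- atot + a
  }
  c(cx / atot, cy / atot)
}

# ---------------------------------------------------------------------------
# Record collections

#' Construct or validate a farm record table
#'
#' @param farm_id character identifiers
#' @param x,y planar coordinates in metres
#' @param permitted_head integer permitted head count, >= 1
#' @param lagoon_count integer manure-lagoon count, >= 0
#' @return data.frame of class `farm_records`
#' @export
farm_records <- function(farm_id, x, y, permitted_head, lagoon_count) {
  df <- data.frame(farm_id = as.character(farm_id), x = as.numeric(x),
                   y = as.numeric(y), permitted_head = as.numeric(permitted_head),
                   lagoon_count = as.numeric(lagoon_count),
                   stringsAsFactors = FALSE)
  validate_farms(df)
  class(df) <- c("farm_records", "data.frame")
  df
}

#' @rdname farm_records
#' @param farms object to validate
#' @export
validate_farms <- function(farms) {
  req <- c("farm_id", "x", "y", "permitted_head", "lagoon_count")
  miss <- setdiff(req, names(farms))
  if (length(miss)) stop("farm table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(farms)) {
    if (!all(is.finite(farms$x)) || !all(is.finite(farms$y)))
      stop("farm coordinates must be finite")
    if (any(farms$permitted_head < 1)) stop("permitted_head must be >= 1")
    if (any(farms$lagoon_count < 0)) stop("lagoon_count must be >= 0")
  }
  invisible(farms)
}

#' Construct or validate an address record table
#'
#' @param address_id character identifiers, unique
#' @param x,y planar coordinates in metres
#' @return data.frame of class `address_records`
#' @export
address_records <- function(address_id, x, y) {
  df <- data.frame(address_id = as.character(address_id), x = as.numeric(x),
                   y = as.numeric(y), stringsAsFactors = FALSE)
  validate_addresses(df)
  class(df) <- c("address_records", "data.frame")
  df
}

#' @rdname address_records
#' @param addresses object to validate
#' @export
validate_addresses <- function(addresses) {
  req <- c("address_id", "x", "y")
  miss <- setdiff(req, names(addresses))
  if (length(miss)) stop("address table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(addresses$address_id))
    stop("duplicate address_id values")
  if (nrow(addresses) && (!all(is.finite(addresses$x)) || !all(is.finite(addresses$y))))
    stop("address coordinates must be finite")
  invisible(addresses)
}

#' Construct or validate a tract collection
#'
#' A tract collection is a data.frame with columns `tract_id`, `land_area`
#' (square miles), `urban` (logical, NA = undetermined), `svi_rank`,
#' `eji_rank` (percentile fractions in \[0,1\], NA = missing) and a
#' `geometry` list column of multipolygons in metres.
#'
#' @param tract_id character identifiers, unique
#' @param geometry list of multipolygons (list of polygons; polygon = list
#'   of ring matrices)
#' @param land_area square miles; computed from geometry when NULL/NA
#' @param urban logical or NA
#' @param svi_rank,eji_rank percentile ranks in \[0,1\] or NA
#' @return data.frame of class `tract_records`
#' @export
tract_records <- function(tract_id, geometry, land_area = NULL,
                          urban = NA, svi_rank = NA_real_, eji_rank = NA_real_) {
  tract_id <- as.character(tract_id)
  n <- length(tract_id)
  geometry <- lapply(geometry, .as_multipolygon)
  if (is.null(land_area)) land_area <- rep(NA_real_, n)
  land_area <- as.numeric(land_area)
  need <- is.na(land_area)
  if (any(need))
    land_area[need] <- vapply(geometry[need], multipolygon_area, numeric(1L))
  df <- data.frame(tract_id = tract_id, land_area = land_area,
                   urban = rep_len(as.logical(urban), n),
                   svi_rank = rep_len(as.numeric(svi_rank), n),
                   eji_rank = rep_len(as.numeric(eji_rank), n),
                   stringsAsFactors = FALSE)
  df$geometry <- geometry
  validate_tracts(df)
  class(df) <- c("tract_records", "data.frame")
  df
}

.as_multipolygon <- function(g) {
  if (is.matrix(g)) return(list(list(g)))        # bare ring
  if (is.list(g) && length(g) && is.matrix(g[[1L]])) return(list(g))  # polygon
  g                                              # already multipolygon
}

#' @rdname tract_records
#' @param tracts object to validate
#' @export
validate_tracts <- function(tracts) {
  req <- c("tract_id", "land_area", "urban", "svi_rank", "eji_rank", "geometry")
  miss <- setdiff(req, names(tracts))
  if (length(miss)) stop("tract table missing columns: ", paste(miss, collapse = ", "))
  dup <- unique(tracts$tract_id[duplicated(tracts$tract_id)])
  if (length(dup)) stop("duplicate tract_id: ", paste(dup, collapse = ", "))
  if (any(tracts$land_area <= 0)) stop("land_area must be > 0")
  for (v in c("svi_rank", "eji_rank")) {
    r <- tracts[[v]]
    bad <- !is.na(r) & (r < 0 | r > 1)
    if (any(bad))
      stop(v, " outside [0,1] for tract ", paste(tracts$tract_id[bad], collapse = ", "))
  }
  invisible(tracts)
}

#' Assign points to tracts
#'
#' Containment uses [point_in_multipolygon()] with on-edge points counting
#' as inside; a point on a shared boundary of several tracts is assigned to
#' the lexicographically smallest `tract_id`, so assignment is a partition.
#'
#' @param pts n x 2 matrix of coordinates in metres
#' @param tracts a `tract_records` collection
#' @return character vector of tract ids (NA for points in no tract)
#' @export
assign_tracts <- function(pts, tracts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2L)
  out <- rep(NA_character_, nrow(pts))
  ord <- order(tracts$tract_id, decreasing = TRUE)
  # iterate from largest id to smallest so the smallest id wins ties
  for (i in ord) {
    bb <- .mp_bbox(tracts$geometry[[i]])
    cand <- which(pts[, 1L] >= bb["xmin"] & pts[, 1L] <= bb["xmax"] &
                    pts[, 2L] >= bb["ymin"] & pts[, 2L] <= bb["ymax"])
    if (!length(cand)) next
    hit <- cand[point_in_multipolygon(pts[cand, , drop = FALSE], tracts$geometry[[i]])]
    out[hit] <- tracts$tract_id[i]
  }
  out
}

# ---------------------------------------------------------------------------
# GeoJSON interchange (RFC 7946 subset)

.read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  gj
}

.coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
}

#' Read point features from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Point features.  For
#'   `kind = "farm"` each feature must carry `permitted_head` and
#'   `lagoon_count` properties; identifiers come from `farm_id` /
#'   `address_id` properties (feature order index when absent).
#' @param kind `"farm"` or `"address"`
#' @return `farm_records` or `address_records`
#' @export
read_points <- function(path, kind = c("farm", "address")) {
  kind <- match.arg(kind)
  gj <- .read_geojson(path)
  feats <- gj$features
  parse_one <- function(i) {
    f <- feats[[i]]
    g <- f$geometry
    if (is.null(g$type) || g$type != "Point")
      stop("feature ", i, ": expected Point geometry, got ",
           if (is.null(g$type)) "none" else g$type)
    pr <- f$properties
    if (kind == "farm") {
      for (fld in c("permitted_head", "lagoon_count"))
        if (is.null(pr[[fld]]))
          stop("feature ", i, ": missing required property '", fld, "'")
      id <- if (!is.null(pr$farm_id)) as.character(pr$farm_id) else as.character(i)
      c(id = id, x = g$coordinates[[1L]], y = g$coordinates[[2L]],
        head = pr$permitted_head, lag = pr$lagoon_count)
    } else {
      id <- if (!is.null(pr$address_id)) as.character(pr$address_id) else as.character(i)
      c(id = id, x = g$coordinates[[1L]], y = g$coordinates[[2L]])
    }
  }
  rows <- lapply(seq_along(feats), parse_one)
  if (kind == "farm") {
    if (!length(rows))
      return(farm_records(character(), numeric(), numeric(), numeric(), numeric()))
    farm_records(vapply(rows, `[[`, "", "id"),
                 as.numeric(vapply(rows, `[[`, "", "x")),
                 as.numeric(vapply(rows, `[[`, "", "y")),
                 as.numeric(vapply(rows, `[[`, "", "head")),
                 as.numeric(vapply(rows, `[[`, "", "lag")))
  } else {
    if (!length(rows))
      return(address_records(character(), numeric(), numeric()))
    address_records(vapply(rows, `[[`, "", "id"),
                    as.numeric(vapply(rows, `[[`, "", "x")),
                    as.numeric(vapply(rows, `[[`, "", "y")))
  }
}

.parse_geojson_polygon <- function(g, i) {
  if (g$type == "Polygon") {
    list(lapply(g$coordinates, .coords_to_matrix))
  } else if (g$type == "MultiPolygon") {
    lapply(g$coordinates, function(poly) lapply(poly, .coords_to_matrix))
  } else {
    stop("feature ", i, ": expected Polygon/MultiPolygon, got ", g$type)
  }
}

#' Read census tracts from GeoJSON
#'
#' Features must be Polygon or MultiPolygon with a `tract_id` property;
#' `land_area` (square miles), `urban`, `svi_rank` and `eji_rank` are
#' optional.  Missing ranks stay missing (NA), never zero; missing
#' land_area is computed from the geometry.
#'
#' @param path GeoJSON file
#' @return `tract_records`
#' @export
read_tracts <- function(path) {
  gj <- .read_geojson(path)
  feats <- gj$features
  n <- length(feats)
  ids <- character(n); la <- rep(NA_real_, n)
  urb <- rep(NA, n); svi <- rep(NA_real_, n); eji <- rep(NA_real_, n)
  geom <- vector("list", n)
  for (i in seq_len(n)) {
    f <- feats[[i]]
    pr <- f$properties
    if (is.null(pr$tract_id)) stop("feature ", i, ": missing tract_id")
    ids[i] <- as.character(pr$tract_id)
    geom[[i]] <- .parse_geojson_polygon(f$geometry, i)
    if (!is.null(pr$land_area)) la[i] <- as.numeric(pr$land_area)
    if (!is.null(pr$urban)) urb[i] <- as.logical(pr$urban)
    if (!is.null(pr$svi_rank) && !is.na(pr$svi_rank)) svi[i] <- as.numeric(pr$svi_rank)
    if (!is.null(pr$eji_rank) && !is.na(pr$eji_rank)) eji[i] <- as.numeric(pr$eji_rank)
  }
  tract_records(ids, geom, land_area = la, urban = urb,
                svi_rank = svi, eji_rank = eji)
}

#' Read bare polygons (e.g. city limits) from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon/MultiPolygon features
#' @return list of polygons (each a list of ring matrices); multipolygon
#'   features contribute one polygon per part
#' @export
read_polygons <- function(path) {
  gj <- .read_geojson(path)
  out <- list()
  for (i in seq_along(gj$features)) {
    mp <- .parse_geojson_polygon(gj$features[[i]]$geometry, i)
    out <- c(out, mp)
  }
  out
}

.fmt_num <- function(x) {
  # shortest representation that round-trips at 12 significant digits
  v <- vapply(x, function(z) formatC(z, digits = 12, format = "g"), "")
  trimws(v)
}

.geojson_ring <- function(m) {
  m <- .ring_mat(m)
  m <- rbind(m, m[1L, ])  # explicit closure on write
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
}

.write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  txt <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Write point/tract/polygon collections as GeoJSON
#'
#' Deterministic output: identical inputs give byte-identical files.
#'
#' @param farms,addresses,tracts,polys collections as returned by the
#'   constructors in this package
#' @param path output file
#' @name write_geojson
#' @export
write_farms_geojson <- function(farms, path) {
  feats <- lapply(seq_len(nrow(farms)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(farms$x[i], farms$y[i])),
    properties = list(farm_id = farms$farm_id[i],
                      permitted_head = farms$permitted_head[i],
                      lagoon_count = farms$lagoon_count[i])))
  .write_geojson(feats, path)
}

#' @rdname write_geojson
#' @export
write_addresses_geojson <- function(addresses, path) {
  feats <- lapply(seq_len(nrow(addresses)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(addresses$x[i], addresses$y[i])),
    properties = list(address_id = addresses$address_id[i])))
  .write_geojson(feats, path)
}

#' @rdname write_geojson
#' @export
write_tracts_geojson <- function(tracts, path) {
  feats <- lapply(seq_len(nrow(tracts)), function(i) {
    mp <- tracts$geometry[[i]]
    geom <- if (length(mp) == 1L) {
      list(type = "Polygon", coordinates = lapply(mp[[1L]], .geojson_ring))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(mp, function(poly) lapply(poly, .geojson_ring)))
    }
    props <- list(tract_id = tracts$tract_id[i], land_area = tracts$land_area[i],
                  urban = tracts$urban[i], svi_rank = tracts$svi_rank[i],
                  eji_rank = tracts$eji_rank[i])
    list(type = "Feature", geometry = geom, properties = props)
  })
  .write_geojson(feats, path)
}

#' @rdname write_geojson
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(polys, function(poly) {
    if (is.matrix(poly)) poly <- list(poly)
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = lapply(poly, .geojson_ring)),
         properties = structure(list(), names = character()))
  })
  .write_geojson(feats, path)
}

# ---------------------------------------------------------------------------
# Exposure table CSV

#' Write / read the per-tract exposure table
#'
#' CSV with header
#' `tract_id,idx1_count,idx2_percent,idx3_density,idx1_class,idx2_class,idx3_class`,
#' rows ordered by `tract_id`, numeric values at 12 significant digits so a
#' write/read round trip is lossless to well below 1e-9.
#'
#' @param table exposure table (see [build_exposure_table()])
#' @param path CSV file path
#' @export
write_exposure_table <- function(table, path) {
  cols <- c("tract_id", "idx1_count", "idx2_percent", "idx3_density",
            "idx1_class", "idx2_class", "idx3_class")
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("exposure table missing columns: ", paste(miss, collapse = ", "))
  tb <- table[order(table$tract_id), cols, drop = FALSE]
  lines <- paste(cols, collapse = ",")
  if (nrow(tb)) {
    body <- paste(tb$tract_id,
                  .fmt_num(tb$idx1_count), .fmt_num(tb$idx2_percent),
                  .fmt_num(tb$idx3_density),
                  tb$idx1_class, tb$idx2_class, tb$idx3_class, sep = ",")
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_exposure_table
#' @export
read_exposure_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tract_id = "character"))
  df
}
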