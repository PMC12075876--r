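# Index 1: per-tract count of unique addresses within one mile of any farm.

#' Buffer-index configuration
#'
#' @param radius buffer radius in metres; default one mile (1,609.344 m)
#' @param assignment `"address_tract"` (default): count addresses located in
#'   the tract that are within radius of any farm anywhere;
#'   `"farm_tract"`: count addresses anywhere within radius of any farm
#'   located in the tract.  The two readings differ only near tract borders.
#' @return classed list
#' @export
buffer_config <- function(radius = METERS_PER_MILE,
                          assignment = c("address_tract", "farm_tract")) {
  stopifnot(radius > 0)
  structure(list(radius = radius, assignment = match.arg(assignment)),
            class = "buffer_config")
}

# Uniform-grid spatial index: bucket points by floor(coord / cell).
.grid_key <- function(ix, iy) paste(ix, iy, sep = ":")

.build_grid <- function(x, y, cell) {
  ix <- floor(x / cell); iy <- floor(y / cell)
  split(seq_along(x), .grid_key(ix, iy))
}

#' Addresses within a radius of any farm
#'
#' Inclusive (<=) metric contract: an address is in the result iff its
#' minimum distance to a farm is at most `radius`, each id at most once no
#' matter how many farms are in range.  Implemented with a uniform-grid
#' spatial index of cell size `radius`, so only the 3 x 3 neighbourhood of
#' an address's cell is scanned.
#'
#' @param farms `farm_records`
#' @param addresses `address_records`
#' @param radius metres, > 0
#' @return sorted character vector of qualifying `address_id`s
#' @export
addresses_near_any_farm <- function(farms, addresses, radius = METERS_PER_MILE) {
  stopifnot(radius > 0)
  if (nrow(farms) == 0L || nrow(addresses) == 0L) return(character())
  grid <- .build_grid(farms$x, farms$y, radius)
  aix <- floor(addresses$x / radius); aiy <- floor(addresses$y / radius)
  acell <- .grid_key(aix, aiy)
  hit <- logical(nrow(addresses))
  fx <- farms$x; fy <- farms$y
  r2 <- radius^2
  for (key in unique(acell)) {
    a_idx <- which(acell == key)
    ij <- as.integer(strsplit(key, ":", fixed = TRUE)[[1L]])
    neigh <- as.vector(outer(ij[1L] + (-1:1), ij[2L] + (-1:1), .grid_key))
    f_idx <- unlist(grid[neigh], use.names = FALSE)
    if (is.null(f_idx) || !length(f_idx)) next
    d2 <- outer(addresses$x[a_idx], fx[f_idx], "-")^2 +
      outer(addresses$y[a_idx], fy[f_idx], "-")^2
    hit[a_idx] <- rowSums(d2 <= r2) > 0L
  }
  sort(addresses$address_id[hit])
}

#' Index 1: unique in-buffer addresses per census tract
#'
#' For the default `address_tract` assignment, each tract counts its own
#' addresses whose distance to the nearest farm (anywhere) is within the
#' radius.  For `farm_tract`, each tract counts the deduplicated addresses
#' (anywhere) within radius of the farms located in that tract.  Tracts with
#' no qualifying address report 0; addresses falling outside every tract are
#' excluded with a warning.
#'
#' @param farms `farm_records`
#' @param addresses `address_records`
#' @param tracts `tract_records`
#' @param cfg a [buffer_config()]
#' @return named numeric vector of counts, one entry per tract, ordered by
#'   `tract_id`
#' @export
idx1_per_tract <- function(farms, addresses, tracts, cfg = buffer_config()) {
  stopifnot(inherits(cfg, "buffer_config"))
  ids <- sort(tracts$tract_id)
  counts <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(addresses) == 0L || nrow(farms) == 0L) return(counts)
  if (cfg$assignment == "address_tract") {
    near <- addresses_near_any_farm(farms, addresses, cfg$radius)
    qual <- addresses[addresses$address_id %in% near, , drop = FALSE]
    if (!nrow(qual)) return(counts)
    tid <- assign_tracts(cbind(qual$x, qual$y), tracts)
    lost <- sum(is.na(tid))
    if (lost > 0L)
      warning(lost, " qualifying address(es) outside all tracts; excluded")
    tab <- table(tid[!is.na(tid)])
    counts[names(tab)] <- as.numeric(tab)
  } else {
    ftid <- assign_tracts(cbind(farms$x, farms$y), tracts)
    lost <- sum(is.na(ftid))
    if (lost > 0L)
      warning(lost, " farm(s) outside all tracts; excluded")
    for (id in unique(ftid[!is.na(ftid)])) {
      sub <- farms[which(ftid == id), , drop = FALSE]
      counts[id] <- length(addresses_near_any_farm(sub, addresses, cfg$radius))
    }
  }
  counts
}
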