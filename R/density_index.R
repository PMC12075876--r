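# Index 3: permitted head per square mile of tract land area.

#' Index 3: swine density per square mile
#'
#' Sums the permitted head of the farms located in each tract (point
#' containment with the partition convention of [assign_tracts()]) and
#' divides by the tract's land area in square miles.  Tracts without farms
#' report 0; farms outside every tract are excluded with a warning.  Farms
#' are atoms at their permit point: no areal apportionment across tracts.
#'
#' @param farms `farm_records`
#' @param tracts `tract_records` with `land_area` > 0 (square miles)
#' @return named numeric vector of densities (head per square mile), one
#'   entry per tract, ordered by `tract_id`
#' @export
idx3_per_tract <- function(farms, tracts) {
  ids <- sort(tracts$tract_id)
  area <- tracts$land_area[match(ids, tracts$tract_id)]
  dens <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(farms) == 0L) return(dens)
  tid <- assign_tracts(cbind(farms$x, farms$y), tracts)
  lost <- sum(is.na(tid))
  if (lost > 0L) warning(lost, " farm(s) outside all tracts; excluded")
  keep <- !is.na(tid)
  if (any(keep)) {
    sums <- tapply(farms$permitted_head[keep], tid[keep], sum)
    dens[names(sums)] <- as.numeric(sums)
  }
  dens / area
}
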