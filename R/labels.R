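# Stress class schemes.
#
# Soil moisture treatments define five classes by volumetric water content
# band: severe dry (<= 10%), dry (20 +- 2%), optimal (30 +- 3%), wet
# (40 +- 3%) and severe wet (~50%). Image-only classification works on a
# coarser three-level scheme (dry side / optimal / wet side) obtained by
# consolidating the extremes with their neighbours.

#' Stress class levels
#'
#' @return Character vector of class codes in canonical order.
#' @export
stress_levels5 <- function() c("SD", "D", "O", "W", "SW")

#' @rdname stress_levels5
#' @export
stress_levels3 <- function() c("DRY_SIDE", "OPTIMAL", "WET_SIDE")

#' Display names for the three-level scheme
#'
#' Defaults follow the deployed decision labels ("Severe Dry", "Optimal",
#' "Severe Wet").
#'
#' @return Named character vector keyed by [stress_levels3()].
#' @export
stress3_display <- function() {
  c(DRY_SIDE = "Severe Dry", OPTIMAL = "Optimal", WET_SIDE = "Severe Wet")
}

#' Default 5-to-3 class mapping
#'
#' SD and D collapse onto the dry side, O stays optimal, W and SW collapse
#' onto the wet side. The mapping is a plain named vector and can be
#' replaced wholesale where a different consolidation is wanted.
#'
#' @return Named character vector from 5-level to 3-level codes.
#' @export
default_5to3_mapping <- function() {
  c(SD = "DRY_SIDE", D = "DRY_SIDE", O = "OPTIMAL",
    W = "WET_SIDE", SW = "WET_SIDE")
}

#' Map five-level stress labels to the three-level scheme
#'
#' @param label Vector of 5-level codes (`SD`, `D`, `O`, `W`, `SW`).
#' @param mapping Named mapping table; defaults to
#'   [default_5to3_mapping()].
#' @return Vector of 3-level codes, same length as `label`.
#' @export
map_5_to_3 <- function(label, mapping = default_5to3_mapping()) {
  label <- as.character(label)
  bad <- setdiff(unique(label), names(mapping))
  if (length(bad)) {
    stop_invalid("unknown stress label(s): ", paste(bad, collapse = ", "))
  }
  if (!all(mapping %in% stress_levels3())) {
    stop_invalid("mapping values must be in ",
                 paste(stress_levels3(), collapse = ", "))
  }
  unname(mapping[label])
}

#' Soil VWC bands of the five stress classes
#'
#' Band half-widths follow the treatment definitions (the severe-wet
#' treatment is nominally 50%; it is given a +-1% band so draws are
#' non-degenerate).
#'
#' @return Data frame with `class`, `lo`, `hi` (percent VWC).
#' @export
stress_vwc_bands <- function() {
  data.frame(class = stress_levels5(),
             lo = c(2, 18, 27, 37, 49),
             hi = c(10, 22, 33, 43, 51))
}

#' Collapse 5-class probabilities to 3 classes
#'
#' Sums the probabilities of merged classes under the mapping, yielding a
#' 3-class vector on the canonical [stress_levels3()] order.
#'
#' @param p Named numeric vector (or matrix with named columns) of
#'   5-class probabilities.
#' @param mapping Named 5-to-3 mapping.
#' @return Probability vector/matrix over the 3-level classes.
#' @export
collapse_proba_5to3 <- function(p, mapping = default_5to3_mapping()) {
  if (is.matrix(p)) {
    out <- sapply(stress_levels3(), function(l3) {
      src <- names(mapping)[mapping == l3]
      rowSums(p[, intersect(src, colnames(p)), drop = FALSE])
    })
    return(out / rowSums(out))
  }
  if (is.null(names(p))) names(p) <- stress_levels5()
  out <- vapply(stress_levels3(), function(l3) {
    sum(p[names(mapping)[mapping == l3]], na.rm = TRUE)
  }, numeric(1))
  out / sum(out)
}
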