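# Run-length mask serialization (text-only interchange for arbitrary
# region masks, e.g. the generator's elliptical leaves).

mask_to_rle <- function(mask) {
  v <- as.vector(mask)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(dim = dim(mask), starts = starts[keep], lengths = r$lengths[keep])
}

rle_to_mask <- function(rl) {
  d <- unlist(rl$dim)
  starts <- unlist(rl$starts); lens <- unlist(rl$lengths)
  m <- logical(prod(d))
  for (i in seq_along(starts)) {
    m[starts[i] + seq_len(lens[i]) - 1L] <- TRUE
  }
  matrix(m, d[1], d[2])
}

#' Read / write region masks as run-length JSON
#'
#' Stores a three-region [region_set()] as a JSON array of run-length
#' encoded masks (column-major runs over the logical mask).
#'
#' @param regions A `region_set`.
#' @param path JSON path.
#' @export
write_region_masks <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  jsonlite::write_json(lapply(regions$masks, mask_to_rle), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_region_masks
#' @return [read_region_masks()] returns a `region_set`.
#' @export
read_region_masks <- function(path) {
  rls <- jsonlite::read_json(path, simplifyVector = FALSE)
  region_set(lapply(rls, rle_to_mask))
}
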