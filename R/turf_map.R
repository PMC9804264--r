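#' Annual cover map of one turf
#'
#' A `turf_map` is the per-year snapshot of a gridded turf: for every taxon
#' and quadrant it stores the canopy-cover area of the demographic unit
#' rooted there (all shoots of one taxon in one quadrant form one unit, so
#' each taxon occupies a quadrant at most once). Zero-cover rows are
#' dropped: absence is implicit.
#'
#' @param turf_id turf identifier (scalar, coerced to character).
#' @param year survey year (integer scalar).
#' @param grid a [make_grid()] specification.
#' @param cover data frame with columns `taxon`, `row`, `col` (0-based
#'   quadrant indices) and `cover_cm2`; an optional `uid` column carries
#'   unit identities (used by the synthetic generator's ground truth).
#' @return An object of class `turf_map`.
#' @export
turf_map <- function(turf_id, year, grid, cover) {
  stopifnot(inherits(grid, "grid_spec"))
  need <- c("taxon", "row", "col", "cover_cm2")
  if (!all(need %in% names(cover)))
    stop_input("cover needs columns ", paste(need, collapse = ", "))
  cover <- as.data.frame(cover, stringsAsFactors = FALSE)
  cover$taxon <- as.character(cover$taxon)
  cover$row <- as.integer(cover$row)
  cover$col <- as.integer(cover$col)
  cover$cover_cm2 <- as.numeric(cover$cover_cm2)
  cover <- cover[cover$cover_cm2 > 0, , drop = FALSE]
  if (nrow(cover)) {
    check_finite(cover$cover_cm2, "cover_cm2")
    if (any(cover$cover_cm2 > grid$quadrant_area_cm2 + 1e-9))
      stop_input("cover_cm2 exceeds the quadrant area (",
                 grid$quadrant_area_cm2, " cm2)")
    if (any(cover$row < 0 | cover$row >= grid$n_side |
            cover$col < 0 | cover$col >= grid$n_side))
      stop_input("quadrant indices outside the grid")
    key <- paste(cover$taxon, cover$row, cover$col)
    if (anyDuplicated(key))
      stop_input("a taxon occupies some quadrant more than once")
  }
  rownames(cover) <- NULL
  structure(list(turf_id = as.character(turf_id), year = as.integer(year),
                 grid = grid, cover = cover),
            class = "turf_map")
}

#' @export
print.turf_map <- function(x, ...) {
  cat(sprintf("<turf_map> turf %s, year %d: %d units, %d taxa, %.1f cm2 inner cover\n",
              x$turf_id, x$year, nrow(x$cover),
              length(unique(x$cover$taxon)), total_cover(x)))
  invisible(x)
}

#' Total cover on a turf map
#'
#' @param map a [turf_map()].
#' @param inner_only restrict to the demographically modelled inner
#'   quadrants (default) or include the buffer ring.
#' @param by_taxon return a named per-taxon vector instead of the total.
#' @return Cover in cm2.
#' @export
total_cover <- function(map, inner_only = TRUE, by_taxon = FALSE) {
  cv <- map$cover
  if (inner_only && nrow(cv))
    cv <- cv[is_inner(map$grid, cv$row, cv$col), , drop = FALSE]
  if (!by_taxon) return(sum(cv$cover_cm2))
  if (!nrow(cv)) return(stats::setNames(numeric(0), character(0)))
  tapply(cv$cover_cm2, cv$taxon, sum)
}

map_taxa <- function(map) unique(map$cover$taxon)

# per-taxon cover matrices (n_side x n_side), 1-based [row+1, col+1]
cover_matrices <- function(map, taxa = map_taxa(map)) {
  n <- map$grid$n_side
  out <- lapply(taxa, function(tx) {
    m <- matrix(0, n, n)
    cv <- map$cover[map$cover$taxon == tx, , drop = FALSE]
    if (nrow(cv)) m[cbind(cv$row + 1L, cv$col + 1L)] <- cv$cover_cm2
    m
  })
  names(out) <- taxa
  out
}

#' Read turf maps from a long-format CSV
#'
#' Expected columns: `turf_id`, `year`, `taxon`, `row`, `col` and either
#' `cover_cm2` or `cover_class` (decoded with `scale`). Absent
#' (taxon, quadrant) rows mean zero cover.
#'
#' @param path CSV file path.
#' @param grid a [make_grid()] shared by all turfs in the file.
#' @param scale a [cover_scale()] used when only `cover_class` is present.
#' @return Nested list `maps[[turf_id]][[as.character(year)]]` of
#'   [turf_map()] objects, years sorted increasingly.
#' @export
read_turf_maps <- function(path, grid = make_grid(), scale = cover_scale()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cover_cm2" %in% names(d)) {
    if (!"cover_class" %in% names(d))
      stop_input("need a cover_cm2 or cover_class column")
    d$cover_cm2 <- decode_cover(d$cover_class, scale)
  }
  out <- list()
  for (tid in unique(as.character(d$turf_id))) {
    dt <- d[as.character(d$turf_id) == tid, , drop = FALSE]
    yrs <- sort(unique(dt$year))
    out[[tid]] <- lapply(yrs, function(y)
      turf_map(tid, y, grid, dt[dt$year == y, , drop = FALSE]))
    names(out[[tid]]) <- as.character(yrs)
  }
  out
}

#' Write turf maps to a long-format CSV
#'
#' @param maps a single [turf_map()], a flat list of them, or the nested
#'   list returned by [read_turf_maps()].
#' @param path output CSV path.
#' @param scale optional [cover_scale()]; when given, an ordinal
#'   `cover_class` column is written alongside `cover_cm2`.
#' @return `path`, invisibly.
#' @export
write_turf_maps <- function(maps, path, scale = NULL) {
  maps <- flatten_maps(maps)
  rows <- lapply(maps, function(m) {
    if (!nrow(m$cover)) return(NULL)
    data.frame(turf_id = m$turf_id, year = m$year,
               m$cover[c("taxon", "row", "col", "cover_cm2")],
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (!is.null(scale)) d$cover_class <- encode_cover(d$cover_cm2, scale)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

flatten_maps <- function(maps) {
  if (inherits(maps, "turf_map")) return(list(maps))
  out <- list()
  for (m in maps) {
    if (inherits(m, "turf_map")) out[[length(out) + 1L]] <- m
    else for (mm in m) out[[length(out) + 1L]] <- mm
  }
  out
}
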