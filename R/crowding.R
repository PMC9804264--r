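#' Neighbourhood crowding
#'
#' Crowding on a focal (taxon, quadrant) pair is a kernel-weighted sum of
#' neighbours' cover, split into a conspecific component `w_i` and a
#' heterospecific component `w_j`. Conspecific neighbours are units of the
#' focal taxon in *other* quadrants (one unit per taxon per quadrant, so
#' the focal quadrant is excluded); heterospecific neighbours can share the
#' focal quadrant and enter at distance 0 with weight 1. Distances are
#' between quadrant centres; neighbours outside the turf do not exist (no
#' wrap-around), so edge quadrants see fewer neighbours.
#'
#' @param map a [turf_map()].
#' @param taxon focal taxon (may be absent from the map: `w_i = 0`).
#' @param quadrant focal quadrant, length-2 integer `(row, col)`, 0-based.
#' @param kernel a [kernel_spec()].
#' @return List with fields `w_i` and `w_j` (cm2, kernel-weighted).
#' @export
compute_crowding <- function(map, taxon, quadrant, kernel = kernel_spec()) {
  g <- map$grid
  row <- as.integer(quadrant[1]); col <- as.integer(quadrant[2])
  if (row < 0 || row >= g$n_side || col < 0 || col >= g$n_side)
    stop_input("quadrant outside the grid")
  f <- crowding_fields(map, kernel)
  crowding_at(f, taxon, row, col)
}

# offsets (in quadrant steps) reaching within the truncation radius,
# with their kernel weights; includes the (0,0) offset at weight 1
kernel_offsets <- function(kernel, grid) {
  qs <- grid$quadrant_side_m
  r <- floor(kernel$truncation_m / qs + 1e-9)
  dd <- expand.grid(dr = -(r + 1):(r + 1), dc = -(r + 1):(r + 1))
  # same floating comparison as kernel_weight() so that the stamp agrees
  # exactly with a naive all-pairs distance loop
  dist <- qs * sqrt(dd$dr^2 + dd$dc^2)
  keep <- dist <= kernel$truncation_m
  data.frame(dr = dd$dr[keep], dc = dd$dc[keep],
             w = exp(-dist[keep]^2 / (2 * kernel$sigma_m^2)))
}

# kernel-smoothed field: out[r, c] = sum_off w_off * m[r + dr, c + dc]
smooth_field <- function(m, off) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (k in seq_len(nrow(off))) {
    dr <- off$dr[k]; dc <- off$dc[k]; w <- off$w[k]
    r_dst <- max(1, 1 - dr):min(n, n - dr)
    c_dst <- max(1, 1 - dc):min(n, n - dc)
    out[r_dst, c_dst] <- out[r_dst, c_dst] + w * m[r_dst + dr, c_dst + dc]
  }
  out
}

# Precompute smoothed cover fields for every taxon plus the community
# total; crowding at any quadrant is then two lookups. This is the fast
# path used by the simulator every year.
crowding_fields <- function(map, kernel = kernel_spec(),
                            taxa = map_taxa(map)) {
  off <- kernel_offsets(kernel, map$grid)
  cov <- cover_matrices(map, taxa)
  sm <- lapply(cov, smooth_field, off = off)
  tot <- Reduce(`+`, sm)
  if (is.null(tot)) tot <- matrix(0, map$grid$n_side, map$grid$n_side)
  structure(list(cover = cov, smooth = sm, smooth_tot = tot,
                 grid = map$grid), class = "crowding_fields")
}

# row/col 0-based; taxon may be missing from the fields (w_i = 0)
crowding_at <- function(fields, taxon, row, col) {
  i <- cbind(row + 1L, col + 1L)
  if (taxon %in% names(fields$smooth)) {
    si <- fields$smooth[[taxon]][i]
    ci <- fields$cover[[taxon]][i]
  } else {
    si <- rep(0, length(row)); ci <- si
  }
  list(w_i = pmax(si - ci, 0), w_j = pmax(fields$smooth_tot[i] - si, 0))
}
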