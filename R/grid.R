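#' Grid geometry of a turf
#'
#' A turf is a square block of grassland subdivided into square quadrants.
#' Only the inner quadrants (those further than `buffer_m` from the turf
#' edge) are surveyed and modelled demographically; the buffer ring can
#' carry vegetation that contributes to neighbourhood crowding of inner
#' quadrants but is otherwise static.
#'
#' Quadrant indices are 0-based `(row, col)` from the turf's south-west
#' corner; this convention is used in all CSV interfaces.
#'
#' @param turf_side_m side length of the turf (m).
#' @param quadrant_side_m side length of one quadrant (m); must divide
#'   `turf_side_m` exactly.
#' @param buffer_m width of the unmodelled edge buffer (m); must be a whole
#'   multiple of `quadrant_side_m`.
#' @return An object of class `grid_spec` with derived fields `n_side`
#'   (quadrants per side), `buffer_q` (buffer width in quadrants),
#'   `inner` (0-based index range of inner rows/cols), `n_inner`
#'   (number of inner quadrants) and `quadrant_area_cm2`.
#' @examples
#' g <- make_grid(1, 0.05, 0.10)
#' g$n_inner # 256
#' @export
make_grid <- function(turf_side_m = 1, quadrant_side_m = 0.05,
                      buffer_m = 0.10) {
  check_finite(turf_side_m, "turf_side_m")
  check_finite(quadrant_side_m, "quadrant_side_m")
  check_finite(buffer_m, "buffer_m")
  if (turf_side_m <= 0 || quadrant_side_m <= 0)
    stop_input("turf_side_m and quadrant_side_m must be positive")
  if (buffer_m < 0) stop_input("buffer_m must be non-negative")

  n_side <- round(turf_side_m / quadrant_side_m)
  if (abs(n_side * quadrant_side_m - turf_side_m) > 1e-9)
    stop_input("quadrant_side_m (", quadrant_side_m,
               ") does not divide turf_side_m (", turf_side_m, ") exactly")
  buffer_q <- round(buffer_m / quadrant_side_m)
  if (abs(buffer_q * quadrant_side_m - buffer_m) > 1e-9)
    stop_input("buffer_m (", buffer_m,
               ") is not a whole multiple of quadrant_side_m (",
               quadrant_side_m, ")")
  if (2 * buffer_q >= n_side)
    stop_input("buffer_m leaves no inner quadrants")

  n_in_side <- n_side - 2L * buffer_q
  structure(list(
    turf_side_m = turf_side_m,
    quadrant_side_m = quadrant_side_m,
    buffer_m = buffer_m,
    n_side = as.integer(n_side),
    buffer_q = as.integer(buffer_q),
    inner = c(buffer_q, n_side - buffer_q - 1L),
    n_inner = as.integer(n_in_side^2),
    quadrant_area_cm2 = (quadrant_side_m * 100)^2,
    turf_area_cm2 = (turf_side_m * 100)^2
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %g m turf, %g cm quadrants (%d x %d), %g cm buffer, %d inner quadrants\n",
    x$turf_side_m, x$quadrant_side_m * 100, x$n_side, x$n_side,
    x$buffer_m * 100, x$n_inner))
  invisible(x)
}

is_inner <- function(grid, row, col) {
  row >= grid$inner[1] & row <= grid$inner[2] &
    col >= grid$inner[1] & col <= grid$inner[2]
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$turf_side_m, b$turf_side_m)) &&
    isTRUE(all.equal(a$quadrant_side_m, b$quadrant_side_m)) &&
    isTRUE(all.equal(a$buffer_m, b$buffer_m))
}

#' Gaussian interaction kernel
#'
#' Neighbourhood crowding weights decay with the distance between quadrant
#' centres as `exp(-d^2 / (2 sigma^2))` and are truncated to zero beyond
#' `truncation_m`. The defaults (sigma 5 cm, truncation 15 cm) place about
#' 95% of the kernel mass within a 10-cm radius, consistent with most
#' crowding being exerted within 10 cm of a focal plant.
#'
#' @param sigma_m kernel width (m), > 0.
#' @param truncation_m truncation radius (m), >= `sigma_m`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma_m = 0.05, truncation_m = 0.15) {
  check_finite(sigma_m, "sigma_m")
  check_finite(truncation_m, "truncation_m")
  if (sigma_m <= 0) stop_input("sigma_m must be > 0")
  if (truncation_m < sigma_m)
    stop_input("truncation_m must be >= sigma_m")
  structure(list(sigma_m = sigma_m, truncation_m = truncation_m),
            class = "kernel_spec")
}

#' Kernel weight at a given distance
#'
#' @param distance_m distance(s) between quadrant centres (m), >= 0.
#' @param kernel a [kernel_spec()].
#' @return Weights in `[0, 1]`; 1 at distance 0, 0 beyond the truncation
#'   radius.
#' @export
kernel_weight <- function(distance_m, kernel = kernel_spec()) {
  check_finite(distance_m, "distance_m")
  if (any(distance_m < 0)) stop_input("distance_m must be >= 0")
  w <- exp(-distance_m^2 / (2 * kernel$sigma_m^2))
  w[distance_m > kernel$truncation_m] <- 0
  w
}

#' Ordinal canopy-cover scale
#'
#' Field surveys record canopy cover per quadrant on an ordinal scale of
#' cover-fraction classes. The default scale has 7 classes: an absence
#' class and six presence classes with upper bounds 2, 6, 14, 30, 60 and
#' 100% of the quadrant, decoded to midpoint areas 0, 0.25, 1, 2.5, 5.5,
#' 11.25 and 20 cm2 on the default 25-cm2 quadrant. All I/O also accepts
#' raw continuous cover, so the scale can be bypassed entirely.
#'
#' @param upper_frac upper cover-fraction bound of each presence class
#'   (strictly increasing, last equal to 1).
#' @param midpoint_cm2 decoded cover area of each class including the
#'   absence class (so `length(midpoint_cm2) == length(upper_frac) + 1`),
#'   strictly increasing, first element 0.
#' @param quadrant_area_cm2 area of one quadrant (cm2).
#' @return An object of class `cover_scale`.
#' @export
cover_scale <- function(upper_frac = c(0.02, 0.06, 0.14, 0.30, 0.60, 1.00),
                        midpoint_cm2 = c(0, 0.25, 1.0, 2.5, 5.5, 11.25, 20),
                        quadrant_area_cm2 = 25) {
  check_finite(upper_frac, "upper_frac")
  check_finite(midpoint_cm2, "midpoint_cm2")
  if (length(midpoint_cm2) != length(upper_frac) + 1L)
    stop_input("need one midpoint per class including the absence class")
  if (any(diff(upper_frac) <= 0) || upper_frac[length(upper_frac)] != 1)
    stop_input("upper_frac must be strictly increasing and end at 1")
  if (any(diff(midpoint_cm2) <= 0) || midpoint_cm2[1] != 0)
    stop_input("midpoints must be strictly increasing from 0")
  structure(list(upper_frac = upper_frac, midpoint_cm2 = midpoint_cm2,
                 quadrant_area_cm2 = quadrant_area_cm2,
                 n_classes = length(midpoint_cm2)),
            class = "cover_scale")
}

#' Encode continuous cover to an ordinal class
#'
#' Class 0 is exact absence; class k (k >= 1) covers the fraction interval
#' `(upper_frac[k-1], upper_frac[k]]`.
#'
#' @param cover_cm2 cover areas (cm2) in `[0, quadrant area]`.
#' @param scale a [cover_scale()].
#' @return Integer class codes.
#' @export
encode_cover <- function(cover_cm2, scale = cover_scale()) {
  check_finite(cover_cm2, "cover_cm2")
  if (any(cover_cm2 < 0 | cover_cm2 > scale$quadrant_area_cm2 + 1e-9))
    stop_input("cover_cm2 outside [0, ", scale$quadrant_area_cm2, "]")
  frac <- pmin(cover_cm2 / scale$quadrant_area_cm2, 1)
  code <- findInterval(frac, c(0, scale$upper_frac), left.open = TRUE)
  as.integer(code) # exact zero falls in no left-open interval -> 0
}

#' Decode an ordinal class to its midpoint cover
#'
#' @param code integer class codes as produced by [encode_cover()].
#' @param scale a [cover_scale()].
#' @return Midpoint cover areas (cm2); `decode_cover(encode_cover(m)) == m`
#'   for every class midpoint `m`.
#' @export
decode_cover <- function(code, scale = cover_scale()) {
  if (any(code < 0 | code >= scale$n_classes | code != round(code)))
    stop_input("class codes must be integers in [0, ", scale$n_classes - 1, "]")
  scale$midpoint_cm2[code + 1L]
}
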