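#' Vital-rate parameter sets
#'
#' Three parametric models govern each taxon's demography, all driven by
#' the previous summer's mean temperature `T` (degrees C), optionally soil
#' moisture `M` (unit scale), the unit's size `u` (cm2) and the crowding
#' pair `(w_i, w_j)`:
#'
#' * **Survival** (Bernoulli, logit scale):
#'   `logit(s) = lambda_S(T, M) + b_S u - alpha_iiS(T) w_i - alpha_ijS(T) w_j`
#'   with a sigmoidal intrinsic rate
#'   `lambda_S = lam_max / (1 + exp(k_sig (T - (T_infl0 + m_moist M))))`
#'   whose inflection shifts with moisture, and interaction coefficients
#'   linear in temperature, `alpha = a0 + a1 T` (so either sign is
#'   possible: competition or facilitation).
#' * **Growth** (Gaussian on the next size):
#'   `E(u') = lambda_G(T) + b_G u - alpha_iiG(T) w_i - alpha_ijG(T) w_j`
#'   with a Gaussian intrinsic rate
#'   `lambda_G = g_max exp(-(T - T_opt)^2 / (2 sigma_T^2))` and strictly
#'   positive, exponential-in-temperature interaction coefficients
#'   `alpha = exp(c + d T)` (neighbour effects on growth are always
#'   competitive). Realised sizes add noise with SD `sigma_eps` and are
#'   truncated to `[u_min, quadrant area]`.
#' * **Recruitment** (Bernoulli per taxon x previously unoccupied
#'   quadrant):
#'   `logit(r) = alpha_iiR(T) w_i - alpha_ijR(T) w_j + theta_R`
#'   with positive exponential coefficients: conspecific neighbours act as
#'   propagule sources (facilitative), heterospecifics compete. The
#'   background rate `theta_R` is fixed at -5 so empty neighbourhoods
#'   recruit rarely.
#'
#' @param lam_max,T_infl0,m_moist,k_sig,b_S,a_ii0,a_ii1,a_ij0,a_ij1
#'   survival parameters (see above); `k_sig > 0`.
#' @name vital_params
NULL

#' @rdname vital_params
#' @export
survival_params <- function(lam_max, T_infl0, m_moist = 0, k_sig = 1,
                            b_S = 0, a_ii0 = 0, a_ii1 = 0,
                            a_ij0 = 0, a_ij1 = 0) {
  p <- list(lam_max = lam_max, T_infl0 = T_infl0, m_moist = m_moist,
            k_sig = k_sig, b_S = b_S, a_ii0 = a_ii0, a_ii1 = a_ii1,
            a_ij0 = a_ij0, a_ij1 = a_ij1)
  for (nm in names(p)) check_finite(p[[nm]], nm)
  if (k_sig <= 0) stop_input("k_sig must be > 0")
  structure(p, class = "survival_params")
}

#' @rdname vital_params
#' @param g_max,T_opt,sigma_T,b_G,c_ii,d_ii,c_ij,d_ij,sigma_eps growth
#'   parameters; `sigma_T > 0`, `sigma_eps > 0`.
#' @export
growth_params <- function(g_max, T_opt, sigma_T, b_G = 0, c_ii = -20,
                          d_ii = 0, c_ij = -20, d_ij = 0, sigma_eps = 0.3) {
  p <- list(g_max = g_max, T_opt = T_opt, sigma_T = sigma_T, b_G = b_G,
            c_ii = c_ii, d_ii = d_ii, c_ij = c_ij, d_ij = d_ij,
            sigma_eps = sigma_eps)
  for (nm in names(p)) check_finite(p[[nm]], nm)
  if (sigma_T <= 0) stop_input("sigma_T must be > 0")
  if (sigma_eps <= 0) stop_input("sigma_eps must be > 0")
  structure(p, class = "growth_params")
}

#' @rdname vital_params
#' @param r_ii0,r_ii1,r_ij0,r_ij1 recruitment coefficients on the log
#'   scale, `alpha = exp(r0 + r1 T) > 0`.
#' @param theta_R background recruitment logit; fixed at -5 unless
#'   explicitly overridden.
#' @param u_init initial size of a recruit (cm2), default the smallest
#'   presence-class midpoint of the default ordinal scale.
#' @export
recruitment_params <- function(r_ii0, r_ii1 = 0, r_ij0, r_ij1 = 0,
                               theta_R = -5, u_init = 0.25) {
  p <- list(r_ii0 = r_ii0, r_ii1 = r_ii1, r_ij0 = r_ij0, r_ij1 = r_ij1,
            theta_R = theta_R, u_init = u_init)
  for (nm in names(p)) check_finite(p[[nm]], nm)
  if (u_init <= 0) stop_input("u_init must be > 0")
  structure(p, class = "recruitment_params")
}

#' @rdname vital_params
#' @param taxon taxon identifier.
#' @param survival,growth,recruitment the three component parameter sets.
#' @export
taxon_params <- function(taxon, survival, growth, recruitment) {
  stopifnot(inherits(survival, "survival_params"),
            inherits(growth, "growth_params"),
            inherits(recruitment, "recruitment_params"))
  structure(list(taxon = as.character(taxon), survival = survival,
                 growth = growth, recruitment = recruitment),
            class = "taxon_params")
}

#' Survival logit
#'
#' @param p a [survival_params()].
#' @param T_prev previous-summer mean temperature (degrees C).
#' @param moisture soil moisture (unit scale).
#' @param u_prev unit size in the previous year (cm2), > 0.
#' @param w_i,w_j conspecific / heterospecific crowding (cm2), >= 0.
#' @return Logit of the survival probability (vectorised).
#' @export
survival_logit <- function(p, T_prev, moisture, u_prev, w_i, w_j) {
  stopifnot(inherits(p, "survival_params"))
  check_finite(T_prev, "T_prev"); check_finite(moisture, "moisture")
  check_finite(u_prev, "u_prev")
  check_finite(w_i, "w_i"); check_finite(w_j, "w_j")
  if (any(u_prev <= 0)) stop_input("u_prev must be > 0")
  if (any(w_i < 0) || any(w_j < 0)) stop_input("crowding must be >= 0")
  lam <- p$lam_max / (1 + exp(p$k_sig * (T_prev - (p$T_infl0 + p$m_moist * moisture))))
  lam + p$b_S * u_prev -
    (p$a_ii0 + p$a_ii1 * T_prev) * w_i -
    (p$a_ij0 + p$a_ij1 * T_prev) * w_j
}

#' Expected next size under the growth model
#'
#' @param p a [growth_params()].
#' @inheritParams survival_logit
#' @return Expected size the following year (cm2, untruncated mean).
#' @export
growth_mean <- function(p, T_prev, u_prev, w_i, w_j) {
  stopifnot(inherits(p, "growth_params"))
  check_finite(T_prev, "T_prev"); check_finite(u_prev, "u_prev")
  check_finite(w_i, "w_i"); check_finite(w_j, "w_j")
  if (any(u_prev <= 0)) stop_input("u_prev must be > 0")
  lam <- p$g_max * exp(-(T_prev - p$T_opt)^2 / (2 * p$sigma_T^2))
  lam + p$b_G * u_prev -
    exp(p$c_ii + p$d_ii * T_prev) * w_i -
    exp(p$c_ij + p$d_ij * T_prev) * w_j
}

# stochastic growth realisation: additive Gaussian noise, truncated to
# [u_min, u_max]; a realised size at u_min does NOT imply death (death is
# governed solely by the survival model)
growth_draw <- function(p, T_prev, u_prev, w_i, w_j,
                        u_min = 0.1, u_max = 25) {
  mu <- growth_mean(p, T_prev, u_prev, w_i, w_j)
  pmin(pmax(mu + stats::rnorm(length(mu), 0, p$sigma_eps), u_min), u_max)
}

#' Recruitment logit for a previously unoccupied quadrant
#'
#' @param p a [recruitment_params()].
#' @inheritParams survival_logit
#' @param occupied logical; the model is only defined for quadrants the
#'   focal taxon does not already occupy, so any `TRUE` is a contract
#'   violation.
#' @return Logit of the recruitment probability (vectorised).
#' @export
recruitment_logit <- function(p, T_prev, w_i, w_j, occupied = FALSE) {
  stopifnot(inherits(p, "recruitment_params"))
  check_finite(T_prev, "T_prev")
  check_finite(w_i, "w_i"); check_finite(w_j, "w_j")
  if (any(w_i < 0) || any(w_j < 0)) stop_input("crowding must be >= 0")
  if (any(occupied))
    stop_input("recruitment_logit called on an occupied quadrant")
  exp(p$r_ii0 + p$r_ii1 * T_prev) * w_i -
    exp(p$r_ij0 + p$r_ij1 * T_prev) * w_j + p$theta_R
}

#' Read and write taxon parameter sets as JSON
#'
#' The JSON layout is `{taxon: {survival: {...}, growth: {...},
#' recruitment: {...}}}` with field names exactly as in the parameter
#' constructors; unknown or missing fields are rejected.
#'
#' @param params named list of [taxon_params()].
#' @param path JSON file path.
#' @return `read_params()` returns a named list of [taxon_params()];
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  out <- lapply(params, function(tp) list(
    survival = unclass(tp$survival),
    growth = unclass(tp$growth),
    recruitment = unclass(tp$recruitment)))
  names(out) <- vapply(params, function(tp) tp$taxon, character(1))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctors <- list(survival = survival_params, growth = growth_params,
                recruitment = recruitment_params)
  out <- lapply(names(raw), function(tx) {
    blk <- raw[[tx]]
    if (!setequal(names(blk), names(ctors)))
      stop_input("taxon '", tx, "': expected survival/growth/recruitment blocks")
    parts <- lapply(names(ctors), function(kind) {
      fields <- blk[[kind]]
      allowed <- names(formals(ctors[[kind]]))
      bad <- setdiff(names(fields), allowed)
      if (length(bad))
        stop_input("taxon '", tx, "' ", kind, ": unknown field(s) ",
                   paste(bad, collapse = ", "))
      do.call(ctors[[kind]], fields)
    })
    taxon_params(tx, parts[[1]], parts[[2]], parts[[3]])
  })
  names(out) <- names(raw)
  out
}
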