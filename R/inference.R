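#' @title MAP fitting of the vital-rate models
#' @description
#' Baseline inference is penalised maximum likelihood: a Gaussian
#' weakly-regularising prior (SD 2 on intercept-like parameters, SD 1 on
#' slopes and on log-scale positive parameters) added to the exact
#' Bernoulli or Gaussian likelihood of the corresponding vital-rate model,
#' optimised with seeded multi-start BFGS (3 starts, tolerance 1e-8) and
#' uncertainty from the curvature (inverse Hessian) at the optimum.
#' Positivity-constrained parameters (`k_sig`, `sigma_T`, `sigma_eps`)
#' are optimised on the log scale, where their priors and standard errors
#' live. To avoid ridge-like collinearity (temperature is far from zero,
#' so an intercept and a temperature slope are nearly confounded), the
#' internal coordinates centre temperature and moisture on their data
#' means: interaction coefficients are parameterised as their value at
#' the mean temperature plus a slope, and the survival inflection as its
#' value at mean moisture. [internalise_params()] maps a natural
#' parameter set into a fit's internal coordinates (useful for
#' comparing estimates and truth on the scale where standard errors
#' live). Location parameters with no natural zero (`T_infl0`, `T_opt`)
#' have their prior centred on the mean observed temperature.
#' @name inference
NULL

# ---- generic MAP engine ----------------------------------------------

map_fit <- function(nll, start, prior_mean, prior_sd, n_starts = 3,
                    seed = 1, jitter_sd = 0.5, reltol = 1e-8,
                    parscale = NULL) {
  nlp <- function(th) {
    v <- nll(th) + sum(((th - prior_mean) / prior_sd)^2) / 2
    if (!is.finite(v)) 1e12 else v
  }
  parscale <- parscale %||% rep(1, length(start))
  starts <- list(start)
  if (n_starts > 1) {
    jit <- with_seed(seed, matrix(stats::rnorm((n_starts - 1) * length(start),
                                               0, jitter_sd),
                                  nrow = n_starts - 1))
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- start + jit[k, ] * parscale
  }
  best <- NULL
  conv <- 1L
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nlp, method = "BFGS",
                   control = list(maxit = 1000, reltol = reltol,
                                  parscale = parscale)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence
    }
  }
  if (is.null(best)) stop_input("MAP optimisation failed from every start")
  H <- tryCatch(numDeriv::hessian(nlp, best$par), error = function(e) NULL)
  se <- rep(NA_real_, length(start))
  vcov <- NULL
  kappa <- NA_real_
  if (!is.null(H) && all(is.finite(H))) {
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov)) {
      dg <- diag(vcov)
      se <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0) kappa <- max(ev) / min(ev)
  }
  names(best$par) <- names(start)
  names(se) <- names(start)
  list(par = best$par, se = se, vcov = vcov, logpost = -best$value,
       convergence = conv, hessian_condition = kappa)
}

new_vital_fit <- function(model, engine, estimate, n_obs, diagnostics) {
  structure(list(model = model, estimate = estimate,
                 internal = engine$par, se = engine$se, vcov = engine$vcov,
                 logpost = engine$logpost, n_obs = n_obs,
                 diagnostics = c(diagnostics,
                                 list(convergence = engine$convergence,
                                      hessian_condition = engine$hessian_condition))),
            class = "vital_fit")
}

#' @export
print.vital_fit <- function(x, ...) {
  cat(sprintf("<vital_fit> %s model, n = %d, log-posterior %.2f\n",
              x$model, x$n_obs, x$logpost))
  est <- cbind(estimate = x$internal, se = x$se)
  print(round(est, 4))
  invisible(x)
}

# ---- survival ---------------------------------------------------------

bernoulli_nll <- function(y, eta) {
  -sum(y * stats::plogis(eta, log.p = TRUE) +
         (1 - y) * stats::plogis(-eta, log.p = TRUE))
}

# internal coordinates: Tc/Mc are temperature/moisture minus their data
# means; *_c coefficients are values at the data means
survival_eta <- function(th, d, Tbar, Mbar) {
  Tc <- d$T_prev - Tbar
  lam <- th["lam_max"] /
    (1 + exp(exp(th["log_k_sig"]) *
               (d$T_prev - th["T_infl_c"] -
                  th["m_moist"] * (d$moisture - Mbar))))
  lam + th["b_S"] * d$size_from_cm2 -
    (th["a_ii_c"] + th["a_ii1"] * Tc) * d$w_con -
    (th["a_ij_c"] + th["a_ij1"] * Tc) * d$w_het
}

#' Fit the survival model
#'
#' @param records demography records restricted to `survival`/`death`
#'   events, annotated with `T_prev`, `moisture`, `size_from_cm2`,
#'   `w_con`, `w_het` (see [build_demography_table()] and
#'   [attach_climate()]).
#' @param n_starts,seed multi-start control; deterministic given `seed`.
#' @return A `vital_fit` whose `estimate` is a [survival_params()].
#'   One-outcome-class data is fitted anyway (the prior bounds the
#'   estimates) with `diagnostics$separation = TRUE` and a warning.
#' @export
fit_survival <- function(records, n_starts = 3, seed = 1) {
  d <- records[records$event %in% c("survival", "death"), , drop = FALSE]
  need <- c("T_prev", "moisture", "size_from_cm2", "w_con", "w_het")
  if (!all(need %in% names(d)))
    stop_input("records need columns ", paste(need, collapse = ", "))
  if (!nrow(d)) stop_input("no survival/death records")
  y <- as.integer(d$event == "survival")
  one_class <- length(unique(y)) < 2
  if (one_class)
    warning("survival data has a single outcome class; ",
            "estimates are prior-bounded (separation)")
  Tbar <- mean(d$T_prev)
  Mbar <- mean(d$moisture)
  sT <- max(stats::sd(d$T_prev), 0.1)
  swi <- max(mean(d$w_con), 1)
  swj <- max(mean(d$w_het), 1)
  start <- c(lam_max = 2, T_infl_c = Tbar, m_moist = 0, log_k_sig = 0,
             b_S = 0, a_ii_c = 0, a_ii1 = 0, a_ij_c = 0, a_ij1 = 0)
  pm <- c(0, Tbar, 0, 0, 0, 0, 0, 0, 0)
  ps <- c(2, 2, 1, 1, 1, 2, 1, 2, 1)
  scl <- c(1, 1, 1, 0.5, 1 / max(mean(d$size_from_cm2), 1),
           1 / swi, 1 / (swi * sT), 1 / swj, 1 / (swj * sT))
  eng <- map_fit(function(th) bernoulli_nll(y, survival_eta(th, d, Tbar, Mbar)),
                 start, pm, ps, n_starts, seed, parscale = scl)
  eta_hat <- survival_eta(eng$par, d, Tbar, Mbar)
  sep <- one_class || all(abs(eta_hat) > 10)
  p <- eng$par
  est <- survival_params(
    lam_max = unname(p["lam_max"]),
    T_infl0 = unname(p["T_infl_c"] - p["m_moist"] * Mbar),
    m_moist = unname(p["m_moist"]),
    k_sig = exp(unname(p["log_k_sig"])),
    b_S = unname(p["b_S"]),
    a_ii0 = unname(p["a_ii_c"] - p["a_ii1"] * Tbar),
    a_ii1 = unname(p["a_ii1"]),
    a_ij0 = unname(p["a_ij_c"] - p["a_ij1"] * Tbar),
    a_ij1 = unname(p["a_ij1"]))
  fit <- new_vital_fit("survival", eng, est, nrow(d),
                       list(separation = sep))
  fit$centering <- c(T = Tbar, M = Mbar)
  fit
}

# ---- growth -----------------------------------------------------------

growth_mu <- function(th, d, Tbar) {
  Tc <- d$T_prev - Tbar
  lam <- th["g_max"] *
    exp(-(d$T_prev - th["T_opt"])^2 / (2 * exp(2 * th["log_sigma_T"])))
  lam + th["b_G"] * d$size_from_cm2 -
    exp(th["c_ii_c"] + th["d_ii"] * Tc) * d$w_con -
    exp(th["c_ij_c"] + th["d_ij"] * Tc) * d$w_het
}

#' Fit the growth model
#'
#' @param records demography records restricted to `survival` events
#'   (size pairs), annotated like [fit_survival()]'s input plus
#'   `size_to_cm2`.
#' @inheritParams fit_survival
#' @return A `vital_fit` whose `estimate` is a [growth_params()]. Data
#'   observed at fewer than 2 distinct temperatures leaves `T_opt` and
#'   `sigma_T` unidentifiable: flagged as `diagnostics$ridge`.
#' @export
fit_growth <- function(records, n_starts = 3, seed = 1) {
  d <- records[records$event == "survival", , drop = FALSE]
  need <- c("T_prev", "size_from_cm2", "size_to_cm2", "w_con", "w_het")
  if (!all(need %in% names(d)))
    stop_input("records need columns ", paste(need, collapse = ", "))
  if (!nrow(d)) stop_input("no survival (growth) records")
  y <- d$size_to_cm2
  Tbar <- mean(d$T_prev)
  sT <- max(stats::sd(d$T_prev), 0.1)
  start <- c(g_max = 1, T_opt = Tbar, log_sigma_T = log(2), b_G = 0.5,
             c_ii_c = -5, d_ii = 0, c_ij_c = -5, d_ij = 0,
             log_sigma_eps = log(max(stats::sd(y), 0.1)))
  pm <- c(0, Tbar, 0, 0, 0, 0, 0, 0, 0)
  ps <- c(2, 2, 1, 1, 2, 1, 2, 1, 1)
  scl <- c(1, 1, 0.5, 0.2, 1, 1 / sT, 1, 1 / sT, 0.5)
  nll <- function(th) {
    mu <- growth_mu(th, d, Tbar)
    -sum(stats::dnorm(y, mu, exp(th["log_sigma_eps"]), log = TRUE))
  }
  eng <- map_fit(nll, start, pm, ps, n_starts, seed, parscale = scl)
  ridge <- length(unique(d$T_prev)) < 2 ||
    (is.finite(eng$hessian_condition) && eng$hessian_condition > 1e8) ||
    anyNA(eng$se[c("T_opt", "log_sigma_T")])
  p <- eng$par
  est <- growth_params(
    g_max = unname(p["g_max"]), T_opt = unname(p["T_opt"]),
    sigma_T = exp(unname(p["log_sigma_T"])),
    b_G = unname(p["b_G"]),
    c_ii = unname(p["c_ii_c"] - p["d_ii"] * Tbar),
    d_ii = unname(p["d_ii"]),
    c_ij = unname(p["c_ij_c"] - p["d_ij"] * Tbar),
    d_ij = unname(p["d_ij"]),
    sigma_eps = exp(unname(p["log_sigma_eps"])))
  fit <- new_vital_fit("growth", eng, est, nrow(d), list(ridge = ridge))
  fit$centering <- c(T = Tbar)
  fit
}

# ---- recruitment ------------------------------------------------------

recruitment_eta <- function(th, d, theta_R, Tbar) {
  Tc <- d$T_prev - Tbar
  exp(th["r_ii_c"] + th["r_ii1"] * Tc) * d$w_con -
    exp(th["r_ij_c"] + th["r_ij1"] * Tc) * d$w_het + theta_R
}

#' Fit the recruitment model
#'
#' @param trials per-quadrant recruitment trials from
#'   [build_recruitment_table()], annotated with `T_prev` (outcomes only
#'   from quadrants the taxon did not occupy at year t).
#' @param theta_R fixed background recruitment logit (default -5, not
#'   estimated).
#' @inheritParams fit_survival
#' @param u_init recruit size recorded into the returned parameter set.
#' @return A `vital_fit` whose `estimate` is a [recruitment_params()].
#' @export
fit_recruitment <- function(trials, theta_R = -5, n_starts = 3, seed = 1,
                            u_init = 0.25) {
  need <- c("recruited", "T_prev", "w_con", "w_het")
  if (!all(need %in% names(trials)))
    stop_input("trials need columns ", paste(need, collapse = ", "))
  if (!nrow(trials)) stop_input("no recruitment trials")
  y <- trials$recruited
  Tbar <- mean(trials$T_prev)
  sT <- max(stats::sd(trials$T_prev), 0.1)
  start <- c(r_ii_c = -3, r_ii1 = 0, r_ij_c = -3, r_ij1 = 0)
  pm <- c(0, 0, 0, 0)
  ps <- c(2, 1, 2, 1)
  scl <- c(1, 1 / sT, 1, 1 / sT)
  eng <- map_fit(function(th)
    bernoulli_nll(y, recruitment_eta(th, trials, theta_R, Tbar)),
    start, pm, ps, n_starts, seed, parscale = scl)
  p <- eng$par
  est <- recruitment_params(
    r_ii0 = unname(p["r_ii_c"] - p["r_ii1"] * Tbar),
    r_ii1 = unname(p["r_ii1"]),
    r_ij0 = unname(p["r_ij_c"] - p["r_ij1"] * Tbar),
    r_ij1 = unname(p["r_ij1"]),
    theta_R = theta_R, u_init = u_init)
  fit <- new_vital_fit("recruitment", eng, est, nrow(trials),
                       list(separation = length(unique(y)) < 2))
  fit$centering <- c(T = Tbar)
  fit
}

#' Fit all three vital-rate models for one taxon
#'
#' @param demog annotated demography table ([build_demography_table()] +
#'   [attach_climate()]).
#' @param recruit_trials annotated recruitment trials.
#' @param taxon focal taxon.
#' @inheritParams fit_recruitment
#' @return List with the assembled [taxon_params()] (`params`) and the
#'   three `vital_fit`s (`fits`).
#' @export
fit_taxon <- function(demog, recruit_trials, taxon, theta_R = -5,
                      n_starts = 3, seed = 1, u_init = 0.25) {
  ds <- demog[demog$taxon == taxon, , drop = FALSE]
  dr <- recruit_trials[recruit_trials$taxon == taxon, , drop = FALSE]
  fs <- fit_survival(ds, n_starts, seed)
  fg <- fit_growth(ds, n_starts, seed)
  fr <- fit_recruitment(dr, theta_R, n_starts, seed, u_init)
  list(params = taxon_params(taxon, fs$estimate, fg$estimate, fr$estimate),
       fits = list(survival = fs, growth = fg, recruitment = fr))
}

#' Map natural-scale parameters into a fit's internal coordinates
#'
#' The fitters optimise centred, log-transformed coordinates (see
#' [inference]); standard errors live on that scale. This maps a
#' natural-scale parameter set (for example the truth of a simulation)
#' into the internal coordinates of a given fit, so estimates and truth
#' can be compared in units of standard errors.
#'
#' @param params a [survival_params()], [growth_params()] or
#'   [recruitment_params()] matching the fit's model.
#' @param fit a `vital_fit`.
#' @return Named numeric vector in the fit's internal coordinates.
#' @export
internalise_params <- function(params, fit) {
  stopifnot(inherits(fit, "vital_fit"))
  ct <- fit$centering
  if (fit$model == "survival") {
    stopifnot(inherits(params, "survival_params"))
    p <- params
    c(lam_max = p$lam_max,
      T_infl_c = p$T_infl0 + p$m_moist * ct[["M"]],
      m_moist = p$m_moist, log_k_sig = log(p$k_sig), b_S = p$b_S,
      a_ii_c = p$a_ii0 + p$a_ii1 * ct[["T"]], a_ii1 = p$a_ii1,
      a_ij_c = p$a_ij0 + p$a_ij1 * ct[["T"]], a_ij1 = p$a_ij1)
  } else if (fit$model == "growth") {
    stopifnot(inherits(params, "growth_params"))
    p <- params
    c(g_max = p$g_max, T_opt = p$T_opt, log_sigma_T = log(p$sigma_T),
      b_G = p$b_G,
      c_ii_c = p$c_ii + p$d_ii * ct[["T"]], d_ii = p$d_ii,
      c_ij_c = p$c_ij + p$d_ij * ct[["T"]], d_ij = p$d_ij,
      log_sigma_eps = log(p$sigma_eps))
  } else {
    stopifnot(inherits(params, "recruitment_params"))
    p <- params
    c(r_ii_c = p$r_ii0 + p$r_ii1 * ct[["T"]], r_ii1 = p$r_ii1,
      r_ij_c = p$r_ij0 + p$r_ij1 * ct[["T"]], r_ij1 = p$r_ij1)
  }
}

#' Attach climate covariates to demographic records
#'
#' Joins `T_prev` and `moisture` from a climate series onto records by
#' `year_from` (optionally per site via a turf-to-site map).
#'
#' @param records demography or recruitment-trial table.
#' @param climate a [climate_series()], or a named list of them keyed by
#'   site when `turf_site` is given.
#' @param turf_site optional named character vector mapping `turf_id` to
#'   the site whose climate series applies.
#' @return `records` with `T_prev` and `moisture` columns added.
#' @export
attach_climate <- function(records, climate, turf_site = NULL) {
  get_one <- function(cs, yrs) {
    i <- match(yrs, cs$year)
    if (anyNA(i)) stop_input("climate series does not cover all record years")
    list(T_prev = cs$T_summer_C[i], moisture = cs$moisture[i])
  }
  if (is.null(turf_site)) {
    stopifnot(inherits(climate, "climate_series"))
    v <- get_one(climate, records$year_from)
    records$T_prev <- v$T_prev
    records$moisture <- v$moisture
  } else {
    records$T_prev <- NA_real_
    records$moisture <- NA_real_
    for (tid in unique(records$turf_id)) {
      cs <- climate[[turf_site[[tid]]]]
      sel <- records$turf_id == tid
      v <- get_one(cs, records$year_from[sel])
      records$T_prev[sel] <- v$T_prev
      records$moisture[sel] <- v$moisture
    }
  }
  records
}

#' Select taxa with enough observations to fit
#'
#' @param records demography table.
#' @param min_obs minimum number of records per taxon (default 1000).
#' @return Character vector of taxa with at least `min_obs` records.
#' @export
select_taxa <- function(records, min_obs = 1000) {
  if (!nrow(records)) return(character(0))
  tab <- table(records$taxon)
  sort(names(tab)[tab >= min_obs])
}

#' Validate a fitted taxon against observed cover changes
#'
#' Simulates `h` years of community dynamics forward from each turf's
#' initial map (with `n_reps` replicates) and compares the predicted
#' (median) versus observed log-transformed ratio of final to initial
#' cover of the focal taxon in each turf. The model is included when its
#' sum of squared residuals is at most `inclusion_threshold` (80%) of the
#' null expectation of no cover change.
#'
#' @param taxon focal taxon (must be present in at least one initial map).
#' @param params named list of [taxon_params()] for the whole community.
#' @param initial_maps list of [turf_map()]s (year `y0`).
#' @param observed_final list of [turf_map()]s of the same turfs at year
#'   `y0 + h`.
#' @param climate a [climate_series()] covering years `y0 .. y0 + h`.
#' @param kernel a [kernel_spec()].
#' @param n_reps simulation replicates per turf (predicted ratio uses the
#'   median across replicates).
#' @param seed RNG seed.
#' @param pseudo pseudo-count for [log_cover_ratio()].
#' @param inclusion_threshold SSR-ratio inclusion boundary (default 0.80).
#' @param u_min smallest realisable size (cm2).
#' @return A `validation_result`: per-turf table of predicted and observed
#'   log cover ratios, `ssr_model`, `ssr_null`, `ssr_ratio` and the
#'   `included` flag.
#' @export
validate_taxon <- function(taxon, params, initial_maps, observed_final,
                           climate, kernel = kernel_spec(), n_reps = 20,
                           seed = 1, pseudo = 0.25,
                           inclusion_threshold = 0.80, u_min = 0.1) {
  initial_maps <- flatten_maps(initial_maps)
  observed_final <- flatten_maps(observed_final)
  ids <- vapply(initial_maps, function(m) m$turf_id, character(1))
  fin_ids <- vapply(observed_final, function(m) m$turf_id, character(1))
  present <- any(vapply(initial_maps, function(m)
    taxon %in% map_taxa(m), logical(1)))
  if (!present)
    stop_input("taxon '", taxon, "' absent from every initial map")

  rows <- lapply(seq_along(initial_maps), function(k) {
    m0 <- initial_maps[[k]]
    mf <- observed_final[[match(ids[k], fin_ids)]]
    h <- mf$year - m0$year
    if (is.na(h) || h < 1) stop_input("final maps must be >= 1 year ahead")
    ci <- climate[climate$year >= m0$year & climate$year < mf$year, ,
                  drop = FALSE]
    if (nrow(ci) < h) stop_input("climate series does not cover the horizon")
    pred <- vapply(seq_len(n_reps), function(r) with_seed(
      derive_seed(seed, k * 1000 + r), {
        st <- m0
        for (j in seq_len(h))
          st <- step_year(st, ci$T_summer_C[j], ci$moisture[j], params,
                          kernel, u_min)
        unname(total_cover(st, by_taxon = TRUE)[taxon]) %||% 0
      }), numeric(1))
    pred[is.na(pred)] <- 0
    init <- sum(total_cover(m0, by_taxon = TRUE)[taxon], na.rm = TRUE)
    obs <- sum(total_cover(mf, by_taxon = TRUE)[taxon], na.rm = TRUE)
    data.frame(turf_id = ids[k], initial_cover = init,
               observed_cover = obs,
               predicted_cover = stats::median(pred),
               stringsAsFactors = FALSE)
  })
  per_turf <- do.call(rbind, rows)
  per_turf$predicted_ratio <- log_cover_ratio(per_turf$initial_cover,
                                              per_turf$predicted_cover,
                                              pseudo)
  per_turf$observed_ratio <- log_cover_ratio(per_turf$initial_cover,
                                             per_turf$observed_cover,
                                             pseudo)
  ssr_model <- sum((per_turf$predicted_ratio - per_turf$observed_ratio)^2)
  ssr_null <- sum(per_turf$observed_ratio^2)
  ratio <- if (ssr_null > 0) ssr_model / ssr_null else
    if (ssr_model == 0) 0 else Inf
  structure(list(taxon = taxon, per_turf = per_turf,
                 ssr_model = ssr_model, ssr_null = ssr_null,
                 ssr_ratio = ratio,
                 included = ratio <= inclusion_threshold),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s: SSR ratio %.3f (model %.3f / null %.3f) -> %s\n",
              x$taxon, x$ssr_ratio, x$ssr_model, x$ssr_null,
              if (x$included) "included" else "excluded"))
  invisible(x)
}
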