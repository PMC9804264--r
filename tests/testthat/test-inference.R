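test_that("MAP matches a dense grid-search oracle on a 2-parameter toy", {
  # single temperature: the centred temperature slopes have no likelihood
  # contribution and sit exactly at their prior mean (0), leaving a
  # 2-parameter model (r_ii_c, r_ij_c)
  set.seed(41)
  n <- 4000
  d <- data.frame(T_prev = 14, w_con = rexp(n, 1 / 10),
                  w_het = rexp(n, 1 / 40))
  eta <- exp(-2.2) * d$w_con - exp(-4.1) * d$w_het - 5
  d$recruited <- as.integer(runif(n) < plogis(eta))
  fit <- fit_recruitment(d, seed = 1)
  expect_equal(unname(fit$internal["r_ii1"]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$internal["r_ij1"]), 0, tolerance = 1e-6)

  # independent oracle: dense grid over the two free coordinates of the
  # same negative log posterior
  nlp <- function(a, b) {
    eta <- exp(a) * d$w_con - exp(b) * d$w_het - 5
    -sum(d$recruited * plogis(eta, log.p = TRUE) +
           (1 - d$recruited) * plogis(-eta, log.p = TRUE)) +
      (a^2 + b^2) / (2 * 4)
  }
  aa <- seq(-3, -1.5, by = 0.01)
  bb <- seq(-5, -3, by = 0.01)
  vals <- outer(aa, bb, Vectorize(nlp))
  best <- which(vals == min(vals), arr.ind = TRUE)
  expect_equal(unname(fit$internal["r_ii_c"]), aa[best[1]],
               tolerance = 0.011)
  expect_equal(unname(fit$internal["r_ij_c"]), bb[best[2]],
               tolerance = 0.011)
})

test_that("single fits recover generating parameters", {
  f <- fit_survival(sim_survival_data(4000, 101), seed = 1)
  z <- abs(f$internal - internalise_params(truth_survival, f)) / f$se
  expect_true(all(is.finite(z)))
  expect_lt(max(z), 4)
  expect_equal(f$estimate$k_sig, truth_survival$k_sig, tolerance = 0.5)
  expect_false(f$diagnostics$separation)

  # near-noise-free growth data pins the estimates onto the truth
  fg <- fit_growth(sim_growth_data(3000, 102, sigma = 1e-3), seed = 1)
  expect_equal(fg$estimate$g_max, truth_growth$g_max, tolerance = 0.02)
  expect_equal(fg$estimate$T_opt, truth_growth$T_opt, tolerance = 0.02)
  expect_equal(fg$estimate$b_G, truth_growth$b_G, tolerance = 0.005)
  expect_equal(fg$estimate$sigma_T, truth_growth$sigma_T, tolerance = 0.05)
})

test_that("degenerate designs are flagged, not fatal", {
  # all-survive data: separation flagged, prior-bounded estimates returned
  d <- sim_survival_data(500, 103)
  d$event <- "survival"
  expect_warning(f <- fit_survival(d, seed = 1), "single outcome")
  expect_true(f$diagnostics$separation)
  expect_true(all(is.finite(f$internal)))

  # zero-crowding data: interaction coefficients shrink to the prior mean
  d2 <- sim_survival_data(3000, 104)
  d2$w_con <- 0; d2$w_het <- 0
  f2 <- fit_survival(d2, seed = 1)
  expect_lt(max(abs(f2$internal[c("a_ii_c", "a_ii1", "a_ij_c", "a_ij1")])),
            0.02)

  # single-temperature growth data: T_opt/sigma_T ridge flagged
  d3 <- sim_growth_data(1500, 105)
  d3$T_prev <- 15
  d3$size_to_cm2 <- growth_mean(truth_growth, d3$T_prev, d3$size_from_cm2,
                                d3$w_con, d3$w_het) + rnorm(1500, 0, 0.5)
  f3 <- fit_growth(d3, seed = 1)
  expect_true(f3$diagnostics$ridge)
})

test_that("theta_R is a fixed constant, overridable but never fitted", {
  d <- sim_recruitment_data(8000, 106)
  f5 <- fit_recruitment(d, seed = 1)
  expect_equal(f5$estimate$theta_R, -5) # the default, carried verbatim
  f0 <- fit_recruitment(d, theta_R = 0, seed = 1)
  expect_equal(f0$estimate$theta_R, 0) # an override, carried verbatim
  expect_false("theta_R" %in% names(f5$internal))
  # the matching offset fits the data better: theta_R has a real,
  # non-absorbable role (there is no free intercept in the model)
  loglik <- function(f, theta) {
    eta <- recruitment_logit(f$estimate, d$T_prev, d$w_con, d$w_het)
    sum(d$recruited * plogis(eta, log.p = TRUE) +
          (1 - d$recruited) * plogis(-eta, log.p = TRUE))
  }
  expect_gt(loglik(f5), loglik(f0))
})

test_that("select_taxa applies the minimum-observation rule", {
  rec <- data.frame(taxon = c(rep("a", 1000), rep("b", 999), rep("c", 1500)))
  expect_equal(select_taxa(rec), c("a", "c"))
  expect_equal(select_taxa(rec, min_obs = 2000), character(0))
  expect_equal(select_taxa(rec[0, , drop = FALSE]), character(0))
})

test_that("validation compares simulated and observed log cover ratios", {
  g <- make_grid(0.5, 0.05, 0.05)
  params <- list(resident = static_taxon())
  full <- expand.grid(row = g$inner[1]:g$inner[2],
                      col = g$inner[1]:g$inner[2])
  clim <- constant_scenario(12.3, 5)

  mk <- function(tid, year, size) turf_map(tid, year, g,
    data.frame(taxon = "resident", full, cover_cm2 = size))

  # predictions identical to observations: ratio 0, included
  init <- list(mk("A", 2017, 20))
  obs <- list(mk("A", 2018, 25)) # deterministic growth is pinned at 25
  v <- validate_taxon("resident", params, init, obs, clim, n_reps = 3)
  expect_equal(v$ssr_model, 0)
  expect_equal(v$ssr_ratio, 0)
  expect_true(v$included)

  # predictions identical to the null (the static taxon at its pinned
  # size predicts no change) while observations changed: ratio 1, excluded
  init_null <- list(mk("A", 2017, 25))
  obs_chg <- list(mk("A", 2018, 20))
  v1 <- validate_taxon("resident", params, init_null, obs_chg, clim,
                       n_reps = 3)
  expect_equal(v1$ssr_ratio, 1, tolerance = 1e-9)
  expect_false(v1$included)

  # constructed boundary: ssr_model = 0.8 * ssr_null (within float safety)
  n <- nrow(full)
  ra <- log((n * 25 + 0.25) / (n * 20 + 0.25))
  pb <- sqrt(0.8 * (1 - 1e-9)) * ra
  uB <- ((n * 25 + 0.25) / exp(pb) - 0.25) / n
  init2 <- list(mk("A", 2017, 20), mk("B", 2017, uB))
  obs2 <- list(mk("A", 2018, 25), mk("B", 2018, uB))
  v2 <- validate_taxon("resident", params, init2, obs2, clim, n_reps = 3)
  expect_equal(v2$ssr_ratio, 0.8, tolerance = 1e-6)
  expect_true(v2$included)

  # turf-order invariance; a perfect turf never increases the ratio
  v2r <- validate_taxon("resident", params, rev(init2), rev(obs2), clim,
                        n_reps = 3)
  expect_equal(v2r$ssr_ratio, v2$ssr_ratio, tolerance = 1e-12)
  v_b_only <- validate_taxon("resident", params, init2[2], obs2[2], clim,
                             n_reps = 3)
  expect_lte(v2$ssr_ratio, v_b_only$ssr_ratio)

  expect_error(validate_taxon("ghost", params, init, obs, clim),
               "absent")
})
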