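# shared fixtures and independent oracles

# independent all-pairs brute-force crowding (the oracle for the
# stamp-convolution implementation)
brute_crowding <- function(map, taxon, row, col, kernel) {
  cv <- map$cover
  qs <- map$grid$quadrant_side_m
  d <- qs * sqrt((cv$row - row)^2 + (cv$col - col)^2)
  w <- ifelse(d <= kernel$truncation_m, exp(-d^2 / (2 * kernel$sigma_m^2)), 0)
  con <- cv$taxon == taxon
  same <- cv$row == row & cv$col == col
  list(w_i = sum(w[con & !same] * cv$cover_cm2[con & !same]),
       w_j = sum(w[!con] * cv$cover_cm2[!con]))
}

random_map <- function(grid, n_units, n_taxa = 4, seed = NULL,
                       turf_id = "t", year = 2017L) {
  gen <- function() {
    cov <- data.frame(
      taxon = sample(paste0("sp", seq_len(n_taxa)), n_units, TRUE),
      row = sample(seq_len(grid$n_side), n_units, TRUE) - 1L,
      col = sample(seq_len(grid$n_side), n_units, TRUE) - 1L,
      cover_cm2 = stats::runif(n_units, 0.1, grid$quadrant_area_cm2))
    cov <- cov[!duplicated(cov[c("taxon", "row", "col")]), ]
    turf_map(turf_id, year, grid, cov)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# covariate world for parameter-recovery harnesses: four site
# temperatures spanning 5.5 K, varying moisture, exponential crowding
sim_covariates <- function(n, seed) {
  set.seed(seed)
  data.frame(T_prev = sample(c(12.3, 14.5, 15.6, 17.8), n, TRUE),
             moisture = stats::runif(n, 0.2, 0.8),
             size_from_cm2 = stats::runif(n, 0.5, 15),
             w_con = stats::rexp(n, 1 / 15),
             w_het = stats::rexp(n, 1 / 40))
}

truth_survival <- survival_params(lam_max = 4, T_infl0 = 15, m_moist = -1,
                                  k_sig = 1.2, b_S = 0.1, a_ii0 = 0.01,
                                  a_ii1 = 0.002, a_ij0 = 0.005,
                                  a_ij1 = 0.001)
truth_growth <- growth_params(g_max = 2, T_opt = 15, sigma_T = 2,
                              b_G = 0.7, c_ii = -5, d_ii = 0.05,
                              c_ij = -5, d_ij = 0.03, sigma_eps = 0.5)
truth_recruitment <- recruitment_params(r_ii0 = -3, r_ii1 = 0.1,
                                        r_ij0 = -5, r_ij1 = 0.05)

sim_survival_data <- function(n, seed, truth = truth_survival) {
  d <- sim_covariates(n, seed)
  eta <- survival_logit(truth, d$T_prev, d$moisture, d$size_from_cm2,
                        d$w_con, d$w_het)
  d$event <- ifelse(stats::runif(n) < stats::plogis(eta),
                    "survival", "death")
  d
}

sim_growth_data <- function(n, seed, truth = truth_growth,
                            sigma = truth$sigma_eps) {
  d <- sim_covariates(n, seed)
  mu <- growth_mean(truth, d$T_prev, d$size_from_cm2, d$w_con, d$w_het)
  d$size_to_cm2 <- mu + stats::rnorm(n, 0, sigma)
  d$event <- "survival"
  d
}

sim_recruitment_data <- function(n, seed, truth = truth_recruitment) {
  set.seed(seed)
  d <- data.frame(T_prev = sample(c(12.3, 14.5, 15.6, 17.8), n, TRUE),
                  w_con = stats::rexp(n, 1 / 10),
                  w_het = stats::rexp(n, 1 / 40))
  eta <- recruitment_logit(truth, d$T_prev, d$w_con, d$w_het)
  d$recruited <- as.integer(stats::runif(n) < stats::plogis(eta))
  d
}

# fate key: a demographic record is identified by its taxon, year and
# anchor quadrant (origin for survivals/deaths, destination for recruits)
fate_key <- function(d) {
  ifelse(d$event == "recruit",
         paste(d$turf_id, d$taxon, d$year_to, d$event, d$row_to, d$col_to),
         paste(d$turf_id, d$taxon, d$year_from, d$event, d$row_from,
               d$col_from))
}

# deterministic "resident"-style taxon: certain survival, growth pinned
# at the quadrant cap, no recruitment
static_taxon <- function(name = "resident", T_ref = 12.3) {
  taxon_params(name,
               survival_params(lam_max = 40, T_infl0 = 100, k_sig = 1),
               growth_params(g_max = 30, T_opt = T_ref, sigma_T = 1000,
                             b_G = 0, sigma_eps = 0.05),
               recruitment_params(r_ii0 = -30, r_ij0 = -30,
                                  theta_R = -30))
}
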