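#' Design of a synthetic transplant study
#'
#' The synthetic-data generator emulates a whole-community transplant
#' design: turfs from one home meadow moved to sites spanning ~0-5.5 K of
#' warming (default offsets 0, 2.2, 3.3 and 5.5 K), surveyed annually on
#' a 1-m2 grid of 5x5 cm quadrants with a 10-cm buffer. Every input the
#' pipeline needs is produced with known ground truth: taxon parameters,
#' multi-year cover maps generated by the package's own vital-rate models,
#' the exact fate of every unit (the tracking oracle) and per-site climate
#' series. Defaults are smaller than a field campaign (8 taxa, 3 turfs per
#' site) to keep test runs fast; `field_scale = TRUE` switches to 10 turfs
#' at 5 sites.
#'
#' @param n_taxa number of taxa (>= 2; the first is a warm-optimum taxon,
#'   the second a cold-adapted monotonic decliner).
#' @param n_turfs_per_site turfs transplanted to each site.
#' @param site_offsets_K warming offsets of the transplant sites (K).
#' @param T_home_C mean summer temperature at the home site (degrees C).
#' @param n_years survey years per turf.
#' @param grid,kernel geometry and interaction kernel.
#' @param moisture constant soil moisture.
#' @param init_occupancy per-taxon probability that an inner quadrant
#'   holds a unit in the first year.
#' @param displacement_rate probability that a unit's recorded location
#'   is displaced by one quadrant (observation noise / re-sprouting).
#' @param populate_buffer whether initial maps also occupy the buffer
#'   ring (buffer units crowd inner quadrants but are not tracked).
#' @param burn_in equilibrate each turf at the home climate before the
#'   transplant (the field community is an intact meadow, i.e. near its
#'   home-climate equilibrium, when excavated).
#' @param burn_in_criterion halting criterion for that burn-in; slightly
#'   stricter than the projection default so the home-site series stays
#'   quasi-stable.
#' @param field_scale use the field-campaign scale (10 turfs, 5 sites
#'   with offsets 0, 1.4, 2.2, 3.3, 5.5 K).
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_taxa = 8, n_turfs_per_site = 3,
                             site_offsets_K = c(0, 2.2, 3.3, 5.5),
                             T_home_C = 12.3, n_years = 4,
                             grid = make_grid(1, 0.05, 0.10),
                             kernel = kernel_spec(0.05, 0.15),
                             moisture = 0.5, init_occupancy = 0.22,
                             displacement_rate = 0.2,
                             populate_buffer = TRUE,
                             burn_in = TRUE,
                             burn_in_criterion = equilibrium_criterion(0.02),
                             field_scale = FALSE) {
  if (field_scale) {
    n_turfs_per_site <- 10
    site_offsets_K <- c(0, 1.4, 2.2, 3.3, 5.5)
  }
  stopifnot(n_taxa >= 2, n_turfs_per_site >= 1, n_years >= 2,
            all(is.finite(site_offsets_K)))
  structure(list(n_taxa = n_taxa, n_turfs_per_site = n_turfs_per_site,
                 site_offsets_K = site_offsets_K, T_home_C = T_home_C,
                 n_years = as.integer(n_years), grid = grid,
                 kernel = kernel, moisture = moisture,
                 init_occupancy = init_occupancy,
                 displacement_rate = displacement_rate,
                 populate_buffer = populate_buffer,
                 burn_in = burn_in,
                 burn_in_criterion = burn_in_criterion),
            class = "synthetic_design")
}

#' Sample a community's taxon parameters
#'
#' Draws parameter sets satisfying every vital-rate invariant and giving
#' viable dynamics near the home climate: survival sigmoids with
#' inflections 1.5-3.5 K above home (so most taxa decline under strong
#' warming), Gaussian growth optima near home temperature, and
#' recruitment roughly balancing background mortality. Two taxa are
#' special by construction: the first has a warm growth optimum 2-4 K
#' above home (it benefits from moderate warming), the second is
#' cold-adapted with a low, steep survival inflection (a monotonic
#' decliner under warming).
#'
#' @param design a [synthetic_design()].
#' @param seed RNG seed (NULL: use the current stream).
#' @return Named list of [taxon_params()].
#' @export
sample_taxon_params <- function(design, seed = 1) {
  with_seed(seed, {
    T0 <- design$T_home_C
    M <- design$moisture
    taxa <- c("warm_forb", "cold_shrub",
              if (design$n_taxa > 2)
                sprintf("taxon%02d", seq_len(design$n_taxa - 2) + 2))
    out <- lapply(seq_along(taxa), function(i) {
      warm <- i == 1L
      cold <- i == 2L
      # survival: inflection of the effective sigmoid sits above home
      # temperature; cold decliners have it low and steep
      infl_eff <- T0 + if (warm) stats::runif(1, 4, 5.5) else
        if (cold) stats::runif(1, 1, 2) else stats::runif(1, 1.5, 3.5)
      k_sig <- if (cold) stats::runif(1, 1.2, 1.8) else
        stats::runif(1, 0.8, 1.4)
      m_moist <- stats::runif(1, -1, 1)
      sp <- survival_params(
        lam_max = stats::runif(1, 3, 4.5),
        T_infl0 = infl_eff - m_moist * M,
        m_moist = m_moist, k_sig = k_sig,
        b_S = stats::runif(1, 0.05, 0.15),
        a_ii0 = stats::runif(1, 0.002, 0.006),
        a_ii1 = stats::runif(1, 0, 3e-4),
        a_ij0 = stats::runif(1, 0.002, 0.005),
        a_ij1 = stats::runif(1, 0, 3e-4))
      # growth: Gaussian temperature response; warm taxon peaks 2-4 K
      # above home
      T_opt <- T0 + if (warm) stats::runif(1, 2, 4) else
        if (cold) stats::runif(1, -1, 0) else stats::runif(1, -0.5, 1.5)
      d_ii <- stats::runif(1, 0, 0.06)
      d_ij <- stats::runif(1, 0, 0.06)
      gp <- growth_params(
        g_max = stats::runif(1, 1.5, 3), T_opt = T_opt,
        sigma_T = stats::runif(1, 2, 3.5),
        b_G = stats::runif(1, 0.6, 0.8),
        c_ii = log(stats::runif(1, 0.001, 0.004)) - d_ii * T0,
        d_ii = d_ii,
        c_ij = log(stats::runif(1, 0.001, 0.003)) - d_ij * T0,
        d_ij = d_ij,
        sigma_eps = stats::runif(1, 0.25, 0.5))
      # recruitment: conspecific propagule pressure balances mortality
      r_ii1 <- stats::runif(1, 0.05, 0.15)
      r_ij1 <- stats::runif(1, 0.02, 0.08)
      rp <- recruitment_params(
        r_ii0 = log(stats::runif(1, 0.08, 0.15)) - r_ii1 * T0,
        r_ii1 = r_ii1,
        r_ij0 = log(stats::runif(1, 0.002, 0.004)) - r_ij1 * T0,
        r_ij1 = r_ij1)
      taxon_params(taxa[i], sp, gp, rp)
    })
    names(out) <- taxa
    out
  })
}

random_initial_map <- function(design, params, turf_id, year = 2017L) {
  g <- design$grid
  sc <- cover_scale(quadrant_area_cm2 = g$quadrant_area_cm2)
  lo <- if (design$populate_buffer) 0L else g$inner[1]
  hi <- if (design$populate_buffer) g$n_side - 1L else g$inner[2]
  q <- expand.grid(row = lo:hi, col = lo:hi)
  rows <- lapply(names(params), function(tx) {
    occ <- stats::runif(nrow(q)) < design$init_occupancy
    if (!any(occ)) return(NULL)
    sz <- sample(sc$midpoint_cm2[3:5], sum(occ), replace = TRUE)
    data.frame(taxon = tx, row = q$row[occ], col = q$col[occ],
               cover_cm2 = sz, stringsAsFactors = FALSE)
  })
  cov <- do.call(rbind, rows)
  if (is.null(cov))
    cov <- data.frame(taxon = character(0), row = integer(0),
                      col = integer(0), cover_cm2 = numeric(0))
  cov$uid <- seq_len(nrow(cov))
  turf_map(turf_id, year, g, cov)
}

# One-quadrant orthogonal displacement of inner units (re-sprouting /
# observation error), avoiding same-taxon collisions. Applied to each
# newly generated annual map, so a unit's apparent year-to-year movement
# is at most one quadrant. Returns the perturbed map plus the uid ->
# (row, col) moves made.
displace_map <- function(map, rate) {
  if (rate <= 0) return(list(map = map, moved = NULL))
  g <- map$grid
  cv <- map$cover
  steps <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  moved <- list()
  for (tx in unique(cv$taxon)) {
    idx <- which(cv$taxon == tx & is_inner(g, cv$row, cv$col))
    occ <- paste(cv$row[cv$taxon == tx], cv$col[cv$taxon == tx])
    for (i in idx) {
      if (stats::runif(1) >= rate) next
      dirs <- steps[sample.int(4), , drop = FALSE]
      for (k in 1:4) {
        r2 <- cv$row[i] + dirs[k, 1]; c2 <- cv$col[i] + dirs[k, 2]
        if (r2 < g$inner[1] || r2 > g$inner[2] ||
            c2 < g$inner[1] || c2 > g$inner[2]) next
        if (paste(r2, c2) %in% occ) next
        occ <- c(setdiff(occ, paste(cv$row[i], cv$col[i])), paste(r2, c2))
        cv$row[i] <- r2; cv$col[i] <- c2
        moved[[as.character(cv$uid[i])]] <- c(r2, c2)
        break
      }
    }
  }
  list(map = turf_map(map$turf_id, map$year, g, cv), moved = moved)
}

#' Generate synthetic turf series with ground-truth demography
#'
#' Forward-simulates every turf with [step_year()] at its site's constant
#' temperature and records the exact fate (survival, death, recruitment)
#' of every unit. Emitted maps optionally carry one-quadrant location
#' displacement at `design$displacement_rate`, emulating re-sprouting and
#' observation error; ground-truth records are expressed in the emitted
#' (displaced) coordinates, so they remain the oracle for the tracking
#' module.
#'
#' @param design a [synthetic_design()].
#' @param params named list of [taxon_params()] (default: sampled from
#'   the design).
#' @param seed RNG seed.
#' @return List with `maps` (nested `[[turf]][[year]]` observed maps),
#'   `truth` (ground-truth demography table in observed coordinates,
#'   with `uid`), `params`, `climate` (named list of per-site constant
#'   [climate_series()]), `turf_site` (named vector mapping turfs to
#'   sites) and `design`.
#' @export
generate_turf_series <- function(design, params = NULL, seed = 1) {
  params <- params %||% sample_taxon_params(design, seed = derive_seed(seed, 999))
  with_seed(seed, {
    sites <- sprintf("site%d", seq_along(design$site_offsets_K))
    years <- seq(2017L, length.out = design$n_years)
    climate <- lapply(seq_along(sites), function(s)
      constant_scenario(design$T_home_C + design$site_offsets_K[s],
                        design$n_years, year0 = years[1],
                        moisture = design$moisture, id = sites[s]))
    names(climate) <- sites

    maps <- list(); truth <- list(); turf_site <- character(0)
    for (s in seq_along(sites)) {
      Ts <- design$T_home_C + design$site_offsets_K[s]
      for (k in seq_len(design$n_turfs_per_site)) {
        tid <- sprintf("%s_t%02d", sites[s], k)
        turf_site[tid] <- sites[s]
        true_map <- random_initial_map(design, params, tid, years[1])
        if (isTRUE(design$burn_in)) {
          eq <- equilibrate(true_map, design$T_home_C, design$moisture,
                            params, design$kernel,
                            design$burn_in_criterion)
          true_map <- turf_map(tid, years[1], design$grid, eq$cover)
        }
        true_series <- list(true_map)
        recs <- list()
        for (y in seq_len(design$n_years - 1)) {
          nxt <- step_year(true_series[[y]], Ts, design$moisture, params,
                           design$kernel, detail = TRUE)
          r <- attr(nxt, "records")
          attr(nxt, "records") <- NULL
          dsp <- displace_map(nxt, design$displacement_rate)
          # re-sprouting moved some units: record their new position
          if (length(dsp$moved) && !is.null(r)) {
            hit <- match(as.character(r$uid), names(dsp$moved))
            for (j in which(!is.na(hit) & r$event != "death")) {
              r$row_to[j] <- dsp$moved[[hit[j]]][1]
              r$col_to[j] <- dsp$moved[[hit[j]]][2]
            }
          }
          recs[[y]] <- r
          true_series[[y + 1]] <- dsp$map
        }
        names(true_series) <- as.character(years)
        maps[[tid]] <- true_series
        truth[[length(truth) + 1L]] <- do.call(rbind, recs)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(maps = maps, truth = truth, params = params, climate = climate,
         turf_site = turf_site, design = design)
  })
}

#' Write a complete miniature study to disk
#'
#' Produces `maps.csv`, `climate.csv`, `true_params.json`,
#' `true_demography.csv` and `config.yaml` in `out_dir`: a full synthetic
#' study sized to run the whole pipeline (track, fit, validate, simulate,
#' summarise) in minutes. Byte-identical output for identical seeds.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed RNG seed.
#' @param design a [synthetic_design()].
#' @return Invisibly, the [generate_turf_series()] result.
#' @export
make_fixture_suite <- function(out_dir, seed = 1,
                               design = synthetic_design()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_turf_series(design, seed = seed)
  write_turf_maps(gen$maps, file.path(out_dir, "maps.csv"))
  write_climate(gen$climate, file.path(out_dir, "climate.csv"))
  write_params(gen$params, file.path(out_dir, "true_params.json"))
  truth <- gen$truth
  utils::write.csv(truth, file.path(out_dir, "true_demography.csv"),
                   row.names = FALSE, quote = FALSE)
  g <- design$grid; kn <- design$kernel
  yaml::write_yaml(list(
    seed = seed,
    grid = list(turf_side_m = g$turf_side_m,
                quadrant_side_m = g$quadrant_side_m,
                buffer_m = g$buffer_m),
    kernel = list(sigma_m = kn$sigma_m, truncation_m = kn$truncation_m),
    moisture = design$moisture,
    T_home_C = design$T_home_C,
    site_offsets_K = design$site_offsets_K,
    turf_site = as.list(gen$turf_site),
    displacement_rate = design$displacement_rate),
    file.path(out_dir, "config.yaml"))
  invisible(gen)
}

#' Two-taxon fixture demonstrating the ecological-lag mechanism
#'
#' A constructed community in which demographic lags decide a taxon's
#' fate. The `resident` taxon is deterministic and static: certain
#' survival, growth pinned at the quadrant cap, no recruitment, filling
#' every inner quadrant. The `warm_forb` taxon has a warm growth optimum
#' (home + 4 K) and strongly size-dependent survival: under the cool
#' starting climate its adults shrink slowly and only die once small, so
#' with annual time steps it persists for a decade or more -- long enough
#' for gradual warming to reverse its decline. A lag-free run, which
#' re-equilibrates the community to each year's climate, drives it
#' through the whole shrink-and-die cascade within the first year's
#' equilibration and extinguishes it immediately.
#'
#' The bundled equilibrium criterion is deliberately strict (1e-5 on
#' both thresholds) so that the slow shrink of even a single warm unit
#' (about 0.2 cm2 per year) keeps year-1 equilibration running through
#' the whole death cascade. Both taxa have their background recruitment
#' overridden off (`theta_R = -30`) and near-zero growth noise; the
#' resident is pinned at the quadrant cap, so once the warm taxon is
#' gone the community is exactly static and equilibration halts at
#' once.
#'
#' @param T_home_C starting mean summer temperature (degrees C).
#' @param delta_K gradual warming by the final year (K).
#' @param n_years length of the warming scenario.
#' @param n_warm_units initial number of warm-taxon units.
#' @param grid turf geometry.
#' @return List with `params`, `initial` (a [turf_map()]), `climate`
#'   (linear [gradual_scenario()]), `criterion` and `kernel`.
#' @export
make_lag_fixture <- function(T_home_C = 12.3, delta_K = 4, n_years = 31,
                             n_warm_units = 100,
                             grid = make_grid(1, 0.05, 0.10)) {
  params <- list(
    resident = taxon_params(
      "resident",
      survival_params(lam_max = 40, T_infl0 = 100, k_sig = 1),
      growth_params(g_max = 30, T_opt = T_home_C, sigma_T = 1000,
                    b_G = 0, sigma_eps = 0.01),
      recruitment_params(r_ii0 = -30, r_ij0 = -30, theta_R = -30)),
    warm_forb = taxon_params(
      "warm_forb",
      survival_params(lam_max = -6.5, T_infl0 = T_home_C + 2.5,
                      k_sig = 1.2, b_S = 0.55),
      growth_params(g_max = 3, T_opt = T_home_C + 4, sigma_T = 1.5,
                    b_G = 0.97, sigma_eps = 0.01),
      recruitment_params(r_ii0 = -30, r_ij0 = -30, theta_R = -30)))
  inr <- grid$inner[1]:grid$inner[2]
  res <- expand.grid(row = inr, col = inr)
  res <- data.frame(taxon = "resident", res,
                    cover_cm2 = grid$quadrant_area_cm2)
  # warm units on an evenly spaced sub-lattice of inner quadrants
  pick <- round(seq(1, nrow(res), length.out = n_warm_units))
  warm <- data.frame(taxon = "warm_forb", res[pick, c("row", "col")],
                     cover_cm2 = 20)
  initial <- turf_map("lagdemo", 2017L, grid, rbind(res, warm))
  climate <- gradual_scenario(T_home_C, delta_K, 2017L,
                              2017L + n_years - 1L, shape = "linear",
                              interannual_sd = 0, id = "lag_demo")
  list(params = params, initial = initial, climate = climate,
       criterion = equilibrium_criterion(1e-5, 1e-5, max_years = 400),
       kernel = kernel_spec())
}
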