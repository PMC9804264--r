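#' Quasi-equilibrium halting criterion
#'
#' Burn-in and lag-free simulations iterate annual updates under a fixed
#' climate until the community's total inner cover is quasi-stable between
#' two subsequent years: either the total cover growth rate
#' `|C'/C - 1|` drops below `growth_rate_threshold` (default 0.05) or the
#' absolute change `|C' - C|` drops below `cover_change_threshold` of the
#' turf's total area (default 0.005, i.e. 0.5%).
#'
#' @param growth_rate_threshold dimensionless threshold on the total-cover
#'   growth rate, > 0.
#' @param cover_change_threshold threshold on the absolute cover change as
#'   a fraction of total turf area, > 0.
#' @param max_years safety cap on the number of iterations.
#' @return An object of class `equilibrium_criterion`.
#' @export
equilibrium_criterion <- function(growth_rate_threshold = 0.05,
                                  cover_change_threshold = 0.005,
                                  max_years = 500L) {
  if (growth_rate_threshold <= 0 || cover_change_threshold <= 0)
    stop_input("thresholds must be > 0")
  structure(list(growth_rate_threshold = growth_rate_threshold,
                 cover_change_threshold = cover_change_threshold,
                 max_years = as.integer(max_years)),
            class = "equilibrium_criterion")
}

#' Advance a community by one year
#'
#' The annual update is synchronous: survival, growth and recruitment
#' probabilities for every unit and empty quadrant are all computed from
#' the start-of-year map (and its crowding fields) before any fate is
#' realised. Each inner unit survives with probability
#' `plogis(survival_logit(...))`; survivors draw a new size from the
#' growth model (Gaussian noise, truncated to `[u_min, quadrant area]`);
#' every (taxon, inner quadrant not occupied by that taxon) pair recruits
#' with probability `plogis(recruitment_logit(...))`, recruits starting at
#' `u_init`. Buffer units persist unchanged. Extinction is absorbing: a
#' taxon with zero cover anywhere on the turf cannot recruit (the
#' simulations include no immigration).
#'
#' @param state a [turf_map()] (the community state at the current year).
#' @param T_prev previous-summer mean temperature (degrees C) driving the
#'   transition.
#' @param moisture soil moisture.
#' @param params named list of [taxon_params()]; must cover every taxon
#'   present on the map.
#' @param kernel a [kernel_spec()].
#' @param u_min smallest realisable size (cm2).
#' @param detail if `TRUE`, attach the realised demographic records as
#'   attribute `"records"` of the returned map (used as ground truth by
#'   the synthetic-data generator).
#' @return A [turf_map()] for the next year. Stochastic: consumes the
#'   current RNG stream; identical states, arguments and RNG states yield
#'   identical results.
#' @export
step_year <- function(state, T_prev, moisture, params,
                      kernel = kernel_spec(), u_min = 0.1,
                      detail = FALSE) {
  stopifnot(inherits(state, "turf_map"))
  g <- state$grid
  present <- map_taxa(state)
  missing_p <- setdiff(present, names(params))
  if (length(missing_p))
    stop_input("missing taxon params for: ", paste(missing_p, collapse = ", "))
  sim_taxa <- union(present, names(params))
  fields <- crowding_fields(state, kernel, taxa = sim_taxa)
  inr <- g$inner[1]:g$inner[2]
  allq <- expand.grid(row = inr, col = inr)
  have_uid <- "uid" %in% names(state$cover)
  next_uid <- if (have_uid && nrow(state$cover))
    max(state$cover$uid) + 1L else 1L

  new_rows <- list()
  recs <- list()
  alive <- total_cover(state, inner_only = FALSE, by_taxon = TRUE)

  for (tx in sim_taxa) {
    tp <- params[[tx]]
    cv <- state$cover[state$cover$taxon == tx, , drop = FALSE]
    inner <- is_inner(g, cv$row, cv$col)
    un <- cv[inner, , drop = FALSE]
    buf <- cv[!inner, , drop = FALSE]

    if (nrow(un)) {
      w <- crowding_at(fields, tx, un$row, un$col)
      eta <- survival_logit(tp$survival, T_prev, moisture,
                            un$cover_cm2, w$w_i, w$w_j)
      surv <- stats::runif(nrow(un)) < inv_logit(eta)
      # growth sizes drawn for all units in fixed order to keep the RNG
      # consumption independent of realised survival
      unew <- growth_draw(tp$growth, T_prev, un$cover_cm2, w$w_i, w$w_j,
                          u_min = u_min, u_max = g$quadrant_area_cm2)
      sv <- un[surv, , drop = FALSE]
      if (nrow(sv)) {
        sv$cover_cm2 <- unew[surv]
        new_rows[[length(new_rows) + 1L]] <- sv
      }
      if (detail) {
        if (any(surv)) recs[[length(recs) + 1L]] <- data.frame(
          turf_id = state$turf_id, taxon = tx,
          year_from = state$year, year_to = state$year + 1L,
          event = "survival",
          row_from = un$row[surv], col_from = un$col[surv],
          row_to = un$row[surv], col_to = un$col[surv],
          size_from_cm2 = un$cover_cm2[surv], size_to_cm2 = unew[surv],
          uid = if (have_uid) un$uid[surv] else NA_integer_,
          stringsAsFactors = FALSE)
        if (any(!surv)) recs[[length(recs) + 1L]] <- data.frame(
          turf_id = state$turf_id, taxon = tx,
          year_from = state$year, year_to = state$year + 1L,
          event = "death",
          row_from = un$row[!surv], col_from = un$col[!surv],
          row_to = NA_integer_, col_to = NA_integer_,
          size_from_cm2 = un$cover_cm2[!surv], size_to_cm2 = NA_real_,
          uid = if (have_uid) un$uid[!surv] else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    if (nrow(buf)) new_rows[[length(new_rows) + 1L]] <- buf

    # recruitment: absorbing extinction -- only extant taxa produce seeds
    if (isTRUE(alive[tx] > 0)) {
      occ_key <- paste(cv$row, cv$col)
      empty <- allq[!(paste(allq$row, allq$col) %in% occ_key), ,
                    drop = FALSE]
      if (nrow(empty)) {
        w <- crowding_at(fields, tx, empty$row, empty$col)
        eta <- recruitment_logit(tp$recruitment, T_prev, w$w_i, w$w_j)
        rec <- stats::runif(nrow(empty)) < inv_logit(eta)
        if (any(rec)) {
          nr <- sum(rec)
          newu <- data.frame(taxon = tx, row = empty$row[rec],
                             col = empty$col[rec],
                             cover_cm2 = tp$recruitment$u_init,
                             stringsAsFactors = FALSE)
          if (have_uid) {
            newu$uid <- seq(next_uid, length.out = nr)
            next_uid <- next_uid + nr
          }
          new_rows[[length(new_rows) + 1L]] <- newu
          if (detail) recs[[length(recs) + 1L]] <- data.frame(
            turf_id = state$turf_id, taxon = tx,
            year_from = state$year, year_to = state$year + 1L,
            event = "recruit",
            row_from = NA_integer_, col_from = NA_integer_,
            row_to = empty$row[rec], col_to = empty$col[rec],
            size_from_cm2 = NA_real_,
            size_to_cm2 = tp$recruitment$u_init,
            uid = if (have_uid) newu$uid else NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  cols <- c("taxon", "row", "col", "cover_cm2", if (have_uid) "uid")
  newcov <- if (length(new_rows))
    do.call(rbind, lapply(new_rows, function(d) d[cols])) else
    state$cover[0, cols, drop = FALSE]
  out <- turf_map(state$turf_id, state$year + 1L, g, newcov)
  if (detail) {
    attr(out, "records") <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  out
}

#' Iterate to quasi-equilibrium under constant climate
#'
#' @inheritParams step_year
#' @param T_const constant mean summer temperature (degrees C).
#' @param criterion an [equilibrium_criterion()].
#' @return The first state meeting the criterion, with attributes
#'   `years_run` and `trajectory` (total inner cover per iteration).
#'   Errors if `max_years` is reached, attaching the cover trajectory to
#'   the condition.
#' @export
equilibrate <- function(state, T_const, moisture, params,
                        kernel = kernel_spec(),
                        criterion = equilibrium_criterion(),
                        u_min = 0.1) {
  stopifnot(inherits(criterion, "equilibrium_criterion"))
  g <- state$grid
  abs_thresh <- criterion$cover_change_threshold * g$turf_area_cm2
  traj <- total_cover(state)
  for (it in seq_len(criterion$max_years)) {
    c0 <- traj[length(traj)]
    state <- step_year(state, T_const, moisture, params, kernel, u_min)
    c1 <- total_cover(state)
    traj <- c(traj, c1)
    rate_ok <- c0 > 0 && abs(c1 / c0 - 1) < criterion$growth_rate_threshold
    abs_ok <- abs(c1 - c0) < abs_thresh
    if (rate_ok || abs_ok) {
      attr(state, "years_run") <- it
      attr(state, "trajectory") <- traj
      return(state)
    }
  }
  cond <- simpleError(paste0("equilibrate: no quasi-equilibrium within ",
                             criterion$max_years, " years"))
  cond$trajectory <- traj
  stop(cond)
}

record_state <- function(state, taxa) {
  cov <- total_cover(state, by_taxon = TRUE)
  full <- stats::setNames(rep(0, length(taxa)), taxa)
  full[names(cov)] <- cov
  full
}

# one replicate projection along a climate series; returns per-year
# taxon-cover matrix (years x taxa). The transition from year y to y + 1
# is driven by year y's climate (the previous summer).
project_once <- function(state, climate, params, kernel, taxa, u_min) {
  n <- nrow(climate)
  covs <- matrix(0, n, length(taxa), dimnames = list(climate$year, taxa))
  covs[1, ] <- record_state(state, taxa)
  if (n > 1) for (k in seq_len(n - 1)) {
    state <- step_year(state, climate$T_summer_C[k], climate$moisture[k],
                       params, kernel, u_min)
    covs[k + 1, ] <- record_state(state, taxa)
  }
  covs
}

ensemble_from_covers <- function(cover_list, years, scenario_id) {
  taxa <- colnames(cover_list[[1]])
  covers <- do.call(rbind, lapply(seq_along(cover_list), function(r) {
    m <- cover_list[[r]]
    data.frame(replicate = r, year = rep(years, times = ncol(m)),
               taxon = rep(taxa, each = nrow(m)),
               total_cover_cm2 = as.vector(m), stringsAsFactors = FALSE)
  }))
  diversity <- do.call(rbind, lapply(seq_along(cover_list), function(r) {
    m <- cover_list[[r]]
    H <- apply(m, 1, function(x) if (sum(x) > 0) shannon(x) else NA_real_)
    data.frame(replicate = r, year = years, shannon = unname(H))
  }))
  qs <- function(x) if (all(is.na(x))) c(NA_real_, NA_real_, NA_real_) else
    stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE, na.rm = TRUE)
  arr <- array(unlist(cover_list),
               dim = c(length(years), length(taxa), length(cover_list)))
  summ <- do.call(rbind, lapply(seq_along(taxa), function(j) {
    q <- t(apply(arr[, j, , drop = FALSE], 1, qs))
    data.frame(year = years, taxon = taxa[j], q05 = q[, 1],
               median = q[, 2], q95 = q[, 3], stringsAsFactors = FALSE)
  }))
  hmat <- matrix(diversity$shannon, nrow = length(years)) # years x reps
  hq <- t(apply(hmat, 1, qs))
  div_summ <- data.frame(year = years, q05 = hq[, 1], median = hq[, 2],
                         q95 = hq[, 3])
  structure(list(scenario_id = scenario_id, years = years, taxa = taxa,
                 covers = covers, diversity = diversity,
                 summary = summ, diversity_summary = div_summ,
                 n_reps = length(cover_list)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> scenario %s: %d taxa, years %d-%d, %d replicates\n",
              x$scenario_id, length(x$taxa), min(x$years), max(x$years),
              x$n_reps))
  invisible(x)
}

#' Project a community under a climate scenario (replicate ensemble)
#'
#' Runs `n_reps` seeded replicates of year-by-year projection of the
#' (post-burn-in) state over the climate series and summarises the
#' ensemble with the per-year median and 5%/95% quantiles of every taxon's
#' total cover and of Shannon diversity.
#'
#' @inheritParams step_year
#' @param initial the initial [turf_map()] (typically post burn-in).
#' @param climate a [climate_series()].
#' @param n_reps number of replicate trajectories (default 20).
#' @param seed integer seed; replicate r uses a sub-seed derived from
#'   `(seed, r)`, so runs are reproducible and replicates independent.
#' @param taxa taxa to report (default: taxa with parameters).
#' @return A `trajectory_ensemble`: long per-replicate cover and diversity
#'   tables plus quantile summaries.
#' @export
run_scenario <- function(initial, climate, params, kernel = kernel_spec(),
                         n_reps = 20, seed = 1, u_min = 0.1, taxa = NULL) {
  stopifnot(inherits(initial, "turf_map"), inherits(climate, "climate_series"))
  taxa <- taxa %||% union(names(params), map_taxa(initial))
  cover_list <- lapply(seq_len(n_reps), function(r)
    with_seed(derive_seed(seed, r),
              project_once(initial, climate, params, kernel, taxa, u_min)))
  ensemble_from_covers(cover_list, climate$year, attr(climate, "scenario_id"))
}

#' Project with ecological lags removed
#'
#' The lag-free counterfactual: every year the community is re-equilibrated
#' to that year's climate (with the same quasi-equilibrium criterion as the
#' burn-in) before the year's state is recorded, so abundances track the
#' moving climate-driven equilibrium instead of lagging behind it.
#'
#' @inheritParams run_scenario
#' @param criterion an [equilibrium_criterion()]; equilibration failure in
#'   any year propagates with the year attached.
#' @return A `trajectory_ensemble`.
#' @export
run_no_lag <- function(initial, climate, params, kernel = kernel_spec(),
                       criterion = equilibrium_criterion(), n_reps = 20,
                       seed = 1, u_min = 0.1, taxa = NULL) {
  stopifnot(inherits(initial, "turf_map"), inherits(climate, "climate_series"))
  taxa <- taxa %||% union(names(params), map_taxa(initial))
  one_rep <- function(r) {
    state <- initial
    n <- nrow(climate)
    covs <- matrix(0, n, length(taxa),
                   dimnames = list(climate$year, taxa))
    for (k in seq_len(n)) {
      state <- tryCatch(
        equilibrate(state, climate$T_summer_C[k], climate$moisture[k],
                    params, kernel, criterion, u_min),
        error = function(e) stop_input("no-lag equilibration failed in year ",
                                       climate$year[k], ": ",
                                       conditionMessage(e)))
      covs[k, ] <- record_state(state, taxa)
    }
    covs
  }
  cover_list <- lapply(seq_len(n_reps), function(r)
    with_seed(derive_seed(seed, r), one_rep(r)))
  ensemble_from_covers(cover_list, climate$year,
                       paste0(attr(climate, "scenario_id"), "_no_lag"))
}

#' Project under a stepwise climate jump
#'
#' Convenience wrapper: builds a [stepwise_scenario()] from a window of a
#' source series (for example the 2088-2098 window of a gradual scenario)
#' and projects the community under it, so gradual and stepwise
#' comparisons can share seeds.
#'
#' @inheritParams run_scenario
#' @param source_climate the source [climate_series()].
#' @param window length-2 year window `c(start, end)` within the source.
#' @param n_years length of the stepwise series.
#' @return A `trajectory_ensemble`.
#' @export
run_stepwise <- function(initial, source_climate, window, n_years, params,
                         kernel = kernel_spec(), n_reps = 20, seed = 1,
                         u_min = 0.1, taxa = NULL) {
  clim <- stepwise_scenario(source_climate, window[1], window[2], n_years,
                            seed = derive_seed(seed, 0))
  run_scenario(initial, clim, params, kernel, n_reps = n_reps,
               seed = seed, u_min = u_min, taxa = taxa)
}
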