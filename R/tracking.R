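#' Track demographic units between two consecutive annual maps
#'
#' Units of each taxon in year `t` are linked to at most one same-taxon
#' unit in year `t + 1`. The matcher is a deterministic greedy two-pass
#' assignment: pass 1 links units that stayed in their quadrant; pass 2
#' links remaining units by smallest centre distance within the
#' displacement radius (accommodating small location changes from
#' re-sprouting and observation error), breaking ties by smallest size
#' change and then row-major order. Unlinked year-`t` units are deaths;
#' unlinked year-`t + 1` units are recruits. Only inner-grid units are
#' tracked (the buffer is not surveyed demographically).
#'
#' @param map_t,map_t1 [turf_map()]s of the same turf and grid with
#'   `map_t1$year == map_t$year + 1`.
#' @param max_displacement_quadrants matching radius in quadrant widths;
#'   a pair is linkable when the centre distance is at most
#'   `max_displacement_quadrants * quadrant_side_m` (default 1, i.e. the
#'   four orthogonal neighbours).
#' @return Data frame of demographic records with columns `turf_id`,
#'   `taxon`, `year_from`, `year_to`, `event` (survival/death/recruit),
#'   `row_from`, `col_from`, `row_to`, `col_to`, `size_from_cm2`,
#'   `size_to_cm2` (coordinates/sizes are `NA` where undefined).
#' @export
link_years <- function(map_t, map_t1, max_displacement_quadrants = 1) {
  stopifnot(inherits(map_t, "turf_map"), inherits(map_t1, "turf_map"))
  if (map_t$turf_id != map_t1$turf_id || !same_grid(map_t$grid, map_t1$grid))
    stop_input("maps must share turf_id and grid")
  if (map_t1$year != map_t$year + 1L)
    stop_input("maps must be consecutive years (got ", map_t$year,
               " and ", map_t1$year, ")")
  g <- map_t$grid
  inner_units <- function(m) {
    cv <- m$cover
    cv[is_inner(g, cv$row, cv$col), , drop = FALSE]
  }
  a <- inner_units(map_t)
  b <- inner_units(map_t1)
  max_d <- (max_displacement_quadrants + 1e-9) * g$quadrant_side_m

  recs <- list()
  for (tx in union(unique(a$taxon), unique(b$taxon))) {
    ua <- a[a$taxon == tx, , drop = FALSE]
    ub <- b[b$taxon == tx, , drop = FALSE]
    na <- nrow(ua); nb <- nrow(ub)
    link_a <- rep(NA_integer_, na) # index into ub
    used_b <- rep(FALSE, nb)

    if (na && nb) {
      # pass 1: same quadrant
      kb <- paste(ub$row, ub$col)
      m1 <- match(paste(ua$row, ua$col), kb)
      ok <- !is.na(m1)
      link_a[ok] <- m1[ok]
      used_b[m1[ok]] <- TRUE
      # pass 2: nearest centre within the displacement radius
      ia <- which(is.na(link_a)); ib <- which(!used_b)
      if (length(ia) && length(ib)) {
        cand <- expand.grid(i = ia, j = ib)
        d <- g$quadrant_side_m * sqrt(
          (ua$row[cand$i] - ub$row[cand$j])^2 +
          (ua$col[cand$i] - ub$col[cand$j])^2)
        keep <- d <= max_d
        cand <- cand[keep, , drop = FALSE]; d <- d[keep]
        if (nrow(cand)) {
          dsz <- abs(ub$cover_cm2[cand$j] - ua$cover_cm2[cand$i])
          rm_ord <- ua$row[cand$i] * g$n_side + ua$col[cand$i]
          o <- order(d, dsz, rm_ord)
          for (k in o) {
            i <- cand$i[k]; j <- cand$j[k]
            if (is.na(link_a[i]) && !used_b[j]) {
              link_a[i] <- j
              used_b[j] <- TRUE
            }
          }
        }
      }
    }

    mk <- function(event, rf, cf, rt, ct, sf, st) {
      if (!length(rf) && !length(rt)) return(NULL)
      n <- max(length(rf), length(rt))
      data.frame(turf_id = map_t$turf_id, taxon = tx,
                 year_from = map_t$year, year_to = map_t1$year,
                 event = event,
                 row_from = if (length(rf)) rf else rep(NA_integer_, n),
                 col_from = if (length(cf)) cf else rep(NA_integer_, n),
                 row_to = if (length(rt)) rt else rep(NA_integer_, n),
                 col_to = if (length(ct)) ct else rep(NA_integer_, n),
                 size_from_cm2 = if (length(sf)) sf else rep(NA_real_, n),
                 size_to_cm2 = if (length(st)) st else rep(NA_real_, n),
                 stringsAsFactors = FALSE)
    }
    sv <- which(!is.na(link_a))
    if (length(sv))
      recs[[length(recs) + 1L]] <- mk("survival",
        ua$row[sv], ua$col[sv], ub$row[link_a[sv]], ub$col[link_a[sv]],
        ua$cover_cm2[sv], ub$cover_cm2[link_a[sv]])
    dd <- which(is.na(link_a))
    if (length(dd))
      recs[[length(recs) + 1L]] <- mk("death",
        ua$row[dd], ua$col[dd], integer(0), integer(0),
        ua$cover_cm2[dd], numeric(0))
    rc <- which(!used_b)
    if (length(rc))
      recs[[length(recs) + 1L]] <- mk("recruit",
        integer(0), integer(0), ub$row[rc], ub$col[rc],
        numeric(0), ub$cover_cm2[rc])
  }
  if (!length(recs)) return(empty_demography())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

empty_demography <- function() {
  data.frame(turf_id = character(0), taxon = character(0),
             year_from = integer(0), year_to = integer(0),
             event = character(0),
             row_from = integer(0), col_from = integer(0),
             row_to = integer(0), col_to = integer(0),
             size_from_cm2 = numeric(0), size_to_cm2 = numeric(0),
             w_con = numeric(0), w_het = numeric(0),
             stringsAsFactors = FALSE)
}

#' Build the full demography table for a set of turf series
#'
#' Applies [link_years()] to every pair of consecutive annual maps of
#' every turf and annotates each record with the crowding covariates
#' `w_con` (`w_i`) and `w_het` (`w_j`) computed on the year-from map, at
#' the year-from quadrant for survivals and deaths and at the destination
#' quadrant for recruits (the empty quadrant whose occupancy the
#' recruitment model explains).
#'
#' @param maps a flat or nested list of [turf_map()]s (as from
#'   [read_turf_maps()]); years with gaps emit a warning and the missing
#'   transition is skipped.
#' @param kernel a [kernel_spec()].
#' @param max_displacement matching radius in quadrant widths.
#' @return Data frame of annotated demographic records.
#' @export
build_demography_table <- function(maps, kernel = kernel_spec(),
                                   max_displacement = 1) {
  maps <- flatten_maps(maps)
  ids <- vapply(maps, function(m) m$turf_id, character(1))
  out <- list()
  for (tid in unique(ids)) {
    ms <- maps[ids == tid]
    yrs <- vapply(ms, function(m) m$year, integer(1))
    ms <- ms[order(yrs)]; yrs <- sort(yrs)
    if (length(ms) < 2) {
      warning("turf ", tid, ": fewer than 2 years, skipped")
      next
    }
    for (k in seq_len(length(ms) - 1)) {
      if (yrs[k + 1] != yrs[k] + 1) {
        warning("turf ", tid, ": gap between years ", yrs[k], " and ",
                yrs[k + 1], ", transition skipped")
        next
      }
      rec <- link_years(ms[[k]], ms[[k + 1]], max_displacement)
      if (!nrow(rec)) next
      fields <- crowding_fields(ms[[k]], kernel)
      r0 <- ifelse(is.na(rec$row_from), rec$row_to, rec$row_from)
      c0 <- ifelse(is.na(rec$col_from), rec$col_to, rec$col_from)
      w <- mapply(function(tx, r, c) unlist(crowding_at(fields, tx, r, c)),
                  rec$taxon, r0, c0)
      rec$w_con <- w[1, ]
      rec$w_het <- w[2, ]
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) return(empty_demography())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-quadrant recruitment trials
#'
#' The recruitment model is a Bernoulli trial for every (taxon, inner
#' quadrant unoccupied by that taxon) pair: did a recruit of the taxon
#' appear there the following year? This builds the full trial table
#' (successes *and* failures) with the year-from crowding covariates,
#' which is the likelihood's sufficient data.
#'
#' @inheritParams build_demography_table
#' @param taxa taxa to build trials for; default: every taxon seen in any
#'   map of the turf's series.
#' @return Data frame with columns `turf_id`, `taxon`, `year_from`,
#'   `year_to`, `row`, `col`, `recruited` (0/1), `w_con`, `w_het`.
#' @export
build_recruitment_table <- function(maps, kernel = kernel_spec(),
                                    max_displacement = 1, taxa = NULL) {
  maps <- flatten_maps(maps)
  ids <- vapply(maps, function(m) m$turf_id, character(1))
  out <- list()
  for (tid in unique(ids)) {
    ms <- maps[ids == tid]
    yrs <- vapply(ms, function(m) m$year, integer(1))
    ms <- ms[order(yrs)]; yrs <- sort(yrs)
    if (length(ms) < 2) next
    turf_taxa <- taxa %||% unique(unlist(lapply(ms, map_taxa)))
    g <- ms[[1]]$grid
    inr <- g$inner[1]:g$inner[2]
    allq <- expand.grid(row = inr, col = inr)
    for (k in seq_len(length(ms) - 1)) {
      if (yrs[k + 1] != yrs[k] + 1) next
      rec <- link_years(ms[[k]], ms[[k + 1]], max_displacement)
      fields <- crowding_fields(ms[[k]], kernel, taxa = turf_taxa)
      for (tx in turf_taxa) {
        cv <- ms[[k]]$cover
        occ <- cv[cv$taxon == tx, c("row", "col"), drop = FALSE]
        empty <- allq[!(paste(allq$row, allq$col) %in%
                          paste(occ$row, occ$col)), , drop = FALSE]
        if (!nrow(empty)) next
        rk <- rec[rec$taxon == tx & rec$event == "recruit", , drop = FALSE]
        hit <- paste(empty$row, empty$col) %in% paste(rk$row_to, rk$col_to)
        w <- crowding_at(fields, tx, empty$row, empty$col)
        out[[length(out) + 1L]] <- data.frame(
          turf_id = tid, taxon = tx,
          year_from = yrs[k], year_to = yrs[k + 1],
          row = empty$row, col = empty$col,
          recruited = as.integer(hit),
          w_con = w$w_i, w_het = w$w_j, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(turf_id = character(0), taxon = character(0),
                      year_from = integer(0), year_to = integer(0),
                      row = integer(0), col = integer(0),
                      recruited = integer(0), w_con = numeric(0),
                      w_het = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
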