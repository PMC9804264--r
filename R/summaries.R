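#' Shannon diversity
#'
#' `H = -sum(p log p)` over taxa with positive cover, where `p` is the
#' relative cover. Natural log by default, so `H` is in nats and bounded
#' by `log(S)` for `S` taxa.
#'
#' @param covers non-negative per-taxon total covers, at least one
#'   positive.
#' @param base logarithm base.
#' @return Shannon index.
#' @export
shannon <- function(covers, base = exp(1)) {
  check_finite(covers, "covers")
  if (any(covers < 0)) stop_input("covers must be >= 0")
  covers <- covers[covers > 0]
  if (!length(covers)) stop_input("Shannon index undefined for all-zero cover")
  p <- covers / sum(covers)
  -sum(p * log(p, base = base))
}

#' Log cover ratio
#'
#' `log((final + c) / (initial + c))`; the pseudo-count `c` (default
#' 0.25 cm2, one minimal ordinal-class midpoint) keeps zero covers finite.
#'
#' @param initial,final total covers (cm2), >= 0; vectorised.
#' @param pseudo pseudo-count `c`, > 0.
#' @return Log ratios.
#' @export
log_cover_ratio <- function(initial, final, pseudo = 0.25) {
  check_finite(initial, "initial"); check_finite(final, "final")
  if (any(initial < 0) || any(final < 0)) stop_input("covers must be >= 0")
  if (pseudo <= 0) stop_input("pseudo must be > 0")
  log((final + pseudo) / (initial + pseudo))
}

#' Principal coordinates ordination of community observations
#'
#' Classical (metric) multidimensional scaling on Euclidean distances
#' between community observations (rows: turf-years or scenario-years;
#' columns: taxa). With Euclidean input this equals PCA of the centred
#' matrix up to axis sign; axis signs are fixed by orienting each axis so
#' its largest-magnitude taxon loading is positive. Per-taxon vectors are
#' the correlations of taxon cover with the first two axis scores, and a
#' taxon is flagged when those two axes explain more than `flag_r2` of its
#' cover variation (R2 of the regression of its cover on the two scores).
#'
#' @param mat numeric matrix or data frame, >= 3 rows, non-negative.
#' @param flag_r2 R2 threshold for flagging well-explained taxa.
#' @return An `ordination_result`: `coordinates` (rows x axes),
#'   `variance_prop` per axis, `eig`, and `taxon_vectors` (per-taxon axis
#'   correlations, R2 on axes 1-2, and the `flagged` indicator).
#' @export
pcoa <- function(mat, flag_r2 = 0.9) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop_input("need >= 3 observations")
  check_finite(as.vector(mat), "mat")
  D <- stats::dist(mat)
  if (all(D < 1e-12))
    stop_input("degenerate input: all observations identical")
  k <- min(nrow(mat) - 1L, ncol(mat))
  mds <- stats::cmdscale(D, k = k, eig = TRUE)
  eig <- mds$eig
  pos <- eig > max(eig) * 1e-9
  scores <- mds$points[, seq_len(min(sum(pos), ncol(mds$points))),
                       drop = FALSE]
  varprop <- eig[pos][seq_len(ncol(scores))] / sum(eig[pos])

  # orient: largest-|loading| taxon positive on each axis
  for (a in seq_len(ncol(scores))) {
    if (stats::sd(scores[, a]) == 0) next
    lo <- suppressWarnings(apply(mat, 2, function(x)
      if (stats::sd(x) == 0) 0 else stats::cor(x, scores[, a])))
    lo[is.na(lo)] <- 0
    if (length(lo) && lo[which.max(abs(lo))] < 0) scores[, a] <- -scores[, a]
  }
  colnames(scores) <- paste0("axis", seq_len(ncol(scores)))

  n2 <- min(2L, ncol(scores))
  tv <- do.call(rbind, lapply(colnames(mat) %||% seq_len(ncol(mat)),
                              function(tx) {
    x <- mat[, tx]
    if (stats::sd(x) == 0)
      return(data.frame(taxon = as.character(tx), cor_axis1 = 0,
                        cor_axis2 = 0, r2_axes12 = 0, flagged = FALSE))
    cors <- vapply(seq_len(n2), function(a)
      if (stats::sd(scores[, a]) == 0) 0 else stats::cor(x, scores[, a]),
      numeric(1))
    # exact fits (e.g. one-taxon gradients) are legitimate here
    r2 <- suppressWarnings(
      summary(stats::lm(x ~ scores[, seq_len(n2)]))$r.squared)
    data.frame(taxon = as.character(tx), cor_axis1 = cors[1],
               cor_axis2 = if (n2 > 1) cors[2] else NA_real_,
               r2_axes12 = r2, flagged = r2 > flag_r2,
               stringsAsFactors = FALSE)
  }))
  structure(list(coordinates = scores, variance_prop = unname(varprop),
                 eig = eig, taxon_vectors = tv),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d observations, %d axes; axis 1: %.1f%%, axis 2: %.1f%%\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$variance_prop[1],
              if (length(x$variance_prop) > 1) 100 * x$variance_prop[2] else NA))
  invisible(x)
}

#' Compare trajectory ensembles across scenarios
#'
#' Tabulates the contrasts used to interpret scenario runs: the per-taxon
#' first-extinction year (first year with zero cover, per replicate;
#' extinction is absorbing), summarised by its median across replicates;
#' each scenario's diversity minimum and final value (of the ensemble
#' median trajectory); and the per-year, per-taxon differences of the
#' ensemble median covers of every scenario against the first.
#'
#' @param ensembles list of `trajectory_ensemble`s sharing taxa and years.
#' @return A `trajectory_report` with elements `extinction`
#'   (scenario x taxon median first-extinction year, NA if never),
#'   `diversity` (per-scenario minimum / final median diversity) and
#'   `median_diff` (long data frame of median-cover differences relative
#'   to the first ensemble).
#' @export
compare_trajectories <- function(ensembles) {
  stopifnot(length(ensembles) >= 1)
  taxa <- ensembles[[1]]$taxa
  years <- ensembles[[1]]$years
  for (e in ensembles)
    if (!identical(e$taxa, taxa) || !identical(e$years, years))
      stop_input("ensembles must share taxa and year ranges")
  ids <- vapply(ensembles, function(e) e$scenario_id, character(1))

  ext <- do.call(rbind, lapply(ensembles, function(e) {
    per_tax <- vapply(taxa, function(tx) {
      sub <- e$covers[e$covers$taxon == tx, ]
      yrs <- vapply(split(sub, sub$replicate), function(d) {
        z <- d$year[d$total_cover_cm2 == 0]
        if (length(z)) min(z) else NA_real_
      }, numeric(1))
      if (all(is.na(yrs))) NA_real_ else stats::median(yrs, na.rm = TRUE)
    }, numeric(1))
    data.frame(scenario = e$scenario_id, taxon = taxa,
               median_extinction_year = unname(per_tax),
               stringsAsFactors = FALSE)
  }))

  div <- do.call(rbind, lapply(ensembles, function(e) {
    m <- e$diversity_summary$median
    data.frame(scenario = e$scenario_id,
               min_diversity = if (all(is.na(m))) NA_real_ else min(m, na.rm = TRUE),
               final_diversity = m[length(m)], stringsAsFactors = FALSE)
  }))

  base <- ensembles[[1]]$summary
  diffs <- do.call(rbind, lapply(seq_along(ensembles)[-1], function(k) {
    s <- ensembles[[k]]$summary
    data.frame(scenario = ids[k], reference = ids[1],
               year = s$year, taxon = s$taxon,
               median_diff_cm2 = s$median - base$median,
               stringsAsFactors = FALSE)
  }))
  if (length(ensembles) == 1)
    diffs <- data.frame(scenario = character(0), reference = character(0),
                        year = integer(0), taxon = character(0),
                        median_diff_cm2 = numeric(0))

  structure(list(extinction = ext, diversity = div, median_diff = diffs),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("<trajectory_report>\n\nDiversity per scenario:\n")
  print(x$diversity, row.names = FALSE)
  cat("\nMedian first-extinction years (NA = persists):\n")
  print(stats::reshape(x$extinction, direction = "wide",
                       idvar = "taxon", timevar = "scenario"),
        row.names = FALSE)
  invisible(x)
}
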