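#' Inverse-distance weight of a twin pair at a target location
#'
#' The weighting kernel is `w = 1 / max(d, d_floor)^p`, where `d` is the
#' Euclidean distance between the pair's location and the target in the
#' (projected, planar) map units, and `p` controls how quickly a pair's
#' influence drops off with distance. `p = 0.5` gives the gentle smoothing
#' used for national aetiology maps; `p = 0` collapses to uniform weights.
#' The distance floor keeps the kernel finite when a pair sits exactly on
#' the target.
#'
#' @param target a list/row with `x`, `y` (a target-location table row) or a
#'   length-2 numeric `c(x, y)`.
#' @param pair_xy numeric matrix or data frame of pair coordinates
#'   (columns `x`, `y`), or a length-2 vector.
#' @param p power parameter, `>= 0` (default 0.5).
#' @param d_floor distance floor in map units, `> 0` (default 1e-6).
#' @return numeric vector of weights, one per pair.
#' @export
#' @examples
#' pair_weight(c(0, 0), c(4, 0), p = 0.5)  # 1/sqrt(4) = 0.5
pair_weight <- function(target, pair_xy, p = 0.5, d_floor = 1e-6) {
  tx <- if (is.list(target)) as.numeric(target$x) else as.numeric(target[1])
  ty <- if (is.list(target)) as.numeric(target$y) else as.numeric(target[2])
  if (is.data.frame(pair_xy)) pair_xy <- as.matrix(pair_xy[, c("x", "y")])
  if (is.null(dim(pair_xy))) pair_xy <- matrix(pair_xy, ncol = 2)
  if (!is.finite(tx) || !is.finite(ty) || any(!is.finite(pair_xy)))
    stopf("coordinates must be finite")
  if (!is.finite(p) || p < 0) stopf("p must be >= 0")
  if (!is.finite(d_floor) || d_floor <= 0) stopf("d_floor must be > 0")
  d <- sqrt((pair_xy[, 1] - tx)^2 + (pair_xy[, 2] - ty)^2)
  1 / pmax(d, d_floor)^p
}

#' Per-target inverse-distance weight sets for a cohort
#'
#' One weight set per target location: every pair receives a strictly
#' positive weight at every target, plus Kish effective sample sizes
#' computed separately for the MZ and DZ groups.
#'
#' @param targets data frame with columns `target_id`, `x`, `y`.
#' @param pairs twin cohort data frame (planar coordinates `x`, `y`).
#' @param p,d_floor kernel parameters, see [pair_weight()].
#' @return list of `weight_set` objects with fields `target_id`, `weights`,
#'   `p`, `ess_mz`, `ess_dz`.
#' @export
weight_matrix <- function(targets, pairs, p = 0.5, d_floor = 1e-6) {
  if (nrow(pairs) == 0L) stopf("empty cohort")
  .assert_cols(targets, c("target_id", "x", "y"), "targets")
  .assert_cols(pairs, c("x", "y"), "twin cohort")
  if (identical(attr(pairs, "crs"), "lonlat"))
    stopf("cohort coordinates are geographic (lon/lat); project to a planar CRS first (see project_coordinates)")
  px <- as.numeric(pairs$x); py <- as.numeric(pairs$y)
  if (any(!is.finite(px)) || any(!is.finite(py)))
    stopf("non-finite pair coordinates")
  zyg <- .normalize_zygosity(pairs$zygosity)
  mz <- zyg == "MZ"; dz <- .is_dz(zyg)
  lapply(seq_len(nrow(targets)), function(i) {
    w <- pair_weight(c(targets$x[i], targets$y[i]), cbind(px, py), p, d_floor)
    structure(list(
      target_id = targets$target_id[i], weights = w, p = p,
      ess_mz = if (any(mz)) effective_sample_size(w[mz]) else NA_real_,
      ess_dz = if (any(dz)) effective_sample_size(w[dz]) else NA_real_),
      class = "weight_set")
  })
}

#' Kish effective sample size
#'
#' `(sum(w))^2 / sum(w^2)`: the equal-weight sample size carrying the same
#' information as the weighted sample. Equals `n` for equal weights, 1 when
#' a single weight dominates, and is invariant to rescaling all weights.
#'
#' @param weights non-negative weights, at least one positive.
#' @return scalar effective sample size.
#' @export
#' @examples
#' effective_sample_size(c(1, 1, 1, 1))  # 4
effective_sample_size <- function(weights) {
  if (length(weights) == 0L) stopf("no weights supplied")
  if (any(!is.finite(weights)) || any(weights < 0))
    stopf("weights must be finite and non-negative")
  s <- sum(weights)
  if (s == 0) stopf("all weights are zero")
  s^2 / sum(weights^2)
}
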