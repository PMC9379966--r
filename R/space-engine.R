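#' Standardize phenotypes to population mean 0, SD 1
#'
#' All observed phenotype values (both twins pooled) are centred and scaled
#' by the population standard deviation (denominator n, not n-1), so areas
#' where total variance exceeds or falls short of the population average
#' are directly visible in the raw component maps. Missingness is
#' preserved.
#'
#' @param pairs twin cohort data frame.
#' @return the cohort with `y1`, `y2` standardized.
#' @export
standardize_phenotype <- function(pairs) {
  yy <- c(pairs$y1, pairs$y2)
  obs <- is.finite(yy)
  if (sum(obs) < 2L || length(unique(yy[obs])) < 2L)
    stopf("need at least 2 distinct observed phenotype values to standardize")
  m <- mean(yy[obs])
  s <- sqrt(mean((yy[obs] - m)^2))
  pairs$y1 <- (pairs$y1 - m) / s
  pairs$y2 <- (pairs$y2 - m) / s
  attr(pairs, "standardized") <- TRUE
  pairs
}

#' Target locations from region centroids
#'
#' One target per unique region identifier represented by at least one
#' pair, located at the region's centroid (the small-area geography
#' convention: one target per populated administrative cell).
#'
#' @param pairs twin cohort data frame with a `region_id` column.
#' @param region_centroids data frame with columns `region_id`, `x`, `y`.
#' @return target data frame (`target_id`, `x`, `y`, `source`).
#' @export
region_centroid_targets <- function(pairs, region_centroids) {
  .assert_cols(pairs, "region_id", "twin cohort")
  .assert_cols(region_centroids, c("region_id", "x", "y"), "region centroid table")
  ids <- sort(unique(as.character(pairs$region_id)))
  miss <- setdiff(ids, as.character(region_centroids$region_id))
  if (length(miss))
    stopf("region_id(s) missing from the centroid table: %s",
          paste(utils::head(miss, 10L), collapse = ", "))
  idx <- match(ids, as.character(region_centroids$region_id))
  data.frame(target_id = ids,
             x = as.numeric(region_centroids$x[idx]),
             y = as.numeric(region_centroids$y[idx]),
             source = "region_centroid", stringsAsFactors = FALSE)
}

#' Density-representative target locations by seeded k-means
#'
#' Selects k targets representative of local sampling density (the
#' anonymity-preserving alternative to exact participant locations):
#' centroids of a seeded k-means on the pair coordinates. Centers are
#' sorted by (x, y) so the output is order-stable; the whole operation is
#' deterministic given the seed.
#'
#' @param pairs twin cohort data frame, or a 2-column coordinate matrix.
#' @param k number of targets (`0 < k <=` number of pairs).
#' @param seed integer seed.
#' @return target data frame (`target_id`, `x`, `y`, `source`).
#' @export
density_representative_targets <- function(pairs, k, seed = 1L) {
  xy <- if (is.data.frame(pairs)) cbind(x = as.numeric(pairs$x), y = as.numeric(pairs$y))
        else cbind(x = as.numeric(pairs[, 1]), y = as.numeric(pairs[, 2]))
  if (!is.numeric(k) || k <= 0) stopf("k must be a positive integer")
  k <- as.integer(k)
  if (k > nrow(xy)) stopf("k (%d) exceeds the number of pairs (%d)", k, nrow(xy))
  uxy <- unique(xy)
  centers <- if (k >= nrow(uxy)) {
    uxy
  } else {
    km <- with_seed(seed, stats::kmeans(xy, centers = k, nstart = 5L,
                                        iter.max = 100L))
    km$centers
  }
  ord <- order(centers[, 1], centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  data.frame(target_id = sprintf("T%05d", seq_len(nrow(centers))),
             x = unname(centers[, 1]), y = unname(centers[, 2]),
             source = "density_representative", stringsAsFactors = FALSE)
}

#' Distance-weighted mean trait per target location
#'
#' For each target, the inverse-distance-weighted average of pair mean
#' scores (each pair contributes the mean of its observed twin scores),
#' i.e. the "prevalence surface" companion to the aetiology maps.
#'
#' @param pairs twin cohort data frame (standardized phenotypes expected).
#' @param targets target data frame.
#' @param p,d_floor kernel parameters, see [pair_weight()].
#' @return data frame `target_id`, `x`, `y`, `weighted_mean_trait`.
#' @export
weighted_mean_map <- function(pairs, targets, p = 0.5, d_floor = 1e-6) {
  ws <- weight_matrix(targets, pairs, p, d_floor)
  ybar <- rowMeans(cbind(pairs$y1, pairs$y2), na.rm = TRUE)
  wm <- vapply(ws, function(s) {
    sum(s$weights * ybar) / sum(s$weights)
  }, numeric(1))
  data.frame(target_id = targets$target_id, x = targets$x, y = targets$y,
             weighted_mean_trait = wm, stringsAsFactors = FALSE)
}

.space_na_row <- function(tg) {
  data.frame(target_id = tg$target_id, x = tg$x, y = tg$y,
             a2_raw = NA_real_, c2_or_d2_raw = NA_real_, e2_raw = NA_real_,
             a2_std = NA_real_, c2_or_d2_std = NA_real_, e2_std = NA_real_,
             total_variance = NA_real_,
             a2_lo = NA_real_, a2_hi = NA_real_,
             c2_or_d2_lo = NA_real_, c2_or_d2_hi = NA_real_,
             e2_lo = NA_real_, e2_hi = NA_real_,
             ess_mz = NA_real_, ess_dz = NA_real_,
             converged = FALSE, weighted_mean_trait = NA_real_,
             stringsAsFactors = FALSE)
}

#' Run the geographically weighted twin analysis
#'
#' The core mapping engine: for every target location, compute
#' inverse-distance weights for all pairs, maximize the weighted FIML twin
#' likelihood (started at the population-fit estimates, so every location
#' is optimized deterministically from the same point), and record raw and
#' proportional variance components, confidence intervals, Kish effective
#' sample sizes and the distance-weighted mean trait. Each location is an
#' independent pure computation: results do not depend on target or pair
#' ordering, and the choice of targets affects only where results are
#' reported, never any pair's data. Non-convergent locations are flagged,
#' not dropped.
#'
#' @param pairs twin cohort data frame with standardized phenotypes.
#' @param targets target data frame (`target_id`, `x`, `y`).
#' @param spec a [model_spec()].
#' @param config list: `p` (default 0.5), `d_floor` (1e-6), `ci_method`
#'   (`"information"`), plus [fit_model()] optimizer entries.
#' @return data frame of class `space_result`, one row per target.
#' @export
#' @examples
#' coh <- simulate_cohort(make_homogeneous_field(),
#'                        cohort_config(n_pairs = 400, seed = 2))
#' coh <- standardize_phenotype(coh)
#' tg <- density_representative_targets(coh, k = 4, seed = 2)
#' res <- run_space(coh, tg, config = list(ci_method = "none"))
#' res[, c("target_id", "a2_raw", "e2_raw")]
run_space <- function(pairs, targets, spec = model_spec(), config = list()) {
  p <- config$p %||% 0.5
  d_floor <- config$d_floor %||% 1e-6
  .assert_cols(targets, c("target_id", "x", "y"), "targets")
  pop_fit <- fit_model(pairs, NULL, spec,
                       utils::modifyList(config, list(ci_method = "none")))
  cfg_loc <- utils::modifyList(config, list(start = pop_fit$par))
  ws <- weight_matrix(targets, pairs, p, d_floor)
  ybar <- rowMeans(cbind(pairs$y1, pairs$y2), na.rm = TRUE)
  failures <- character()
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    w <- ws[[i]]$weights
    row <- tryCatch({
      fit <- fit_model(pairs, w, spec, cfg_loc)
      ci <- fit$ci %||% list(a2 = c(NA, NA), c2_or_d2 = c(NA, NA), e2 = c(NA, NA))
      getci <- function(nm) ci[[nm]] %||% c(NA_real_, NA_real_)
      data.frame(target_id = tg$target_id, x = tg$x, y = tg$y,
                 a2_raw = fit$components$a2,
                 c2_or_d2_raw = fit$components$c2_or_d2,
                 e2_raw = fit$components$e2,
                 a2_std = fit$components_std$a2,
                 c2_or_d2_std = fit$components_std$c2_or_d2,
                 e2_std = fit$components_std$e2,
                 total_variance = fit$components$a2 + fit$components$c2_or_d2 +
                   fit$components$e2,
                 a2_lo = getci("a2")[1], a2_hi = getci("a2")[2],
                 c2_or_d2_lo = getci("c2_or_d2")[1], c2_or_d2_hi = getci("c2_or_d2")[2],
                 e2_lo = getci("e2")[1], e2_hi = getci("e2")[2],
                 ess_mz = fit$ess_mz, ess_dz = fit$ess_dz,
                 converged = fit$converged,
                 weighted_mean_trait = sum(w * ybar) / sum(w),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", tg$target_id, conditionMessage(e)))
      .space_na_row(tg)
    })
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(failures))
    message(sprintf("run_space: %d of %d locations failed to fit:\n  %s",
                    length(failures), nrow(targets),
                    paste(utils::head(failures, 10L), collapse = "\n  ")))
  attr(out, "spec") <- spec
  attr(out, "config") <- list(p = p, d_floor = d_floor)
  attr(out, "population_fit") <- pop_fit
  class(out) <- c("space_result", "data.frame")
  out
}

#' Historical-location sensitivity analysis
#'
#' Re-runs the full spatial analysis with each pair placed at each of its
#' historical residential locations (snapshot columns `x_<label>`,
#' `y_<label>` in the cohort), and reports how strongly the resulting
#' genetic-influence maps correlate across snapshots. Stable maps across
#' residential histories indicate the detected geography is not an
#' artefact of the single location used.
#'
#' @param pairs twin cohort data frame with snapshot columns.
#' @param targets target data frame.
#' @param spec a [model_spec()].
#' @param config as in [run_space()].
#' @param labels snapshot labels to use; default: all detected. Every pair
#'   must have both coordinates for every label.
#' @return list with `results` (named list of `space_result`, including
#'   `"current"`) and `a2_correlation` (Pearson correlation matrix of the
#'   a2_raw maps).
#' @export
location_sensitivity <- function(pairs, targets, spec = model_spec(),
                                 config = list(), labels = NULL) {
  snap_x <- grep("^x_", names(pairs), value = TRUE)
  found <- sub("^x_", "", snap_x)
  if (is.null(labels)) labels <- found
  if (!length(labels)) stopf("no location snapshot columns (x_<label>, y_<label>) found")
  for (lb in labels) {
    xc <- paste0("x_", lb); yc <- paste0("y_", lb)
    if (!xc %in% names(pairs) || !yc %in% names(pairs))
      stopf("snapshot '%s' is missing column %s", lb,
            if (xc %in% names(pairs)) yc else xc)
    if (anyNA(pairs[[xc]]) || anyNA(pairs[[yc]]))
      stopf("snapshot '%s' has missing coordinates for %d pair(s)", lb,
            sum(is.na(pairs[[xc]]) | is.na(pairs[[yc]])))
  }
  results <- list(current = run_space(pairs, targets, spec, config))
  for (lb in labels) {
    ph <- pairs
    ph$x <- as.numeric(pairs[[paste0("x_", lb)]])
    ph$y <- as.numeric(pairs[[paste0("y_", lb)]])
    results[[lb]] <- run_space(ph, targets, spec, config)
  }
  amat <- vapply(results, function(r) r$a2_raw, numeric(nrow(targets)))
  list(results = results,
       a2_correlation = stats::cor(amat, use = "pairwise.complete.obs"))
}
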