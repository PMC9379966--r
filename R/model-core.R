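#' Specify a twin variance-decomposition model
#'
#' A model specification names which variance components are estimated
#' (`ACE`, `ADE`, `AE`, `CE` or `E`; `E` is always present), whether the
#' magnitudes of the components are equated across sexes or allowed to
#' differ (quantitative sex limitation), and which mean-model covariates
#' are included. `ADE` replaces the shared environment C with non-additive
#' (dominance) genetic variance D; C and D are not jointly identifiable
#' from MZ/DZ twin pairs, and the quantitative sex-limitation variant is
#' only offered for C-based models.
#'
#' @param components one of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param sex_limitation `"equated"` (same A/C/E magnitudes in males and
#'   females) or `"quantitative"` (sex-specific magnitudes, see
#'   [fit_sex_limitation()]).
#' @param covariates character subset of `c("sex", "age")` entering the
#'   mean model.
#' @return an object of class `twin_model_spec`.
#' @export
#' @examples
#' model_spec("ACE", covariates = "sex")
model_spec <- function(components = "ACE", sex_limitation = "equated",
                       covariates = "sex") {
  components <- match.arg(components, c("ACE", "ADE", "AE", "CE", "E"))
  sex_limitation <- match.arg(sex_limitation, c("equated", "quantitative"))
  if (length(covariates) == 1L && is.na(covariates)) covariates <- character()
  covariates <- as.character(covariates)
  if (length(setdiff(covariates, c("sex", "age"))))
    stopf("covariates must be a subset of c('sex', 'age')")
  if (components == "ADE" && sex_limitation == "quantitative")
    stopf("ADE cannot be combined with quantitative sex limitation")
  structure(list(components = components, sex_limitation = sex_limitation,
                 covariates = covariates),
            class = "twin_model_spec")
}

#' @export
print.twin_model_spec <- function(x, ...) {
  cat("<twin_model_spec> ", x$components,
      ", sex limitation: ", x$sex_limitation,
      ", covariates: ", if (length(x$covariates)) paste(x$covariates, collapse = "+") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Variance components of a twin model
#'
#' Container for the additive-genetic (a2), shared-environmental or
#' dominance (c2_or_d2) and non-shared-environmental (e2) variances, either
#' on the raw scale of the phenotype or as proportions of total variance.
#'
#' @param a2,c2_or_d2,e2 non-negative variances.
#' @param scale `"raw"` or `"proportional"`; proportional components must
#'   sum to 1 (within 1e-10).
#' @param role `"C"` or `"D"`, the interpretation of the middle component.
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(a2, c2_or_d2, e2, scale = "raw", role = "C") {
  scale <- match.arg(scale, c("raw", "proportional"))
  role <- match.arg(role, c("C", "D"))
  v <- c(a2 = a2, c2_or_d2 = c2_or_d2, e2 = e2)
  if (any(!is.finite(v)) || any(v < 0))
    stopf("variance components must be finite and non-negative, got (%s)",
          paste(signif(v, 4), collapse = ", "))
  if (scale == "proportional" && abs(sum(v) - 1) > 1e-10)
    stopf("proportional components must sum to 1 (got %.12f)", sum(v))
  structure(list(a2 = unname(a2), c2_or_d2 = unname(c2_or_d2), e2 = unname(e2),
                 scale = scale, role = role),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  lab <- if (x$role == "D") "d2" else "c2"
  cat(sprintf("<variance_components %s> a2 = %.4f, %s = %.4f, e2 = %.4f\n",
              x$scale, x$a2, lab, x$c2_or_d2, x$e2))
  invisible(x)
}

#' Mean model for a twin phenotype
#'
#' Fixed-effect mean structure: intercept plus optional sex and age terms.
#' Sex enters with effect coding (+0.5 male, -0.5 female), age in years.
#'
#' @param intercept,beta_sex,beta_age finite reals.
#' @return an object of class `mean_model`.
#' @export
mean_model <- function(intercept = 0, beta_sex = 0, beta_age = 0) {
  v <- c(intercept, beta_sex, beta_age)
  if (any(!is.finite(v))) stopf("mean model coefficients must be finite")
  structure(list(intercept = intercept, beta_sex = beta_sex, beta_age = beta_age),
            class = "mean_model")
}

# correlation coefficients for the middle component by role
.mid_coef <- function(zyg, role) {
  if (role == "D") ifelse(zyg == "MZ", 1, 0.25) else 1
}

#' Model-implied twin-pair covariance matrix
#'
#' Under the biometrical model, additive genetic effects correlate 1 in MZ
#' and 0.5 in DZ pairs, the shared environment correlates 1 in both, the
#' non-shared environment is uncorrelated, and dominance (D, in the ADE
#' variant) correlates 1 in MZ and 0.25 in DZ pairs.
#'
#' @param components a [variance_components()] on the raw scale (a plain
#'   named list with `a2`, `c2_or_d2`, `e2` is accepted).
#' @param zygosity `"MZ"`, `"DZss"` or `"DZos"` (long forms accepted).
#' @param spec a [model_spec()]; its `components` decides whether the middle
#'   variance acts as C or as D.
#' @return symmetric 2x2 covariance matrix.
#' @export
#' @examples
#' expected_covariance(variance_components(0.65, 0, 0.35), "MZ", model_spec())
expected_covariance <- function(components, zygosity, spec = model_spec()) {
  zyg <- .normalize_zygosity(zygosity)
  if (length(zyg) != 1L) stopf("expected_covariance takes a single zygosity")
  a2 <- components$a2; m2 <- components$c2_or_d2; e2 <- components$e2
  if (any(!is.finite(c(a2, m2, e2))) || any(c(a2, m2, e2) < 0))
    stopf("variance components must be finite and non-negative")
  if (!is.null(components$scale) && components$scale != "raw")
    stopf("expected_covariance requires raw-scale components")
  role <- if (spec$components == "ADE") "D" else "C"
  alpha <- if (zyg == "MZ") 1 else 0.5
  v <- a2 + m2 + e2
  cv <- alpha * a2 + .mid_coef(zyg, role) * m2
  matrix(c(v, cv, cv, v), 2, 2)
}

# --- vectorized likelihood machinery -------------------------------------

# Precompute per-pair arrays once per fit. Missing phenotypes contribute
# univariate marginals (FIML); age NA is treated as the cohort mean when age
# is not a covariate, and rejected when it is.
.cohort_arrays <- function(pairs, spec) {
  .assert_cols(pairs, c("zygosity", "sex1", "sex2", "y1", "y2"), "twin cohort")
  zyg <- .normalize_zygosity(pairs$zygosity)
  y1 <- as.numeric(pairs$y1); y2 <- as.numeric(pairs$y2)
  obs1 <- is.finite(y1); obs2 <- is.finite(y2)
  if (any(!obs1 & !obs2))
    stopf("pair(s) with both phenotypes missing: rows %s",
          paste(utils::head(which(!obs1 & !obs2), 5L), collapse = ", "))
  use_sex <- "sex" %in% spec$covariates
  use_age <- "age" %in% spec$covariates
  sx1 <- .sex_code(pairs$sex1); sx2 <- .sex_code(pairs$sex2)
  bad_mz <- zyg == "MZ" & sx1 != sx2
  if (any(bad_mz))
    stopf("MZ pair(s) with discordant sexes: rows %s",
          paste(utils::head(which(bad_mz), 5L), collapse = ", "))
  age <- if ("age" %in% names(pairs)) as.numeric(pairs$age) else rep(NA_real_, nrow(pairs))
  if (use_age) {
    if (anyNA(age)) stopf("age is a covariate but missing for %d pair(s)", sum(is.na(age)))
  } else age[] <- 0
  list(n = nrow(pairs), zyg = zyg, y1 = y1, y2 = y2, obs1 = obs1, obs2 = obs2,
       sx1 = sx1, sx2 = sx2, age = age,
       alpha = ifelse(zyg == "MZ", 1, 0.5),
       use_sex = use_sex, use_age = use_age)
}

# log-density of each pair given per-pair means/variances/covariance,
# with univariate marginals where one twin's phenotype is absent
.pair_ll_vec <- function(arr, mu1, mu2, v1, v2, cv) {
  ll <- numeric(arr$n)
  both <- arr$obs1 & arr$obs2
  if (any(both)) {
    z1 <- arr$y1[both] - mu1[both]; z2 <- arr$y2[both] - mu2[both]
    d <- v1[both] * v2[both] - cv[both]^2
    if (any(d <= 0) || any(v1[both] <= 0))
      return(NULL)  # singular/non-PD covariance; caller decides
    q <- (v2[both] * z1^2 - 2 * cv[both] * z1 * z2 + v1[both] * z2^2) / d
    ll[both] <- -log(2 * pi) - 0.5 * log(d) - 0.5 * q
  }
  only1 <- arr$obs1 & !arr$obs2
  if (any(only1)) {
    if (any(v1[only1] <= 0)) return(NULL)
    z <- arr$y1[only1] - mu1[only1]
    ll[only1] <- -0.5 * log(2 * pi * v1[only1]) - z^2 / (2 * v1[only1])
  }
  only2 <- arr$obs2 & !arr$obs1
  if (any(only2)) {
    if (any(v2[only2] <= 0)) return(NULL)
    z <- arr$y2[only2] - mu2[only2]
    ll[only2] <- -0.5 * log(2 * pi * v2[only2]) - z^2 / (2 * v2[only2])
  }
  ll
}

# free path-coefficient labels by model
.free_paths <- function(components) {
  switch(components,
         ACE = c("a", "c", "e"), ADE = c("a", "d", "e"),
         AE = c("a", "e"), CE = c("c", "e"), E = "e")
}

.par_names <- function(spec) {
  c(.free_paths(spec$components), "mu",
    if ("sex" %in% spec$covariates) "b_sex",
    if ("age" %in% spec$covariates) "b_age")
}

# theta -> (a2, m2, e2, mean coefs) for the equated model
.unpack_theta <- function(theta, spec) {
  nm <- .par_names(spec)
  th <- stats::setNames(theta, nm)
  a2 <- if ("a" %in% nm) th[["a"]]^2 else 0
  m2 <- if ("c" %in% nm) th[["c"]]^2 else if ("d" %in% nm) th[["d"]]^2 else 0
  e2 <- th[["e"]]^2
  list(a2 = a2, m2 = m2, e2 = e2, mu = th[["mu"]],
       b_sex = if ("b_sex" %in% nm) th[["b_sex"]] else 0,
       b_age = if ("b_age" %in% nm) th[["b_age"]] else 0)
}

.ll_equated <- function(theta, arr, spec, w) {
  p <- .unpack_theta(theta, spec)
  role <- if (spec$components == "ADE") "D" else "C"
  v <- p$a2 + p$m2 + p$e2
  cv <- arr$alpha * p$a2 + .mid_coef(arr$zyg, role) * p$m2
  mu1 <- p$mu + p$b_sex * arr$sx1 + p$b_age * arr$age
  mu2 <- p$mu + p$b_sex * arr$sx2 + p$b_age * arr$age
  ll <- .pair_ll_vec(arr, mu1, mu2, rep(v, arr$n), rep(v, arr$n), cv)
  if (is.null(ll)) return(-1e10)
  sum(w * ll)
}

#' Log-likelihood of one twin pair
#'
#' Bivariate-normal log-density of the pair's phenotypes given the mean
#' model and the model-implied covariance; reduces to the univariate
#' marginal when one twin's phenotype is missing (the full-information
#' maximum-likelihood contract).
#'
#' @param pair a single-row data frame or list with fields `y1`, `y2`,
#'   `zygosity`, `sex1`, `sex2` and optionally `age`.
#' @param components raw-scale [variance_components()].
#' @param mm a [mean_model()].
#' @param spec a [model_spec()].
#' @return scalar log-likelihood.
#' @export
pair_loglik <- function(pair, components, mm = mean_model(), spec = model_spec()) {
  pairs <- as.data.frame(pair, stringsAsFactors = FALSE)
  if (nrow(pairs) != 1L) stopf("pair_loglik takes a single pair")
  if (!"age" %in% names(pairs)) pairs$age <- 0
  arr <- .cohort_arrays(pairs, spec)
  role <- if (spec$components == "ADE") "D" else "C"
  v <- components$a2 + components$c2_or_d2 + components$e2
  cv <- arr$alpha * components$a2 + .mid_coef(arr$zyg, role) * components$c2_or_d2
  mu1 <- mm$intercept + mm$beta_sex * arr$sx1 + mm$beta_age * arr$age
  mu2 <- mm$intercept + mm$beta_sex * arr$sx2 + mm$beta_age * arr$age
  ll <- .pair_ll_vec(arr, mu1, mu2, v, v, cv)
  if (is.null(ll))
    stopf("singular model-implied covariance (total variance %.3g, covariance %.3g)", v, cv)
  ll[1L]
}

#' Weighted FIML log-likelihood of a cohort
#'
#' Sum of per-pair log-likelihoods, each multiplied by its (non-negative)
#' spatial weight. With unit weights this is the ordinary FIML twin-model
#' log-likelihood.
#'
#' @param pairs twin cohort data frame (see [read_cohort_csv()] for the dialect).
#' @param weights non-negative weights, one per pair.
#' @param components raw-scale [variance_components()].
#' @param mm a [mean_model()].
#' @param spec a [model_spec()].
#' @return scalar weighted log-likelihood.
#' @export
weighted_loglik <- function(pairs, weights, components, mm = mean_model(),
                            spec = model_spec()) {
  if (length(weights) != nrow(pairs))
    stopf("length(weights) [%d] != number of pairs [%d]", length(weights), nrow(pairs))
  if (any(!is.finite(weights)) || any(weights < 0))
    stopf("weights must be finite and non-negative")
  arr <- .cohort_arrays(pairs, spec)
  role <- if (spec$components == "ADE") "D" else "C"
  v <- components$a2 + components$c2_or_d2 + components$e2
  cv <- arr$alpha * components$a2 + .mid_coef(arr$zyg, role) * components$c2_or_d2
  mu1 <- mm$intercept + mm$beta_sex * arr$sx1 + mm$beta_age * arr$age
  mu2 <- mm$intercept + mm$beta_sex * arr$sx2 + mm$beta_age * arr$age
  ll <- .pair_ll_vec(arr, mu1, mu2, rep(v, arr$n), rep(v, arr$n), cv)
  if (is.null(ll)) stopf("singular model-implied covariance")
  sum(weights * ll)
}

# Falconer-style moment start values from weighted twin correlations,
# clipped away from the boundary; deterministic.
.start_values <- function(arr, w, spec) {
  wcor <- function(sel) {
    sel <- sel & arr$obs1 & arr$obs2
    if (sum(sel) < 3L) return(NA_real_)
    ws <- w[sel]
    # double-entered weighted correlation (symmetric in twin order)
    xa <- c(arr$y1[sel], arr$y2[sel]); xb <- c(arr$y2[sel], arr$y1[sel])
    wd <- c(ws, ws)
    m <- sum(wd * xa) / sum(wd)
    va <- sum(wd * (xa - m)^2) / sum(wd)
    cv <- sum(wd * (xa - m) * (xb - m)) / sum(wd)
    if (va <= 0) NA_real_ else cv / va
  }
  vtot <- {
    yy <- c(arr$y1[arr$obs1], arr$y2[arr$obs2])
    wy <- c(w[arr$obs1], w[arr$obs2])
    m <- sum(wy * yy) / sum(wy)
    max(sum(wy * (yy - m)^2) / sum(wy), 1e-3)
  }
  rmz <- wcor(arr$zyg == "MZ"); rdz <- wcor(.is_dz(arr$zyg))
  if (!is.finite(rmz)) rmz <- 0.6
  if (!is.finite(rdz)) rdz <- 0.3
  a2 <- clamp(2 * (rmz - rdz), 0.01, 0.99)
  c2 <- clamp(2 * rdz - rmz, 0.01, 0.99)
  e2 <- clamp(1 - rmz, 0.01, 0.99)
  s <- a2 + c2 + e2
  raw <- vtot * c(a = a2, c = c2, e = e2) / s
  nm <- .par_names(spec)
  start <- stats::setNames(numeric(length(nm)), nm)
  if ("a" %in% nm) start[["a"]] <- sqrt(raw[["a"]])
  if ("c" %in% nm) start[["c"]] <- sqrt(raw[["c"]])
  if ("d" %in% nm) start[["d"]] <- sqrt(raw[["c"]])
  start[["e"]] <- sqrt(raw[["e"]])
  mobs <- {
    yy <- c(arr$y1[arr$obs1], arr$y2[arr$obs2])
    wy <- c(w[arr$obs1], w[arr$obs2])
    sum(wy * yy) / sum(wy)
  }
  start[["mu"]] <- mobs
  start
}

# normalize weights to sum to the number of contributing pairs; positive
# rescaling leaves the maximizer unchanged but makes log-likelihoods and
# information matrices comparable across target locations
.normalize_weights <- function(w) {
  npos <- sum(w > 0)
  if (npos == 0L) stopf("all weights are zero")
  w * (npos / sum(w))
}

#' Fit a twin variance-decomposition model by weighted FIML
#'
#' Maximizes the weighted FIML log-likelihood over path coefficients
#' (variances are squared paths, hence non-negative by construction) and
#' mean-model coefficients, from deterministic moment-based start values.
#' Weights are first normalized to sum to the number of contributing pairs,
#' which leaves point estimates unchanged but keeps log-likelihoods and
#' observed-information matrices comparable across target locations.
#'
#' @param pairs twin cohort data frame.
#' @param weights optional non-negative per-pair weights (default uniform).
#' @param spec a [model_spec()].
#' @param config list; recognised entries `start` (named start vector on the
#'   path scale), `ci_method` (`"information"`, `"profile"` or `"none"`),
#'   `maxit`, `reltol`.
#' @return an object of class `twin_fit`: raw and proportional
#'   [variance_components()], [mean_model()], `loglik`, 95% `ci` per raw
#'   component, Kish `ess_mz`/`ess_dz`, `converged`, `boundary_e2`, `n_eval`.
#' @export
#' @examples
#' cfg <- cohort_config(n_pairs = 600, seed = 7)
#' coh <- simulate_cohort(make_homogeneous_field(0.6, 0.1, 0.3), cfg)
#' fit <- fit_model(coh)
#' fit$components_std
fit_model <- function(pairs, weights = NULL, spec = model_spec(), config = list()) {
  if (is.null(weights)) weights <- rep(1, nrow(pairs))
  if (length(weights) != nrow(pairs))
    stopf("length(weights) [%d] != number of pairs [%d]", length(weights), nrow(pairs))
  if (any(!is.finite(weights)) || any(weights < 0))
    stopf("weights must be finite and non-negative")
  arr <- .cohort_arrays(pairs, spec)
  pos <- weights > 0
  if (spec$components %in% c("ACE", "ADE", "AE")) {
    if (sum(pos & arr$zyg == "MZ") < 2L || sum(pos & .is_dz(arr$zyg)) < 2L)
      stopf("need at least 2 MZ and 2 DZ pairs with positive weight (components not identifiable)")
  }
  w <- .normalize_weights(weights)
  start <- config$start %||% .start_values(arr, w, spec)
  nm <- .par_names(spec)
  if (!identical(names(start), nm))
    stopf("start values must be named %s", paste(nm, collapse = ", "))
  negll <- function(theta) -.ll_equated(theta, arr, spec, w)
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = config$maxit %||% 500L,
                                     reltol = config$reltol %||% 1e-12))
  p <- .unpack_theta(opt$par, spec)
  role <- if (spec$components == "ADE") "D" else "C"
  comp <- variance_components(p$a2, p$m2, p$e2, "raw", role)
  tot <- p$a2 + p$m2 + p$e2
  comp_std <- variance_components(p$a2 / tot, p$m2 / tot, p$e2 / tot,
                                  "proportional", role)
  mm <- mean_model(p$mu, p$b_sex, p$b_age)
  fit <- structure(list(
    components = comp, components_std = comp_std, mean_model = mm,
    loglik = -opt$value, par = opt$par, spec = spec,
    ci = NULL, ci_available = FALSE,
    ess_mz = if (any(arr$zyg == "MZ")) effective_sample_size(w[arr$zyg == "MZ"]) else NA_real_,
    ess_dz = if (any(.is_dz(arr$zyg))) effective_sample_size(w[.is_dz(arr$zyg)]) else NA_real_,
    n_pairs = sum(pos),
    converged = opt$convergence == 0L,
    boundary_e2 = p$e2 < 1e-4 * max(tot, 1e-12),
    n_eval = unname(opt$counts["function"])), class = "twin_fit")
  ci_method <- config$ci_method %||% "information"
  if (!identical(ci_method, "none"))
    fit$ci <- confidence_intervals(fit, pairs, weights, config)
  fit$ci_available <- !is.null(fit$ci) && all(is.finite(unlist(fit$ci)))
  fit
}

#' @export
print.twin_fit <- function(x, ...) {
  lab <- if (x$components$role == "D") "d2" else "c2"
  cat(sprintf("<twin_fit %s> a2 = %.4f, %s = %.4f, e2 = %.4f (raw; total %.4f)\n",
              x$spec$components, x$components$a2, lab, x$components$c2_or_d2,
              x$components$e2,
              x$components$a2 + x$components$c2_or_d2 + x$components$e2))
  cat(sprintf("  loglik = %.3f, ess MZ/DZ = %.0f/%.0f, converged = %s\n",
              x$loglik, x$ess_mz, x$ess_dz, x$converged))
  invisible(x)
}

#' 95% confidence intervals for raw variance components
#'
#' Default method: observed information of the weighted objective at the
#' optimum (weights normalized to sum to the number of contributing pairs,
#' so rescaling all weights cannot shrink the intervals), delta-method
#' propagated from path coefficients to variances; lower bounds truncated
#' at 0. `ci_method = "profile"` instead inverts the likelihood-ratio
#' statistic per component. A singular information matrix yields `NA`
#' bounds rather than an error.
#'
#' @param fit a converged [fit_model()] result.
#' @param pairs,weights the data and weights the model was fitted to.
#' @param config list; `ci_method` as above, `level` (default 0.95).
#' @return named list of `c(lower, upper)` per free variance component.
#' @export
confidence_intervals <- function(fit, pairs, weights = NULL, config = list()) {
  if (is.null(weights)) weights <- rep(1, nrow(pairs))
  spec <- fit$spec
  arr <- .cohort_arrays(pairs, spec)
  w <- .normalize_weights(weights)
  level <- config$level %||% 0.95
  zq <- stats::qnorm(1 - (1 - level) / 2)
  method <- config$ci_method %||% "information"
  paths <- .free_paths(spec$components)
  comp_of <- c(a = "a2", c = "c2_or_d2", d = "c2_or_d2", e = "e2")
  est <- c(a2 = fit$components$a2, c2_or_d2 = fit$components$c2_or_d2,
           e2 = fit$components$e2)
  out <- list()
  if (identical(method, "profile")) {
    for (pth in paths) {
      out[[comp_of[[pth]]]] <- .profile_ci(fit, arr, w, pth, level)
    }
    return(out)
  }
  negll <- function(theta) -.ll_equated(theta, arr, spec, w)
  H <- tryCatch(stats::optimHess(fit$par, negll), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  for (pth in paths) {
    cname <- comp_of[[pth]]
    if (is.null(V) || V[pth, pth] < 0) {
      out[[cname]] <- c(NA_real_, NA_real_)
      next
    }
    path_hat <- fit$par[[pth]]
    se <- abs(2 * path_hat) * sqrt(V[pth, pth])   # delta method for path^2
    out[[cname]] <- c(max(0, est[[cname]] - zq * se), est[[cname]] + zq * se)
  }
  out
}

# profile-likelihood CI on the variance scale for one path coefficient
.profile_ci <- function(fit, arr, w, pth, level) {
  spec <- fit$spec
  nm <- .par_names(spec)
  free <- setdiff(nm, pth)
  crit <- stats::qchisq(level, 1) / 2
  prof <- function(path_val) {
    f <- function(th_free) {
      theta <- stats::setNames(numeric(length(nm)), nm)
      theta[free] <- th_free; theta[[pth]] <- path_val
      -.ll_equated(theta, arr, spec, w)
    }
    o <- stats::optim(fit$par[free], f, method = "BFGS",
                      control = list(maxit = 200L, reltol = 1e-9))
    -o$value
  }
  llmax <- fit$loglik
  g <- function(path_val) llmax - prof(path_val) - crit
  hat <- abs(fit$par[[pth]])
  step <- max(0.1, hat)
  upper_path <- tryCatch({
    hi <- hat + step
    k <- 0
    while (g(hi) < 0 && k < 12) { hi <- hi + step; k <- k + 1 }
    if (g(hi) < 0) NA_real_ else stats::uniroot(g, c(hat, hi), tol = 1e-6)$root
  }, error = function(e) NA_real_)
  lower_path <- tryCatch({
    if (g(0) <= 0) 0 else stats::uniroot(g, c(0, hat), tol = 1e-6)$root
  }, error = function(e) NA_real_)
  c(lower_path^2, upper_path^2)
}

#' Share of phenotypic variance explained by mean-model covariates
#'
#' For each covariate in the mean model, the variance of its fitted
#' contribution across individual twins with observed phenotypes, divided
#' by the total phenotypic variance.
#'
#' @param pairs twin cohort data frame.
#' @param mm a fitted [mean_model()].
#' @return named numeric proportions (`sex`, `age`).
#' @export
variance_explained_by_covariates <- function(pairs, mm) {
  y <- c(pairs$y1, pairs$y2)
  sx <- c(.sex_code(pairs$sex1), .sex_code(pairs$sex2))
  age <- if ("age" %in% names(pairs)) rep(as.numeric(pairs$age), 2) else rep(0, length(y))
  obs <- is.finite(y)
  y <- y[obs]; sx <- sx[obs]; age <- age[obs]
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stopf("phenotype has zero variance")
  term_sex <- mm$beta_sex * sx
  term_age <- mm$beta_age * ifelse(is.finite(age), age, mean(age, na.rm = TRUE))
  c(sex = stats::var(term_sex) / vy,
    age = if (all(is.finite(term_age))) stats::var(term_age) / vy else 0)
}
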