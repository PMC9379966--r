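#' Quantitative sex-limitation twin model
#'
#' Allows the magnitudes of the A, C and E path coefficients to differ
#' between males and females while the same influences operate in both
#' sexes. Same-sex pairs follow the ordinary biometrical expectations with
#' their sex's paths; opposite-sex DZ pairs have expected cross-covariance
#' `0.5 * a_m * a_f + c_m * c_f`. The fitted model is compared to the
#' sex-equated ACE model by a likelihood-ratio test with 3 degrees of
#' freedom (a, c, e equated; no boundary correction, so the reference
#' distribution is approximate).
#'
#' Without opposite-sex DZ pairs the male and female shared-environment
#' paths are only weakly identified; a warning is emitted in that case.
#'
#' @param pairs twin cohort data frame containing male-male, female-female
#'   and (ideally) opposite-sex DZ pairs.
#' @param weights optional non-negative per-pair weights.
#' @param config list; `covariates` (default `"sex"`), plus the
#'   [fit_model()] optimizer entries.
#' @return list with `male` and `female` raw [variance_components()],
#'   sex-specific proportional components (`male_std`, `female_std`),
#'   `mean_model`, `loglik`, `converged`, `equated_fit`, and
#'   `lrt_vs_equated` = list(statistic, df, p).
#' @export
fit_sex_limitation <- function(pairs, weights = NULL, config = list()) {
  if (is.null(weights)) weights <- rep(1, nrow(pairs))
  covariates <- config$covariates %||% "sex"
  spec <- model_spec("ACE", "quantitative", covariates)
  arr <- .cohort_arrays(pairs, spec)
  sexes_present <- function(sel) unique(c(arr$sx1[sel], arr$sx2[sel]))
  if (length(sexes_present(rep(TRUE, arr$n))) < 2L)
    stopf("sex-limitation model needs both male and female twins")
  has_os <- any(arr$zyg == "DZos")
  if (!has_os)
    warnf("no opposite-sex DZ pairs: male and female C paths are confounded with A; estimates may be unstable")
  w <- .normalize_weights(weights)

  use_sex <- "sex" %in% covariates
  use_age <- "age" %in% covariates
  nm <- c("a_m", "c_m", "e_m", "a_f", "c_f", "e_f", "mu",
          if (use_sex) "b_sex", if (use_age) "b_age")
  male1 <- arr$sx1 > 0; male2 <- arr$sx2 > 0
  alpha <- arr$alpha
  os <- arr$zyg == "DZos"

  ll_fun <- function(theta) {
    th <- stats::setNames(theta, nm)
    a2_1 <- ifelse(male1, th[["a_m"]]^2, th[["a_f"]]^2)
    c2_1 <- ifelse(male1, th[["c_m"]]^2, th[["c_f"]]^2)
    e2_1 <- ifelse(male1, th[["e_m"]]^2, th[["e_f"]]^2)
    a2_2 <- ifelse(male2, th[["a_m"]]^2, th[["a_f"]]^2)
    c2_2 <- ifelse(male2, th[["c_m"]]^2, th[["c_f"]]^2)
    e2_2 <- ifelse(male2, th[["e_m"]]^2, th[["e_f"]]^2)
    v1 <- a2_1 + c2_1 + e2_1
    v2 <- a2_2 + c2_2 + e2_2
    # same-sex: usual alpha * a2 + c2 with that sex's paths;
    # opposite-sex DZ: cross products of male and female paths
    cv <- ifelse(os,
                 0.5 * th[["a_m"]] * th[["a_f"]] + th[["c_m"]] * th[["c_f"]],
                 alpha * a2_1 + c2_1)
    b_sex <- if (use_sex) th[["b_sex"]] else 0
    b_age <- if (use_age) th[["b_age"]] else 0
    mu1 <- th[["mu"]] + b_sex * arr$sx1 + b_age * arr$age
    mu2 <- th[["mu"]] + b_sex * arr$sx2 + b_age * arr$age
    ll <- .pair_ll_vec(arr, mu1, mu2, v1, v2, cv)
    if (is.null(ll)) return(-1e10)
    sum(w * ll)
  }

  eq_spec <- model_spec("ACE", "equated", covariates)
  eq_fit <- fit_model(pairs, weights, eq_spec,
                      utils::modifyList(config, list(ci_method = "none")))
  start <- stats::setNames(numeric(length(nm)), nm)
  start[c("a_m", "a_f")] <- eq_fit$par[["a"]]
  start[c("c_m", "c_f")] <- max(eq_fit$par[["c"]], 0.05)
  start[c("e_m", "e_f")] <- eq_fit$par[["e"]]
  start[["mu"]] <- eq_fit$par[["mu"]]
  if (use_sex) start[["b_sex"]] <- eq_fit$par[["b_sex"]]
  if (use_age) start[["b_age"]] <- eq_fit$par[["b_age"]]

  opt <- stats::optim(start, function(th) -ll_fun(th), method = "BFGS",
                      control = list(maxit = config$maxit %||% 1000L,
                                     reltol = config$reltol %||% 1e-12))
  th <- stats::setNames(opt$par, nm)
  male <- variance_components(th[["a_m"]]^2, th[["c_m"]]^2, th[["e_m"]]^2)
  female <- variance_components(th[["a_f"]]^2, th[["c_f"]]^2, th[["e_f"]]^2)
  tot_m <- th[["a_m"]]^2 + th[["c_m"]]^2 + th[["e_m"]]^2
  tot_f <- th[["a_f"]]^2 + th[["c_f"]]^2 + th[["e_f"]]^2
  loglik <- -opt$value
  stat <- max(0, 2 * (loglik - eq_fit$loglik))
  df <- 3L
  list(male = male, female = female,
       male_std = variance_components(th[["a_m"]]^2 / tot_m, th[["c_m"]]^2 / tot_m,
                                      th[["e_m"]]^2 / tot_m, "proportional"),
       female_std = variance_components(th[["a_f"]]^2 / tot_f, th[["c_f"]]^2 / tot_f,
                                        th[["e_f"]]^2 / tot_f, "proportional"),
       mean_model = mean_model(th[["mu"]],
                               if (use_sex) th[["b_sex"]] else 0,
                               if (use_age) th[["b_age"]] else 0),
       loglik = loglik, converged = opt$convergence == 0L,
       equated_fit = eq_fit,
       lrt_vs_equated = list(statistic = stat, df = df,
                             p = stats::pchisq(stat, df, lower.tail = FALSE)))
}
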