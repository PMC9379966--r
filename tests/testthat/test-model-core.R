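test_that("expected_covariance matches the biometrical expectations", {
  ace <- model_spec("ACE")
  S <- expected_covariance(variance_components(0.65, 0, 0.35), "MZ", ace)
  expect_equal(S, matrix(c(1, 0.65, 0.65, 1), 2, 2))
  S <- expected_covariance(variance_components(0.65, 0, 0.35), "DZss", ace)
  expect_equal(S[1, 2], 0.325)
  # ADE: DZ dominance coefficient 1/4
  ade <- model_spec("ADE")
  S <- expected_covariance(variance_components(0.5, 0.2, 0.3, role = "D"), "DZos", ade)
  expect_equal(S[1, 2], 0.5 * 0.5 + 0.25 * 0.2)
  expect_equal(S[1, 1], 1.0)
  # property: symmetric PSD, diagonal = total, MZ cov > DZ cov when a2 > 0
  set.seed(4)
  for (i in 1:25) {
    v <- runif(3, 0.05, 1)
    comp <- variance_components(v[1], v[2], v[3])
    Smz <- expected_covariance(comp, "MZ", ace)
    Sdz <- expected_covariance(comp, "DZss", ace)
    expect_equal(Smz[1, 1], sum(v))
    expect_true(all(eigen(Smz, only.values = TRUE)$values >= -1e-12))
    expect_gt(Smz[1, 2], Sdz[1, 2])
  }
  expect_error(expected_covariance(list(a2 = -0.1, c2_or_d2 = 0, e2 = 1), "MZ", ace),
               "non-negative")
  expect_error(expected_covariance(variance_components(1, 0, 1), "XZ", ace),
               "zygosity")
})

test_that("pair_loglik is a bivariate/univariate normal log-density", {
  p0 <- list(pair_id = "p", zygosity = "MZ", sex1 = "M", sex2 = "M",
             age = 10, y1 = 0, y2 = 0)
  # identity covariance: two independent standard normals at 0
  ll <- pair_loglik(p0, variance_components(0, 0, 1))
  expect_equal(ll, -log(2 * pi), tolerance = 1e-12)

  # frozen against the generic dense-matrix normal density (independent oracle)
  p1 <- list(pair_id = "p", zygosity = "MZ", sex1 = "F", sex2 = "F",
             age = 10, y1 = 1.2, y2 = -0.4)
  comp <- variance_components(0.6, 0.1, 0.3)
  ll <- pair_loglik(p1, comp)
  S <- expected_covariance(comp, "MZ")
  expect_equal(ll, mvn_logdens(c(1.2, -0.4), c(0, 0), S), tolerance = 1e-10)

  # FIML: absent co-twin -> univariate marginal
  p2 <- list(pair_id = "p", zygosity = "DZss", sex1 = "M", sex2 = "M",
             age = 10, y1 = 0.5, y2 = NA_real_)
  ll <- pair_loglik(p2, variance_components(0.5, 0.2, 0.3))
  expect_equal(ll, -0.5 * log(2 * pi) - 0.125, tolerance = 1e-10)

  # swapping twins within a same-sex pair changes nothing
  p3 <- list(pair_id = "p", zygosity = "DZss", sex1 = "M", sex2 = "M",
             age = 10, y1 = 0.9, y2 = -1.1)
  p3s <- p3; p3s$y1 <- p3$y2; p3s$y2 <- p3$y1
  mm <- mean_model(0.2, 0.3, 0)
  expect_equal(pair_loglik(p3, comp, mm), pair_loglik(p3s, comp, mm))

  p4 <- list(pair_id = "p", zygosity = "MZ", sex1 = "M", sex2 = "M",
             age = 10, y1 = NA_real_, y2 = NA_real_)
  expect_error(pair_loglik(p4, comp), "both phenotypes missing")
})

test_that("weighted_loglik is the weighted sum of pair log-likelihoods", {
  coh <- make_cohort(n = 20, seed = 3, incomplete_pair_fraction = 0.1)
  comp <- variance_components(0.55, 0.15, 0.3)
  mm <- mean_model(0.1, 0.2, 0.01)
  spec <- model_spec("ACE", covariates = c("sex", "age"))
  per_pair <- vapply(seq_len(nrow(coh)),
                     function(i) pair_loglik(coh[i, ], comp, mm, spec), numeric(1))
  expect_equal(weighted_loglik(coh, rep(1, 20), comp, mm, spec), sum(per_pair),
               tolerance = 1e-12)
  # oracle equivalence on a <= 20-pair cohort, 1e-8
  expect_equal(weighted_loglik(coh, rep(1, 20), comp, mm, spec),
               oracle_loglik(coh, comp, mm, spec), tolerance = 1e-8)
  # linearity and zero-weight exclusion
  expect_equal(weighted_loglik(coh, rep(0.5, 20), comp, mm, spec),
               0.5 * sum(per_pair), tolerance = 1e-12)
  w <- rep(0, 20); w[1] <- 1; w[3] <- 2
  expect_equal(weighted_loglik(coh, w, comp, mm, spec),
               per_pair[1] + 2 * per_pair[3], tolerance = 1e-12)
  expect_error(weighted_loglik(coh, rep(1, 19), comp, mm, spec), "length")
})

test_that("fit_model recovers generating components and is weight-scale invariant", {
  coh <- simulate_cohort(make_homogeneous_field(0.65, 0, 0.35),
                         cohort_config(n_pairs = 5000, seed = 102))
  fit <- fit_model(coh, config = list(ci_method = "none"))
  expect_true(fit$converged)
  est <- raw_components(fit)
  expect_lt(abs(est[["a2"]] - 0.65), 0.03)
  expect_lt(est[["c2"]], 0.05)
  expect_lt(abs(est[["e2"]] - 0.35), 0.03)
  # proportional components sum to 1
  expect_equal(fit$components_std$a2 + fit$components_std$c2_or_d2 +
                 fit$components_std$e2, 1, tolerance = 1e-10)
  # location shift: same variances, shifted intercept
  coh5 <- coh; coh5$y1 <- coh5$y1 + 5; coh5$y2 <- coh5$y2 + 5
  fit5 <- fit_model(coh5, config = list(ci_method = "none"))
  expect_equal(raw_components(fit5), est, tolerance = 1e-5)
  expect_equal(fit5$mean_model$intercept, fit$mean_model$intercept + 5,
               tolerance = 1e-4)
  # uniform-weight reduction: any common weight value gives the same fit
  for (cw in c(0.1, 7)) {
    fitc <- fit_model(coh, rep(cw, nrow(coh)), config = list(ci_method = "none"))
    expect_equal(raw_components(fitc), est, tolerance = 1e-6)
  }
})

test_that("fit_model flags degenerate cohorts and rejects unidentifiable ones", {
  coh <- make_cohort(n = 300, seed = 9, incomplete_pair_fraction = 0)
  dup <- coh; dup$y2 <- dup$y1; dup$sex2 <- dup$sex1; dup$zygosity[dup$zygosity == "DZos"] <- "DZss"
  fit <- fit_model(dup, config = list(ci_method = "none"))
  expect_true(fit$boundary_e2)
  expect_lt(fit$components$e2, 1e-3)
  mz_only <- coh[coh$zygosity == "MZ", ]
  expect_error(fit_model(mz_only), "identifiable")
  # all-DZ via zero MZ weights is equally unidentifiable
  w <- ifelse(coh$zygosity == "MZ", 0, 1)
  expect_error(fit_model(coh, w), "identifiable")
})

test_that("confidence intervals are weight-scale invariant and truncate at 0", {
  coh <- simulate_cohort(make_homogeneous_field(0.65, 0, 0.35),
                         cohort_config(n_pairs = 2000, seed = 77))
  f1 <- fit_model(coh)
  f2 <- fit_model(coh, rep(2, nrow(coh)))  # doubling weights must not shrink CIs
  expect_equal(f1$ci, f2$ci, tolerance = 1e-6)
  expect_true(f1$ci$a2[1] <= f1$components$a2 && f1$components$a2 <= f1$ci$a2[2])
  # c2 sits at the 0 boundary here: lower bound exactly 0
  expect_identical(f1$ci$c2_or_d2[1], 0)
  expect_lte(f1$ess_mz, sum(coh$zygosity == "MZ"))
  expect_lte(f1$ess_dz, sum(coh$zygosity != "MZ"))
})

test_that("profile-likelihood CIs are available as a config option", {
  coh <- make_cohort(n = 800, seed = 15, a2 = 0.5, c2 = 0.2, e2 = 0.3)
  fit <- fit_model(coh, config = list(ci_method = "profile"))
  ci <- fit$ci
  expect_true(all(is.finite(unlist(ci))))
  expect_true(ci$a2[1] <= fit$components$a2 && fit$components$a2 <= ci$a2[2])
  expect_true(ci$e2[1] <= fit$components$e2 && fit$components$e2 <= ci$e2[2])
  expect_gte(ci$c2_or_d2[1], 0)
})

test_that("ADE is offered as an alternative and never alongside C", {
  expect_error(model_spec("ADE", "quantitative"), "ADE")
  coh <- make_cohort(n = 2000, seed = 23, a2 = 0.6, c2 = 0, e2 = 0.4)
  fit <- fit_model(coh, spec = model_spec("ADE"), config = list(ci_method = "none"))
  expect_true(fit$converged)
  expect_identical(fit$components$role, "D")
  expect_equal(fit$components_std$a2 + fit$components_std$c2_or_d2 +
                 fit$components_std$e2, 1, tolerance = 1e-10)
  # with no true C or D, the broad genetic estimate stays near truth
  expect_lt(abs(fit$components$a2 + fit$components$c2_or_d2 - 0.6), 0.08)
})

test_that("variance_explained_by_covariates recovers the calibrated sex share", {
  coh <- make_cohort(n = 50, seed = 2)
  expect_equal(variance_explained_by_covariates(coh, mean_model(0, 0, 0))[["sex"]], 0)
  big <- simulate_cohort(make_homogeneous_field(0.65, 0, 0.35),
                         cohort_config(n_pairs = 10000, seed = 19,
                                       sex_variance_share = 0.026))
  fit <- fit_model(big, config = list(ci_method = "none"))
  share <- variance_explained_by_covariates(big, fit$mean_model)[["sex"]]
  expect_lt(abs(share - 0.026), 0.005)
  # covariate constant across twins -> 0 share
  allm <- big; allm$sex1 <- "M"; allm$sex2 <- "M"
  expect_equal(variance_explained_by_covariates(allm, fit$mean_model)[["sex"]], 0)
  const <- big; const$y1 <- 1; const$y2 <- 1
  expect_error(variance_explained_by_covariates(const, fit$mean_model), "variance")
})

test_that("interior-truth fits are unbiased on average (small replicate set)", {
  est <- t(vapply(1:12, function(s) {
    coh <- simulate_cohort(make_homogeneous_field(0.5, 0.2, 0.3),
                           cohort_config(n_pairs = 3000, seed = 400 + s))
    raw_components(fit_model(coh, config = list(ci_method = "none")))
  }, numeric(3)))
  bias <- colMeans(est) - c(0.5, 0.2, 0.3)
  expect_true(all(abs(bias) < 0.03))
})

test_that("sex-limitation model nests the equated model and needs DZos pairs", {
  coh <- make_cohort(n = 1200, seed = 31, a2 = 0.5, c2 = 0.2, e2 = 0.3)
  sl <- fit_sex_limitation(coh)
  expect_gte(sl$loglik, sl$equated_fit$loglik - 1e-6)
  expect_gte(sl$lrt_vs_equated$statistic, 0)
  expect_identical(sl$lrt_vs_equated$df, 3L)
  ss <- coh[coh$zygosity != "DZos", ]
  expect_warning(fit_sex_limitation(ss), "opposite-sex")
})
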