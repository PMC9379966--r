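test_that("standardize_phenotype centres and scales by the population SD", {
  coh <- data.frame(pair_id = c("a", "b", "c"), zygosity = "MZ",
                    sex1 = "M", sex2 = "M", age = 10,
                    y1 = c(1, 2, 3), y2 = NA_real_, x = 0, y = 0)
  std <- standardize_phenotype(coh)
  expect_equal(std$y1, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_true(all(is.na(std$y2)))
  # idempotence
  big <- make_cohort(n = 2000, seed = 6)
  s1 <- standardize_phenotype(big)
  s2 <- standardize_phenotype(s1)
  expect_equal(s2$y1, s1$y1, tolerance = 1e-10)
  yy <- c(s1$y1, s1$y2)
  expect_equal(mean(yy[is.finite(yy)]), 0, tolerance = 1e-10)
  expect_equal(mean(yy[is.finite(yy)]^2), 1, tolerance = 1e-10)
  const <- coh; const$y1 <- 1; const$y2 <- 1
  expect_error(standardize_phenotype(const), "distinct")
})

test_that("region centroid targets cover exactly the populated regions", {
  coh <- make_cohort(n = 10, seed = 2)
  coh$region_id <- rep(c("R1", "R2", "R3"), c(4, 3, 3))
  cent <- data.frame(region_id = c("R1", "R2", "R3", "R4"),
                     x = 1:4, y = 1:4)
  tg <- region_centroid_targets(coh, cent)
  expect_equal(nrow(tg), 3L)
  expect_setequal(tg$target_id, c("R1", "R2", "R3"))
  coh$region_id[1] <- "R9"
  expect_error(region_centroid_targets(coh, cent), "R9")
  one <- coh[2:5, ]; one$region_id <- "R2"
  expect_equal(nrow(region_centroid_targets(one, cent)), 1L)
})

test_that("a nationally sized region fixture yields one target per populated region", {
  n_regions <- 4199
  pairs <- data.frame(pair_id = as.character(seq_len(n_regions)),
                      region_id = sprintf("S%04d", seq_len(n_regions)))
  cent <- data.frame(region_id = sprintf("S%04d", seq_len(n_regions + 100)),
                     x = runif(n_regions + 100), y = runif(n_regions + 100))
  tg <- region_centroid_targets(pairs, cent)
  expect_equal(nrow(tg), 4199L)
})

test_that("density-representative targets land on the sampling clusters", {
  cfg <- cohort_config(n_pairs = 200, seed = 33,
                       settlement_centers = data.frame(
                         x = c(0.2, 0.8), y = c(0.2, 0.8),
                         mass = c(1, 1), spread = c(0.03, 0.03)))
  coh <- simulate_cohort(make_homogeneous_field(), cfg)
  tg <- density_representative_targets(coh, k = 2, seed = 5)
  tg <- tg[order(tg$x), ]
  # oracle: the generated cluster centres, tolerance = cluster SD
  expect_lt(abs(tg$x[1] - 0.2), 0.03); expect_lt(abs(tg$y[1] - 0.2), 0.03)
  expect_lt(abs(tg$x[2] - 0.8), 0.03); expect_lt(abs(tg$y[2] - 0.8), 0.03)
  # determinism and k = n fixed point
  expect_identical(density_representative_targets(coh, k = 2, seed = 5),
                   density_representative_targets(coh, k = 2, seed = 5))
  small <- coh[1:15, ]
  tg_n <- density_representative_targets(small, k = 15, seed = 1)
  expect_setequal(round(tg_n$x, 9), round(small$x, 9))
  expect_error(density_representative_targets(coh, k = 0), "positive")
  expect_error(density_representative_targets(coh, k = 1e6), "exceeds")
})

test_that("weighted_mean_map averages pair means with distance weights", {
  coh <- make_cohort(n = 100, seed = 4, incomplete_pair_fraction = 0)
  tg <- data.frame(target_id = c("A", "B"), x = c(0.1, 0.9), y = c(0.1, 0.9))
  cons <- coh; cons$y1 <- 2.5; cons$y2 <- 2.5
  wm <- weighted_mean_map(cons, tg)
  expect_equal(wm$weighted_mean_trait, c(2.5, 2.5))
  std <- standardize_phenotype(coh)
  wm0 <- weighted_mean_map(std, tg, p = 0)
  expect_equal(wm0$weighted_mean_trait, rep(0, 2), tolerance = 1e-10)
  rng <- range(rowMeans(cbind(std$y1, std$y2), na.rm = TRUE))
  wmp <- weighted_mean_map(std, tg, p = 2)
  expect_true(all(wmp$weighted_mean_trait >= rng[1] &
                  wmp$weighted_mean_trait <= rng[2]))
})

test_that("a north-south mean gradient appears in the weighted mean map", {
  f <- aetiology_field(function(x, y) rep(0.6, length(x)),
                       function(x, y) rep(0, length(x)),
                       function(x, y) rep(0.4, length(x)),
                       mean_fn = function(x, y) 3 * y)
  coh <- simulate_cohort(f, cohort_config(n_pairs = 6000, seed = 8,
                                          sex_variance_share = 0))
  tg <- density_representative_targets(coh, k = 30, seed = 8)
  wm <- weighted_mean_map(coh, tg, p = 0.5)
  expect_gte(cor(tg$y, wm$weighted_mean_trait, method = "spearman"), 0.9)
})

test_that("run_space output is order-invariant with coherent per-row identities", {
  coh <- make_cohort(n = 600, seed = 14)
  coh <- standardize_phenotype(coh)
  tg <- density_representative_targets(coh, k = 6, seed = 14)
  res <- run_space(coh, tg, config = list(ci_method = "none"))
  expect_equal(nrow(res), 6L)
  expect_true(all(res$converged))
  expect_equal(res$a2_std + res$c2_or_d2_std + res$e2_std, rep(1, 6),
               tolerance = 1e-10)
  expect_equal(res$total_variance, res$a2_raw + res$c2_or_d2_raw + res$e2_raw,
               tolerance = 1e-12)
  # permuting targets only reorders rows
  perm_t <- c(4, 2, 6, 1, 3, 5)
  res_t <- run_space(coh, tg[perm_t, ], config = list(ci_method = "none"))
  expect_equal(res_t$a2_raw, res$a2_raw[perm_t], tolerance = 1e-12)
  # permuting pairs changes nothing numerically
  set.seed(1); perm_p <- sample.int(nrow(coh))
  res_p <- run_space(coh[perm_p, ], tg, config = list(ci_method = "none"))
  expect_equal(res_p$a2_raw, res$a2_raw, tolerance = 1e-8)
  expect_equal(res_p$weighted_mean_trait, res$weighted_mean_trait, tolerance = 1e-10)
})

test_that("location sensitivity distinguishes stable from scrambled histories", {
  field <- make_step_field(0.5)
  coh <- simulate_cohort(field, cohort_config(n_pairs = 3000, seed = 25))
  coh <- standardize_phenotype(coh)
  tg <- density_representative_targets(coh, k = 25, seed = 25)
  # identical snapshot -> identical maps; scrambled -> decorrelated
  coh$x_birth <- coh$x; coh$y_birth <- coh$y
  set.seed(2); perm <- sample.int(nrow(coh))
  coh$x_scr <- coh$x[perm]; coh$y_scr <- coh$y[perm]
  # jitter far smaller than the inter-target spacing
  set.seed(3)
  coh$x_jit <- coh$x + rnorm(nrow(coh), 0, 0.005)
  coh$y_jit <- coh$y + rnorm(nrow(coh), 0, 0.005)
  sens <- location_sensitivity(coh, tg, config = list(ci_method = "none"))
  expect_setequal(names(sens$results), c("current", "birth", "scr", "jit"))
  expect_equal(sens$results$birth$a2_raw, sens$results$current$a2_raw,
               tolerance = 1e-12)
  expect_equal(sens$a2_correlation["current", "birth"], 1, tolerance = 1e-8)
  expect_gte(sens$a2_correlation["current", "jit"], 0.95)
  expect_lt(abs(sens$a2_correlation["current", "scr"]), 0.5)
  # ragged snapshots are rejected
  bad <- coh; bad$x_birth[5] <- NA
  expect_error(location_sensitivity(bad, tg), "birth")
})
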