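#' Spatial aetiology field
#'
#' A stated "ground truth" for simulation: functions mapping planar
#' coordinates to the local additive-genetic, shared-environmental and
#' non-shared-environmental variances and to the local trait mean. Used by
#' [simulate_cohort()] so that every pipeline stage can be tested against a
#' known gene-by-geography interaction without restricted registry data.
#'
#' @param a2_fn,c2_fn,e2_fn vectorized functions `(x, y) -> variance >= 0`.
#' @param mean_fn vectorized function `(x, y) -> trait mean` (default 0).
#' @param description short label.
#' @return an object of class `aetiology_field`.
#' @export
aetiology_field <- function(a2_fn, c2_fn, e2_fn,
                            mean_fn = function(x, y) rep(0, length(x)),
                            description = "") {
  stopifnot(is.function(a2_fn), is.function(c2_fn), is.function(e2_fn),
            is.function(mean_fn))
  structure(list(a2_fn = a2_fn, c2_fn = c2_fn, e2_fn = e2_fn,
                 mean_fn = mean_fn, description = description),
            class = "aetiology_field")
}

#' @export
print.aetiology_field <- function(x, ...) {
  cat("<aetiology_field>", x$description, "\n")
  invisible(x)
}

#' Evaluate an aetiology field at coordinates
#'
#' @param field an [aetiology_field()].
#' @param x,y coordinate vectors.
#' @return data frame with columns `a2`, `c2`, `e2`, `mean`.
#' @export
field_eval <- function(field, x, y) {
  out <- data.frame(a2 = as.numeric(field$a2_fn(x, y)),
                    c2 = as.numeric(field$c2_fn(x, y)),
                    e2 = as.numeric(field$e2_fn(x, y)),
                    mean = as.numeric(field$mean_fn(x, y)))
  if (any(!is.finite(as.matrix(out))))
    stopf("field evaluates to non-finite values")
  if (any(out$a2 < 0) || any(out$c2 < 0) || any(out$e2 < 0))
    stopf("field variance components must be non-negative everywhere sampled")
  if (any(out$a2 + out$c2 + out$e2 <= 0))
    stopf("field total variance must be positive everywhere sampled")
  out
}

#' Spatially constant aetiology field
#'
#' @param a2,c2,e2 variances; defaults give the classic high-heritability,
#'   no-shared-environment regime for autistic-like traits
#'   (a2 = 0.65, c2 = 0, e2 = 0.35 on the standardized scale).
#' @param mean constant trait mean.
#' @return an [aetiology_field()].
#' @export
make_homogeneous_field <- function(a2 = 0.65, c2 = 0, e2 = 0.35, mean = 0) {
  k <- function(v) function(x, y) rep(v, length(x))
  aetiology_field(k(a2), k(c2), k(e2), k(mean),
                  sprintf("homogeneous a2=%.2f c2=%.2f e2=%.2f", a2, c2, e2))
}

#' Two-level (west/east) step aetiology field
#'
#' Components equal `low` strictly west of `boundary_x` and `high` at or
#' east of it (closed-right convention: a point exactly on the boundary
#' belongs to the high side).
#'
#' @param boundary_x x coordinate of the step.
#' @param low,high named numeric vectors with entries `a2`, `c2`, `e2` and
#'   optionally `mean`.
#' @return an [aetiology_field()].
#' @export
#' @examples
#' f <- make_step_field(0, c(a2 = 0.5, c2 = 0, e2 = 0.5),
#'                         c(a2 = 0.8, c2 = 0, e2 = 0.2))
#' field_eval(f, c(-1, 1), c(0, 0))$a2
make_step_field <- function(boundary_x,
                            low = c(a2 = 0.55, c2 = 0, e2 = 0.45),
                            high = c(a2 = 0.91, c2 = 0, e2 = 0.35)) {
  pick <- function(comp) {
    lo <- if (comp %in% names(low)) unname(low[[comp]]) else 0
    hi <- if (comp %in% names(high)) unname(high[[comp]]) else 0
    function(x, y) ifelse(x >= boundary_x, hi, lo)
  }
  aetiology_field(pick("a2"), pick("c2"), pick("e2"), pick("mean"),
                  sprintf("step at x=%.3g", boundary_x))
}

#' Linear-gradient aetiology field
#'
#' Each component interpolates linearly from `start` to `end` along one
#' axis of a domain normalized to `[0, 1]`; coordinates outside `[0, 1]`
#' are clamped. Constant off-axis.
#'
#' @param start,end named numeric vectors (`a2`, `c2`, `e2`, optional `mean`).
#' @param axis `"x"` or `"y"`.
#' @return an [aetiology_field()].
#' @export
make_gradient_field <- function(start = c(a2 = 0.55, c2 = 0, e2 = 0.45),
                                end = c(a2 = 0.91, c2 = 0, e2 = 0.35),
                                axis = "y") {
  axis <- match.arg(axis, c("x", "y"))
  pick <- function(comp) {
    s <- if (comp %in% names(start)) unname(start[[comp]]) else 0
    e <- if (comp %in% names(end)) unname(end[[comp]]) else 0
    function(x, y) {
      t <- clamp(if (axis == "x") x else y, 0, 1)
      s + t * (e - s)
    }
  }
  aetiology_field(pick("a2"), pick("c2"), pick("e2"), pick("mean"),
                  sprintf("gradient along %s", axis))
}

#' Configuration of a synthetic spatial twin cohort
#'
#' Defaults emulate a Nordic-registry-scale childhood cohort on a unit
#' square: ~8300 twin pairs, half MZ, the DZ half split evenly between
#' same-sex and opposite-sex pairs, ~0.8% incomplete pairs (one twin's
#' phenotype missing), a sex covariate carrying 2.6% of trait variance,
#' no age effect (set `age_variance_share = 0.003` for a UK-like cohort),
#' ages uniform on 9-12 years, and settlement clusters of unequal mass so
#' that sampling density varies over the map.
#'
#' @param n_pairs number of twin pairs (>= 4).
#' @param mz_fraction proportion of pairs that are MZ.
#' @param opposite_sex_dz_fraction proportion of DZ pairs that are
#'   opposite-sex.
#' @param incomplete_pair_fraction proportion of pairs with one phenotype
#'   blanked.
#' @param sex_variance_share,age_variance_share proportions of total trait
#'   variance carried by the sex / age mean effects.
#' @param domain bounding rectangle `c(xmin, ymin, xmax, ymax)`.
#' @param settlement_centers data frame with columns `x`, `y`, `mass`,
#'   `spread` describing population clusters.
#' @param region_grid number of region cells per axis used to assign
#'   `region_id` (SAMS-like small areas).
#' @param sex_components optional quantitative sex limitation in the
#'   generating model: `list(male = c(a2 =, c2 =, e2 =), female = c(...))`.
#'   When set, these (spatially constant) sex-specific variances replace
#'   the field's components — each twin's deviations are scaled by their
#'   own sex's paths, so opposite-sex DZ pairs have cross-covariance
#'   `0.5*a_m*a_f + c_m*c_f` — while the field still supplies the mean
#'   surface.
#' @param seed integer seed; every generator output is a pure function of
#'   (config, field, seed).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 8300, mz_fraction = 0.5,
                          opposite_sex_dz_fraction = 0.5,
                          incomplete_pair_fraction = 0.008,
                          sex_variance_share = 0.026,
                          age_variance_share = 0,
                          domain = c(0, 0, 1, 1),
                          settlement_centers = NULL,
                          region_grid = 10L,
                          sex_components = NULL,
                          seed = 1L) {
  if (n_pairs < 4) stopf("n_pairs must be >= 4")
  fr <- c(mz_fraction, opposite_sex_dz_fraction, incomplete_pair_fraction,
          sex_variance_share, age_variance_share)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stopf("fractions/shares must lie in [0, 1]")
  if (sex_variance_share + age_variance_share >= 1)
    stopf("covariate variance shares must sum to < 1")
  if (length(domain) != 4L || domain[3] <= domain[1] || domain[4] <= domain[2])
    stopf("domain must be c(xmin, ymin, xmax, ymax) with positive extent")
  if (is.null(settlement_centers)) {
    w <- domain[3] - domain[1]; h <- domain[4] - domain[2]
    settlement_centers <- data.frame(
      x = domain[1] + w * c(0.30, 0.70, 0.50),
      y = domain[2] + h * c(0.30, 0.70, 0.88),
      mass = c(5, 3, 2),
      spread = c(0.08, 0.06, 0.10) * min(w, h))
  }
  .assert_cols(settlement_centers, c("x", "y", "mass", "spread"),
               "settlement_centers")
  if (nrow(settlement_centers) == 0L) stopf("at least one settlement center required")
  if (any(settlement_centers$mass <= 0)) stopf("settlement masses must be positive")
  if (!is.null(sex_components)) {
    for (sx in c("male", "female")) {
      v <- sex_components[[sx]]
      if (is.null(v) || !all(c("a2", "c2", "e2") %in% names(v)) ||
          any(!is.finite(v)) || any(v < 0))
        stopf("sex_components$%s must be a named non-negative vector c(a2=, c2=, e2=)", sx)
    }
  }
  structure(list(n_pairs = as.integer(n_pairs), mz_fraction = mz_fraction,
                 opposite_sex_dz_fraction = opposite_sex_dz_fraction,
                 incomplete_pair_fraction = incomplete_pair_fraction,
                 sex_variance_share = sex_variance_share,
                 age_variance_share = age_variance_share,
                 domain = as.numeric(domain),
                 settlement_centers = settlement_centers,
                 region_grid = as.integer(region_grid),
                 sex_components = sex_components,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.sample_locations_impl <- function(config) {
  n <- config$n_pairs
  ctr <- config$settlement_centers
  idx <- sample.int(nrow(ctr), n, replace = TRUE, prob = ctr$mass)
  x <- ctr$x[idx] + stats::rnorm(n, 0, ctr$spread[idx])
  y <- ctr$y[idx] + stats::rnorm(n, 0, ctr$spread[idx])
  dom <- config$domain
  out <- !(x >= dom[1] & x <= dom[3] & y >= dom[2] & y <= dom[4])
  tries <- 0L
  while (any(out) && tries < 1000L) {
    m <- sum(out)
    x[out] <- ctr$x[idx[out]] + stats::rnorm(m, 0, ctr$spread[idx[out]])
    y[out] <- ctr$y[idx[out]] + stats::rnorm(m, 0, ctr$spread[idx[out]])
    out <- !(x >= dom[1] & x <= dom[3] & y >= dom[2] & y <= dom[4])
    tries <- tries + 1L
  }
  if (any(out)) {  # pathological spread: clamp the stragglers
    x[out] <- clamp(x[out], dom[1], dom[3])
    y[out] <- clamp(y[out], dom[2], dom[4])
  }
  cbind(x = x, y = y)
}

#' Sample pair locations from the settlement mixture
#'
#' Cluster membership is drawn with probability proportional to settlement
#' mass; coordinates are Gaussian around the chosen center with its spread,
#' rejection-resampled into the domain rectangle. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return n_pairs x 2 matrix of coordinates.
#' @export
sample_locations <- function(config) {
  with_seed(config$seed, .sample_locations_impl(config))
}

#' Simulate a geographically embedded twin cohort
#'
#' At each pair's sampled location the phenotypes are drawn from a
#' bivariate normal whose covariance is the model-implied twin covariance
#' for the local field components (A correlating 1 in MZ and 0.5 in DZ
#' pairs, C correlating 1, E uncorrelated), plus the local field mean and
#' sex/age mean effects scaled so that their marginal variance shares match
#' the config. A configured fraction of pairs has one phenotype blanked.
#'
#' @param field an [aetiology_field()].
#' @param config a [cohort_config()].
#' @return a twin cohort data frame (class `twin_cohort`) in the package's
#'   CSV dialect, with planar coordinates on attribute `crs = "planar"`.
#' @export
#' @examples
#' coh <- simulate_cohort(make_homogeneous_field(),
#'                        cohort_config(n_pairs = 100, seed = 1))
#' table(coh$zygosity)
simulate_cohort <- function(field, config) {
  stopifnot(inherits(field, "aetiology_field"), inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_pairs
    xy <- .sample_locations_impl(config)
    fv <- field_eval(field, xy[, 1], xy[, 2])

    zyg <- ifelse(stats::runif(n) < config$mz_fraction, "MZ", "DZ")
    zyg[zyg == "DZ"] <- ifelse(
      stats::runif(sum(zyg == "DZ")) < config$opposite_sex_dz_fraction,
      "DZos", "DZss")

    sex1 <- ifelse(stats::runif(n) < 0.5, "M", "F")
    sex2 <- sex1
    os <- zyg == "DZos"
    sex2[os] <- ifelse(sex1[os] == "M", "F", "M")

    age <- stats::runif(n, 9, 12)

    # per-twin path scaling: field components, or sex-specific overrides
    if (is.null(config$sex_components)) {
      sa1 <- sa2 <- sqrt(fv$a2)
      sc1 <- sc2 <- sqrt(fv$c2)
      se1 <- se2 <- sqrt(fv$e2)
    } else {
      sx <- config$sex_components
      pick <- function(sex, comp)
        ifelse(sex == "M", sqrt(sx$male[[comp]]), sqrt(sx$female[[comp]]))
      sa1 <- pick(sex1, "a2"); sa2 <- pick(sex2, "a2")
      sc1 <- pick(sex1, "c2"); sc2 <- pick(sex2, "c2")
      se1 <- pick(sex1, "e2"); se2 <- pick(sex2, "e2")
    }

    # standardized deviates with the biometrical twin correlations
    gs <- stats::rnorm(n); g1 <- stats::rnorm(n); g2 <- stats::rnorm(n)
    mz <- zyg == "MZ"
    G1 <- ifelse(mz, gs, sqrt(0.5) * gs + sqrt(0.5) * g1)
    G2 <- ifelse(mz, gs, sqrt(0.5) * gs + sqrt(0.5) * g2)
    Csh <- stats::rnorm(n)
    A1 <- sa1 * G1; A2 <- sa2 * G2
    C1 <- sc1 * Csh; C2 <- sc2 * Csh
    E1 <- se1 * stats::rnorm(n)
    E2 <- se2 * stats::rnorm(n)

    # scale covariate effects so their share of total variance matches config
    vbar <- mean(c(sa1^2 + sc1^2 + se1^2, sa2^2 + sc2^2 + se2^2))
    s_sex <- config$sex_variance_share; s_age <- config$age_variance_share
    resid_share <- 1 - s_sex - s_age
    b_sex <- if (s_sex > 0) sqrt(s_sex * vbar / resid_share) / 0.5 else 0
    b_age <- if (s_age > 0) sqrt(s_age * vbar / resid_share / 0.75) else 0
    sx1 <- .sex_code(sex1); sx2 <- .sex_code(sex2)

    y1 <- fv$mean + b_sex * sx1 + b_age * (age - 10.5) + A1 + C1 + E1
    y2 <- fv$mean + b_sex * sx2 + b_age * (age - 10.5) + A2 + C2 + E2

    n_inc <- round(config$incomplete_pair_fraction * n)
    if (n_inc > 0) {
      miss <- sample.int(n, n_inc)
      drop_first <- stats::runif(n_inc) < 0.5
      y1[miss[drop_first]] <- NA_real_
      y2[miss[!drop_first]] <- NA_real_
    }

    dom <- config$domain; g <- config$region_grid
    cx <- pmin(1L + floor((xy[, 1] - dom[1]) / (dom[3] - dom[1]) * g), g)
    cy <- pmin(1L + floor((xy[, 2] - dom[2]) / (dom[4] - dom[2]) * g), g)

    coh <- data.frame(
      pair_id = sprintf("P%06d", seq_len(n)),
      zygosity = zyg, sex1 = sex1, sex2 = sex2,
      age = age, y1 = y1, y2 = y2,
      x = xy[, 1], y = xy[, 2],
      region_id = sprintf("R%02d_%02d", cx, cy),
      stringsAsFactors = FALSE)
    attr(coh, "crs") <- "planar"
    class(coh) <- c("twin_cohort", "data.frame")
    coh
  })
}

#' Monotone right-skew transform of simulated phenotypes
#'
#' Registry trait scores (symptom counts) are heavily right-skewed; this
#' exponential warp `(exp(k*y) - 1)/k` turns the simulated Gaussian scores
#' into right-skewed ones while preserving rank order. `skew_strength = 0`
#' is the identity. Note the FIML twin model assumes normality, so fits on
#' skewed scores are a robustness exercise, not the stated world.
#'
#' @param pairs twin cohort data frame.
#' @param skew_strength `k >= 0`.
#' @return the cohort with transformed `y1`, `y2`.
#' @export
skew_transform <- function(pairs, skew_strength) {
  if (!is.finite(skew_strength) || skew_strength < 0)
    stopf("skew_strength must be >= 0")
  if (skew_strength == 0) return(pairs)
  k <- skew_strength
  warp <- function(v) (exp(k * v) - 1) / k
  pairs$y1 <- warp(pairs$y1)
  pairs$y2 <- warp(pairs$y2)
  pairs
}
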