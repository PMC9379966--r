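# fixtures are built in code; nothing is read from disk

make_cohort <- function(n = 400, seed = 1, a2 = 0.6, c2 = 0.1, e2 = 0.3, ...) {
  simulate_cohort(make_homogeneous_field(a2, c2, e2),
                  cohort_config(n_pairs = n, seed = seed, ...))
}

# independent generic multivariate-normal log-density (dense quadratic form)
mvn_logdens <- function(y, mu, S) {
  k <- length(y)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  q <- as.numeric(t(y - mu) %*% solve(S) %*% (y - mu))
  -0.5 * (k * log(2 * pi) + ld + q)
}

# brute-force FIML log-likelihood: builds each pair's expected covariance
# via expected_covariance() and evaluates generic normal densities
oracle_loglik <- function(pairs, comp, mm, spec = model_spec()) {
  total <- 0
  for (i in seq_len(nrow(pairs))) {
    S <- expected_covariance(comp, pairs$zygosity[i], spec)
    sx <- c(ifelse(pairs$sex1[i] == "M", 0.5, -0.5),
            ifelse(pairs$sex2[i] == "M", 0.5, -0.5))
    age <- if ("age" %in% names(pairs)) pairs$age[i] else 0
    mu <- mm$intercept + mm$beta_sex * sx + mm$beta_age * age
    y <- c(pairs$y1[i], pairs$y2[i])
    obs <- is.finite(y)
    total <- total + if (all(obs)) mvn_logdens(y, mu, S)
      else stats::dnorm(y[obs], mu[obs], sqrt(S[1, 1]), log = TRUE)
  }
  total
}

raw_components <- function(fit) {
  c(a2 = fit$components$a2, c2 = fit$components$c2_or_d2, e2 = fit$components$e2)
}
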