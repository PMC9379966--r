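# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run expr with a private RNG state: seed the generator, restore whatever
# state the caller had. Keeps every generator a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number, got %s", deparse(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# zygosity vocabulary: CSV dialect {MZ, DZss, DZos}; long forms accepted
.normalize_zygosity <- function(z) {
  z <- as.character(z)
  map <- c(MZ = "MZ", DZss = "DZss", DZos = "DZos",
           DZ_same_sex = "DZss", DZ_opposite_sex = "DZos", DZ = "DZss")
  out <- map[z]
  if (anyNA(out)) {
    bad <- unique(z[is.na(out)])
    stopf("unknown zygosity value(s): %s (expected MZ, DZss or DZos)",
          paste(bad, collapse = ", "))
  }
  unname(out)
}

.is_dz <- function(z) z %in% c("DZss", "DZos")

# effect coding keeps the intercept at the (balanced) grand mean
.sex_code <- function(s) {
  s <- as.character(s)
  out <- ifelse(s == "M", 0.5, ifelse(s == "F", -0.5, NA_real_))
  if (anyNA(out)) stopf("sex values must be 'M' or 'F', got: %s",
                        paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

.assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what, paste(miss, collapse = ", "))
}
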