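#' @keywords internal
"_PACKAGE"

# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Batch keys are "<level1>:<level2>" strings, e.g. "site03:F" or "w2:M".
make_batch_key <- function(df, batch_vars) {
  for (v in batch_vars) {
    if (!v %in% names(df)) stop_field(v, "column required to form batch keys")
  }
  do.call(paste, c(unname(df[batch_vars]), sep = ":"))
}

roi_cols <- function(cohort) {
  grep("^roi_", names(cohort), value = TRUE)
}

roi_names_of <- function(cohort) {
  sub("^roi_", "", roi_cols(cohort))
}

# Draw from a triangular density on [lo, hi] with the given mode, by
# inverse-CDF; used for the peaked wave-2 age distribution.
rtriangular <- function(n, lo, hi, mode) {
  stopifnot(lo < hi, mode >= lo, mode <= hi)
  u <- stats::runif(n)
  f <- (mode - lo) / (hi - lo)
  ifelse(u < f,
    lo + sqrt(u * (hi - lo) * (mode - lo)),
    hi - sqrt((1 - u) * (hi - lo) * (hi - mode))
  )
}

# Population (1/n) variance; the evaluation metrics use population moments.
pop_var <- function(x) mean((x - mean(x))^2)

# Derive a substream seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}
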