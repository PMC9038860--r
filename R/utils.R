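# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (printed clinical convention: 0.625 -> 0.63)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_spacing <- function(spacing_mm) {
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stopf("`spacing_mm` must be three positive finite numbers")
  }
  as.numeric(spacing_mm)
}

check_grid3d <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3) {
    stopf("`%s` must be a 3-D array, got %s", what,
          paste(dim(x) %||% length(x), collapse = "x"))
  }
  invisible(x)
}

# deterministic per-patient seed derivation from a single top-level seed;
# kept below .Machine$integer.max
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 100003 + index * 7919) %% 2147483629)
}
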