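#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: fold integers into [1, 2147483562].
# Products stay below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(master, ...) {
  keys <- c(master, ...)
  s <- 12345
  for (k in keys) s <- (s * 69069 + as.numeric(k)) %% 2147483562
  as.integer(s + 1)
}

# Full ("open") convolution truncated to the length of x.
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(x, rev(kernel), type = "open")
  y[seq_len(n)]
}

# Residuals from a least-squares linear trend fit (with intercept).
detrend_linear <- function(y) {
  n <- length(y)
  x <- cbind(1, seq_len(n))
  stats::.lm.fit(x, y)$residuals
}

# atanh with clipping at |r| = 1 - eps; returns list(z, n_clipped).
fisher_z <- function(r, eps = 1e-6) {
  clipped <- abs(r) >= 1 - eps
  r2 <- pmin(pmax(r, -1 + eps), 1 - eps)
  list(z = atanh(r2), n_clipped = sum(clipped, na.rm = TRUE))
}

# One-sample t that tolerates zero-variance input (all values identical):
# mean 0, sd 0 is reported as t = 0, p = 1 rather than NaN.
safe_t_one <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(list(t = NA_real_, p = NA_real_, mean = mean(x), n = n))
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, mean = 0, n = n))
    return(list(t = sign(m) * Inf, p = 0, mean = m, n = n))
  }
  tt <- stats::t.test(x)
  list(t = unname(tt$statistic), p = tt$p.value, mean = m, n = n)
}

# md5 of an arbitrary R object via canonical JSON serialization.
object_md5 <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
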