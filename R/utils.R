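# Shared internal helpers: argument checks, exact rational score thresholds,
# seeded RNG scoping, and atomic file writes.

stop_param <- function(msg, ...) abort(msg, class = "embryogem_parameter_error", ...)
stop_consistency <- function(msg, ...) abort(msg, class = "embryogem_consistency_error", ...)
stop_format <- function(msg, ...) abort(msg, class = "embryogem_format_error", ...)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_param(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

assert_binary_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask)) {
    stop_param(sprintf("`%s` must be a logical matrix with no missing values", name))
  }
  invisible(mask)
}

assert_grey_matrix <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L) {
    stop_param(sprintf("`%s` must be a non-empty numeric matrix", name))
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop_param(sprintf("`%s` must hold greyscale intensities in [0, 255]", name))
  }
  invisible(img)
}

# Best rational approximation p/q of x (continued fractions, q <= max_denom).
# Used so that score >= threshold is decided on integers: n * q >= p * t is
# exact for all n, t, p, q well below 2^53, avoiding float boundary errors at
# printed thresholds such as 0.1 or 0.25.
as_rational <- function(x, max_denom = 1e6) {
  assert_scalar_number(x, "threshold", 0, 1)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_denom) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < .Machine$double.eps) break
    rem <- r - a
    if (rem < .Machine$double.eps) break
    r <- 1 / rem
  }
  c(num = p1, den = q1)
}

# n/t >= threshold, decided exactly on integer cross-products.
score_passes <- function(n, t, threshold) {
  pq <- as_rational(threshold)
  n * pq[["den"]] >= pq[["num"]] * t
}

# round-half-up (no banker's rounding), as documented for subsample sizes
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Write text/binary via a temp file in the same directory, then rename, so a
# failure never leaves a partial output behind.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".tmp.", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, tmp_target <- path)) {
    stop_format(sprintf("could not move temporary file into place at '%s'", path))
  }
  invisible(path)
}

`%||%` <- rlang::`%||%`
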