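# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; NULL seed uses
# the ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), force(expr))
}

# Derive a stream seed from a root seed and a stage label, staying inside
# 32-bit integer range. Polynomial rolling hash so that distinct labels
# yield distinct streams (a weak digit-sum hash collides badly across
# enumerated labels like "run-1" ... "run-1000").
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

check_number <- function(x, name, min = -Inf, max = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %g", name, min))
  if (x > max) abort(sprintf("`%s` must be <= %g", name, max))
  invisible(x)
}

# Centered moving average that keeps endpoints by shrinking the window.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Levenberg-Marquardt least squares via nls.lm (robust to zero-residual
# exact fits, where nls() reports a singular gradient). Returns NULL on
# failure, else list(par = named list, se = named numeric (NA if the
# covariance is unavailable)).
lm_fit <- function(residual_fn, start, lower = NULL, upper = NULL,
                   maxiter = 200) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = residual_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = maxiter)),
    error = function(e) NULL
  )
  if (is.null(out) || !out$info %in% c(1, 2, 3, 4, -1)) return(NULL)
  se <- tryCatch({
    s <- summary(out)
    stats::setNames(s$coefficients[, "Std. Error"], names(start))
  }, error = function(e) stats::setNames(rep(NA_real_, length(start)),
                                         names(start)))
  list(par = as.list(out$par), se = se)
}

new_fit <- function(class, ...) {
  structure(list(...), class = c(class, "polexchange_fit"))
}

#' @export
print.polexchange_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flds <- x[!vapply(x, is.list, logical(1))]
  for (nm in names(flds)) {
    v <- flds[[nm]]
    if (is.numeric(v) && length(v) <= 4) {
      cat(" ", nm, ": ", paste(signif(v, 5), collapse = ", "), "\n", sep = "")
    } else if (is.character(v) && length(v) == 1) {
      cat(" ", nm, ": ", v, "\n", sep = "")
    }
  }
  invisible(x)
}
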