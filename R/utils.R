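# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers can distinguish user-input
# problems from numerical failures.
stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("chemotaxkit_input_error", "error")))
}

stop_compute <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("chemotaxkit_computation_error", "error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) {
    stop_input("`%s` must be > %g (got %g)", name, min, x)
  }
  if (!strict_min && x < min) {
    stop_input("`%s` must be >= %g (got %g)", name, min, x)
  }
  if (x > max) stop_input("`%s` must be <= %g (got %g)", name, max, x)
  invisible(x)
}

# Normalize a 2-vector to unit length; error on zero norm.
unit2 <- function(v, name = "vector") {
  if (!is.numeric(v) || length(v) != 2L || !all(is.finite(v))) {
    stop_input("`%s` must be a finite 2D vector", name)
  }
  n <- sqrt(sum(v^2))
  if (n == 0) stop_input("`%s` has zero norm", name)
  v / n
}

is_unit2 <- function(v, tol = 1e-8) {
  is.numeric(v) && length(v) == 2L && all(is.finite(v)) &&
    abs(sqrt(sum(v^2)) - 1) < tol
}

# Vectorized truncated-normal draws (support [0, Inf)): redraw negatives
# until all accepted, so the draw sequence is fully determined by the seed.
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Atomic write: stream to a sibling temp file, then rename into place.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop_compute("atomic rename to '%s' failed", path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
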