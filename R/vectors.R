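# Small 3-vector helpers used throughout the model. All directions in the
# public API are unit vectors; magnitudes live in the scatter eigenvalues.

vec3_norm <- function(v) sqrt(sum(v * v))

#' Normalize a 3-vector to unit length
#'
#' @param v Numeric vector of length 3.
#' @return Unit vector parallel to `v`.
#' @export
unit3 <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  n <- vec3_norm(v)
  if (n < 1e-300) stop("cannot normalize a zero-norm direction")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

is_unit3 <- function(v, tol = 1e-12) {
  is.numeric(v) && length(v) == 3L && all(is.finite(v)) &&
    abs(vec3_norm(v) - 1) <= tol
}

check_unit3 <- function(v, what) {
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)))
    stop(sprintf("%s must be a finite numeric 3-vector", what))
  if (abs(vec3_norm(v) - 1) > 1e-9)
    stop(sprintf("%s must have unit norm (got %.6g)", what, vec3_norm(v)))
  invisible(v)
}

# Rodrigues rotation: matrix rotating by `angle` (radians, right-handed)
# about the unit axis `axis`.
rotation_about_axis <- function(axis, angle) {
  u <- unit3(axis)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), nrow = 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

clamp1 <- function(x) pmin(1, pmax(-1, x))
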