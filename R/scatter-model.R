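#' Fiber scatterer
#'
#' A fiber is a cylinder-shaped microstructure that produces ultra-small-angle
#' X-ray scatter. Its scatter distribution is an oblate 3-D Gaussian: the two
#' equal large eigenvalues `sigma_perp_sq` describe scatter perpendicular to
#' the fiber axis, the smallest eigenvalue `sigma_par_sq` scatter along it.
#' The direction is normalized on construction; scatter magnitude lives only
#' in the eigenvalues.
#'
#' The isotropic and anisotropic signal components are derived quantities:
#' `d_iso = sigma_perp_sq` and `d_aniso = -(sigma_perp_sq - sigma_par_sq)`,
#' so the anisotropic part is the (non-positive) reduction of observed scatter
#' along the fiber axis.
#'
#' @param direction Numeric 3-vector, the cylinder axis. Normalized internally.
#' @param sigma_perp_sq Variance perpendicular to the axis (a.u.), `>= 0`.
#' @param sigma_par_sq Variance along the axis (a.u.),
#'   `0 <= sigma_par_sq <= sigma_perp_sq`.
#' @param radius,length Optional cylinder cross-section radius and height
#'   (same length unit), used only by the chord-length factor
#'   [chord_factor()]. If both are given, `length >= radius` is required.
#' @return An object of class `fiber_scatterer` with fields `direction`
#'   (unit vector), `sigma_perp_sq`, `sigma_par_sq`, `d_iso`, `d_aniso`,
#'   `radius`, `length`.
#' @examples
#' fiber_scatterer(c(1, 1, 1), sigma_perp_sq = 1, sigma_par_sq = 0.5)
#' @export
fiber_scatterer <- function(direction, sigma_perp_sq, sigma_par_sq,
                            radius = NULL, length = NULL) {
  f <- unit3(direction)
  stopifnot(is.numeric(sigma_perp_sq), length(sigma_perp_sq) == 1L,
            is.numeric(sigma_par_sq), length(sigma_par_sq) == 1L)
  if (sigma_par_sq < 0 || sigma_perp_sq < sigma_par_sq)
    stop("eigenvalues must satisfy 0 <= sigma_par_sq <= sigma_perp_sq")
  if (!is.null(radius) && radius <= 0) stop("radius must be positive")
  if (!is.null(length) && length <= 0) stop("length must be positive")
  if (!is.null(radius) && !is.null(length) && length < radius)
    stop("cylinder length must be at least the radius")
  structure(
    list(direction = f,
         sigma_perp_sq = sigma_perp_sq,
         sigma_par_sq = sigma_par_sq,
         d_iso = sigma_perp_sq,
         d_aniso = -(sigma_perp_sq - sigma_par_sq),
         radius = radius,
         length = length),
    class = "fiber_scatterer")
}

#' @export
print.fiber_scatterer <- function(x, ...) {
  cat(sprintf("<fiber_scatterer> f = (%.4f, %.4f, %.4f)\n",
              x$direction[1L], x$direction[2L], x$direction[3L]))
  cat(sprintf("  sigma_perp^2 = %g, sigma_par^2 = %g  (d_iso = %g, d_aniso = %g)\n",
              x$sigma_perp_sq, x$sigma_par_sq, x$d_iso, x$d_aniso))
  if (!is.null(x$radius))
    cat(sprintf("  cylinder radius = %g, length = %g\n",
                x$radius, if (is.null(x$length)) NA_real_ else x$length))
  invisible(x)
}

#' Scatter spheroid of a fiber
#'
#' Maps a fiber to the eigenbasis and eigenvalues of its 3-D Gaussian scatter
#' covariance. The smallest eigenvalue's eigenvector `b3` is collinear with
#' the fiber axis; `b1`, `b2` are an arbitrary orthonormal completion of the
#' scatter plane (all directions within it are physically indistinguishable).
#'
#' @param fiber A [fiber_scatterer()].
#' @return Object of class `scatter_spheroid` with `basis` (3 x 3 matrix,
#'   columns `b1`, `b2`, `b3`) and `eigenvalues`
#'   `(sigma_perp_sq, sigma_perp_sq, sigma_par_sq)`.
#' @export
spheroid_from_fiber <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_scatterer"))
  E <- plane_basis(fiber$direction)
  basis <- cbind(E[, 1L], E[, 2L], fiber$direction)
  colnames(basis) <- c("b1", "b2", "b3")
  structure(
    list(basis = basis,
         eigenvalues = c(fiber$sigma_perp_sq, fiber$sigma_perp_sq,
                         fiber$sigma_par_sq)),
    class = "scatter_spheroid")
}

#' Covariance matrix of a scatter spheroid
#'
#' Reconstructs the full 3 x 3 Gaussian covariance
#' `Sigma = sum_i sigma_i^2 b_i b_i^T`.
#'
#' @param spheroid A `scatter_spheroid`.
#' @return Symmetric 3 x 3 matrix.
#' @export
scatter_covariance <- function(spheroid) {
  stopifnot(inherits(spheroid, "scatter_spheroid"))
  B <- spheroid$basis
  B %*% diag(spheroid$eigenvalues) %*% t(B)
}

#' @export
print.scatter_spheroid <- function(x, ...) {
  cat("<scatter_spheroid>\n  eigenvalues:",
      paste(signif(x$eigenvalues, 6), collapse = ", "), "\n")
  cat(sprintf("  b3 (fiber axis) = (%.4f, %.4f, %.4f)\n",
              x$basis[1L, 3L], x$basis[2L, 3L], x$basis[3L, 3L]))
  invisible(x)
}

#' Divergence rotation of a cone-beam ray
#'
#' For a ray `r` diverging from the central ray `c` by angle `alpha`, the
#' relative geometry is corrected by rotating the fiber in the plane spanned
#' by `c` and `r` in the opposite direction: a rotation about the axis
#' `c x r` by `-alpha`. For a parallel projection (`c == r`) this is the
#' identity.
#'
#' @param central_ray,ray Unit 3-vectors with mutual angle below `pi/2`.
#' @return Orthonormal 3 x 3 rotation matrix with determinant +1.
#' @export
divergence_rotation <- function(central_ray, ray) {
  check_unit3(central_ray, "central_ray")
  check_unit3(ray, "ray")
  cosa <- clamp1(sum(central_ray * ray))
  alpha <- acos(cosa)
  # acos() resolves the angle only to ~1e-8 near cosa = 1; below that the
  # rotation axis c x r is numerically undefined and R_alpha is the identity
  if (alpha < 1e-7) return(diag(3L))
  if (alpha >= pi / 2)
    stop("divergence angle must be below pi/2 (antiparallel or sideways ray)")
  axis <- cross3(central_ray, ray)
  rotation_about_axis(axis, -alpha)
}

#' Orthonormal basis of the plane perpendicular to a ray
#'
#' Returns the 3 x 2 matrix `E` whose columns span the virtual projection
#' plane with normal `ray`. The first column is chosen deterministically by
#' crossing `ray` with the global axis of its smallest absolute component;
#' the second is `ray x e1`. Downstream quantities do not depend on this
#' choice.
#'
#' @param ray Unit 3-vector.
#' @return 3 x 2 matrix with orthonormal columns, both perpendicular to `ray`.
#' @export
plane_basis <- function(ray) {
  check_unit3(ray, "ray")
  k <- which.min(abs(ray))
  axis <- c(0, 0, 0)
  axis[k] <- 1
  e1 <- unit3(cross3(ray, axis))
  e2 <- cross3(ray, e1)
  matrix(c(e1, e2), nrow = 3L, ncol = 2L)
}

#' Ray context: one ray's geometry relative to a view
#'
#' Bundles the per-point projection geometry: the ray direction `r`, the
#' view's central ray `c`, the interferometer sensitivity direction `s`, and
#' the divergence angle `alpha = angle(c, r)`.
#'
#' @param ray Unit 3-vector, direction of the X-ray through the point.
#' @param sensitivity Unit 3-vector, the direction along which the
#'   interference pattern is sampled (perpendicular to the grating bars).
#' @param central_ray Unit 3-vector; defaults to `ray` (parallel beam).
#' @return Object of class `ray_context` with fields `ray`, `central_ray`,
#'   `sensitivity`, `divergence_angle`.
#' @export
ray_context <- function(ray, sensitivity, central_ray = ray) {
  check_unit3(ray, "ray")
  check_unit3(sensitivity, "sensitivity")
  check_unit3(central_ray, "central_ray")
  alpha <- acos(clamp1(sum(central_ray * ray)))
  if (alpha >= pi / 2)
    stop("divergence angle must lie in [0, pi/2)")
  structure(
    list(ray = ray, central_ray = central_ray, sensitivity = sensitivity,
         divergence_angle = alpha),
    class = "ray_context")
}

#' @export
print.ray_context <- function(x, ...) {
  cat(sprintf("<ray_context> alpha = %.4g rad\n", x$divergence_angle))
  cat(sprintf("  r = (%.4f, %.4f, %.4f), s = (%.4f, %.4f, %.4f)\n",
              x$ray[1L], x$ray[2L], x$ray[3L],
              x$sensitivity[1L], x$sensitivity[2L], x$sensitivity[3L]))
  invisible(x)
}

#' Alignment of a fiber with the sensitivity direction
#'
#' The scalar projection of the (divergence-corrected) fiber onto the
#' sensitivity direction. The canonical `"plane"` mode projects both the
#' rotated fiber and the sensitivity onto the virtual plane perpendicular to
#' the ray before taking the inner product,
#' `s^T E E^T (R_alpha f)`. The `"direct"` mode evaluates
#' `s^T (R_alpha f)`; the two agree exactly when `s` is perpendicular to the
#' ray, and `"direct"` therefore enforces `|s . r| < 1e-9`.
#'
#' @param fiber_dir Unit 3-vector, fiber axis.
#' @param ctx A [ray_context()].
#' @param mode `"plane"` (default) or `"direct"`.
#' @return Scalar in `[-1, 1]` for unit inputs.
#' @export
alignment <- function(fiber_dir, ctx, mode = c("plane", "direct")) {
  mode <- match.arg(mode)
  check_unit3(fiber_dir, "fiber_dir")
  stopifnot(inherits(ctx, "ray_context"))
  R <- divergence_rotation(ctx$central_ray, ctx$ray)
  f_rot <- drop(R %*% fiber_dir)
  if (mode == "direct") {
    if (abs(sum(ctx$sensitivity * ctx$ray)) > 1e-9)
      stop("mode \"direct\" requires the sensitivity perpendicular to the ray")
    return(sum(ctx$sensitivity * f_rot))
  }
  E <- plane_basis(ctx$ray)
  s_plane <- drop(crossprod(E, ctx$sensitivity))   # s' = E^T s
  f_plane <- drop(crossprod(E, f_rot))             # f' = E^T (R_alpha f)
  sum(s_plane * f_plane)
}

#' Projected variance of one scatter eigen-component
#'
#' The measured contribution of eigen-pair `(sigma_sq, basis_vec)` along the
#' sensitivity direction. The inner product is squared so the result is
#' invariant under `b -> -b` and has period `pi`, matching the symmetry of
#' the scatter distribution.
#'
#' @param sigma_sq Non-negative variance (a.u.).
#' @param basis_vec Unit 3-vector, the eigenvector.
#' @param ctx A [ray_context()].
#' @return `sigma_sq * alignment(basis_vec, ctx)^2`, in `[0, sigma_sq]` for
#'   unit vectors with `s` perpendicular to `r`.
#' @export
projected_variance <- function(sigma_sq, basis_vec, ctx) {
  stopifnot(is.numeric(sigma_sq), length(sigma_sq) == 1L)
  if (sigma_sq < 0) stop("variance must be non-negative")
  sigma_sq * alignment(basis_vec, ctx, mode = "plane")^2
}

#' Point dark-field signal of a fiber
#'
#' The observed dark-field scatter value at one sample point,
#' `d = d_iso + d_aniso * (s^T (R_alpha f))^2`, where
#' `d_iso = sigma_perp_sq` and `d_aniso = -(sigma_perp_sq - sigma_par_sq)`.
#' The squared inner product gives the signal its period of `pi`; with the
#' sensitivity perpendicular to the ray the value lies between the two
#' scatter eigenvalues.
#'
#' @param fiber A [fiber_scatterer()].
#' @param ctx A [ray_context()].
#' @return Scatter value `d` (a.u.).
#' @examples
#' f <- fiber_scatterer(c(1, 1, 1), 1, 0.5)
#' ctx <- ray_context(ray = c(0, 0, 1), sensitivity = c(1, 0, 0))
#' darkfield_point_signal(f, ctx)  # 1 - 0.5/3 = 0.8333...
#' @export
darkfield_point_signal <- function(fiber, ctx) {
  stopifnot(inherits(fiber, "fiber_scatterer"))
  a <- alignment(fiber$direction, ctx, mode = "plane")
  fiber$d_iso + fiber$d_aniso * a^2
}
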