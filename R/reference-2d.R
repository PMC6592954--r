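# Closed-form prior 2-D dark-field projection models and numerical checks
# that the general 3-D model reduces to each of them under the corresponding
# constraints (parallel beam, sensitivity s = (1, 0, 0), one rotation angle).

#' Parameters of a 2-D dark-field projection model
#'
#' @param A Isotropic scatter contribution (a.u., `>= 0`).
#' @param B Anisotropic scatter contribution (a.u., `A + B >= 0`).
#' @param start_angle Starting angle of the fiber (radians): theta for the
#'   optical-axis rotation model, phi for the azimuthal model, Theta for the
#'   axial-sensitivity model.
#' @param model One of `"revol"`, `"bayer"`, `"schaff"`.
#' @return Object of class `two_d_model_params`.
#' @export
two_d_model_params <- function(A, B, start_angle = 0,
                               model = c("revol", "bayer", "schaff")) {
  model <- match.arg(model)
  stopifnot(is.numeric(A), length(A) == 1L, is.numeric(B), length(B) == 1L)
  if (A < 0 || A + B < 0) stop("require A >= 0 and A + B >= 0")
  structure(list(A = A, B = B, start_angle = start_angle, model = model),
            class = "two_d_model_params")
}

#' Revol-type 2-D signal: rotation about the optical axis
#'
#' `A + B * sin^2(omega - theta)` for a fiber rotating in the plane
#' perpendicular to the beam, starting at angle theta.
#'
#' @param params A [two_d_model_params()].
#' @param omega Rotation angle(s), radians.
#' @return Signal values (a.u.), period `pi`.
#' @export
revol_signal <- function(params, omega) {
  stopifnot(inherits(params, "two_d_model_params"))
  params$A + params$B * sin(omega - params$start_angle)^2
}

#' Bayer-type 2-D signal: azimuthal fiber angle
#'
#' `A + B * sin^2(phi - omega)` for a fiber whose projection makes azimuthal
#' angle phi in the plane containing the beam, under tomographic rotation
#' omega about the vertical axis.
#'
#' @param params A [two_d_model_params()].
#' @param phi Azimuthal fiber angle (radians).
#' @param omega Tomographic rotation angle(s), radians.
#' @return Signal values (a.u.).
#' @export
bayer_signal <- function(params, phi, omega) {
  stopifnot(inherits(params, "two_d_model_params"))
  params$A + params$B * sin(phi - omega)^2
}

#' Schaff-type projection: sensitivity along the rotation axis
#'
#' With the sensitivity parallel to the rotation axis (here x, per the 2-D
#' convention s = (1, 0, 0)), the projected fiber component is invariant
#' under the tomographic rotation about that axis and equals `f_x` for every
#' rotation angle.
#'
#' @param f Unit 3-vector, fiber direction.
#' @param Theta Starting angle (radians).
#' @param omega Rotation angle(s), radians.
#' @return The projected component, one value per `omega` (all equal `f[1]`).
#' @export
schaff_projection <- function(f, Theta, omega) {
  check_unit3(f, "f")
  vapply(omega, function(om) {
    Rx <- rotation_about_axis(c(1, 0, 0), om - Theta)
    sum(c(1, 0, 0) * drop(Rx %*% f))
  }, numeric(1))
}

# Fiber rotation parameterization of each 2-D model: returns f(omega).
two_d_fiber_rotation <- function(model, f, start_angle, omega) {
  switch(model,
    revol = drop(rotation_about_axis(c(0, 0, 1), omega - start_angle) %*% f),
    bayer = drop(rotation_about_axis(c(0, 1, 0), start_angle - omega) %*% f),
    schaff = drop(rotation_about_axis(c(1, 0, 0), omega - start_angle) %*% f),
    stop("unknown 2-D model tag: ", model))
}

#' Check the reduction of the 3-D model to a 2-D model
#'
#' Evaluates the general 3-D point signal (parallel beam, sensitivity
#' `s = (1, 0, 0)`) under the fiber rotation of the chosen 2-D model and
#' compares it with the matched closed form over a rotation-angle grid.
#'
#' The closed-form constants are derived symbolically from the fiber, not
#' hard-coded per case: for the optical-axis and azimuthal models the
#' sensitivity-alignment is a sinusoid `rho * cos(omega - omega0)` whose
#' amplitude `rho` is the fiber's norm in the rotation-invariant plane, so
#' `A = d_iso + d_aniso * rho^2` and `B = -d_aniso * rho^2` with phase
#' `omega0`. For the axial-sensitivity model the projected component is the
#' constant `f_x`, so the matched form is the constant
#' `d_iso + d_aniso * f_x^2`.
#'
#' @param model `"revol"`, `"bayer"` or `"schaff"`.
#' @param fiber A [fiber_scatterer()].
#' @param start_angle Starting angle of the 2-D parameterization (radians).
#' @param omega Rotation-angle grid (radians); default 720 points over
#'   `[0, 2*pi)`.
#' @return Maximum absolute deviation between the 3-D model and the matched
#'   closed form over the grid.
#' @export
check_reduction <- function(model = c("revol", "bayer", "schaff"), fiber,
                            start_angle = 0,
                            omega = seq(0, 2 * pi, length.out = 721L)[-721L]) {
  model <- match.arg(model)
  stopifnot(inherits(fiber, "fiber_scatterer"))
  s <- c(1, 0, 0)
  beam <- c(0, 0, 1)
  ctx <- ray_context(ray = beam, sensitivity = s)
  d3 <- vapply(omega, function(om) {
    f_om <- two_d_fiber_rotation(model, fiber$direction, start_angle, om)
    fib_om <- fiber_scatterer(f_om, fiber$sigma_perp_sq, fiber$sigma_par_sq)
    darkfield_point_signal(fib_om, ctx)
  }, numeric(1))

  f <- fiber$direction
  if (model == "schaff") {
    closed <- rep(fiber$d_iso + fiber$d_aniso * f[1L]^2, length(omega))
    return(max(abs(d3 - closed)))
  }
  if (model == "revol") {
    # s^T f(omega) = f_x cos(omega - theta) - f_y sin(omega - theta)
    rho <- sqrt(f[1L]^2 + f[2L]^2)
    omega0 <- start_angle - atan2(f[2L], f[1L])
  } else {
    # s^T f(omega) = f_x cos(theta - omega) + f_z sin(theta - omega)
    rho <- sqrt(f[1L]^2 + f[3L]^2)
    omega0 <- start_angle - atan2(f[3L], f[1L])
  }
  A <- fiber$d_iso + fiber$d_aniso * rho^2
  B <- -fiber$d_aniso * rho^2
  closed <- A + B * sin(omega - omega0)^2
  max(abs(d3 - closed))
}
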