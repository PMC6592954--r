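# End-to-end experiments: trajectory signal traces, single-fiber plane
# sweeps with the chord-length factor, and the rotating tilted-rod
# simulation. All runs are deterministic given their arguments.

#' Signal trace
#'
#' A labelled 1-D dark-field signal over rotation (or sweep) angle.
#'
#' @param label Character label.
#' @param omega_deg Strictly increasing angles in degrees.
#' @param values Signal values (a.u.), same length as `omega_deg`.
#' @param meta Optional list of metadata (fiber, trajectory, flags).
#' @return Object of class `signal_trace`.
#' @export
signal_trace <- function(label, omega_deg, values, meta = list()) {
  stopifnot(is.character(label), length(omega_deg) == length(values),
            all(diff(omega_deg) > 0))
  structure(list(label = label, omega_deg = as.numeric(omega_deg),
                 values = as.numeric(values), meta = meta),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> \"%s\": %d samples, value range [%.6g, %.6g]\n",
              x$label, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a signal trace as CSV
#'
#' Two columns, `omega_deg` and `value`, written with full double precision
#' so the file round-trips exactly.
#'
#' @param trace A [signal_trace()].
#' @param path CSV file path.
#' @return `write_trace()`: `path`, invisibly. `read_trace()`: a
#'   [signal_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  df <- data.frame(omega_deg = sprintf("%.17g", trace$omega_deg),
                   value = sprintf("%.17g", trace$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param label Label to attach to the trace read back.
#' @export
read_trace <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  signal_trace(label, df$omega_deg, df$value)
}

#' Point signal along a trajectory
#'
#' Evaluates the dark-field point signal of a fiber at a fixed sample point
#' for every view of a trajectory.
#'
#' @param trajectory A `trajectory`.
#' @param fiber A [fiber_scatterer()].
#' @param point Sample point (default: the isocenter).
#' @param beam `"cone"` (default) or `"parallel"`.
#' @param label Trace label.
#' @return A [signal_trace()] over the trajectory's rotation angles.
#' @export
trajectory_point_signal <- function(trajectory, fiber, point = c(0, 0, 0),
                                    beam = c("cone", "parallel"),
                                    label = trajectory$kind) {
  beam <- match.arg(beam)
  stopifnot(inherits(trajectory, "trajectory"))
  vals <- vapply(trajectory$views, function(v) {
    darkfield_point_signal(fiber, ray_context_at(v, point, beam))
  }, numeric(1))
  omega <- vapply(trajectory$views, function(v) v$rotation_angle * 180 / pi,
                  numeric(1))
  signal_trace(label, omega, vals,
               meta = list(fiber = fiber$direction, beam = beam,
                           kind = trajectory$kind))
}

#' Trajectory comparison experiment
#'
#' Simulates the point dark-field signal of two fibers (one in the rotation
#' plane, one elevated out of it) at the isocenter over three trajectories:
#' a circle with in-plane sensitivity, a circle with axial sensitivity, and
#' a helix with the sensitivity aligned to the trajectory. No chord factor
#' is applied (point fibers). Defaults are the reference configuration:
#' source-isocenter distance 600, source-detector distance 1200, a full turn
#' in 1.5 degree increments, helix pitch 0.5, scatter eigenvalues
#' `sigma_perp_sq = 1`, `sigma_par_sq = 0.5`, fibers `(1,0,0)` and
#' (normalized) `(1,1,1)`.
#'
#' @param sid,sdd Source-isocenter / source-detector distances.
#' @param step_deg Angular increment (degrees).
#' @param pitch Helix pitch (axial advance per full turn).
#' @param sigma_perp_sq,sigma_par_sq Scatter eigenvalues (a.u.).
#' @param fiber_inplane,fiber_elevated Fiber directions (normalized
#'   internally).
#' @param beam Beam model; the fiber sits at the isocenter, where cone and
#'   parallel circle beams coincide.
#' @return Named list of six [signal_trace()]s:
#'   `circle_inplane_*`, `circle_axial_*`, `helix_*` for suffixes
#'   `inplane` / `elevated`.
#' @export
run_trajectory_experiment <- function(sid = 600, sdd = 1200, step_deg = 1.5,
                                      pitch = 0.5,
                                      sigma_perp_sq = 1, sigma_par_sq = 0.5,
                                      fiber_inplane = c(1, 0, 0),
                                      fiber_elevated = c(1, 1, 1),
                                      beam = c("cone", "parallel")) {
  beam <- match.arg(beam)
  f_in <- fiber_scatterer(fiber_inplane, sigma_perp_sq, sigma_par_sq)
  f_el <- fiber_scatterer(fiber_elevated, sigma_perp_sq, sigma_par_sq)
  tr_a <- circle_trajectory(0, 360, step_deg, sid, sdd, "in_plane")
  tr_b <- circle_trajectory(0, 360, step_deg, sid, sdd, "axial")
  tr_c <- helix_trajectory(0, 360, step_deg, sid, sdd, pitch)
  out <- list()
  for (nm in c("inplane", "elevated")) {
    fib <- if (nm == "inplane") f_in else f_el
    out[[paste0("circle_inplane_", nm)]] <-
      trajectory_point_signal(tr_a, fib, beam = beam,
                              label = paste0("circle in-plane s, ", nm, " fiber"))
    out[[paste0("circle_axial_", nm)]] <-
      trajectory_point_signal(tr_b, fib, beam = beam,
                              label = paste0("circle axial s, ", nm, " fiber"))
    out[[paste0("helix_", nm)]] <-
      trajectory_point_signal(tr_c, fib, beam = beam,
                              label = paste0("helix, ", nm, " fiber"))
  }
  out
}

#' Sweep a fiber through one coordinate plane
#'
#' Rotates a unit fiber through a full turn in one coordinate plane under a
#' parallel beam along +z with sensitivity (1, 0, 0), evaluating the point
#' contribution at each angle (optionally with the chord-length factor of
#' the finite cylinder).
#'
#' @param plane `"xy"`, `"xz"` or `"yz"`; at sweep angle `theta` the fiber is
#'   `(cos, sin, 0)`, `(cos, 0, sin)` or `(0, cos, sin)` in that plane.
#' @param sigma_perp_sq,sigma_par_sq Scatter eigenvalues.
#' @param radius,length Cylinder geometry for the chord factor (ignored when
#'   `use_chord = FALSE`).
#' @param step_deg Sweep increment in degrees.
#' @param use_chord Apply the chord-length factor.
#' @return A [signal_trace()] over the sweep angle.
#' @export
fiber_plane_sweep <- function(plane = c("xy", "xz", "yz"),
                              sigma_perp_sq, sigma_par_sq,
                              radius = NULL, length = NULL,
                              step_deg = 1, use_chord = FALSE) {
  plane <- match.arg(plane)
  ctx <- ray_context(ray = c(0, 0, 1), sensitivity = c(1, 0, 0))
  deg <- seq(0, 360 - step_deg / 2, by = step_deg)
  vals <- vapply(deg, function(d) {
    th <- d * pi / 180
    f <- switch(plane,
                xy = c(cos(th), sin(th), 0),
                xz = c(cos(th), 0, sin(th)),
                yz = c(0, cos(th), sin(th)))
    fib <- fiber_scatterer(f, sigma_perp_sq, sigma_par_sq,
                           radius = radius, length = length)
    point_contribution(fib, ctx, use_chord = use_chord)
  }, numeric(1))
  signal_trace(paste0(plane, "-plane sweep"), deg, vals,
               meta = list(plane = plane, use_chord = use_chord))
}

#' Single-fiber plane-sweep experiment
#'
#' Sweeps one finite cylindrical fiber through the three coordinate planes
#' under a parallel beam along +z with sensitivity (1, 0, 0), applying the
#' chord-length factor. Defaults are the reference teflon fiber: scatter
#' eigenvalues 1.5 and 0.3, radius 1.79 and length 15 (micrometers). The
#' xy-plane sweep keeps the fiber perpendicular to the beam (pure
#' orientation sinusoid between the eigenvalues); the xz and yz sweeps
#' incline the fiber into the beam, where the growing intersection length
#' dominates the signal.
#'
#' @inheritParams fiber_plane_sweep
#' @return Named list of three [signal_trace()]s: `xy`, `xz`, `yz`.
#' @export
run_single_fiber_planes <- function(sigma_perp_sq = 1.5, sigma_par_sq = 0.3,
                                    radius = 1.79, length = 15,
                                    step_deg = 1, use_chord = TRUE) {
  out <- lapply(c(xy = "xy", xz = "xz", yz = "yz"), function(p)
    fiber_plane_sweep(p, sigma_perp_sq, sigma_par_sq,
                      radius = radius, length = length,
                      step_deg = step_deg, use_chord = use_chord))
  out
}

#' Rotating tilted-rod experiment
#'
#' Simulates the central-pixel dark-field signal of a homogeneous
#' fiber-reinforced rod rotating about the vertical axis, for several
#' elevation (tilt) angles of the rod relative to the rotation axis. Uses
#' the analytic cylinder projector: per view, `-log D` is the exact
#' ray-cylinder chord length times the orientation-dependent point scatter
#' value. Defaults are the reference configuration: rod diameter 40 (pixel
#' units), scatter eigenvalues 1.4 and 1, 100 views over 180 degrees,
#' in-plane sensitivity, elevation angles 10..50 degrees.
#'
#' @param elevations_deg Elevation angles of the rod axis from the rotation
#'   axis (degrees).
#' @param sigma_perp_sq,sigma_par_sq Scatter eigenvalues.
#' @param diameter Rod diameter (pixel units).
#' @param half_length Rod half-length (same units).
#' @param n_views Number of views over `span_deg`.
#' @param span_deg Total rotation (degrees).
#' @param sid,sdd Source-isocenter / source-detector distances.
#' @param angle_offset_deg Azimuthal offset of the rod's tilt plane,
#'   modelling a rod not aligned with the detector plane at the start.
#' @param beam Beam model.
#' @return Named list of [signal_trace()]s, one per elevation angle
#'   (`elev10`, `elev20`, ...), values `-log D` at the central pixel.
#' @export
run_carbon_rod <- function(elevations_deg = c(10, 20, 30, 40, 50),
                           sigma_perp_sq = 1.4, sigma_par_sq = 1,
                           diameter = 40, half_length = 100,
                           n_views = 100, span_deg = 180,
                           sid = 600, sdd = 1200,
                           angle_offset_deg = 0,
                           beam = c("parallel", "cone")) {
  beam <- match.arg(beam)
  step <- span_deg / n_views
  tr <- circle_trajectory(0, span_deg, step, sid, sdd, "in_plane")
  detector <- list(n_pixels = 1L, pitch = 1)
  out <- list()
  for (e in elevations_deg) {
    er <- e * pi / 180
    axis <- c(sin(er), cos(er), 0)
    axis <- drop(rotation_about_axis(c(0, 1, 0),
                                     angle_offset_deg * pi / 180) %*% axis)
    fib <- fiber_scatterer(axis, sigma_perp_sq, sigma_par_sq)
    rod <- cylinder_phantom(c(0, 0, 0), axis, diameter / 2, half_length, fib)
    vals <- vapply(tr$views, function(v)
      project_cylinder(rod, v, detector, beam), numeric(1))
    omega <- vapply(tr$views, function(v) v$rotation_angle * 180 / pi,
                    numeric(1))
    out[[sprintf("elev%g", e)]] <-
      signal_trace(sprintf("rod elevation %g deg", e), omega, vals,
                   meta = list(elevation_deg = e, diameter = diameter))
  }
  out
}

#' Seeded random fiber phantom
#'
#' Generates a reproducible [voxel_phantom()] for projector tests: a given
#' number of randomly placed fiber voxels with random unit directions and
#' eigenvalues drawn from the given ranges (the parallel variance is drawn
#' as a fraction of the perpendicular one, so the phantom invariants
#' `d_aniso <= 0` and `d_iso + d_aniso >= 0` hold by construction).
#' Non-fiber voxels are empty. The global RNG state is restored on exit.
#'
#' @param seed Integer seed fixing all randomness.
#' @param shape Grid shape `(nx, ny, nz)`.
#' @param n_fibers Number of fiber voxels (`<= prod(shape)`).
#' @param sigma_perp_range Range of the perpendicular variance.
#' @param sigma_par_frac_range Range of `sigma_par_sq / sigma_perp_sq`,
#'   within `[0, 1]`.
#' @param spacing,origin Grid geometry, as in [voxel_phantom()].
#' @return A [voxel_phantom()].
#' @export
generate_fiber_phantom <- function(seed, shape = c(8L, 8L, 8L),
                                   n_fibers = 12L,
                                   sigma_perp_range = c(0.5, 1.5),
                                   sigma_par_frac_range = c(0.2, 1),
                                   spacing = 1, origin = c(0, 0, 0)) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_fibers >= 0,
            n_fibers <= prod(shape),
            sigma_perp_range[1L] >= 0, diff(sigma_perp_range) >= 0,
            sigma_par_frac_range[1L] >= 0, sigma_par_frac_range[2L] <= 1,
            diff(sigma_par_frac_range) >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  shape <- as.integer(shape)
  d_iso <- array(0, shape)
  d_aniso <- array(0, shape)
  fibers <- array(NA_real_, c(shape, 3L))
  if (n_fibers > 0) {
    cells <- sample.int(prod(shape), n_fibers)
    idx <- arrayInd(cells, shape)
    for (m in seq_len(n_fibers)) {
      i <- idx[m, 1L]; j <- idx[m, 2L]; k <- idx[m, 3L]
      sp <- stats::runif(1, sigma_perp_range[1L], sigma_perp_range[2L])
      frac <- stats::runif(1, sigma_par_frac_range[1L],
                           sigma_par_frac_range[2L])
      f <- unit3(stats::rnorm(3))
      d_iso[i, j, k] <- sp
      d_aniso[i, j, k] <- -(sp - sp * frac)
      fibers[i, j, k, ] <- f
    }
  }
  voxel_phantom(d_iso, d_aniso, fibers, spacing = spacing, origin = origin)
}
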