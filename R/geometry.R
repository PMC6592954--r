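# Acquisition trajectories and per-point ray geometry.
#
# Global convention: rotation axis = global y; at rotation angle 0 the source
# sits at (0, 0, sid) and the central ray points along -z toward the
# isocenter (origin); rotation is right-handed about +y. All acceptance
# quantities (trace extrema, constancy, periodicity) are invariant to this
# choice of axes and start phase.

new_view_geometry <- function(rotation_angle, source_position, central_ray,
                              sensitivity, sid, sdd) {
  structure(
    list(rotation_angle = rotation_angle,
         source_position = source_position,
         central_ray = central_ray,
         sensitivity = sensitivity,
         source_isocenter_distance = sid,
         source_detector_distance = sdd),
    class = "view_geometry")
}

new_trajectory <- function(views, kind, pitch = NULL) {
  structure(list(views = views, kind = kind, pitch = pitch),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> kind = %s, %d views", x$kind, length(x$views)))
  if (!is.null(x$pitch)) cat(sprintf(", pitch = %g", x$pitch))
  cat("\n")
  if (length(x$views)) {
    om <- range(vapply(x$views, function(v) v$rotation_angle, numeric(1)))
    cat(sprintf("  rotation angle: %.4g .. %.4g rad\n", om[1L], om[2L]))
  }
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$views)

circle_source <- function(omega, sid) {
  c(sid * sin(omega), 0, sid * cos(omega))
}

#' Circular acquisition trajectory
#'
#' Builds the views of a circular 2-D trajectory: the source moves on a
#' circle of radius `sid` about the rotation axis (global y), the central ray
#' points from the source toward the isocenter. Two sensitivity modes are
#' supported, both perpendicular to the central ray: `"in_plane"` places the
#' sensitivity in the rotation plane (detector vector `{1, 0}`), `"axial"`
#' aligns it with the rotation axis (detector vector `{0, 1}`).
#'
#' The angular grid is half-open, `[start_deg, stop_deg)`, so a full turn at
#' a 1.5 degree increment yields 240 views.
#'
#' @param start_deg,stop_deg,step_deg Rotation angle grid in degrees;
#'   `stop_deg > start_deg`, `step_deg > 0`.
#' @param sid,sdd Source-isocenter and source-detector distances
#'   (setup length units, both positive).
#' @param sensitivity_mode `"in_plane"` or `"axial"`.
#' @return A `trajectory` whose `views` are `view_geometry` objects.
#' @examples
#' tr <- circle_trajectory(0, 360, 1.5, sid = 600, sdd = 1200)
#' length(tr)  # 240
#' @export
circle_trajectory <- function(start_deg, stop_deg, step_deg, sid, sdd,
                              sensitivity_mode = c("in_plane", "axial")) {
  sensitivity_mode <- match.arg(sensitivity_mode)
  if (stop_deg <= start_deg) stop("stop_deg must exceed start_deg")
  if (step_deg <= 0) stop("step_deg must be positive")
  if (sid <= 0 || sdd <= 0) stop("sid and sdd must be positive")
  deg <- seq(start_deg, stop_deg - step_deg / 2, by = step_deg)
  views <- lapply(deg, function(d) {
    om <- d * pi / 180
    src <- circle_source(om, sid)
    cr <- c(-sin(om), 0, -cos(om))
    s <- if (sensitivity_mode == "in_plane") c(cos(om), 0, -sin(om))
         else c(0, 1, 0)
    new_view_geometry(om, src, cr, s, sid, sdd)
  })
  kind <- if (sensitivity_mode == "in_plane") "circle_inplane" else "circle_axial"
  new_trajectory(views, kind)
}

#' Helical acquisition trajectory
#'
#' The source moves on a helix about the global y axis: circular motion of
#' radius `sid` plus an axial advance of `pitch` length units per full turn
#' (2*pi). The central ray points horizontally from the source toward the
#' rotation axis. The sensitivity direction is aligned with the trajectory:
#' the component of the helix tangent perpendicular to the central ray,
#' renormalized. With `pitch = 0` the geometry degenerates to the in-plane
#' circle.
#'
#' @inheritParams circle_trajectory
#' @param pitch Axial advance per full turn (`>= 0`).
#' @return A `trajectory` of kind `"helix"`.
#' @export
helix_trajectory <- function(start_deg, stop_deg, step_deg, sid, sdd, pitch) {
  if (stop_deg <= start_deg) stop("stop_deg must exceed start_deg")
  if (step_deg <= 0) stop("step_deg must be positive")
  if (sid <= 0 || sdd <= 0) stop("sid and sdd must be positive")
  if (pitch < 0) stop("pitch must be non-negative")
  deg <- seq(start_deg, stop_deg - step_deg / 2, by = step_deg)
  om0 <- start_deg * pi / 180
  views <- lapply(deg, function(d) {
    om <- d * pi / 180
    src <- circle_source(om, sid)
    src[2L] <- pitch * (om - om0) / (2 * pi)
    cr <- c(-sin(om), 0, -cos(om))
    # analytic helix tangent d(source)/d(omega); already perpendicular to cr
    tangent <- c(sid * cos(om), pitch / (2 * pi), -sid * sin(om))
    s <- unit3(tangent - sum(tangent * cr) * cr)
    new_view_geometry(om, src, cr, s, sid, sdd)
  })
  new_trajectory(views, "helix", pitch = pitch)
}

#' Per-point ray context of a view
#'
#' Builds the [ray_context()] for a sample point under a view: for a
#' parallel beam every ray equals the central ray (divergence 0); for a cone
#' beam the ray runs from the source through the point and the divergence
#' angle is the angle to the central ray.
#'
#' @param view A `view_geometry` (element of a trajectory's `views`).
#' @param point Numeric 3-vector, world coordinates of the sample point.
#' @param beam `"parallel"` or `"cone"`.
#' @return A [ray_context()].
#' @export
ray_context_at <- function(view, point, beam = c("parallel", "cone")) {
  beam <- match.arg(beam)
  stopifnot(inherits(view, "view_geometry"))
  if (beam == "parallel")
    return(ray_context(ray = view$central_ray,
                       sensitivity = view$sensitivity,
                       central_ray = view$central_ray))
  delta <- point - view$source_position
  n <- vec3_norm(delta)
  if (n < 1e-12) stop("point coincides with the source position")
  ray_context(ray = delta / n,
              sensitivity = view$sensitivity,
              central_ray = view$central_ray)
}

#' Export a trajectory to CSV
#'
#' One row per view: rotation angle in degrees, source position, central ray
#' and sensitivity direction (xyz each). Values are written with full double
#' precision so that [read_trajectory_csv()] round-trips exactly.
#'
#' @param trajectory A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  rows <- lapply(trajectory$views, function(v) {
    data.frame(omega_deg = v$rotation_angle * 180 / pi,
               src_x = v$source_position[1L], src_y = v$source_position[2L],
               src_z = v$source_position[3L],
               c_x = v$central_ray[1L], c_y = v$central_ray[2L],
               c_z = v$central_ray[3L],
               s_x = v$sensitivity[1L], s_y = v$sensitivity[2L],
               s_z = v$sensitivity[3L])
  })
  df <- do.call(rbind, rows)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a trajectory from CSV
#'
#' Reads a file written by [write_trajectory_csv()]. Distances are not stored
#' in the CSV; they are re-derived from the source positions (sid) or must be
#' supplied (sdd).
#'
#' @param path CSV file path.
#' @param sdd Source-detector distance to attach to each view.
#' @param kind Trajectory kind tag.
#' @return A `trajectory`.
#' @export
read_trajectory_csv <- function(path, sdd = NA_real_, kind = "custom") {
  df <- utils::read.csv(path)
  views <- lapply(seq_len(nrow(df)), function(i) {
    src <- c(df$src_x[i], df$src_y[i], df$src_z[i])
    new_view_geometry(df$omega_deg[i] * pi / 180, src,
                      c(df$c_x[i], df$c_y[i], df$c_z[i]),
                      c(df$s_x[i], df$s_y[i], df$s_z[i]),
                      sid = vec3_norm(c(src[1L], 0, src[3L])), sdd = sdd)
  })
  new_trajectory(views, kind)
}
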