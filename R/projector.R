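# Forward projection: chord-length factor, voxel and analytic cylinder
# phantoms, dark-field line integrals and Beer-Lambert transmission.

#' Chord-length factor of a finite fiber cylinder
#'
#' The point scatter value scales with the average length of the projection
#' rays through the fiber cylinder. This factor normalizes that length to the
#' perpendicular case: with `gamma` the angle between the ray and the fiber
#' axis,
#' `C(gamma) = min(1 / sin(gamma), length / mean_perp_chord)` where
#' `mean_perp_chord = (pi/4) * diameter` is the mean chord of a circle. Thus
#' `C = 1` for a perpendicular ray, grows as the ray tilts toward the axis,
#' and saturates at the cap set by the cylinder height so the path never
#' exceeds the cylinder diagonal scale.
#'
#' @param fiber A [fiber_scatterer()] with `radius` and `length` set.
#' @param ray Unit 3-vector, ray direction.
#' @return Dimensionless factor `C >= 1`.
#' @export
chord_factor <- function(fiber, ray) {
  stopifnot(inherits(fiber, "fiber_scatterer"))
  if (is.null(fiber$radius) || is.null(fiber$length))
    stop("chord_factor needs the fiber radius and length; ",
         "for point fibers use C = 1 (use_chord = FALSE)")
  check_unit3(ray, "ray")
  cosg <- clamp1(sum(ray * fiber$direction))
  sing <- sqrt(max(0, 1 - cosg^2))
  mean_perp_chord <- (pi / 4) * 2 * fiber$radius
  cap <- fiber$length / mean_perp_chord
  if (sing < 1e-300) return(cap)
  min(1 / sing, cap)
}

#' Per-point dark-field contribution
#'
#' The voxel-level scatter value: the orientation-dependent point signal of
#' [darkfield_point_signal()], optionally scaled by the chord-length factor
#' [chord_factor()] for a finite fiber cylinder.
#'
#' @param fiber A [fiber_scatterer()].
#' @param ctx A [ray_context()].
#' @param use_chord If `TRUE`, multiply by `chord_factor(fiber, ctx$ray)`
#'   (requires the fiber radius and length).
#' @return Non-negative scatter value `d(x)` (a.u.).
#' @export
point_contribution <- function(fiber, ctx, use_chord = FALSE) {
  d <- darkfield_point_signal(fiber, ctx)
  if (use_chord) d <- chord_factor(fiber, ctx$ray) * d
  d
}

#' Voxel phantom
#'
#' A regular 3-D grid of scatter voxels. Each voxel carries an isotropic
#' value `d_iso >= 0`, an anisotropic value `d_aniso <= 0`, and optionally a
#' unit fiber direction; voxels without a direction are isotropic and must
#' have `d_aniso = 0`. `d_iso + d_aniso >= 0` everywhere, so every point
#' signal is non-negative and the transmitted dark-field lies in (0, 1].
#'
#' Voxel `(i, j, k)` (0-based) covers the half-open cell
#' `origin + [i, i+1) * spacing` per axis, with its center at
#' `origin + (i + 0.5) * spacing`.
#'
#' @param d_iso 3-D array `(nx, ny, nz)` of isotropic values.
#' @param d_aniso 3-D array of the same shape, non-positive; defaults to 0.
#' @param fibers 4-D array `(nx, ny, nz, 3)` of fiber directions, `NA` where
#'   isotropic; defaults to all-isotropic.
#' @param spacing Voxel edge length (one scalar, isotropic voxels).
#' @param origin 3-vector, world position of the grid corner.
#' @return Object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(d_iso, d_aniso = NULL, fibers = NULL,
                          spacing = 1, origin = c(0, 0, 0)) {
  stopifnot(is.array(d_iso), length(dim(d_iso)) == 3L)
  dm <- dim(d_iso)
  if (is.null(d_aniso)) d_aniso <- array(0, dm)
  stopifnot(identical(dim(d_aniso), dm))
  if (any(d_iso < 0)) stop("d_iso must be non-negative everywhere")
  if (any(d_aniso > 0)) stop("d_aniso must be non-positive everywhere")
  if (any(d_iso + d_aniso < 0))
    stop("d_iso + d_aniso must be non-negative everywhere")
  if (!is.null(fibers)) {
    stopifnot(is.array(fibers), identical(dim(fibers), c(dm, 3L)))
    iso_mask <- is.na(fibers[, , , 1L, drop = FALSE])
    dim(iso_mask) <- dm
    if (any(d_aniso[iso_mask] != 0))
      stop("voxels without a fiber direction must have d_aniso = 0")
  } else if (any(d_aniso != 0)) {
    stop("non-zero d_aniso requires fiber directions")
  }
  stopifnot(length(spacing) == 1L, spacing > 0, length(origin) == 3L)
  structure(list(dim = dm, spacing = spacing, origin = origin,
                 d_iso = d_iso, d_aniso = d_aniso, fibers = fibers),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels, spacing %g\n",
              x$dim[1L], x$dim[2L], x$dim[3L], x$spacing))
  n_fib <- if (is.null(x$fibers)) 0L else sum(!is.na(x$fibers[, , , 1L]))
  cat(sprintf("  %d fiber voxels, max d_iso = %g\n", n_fib, max(x$d_iso)))
  invisible(x)
}

# Intersection of the ray origin + t*dir with the phantom bounding box;
# returns c(t_enter, t_exit) or NULL if the ray misses.
ray_box_interval <- function(origin, dir, box_lo, box_hi) {
  t0 <- -Inf
  t1 <- Inf
  for (k in 1:3) {
    if (abs(dir[k]) < 1e-300) {
      if (origin[k] < box_lo[k] || origin[k] > box_hi[k]) return(NULL)
    } else {
      ta <- (box_lo[k] - origin[k]) / dir[k]
      tb <- (box_hi[k] - origin[k]) / dir[k]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

#' Dark-field line integral through a voxel phantom
#'
#' Midpoint-rule sampling of the per-voxel scatter value `d(x)` along a ray:
#' the ray is clipped to the grid bounding box, divided into `n =
#' ceiling(chord / step)` equal sub-intervals, and `d` is evaluated at each
#' midpoint with nearest-voxel lookup (half-open cells). Each sample's ray
#' context comes from [ray_context_at()], so cone-beam divergence is applied
#' per sample point. The estimate converges to the analytic integral as
#' `step -> 0` with first-order error.
#'
#' @param phantom A [voxel_phantom()].
#' @param view A `view_geometry` supplying the sensitivity and central ray.
#' @param origin Numeric 3-vector, a point on the ray.
#' @param direction Unit 3-vector, ray direction.
#' @param step Target sampling step (length units); default `spacing / 4`.
#' @param beam `"parallel"` or `"cone"`.
#' @return The integral of `d(x)` along the ray (a.u. * length); 0 if the
#'   ray misses the grid.
#' @export
line_integral <- function(phantom, view, origin, direction,
                          step = phantom$spacing / 4,
                          beam = c("parallel", "cone")) {
  beam <- match.arg(beam)
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (step <= 0) stop("step must be positive")
  dir <- unit3(direction)
  box_lo <- phantom$origin
  box_hi <- phantom$origin + phantom$dim * phantom$spacing
  iv <- ray_box_interval(origin, dir, box_lo, box_hi)
  if (is.null(iv)) return(0)
  len <- iv[2L] - iv[1L]
  n <- max(1L, as.integer(ceiling(len / step)))
  h <- len / n
  tmid <- iv[1L] + (seq_len(n) - 0.5) * h

  # parallel beam: the context (hence the projected sensitivity) is the
  # same for every sample, so precompute the effective alignment vector
  if (beam == "parallel") {
    E <- plane_basis(view$central_ray)
    s_eff <- drop(E %*% crossprod(E, view$sensitivity))
  }

  total <- 0
  for (t in tmid) {
    p <- origin + t * dir
    idx <- floor((p - phantom$origin) / phantom$spacing)
    if (any(idx < 0) || any(idx >= phantom$dim)) next
    i <- idx[1L] + 1L
    j <- idx[2L] + 1L
    k <- idx[3L] + 1L
    di <- phantom$d_iso[i, j, k]
    da <- phantom$d_aniso[i, j, k]
    if (da == 0 || is.null(phantom$fibers)) {
      total <- total + di
      next
    }
    f <- phantom$fibers[i, j, k, ]
    if (anyNA(f)) {
      total <- total + di
      next
    }
    if (beam == "parallel") {
      a <- sum(s_eff * f)
    } else {
      ctx <- ray_context_at(view, p, beam = "cone")
      a <- alignment(f, ctx, mode = "plane")
    }
    total <- total + di + da * a^2
  }
  total * h
}

#' Beer-Lambert dark-field transmission
#'
#' Converts a dark-field line integral into the measured visibility ratio
#' `D = exp(-integral)`; its negative logarithm recovers the integral
#' exactly.
#'
#' @param integral_value Non-negative line integral.
#' @return `D` in (0, 1].
#' @export
transmit <- function(integral_value) {
  if (any(integral_value < 0)) stop("line integral must be non-negative")
  exp(-integral_value)
}

#' @rdname transmit
#' @param D Dark-field transmission values in (0, 1].
#' @export
neg_log <- function(D) {
  if (any(D <= 0) || any(D > 1)) stop("D must lie in (0, 1]")
  0 - log(D)  # 0 - x avoids the negative zero at D = 1
}

#' Analytic cylinder phantom
#'
#' A homogeneous finite cylinder (a rod of aligned micro-fibers): axis point,
#' unit axis direction, radius, half-length, and one [fiber_scatterer()]
#' whose direction is parallel to the axis. Projected analytically (exact
#' ray-cylinder chord lengths, no voxelization).
#'
#' @param axis_point 3-vector on the cylinder axis (the center).
#' @param axis Unit 3-vector, cylinder axis direction.
#' @param radius Cylinder radius (`> 0`).
#' @param half_length Half the cylinder height (`>= radius`).
#' @param scatter A [fiber_scatterer()] with direction parallel to `axis`.
#' @return Object of class `cylinder_phantom`.
#' @export
cylinder_phantom <- function(axis_point, axis, radius, half_length, scatter) {
  a <- unit3(axis)
  stopifnot(radius > 0, half_length >= radius,
            inherits(scatter, "fiber_scatterer"))
  if (abs(abs(sum(a * scatter$direction)) - 1) > 1e-9)
    stop("scatter fiber direction must be parallel to the cylinder axis")
  structure(list(axis_point = axis_point, axis = a, radius = radius,
                 half_length = half_length, scatter = scatter),
            class = "cylinder_phantom")
}

#' Ray-cylinder chord length
#'
#' Exact intersection length of a ray with a finite capped cylinder.
#'
#' @param phantom A [cylinder_phantom()].
#' @param origin 3-vector on the ray.
#' @param direction Unit 3-vector, ray direction.
#' @return Chord length (`>= 0`).
#' @export
ray_cylinder_chord <- function(phantom, origin, direction) {
  stopifnot(inherits(phantom, "cylinder_phantom"))
  dir <- unit3(direction)
  a <- phantom$axis
  p0 <- origin - phantom$axis_point
  # radial (perpendicular-to-axis) components of ray origin and direction
  d_perp <- dir - sum(dir * a) * a
  p_perp <- p0 - sum(p0 * a) * a
  A <- sum(d_perp * d_perp)
  # axial slab |(p0 + t dir) . a| <= half_length
  da <- sum(dir * a)
  pa <- sum(p0 * a)
  if (abs(da) < 1e-14) {
    if (abs(pa) > phantom$half_length) return(0)
    slab <- c(-Inf, Inf)
  } else {
    ta <- (-phantom$half_length - pa) / da
    tb <- (phantom$half_length - pa) / da
    slab <- sort(c(ta, tb))
  }
  if (A < 1e-28) {
    # ray parallel to the axis: inside the radius or a miss
    if (sum(p_perp * p_perp) > phantom$radius^2) return(0)
    tube <- c(-Inf, Inf)
  } else {
    B <- 2 * sum(p_perp * d_perp)
    C <- sum(p_perp * p_perp) - phantom$radius^2
    disc <- B^2 - 4 * A * C
    if (disc <= 0) return(0)
    sq <- sqrt(disc)
    tube <- sort(c((-B - sq) / (2 * A), (-B + sq) / (2 * A)))
  }
  lo <- max(slab[1L], tube[1L])
  hi <- min(slab[2L], tube[2L])
  max(0, hi - lo)
}

#' Project a cylinder phantom onto one detector row
#'
#' Analytic projection for one view: for each detector pixel the exact chord
#' length of the ray through the finite cylinder is multiplied by the
#' orientation-dependent point scatter value of the rod's fiber under that
#' ray's context, giving the per-pixel dark-field `-log D`. The exact chord
#' replaces the mean-chord approximation of [chord_factor()]. Pixels whose
#' ray misses the cylinder read zero.
#'
#' The detector row lies in the rotation plane: pixel `j` (centered grid) is
#' offset by `(j - (n-1)/2) * pitch` along the in-plane direction
#' perpendicular to the central ray.
#'
#' @param phantom A [cylinder_phantom()].
#' @param view A `view_geometry`.
#' @param detector List with `n_pixels` (positive integer) and `pitch`
#'   (pixel spacing, `> 0`).
#' @param beam `"parallel"` or `"cone"`.
#' @return Numeric vector of `-log D` values, one per pixel.
#' @export
project_cylinder <- function(phantom, view, detector,
                             beam = c("parallel", "cone")) {
  beam <- match.arg(beam)
  stopifnot(inherits(phantom, "cylinder_phantom"),
            inherits(view, "view_geometry"))
  if (is.null(detector$n_pixels) || detector$n_pixels < 1 ||
      is.null(detector$pitch) || detector$pitch <= 0)
    stop("detector must supply n_pixels >= 1 and pitch > 0")
  cr <- view$central_ray
  u <- cross3(cr, c(0, 1, 0))
  nu <- vec3_norm(u)
  if (nu < 1e-12) stop("central ray parallel to the rotation axis")
  u <- u / nu
  n <- as.integer(detector$n_pixels)
  offsets <- (seq_len(n) - 1 - (n - 1) / 2) * detector$pitch
  iso <- view$source_position + view$source_isocenter_distance * cr
  vapply(offsets, function(x) {
    if (beam == "parallel") {
      origin <- iso + x * u
      dir <- cr
      ctx <- ray_context(cr, view$sensitivity, cr)
    } else {
      det_pt <- view$source_position + view$source_detector_distance * cr + x * u
      dir <- unit3(det_pt - view$source_position)
      origin <- view$source_position
      ctx <- ray_context(dir, view$sensitivity, cr)
    }
    chord <- ray_cylinder_chord(phantom, origin, dir)
    if (chord <= 0) return(0)
    chord * darkfield_point_signal(phantom$scatter, ctx)
  }, numeric(1))
}

#' Cylinder sinogram over a trajectory
#'
#' Stacks [project_cylinder()] rows for every view of a trajectory.
#'
#' @inheritParams project_cylinder
#' @param trajectory A `trajectory`.
#' @return Object of class `sinogram`: `values` (views x pixels matrix of
#'   `-log D`), `omega_deg`, `pixel_coords`.
#' @export
cylinder_sinogram <- function(phantom, trajectory, detector,
                              beam = c("parallel", "cone")) {
  beam <- match.arg(beam)
  stopifnot(inherits(trajectory, "trajectory"))
  rows <- t(vapply(trajectory$views,
                   function(v) project_cylinder(phantom, v, detector, beam),
                   numeric(as.integer(detector$n_pixels))))
  n <- as.integer(detector$n_pixels)
  structure(
    list(values = rows,
         omega_deg = vapply(trajectory$views,
                            function(v) v$rotation_angle * 180 / pi,
                            numeric(1)),
         pixel_coords = (seq_len(n) - 1 - (n - 1) / 2) * detector$pitch),
    class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d pixels, -log D in [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a sinogram
#'
#' `write_sinogram()` stores the values as 32-bit little-endian float raw
#' data (row-major: pixel index fastest) next to a JSON sidecar carrying the
#' shape, rotation angles and pixel coordinates, and optionally a float TIFF
#' if the tiff package is installed. `read_sinogram()` reads the pair back.
#'
#' @param sinogram A `sinogram`.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.raw` and `<prefix>.json` (and `<prefix>.tif` if requested).
#' @param tiff Also write a TIFF copy (requires the tiff package).
#' @return `path_prefix`, invisibly.
#' @export
write_sinogram <- function(sinogram, path_prefix, tiff = FALSE) {
  stopifnot(inherits(sinogram, "sinogram"))
  raw_path <- paste0(path_prefix, ".raw")
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(sinogram$values)), con, size = 4L,
           endian = "little")
  meta <- list(shape = dim(sinogram$values),
               order = "row-major (pixel fastest)",
               dtype = "float32le",
               omega_deg = sinogram$omega_deg,
               pixel_coords = sinogram$pixel_coords)
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (tiff) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("TIFF output requires the tiff package")
    tiff::writeTIFF(sinogram$values / max(sinogram$values, 1e-300),
                    paste0(path_prefix, ".tif"), bits.per.sample = 32L)
  }
  invisible(path_prefix)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(paste0(path_prefix, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  structure(
    list(values = matrix(vals, nrow = meta$shape[1L],
                         ncol = meta$shape[2L], byrow = TRUE),
         omega_deg = meta$omega_deg,
         pixel_coords = meta$pixel_coords),
    class = "sinogram")
}
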