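# Independent oracles used across the test files. These deliberately avoid
# the package's own helpers so they can cross-check them.

# Rodrigues rotation formula applied to a vector (not a matrix product):
# v cos(a) + (u x v) sin(a) + u (u . v)(1 - cos(a))
rodrigues_rotate <- function(v, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  uxv <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  v * cos(angle) + uxv * sin(angle) + u * sum(u * v) * (1 - cos(angle))
}

random_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-3) return(v / n)
  }
}

# Rotation matrix from the Rodrigues vector formula, independent of the
# package's matrix construction.
rotation_about_axis_test <- function(axis, angle) {
  cbind(rodrigues_rotate(c(1, 0, 0), axis, angle),
        rodrigues_rotate(c(0, 1, 0), axis, angle),
        rodrigues_rotate(c(0, 0, 1), axis, angle))
}

# Exact line integral of a piecewise-constant voxel field along a ray:
# collects every voxel-plane crossing and sums value * segment length.
# Independent of the package's midpoint-rule integrator.
exact_voxel_integral <- function(values, spacing, origin, ray_origin, dir,
                                 t_lo = -1e6, t_hi = 1e6) {
  dm <- dim(values)
  ts <- c(t_lo, t_hi)
  for (k in 1:3) {
    if (abs(dir[k]) < 1e-14) next
    planes <- origin[k] + (0:dm[k]) * spacing
    ts <- c(ts, (planes - ray_origin[k]) / dir[k])
  }
  ts <- sort(unique(pmax(t_lo, pmin(t_hi, ts))))
  total <- 0
  for (m in seq_len(length(ts) - 1)) {
    tm <- (ts[m] + ts[m + 1]) / 2
    p <- ray_origin + tm * dir
    idx <- floor((p - origin) / spacing)
    if (any(idx < 0) || any(idx >= dm)) next
    total <- total + values[idx[1] + 1, idx[2] + 1, idx[3] + 1] *
      (ts[m + 1] - ts[m])
  }
  total
}

# Monte-Carlo chord length of a ray through a finite capped cylinder:
# dense sampling of the inside-indicator along the ray.
mc_cylinder_chord <- function(center, axis, radius, half_length,
                              ray_origin, dir, t_range = c(-200, 200),
                              n = 400000L) {
  a <- axis / sqrt(sum(axis^2))
  ts <- seq(t_range[1], t_range[2], length.out = n)
  dt <- ts[2] - ts[1]
  inside <- vapply(ts, function(t) {
    p <- ray_origin + t * dir - center
    ax <- sum(p * a)
    if (abs(ax) > half_length) return(FALSE)
    sum((p - ax * a)^2) <= radius^2
  }, logical(1))
  sum(inside) * dt
}
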