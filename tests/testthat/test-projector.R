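# Chord factor, line integrals, Beer-Lambert transmission, cylinder projector.

teflon <- function() fiber_scatterer(c(1, 0, 0), 1.5, 0.3,
                                     radius = 1.79, length = 15)

test_that("chord factor is 1 perpendicular, symmetric, and saturates at the cap", {
  fib <- teflon()
  expect_equal(chord_factor(fib, c(0, 0, 1)), 1)
  expect_equal(chord_factor(fib, c(0, 1, 0)), 1)

  # symmetric about the perpendicular: C(gamma) = C(pi - gamma)
  for (g in c(0.2, 0.7, 1.2)) {
    r1 <- c(cos(g), 0, sin(g))
    r2 <- c(cos(pi - g), 0, sin(pi - g))
    expect_equal(chord_factor(fib, r1), chord_factor(fib, r2),
                 tolerance = 1e-12)
  }

  # monotone non-decreasing as the ray tilts from perpendicular to the axis
  gammas <- seq(pi / 2, 0.01, length.out = 50)
  C <- vapply(gammas, function(g)
    chord_factor(fib, c(cos(g), 0, sin(g))), numeric(1))
  expect_true(all(diff(C) >= -1e-12))

  # cap: length / ((pi/4) * diameter) for a near-axial ray
  cap <- 15 / ((pi / 4) * 2 * 1.79)
  expect_equal(chord_factor(fib, c(1, 0, 0)), cap, tolerance = 1e-12)
  expect_equal(cap, 5.3348, tolerance = 1e-4)

  # eigenvalues are irrelevant to C
  fib2 <- fiber_scatterer(c(1, 0, 0), 9, 0.1, radius = 1.79, length = 15)
  expect_equal(chord_factor(fib2, c(cos(0.4), 0, sin(0.4))),
               chord_factor(fib, c(cos(0.4), 0, sin(0.4))))

  expect_error(chord_factor(fiber_scatterer(c(1, 0, 0), 1, 0.5), c(0, 0, 1)),
               "C = 1")
})

test_that("point contribution composes the orientation term with the chord factor", {
  ctx <- ray_context(c(0, 0, 1), c(1, 0, 0))
  fib <- teflon()
  expect_equal(point_contribution(fib, ctx, use_chord = FALSE),
               darkfield_point_signal(fib, ctx))
  # fiber tilted into the beam: chord scaling raises the signal
  tilted <- fiber_scatterer(c(cos(1.2), 0, sin(1.2)), 1.5, 0.3,
                            radius = 1.79, length = 15)
  expect_gt(point_contribution(tilted, ctx, use_chord = TRUE),
            point_contribution(tilted, ctx, use_chord = FALSE))
  # isotropic eigenvalues: the signal varies only through C
  iso <- fiber_scatterer(c(cos(1.2), 0, sin(1.2)), 1.5, 1.5,
                         radius = 1.79, length = 15)
  expect_equal(point_contribution(iso, ctx, use_chord = TRUE),
               1.5 * chord_factor(iso, c(0, 0, 1)), tolerance = 1e-12)
})

test_that("voxel phantom validates its scatter invariants", {
  d_iso <- array(1, c(2, 2, 2))
  expect_s3_class(voxel_phantom(d_iso), "voxel_phantom")
  expect_error(voxel_phantom(array(-1, c(2, 2, 2))), "non-negative")
  da <- array(0, c(2, 2, 2)); da[1, 1, 1] <- -2
  fibs <- array(NA_real_, c(2, 2, 2, 3)); fibs[1, 1, 1, ] <- c(1, 0, 0)
  expect_error(voxel_phantom(d_iso, da, fibs), "d_iso \\+ d_aniso")
  da[1, 1, 1] <- -0.5
  expect_s3_class(voxel_phantom(d_iso, da, fibs), "voxel_phantom")
  # anisotropy without a direction is rejected
  expect_error(voxel_phantom(d_iso, da), "fiber")
})

test_that("line integral: empty phantom, homogeneous slab, and additivity", {
  view <- circle_trajectory(0, 360, 90, 600, 1200, "in_plane")$views[[1]]
  empty <- voxel_phantom(array(0, c(4, 4, 4)), spacing = 1,
                         origin = c(-2, -2, -2))
  li <- line_integral(empty, view, c(0.1, 0.2, 50), c(0, 0, -1))
  expect_identical(li, 0)
  expect_identical(transmit(li), 1)

  # homogeneous isotropic cube, axis-aligned ray: q * chord
  q <- 0.07
  cube <- voxel_phantom(array(q, c(8, 8, 8)), spacing = 0.5,
                        origin = c(-2, -2, -2))
  li <- line_integral(cube, view, c(0.3, -0.4, 50), c(0, 0, -1),
                      step = 0.5 / 4)
  expect_equal(li, q * 4, tolerance = 0.01 * q * 4)

  # ray fully outside the grid
  expect_identical(
    line_integral(cube, view, c(10, 0, 50), c(0, 0, -1)), 0)

  # two stacked slabs integrate to the sum of the single-slab integrals
  v1 <- array(0, c(4, 4, 8)); v1[, , 1:4] <- 0.2
  v2 <- array(0, c(4, 4, 8)); v2[, , 5:8] <- 0.5
  both <- v1 + v2
  orig <- c(-2, -2, -4)
  i1 <- line_integral(voxel_phantom(v1, spacing = 1, origin = orig),
                      view, c(0, 0, 50), c(0, 0, -1), step = 0.2)
  i2 <- line_integral(voxel_phantom(v2, spacing = 1, origin = orig),
                      view, c(0, 0, 50), c(0, 0, -1), step = 0.2)
  i12 <- line_integral(voxel_phantom(both, spacing = 1, origin = orig),
                       view, c(0, 0, 50), c(0, 0, -1), step = 0.2)
  expect_equal(i12, i1 + i2, tolerance = 1e-9)
  expect_equal(i12, 0.2 * 4 + 0.5 * 4, tolerance = 0.01 * i12)
})

test_that("line integral converges to the exact traversal with ~first-order error", {
  # heterogeneous phantom + oblique ray, checked against an exact
  # plane-crossing traversal oracle
  set.seed(21)
  vals <- array(runif(6 * 6 * 6, 0, 1), c(6, 6, 6))
  orig <- c(-3, -3, -3)
  ph <- voxel_phantom(vals, spacing = 1, origin = orig)
  view <- circle_trajectory(0, 360, 90, 600, 1200, "in_plane")$views[[1]]

  dirs <- lapply(list(c(0.3, 0.2, -1), c(-0.15, 0.4, -1), c(0.05, -0.3, -1)),
                 function(d) d / sqrt(sum(d^2)))
  # aim each ray through a point near the cube center, starting outside
  anchors <- list(c(0.3, -0.2, 0.1), c(-0.4, 0.13, -0.2), c(0.33, 0.28, 0))
  starts <- mapply(function(d, a) a - 10 * d, dirs, anchors,
                   SIMPLIFY = FALSE)
  exacts <- mapply(function(d, o) exact_voxel_integral(vals, 1, orig, o, d),
                   dirs, starts)
  expect_true(all(exacts > 0.5))  # the rays really cross the cube
  steps <- c(1, 0.5, 0.25, 0.125, 0.0625)
  errs <- sapply(steps, function(st) {
    mean(mapply(function(d, o, ex)
      abs(line_integral(ph, view, o, d, step = st) - ex),
      dirs, starts, exacts))
  })
  # error shrinks roughly linearly with the step (first-order scheme) and
  # reaches sub-percent accuracy at the finest step
  fit <- stats::lm(log(errs) ~ log(steps))
  expect_gt(unname(stats::coef(fit)[2]), 0.5)
  expect_lt(errs[5], errs[1])
  expect_lt(errs[5], 0.01 * mean(exacts))
})

test_that("anisotropic voxels contribute the orientation-dependent value", {
  # single fiber voxel: integral = chord * (d_iso + d_aniso (s.f)^2)
  d_iso <- array(0, c(3, 3, 3)); d_aniso <- array(0, c(3, 3, 3))
  fibs <- array(NA_real_, c(3, 3, 3, 3))
  d_iso[2, 2, 2] <- 1
  d_aniso[2, 2, 2] <- -0.6
  f <- c(1, 1, 0) / sqrt(2)
  fibs[2, 2, 2, ] <- f
  ph <- voxel_phantom(d_iso, d_aniso, fibs, spacing = 1,
                      origin = c(-1.5, -1.5, -1.5))
  view <- circle_trajectory(0, 360, 90, 600, 1200, "in_plane")$views[[1]]
  li <- line_integral(ph, view, c(0, 0, 50), c(0, 0, -1), step = 0.01)
  expected <- 1 * (1 - 0.6 * sum(c(1, 0, 0) * f)^2)
  expect_equal(li, expected, tolerance = 1e-6)
})

test_that("transmission obeys Beer-Lambert with an exact log round-trip", {
  expect_identical(transmit(0), 1)
  expect_equal(transmit(log(2)), 0.5, tolerance = 1e-15)
  v <- c(0, 0.1, 1, 20)
  expect_equal(neg_log(transmit(v)), v, tolerance = 1e-12)
  expect_true(all(transmit(v) > 0 & transmit(v) <= 1))
  expect_error(transmit(-0.1), "non-negative")
  expect_error(neg_log(1.5), "0, 1")
})

test_that("ray-cylinder chords match geometry and a Monte-Carlo oracle", {
  fib <- fiber_scatterer(c(0, 1, 0), 1.4, 1)
  rod <- cylinder_phantom(c(0, 0, 0), c(0, 1, 0), radius = 20,
                          half_length = 100, scatter = fib)
  # perpendicular ray through the axis: chord = diameter
  expect_equal(ray_cylinder_chord(rod, c(0, 0, 500), c(0, 0, -1)), 40,
               tolerance = 1e-10)
  # ray parallel to the axis inside the radius: chord = 2 * half_length
  expect_equal(ray_cylinder_chord(rod, c(5, 500, 3), c(0, -1, 0)), 200,
               tolerance = 1e-10)
  # misses
  expect_identical(ray_cylinder_chord(rod, c(25, 0, 500), c(0, 0, -1)), 0)
  expect_identical(ray_cylinder_chord(rod, c(0, 150, 500), c(0, 0, -1)), 0)

  # oblique rays against the dense-sampling oracle
  set.seed(22)
  for (i in 1:5) {
    axis <- random_unit3()
    rod2 <- cylinder_phantom(c(1, -2, 0.5), axis, radius = 3,
                             half_length = 10,
                             scatter = fiber_scatterer(axis, 1.4, 1))
    o <- c(runif(1, -2, 2), runif(1, -2, 2), 60)
    d <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2), -1)
    d <- d / sqrt(sum(d^2))
    mc <- mc_cylinder_chord(c(1, -2, 0.5), axis, 3, 10, o, d,
                            t_range = c(0, 120), n = 200000L)
    expect_equal(ray_cylinder_chord(rod2, o, d), mc, tolerance = 0.01)
  }
})

test_that("cylinder projection gives chord times point signal, zero off the rod", {
  fib <- fiber_scatterer(c(0, 1, 0), 1.4, 1)
  rod <- cylinder_phantom(c(0, 0, 0), c(0, 1, 0), 20, 100, fib)
  tr <- circle_trajectory(0, 360, 45, 600, 1200, "in_plane")
  det <- list(n_pixels = 7L, pitch = 15)
  row <- project_cylinder(rod, tr$views[[1]], det, beam = "parallel")
  expect_length(row, 7L)
  # outermost pixels (offset 45) miss the radius-20 rod
  expect_identical(row[1], 0)
  expect_identical(row[7], 0)
  # central pixel: chord 40 times the point signal (fiber axial, s in-plane)
  ctx <- ray_context_at(tr$views[[1]], c(0, 0, 0), "parallel")
  expect_equal(row[4], 40 * darkfield_point_signal(fib, ctx),
               tolerance = 1e-9)
  expect_true(all(row >= 0))
  expect_error(project_cylinder(rod, tr$views[[1]],
                                list(n_pixels = 0, pitch = 1)), "detector")
})

test_that("sinograms are non-negative and round-trip through raw + JSON", {
  fib <- fiber_scatterer(c(0.3, 1, 0), 1.4, 1)
  rod <- cylinder_phantom(c(0, 0, 0), c(0.3, 1, 0), 15, 80, fib)
  tr <- circle_trajectory(0, 180, 30, 600, 1200, "in_plane")
  sino <- cylinder_sinogram(rod, tr, list(n_pixels = 9L, pitch = 8),
                            beam = "cone")
  expect_equal(dim(sino$values), c(6L, 9L))
  expect_true(all(sino$values >= 0))
  prefix <- file.path(withr::local_tempdir(), "sino")
  write_sinogram(sino, prefix)
  back <- read_sinogram(prefix)
  expect_equal(back$values, sino$values, tolerance = 1e-6)
  expect_equal(back$omega_deg, sino$omega_deg)
})
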