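test_that("line integrals match closed-form chords and a quadrature oracle", {
  s <- quadric("sphere", c(0, 0, 0), 1, density = 1)
  expect_equal(line_integral(s, c(-5, 0, 0), c(1, 0, 0)), 2)
  expect_equal(line_integral(s, c(-5, 2, 0), c(1, 0, 0)), 0)

  # offset ray through a dense sphere: 2 * rho * sqrt(r^2 - b^2)
  s2 <- quadric("sphere", c(0, 0, 0), 1, density = 2)
  expect_equal(line_integral(s2, c(-5, 0.5, 0), c(1, 0, 0)),
               2 * 2 * sqrt(1 - 0.25))
  # adaptive quadrature of the indicator function along the same ray
  ind <- function(t) 2 * as.numeric((t - 5)^2 + 0.25 <= 1)
  quad <- stats::integrate(function(t) ind(t), 0, 10,
                           subdivisions = 2000L, rel.tol = 1e-10)
  expect_equal(line_integral(s2, c(-5, 0.5, 0), c(1, 0, 0)), quad$value,
               tolerance = 1e-6)

  # oblique unit direction through an ellipsoid vs quadrature
  e <- quadric("ellipsoid", c(0.1, -0.2, 0), c(0.8, 0.5, 0.3),
               density = 1.3)
  dir <- c(2, 1, 0.5); dir <- dir / sqrt(sum(dir^2))
  org <- c(-2, -1.2, -0.4)
  inside <- function(t) {
    p <- outer(t, dir)
    p <- sweep(p, 2, org, "+")
    1.3 * as.numeric(((p[, 1] - 0.1) / 0.8)^2 + ((p[, 2] + 0.2) / 0.5)^2 +
                       (p[, 3] / 0.3)^2 <= 1)
  }
  quad2 <- stats::integrate(inside, 0, 6, subdivisions = 5000L,
                            rel.tol = 1e-9, stop.on.error = FALSE)
  expect_equal(line_integral(e, org, dir), quad2$value, tolerance = 1e-4)

  expect_error(line_integral(s, c(0, 0, 0), c(0, 0, 0)), "direction")
  expect_error(line_integral(s, c(0, 0, 0), c(2, 0, 0)), "unit")
})

test_that("clip planes and cylinders integrate correctly", {
  # half-ellipsoid keeps the upper half: vertical ray sees one semi-axis
  h <- quadric("half_ellipsoid", c(0, 0, 0), c(0.5, 0.5, 0.4), density = 1)
  expect_equal(line_integral(h, c(0, 0, -2), c(0, 0, 1)), 0.4)
  # horizontal ray below the clip plane misses entirely
  expect_equal(line_integral(h, c(-2, 0, -0.1), c(1, 0, 0)), 0)
  # and above it sees the (shrunken) elliptical chord
  above <- line_integral(h, c(-2, 0, 0.2), c(1, 0, 0))
  expect_equal(above, 2 * 0.5 * sqrt(1 - (0.2 / 0.4)^2))

  cyl <- quadric("cylinder", c(0, 0, 0), c(0.3, 0.3, 0.5), density = 2)
  expect_equal(line_integral(cyl, c(-2, 0, 0.4), c(1, 0, 0)), 2 * 0.6)
  expect_equal(line_integral(cyl, c(-2, 0, 0.6), c(1, 0, 0)), 0)
  # axial ray: full height
  expect_equal(line_integral(cyl, c(0.1, 0, -3), c(0, 0, 1)), 2 * 1)
})

test_that("projection is linear in the scene and symmetric for spheres", {
  geom <- projection_geometry(19, 32, 3)
  a <- phantom_scene(list(quadric("sphere", c(0.2, 0, 0), 0.3)))
  b <- phantom_scene(list(quadric("cylinder", c(-0.1, 0.2, 0),
                                  c(0.25, 0.25, 0.8), density = 0.7)))
  ab <- phantom_scene(c(a$primitives, b$primitives))
  expect_equal(project_scene(ab, geom)$data,
               project_scene(a, geom)$data + project_scene(b, geom)$data,
               tolerance = 1e-12)

  expect_equal(project_scene(phantom_scene(list()), geom)$data,
               array(0, c(3, 19, 32)))

  # centered sphere: every angle sees the same profile
  cs <- phantom_scene(list(quadric("sphere", c(0, 0, 0), 0.4)))
  ps <- project_scene(cs, geom)
  expect_equal(ps$data[2, 1, ], ps$data[2, 10, ], tolerance = 1e-12)

  # 0-degree row equals the mirrored 180-degree row for any scene
  off <- project_scene(ab, geom)
  expect_equal(off$data[2, 1, ], rev(off$data[2, 19, ]), tolerance = 1e-9)
})

test_that("per-angle mass is conserved and matches a voxelized projector", {
  scene <- phantom_scene(list(
    quadric("sphere", c(0.15, -0.1, 0), 0.25, density = 1.5),
    quadric("ellipsoid", c(-0.2, 0.1, 0.05), c(0.2, 0.3, 0.15),
            density = 0.8)))
  geom <- projection_geometry(25, 64, 1)
  sino <- project_scene(scene, geom)$data[1, , ]
  sums <- rowSums(sino) * geom$pixel_size
  expect_lt(stats::sd(sums) / mean(sums), 0.01)

  # voxelized rotate-and-sum oracle on a 64^3-equivalent slice grid
  n <- 64L
  xs <- (seq_len(n) - (n + 1) / 2) * (2 / n)
  grid <- expand.grid(x = xs, y = xs)
  # oracle evaluated at z = 0: the ellipsoid cross-section shrinks
  shrink <- 1 - (0.05 / 0.15)^2
  dens <- with(grid,
    1.5 * as.numeric((x - 0.15)^2 + (y + 0.1)^2 <= 0.25^2) +
    0.8 * as.numeric(((x + 0.2) / 0.2)^2 + ((y - 0.1) / 0.3)^2 <= shrink))
  mass_true <- sum(dens) * (2 / n)^2
  expect_equal(mean(sums), mass_true, tolerance = 0.02)
})

test_that("Poisson noise is seeded, unbiased and mean-preserving", {
  p0 <- sinogram_stack(array(0, c(1, 40, 50)))
  n1 <- apply_poisson_noise(p0, flux = 1e6, seed = 42)
  n2 <- apply_poisson_noise(p0, flux = 1e6, seed = 42)
  expect_identical(n1$data, n2$data)
  expect_false(identical(
    n1$data, apply_poisson_noise(p0, flux = 1e6, seed = 43)$data))

  # counts around I0 within 5 standard errors
  counts <- 1e6 * exp(-n1$data)
  se <- sqrt(1e6 / length(counts))
  expect_lt(abs(mean(counts) - 1e6), 5 * se)

  # attenuation estimate unbiased at p = 1 (bias o(1/I0))
  p1 <- array(1, c(1, 250, 400))
  nz <- apply_poisson_noise(sinogram_stack(p1), flux = 1e4, seed = 7)
  lam <- 1e4 * exp(-1)
  se_p <- sqrt(1 / lam / length(p1))  # delta method: sd(p_hat) ~ 1/sqrt(lam)
  expect_lt(abs(mean(nz$data) - 1), 5 * se_p)

  # variance of counts ~ mean of counts on a constant stack
  cts <- round(1e4 * exp(-nz$data))
  expect_equal(stats::var(as.numeric(cts)) / mean(cts), 1, tolerance = 0.05)

  expect_error(apply_poisson_noise(p0, flux = -1), "positive")
})

test_that("corrosion phantom composition and deposit placement", {
  expect_length(corrosion_phantom(n_bubbles = 0, n_deposits = 0,
                                  seed = 1)$primitives, 2L)
  sc <- corrosion_phantom(seed = 5)
  expect_length(sc$primitives, 2 + 3 + 40)
  expect_identical(corrosion_phantom(seed = 5), sc)

  # deposits lie inside the pin cylinder for many seeds
  for (seed in 1:25) {
    sc <- corrosion_phantom(seed = seed)
    pin <- sc$primitives[[1]]
    deposits <- sc$primitives[-(1:5)]
    for (d in deposits) {
      expect_lt(sum(d$center[1:2]^2), pin$semi_axes[1]^2)
      expect_lt(abs(d$center[3] - pin$center[3]), pin$semi_axes[3])
    }
  }
})
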