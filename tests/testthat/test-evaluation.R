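test_that("psnr follows its closed form and symmetry", {
  a <- matrix(0, 4, 4); b <- matrix(0.1, 4, 4)  # MSE 0.01
  expect_equal(psnr(a, b, peak = 1), 20)
  expect_identical(psnr(b, b, peak = 1), Inf)
  set.seed(17)
  x <- matrix(runif(36), 6); y <- matrix(runif(36), 6)
  expect_equal(psnr(x, y, peak = 2),
               10 * log10(4 / mean((x - y)^2)), tolerance = 1e-12)
  expect_equal(psnr(x, y, peak = 1), psnr(y, x, peak = 1))
  expect_error(psnr(x, matrix(0, 2, 2)), "differ")
})

test_that("ssim matches frozen external-reference and closed-form values", {
  set.seed(19)
  a <- matrix(runif(256), 16)
  expect_equal(ssim(a, a), 1)

  # frozen value computed once with an independent reference
  # implementation of the Gaussian-weighted metric (11x11, sigma 1.5,
  # population covariance): a grating against its negative
  x <- 0:23
  g <- outer(sin(2 * pi * x / 6), cos(2 * pi * x / 6))
  expect_equal(ssim(g, -g, peak = 2 * max(g)), 0.1883365581935836,
               tolerance = 1e-9)

  # constants: single-window closed form (structure/contrast terms drop)
  closed <- function(ma, mb, peak)
    (2 * ma * mb + (0.01 * peak)^2) / (ma^2 + mb^2 + (0.01 * peak)^2)
  expect_equal(ssim(matrix(0.3, 16, 16), matrix(0.5, 16, 16), peak = 1),
               closed(0.3, 0.5, 1), tolerance = 1e-12)
  # constant against its negative: negative closed-form value
  expect_equal(ssim(matrix(0.05, 16, 16), matrix(-0.05, 16, 16), peak = 1),
               closed(0.05, -0.05, 1), tolerance = 1e-12)
  expect_lt(ssim(matrix(0.05, 16, 16), matrix(-0.05, 16, 16), peak = 1), 0)
})

test_that("fbp reconstructs density values and positions", {
  # centered disk: interior value equals the density
  sc <- phantom_scene(list(quadric("cylinder", c(0, 0, 0), c(0.4, 0.4, 1),
                                   density = 0.7)))
  s <- project_scene(sc, projection_geometry(181, 128, 1))$data[1, , ]
  rec <- fbp_reconstruct(s)
  expect_equal(rec[64, 64], 0.7, tolerance = 0.01)
  # an off-center disk lands at the right position and value:
  # x = 0.3 -> column ~ 64.5 + 0.3/px, y = -0.2 -> row ~ 64.5 - 0.2/px
  sc2 <- phantom_scene(list(quadric("cylinder", c(0.3, -0.2, 0),
                                    c(0.15, 0.15, 1), density = 1)))
  s2 <- project_scene(sc2, projection_geometry(181, 128, 1))$data[1, , ]
  rec2 <- fbp_reconstruct(s2)
  px <- 2 / 128
  expect_equal(rec2[round(64.5 - 0.2 / px), round(64.5 + 0.3 / px)], 1,
               tolerance = 0.03)
  expect_lt(abs(rec2[round(64.5 + 0.2 / px), round(64.5 - 0.3 / px)]),
            0.03)  # mirrored position is empty space

  z <- fbp_reconstruct(matrix(0, 19, 32))
  expect_true(all(z[!is.na(z)] == 0))
  expect_true(any(is.na(z)))  # field-of-view sentinel
  expect_error(fbp_reconstruct(matrix(0, 5, 8), angles = c(0, 90)),
               "angle count")
})

test_that("reconstruction quality rises with projection count", {
  sc <- phantom_scene(list(
    quadric("sphere", c(0.1, 0, 0), 0.35, density = 1),
    quadric("sphere", c(-0.3, -0.2, 0), 0.12, density = 0.6)))
  full <- project_scene(sc, projection_geometry(721, 128, 1))$data[1, , ]
  noisy <- apply_poisson_noise(full, flux = 1e4, seed = 3)
  truth <- fbp_reconstruct(full)
  scores <- vapply(c(8L, 4L, 2L), function(k) {
    rec <- fbp_reconstruct(downsample_rows(noisy, k))
    masked_quality(rec, truth)$psnr
  }, 0)
  expect_true(all(diff(scores) > 0))  # 91 < 181 < 361 projections
})

test_that("masked metrics exclude sentinel pixels provably", {
  set.seed(23)
  a <- matrix(runif(900), 30); b <- a + 0.05 * matrix(rnorm(900), 30)
  a[1:3, 1:3] <- NA
  q1 <- masked_quality(a, b)
  a2 <- a; a2[is.na(a)] <- 0  # change values underneath the sentinel
  b2 <- b; b2[1:3, 1:3] <- NA
  q2 <- masked_quality(a, b2)
  expect_equal(q1$psnr, q2$psnr)
  expect_equal(q1$ssim, q2$ssim)
  # crop restricted to clean area equals unmasked metrics there
  crop <- list(rows = 15:30, cols = 15:30)
  q3 <- masked_quality(a, b, crop = crop)
  expect_equal(q3$psnr,
               psnr(a[15:30, 15:30], b[15:30, 15:30],
                    peak = diff(range(b[15:30, 15:30]))))
  expect_equal(masked_quality(b, b, crop = crop)$ssim, 1)
})

test_that("the benchmark harness scores held-out heights per method", {
  sim <- simulate_tomogram(n_heights = 12L, n_angles = 181L,
                           detector_width = 64L, seed = 9)
  p <- udnn_init(tiny_config(), 1)
  rep <- run_benchmark(sim$noisy, sim$noiseless,
                       methods = list(cubic = "cubic", oracle = "oracle",
                                      udnn = p),
                       down = 4L, factor = 2L, hold_every = 6L)
  expect_equal(nrow(rep), 2L * 3L)  # heights x methods, sinogram space
  expect_true(all(rep$psnr_db[rep$method == "oracle"] == Inf))
  expect_true(all(is.finite(rep$psnr_db[rep$method != "oracle"])))
  expect_true(all(rep$ssim <= 1))

  # factor divisibility is enforced
  expect_error(run_benchmark(sim$noisy, sim$noiseless, down = 4L,
                             factor = 3L), "divisible")
})
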