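test_that("angular downsampling keeps the arithmetic row sequence", {
  s <- matrix(seq_len(3601 * 2), 3601)
  expect_equal(nrow(downsample_rows(s, 40)), 91L)

  s5 <- matrix(1:10, 5)
  expect_equal(downsample_rows(s5, 2), s5[c(1, 3, 5), ])

  # brute-force index oracle over random sizes
  set.seed(3)
  for (i in 1:20) {
    T <- sample(5:200, 1); k <- sample(1:60, 1)
    kept <- which((seq_len(T) - 1) %% k == 0)  # independent filter
    m <- matrix(rnorm(T * 3), T)
    expect_identical(downsample_rows(m, k), m[kept, , drop = FALSE])
    expect_equal(nrow(downsample_rows(m, k)), floor((T - 1) / k) + 1)
  }
  expect_error(downsample_rows(s5, 0), ">= 1")
})

test_that("patch counts reproduce the full-scale bookkeeping", {
  g40 <- patch_geometry(gap = 40)
  expect_equal(count_patches(3601, g40), 3200L)
  expect_error(count_patches(401, g40), "too short")
  expect_equal(count_patches(721, patch_geometry(gap = 8)), 640L)
})

test_that("training patch rows follow the interleaving layout", {
  g <- patch_geometry(gap = 40, n_out = 1)
  rows <- sinoup:::patch_rows(g, 1L)
  expect_equal(rows$input, 1 + c(0, 40 * (1:10)))
  expect_equal(rows$target[[1]], 1 + seq(20, 380, by = 40))

  g3 <- patch_geometry(gap = 40, n_out = 3)
  rows3 <- sinoup:::patch_rows(g3, 1L)
  expect_equal(rows3$target[[1]], 1 + seq(10, 370, by = 40))
  expect_equal(rows3$target[[2]], 1 + seq(20, 380, by = 40))
  expect_equal(rows3$target[[3]], 1 + seq(30, 390, by = 40))

  expect_error(patch_geometry(gap = 9, n_out = 1), "divisible")

  # ramp sinogram: values equal their row indices, exhaustively at T = 450
  G <- matrix(seq_len(450), 450, 3)
  g8 <- patch_geometry(gap = 8, n_out = 3)
  for (p in extract_training_patches(G, g8, stride = 37L)) {
    rows <- sinoup:::patch_rows(g8, p$start)
    expect_equal(p$input[, 1], rows$input)
    for (ch in 1:3) expect_equal(p$target[, 1, ch], rows$target[[ch]])
  }
  expect_length(extract_training_patches(matrix(1, 90, 2),
                                         patch_geometry(gap = 8)), 9L)
})

test_that("inference tiling covers all gaps with 10-row overlaps", {
  expect_equal(tile_starts(11), 1L)
  expect_length(tile_starts(91), 81L)
  expect_error(tile_starts(10), "at least")
})

test_that("overlap-average merging matches a brute-force accumulator", {
  set.seed(5)
  L <- 15L; W <- 6L; n_out <- 2L
  starts <- tile_starts(L)
  preds <- lapply(starts, function(s) array(rnorm(10 * W * n_out),
                                            c(10, W, n_out)))
  merged <- merge_predictions(preds, starts, L)

  acc <- array(0, c(L - 1, W, n_out)); cnt <- array(0, c(L - 1, W, n_out))
  for (i in seq_along(starts)) for (r in 1:10) {
    gap <- starts[i] + r - 1
    acc[gap, , ] <- acc[gap, , ] + preds[[i]][r, , ]
    cnt[gap, , ] <- cnt[gap, , ] + 1
  }
  expect_equal(merged, acc / cnt, tolerance = 1e-12)

  # single window passes through unchanged
  one <- list(array(rnorm(10 * W * 1), c(10, W, 1)))
  expect_equal(merge_predictions(one, 1L, 11L), one[[1]])

  # constant predictions merge to the constant
  const <- lapply(starts, function(s) array(2.5, c(10, W, 1)))
  expect_true(all(merge_predictions(const, starts, L) == 2.5))

  expect_error(merge_predictions(preds[1:3], starts[1:2], L), "align")
})

test_that("interlacing weaves channels and inverts downsampling", {
  inp <- matrix(rnorm(91 * 4), 91)
  mid1 <- array(rnorm(90 * 4), c(90, 4, 1))
  up2 <- interlace_rows(inp, mid1)
  expect_equal(nrow(up2), 181L)
  expect_equal(up2[seq(1, 181, 2), ], inp)
  expect_identical(downsample_rows(up2, 2L), inp)

  mid3 <- array(rnorm(90 * 4 * 3), c(90, 4, 3))
  up4 <- interlace_rows(inp, mid3)
  expect_equal(nrow(up4), 361L)
  for (ch in 1:3)
    expect_equal(up4[1 + ch + 4 * (0:89), ], mid3[, , ch])
  expect_identical(downsample_rows(up4, 4L), inp)

  expect_error(interlace_rows(inp, mid1[1:10, , , drop = FALSE]), "rows")
})

test_that("patch normalization is an exact invertible affine map", {
  x <- matrix(runif(44, 2, 7), 11)
  nz <- normalize_patch(x)
  expect_equal(range(nz$x), c(0, 1))
  expect_equal(denormalize_patch(nz$x, nz$params), x, tolerance = 1e-12)

  # already spanning [0, 1]: identity parameters
  y <- matrix(c(0, 1, runif(42)), 11)
  ny <- normalize_patch(y)
  expect_equal(ny$params$offset, 0)
  expect_equal(ny$params$scale, 1)

  # constant patch: flagged degenerate, round trip exact
  cst <- matrix(3.3, 5, 5)
  nc <- normalize_patch(cst)
  expect_true(nc$params$degenerate)
  expect_true(all(nc$x == 0))
  expect_identical(denormalize_patch(nc$x, nc$params), cst)
})

test_that("iteration sampling is balanced, shuffled and seeded", {
  plan <- sample_iteration_plan(rep(200L, 3), 100L,
                                patch_geometry(gap = 8), seed = 4)
  expect_equal(nrow(plan), 300L)
  # each iteration visits every sinogram exactly once
  expect_true(all(tapply(plan$sino, plan$iteration,
                         function(s) identical(sort(s), 1:3))))
  expect_equal(unname(table(plan$sino)), rep(100L, 3), ignore_attr = TRUE)
  expect_identical(plan, sample_iteration_plan(rep(200L, 3), 100L,
                                               patch_geometry(gap = 8),
                                               seed = 4))
  # starts stay within the admissible window
  expect_true(all(plan$start >= 1 & plan$start <= 200 - 81))
})
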