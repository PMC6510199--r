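#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE(a, b))` in dB. `NA` pixels (e.g. the sentinel
#' outside a reconstruction's field of view) are excluded pairwise; a zero
#' MSE yields `Inf`.
#'
#' @param a,b Numeric arrays of identical shape (estimate, ground truth).
#' @param peak Peak signal value; default is the data range of `b`.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, peak = NULL) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("shapes differ")
  ok <- !(is.na(a) | is.na(b))
  if (!any(ok)) stop("no overlapping non-missing pixels")
  if (is.null(peak)) peak <- diff(range(b[ok]))
  mse <- mean((a[ok] - b[ok])^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

gaussian_kernel2d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid-mode 2-D correlation of a matrix with a small kernel
filter_valid <- function(m, k) {
  out <- cpp_conv2d_forward(array(m, c(dim(m), 1L)), as.numeric(k),
                            0, nrow(k), ncol(k), 0L, 0L)
  out[, , 1L]
}

#' Structural similarity index
#'
#' Mean local SSIM with Gaussian-weighted 11x11 windows (sigma 1.5) and the
#' standard stabilizers `C1 = (k1 * peak)^2`, `C2 = (k2 * peak)^2`. Border
#' pixels without a full window are not scored. Windows touching an `NA`
#' (sentinel) pixel are excluded from the mean; the sentinel values
#' themselves never influence the score.
#'
#' @param a,b Numeric matrices of identical shape.
#' @param peak Dynamic range of the data; default is the range of `b`.
#' @param k1,k2 Stabilizer constants (0.01, 0.03).
#' @param window Window size (default 11) and `sigma` its Gaussian width.
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, peak = NULL, k1 = 0.01, k2 = 0.03, window = 11L,
                 sigma = 1.5) {
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  if (any(dim(a) < window)) stop("image smaller than the SSIM window")
  bad <- is.na(a) | is.na(b)
  if (is.null(peak)) {
    rng <- range(b[!bad])
    peak <- diff(rng)
    if (peak <= 0) peak <- 1
  }
  a0 <- a; b0 <- b
  a0[bad] <- 0; b0[bad] <- 0
  k <- gaussian_kernel2d(window, sigma)
  c1 <- (k1 * peak)^2; c2 <- (k2 * peak)^2
  mu_a <- filter_valid(a0, k); mu_b <- filter_valid(b0, k)
  saa <- filter_valid(a0 * a0, k) - mu_a^2
  sbb <- filter_valid(b0 * b0, k) - mu_b^2
  sab <- filter_valid(a0 * b0, k) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + c1) * (2 * sab + c2)) /
         ((mu_a^2 + mu_b^2 + c1) * (saa + sbb + c2))
  if (any(bad)) {
    touch <- filter_valid(matrix(as.numeric(bad), nrow(a)),
                          matrix(1, window, window))
    map <- map[touch == 0]
    if (length(map) == 0) stop("no SSIM window free of missing pixels")
  }
  mean(map)
}

ramlak_kernel <- function(n, tau) {
  # spatial-domain Ram-Lak samples: h(0) = 1/(4 tau^2),
  # h(k odd) = -1/(pi k tau)^2, h(k even) = 0, wrapped for the FFT
  h <- numeric(n)
  h[1L] <- 1 / (4 * tau^2)
  ks <- seq(1L, n %/% 2L)
  odd <- ks[ks %% 2L == 1L]
  h[1L + odd] <- -1 / (pi * odd * tau)^2
  h[n + 1L - odd] <- -1 / (pi * odd * tau)^2
  h
}

#' Filtered back projection of one sinogram
#'
#' Plain parallel-beam FBP: Ram-Lak ramp filtering of each projection row
#' in the frequency domain (power-of-two zero padding) followed by
#' linearly interpolated backprojection over all angles. Angles spanning
#' the closed interval 0-180 degrees are trapezoid-weighted so the
#' duplicated 0/180 pair is not double counted. Pixels outside the
#' inscribed circular field of view are set to `NA` (the sentinel honoured
#' by [psnr()] and [ssim()]).
#'
#' @param s Theta x W sinogram matrix.
#' @param angles Projection angles in degrees, one per row; default assumes
#'   an even 0-180 sweep.
#' @param pixel_size Scene units per detector pixel (default `2 / W`).
#' @param mask Apply the circular field-of-view sentinel (default TRUE).
#' @return W x W reconstruction matrix; element (i, j) is the point
#'   x = (j - c) * pixel_size, y = (i - c) * pixel_size, c = (W + 1) / 2.
#' @export
fbp_reconstruct <- function(s, angles = NULL, pixel_size = 2 / ncol(s),
                            mask = TRUE) {
  stopifnot(is.matrix(s))
  ta <- nrow(s); W <- ncol(s)
  if (is.null(angles)) angles <- projection_angles(ta)
  if (length(angles) != ta)
    stop("angle count (", length(angles), ") != sinogram rows (", ta, ")")
  n <- 2^ceiling(log2(2L * W))
  H <- Re(stats::fft(ramlak_kernel(n, pixel_size)))
  q <- matrix(0, ta, W)
  for (t in seq_len(ta)) {
    p <- c(s[t, ], numeric(n - W))
    f <- Re(stats::fft(stats::fft(p) * H, inverse = TRUE)) / n
    q[t, ] <- f[seq_len(W)] * pixel_size
  }
  cgrid <- (W + 1) / 2
  x <- ((seq_len(W)) - cgrid) * pixel_size
  X <- matrix(x, W, W, byrow = TRUE)   # x varies along columns
  Y <- matrix(x, W, W)                 # y varies along rows
  recon <- matrix(0, W, W)
  span <- diff(range(angles))
  wts <- rep(if (ta > 1) (span * pi / 180) / (ta - 1) else pi, ta)
  if (abs(span - 180) < 1e-9) wts[c(1L, ta)] <- wts[c(1L, ta)] / 2
  for (t in seq_len(ta)) {
    th <- angles[t] * pi / 180
    sdet <- -X * sin(th) + Y * cos(th)
    idx <- sdet / pixel_size + cgrid
    i0 <- floor(idx)
    frac <- idx - i0
    i0c <- pmin(pmax(i0, 1L), W)
    i1c <- pmin(pmax(i0 + 1L, 1L), W)
    inside <- (i0 >= 1L) & (i0 < W)
    vals <- (q[t, i0c] * (1 - frac) + q[t, i1c] * frac) * inside
    recon <- recon + wts[t] * vals
  }
  if (mask) {
    r <- (W / 2) * pixel_size
    recon[X^2 + Y^2 > r^2] <- NA_real_
  }
  recon
}

#' Quality metrics on a cropped, sentinel-aware window
#'
#' Scores a reconstruction (or any image) against a reference on a crop,
#' excluding sentinel (`NA`) pixels: they are dropped pairwise from the
#' PSNR and their windows are dropped from the SSIM mean.
#'
#' @param a,b Matrices (estimate, ground truth).
#' @param crop `NULL` for the full frame, or list
#'   `list(rows = i1:i2, cols = j1:j2)`.
#' @param peak Peak for both metrics; default the crop's ground-truth
#'   range.
#' @return List with `psnr`, `ssim`, `n` (scored pixels).
#' @export
masked_quality <- function(a, b, crop = NULL, peak = NULL) {
  if (!is.null(crop)) {
    a <- a[crop$rows, crop$cols, drop = FALSE]
    b <- b[crop$rows, crop$cols, drop = FALSE]
  }
  ok <- !(is.na(a) | is.na(b))
  if (is.null(peak)) {
    peak <- diff(range(b[ok]))
    if (peak <= 0) peak <- 1
  }
  list(psnr = psnr(a, b, peak = peak), ssim = ssim(a, b, peak = peak),
       n = sum(ok))
}

# original-resolution row indices (1-based) reached by upscaling rows kept
# every `down` apart by `factor`; intermediate = not original input rows
upscaled_row_map <- function(n_rows_full, down, factor) {
  if (down %% factor != 0L)
    stop("downsampling factor must be divisible by the upscaling factor")
  kept <- seq(1L, n_rows_full, by = down)
  L <- length(kept)
  up_idx <- 1L + (seq_len(factor * (L - 1L) + 1L) - 1L) * (down %/% factor)
  list(full_rows = up_idx,
       intermediate = which((seq_along(up_idx) - 1L) %% factor != 0L))
}

#' Benchmark upscaling methods against ground truth
#'
#' Reproduces the structure of a held-out sinogram evaluation: every
#' `hold_every`-th height of a fully sampled tomogram is downsampled by
#' `down`, upscaled back by each method and factor, and the predicted
#' intermediate rows are scored against the corresponding rows of the
#' noiseless ground-truth tomogram (sinogram space). Optionally the
#' upscaled sinograms are also reconstructed by filtered back projection
#' and scored against the ground-truth reconstruction on a central crop
#' (reconstruction space).
#'
#' @param noisy,clean [sinogram_stack()]s with identical geometry: the
#'   acquired (noisy) tomogram and its noiseless ground truth. Pass the
#'   same object twice to score against the noisy original.
#' @param methods Named list of methods: each element either the string
#'   `"cubic"`, the string `"oracle"` (intermediate rows copied from the
#'   ground truth; scores an infinite PSNR by construction), or a trained
#'   [udnn_params][udnn_init()] whose `n_out` equals `factor - 1`.
#' @param down Angular downsampling factor emulating the undersampled
#'   acquisition (default 8: 721 rows to 91).
#' @param factor Upscaling factor (must divide `down`).
#' @param hold_every Stride of held-out heights (default 10: heights
#'   1, 11, 21, ...).
#' @param spaces Any of `"sinogram"`, `"reconstruction"`.
#' @param crop_frac Central square fraction used for reconstruction-space
#'   scoring (default 0.5).
#' @return Data frame: method, factor, space, height, psnr_db, ssim, n.
#' @export
run_benchmark <- function(noisy, clean, methods = list(cubic = "cubic"),
                          down = 8L, factor = 2L, hold_every = 10L,
                          spaces = "sinogram", crop_frac = 0.5) {
  stopifnot(inherits(noisy, "sinogram_stack"),
            inherits(clean, "sinogram_stack"),
            identical(dim(noisy$data), dim(clean$data)))
  heights <- seq(1L, dim(noisy$data)[1L], by = hold_every)
  Tfull <- dim(noisy$data)[2L]
  W <- dim(noisy$data)[3L]
  map <- upscaled_row_map(Tfull, down, factor)
  crop <- NULL
  if ("reconstruction" %in% spaces) {
    half <- floor(W * crop_frac / 2)
    ctr <- floor(W / 2)
    crop <- list(rows = (ctr - half):(ctr + half),
                 cols = (ctr - half):(ctr + half))
  }
  rows <- list()
  for (h in heights) {
    G_noisy <- noisy$data[h, , ]
    G_clean <- clean$data[h, , ]
    low <- downsample_rows(G_noisy, down)
    truth_mid <- G_clean[map$full_rows[map$intermediate], , drop = FALSE]
    recon_truth <- if ("reconstruction" %in% spaces)
      fbp_reconstruct(G_clean, clean$angles) else NULL
    for (m in names(methods)) {
      meth <- methods[[m]]
      up <- if (identical(meth, "cubic")) {
        cubic_upscale(low, factor)
      } else if (identical(meth, "oracle")) {
        o <- G_clean[map$full_rows, , drop = FALSE]
        o
      } else {
        stopifnot(inherits(meth, "udnn_params"))
        if (attr(meth, "config")$n_out != factor - 1L)
          stop("model n_out does not match the upscaling factor")
        udnn_upscale(meth, low)
      }
      pred_mid <- up[map$intermediate, , drop = FALSE]
      if ("sinogram" %in% spaces) {
        peak <- diff(range(truth_mid))
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, factor = factor, space = "sinogram", height = h,
          psnr_db = psnr(pred_mid, truth_mid, peak = peak),
          ssim = ssim(pred_mid, truth_mid, peak = peak),
          n = length(truth_mid))
      }
      if ("reconstruction" %in% spaces) {
        rec <- fbp_reconstruct(up, projection_angles(nrow(up)))
        q <- masked_quality(rec, recon_truth, crop = crop)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, factor = factor, space = "reconstruction",
          height = h, psnr_db = q$psnr, ssim = q$ssim, n = q$n)
      }
    }
  }
  do.call(rbind, rows)
}
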