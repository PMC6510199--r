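#' Network architecture configuration
#'
#' Three convolutional layers separated by two rectified linear units map an
#' `n_input x W` patch (one channel) to `n_out` channels of
#' `(n_input - 1) x W` intermediate rows. Padding per layer is solved from
#' the shape contract: the first layer reduces the height by exactly one and
#' all layers preserve the width, so every hidden feature map already has
#' the output's size.
#'
#' @param variant One of `"udnn"`, `"udnn-128"`, `"udnn-32"`, `"udnn-lk"`,
#'   `"udnn-sk"`: the base model (64/32 feature maps, kernels 10x17, 7x13,
#'   7x13), its doubled/halved feature-count variants, and the
#'   larger-kernel (12x19, 9x15, 9x15) / smaller-kernel (8x15, 5x11, 5x11)
#'   variants.
#' @param n_out Output channels (upscaling factor - 1).
#' @param feature_scale Multiplier applied to both feature-map counts, for
#'   reduced desk-scale analogues of the named variants (e.g. 1/8 turns the
#'   128/64 variant into 16/8). Must leave integer counts >= 1.
#' @return Object of class `udnn_config`.
#' @export
udnn_config <- function(variant = c("udnn", "udnn-128", "udnn-32",
                                    "udnn-lk", "udnn-sk"),
                        n_out = 1L, feature_scale = 1) {
  variant <- match.arg(variant)
  spec <- switch(variant,
    "udnn"     = list(n1 = 64L,  n2 = 32L, k = list(c(10L, 17L), c(7L, 13L), c(7L, 13L))),
    "udnn-128" = list(n1 = 128L, n2 = 64L, k = list(c(10L, 17L), c(7L, 13L), c(7L, 13L))),
    "udnn-32"  = list(n1 = 32L,  n2 = 16L, k = list(c(10L, 17L), c(7L, 13L), c(7L, 13L))),
    "udnn-lk"  = list(n1 = 64L,  n2 = 32L, k = list(c(12L, 19L), c(9L, 15L), c(9L, 15L))),
    "udnn-sk"  = list(n1 = 64L,  n2 = 32L, k = list(c(8L, 15L), c(5L, 11L), c(5L, 11L))))
  n1 <- as.integer(spec$n1 * feature_scale)
  n2 <- as.integer(spec$n2 * feature_scale)
  if (n1 < 1L || n2 < 1L || n1 != spec$n1 * feature_scale ||
      n2 != spec$n2 * feature_scale)
    stop("feature_scale must leave integer feature counts >= 1")
  # padding from the shape contract: layer 1 output height = H - 1, width
  # preserved; layers 2-3 preserve both. Needs odd-width kernels, even/odd
  # heights as in the named variants.
  pads <- lapply(seq_along(spec$k), function(i) {
    k <- spec$k[[i]]
    ph <- if (i == 1L) (k[1L] - 2L) %/% 2L else (k[1L] - 1L) %/% 2L
    c(ph, (k[2L] - 1L) %/% 2L)
  })
  structure(list(variant = variant, n1 = n1, n2 = n2, n_out = as.integer(n_out),
                 kernels = spec$k, pads = pads),
            class = "udnn_config")
}

#' @export
print.udnn_config <- function(x, ...) {
  cat(sprintf("udnn_config '%s': features %d/%d, n_out %d\n", x$variant,
              x$n1, x$n2, x$n_out))
  for (i in 1:3)
    cat(sprintf("  layer %d: kernel %dx%d, pad (%d,%d)\n", i,
                x$kernels[[i]][1], x$kernels[[i]][2],
                x$pads[[i]][1], x$pads[[i]][2]))
  invisible(x)
}

#' All named architecture variants
#'
#' @inheritParams udnn_config
#' @return Named list of [udnn_config()]s.
#' @export
udnn_configs <- function(n_out = 1L, feature_scale = 1) {
  variants <- c("udnn", "udnn-128", "udnn-32", "udnn-lk", "udnn-sk")
  stats::setNames(lapply(variants, udnn_config, n_out = n_out,
                         feature_scale = feature_scale), variants)
}

# per-layer channel counts implied by a config
layer_channels <- function(config) {
  list(c(1L, config$n1), c(config$n1, config$n2),
       c(config$n2, config$n_out))
}

#' Initialize network parameters
#'
#' Weights are drawn from a zero-mean Gaussian with standard deviation
#' 0.001 and biases start at zero (the convention of the super-resolution
#' CNN lineage this architecture belongs to); deterministic per seed.
#'
#' @param config A [udnn_config()].
#' @param seed Integer seed.
#' @return Object of class `udnn_params`: list of `w1,b1,w2,b2,w3,b3`,
#'   weight arrays dim (kh, kw, c_in, c_out), with the config attached.
#' @export
udnn_init <- function(config, seed = 1L) {
  ch <- layer_channels(config)
  with_seed(seed, {
    p <- list()
    for (i in 1:3) {
      k <- config$kernels[[i]]
      d <- c(k[1L], k[2L], ch[[i]][1L], ch[[i]][2L])
      p[[paste0("w", i)]] <- array(stats::rnorm(prod(d), 0, 0.001), d)
      p[[paste0("b", i)]] <- numeric(ch[[i]][2L])
    }
    structure(p, config = config, class = "udnn_params")
  })
}

# x: H x W x Cin array; returns Ho x Wo x Cout
conv_layer <- function(x, w, b, pad) {
  d <- dim(w)
  cpp_conv2d_forward(x, as.numeric(w), b, d[1L], d[2L], pad[1L], pad[2L])
}

#' Network forward pass
#'
#' Maps an `H x W` input patch (H >= 11; the network is fully convolutional
#' in height at inference) to `n_out` channels of `(H - 1) x W` predicted
#' intermediate rows: convolution, ReLU, convolution, ReLU, convolution
#' (no final ReLU).
#'
#' @param params A [udnn_params][udnn_init()] object.
#' @param x Input patch: H x W matrix (or H x W x 1 array).
#' @param keep_intermediates Return hidden activations as well (used by the
#'   training backward pass).
#' @return (H - 1) x W x n_out array, or a list of activations when
#'   `keep_intermediates = TRUE`.
#' @export
udnn_forward <- function(params, x, keep_intermediates = FALSE) {
  config <- attr(params, "config")
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1L] + 2L * config$pads[[1L]][1L] < config$kernels[[1L]][1L] ||
      dim(x)[1L] < 2L)
    stop("input height too small for the first-layer kernel")
  a0 <- x
  z1 <- conv_layer(a0, params$w1, params$b1, config$pads[[1L]])
  a1 <- pmax(z1, 0)
  z2 <- conv_layer(a1, params$w2, params$b2, config$pads[[2L]])
  a2 <- pmax(z2, 0)
  out <- conv_layer(a2, params$w3, params$b3, config$pads[[3L]])
  if (keep_intermediates) list(out = out, a0 = a0, a1 = a1, a2 = a2)
  else out
}

# batched forward over a minibatch: xb is (H, W, B), one channel per patch;
# shares a single GEMM per layer across the batch
udnn_forward_batch <- function(params, xb, keep_intermediates = FALSE) {
  config <- attr(params, "config")
  d <- dim(xb)
  x4 <- array(xb, c(d[1L], d[2L], 1L, d[3L]))
  cv <- function(x, w, b, pad) {
    dw <- dim(w)
    cpp_conv2d_forward_batch(x, as.numeric(w), b, dw[1L], dw[2L],
                             pad[1L], pad[2L])
  }
  z1 <- cv(x4, params$w1, params$b1, config$pads[[1L]])
  a1 <- pmax(z1, 0)
  z2 <- cv(a1, params$w2, params$b2, config$pads[[2L]])
  a2 <- pmax(z2, 0)
  out <- cv(a2, params$w3, params$b3, config$pads[[3L]])
  if (keep_intermediates) list(out = out, a0 = x4, a1 = a1, a2 = a2)
  else out
}

# batch gradient (summed over the minibatch) given dL/dout
udnn_backward_batch <- function(params, fw, dout) {
  config <- attr(params, "config")
  bk <- function(x, w, dy, pad) {
    dw <- dim(w)
    cpp_conv2d_backward_batch(x, as.numeric(w), dy, dw[1L], dw[2L],
                              pad[1L], pad[2L])
  }
  bw3 <- bk(fw$a2, params$w3, dout, config$pads[[3L]])
  da2 <- bw3$dx * (fw$a2 > 0)
  bw2 <- bk(fw$a1, params$w2, da2, config$pads[[2L]])
  da1 <- bw2$dx * (fw$a1 > 0)
  bw1 <- bk(fw$a0, params$w1, da1, config$pads[[1L]])
  list(w1 = array(bw1$dw, dim(params$w1)), b1 = as.numeric(bw1$db),
       w2 = array(bw2$dw, dim(params$w2)), b2 = as.numeric(bw2$db),
       w3 = array(bw3$dw, dim(params$w3)), b3 = as.numeric(bw3$db))
}

# gradient of the scalar loss w.r.t. all parameters, given dL/dout;
# fw is udnn_forward(..., keep_intermediates = TRUE)
udnn_backward <- function(params, fw, dout) {
  config <- attr(params, "config")
  bw3 <- cpp_conv2d_backward(fw$a2, as.numeric(params$w3), dout,
                             dim(params$w3)[1L], dim(params$w3)[2L],
                             config$pads[[3L]][1L], config$pads[[3L]][2L])
  da2 <- bw3$dx * (fw$a2 > 0)  # ReLU subgradient: a2 > 0 iff z2 > 0
  bw2 <- cpp_conv2d_backward(fw$a1, as.numeric(params$w2), da2,
                             dim(params$w2)[1L], dim(params$w2)[2L],
                             config$pads[[2L]][1L], config$pads[[2L]][2L])
  da1 <- bw2$dx * (fw$a1 > 0)
  bw1 <- cpp_conv2d_backward(fw$a0, as.numeric(params$w1), da1,
                             dim(params$w1)[1L], dim(params$w1)[2L],
                             config$pads[[1L]][1L], config$pads[[1L]][2L])
  list(w1 = array(bw1$dw, dim(params$w1)), b1 = as.numeric(bw1$db),
       w2 = array(bw2$dw, dim(params$w2)), b2 = as.numeric(bw2$db),
       w3 = array(bw3$dw, dim(params$w3)), b3 = as.numeric(bw3$db))
}

#' Upscale a sinogram with a trained network
#'
#' The full inference pipeline: tile the undersampled sinogram into
#' overlapping 11-row windows, min-max normalize each window, run the
#' network, denormalize, average overlapping predictions per inter-row gap,
#' and interlace the result with the input rows. An L-row sinogram becomes
#' `(n_out + 1) * (L - 1) + 1` rows.
#'
#' @param params Trained [udnn_params][udnn_init()].
#' @param sino L x W sinogram matrix (L >= n_input).
#' @param normalize Apply per-window min-max normalization (default TRUE).
#' @param n_input Window height used for tiling (default 11, matching the
#'   training patch geometry).
#' @return Upscaled sinogram matrix; original rows are preserved verbatim
#'   at their interlaced positions.
#' @export
udnn_upscale <- function(params, sino, normalize = TRUE, n_input = 11L) {
  starts <- tile_starts(nrow(sino), n_input)
  n_in <- n_input
  preds <- lapply(starts, function(s) {
    win <- sino[s + 0:(n_in - 1L), , drop = FALSE]
    if (normalize) {
      nz <- normalize_patch(win)
      denormalize_patch(udnn_forward(params, nz$x), nz$params)
    } else {
      udnn_forward(params, win)
    }
  })
  mid <- merge_predictions(preds, starts, nrow(sino))
  interlace_rows(sino, mid)
}

#' Save network parameters to an HDF5 checkpoint
#'
#' One dataset per tensor plus the architecture stored alongside.
#'
#' @param params A [udnn_params][udnn_init()].
#' @param path Output `.h5` file (overwritten).
#' @return `path`, invisibly.
#' @export
save_udnn <- function(params, path) {
  config <- attr(params, "config")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (nm in names(params)) rhdf5::h5write(params[[nm]], path, nm)
  rhdf5::h5write(config$variant, path, "variant")
  rhdf5::h5write(config$n_out, path, "n_out")
  rhdf5::h5write(c(config$n1, config$n2), path, "features")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load network parameters from an HDF5 checkpoint
#'
#' @param path Checkpoint written by [save_udnn()].
#' @return A [udnn_params][udnn_init()] object.
#' @export
load_udnn <- function(path) {
  variant <- as.character(rhdf5::h5read(path, "variant"))
  n_out <- as.integer(rhdf5::h5read(path, "n_out"))
  feats <- as.integer(rhdf5::h5read(path, "features"))
  config <- udnn_config(variant, n_out = n_out)
  config$n1 <- feats[1L]; config$n2 <- feats[2L]
  p <- list()
  for (nm in c("w1", "b1", "w2", "b2", "w3", "b3")) {
    v <- rhdf5::h5read(path, nm)
    p[[nm]] <- if (grepl("^b", nm)) as.numeric(v) else v
  }
  rhdf5::h5closeAll()
  structure(p, config = config, class = "udnn_params")
}
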