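#' Cubic-interpolation upscaling baseline
#'
#' Upscales a sinogram along the projection (theta) axis by independent 1-D
#' cubic interpolation of each detector column, evaluated at `factor - 1`
#' equispaced positions per inter-row gap. Original rows are preserved
#' exactly at their interlaced slots, so downsampling the result by
#' `factor` returns the input bit-exactly.
#'
#' @param s L x W sinogram matrix, L >= 4 (a cubic spline is
#'   underdetermined below that).
#' @param factor Integer upscaling factor (>= 2).
#' @param method Spline flavour: `"natural"` (natural boundary conditions,
#'   default), `"fmm"` (Forsythe-Malcolm-Moler end conditions), or
#'   `"catmullrom"` (local Catmull-Rom cubic with one-sided end tangents).
#' @return (factor * (L - 1) + 1) x W matrix.
#' @export
cubic_upscale <- function(s, factor = 2L,
                          method = c("natural", "fmm", "catmullrom")) {
  method <- match.arg(method)
  stopifnot(is.matrix(s))
  L <- nrow(s); factor <- as.integer(factor)
  if (L < 4L) stop("cubic interpolation needs at least 4 rows, got ", L)
  if (factor < 2L) stop("factor must be >= 2")
  xs <- seq_len(L)
  xout <- seq(1, L, by = 1 / factor)
  out <- if (method == "catmullrom") {
    catmullrom_columns(s, factor)
  } else {
    apply(s, 2L, function(col)
      stats::spline(xs, col, xout = xout, method = method)$y)
  }
  out[seq(1L, nrow(out), by = factor), ] <- s  # knots verbatim
  out
}

# vectorized Catmull-Rom over all columns; end segments use one-sided
# tangents (endpoint replication)
catmullrom_columns <- function(s, factor) {
  L <- nrow(s)
  ext <- rbind(2 * s[1L, ] - s[2L, ], s, 2 * s[L, ] - s[L - 1L, ])
  out <- matrix(0, factor * (L - 1L) + 1L, ncol(s))
  out[seq(1L, nrow(out), by = factor), ] <- s
  for (j in seq_len(factor - 1L)) {
    t <- j / factor
    w <- 0.5 * c(-t * (1 - t)^2,
                 2 - 5 * t^2 + 3 * t^3,
                 t * (1 + 4 * t - 3 * t^2),
                 -t^2 * (1 - t))
    idx <- seq_len(L - 1L)
    vals <- w[1L] * ext[idx, , drop = FALSE] +
            w[2L] * ext[idx + 1L, , drop = FALSE] +
            w[3L] * ext[idx + 2L, , drop = FALSE] +
            w[4L] * ext[idx + 3L, , drop = FALSE]
    out[factor * (idx - 1L) + 1L + j, ] <- vals
  }
  out
}
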