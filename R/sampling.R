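#' Angular downsampling of a sinogram
#'
#' Keeps every `factor`-th projection row starting from the first, emulating
#' an undersampled acquisition: a 3601-row sinogram downsampled by 40 keeps
#' 91 rows. The resulting row count is `floor((T - 1) / factor) + 1`.
#'
#' @param x A theta-by-width sinogram matrix or a [sinogram_stack()].
#' @param factor Integer downsampling factor (>= 1).
#' @return Object of the same type with the reduced row count.
#' @export
downsample_rows <- function(x, factor) {
  if (factor < 1) stop("factor must be >= 1")
  factor <- as.integer(factor)
  if (inherits(x, "sinogram_stack")) {
    keep <- seq(1L, dim(x$data)[2L], by = factor)
    return(sinogram_stack(x$data[, keep, , drop = FALSE],
                          angles = x$angles[keep],
                          provenance = "downscaled"))
  }
  stopifnot(is.matrix(x))
  x[seq(1L, nrow(x), by = factor), , drop = FALSE]
}

#' Training-patch geometry
#'
#' Describes how input/target rows are drawn from a fully sampled sinogram:
#' a window of `gap * (n_input - 1) + 1` rows supplies `n_input` input rows
#' spaced `gap` apart, and `n_out` channels of `n_input - 1` ground-truth
#' rows at the evenly spaced intermediate offsets. The defaults
#' (`gap = 40`, `n_input = 11`, `n_out = 1`) give 401-row windows with
#' 11 input and 10 target rows, the 40:1 angular spacing of a 91-of-3601
#' acquisition. `gap` must be divisible by `n_out + 1`.
#'
#' @param gap Row spacing between consecutive input rows.
#' @param n_input Number of input rows per patch.
#' @param n_out Output channels = upscaling factor - 1.
#' @return Object of class `patch_geometry`.
#' @export
patch_geometry <- function(gap = 40L, n_input = 11L, n_out = 1L) {
  gap <- as.integer(gap); n_input <- as.integer(n_input)
  n_out <- as.integer(n_out)
  stopifnot(gap >= 1, n_input >= 2, n_out >= 1)
  if (gap %% (n_out + 1L) != 0L)
    stop("gap must be divisible by n_out + 1")
  structure(list(gap = gap, n_input = n_input, n_out = n_out,
                 window = gap * (n_input - 1L) + 1L,
                 step = gap %/% (n_out + 1L)),
            class = "patch_geometry")
}

#' Number of training patches per sinogram
#'
#' With stride 1, window starts run over rows `1 .. T - window` (1-based),
#' so the count is `T - window`: 3200 patches for a 3601-row sinogram with
#' the default 401-row window. The final row (the 180-degree duplicate of
#' row 1) is never a window start.
#'
#' @param n_rows Rows T of the fully sampled sinogram.
#' @param geom A [patch_geometry()].
#' @param stride Start stride (default 1).
#' @return Integer patch count.
#' @export
count_patches <- function(n_rows, geom = patch_geometry(), stride = 1L) {
  if (n_rows < geom$window + 1L)
    stop("sinogram too short: need at least ", geom$window + 1L, " rows")
  length(seq(1L, n_rows - geom$window, by = stride))
}

# 1-based input/target row indices of the patch starting at `start`
patch_rows <- function(geom, start) {
  input <- start + geom$gap * (0:(geom$n_input - 1L))
  target <- lapply(seq_len(geom$n_out), function(ch)
    start + geom$gap * (0:(geom$n_input - 2L)) + geom$step * ch)
  list(input = input, target = target)
}

#' Extract one training patch pair
#'
#' @param G Fully sampled sinogram matrix (T x W).
#' @param start Window start row (1-based, `1 .. T - window`).
#' @param geom A [patch_geometry()].
#' @return List with `input` (n_input x W matrix), `target`
#'   ((n_input - 1) x W x n_out array) and `start`.
#' @export
training_patch <- function(G, start, geom = patch_geometry()) {
  rows <- patch_rows(geom, start)
  target <- array(0, c(geom$n_input - 1L, ncol(G), geom$n_out))
  for (ch in seq_len(geom$n_out))
    target[, , ch] <- G[rows$target[[ch]], , drop = FALSE]
  list(input = G[rows$input, , drop = FALSE], target = target,
       start = start)
}

#' Extract all training patch pairs of a sinogram
#'
#' @inheritParams training_patch
#' @inheritParams count_patches
#' @return List of [training_patch()] results, one per window start.
#' @export
extract_training_patches <- function(G, geom = patch_geometry(),
                                     stride = 1L) {
  n <- count_patches(nrow(G), geom, stride)  # validates length
  starts <- seq(1L, nrow(G) - geom$window, by = stride)
  lapply(starts, function(s) training_patch(G, s, geom))
}

#' Tile an undersampled sinogram into overlapping inference windows
#'
#' Windows of `n_input` consecutive rows with stride 1: starts
#' `1 .. L - n_input + 1`, each overlapping the next by `n_input - 1` rows.
#'
#' @param L Number of rows of the undersampled sinogram.
#' @param n_input Window height (default 11).
#' @return Integer vector of 1-based window starts.
#' @export
tile_starts <- function(L, n_input = 11L) {
  if (L < n_input) stop("need at least ", n_input, " rows, got ", L)
  seq_len(L - n_input + 1L)
}

#' Merge overlapping window predictions by positional averaging
#'
#' Each inference window starting at row `s` predicts the `n_input - 1`
#' inter-row gaps `s .. s + n_input - 2`; a gap covered by several windows
#' receives the mean of their predictions at that position (edge gaps
#' average over fewer windows).
#'
#' @param preds List of predictions aligned with `starts`, each an
#'   (n_input - 1) x W x n_out array.
#' @param starts Window starts from [tile_starts()].
#' @param L Row count of the undersampled input sinogram.
#' @return (L - 1) x W x n_out array of merged intermediate rows.
#' @export
merge_predictions <- function(preds, starts, L) {
  if (length(preds) != length(starts) || length(starts) == 0L)
    stop("predictions and starts must align and be non-empty")
  d <- dim(preds[[1L]])
  acc <- array(0, c(L - 1L, d[2L], d[3L]))
  cnt <- numeric(L - 1L)
  for (i in seq_along(starts)) {
    g <- starts[i] + 0:(d[1L] - 1L)
    acc[g, , ] <- acc[g, , , drop = FALSE] + preds[[i]]
    cnt[g] <- cnt[g] + 1
  }
  if (any(cnt == 0)) stop("gaps not covered by any window; missing starts?")
  sweep(acc, 1L, cnt, "/")
}

#' Interlace input rows with predicted intermediate rows
#'
#' Weaves the `n_out` predicted channels between consecutive input rows:
#' output row `1 + (n_out + 1) * (i - 1)` is input row `i` verbatim, and
#' the rows between input rows `i` and `i + 1` are that gap's channels in
#' order. An L-row input becomes `(n_out + 1) * (L - 1) + 1` rows (91 rows
#' to 181 at 2x, to 361 at 4x).
#'
#' @param input L x W sinogram matrix.
#' @param intermediate (L - 1) x W x n_out array from
#'   [merge_predictions()].
#' @return Upscaled ((n_out + 1) * (L - 1) + 1) x W matrix.
#' @export
interlace_rows <- function(input, intermediate) {
  if (is.matrix(intermediate))
    intermediate <- array(intermediate, c(dim(intermediate), 1L))
  L <- nrow(input); d <- dim(intermediate)
  if (d[1L] != L - 1L || d[2L] != ncol(input))
    stop("intermediate rows must be (L - 1) x W x n_out")
  n_out <- d[3L]
  out <- matrix(0, (n_out + 1L) * (L - 1L) + 1L, ncol(input))
  out[seq(1L, nrow(out), by = n_out + 1L), ] <- input
  for (ch in seq_len(n_out))
    out[(n_out + 1L) * (seq_len(L - 1L) - 1L) + 1L + ch, ] <-
      intermediate[, , ch]
  out
}

#' Min-max normalization of an input patch
#'
#' Affine map of the patch onto `[0, 1]`; the returned parameters invert
#' the transform for the network output. A constant patch maps to all
#' zeros with the scale flagged degenerate, and the inverse restores the
#' constant exactly.
#'
#' @param x Numeric array (finite).
#' @return List with `x` (normalized array) and `params`
#'   (`offset`, `scale`, `degenerate`).
#' @export
normalize_patch <- function(x) {
  if (any(!is.finite(x))) stop("patch values must be finite")
  lo <- min(x); rng <- max(x) - lo
  if (rng <= 0)
    return(list(x = x * 0, params = list(offset = lo, scale = 1,
                                         degenerate = TRUE)))
  list(x = (x - lo) / rng,
       params = list(offset = lo, scale = rng, degenerate = FALSE))
}

#' Invert [normalize_patch()] on a network output
#'
#' @param y Normalized array (e.g. the network prediction).
#' @param params Parameters returned by [normalize_patch()].
#' @return Denormalized array.
#' @export
denormalize_patch <- function(y, params) {
  y * params$scale + params$offset
}

#' Balanced random patch schedule over training sinograms
#'
#' One 'iteration' visits every training sinogram exactly once, drawing one
#' random window start from each, with the sinogram order reshuffled per
#' iteration. Deterministic for a fixed seed.
#'
#' @param n_rows_per_sino Integer vector: row count T of each training
#'   sinogram.
#' @param n_iterations Number of iterations to schedule.
#' @param geom A [patch_geometry()] (bounds the admissible starts).
#' @param seed Integer seed.
#' @return Data frame with columns `iteration`, `sino`, `start`, ordered as
#'   the patches are consumed.
#' @export
sample_iteration_plan <- function(n_rows_per_sino, n_iterations,
                                  geom = patch_geometry(), seed = 1L) {
  stopifnot(length(n_rows_per_sino) >= 1L, n_iterations >= 1L)
  max_start <- n_rows_per_sino - geom$window
  if (any(max_start < 1L)) stop("a training sinogram is too short")
  n <- length(n_rows_per_sino)
  with_seed(seed, {
    rows <- lapply(seq_len(n_iterations), function(it) {
      ord <- sample.int(n)
      data.frame(iteration = it, sino = ord,
                 start = vapply(ord, function(s)
                   sample.int(max_start[s], 1L), 1L))
    })
    do.call(rbind, rows)
  })
}
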