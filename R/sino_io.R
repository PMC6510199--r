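#' Sinogram stack
#'
#' The central container of the pipeline: one sinogram per sample height,
#' stored as a 3-D array ordered (height y, angle theta, detector width x).
#' `s$data[h, , ]` is the theta-by-x sinogram of height `h`.
#'
#' @param data 3-D numeric array, dim (heights, angles, width); a single
#'   matrix (angles x width) is promoted to one height.
#' @param angles Per-row projection angles in degrees (length = dim 2).
#' @param provenance One of `"noiseless"`, `"noisy"`, `"downscaled"`,
#'   `"upscaled"`.
#' @return Object of class `sinogram_stack`.
#' @export
sinogram_stack <- function(data, angles = NULL,
                           provenance = c("noiseless", "noisy",
                                          "downscaled", "upscaled")) {
  provenance <- match.arg(provenance)
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("sinogram values must be finite")
  if (is.null(angles)) angles <- projection_angles(dim(data)[2L])
  stopifnot(length(angles) == dim(data)[2L])
  structure(list(data = data, angles = as.numeric(angles),
                 provenance = provenance),
            class = "sinogram_stack")
}

#' Projection stack
#'
#' A tomogram as captured: a 3-D array ordered (angle theta, height y,
#' width x); `p$data[t, , ]` is the y-by-x projection at angle index `t`.
#'
#' @param data 3-D numeric array, dim (angles, heights, width).
#' @param angles Per-projection angles in degrees (length = dim 1).
#' @return Object of class `projection_stack`.
#' @export
projection_stack <- function(data, angles = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("projection values must be finite")
  if (is.null(angles)) angles <- projection_angles(dim(data)[1L])
  stopifnot(length(angles) == dim(data)[1L])
  structure(list(data = data, angles = as.numeric(angles)),
            class = "projection_stack")
}

#' @export
print.sinogram_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("sinogram_stack:", d[1L], "heights x", d[2L], "angles x", d[3L],
      "detector pixels,", x$provenance, "\n")
  invisible(x)
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("projection_stack:", d[1L], "angles x", d[2L], "heights x", d[3L],
      "detector pixels\n")
  invisible(x)
}

#' Convert a projection stack to sinogram space
#'
#' Pure axis permutation: sinogram `h`, row `t` equals projection `t`,
#' row `h`. Lossless and bit-exact.
#'
#' @param p A [projection_stack()].
#' @return A [sinogram_stack()].
#' @export
projections_to_sinograms <- function(p) {
  stopifnot(inherits(p, "projection_stack"))
  sinogram_stack(aperm(p$data, c(2L, 1L, 3L)), angles = p$angles)
}

#' Convert a sinogram stack back to projection space
#'
#' Inverse of [projections_to_sinograms()]; the round trip is bit-exact.
#'
#' @param s A [sinogram_stack()].
#' @return A [projection_stack()].
#' @export
sinograms_to_projections <- function(s) {
  stopifnot(inherits(s, "sinogram_stack"))
  projection_stack(aperm(s$data, c(2L, 1L, 3L)), angles = s$angles)
}

#' Write a tomogram to HDF5
#'
#' Stores the array under a configurable dataset path (NeXus-style default
#' `/entry/data/data`, layout heights x angles x width for sinogram stacks,
#' angles x heights x width for projection stacks) plus an `angles` dataset
#' alongside it.
#'
#' @param stack A [sinogram_stack()] or [projection_stack()].
#' @param path Output `.h5`/`.nxs` file (overwritten).
#' @param dataset Dataset path inside the file.
#' @return `path`, invisibly.
#' @export
write_tomogram_h5 <- function(stack, path, dataset = "/entry/data/data") {
  stopifnot(inherits(stack, c("sinogram_stack", "projection_stack")))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  dsname <- sub("^/*", "/", dataset)
  grp <- dirname(dsname)
  if (grp != "/") {
    parts <- strsplit(sub("^/", "", grp), "/")[[1L]]
    for (i in seq_along(parts)) {
      g <- paste(parts[seq_len(i)], collapse = "/")
      suppressWarnings(try(rhdf5::h5createGroup(path, g), silent = TRUE))
    }
  }
  rhdf5::h5write(stack$data, path, dsname)
  rhdf5::h5write(stack$angles, path,
                 paste0(sub("/$", "", grp), "/angles"))
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a tomogram from HDF5
#'
#' @param path HDF5 file.
#' @param dataset Dataset path inside the file; a missing dataset is an
#'   error naming the path (no silent fallback).
#' @param layout `"sino"` (heights x angles x width) or `"proj"`
#'   (angles x heights x width): declares the axis order on disk.
#' @param heights Optional integer vector of height indices (1-based) for a
#'   partial, memory-light read of a sinogram-layout file.
#' @param skip_first_row Drop the first height before returning (some
#'   beamline files carry metadata in the first sinogram).
#' @return A [sinogram_stack()] or [projection_stack()] per `layout`.
#' @export
read_tomogram_h5 <- function(path, dataset = "/entry/data/data",
                             layout = c("sino", "proj"), heights = NULL,
                             skip_first_row = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  ls <- rhdf5::h5ls(path)
  present <- paste0(sub("^/$", "", ls$group), "/", ls$name)
  dsname <- sub("^/*", "/", dataset)
  if (!dsname %in% present)
    stop("dataset '", dataset, "' not present in ", path)
  index <- NULL
  if (!is.null(heights)) {
    if (layout != "sino")
      stop("partial height reads require sinogram layout")
    index <- list(heights, NULL, NULL)
  }
  a <- rhdf5::h5read(path, dataset, index = index)
  if (length(dim(a)) != 3L)
    stop("dataset '", dataset, "' has rank ", length(dim(a)),
         ", expected 3")
  angpath <- paste0(dirname(dsname), "/angles")
  angles <- if (angpath %in% present)
    as.numeric(rhdf5::h5read(path, angpath)) else NULL
  rhdf5::h5closeAll()
  if (skip_first_row) {
    if (layout == "sino") a <- a[-1L, , , drop = FALSE]
    else a <- a[, -1L, , drop = FALSE]
  }
  if (layout == "sino") sinogram_stack(a, angles = angles)
  else projection_stack(a, angles = angles)
}

#' Export a single image as 32-bit float TIFF
#'
#' @param img Numeric matrix (e.g. one sinogram or a reconstruction);
#'   `NA` pixels are written as 0.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
export_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  img[is.na(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read back a TIFF written by [export_tiff()]
#'
#' @param path TIFF file.
#' @return Numeric matrix.
#' @export
import_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
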