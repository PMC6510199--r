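#' Quadric scene primitive
#'
#' Builds one geometric primitive of a synthetic scene. Primitives are
#' axis-aligned quadrics with an attenuation density; a parallel X-ray beam
#' through a primitive accumulates `density * chord length`.
#'
#' @param kind One of `"ellipsoid"`, `"sphere"`, `"cylinder"`,
#'   `"half_ellipsoid"`. Cylinders have their axis along z (the rotation /
#'   height axis); `semi_axes` is then `(radius, radius, half_height)`.
#'   A half-ellipsoid is an ellipsoid with a default clip plane keeping its
#'   upper half (`z >= center[3]`), matching a droplet resting on a surface.
#' @param center Numeric length-3 centre in scene units.
#' @param semi_axes Numeric semi-axes, strictly positive. A single value is
#'   recycled to 3 (sphere radius).
#' @param density Attenuation per unit length (dimensionless scene units);
#'   may be negative for an inclusion less dense than its host.
#' @param clip Optional axis-aligned half-space kept after intersection:
#'   a list `list(axis =, sign =, bound =)` with `axis` in 1:3 (x, y, z) and
#'   `sign` +1 (keep `coord >= bound`) or -1 (keep `coord <= bound`).
#' @return An object of class `quadric`.
#' @seealso [phantom_scene()], [line_integral()]
#' @export
quadric <- function(kind = c("ellipsoid", "sphere", "cylinder",
                             "half_ellipsoid"),
                    center = c(0, 0, 0), semi_axes = 1, density = 1,
                    clip = NULL) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  stopifnot(length(center) == 3L, all(is.finite(center)),
            all(is.finite(semi_axes)), is.finite(density))
  if (any(semi_axes <= 0)) stop("semi_axes must be strictly positive")
  if (kind == "sphere" || kind == "half_ellipsoid") {
    if (kind == "half_ellipsoid" && is.null(clip))
      clip <- list(axis = 3L, sign = 1, bound = center[3L])
  }
  if (kind == "sphere") semi_axes <- rep(semi_axes[1L], 3L)
  if (!is.null(clip)) {
    stopifnot(clip$axis %in% 1:3, clip$sign %in% c(-1, 1),
              is.finite(clip$bound))
  }
  structure(list(kind = kind, center = center, semi_axes = semi_axes,
                 density = density, clip = clip),
            class = "quadric")
}

# numeric row encoding consumed by the C++ projector
prim_row <- function(p) {
  kind_code <- if (p$kind == "cylinder") 2 else 1
  cl <- p$clip
  c(kind_code, p$center, p$semi_axes, p$density,
    if (is.null(cl)) c(0, 0, 0) else c(cl$axis, cl$sign, cl$bound))
}

#' Phantom scene: an ordered collection of quadric primitives
#'
#' @param primitives List of [quadric()] objects.
#' @param extent Half-width of the scene bounding cube (scene units).
#' @return Object of class `phantom_scene`.
#' @export
phantom_scene <- function(primitives = list(), extent = 1) {
  stopifnot(all(vapply(primitives, inherits, TRUE, "quadric")), extent > 0)
  structure(list(primitives = primitives, extent = extent),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  kinds <- table(vapply(x$primitives, `[[`, "", "kind"))
  cat("phantom_scene:", length(x$primitives), "primitives (",
      paste(names(kinds), kinds, sep = ":", collapse = ", "),
      "), extent", x$extent, "\n")
  invisible(x)
}

#' Parallel-beam projection geometry
#'
#' Projection angles sweep 0 to 180 degrees inclusive: row `t` (0-based)
#' maps to angle `t * 180 / (n_angles - 1)` degrees, so the first and last
#' rows form the 0/180-degree pair.
#'
#' @param n_angles Number of projection angles (>= 2).
#' @param detector_width Detector pixels across the beam.
#' @param n_heights Number of detector rows (sample heights).
#' @param pixel_size Scene units per detector pixel. The default sizes the
#'   detector to span `[-1, 1]` scene units.
#' @param height_range Scene-unit z interval spanned by the height rows
#'   (length 2), so a reduced number of heights can still sample the whole
#'   object. `NULL` (default) spaces heights by `pixel_size` around z = 0.
#' @return Object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_angles, detector_width, n_heights = 1L,
                                pixel_size = 2 / detector_width,
                                height_range = NULL) {
  stopifnot(n_angles >= 2, detector_width >= 1, n_heights >= 1,
            pixel_size > 0)
  if (is.null(height_range)) {
    half <- (n_heights - 1) / 2 * pixel_size
    height_range <- c(-half, half)
  }
  stopifnot(length(height_range) == 2L, diff(height_range) >= 0)
  structure(list(n_angles = as.integer(n_angles),
                 detector_width = as.integer(detector_width),
                 n_heights = as.integer(n_heights),
                 pixel_size = pixel_size,
                 height_range = as.numeric(height_range)),
            class = "projection_geometry")
}

#' Angles (degrees) of a projection geometry or row count
#'
#' @param n_angles Number of angles, or a `projection_geometry`.
#' @return Numeric vector of angles in degrees, `t * 180 / (n - 1)`.
#' @export
projection_angles <- function(n_angles) {
  if (inherits(n_angles, "projection_geometry"))
    n_angles <- n_angles$n_angles
  if (n_angles == 1L) return(0)
  (seq_len(n_angles) - 1) * 180 / (n_angles - 1)
}

#' Path-weighted density of a ray through one primitive
#'
#' Returns `density * chord length` of the intersection of the ray with the
#' primitive (clip plane applied), 0 when they are disjoint.
#'
#' @param primitive A [quadric()].
#' @param origin Numeric length-3 ray origin.
#' @param direction Numeric length-3 unit direction.
#' @return Scalar path-weighted density in scene units.
#' @export
line_integral <- function(primitive, origin, direction) {
  stopifnot(inherits(primitive, "quadric"),
            length(origin) == 3L, length(direction) == 3L)
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12)
    stop("direction must be a non-degenerate unit vector")
  if (abs(n - 1) > 1e-8) stop("direction must have unit length")
  cpp_line_integral(matrix(prim_row(primitive), nrow = 1),
                    as.numeric(origin), as.numeric(direction))
}

#' Analytic forward projection of a scene
#'
#' Computes noiseless parallel-beam line integrals of every primitive over
#' the full 180-degree sweep, returning them already organised as sinograms
#' (height x angle x detector). The projector is exact: each ray-primitive
#' chord is solved in closed form.
#'
#' @param scene A [phantom_scene()].
#' @param geometry A [projection_geometry()].
#' @return A [sinogram_stack()] with provenance `"noiseless"`.
#' @export
project_scene <- function(scene, geometry) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(geometry, "projection_geometry"))
  prims <- do.call(rbind, lapply(scene$primitives, prim_row))
  if (is.null(prims)) prims <- matrix(0, 0, 11)
  dz <- if (geometry$n_heights > 1L)
    diff(geometry$height_range) / (geometry$n_heights - 1) else 0
  a <- cpp_project_scene(prims, geometry$n_heights, geometry$n_angles,
                         geometry$detector_width, geometry$pixel_size,
                         geometry$height_range[1L], dz)
  sinogram_stack(a, angles = projection_angles(geometry),
                 provenance = "noiseless")
}

#' Poisson counting noise for transmission data
#'
#' Simulates photon counting: expected counts at a pixel with line integral
#' `p` are `flux * exp(-p)`; a Poisson draw `c` is converted back to a noisy
#' line integral `-log(max(c, 1) / flux)` (zero counts are clamped to one so
#' the log stays finite).
#'
#' @param s A [sinogram_stack()] or array of noiseless line integrals
#'   (finite, non-negative).
#' @param flux Incident photon count at zero attenuation (I0 > 0).
#' @param seed Integer seed; the same seed reproduces the same stack.
#' @return Object of the same shape with provenance `"noisy"`.
#' @export
apply_poisson_noise <- function(s, flux = 1e4, seed = 1L) {
  if (flux <= 0) stop("flux (I0) must be positive")
  a <- if (inherits(s, "sinogram_stack")) s$data else s
  if (any(!is.finite(a)) || any(a < 0))
    stop("line integrals must be finite and non-negative")
  counts <- with_seed(seed, stats::rpois(length(a), flux * exp(-a)))
  noisy <- array(-log(pmax(counts, 1) / flux), dim = dim(a))
  if (inherits(s, "sinogram_stack"))
    sinogram_stack(noisy, angles = s$angles, provenance = "noisy")
  else noisy
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Desk-scale corrosion phantom
#'
#' Builds a scene emulating a metal-pin corrosion experiment: a vertical
#' cylindrical pin, a half-ellipsoid droplet of salt water resting on top of
#' it, a few gas bubbles (spheres of reduced density inside the droplet),
#' and many small dense ellipsoidal deposits scattered inside the pin.
#' Placements and radii are drawn uniformly within their admissible regions
#' from a seeded generator, so a given seed always yields the same scene.
#'
#' @param n_bubbles Number of bubble spheres (default 3, the training-scene
#'   count; test scenes conventionally use 4).
#' @param n_deposits Number of deposit ellipsoids inside the pin
#'   (default 40).
#' @param seed Integer seed for the placement generator.
#' @param pin_radius,pin_density Pin cylinder geometry/attenuation.
#' @param droplet_density Droplet attenuation.
#' @param bubble_density Additive bubble density (negative: less dense than
#'   the droplet it sits in).
#' @param deposit_density Additive deposit density.
#' @return A [phantom_scene()] of `2 + n_bubbles + n_deposits` primitives.
#' @export
corrosion_phantom <- function(n_bubbles = 3L, n_deposits = 40L, seed = 1L,
                              pin_radius = 0.28, pin_density = 1,
                              droplet_density = 0.35,
                              bubble_density = -0.25,
                              deposit_density = 0.4) {
  stopifnot(n_bubbles >= 0, n_deposits >= 0)
  with_seed(seed, {
    pin_top <- 0.45
    pin <- quadric("cylinder", center = c(0, 0, (pin_top - 0.95) / 2),
                   semi_axes = c(pin_radius, pin_radius,
                                 (pin_top + 0.95) / 2),
                   density = pin_density)
    drop_ax <- c(0.36, 0.36, 0.38)
    droplet <- quadric("half_ellipsoid", center = c(0, 0, pin_top),
                       semi_axes = drop_ax, density = droplet_density)
    bubbles <- lapply(seq_len(n_bubbles), function(i) {
      r <- stats::runif(1, 0.03, 0.07)
      # uniform placement inside the droplet hemisphere, margin r
      repeat {
        v <- stats::runif(3, -1, 1)
        if (sum(v^2) <= 1 && v[3] >= 0) break
      }
      ctr <- c(0, 0, pin_top) + v * (drop_ax - r)
      quadric("sphere", center = ctr, semi_axes = r,
              density = bubble_density)
    })
    deposits <- lapply(seq_len(n_deposits), function(i) {
      ax <- stats::runif(3, 0.015, 0.045)
      repeat {
        xy <- stats::runif(2, -1, 1)
        if (sum(xy^2) <= 1) break
      }
      ctr <- c(xy * (pin_radius - max(ax[1:2])),
               stats::runif(1, -0.9, pin_top - 0.05))
      quadric("ellipsoid", center = ctr, semi_axes = ax,
              density = deposit_density)
    })
    phantom_scene(c(list(pin, droplet), bubbles, deposits), extent = 1)
  })
}

#' Simulate a fully sampled synthetic tomogram
#'
#' Convenience wrapper: build a seeded corrosion phantom, project it, and
#' optionally add Poisson noise.
#'
#' @inheritParams corrosion_phantom
#' @param n_heights,n_angles,detector_width Acquisition geometry.
#' @param flux Incident photon count for the noise model; `NULL` for a
#'   noiseless tomogram.
#' @return A list with elements `noiseless` and (if `flux` is set) `noisy`,
#'   both [sinogram_stack()]s, plus the `scene` and `geometry` used.
#' @export
simulate_tomogram <- function(n_heights = 64L, n_angles = 721L,
                              detector_width = 256L, n_bubbles = 3L,
                              n_deposits = 40L, flux = 1e4, seed = 1L) {
  scene <- corrosion_phantom(n_bubbles = n_bubbles, n_deposits = n_deposits,
                             seed = seed)
  geom <- projection_geometry(n_angles, detector_width, n_heights,
                              height_range = c(-0.9, 0.8))
  clean <- project_scene(scene, geom)
  out <- list(noiseless = clean, scene = scene, geometry = geom)
  if (!is.null(flux))
    out$noisy <- apply_poisson_noise(clean, flux = flux, seed = seed + 1L)
  out
}
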