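#' Specification of a simulated neurite-image group
#'
#' Describes one group of simulated benchmark images: a thin rectangle
#' (stand-in for a neurite) of excess intensity `delta` on a flat background
#' of 200, blurred by a 7 x 7 mean filter, with per-pixel uniform noise on
#' `[-noise_range, +noise_range]`.  Groups of 50 images at deltas 5, 10, 15
#' and 20 form the ablation benchmark.  The rectangle geometry is
#' configurable; the default is a 6 x 80 pixel horizontal bar centred in a
#' 128 x 128 image.
#'
#' @param size image extent `(height, width)`; default `c(128, 128)`.
#' @param background_level flat background intensity; default 200.
#' @param delta foreground excess intensity above background (> 0).
#' @param rect list with integer vectors `rows` and `cols` (inclusive spans
#'   of the rectangle); default centred 6 x 80.
#' @param mean_filter odd width of the square mean filter; default 7
#'   (1 disables blurring).
#' @param noise_range half-width of the uniform noise; default 2.5
#'   (0 disables noise).
#' @param n_images images per group; default 50.
#' @param seed base RNG seed for the group; per-image streams are derived
#'   from `(seed, index)`.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(size = c(128L, 128L), background_level = 200,
                           delta = 15, rect = NULL, mean_filter = 7,
                           noise_range = 2.5, n_images = 50L, seed = 1L) {
  size <- as.integer(size)
  stopifnot(length(size) == 2L, all(size >= 1L), delta > 0,
            background_level >= 0, mean_filter >= 1, mean_filter %% 2 == 1,
            noise_range >= 0, n_images >= 1L)
  if (is.null(rect)) {
    h <- min(6L, size[1]); w <- min(80L, size[2])
    r0 <- (size[1] - h) %/% 2L; c0 <- (size[2] - w) %/% 2L
    rect <- list(rows = (r0 + 1L):(r0 + h), cols = (c0 + 1L):(c0 + w))
  }
  rect$rows <- as.integer(rect$rows); rect$cols <- as.integer(rect$cols)
  if (min(rect$rows) < 1L || max(rect$rows) > size[1] ||
      min(rect$cols) < 1L || max(rect$cols) > size[2])
    stop("rectangle lies outside the image bounds")
  structure(list(size = size, background_level = background_level,
                 delta = delta, rect = rect,
                 mean_filter = as.integer(mean_filter),
                 noise_range = noise_range, n_images = as.integer(n_images),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic neurite-image group\n")
  cat(sprintf("  %d x %d, background %g, delta %g, rect %dx%d px\n",
              x$size[1], x$size[2], x$background_level, x$delta,
              length(x$rect$rows), length(x$rect$cols)))
  cat(sprintf("  mean filter %dx%d, noise +/-%g, %d image(s), seed %d\n",
              x$mean_filter, x$mean_filter, x$noise_range, x$n_images, x$seed))
  invisible(x)
}

#' Simulate one benchmark image
#'
#' Builds `meanfilter(background + delta * mask) + U(-noise_range, noise_range)`
#' with symmetric-reflection filter boundaries.  The returned ground truth is
#' the pre-filter, pre-noise foreground `delta * mask`.  The RNG stream is
#' derived deterministically from `(spec$seed, index)` so images are
#' reproducible individually and independent across indices.
#'
#' @param spec a [synthetic_spec()].
#' @param index image index within the group, `1 .. spec$n_images`.
#' @return list with matrices `image`, `truth_mask` (0/1) and
#'   `truth_foreground` (`delta * mask`).
#' @export
simulate_image <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), index >= 1L,
            index <= spec$n_images)
  mask <- matrix(0, spec$size[1], spec$size[2])
  mask[spec$rect$rows, spec$rect$cols] <- 1
  clean <- box_filter(spec$background_level + spec$delta * mask,
                      spec$mean_filter)
  img <- clean
  if (spec$noise_range > 0) {
    old <- local_seed((spec$seed %% 1000003L) * 2048L + index)
    on.exit(restore_seed(old))
    img <- img + matrix(stats::runif(length(img), -spec$noise_range,
                                     spec$noise_range),
                        nrow(img), ncol(img))
  }
  list(image = img, truth_mask = mask, truth_foreground = spec$delta * mask)
}

#' Simulate a full group of benchmark images
#'
#' @param spec a [synthetic_spec()].
#' @return list of `spec$n_images` results of [simulate_image()]; all share
#'   the mask and differ only in the noise realisation.
#' @export
simulate_group <- function(spec) {
  lapply(seq_len(spec$n_images), function(i) simulate_image(spec, i))
}

#' Simulate a soma volume with inhomogeneous background (synthetic fixture)
#'
#' Places non-overlapping bright spheres (somas) on a smoothly varying
#' background gradient inside a 3D volume, and returns the ground-truth
#' centre list for evaluating point-matching metrics.  This is a synthetic
#' stand-in for light-sheet soma stacks; it models neither optics nor
#' realistic noise.
#'
#' @param n_somas number of spheres (>= 0).
#' @param radius_range min/max sphere radius in voxels.
#' @param intensity_range min/max sphere excess intensity over the local
#'   background.
#' @param bg_gradient background intensity range `c(low, high)` applied as a
#'   smooth linear ramp across the volume.
#' @param size volume extent `(y, x, z)`.
#' @param seed RNG seed.
#' @param max_tries placement retries before giving up.
#' @return list with `volume` (3D array), `centers` (matrix, columns y,x,z)
#'   and `background` (the noise-free background field).
#' @export
simulate_soma_volume <- function(n_somas = 10L, radius_range = c(3, 5),
                                 intensity_range = c(40, 120),
                                 bg_gradient = c(80, 160),
                                 size = c(64L, 64L, 16L), seed = 1L,
                                 max_tries = 1000L) {
  size <- as.integer(size)
  stopifnot(length(size) == 3L, all(size >= 1L), n_somas >= 0L,
            radius_range[1] > 0, diff(radius_range) >= 0,
            intensity_range[1] > 0, diff(intensity_range) >= 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ramp <- function(n) if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
  bgfield <- bg_gradient[1] + (bg_gradient[2] - bg_gradient[1]) *
    outer(outer(ramp(size[1]), ramp(size[2]), `+`) / 3,
          ramp(size[3]) / 3 * 2, `+`)   # smooth ramp over y+x and z
  vol <- bgfield
  centers <- matrix(numeric(0), 0, 3,
                    dimnames = list(NULL, c("y", "x", "z")))
  radii <- numeric(0)
  tries <- 0L
  while (nrow(centers) < n_somas) {
    if (tries >= max_tries)
      stop("could not place ", n_somas, " non-overlapping somas in ",
           max_tries, " tries")
    tries <- tries + 1L
    r <- stats::runif(1, radius_range[1], radius_range[2])
    ctr <- vapply(seq_len(3), function(a)
      round(stats::runif(1, 1 + r, size[a] - r)), 0)
    if (any(size < 2 * r + 2)) stop("volume too small for the radius range")
    if (nrow(centers) > 0 &&
        any(sqrt(rowSums((centers - matrix(ctr, nrow(centers), 3,
                                           byrow = TRUE))^2)) <
            radii + r + 1))
      next
    amp <- stats::runif(1, intensity_range[1], intensity_range[2])
    yy <- seq_len(size[1]); xx <- seq_len(size[2]); zz <- seq_len(size[3])
    d2 <- outer(outer((yy - ctr[1])^2, (xx - ctr[2])^2, `+`),
                (zz - ctr[3])^2, `+`)
    vol <- vol + amp * exp(-d2 / (2 * (r / 2)^2)) * (d2 <= (1.5 * r)^2)
    centers <- rbind(centers, ctr)
    radii <- c(radii, r)
  }
  list(volume = vol, centers = centers, background = bgfield)
}

# Seed helpers: set a derived seed, returning the previous RNG state so the
# caller can restore it (simulations must not disturb the user's stream).
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
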