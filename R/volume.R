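#' Plan a tiling of a large volume into sub-stacks
#'
#' Splits a volume's index space into disjoint axis-aligned tiles of at most
#' `tile_shape` voxels per axis (default 512 x 512 x 512, the sub-stack size
#' used for processing multi-gigabyte stacks on desktop hardware).  Tiles
#' are half-open, 1-based index ranges; the last tile per axis may be
#' smaller; the order is z-major (z slowest), matching sequential stitching.
#'
#' @param shape integer vector of volume extents (length 2 or 3).
#' @param tile_shape maximum tile extent per axis, same length as `shape`.
#' @return an object of class `"tiling_plan"`: list with `shape`,
#'   `tile_shape` and `tiles`, a list whose elements hold `start` and `end`
#'   (inclusive, 1-based) vectors per axis.
#' @examples
#' plan <- plan_tiles(c(2560, 2560, 512), c(512, 512, 512))
#' length(plan$tiles)  # 25
#' @export
plan_tiles <- function(shape, tile_shape = rep(512L, length(shape))) {
  shape <- as.integer(shape); tile_shape <- as.integer(tile_shape)
  if (length(tile_shape) != length(shape))
    stop("tile_shape must match the number of axes")
  if (any(shape < 1L)) stop("extents must be >= 1")
  if (any(tile_shape < 1L)) stop("tile extents must be >= 1")
  starts <- lapply(seq_along(shape), function(a)
    seq.int(1L, shape[a], by = tile_shape[a]))
  grid <- expand.grid(starts, KEEP.OUT.ATTRS = FALSE)  # last axis (z) slowest
  tiles <- lapply(seq_len(nrow(grid)), function(i) {
    s <- as.integer(grid[i, ])
    list(start = s, end = pmin(s + tile_shape - 1L, shape))
  })
  structure(list(shape = shape, tile_shape = tile_shape, tiles = tiles),
            class = "tiling_plan")
}

#' @export
print.tiling_plan <- function(x, ...) {
  cat("Tiling plan: ", paste(x$shape, collapse = " x "), " volume, ",
      length(x$tiles), " tile(s) of at most ",
      paste(x$tile_shape, collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Decompose a volume tile by tile
#'
#' Applies [rssm()] independently to each tile of a tiling plan and writes
#' the results back into full-size foreground/background arrays at the
#' tile's index ranges — stitching "in sequence", without blending.  Tiling
#' along z only is exactly equivalent to the untiled fit (slices are
#' independent); tiling within a slice plane can differ near seams because
#' the smoothness penalties use implicit zero padding at tile borders.
#'
#' @param vol an [image_volume()], matrix or 3D array.
#' @param params an [rssm_params()] object.
#' @param plan a [plan_tiles()] plan covering `vol` (default: one plan with
#'   512^3 tiles).
#' @param ablation passed to [rssm()].
#' @return list with `foreground` and `background` arrays shaped like the
#'   input, and `reports`, one [rssm()] report list per tile.
#' @export
rssm_tiled <- function(vol, params = rssm_params(), plan = NULL,
                       ablation = "none") {
  vol <- image_volume(vol)
  d <- dim(vol$data)
  if (is.null(plan)) plan <- plan_tiles(d, pmin(d, 512L))
  if (!identical(as.integer(plan$shape), as.integer(d)))
    stop("tiling plan shape does not match the volume")
  fg <- array(0, d); bg <- array(0, d)
  reports <- vector("list", length(plan$tiles))
  for (i in seq_along(plan$tiles)) {
    tl <- plan$tiles[[i]]
    idx <- lapply(seq_along(d), function(a) tl$start[a]:tl$end[a])
    sub <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
    if (length(d) == 2L) dim(sub) <- vapply(idx, length, 0L)
    fit <- tryCatch(rssm(sub, params, ablation = ablation),
                    error = function(e) stop("tile ",
                      paste(tl$start, collapse = ","), "..",
                      paste(tl$end, collapse = ","), ": ",
                      conditionMessage(e), call. = FALSE))
    if (length(d) == 2L) {
      fg[idx[[1]], idx[[2]]] <- fit$foreground
      bg[idx[[1]], idx[[2]]] <- fit$background
    } else {
      fg[idx[[1]], idx[[2]], idx[[3]]] <- fit$foreground
      bg[idx[[1]], idx[[2]], idx[[3]]] <- fit$background
    }
    reports[[i]] <- fit$reports
  }
  list(foreground = fg, background = bg, reports = reports)
}
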