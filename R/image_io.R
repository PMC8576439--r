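#' Grayscale image volume
#'
#' Lightweight container for a nonnegative grayscale image: a numeric matrix
#' `(y, x)` or 3D array `(y, x, z)` (the z index maps to TIFF page order),
#' together with the voxel spacing in micrometres and the originating
#' storage type.  Intensities are held as doubles for computation.
#'
#' @param data numeric matrix or 3D array, all values >= 0.
#' @param spacing voxel size in micrometres per axis, length 2 or 3, all > 0.
#' @param dtype_origin `"uint8"` or `"uint16"`; the storage type the data
#'   came from (or should default to on write).
#' @return an object of class `"image_volume"`.
#' @export
image_volume <- function(data, spacing = NULL, dtype_origin = "uint16") {
  if (inherits(data, "image_volume")) return(data)
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("image data must have 2 or 3 axes, got ", nd)
  if (any(dim(data) < 1L)) stop("every axis must have extent >= 1")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(data < 0)) stop("intensities must be finite and >= 0")
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (length(spacing) != nd) stop("spacing must have one entry per axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be > 0")
  if (!dtype_origin %in% c("uint8", "uint16"))
    stop("dtype_origin must be 'uint8' or 'uint16'")
  structure(list(data = data, spacing = as.numeric(spacing),
                 dtype_origin = dtype_origin), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("Image volume ", paste(dim(x$data), collapse = " x "),
      " (", x$dtype_origin, " origin), spacing ",
      paste(x$spacing, collapse = " x "), " um\n", sep = "")
  cat(sprintf("  intensity range [%g, %g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Read a grayscale TIFF image or stack
#'
#' Reads a single- or multi-page grayscale TIFF; pixel values are returned
#' exactly as stored (no rescaling).  Multi-page files become 3D arrays with
#' the page index as the third axis.
#'
#' @param path path to an existing TIFF file.
#' @param spacing optional voxel spacing in micrometres (not parsed from
#'   file metadata; supply it explicitly when physical distances matter).
#' @return an [image_volume()].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  info <- tiff::readTIFF(path, payload = FALSE)
  bits <- if (!is.null(info$bits.per.sample)) info$bits.per.sample[1] else 16L
  for (p in pages) {
    if (length(dim(p)) == 3L)
      stop("unsupported format: expected grayscale, got ", dim(p)[3], " channels")
  }
  data <- if (length(pages) == 1L) pages[[1L]]
          else array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  image_volume(data, spacing,
               dtype_origin = if (bits <= 8) "uint8" else "uint16")
}

#' Write a grayscale TIFF image or stack
#'
#' Values are rounded to the nearest integer (half away from zero) and
#' clipped to the target dtype range before storage; 3D volumes become
#' multi-page TIFFs in z order.  Integer-valued inputs within range
#' round-trip bit-exactly through [read_volume()].
#'
#' @param vol an [image_volume()], matrix or 3D array.
#' @param path output file path.
#' @param dtype `"uint8"` or `"uint16"`; defaults to the volume's
#'   `dtype_origin`.
#' @return invisibly, the number of pixels clipped to the dtype range
#'   (a warning is emitted when it is nonzero).
#' @export
write_volume <- function(vol, path, dtype = NULL) {
  vol <- image_volume(vol)
  if (is.null(dtype)) dtype <- vol$dtype_origin
  if (!dtype %in% c("uint8", "uint16")) stop("dtype must be 'uint8' or 'uint16'")
  vmax <- if (dtype == "uint8") 255 else 65535
  v <- round_half_away(vol$data)
  n_clipped <- sum(v > vmax | v < 0)
  if (n_clipped > 0)
    warning(n_clipped, " pixel(s) clipped to the ", dtype, " range")
  v <- pmin(pmax(v, 0), vmax)
  pages <- if (length(dim(v)) == 2L) list(v)
           else lapply(seq_len(dim(v)[3]), function(z) v[, , z])
  pages <- lapply(pages, function(p) p / vmax)
  ok <- tryCatch(tiff::writeTIFF(pages, path,
                                 bits.per.sample = if (dtype == "uint8") 8L else 16L),
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(n_clipped)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
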