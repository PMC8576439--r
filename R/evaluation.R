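#' Intensity profile along a line segment
#'
#' Samples an image by bilinear interpolation at `n_samples` evenly spaced
#' points on the segment from `start` to `end` (inclusive of both
#' endpoints).  Coordinates are continuous 1-based `(row, col)` positions.
#'
#' @param img numeric matrix.
#' @param start,end numeric length-2 `(row, col)` endpoints, inside the
#'   image.
#' @param n_samples number of samples, >= 2.
#' @return numeric vector of length `n_samples`.
#' @export
intensity_profile <- function(img, start, end, n_samples = 100L) {
  img <- as_image_matrix(img)
  stopifnot(length(start) == 2L, length(end) == 2L, n_samples >= 2L)
  inb <- function(p) p[1] >= 1 && p[1] <= nrow(img) &&
                     p[2] >= 1 && p[2] <= ncol(img)
  if (!inb(start) || !inb(end)) stop("profile endpoints outside the image")
  t <- seq(0, 1, length.out = n_samples)
  r <- start[1] + t * (end[1] - start[1])
  c <- start[2] + t * (end[2] - start[2])
  r0 <- pmin(floor(r), nrow(img) - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c), ncol(img) - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- img[cbind(r0, c0)];      v01 <- img[cbind(r0, c0 + 1L)]
  v10 <- img[cbind(r0 + 1L, c0)]; v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
    fr * (1 - fc) * v10 + fr * fc * v11
}

#' Pearson correlation of two profiles
#'
#' Standard Pearson r, with the convention that two constant inputs give 0
#' (with a warning) rather than NA, so that benchmark summaries of
#' degenerate profiles stay numeric.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return scalar in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (length(a) < 2L) stop("profiles must have length >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("both profiles constant; correlation undefined, returning 0")
    return(0)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("one profile constant; correlation undefined, returning 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Match detected points against a gold standard
#'
#' Per-point matching rule used for tracing/localization evaluation: a
#' detected point is a true positive iff its nearest gold-standard point
#' lies at Euclidean distance strictly below `radius_um` (default 6
#' micrometres); a gold point is recovered iff some detected point lies
#' within the radius.  Distances are physical: coordinates are multiplied
#' by `spacing` before matching.  By default matching is many-to-one (each
#' detected point judged independently, as skeleton points are);
#' `one_to_one = TRUE` instead greedily assigns closest pairs first, which
#' is appropriate for soma counting where duplicates should count as false
#' positives.
#'
#' @param detected numeric matrix of detected points (rows = points,
#'   columns = coordinates, 2 or 3 of them), in voxel units.
#' @param gold numeric matrix of gold-standard points, same dimensionality.
#' @param radius_um match radius in micrometres (default 6).
#' @param spacing voxel size in micrometres per axis (default 1).
#' @param one_to_one use greedy one-to-one assignment.
#' @return an object of class `"match_result"`: list with counts `tp`, `fp`,
#'   `fn` and metrics `precision` (`tp / detected`), `recall`
#'   (recovered gold / gold) and `f1`.
#' @examples
#' gold <- rbind(c(0, 0), c(100, 0))
#' det  <- rbind(c(0, 1), c(0, 2), c(50, 50))
#' match_points(det, gold)  # tp 2, fp 1, fn 1; precision 2/3, recall 1/2
#' @export
match_points <- function(detected, gold, radius_um = 6,
                         spacing = NULL, one_to_one = FALSE) {
  detected <- as_point_matrix(detected); gold <- as_point_matrix(gold)
  if (ncol(detected) > 0 && ncol(gold) > 0 && ncol(detected) != ncol(gold))
    stop("detected and gold points have different dimensionality")
  stopifnot(radius_um >= 0)
  nd <- nrow(detected); ng <- nrow(gold)
  dimn <- max(ncol(detected), ncol(gold))
  if (is.null(spacing)) spacing <- rep(1, dimn)
  if (nd > 0) detected <- sweep(detected, 2, spacing[seq_len(ncol(detected))], `*`)
  if (ng > 0) gold <- sweep(gold, 2, spacing[seq_len(ncol(gold))], `*`)
  if (nd == 0L || ng == 0L) {
    tp <- 0L; fp <- nd; fn <- ng
  } else {
    D2 <- outer(rowSums(detected^2), rowSums(gold^2), `+`) -
      2 * detected %*% t(gold)
    D2[D2 < 0] <- 0                      # numerical guard
    D <- sqrt(D2)
    if (one_to_one) {
      matched_d <- logical(nd); matched_g <- logical(ng)
      repeat {
        Dm <- D; Dm[matched_d, ] <- Inf; Dm[, matched_g] <- Inf
        if (all(!is.finite(Dm)) || min(Dm) >= radius_um) break
        k <- arrayInd(which.min(Dm), dim(Dm))
        matched_d[k[1]] <- TRUE; matched_g[k[2]] <- TRUE
      }
      tp <- sum(matched_d); fp <- nd - tp; fn <- ng - sum(matched_g)
    } else {
      tp <- sum(apply(D, 1, min) < radius_um)
      fp <- nd - tp
      fn <- sum(apply(D, 2, min) >= radius_um)
    }
  }
  precision <- if (nd > 0) tp / nd else 0
  recall <- if (ng > 0) (ng - fn) / ng else 0
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 precision = precision, recall = recall,
                 f1 = f1_from_pr(precision, recall)),
            class = "match_result")
}

as_point_matrix <- function(p) {
  if (is.null(p) || length(p) == 0L)
    return(matrix(numeric(0), 0, 0))
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  storage.mode(p) <- "double"
  if (anyNA(p) || any(!is.finite(p))) stop("point coordinates must be finite")
  p
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Point matching: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f, recall %.4f, F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2pr/(p+r)`, with 0 when both are 0.
#'
#' @param precision,recall scalars in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @examples
#' f1_from_pr(0.90, 0.97)  # 0.9337, rounds to 0.93
#' @export
f1_from_pr <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Round half away from zero for report display
#'
#' @param x numeric.
#' @param digits decimal places (default 2, matching tabulated scores).
#' @return rounded numeric.
#' @export
round_report <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a point set from tab-separated text
#'
#' Format: an optional first comment line `# spacing: sx sy [sz]` giving the
#' voxel size in micrometres, then a header `x y [z]` and one point per
#' line in voxel units.
#'
#' @param path file path.
#' @return list with `points` (matrix, columns as in the file, reordered to
#'   row/col/slice order y, x, z) and `spacing`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  spacing <- NULL
  if (length(lines) > 0 && grepl("^#\\s*spacing:", lines[1])) {
    spacing <- as.numeric(strsplit(sub("^#\\s*spacing:\\s*", "", lines[1]),
                                   "[\\s,]+", perl = TRUE)[[1]])
    lines <- lines[-1]
  }
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"))
  cols <- intersect(c("y", "x", "z"), names(tab))
  if (!all(c("x", "y") %in% names(tab)))
    stop("point file must have columns x and y (and optionally z)")
  pts <- as.matrix(tab[, cols, drop = FALSE])
  if (is.null(spacing)) spacing <- rep(1, ncol(pts))
  list(points = pts, spacing = spacing)
}

#' Write a point set as tab-separated text
#'
#' @param points matrix with 2 or 3 columns (y, x[, z]) in voxel units.
#' @param path output path.
#' @param spacing voxel size in micrometres per axis.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, spacing = NULL) {
  points <- as_point_matrix(points)
  d <- ncol(points)
  if (is.null(spacing)) spacing <- rep(1, d)
  colnames(points) <- c("y", "x", "z")[seq_len(d)]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# spacing: ", paste(spacing, collapse = " ")), con)
  utils::write.table(points, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
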