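#' Initial foreground/background pair for the iteration
#'
#' Median-clip + repeated smoothing recipe: the observed image is clipped
#' from above at its global median (per slice), then smoothed `n_smooth`
#' times with a 3x3 normalized binomial kernel ([1,2,1] x [1,2,1] / 16,
#' symmetric-reflection boundary).  The smoothed image is the initial
#' background `B0`; the initial foreground is `Is0 = max(Y - B0, 0)`.
#' Twenty passes of the small kernel approximate one wide Gaussian;
#' reflection preserves constants exactly, so a constant image yields
#' `B0 = Y`, `Is0 = 0`.
#'
#' @param Y observed 2D image (matrix).
#' @param n_smooth number of smoothing passes, integer >= 0 (default 20).
#' @return list with matrices `Is0` and `B0`, both nonnegative.
#' @export
rssm_init <- function(Y, n_smooth = 20) {
  Y <- as_image_matrix(Y)
  stopifnot(n_smooth >= 0)
  B0 <- pmin(Y, stats::median(Y))
  for (i in seq_len(n_smooth)) B0 <- binomial_smooth(B0)
  B0 <- pmax(B0, 0)
  list(Is0 = pmax(Y - B0, 0), B0 = B0)
}

# One pass of the separable [1,2,1]/4 kernel with symmetric reflection.
binomial_smooth <- function(img) {
  smooth1 <- function(x) {
    m <- nrow(x)
    if (m == 1L) return(x)
    up   <- x[c(2L, seq_len(m - 1L)), , drop = FALSE]      # reflect row 0 -> row 2
    down <- x[c(seq_len(m - 1L) + 1L, m - 1L), , drop = FALSE]
    (up + 2 * x + down) / 4
  }
  t(smooth1(t(smooth1(img))))
}

# Separable moving-average (box) filter of odd width w, symmetric reflection.
# Used by the synthetic-image generator.
box_filter <- function(img, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (w == 1L) return(img)
  r <- (w - 1L) %/% 2L
  box1 <- function(x) {
    m <- nrow(x)
    idx <- seq.int(1L - r, m + r)
    idx[idx < 1L] <- 2L - idx[idx < 1L]        # reflect about the edge pixel
    idx[idx > m] <- 2L * m - idx[idx > m]
    idx <- pmin(pmax(idx, 1L), m)              # guard tiny extents
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, m, ncol(x))
    for (o in seq_len(w)) out <- out + xp[seq_len(m) + o - 1L, , drop = FALSE]
    out / w
  }
  t(box1(t(box1(img))))
}
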