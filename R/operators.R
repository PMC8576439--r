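#' k-th order forward-difference template
#'
#' Builds the coefficient template of the k-th order forward-difference
#' operator: a vector of length `k + 1` whose first `k` entries are -1 and
#' whose last entry is `k`.  Applied to a signal it computes
#' `k*x(t) - sum_{i=1..k} x(t-i)`, which annihilates constants
#' (the coefficients sum to zero).
#'
#' @param k difference order, integer >= 1.
#' @return numeric vector of length `k + 1`.
#' @examples
#' difference_template(1)  # c(-1, 1)
#' difference_template(2)  # c(-1, -1, 2)
#' @export
difference_template <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("difference order 'k' must be a single integer >= 1")
  c(rep(-1, k), k)
}

#' k-th order forward difference of an image along one axis
#'
#' Applies the k-th order difference template along the rows (`axis = "y"`,
#' first index) or columns (`axis = "x"`, second index) of a 2D image, with
#' implicit zero padding: for an m x n image and `axis = "y"` the output has
#' m + k rows, its first k and last k rows are zero, and row `i + k` holds
#' the template correlation of rows `i .. i+k` of the input.  Images whose
#' extent along the chosen axis is below `k + 1` yield an all-zero output.
#'
#' @param img numeric matrix.
#' @param k difference order, integer >= 1.
#' @param axis `"y"` (down rows, the default) or `"x"` (across columns).
#' @return numeric matrix with `k` extra rows (`axis = "y"`) or columns
#'   (`axis = "x"`).
#' @seealso [adjoint_difference()], [smooth_penalty()], [difference_matrix()]
#' @export
forward_difference <- function(img, k, axis = c("y", "x")) {
  axis <- match.arg(axis)
  img <- as_image_matrix(img)
  tem <- difference_template(k)
  if (axis == "x") return(t(forward_difference(t(img), k, "y")))
  m <- nrow(img); n <- ncol(img)
  out <- matrix(0, m + k, n)
  if (m >= k + 1) {
    idx <- seq_len(m - k)                     # i = 1 .. m-k
    for (l in seq_len(k + 1))                 # out[i+k, ] += img[i+l-1, ] * tem[l]
      out[idx + k, ] <- out[idx + k, ] + img[idx + l - 1L, , drop = FALSE] * tem[l]
  }
  out
}

#' Adjoint of the k-th order forward difference
#'
#' Exact adjoint of [forward_difference()] under the standard (Frobenius)
#' inner product: maps a gradient-shaped array of extent m + k back to image
#' extent m by correlating with the reversed template,
#' `out(i) = sum_{l=1..k+1} grad(i+l-1) * tem(k+2-l)`.
#'
#' @param grad numeric matrix, extent `m + k` along `axis`.
#' @param k difference order used to produce `grad`.
#' @param axis `"y"` or `"x"`, matching the forward call.
#' @return numeric matrix of the original image extent.
#' @export
adjoint_difference <- function(grad, k, axis = c("y", "x")) {
  axis <- match.arg(axis)
  grad <- as_image_matrix(grad)
  tem <- difference_template(k)
  if (axis == "x") return(t(adjoint_difference(t(grad), k, "y")))
  mk <- nrow(grad); n <- ncol(grad)
  if (mk < k) stop("gradient extent (", mk, ") smaller than difference order k = ", k)
  m <- mk - k
  if (m < 1L) return(matrix(0, max(m, 0L), n))
  # The k boundary rows at each end are outside the forward operator's range
  # (it leaves them zero); the exact adjoint ignores them.
  if (k >= 1L) grad[c(seq_len(k), m + seq_len(k)), ] <- 0
  out <- matrix(0, m, n)
  idx <- seq_len(m)
  for (l in seq_len(k + 1))
    out <- out + grad[idx + l - 1L, , drop = FALSE] * tem[k + 2L - l]
  out
}

#' Composite smoothing operator (adjoint times forward) along one axis
#'
#' @param img numeric matrix.
#' @param k difference order.
#' @param axis `"y"` or `"x"`.
#' @return matrix of the same shape as `img`.
#' @keywords internal
composite_difference <- function(img, k, axis = c("y", "x")) {
  axis <- match.arg(axis)
  adjoint_difference(forward_difference(img, k, axis), k, axis)
}

#' Squared k-th order smoothness penalty of an image
#'
#' Sum of squared k-th order forward differences along both image axes,
#' `||D_x img||^2 + ||D_y img||^2` with implicit zero padding.  An axis whose
#' extent is below `k + 1` contributes zero.
#'
#' @inheritParams forward_difference
#' @return scalar, >= 0; exactly 0 for constant images.
#' @export
smooth_penalty <- function(img, k) {
  img <- as_image_matrix(img)
  sum(forward_difference(img, k, "y")^2) + sum(forward_difference(img, k, "x")^2)
}

#' Closed-form bound on the largest eigenvalue of the composite operator
#'
#' Returns `(k^2 + k)^2`, an upper bound on the spectral norm of the
#' adjoint-times-forward difference operator of order `k` along one axis.
#' The bound follows from the template's absolute row/column sums (each at
#' most `2k`, so the operator norm squared is at most `4k^2 <= (k^2+k)^2`).
#'
#' @param k difference order, integer >= 1.
#' @return scalar bound.
#' @export
operator_norm_bound <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("'k' must be a single number >= 1")
  (k^2 + k)^2
}

#' Explicit matrix of the forward-difference operator
#'
#' Dense (m + k) x m matrix A such that `A %*% x` equals
#' `forward_difference(x, k, "y")` for a length-m column signal.  Exists for
#' testing and eigenvalue checks; production code uses the stencil form.
#'
#' @param k difference order.
#' @param m signal length.
#' @return numeric matrix of dimension `(m + k) x m`.
#' @export
difference_matrix <- function(k, m) {
  tem <- difference_template(k)
  A <- matrix(0, m + k, m)
  if (m >= k + 1) {
    for (i in seq_len(m - k))
      for (l in seq_len(k + 1))
        A[i + k, i + l - 1L] <- tem[l]
  }
  A
}

# Coerce to a plain numeric matrix; vectors become 1-column matrices.
as_image_matrix <- function(img) {
  if (inherits(img, "image_volume")) img <- img$data
  if (is.null(dim(img))) img <- matrix(img, ncol = 1L)
  if (length(dim(img)) != 2L) stop("expected a 2D image matrix")
  storage.mode(img) <- "double"
  img
}
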