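#' Model parameters for the sparse-smooth decomposition
#'
#' Collects every constant of the model and its solver.  The defaults are
#' the fixed values used throughout: sparsity weight `lambda1 = 0.1`,
#' foreground smoothness weight `lambda2 = 0.1` at difference order
#' `k0 = 2`, background smoothness weight `lambda3 = 0.5` at order `k1 = 5`,
#' and a hard floor threshold of 3 intensity units on the foreground.
#' `k0 < k1` encodes the prior that the background is smoother than the
#' foreground; violating it is permitted (for diagnostics) but warned about
#' unless `allow_k_override = TRUE`.
#'
#' @param lambda1 L1 sparsity weight on the foreground, >= 0.
#' @param lambda2 foreground smoothness weight, >= 0.
#' @param lambda3 background smoothness weight, >= 0.
#' @param k0 foreground difference order, integer >= 1.
#' @param k1 background difference order, integer >= 1.
#' @param floor hard threshold below which foreground pixels are zeroed
#'   (intensity units of the input; the defaults assume an 8-bit-like scale).
#' @param max_iter iteration cap, >= 1.
#' @param tol relative-change stopping tolerance, > 0.
#' @param prox_mode `"paper"` (hard floor threshold, the method's original update) or
#'   `"soft"` (soft shrinkage by `lambda1/Ls`, the exact proximal map of the
#'   nonnegative L1 penalty).
#' @param allow_k_override suppress the warning when `k0 >= k1`.
#' @return an object of class `"rssm_params"` (a named list).
#' @examples
#' p <- rssm_params()
#' p$lambda1
#' rssm_params(lambda2 = 0, max_iter = 50)
#' @export
rssm_params <- function(lambda1 = 0.1, lambda2 = 0.1, lambda3 = 0.5,
                        k0 = 2, k1 = 5, floor = 3,
                        max_iter = 200, tol = 1e-3,
                        prox_mode = c("paper", "soft"),
                        allow_k_override = FALSE) {
  prox_mode <- match.arg(prox_mode)
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0,
            k0 >= 1, k0 == round(k0), k1 >= 1, k1 == round(k1),
            floor >= 0, max_iter >= 1, tol > 0)
  if (k0 >= k1 && !allow_k_override)
    warning("k0 >= k1: the background is modelled as no smoother than the ",
            "foreground; set allow_k_override = TRUE to silence")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 k0 = as.integer(k0), k1 = as.integer(k1), floor = floor,
                 max_iter = as.integer(max_iter), tol = tol,
                 prox_mode = prox_mode),
            class = "rssm_params")
}

#' @export
print.rssm_params <- function(x, ...) {
  cat("Sparse-smooth model parameters\n")
  cat(sprintf("  lambda1 (sparsity)    : %g\n", x$lambda1))
  cat(sprintf("  lambda2, k0 (fg smooth): %g, order %d\n", x$lambda2, x$k0))
  cat(sprintf("  lambda3, k1 (bg smooth): %g, order %d\n", x$lambda3, x$k1))
  cat(sprintf("  floor threshold       : %g\n", x$floor))
  cat(sprintf("  prox mode             : %s\n", x$prox_mode))
  cat(sprintf("  max_iter / tol        : %d / %g\n", x$max_iter, x$tol))
  invisible(x)
}

#' Value of the sparse-smooth objective
#'
#' Evaluates
#' `0.5*||Y - Is - B||^2 + lambda1*||Is||_1 +
#'  0.5*lambda2*||D^(k0) Is||^2 + 0.5*lambda3*||D^(k1) B||^2`,
#' the convex program whose minimiser defines the decomposition.
#'
#' @param Y observed image (matrix).
#' @param Is foreground estimate, same shape as `Y`.
#' @param B background estimate, same shape as `Y`.
#' @param params an [rssm_params()] object.
#' @return scalar objective value, >= 0 for nonnegative `Is`.
#' @export
rssm_objective <- function(Y, Is, B, params = rssm_params()) {
  Y <- as_image_matrix(Y); Is <- as_image_matrix(Is); B <- as_image_matrix(B)
  check_same_shape(Y, Is, B)
  0.5 * sum((Y - Is - B)^2) +
    params$lambda1 * sum(abs(Is)) +
    0.5 * params$lambda2 * smooth_penalty(Is, params$k0) +
    0.5 * params$lambda3 * smooth_penalty(B, params$k1)
}

#' Gradient of the smooth part of the objective with respect to the foreground
#'
#' `Is + B - Y + lambda2 * (Dx' Dx + Dy' Dy) Is` at order `k0`.  The L1 term
#' is excluded (it is handled by the proximal step).
#'
#' @inheritParams rssm_objective
#' @return matrix of the same shape as `Y`.
#' @export
grad_F_Is <- function(Y, Is, B, params = rssm_params()) {
  Y <- as_image_matrix(Y); Is <- as_image_matrix(Is); B <- as_image_matrix(B)
  check_same_shape(Y, Is, B)
  g <- Is + B - Y
  if (params$lambda2 > 0)
    g <- g + params$lambda2 * (composite_difference(Is, params$k0, "y") +
                               composite_difference(Is, params$k0, "x"))
  g
}

#' Gradient of the smooth part of the objective with respect to the background
#'
#' `Is + B - Y + lambda3 * (Dx' Dx + Dy' Dy) B` at order `k1`.
#'
#' @inheritParams rssm_objective
#' @return matrix of the same shape as `Y`.
#' @export
grad_F_B <- function(Y, Is, B, params = rssm_params()) {
  Y <- as_image_matrix(Y); Is <- as_image_matrix(Is); B <- as_image_matrix(B)
  check_same_shape(Y, Is, B)
  g <- Is + B - Y
  if (params$lambda3 > 0)
    g <- g + params$lambda3 * (composite_difference(B, params$k1, "y") +
                               composite_difference(B, params$k1, "x"))
  g
}

#' Closed-form Lipschitz bounds for the block gradients
#'
#' The Hessian of the smooth part with respect to the foreground is
#' `I + lambda2 (Dx'Dx + Dy'Dy)`; since each composite difference operator of
#' order k has spectral norm below `(k^2+k)^2`, a valid Lipschitz bound is
#' `Ls = 1 + 2*lambda2*(k0^2+k0)^2`, and analogously
#' `LB = 1 + 2*lambda3*(k1^2+k1)^2` for the background.  The reciprocals are
#' safe gradient step sizes.
#'
#' @param params an [rssm_params()] object.
#' @return named list with scalars `Ls` and `LB`.
#' @examples
#' lipschitz_bounds(rssm_params())  # Ls = 8.2, LB = 901
#' @export
lipschitz_bounds <- function(params = rssm_params()) {
  list(Ls = 1 + 2 * params$lambda2 * operator_norm_bound(params$k0),
       LB = 1 + 2 * params$lambda3 * operator_norm_bound(params$k1))
}

check_same_shape <- function(...) {
  dims <- lapply(list(...), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("image arguments must share the same shape")
  invisible(TRUE)
}
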