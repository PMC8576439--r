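#' Hard floor threshold
#'
#' Zeroes every entry strictly below `t`; entries equal to `t` are kept.
#' With the default model this is applied to the foreground iterate with
#' `t = 3` intensity units.
#'
#' @param V numeric matrix or vector.
#' @param t threshold, >= 0.
#' @return object of the same shape with sub-threshold entries set to 0.
#' @examples
#' floor_threshold(c(2.9, 3, 5), 3)  # 0 3 5
#' @export
floor_threshold <- function(V, t) {
  stopifnot(t >= 0)
  V[V < t] <- 0
  V
}

#' One proximal-gradient update of the decomposition
#'
#' Performs one alternating update: a gradient step on the foreground at
#' step size `1/Ls`, a nonnegativity clamp, and the proximal/threshold step
#' (hard floor in `"paper"` mode, soft shrinkage by `lambda1/Ls` in `"soft"`
#' mode); then a gradient step on the background at `1/LB` using the fresh
#' foreground, clamped at zero.  The background update uses the updated
#' foreground (Gauss-Seidel order) so that each block step is a descent step
#' for its own subproblem.
#'
#' @inheritParams rssm_objective
#' @param Ls,LB step-size bounds, normally from [lipschitz_bounds()].
#' @param ablation `"none"`, `"no_sparse"` (drop the L1 term: no floor or
#'   shrinkage, only the nonnegativity clamp) or `"no_smooth"` (the caller is
#'   expected to have set `lambda2 = 0`; the proximal step is unchanged).
#' @return list with matrices `Is` and `B`.
#' @export
pgd_step <- function(Y, Is, B, params = rssm_params(), Ls = NULL, LB = NULL,
                     ablation = c("none", "no_sparse", "no_smooth")) {
  ablation <- match.arg(ablation)
  if (is.null(Ls) || is.null(LB)) {
    lb <- lipschitz_bounds(params)
    if (is.null(Ls)) Ls <- lb$Ls
    if (is.null(LB)) LB <- lb$LB
  }
  Is_next <- pmax(Is - grad_F_Is(Y, Is, B, params) / Ls, 0)
  if (ablation != "no_sparse") {
    Is_next <- if (params$prox_mode == "soft")
      pmax(Is_next - params$lambda1 / Ls, 0)
    else
      floor_threshold(Is_next, params$floor)
  }
  B_next <- pmax(B - grad_F_B(Y, Is_next, B, params) / LB, 0)
  list(Is = Is_next, B = B_next)
}

#' Sparse-smooth foreground/background decomposition of a neuronal image
#'
#' Fits the sparse-smooth model to an observed fluorescence image or stack:
#' the observation is modelled as foreground + background + noise, where the
#' foreground (somas, neurites) is sparse and moderately smooth and the
#' background is smoother.  The decomposition minimises
#' `0.5*||Y - Is - B||^2 + lambda1*||Is||_1 +
#'  0.5*lambda2*||D^(k0) Is||^2 + 0.5*lambda3*||D^(k1) B||^2`
#' subject to `Is, B >= 0`, by proximal gradient descent with closed-form
#' step bounds.  3D stacks are processed slice by slice (the smoothness
#' penalties are 2D; z-resolution is typically anisotropic), each slice
#' getting its own median-based initialization.
#'
#' @param Y observed image: a numeric matrix, a 3D array (y, x, slice), or an
#'   [image_volume()].
#' @param params an [rssm_params()] object.
#' @param init optional list with `Is0` and `B0` matrices (2D input only);
#'   by default [rssm_init()] is used.
#' @param ablation fit the full model (`"none"`), the sparsity-ablation
#'   variant (`"no_sparse"`: L1 term deleted) or the smooth-ablation variant
#'   (`"no_smooth"`: foreground smoothness term deleted).  The background
#'   smoothness term is kept in both variants.
#' @return an object of class `"rssm"`: a list with components
#'   \describe{
#'     \item{foreground, background}{the estimates, same shape as `Y`, >= 0.}
#'     \item{residual}{`Y - foreground - background` (the noise estimate);
#'       the three components sum to `Y` exactly by construction.}
#'     \item{reports}{per-slice list(s) with `iterations`, `converged`,
#'       `objective_trace` (length `iterations + 1`, includes the initial
#'       value) and `final_rel_change`.}
#'     \item{iterations, converged}{totals: sum of per-slice iterations and
#'       all-slices-converged flag.}
#'     \item{params, ablation, dims}{the call configuration.}
#'   }
#' @examples
#' spec <- synthetic_spec(delta = 15, noise_range = 0, mean_filter = 1)
#' sim <- simulate_image(spec, 1)
#' fit <- rssm(sim$image, rssm_params(max_iter = 50))
#' fit
#' cor(as.vector(fit$foreground), as.vector(sim$truth_foreground))
#' @seealso [pgd_step()], [rssm_init()], [rssm_tiled()] for very large
#'   volumes, [simulate_image()] for synthetic benchmarks.
#' @export
rssm <- function(Y, params = rssm_params(), init = NULL,
                 ablation = c("none", "no_sparse", "no_smooth")) {
  ablation <- match.arg(ablation)
  vol <- if (inherits(Y, "image_volume")) Y else image_volume(Y)
  d <- dim(vol$data)
  if (length(d) == 2L) {
    sl <- solve_slice(vol$data, params, init, ablation)
    fit <- structure(list(
      foreground = sl$Is, background = sl$B,
      residual = vol$data - sl$Is - sl$B,
      reports = list(sl$report),
      iterations = sl$report$iterations, converged = sl$report$converged,
      objective_trace = sl$report$objective_trace,
      params = params, ablation = ablation, dims = d), class = "rssm")
    return(fit)
  }
  if (!is.null(init))
    stop("explicit 'init' is only supported for 2D input")
  fg <- array(0, d); bg <- array(0, d)
  reports <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    sl <- tryCatch(solve_slice(vol$data[, , z], params, NULL, ablation),
                   error = function(e) stop("slice ", z, ": ",
                                            conditionMessage(e), call. = FALSE))
    fg[, , z] <- sl$Is; bg[, , z] <- sl$B
    reports[[z]] <- sl$report
  }
  structure(list(
    foreground = fg, background = bg, residual = vol$data - fg - bg,
    reports = reports,
    iterations = sum(vapply(reports, `[[`, 0L, "iterations")),
    converged = all(vapply(reports, `[[`, TRUE, "converged")),
    params = params, ablation = ablation, dims = d), class = "rssm")
}

# Core PGD loop on one 2D slice.
solve_slice <- function(Y, params, init = NULL, ablation = "none") {
  Y <- as_image_matrix(Y)
  if (length(Y) == 0L) stop("empty image")
  eff <- params
  if (ablation == "no_sparse") eff$lambda1 <- 0
  if (ablation == "no_smooth") eff$lambda2 <- 0
  lb <- lipschitz_bounds(eff)
  if (is.null(init)) init <- rssm_init(Y)
  Is <- as_image_matrix(init$Is0); B <- as_image_matrix(init$B0)
  check_same_shape(Y, Is, B)
  trace <- numeric(eff$max_iter + 1L)
  trace[1L] <- rssm_objective(Y, Is, B, eff)
  it <- 0L; converged <- FALSE; rel <- Inf
  eps <- 1e-8
  while (it < eff$max_iter) {
    st <- pgd_step(Y, Is, B, eff, lb$Ls, lb$LB, ablation)
    if (!all(is.finite(st$Is)) || !all(is.finite(st$B)))
      stop("non-finite values at iteration ", it + 1L)
    rel <- max(frob(st$Is - Is) / (frob(Is) + eps),
               frob(st$B - B) / (frob(B) + eps))
    Is <- st$Is; B <- st$B
    it <- it + 1L
    trace[it + 1L] <- rssm_objective(Y, Is, B, eff)
    if (rel < eff$tol) { converged <- TRUE; break }
  }
  list(Is = Is, B = B,
       report = list(iterations = it, converged = converged,
                     objective_trace = trace[seq_len(it + 1L)],
                     final_rel_change = rel))
}

frob <- function(x) sqrt(sum(x^2))

#' @export
print.rssm <- function(x, ...) {
  cat("Sparse-smooth decomposition (", x$ablation, " model)\n", sep = "")
  cat("  image      : ", paste(x$dims, collapse = " x "), "\n", sep = "")
  nsl <- length(x$reports)
  cat(sprintf("  slices     : %d, %s (total %d iterations)\n", nsl,
              if (x$converged) "all converged" else "NOT all converged",
              x$iterations))
  cat(sprintf("  foreground : %d nonzero pixels (%.1f%%), max %.3g\n",
              sum(x$foreground > 0), 100 * mean(x$foreground > 0),
              max(x$foreground)))
  cat(sprintf("  background : mean %.3g\n", mean(x$background)))
  invisible(x)
}

#' @export
summary.rssm <- function(object, ...) {
  reps <- object$reports
  s <- list(
    dims = object$dims, ablation = object$ablation,
    params = object$params, converged = object$converged,
    iterations = vapply(reps, `[[`, 0L, "iterations"),
    final_objective = vapply(reps, function(r) utils::tail(r$objective_trace, 1), 0),
    final_rel_change = vapply(reps, `[[`, 0, "final_rel_change"),
    fg_fraction = mean(object$foreground > 0),
    fg_max = max(object$foreground),
    bg_mean = mean(object$background),
    residual_sd = stats::sd(as.vector(object$residual)))
  class(s) <- "summary.rssm"
  s
}

#' @export
print.summary.rssm <- function(x, ...) {
  cat("Sparse-smooth decomposition summary\n")
  cat("  image              : ", paste(x$dims, collapse = " x "), "\n", sep = "")
  cat("  model variant      : ", x$ablation, "\n", sep = "")
  cat(sprintf("  iterations/slice   : median %g (range %d-%d)\n",
              stats::median(x$iterations), min(x$iterations), max(x$iterations)))
  cat(sprintf("  converged          : %s\n", x$converged))
  cat(sprintf("  final objective    : %s\n",
              paste(signif(x$final_objective, 6), collapse = ", ")))
  cat(sprintf("  foreground fraction: %.4f (max %.4g)\n", x$fg_fraction, x$fg_max))
  cat(sprintf("  background mean    : %.4g\n", x$bg_mean))
  cat(sprintf("  residual sd        : %.4g\n", x$residual_sd))
  invisible(x)
}

#' @export
fitted.rssm <- function(object, ...) object$foreground + object$background

#' @export
residuals.rssm <- function(object, ...) object$residual

#' Display a decomposition
#'
#' Shows the observed slice, the estimated foreground and the estimated
#' background side by side as grayscale images.
#'
#' @param x an `"rssm"` object.
#' @param slice slice index for 3D fits (default 1; ignored for 2D).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.rssm <- function(x, slice = 1L, ...) {
  pick <- function(a) if (length(dim(a)) == 3L) a[, , slice] else a
  Y <- pick(x$foreground + x$background + x$residual)
  panels <- list(observed = Y, foreground = pick(x$foreground),
                 background = pick(x$background))
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(panels)) {
    img <- panels[[nm]]
    graphics::image(t(img[nrow(img):1, , drop = FALSE]),
                    col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                    main = nm, useRaster = TRUE, ...)
  }
  invisible(x)
}
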