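# Independent oracles used across tests.  These deliberately avoid the
# package's stencil code paths: matrices are built entry by entry from the
# template definition, and the optimum of the convex objective is found with
# a generic box-constrained quasi-Newton solver on dense matrices.

# Brute-force construction of the (m+k) x m forward-difference matrix.
oracle_diff_matrix <- function(k, m) {
  tem <- c(rep(-1, k), k)
  A <- matrix(0, m + k, m)
  if (m >= k + 1) {
    for (i in seq_len(m - k))
      for (l in seq_len(k + 1))
        A[i + k, i + l - 1] <- tem[l]
  }
  A
}

# Dense-matrix evaluation of the full objective and its gradient on the
# stacked vector c(Is, B), for n x n images.
oracle_objective_fns <- function(Y, p) {
  n <- nrow(Y)
  A0 <- oracle_diff_matrix(p$k0, n)
  A1 <- oracle_diff_matrix(p$k1, n)
  pen <- function(M, A) sum((A %*% M)^2) + sum((M %*% t(A))^2)
  split2 <- function(v) list(Is = matrix(v[seq_len(n * n)], n, n),
                             B = matrix(v[-seq_len(n * n)], n, n))
  list(
    fn = function(v) {
      s <- split2(v)
      0.5 * sum((Y - s$Is - s$B)^2) + p$lambda1 * sum(abs(s$Is)) +
        0.5 * p$lambda2 * pen(s$Is, A0) + 0.5 * p$lambda3 * pen(s$B, A1)
    },
    gr = function(v) {
      s <- split2(v)
      R <- s$Is + s$B - Y
      gI <- R + p$lambda1 +
        p$lambda2 * (t(A0) %*% (A0 %*% s$Is) +
                     t(t(A0) %*% (A0 %*% t(s$Is))))
      gB <- R +
        p$lambda3 * (t(A1) %*% (A1 %*% s$B) +
                     t(t(A1) %*% (A1 %*% t(s$B))))
      c(gI, gB)
    })
}

# High-precision minimiser of the nonnegatively-constrained objective
# (on the feasible set the L1 term is linear, so the problem is smooth).
oracle_solve <- function(Y, p) {
  fns <- oracle_objective_fns(Y, p)
  o <- stats::optim(rep(1, 2 * length(Y)), fns$fn, fns$gr,
                    method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 5000, factr = 10))
  stopifnot(o$convergence == 0)
  o$value
}

# Central-difference numerical gradient of the smooth part F (no L1 term).
oracle_numeric_grad <- function(Y, Is, B, p, wrt = c("Is", "B"), h = 1e-5) {
  wrt <- match.arg(wrt)
  Fv <- function(Is, B)
    0.5 * sum((Y - Is - B)^2) +
      0.5 * p$lambda2 * smooth_penalty(Is, p$k0) +
      0.5 * p$lambda3 * smooth_penalty(B, p$k1)
  X <- if (wrt == "Is") Is else B
  g <- X * 0
  for (i in seq_along(X)) {
    E <- X * 0; E[i] <- h
    g[i] <- if (wrt == "Is") (Fv(Is + E, B) - Fv(Is - E, B)) / (2 * h)
            else (Fv(Is, B + E) - Fv(Is, B - E)) / (2 * h)
  }
  g
}

# 9x9 one-bright-pixel fixture on a constant floor.
bright_pixel_fixture <- function(floor_level = 20, spike = 70) {
  Y <- matrix(floor_level, 9, 9)
  Y[5, 5] <- spike
  Y
}
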