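test_that("difference template has the defining structure", {
  for (k in c(1, 2, 3, 5, 6)) {
    tem <- difference_template(k)
    expect_length(tem, k + 1)
    expect_equal(sum(tem), 0)           # annihilates constants
    expect_equal(tem[k + 1], k)
    expect_true(all(tem[seq_len(k)] == -1))
  }
  expect_error(difference_template(0), "k")
  expect_error(forward_difference(matrix(1, 3, 3), 0), "k")
})

test_that("forward difference matches hand-computed values", {
  expect_equal(forward_difference(matrix(c(1, 3, 6), 3, 1), 1),
               matrix(c(0, 2, 3, 0), 4, 1))
  expect_equal(forward_difference(matrix(c(1, 2, 3, 4), 4, 1), 2),
               matrix(c(0, 0, 3, 3, 0, 0), 6, 1))
  # constant image: exactly zero for any order
  for (k in 1:4) {
    expect_true(all(forward_difference(matrix(7.5, 6, 5), k, "y") == 0))
    expect_true(all(forward_difference(matrix(7.5, 6, 5), k, "x") == 0))
  }
  # sub-extent input: all-zero output of the padded shape
  out <- forward_difference(matrix(1:4, 2, 2), 3)
  expect_equal(dim(out), c(5L, 2L))
  expect_true(all(out == 0))
})

test_that("stencil form equals the explicit-matrix oracle on all sizes up to 8", {
  set.seed(11)
  for (k in c(1, 2, 5)) {
    for (m in 2:8) {
      A <- oracle_diff_matrix(k, m)
      expect_equal(difference_matrix(k, m), A)
      for (n in c(1, 4, 8)) {
        u <- matrix(rnorm(m * n), m, n)
        expect_equal(forward_difference(u, k, "y"), A %*% u, tolerance = 1e-12)
        expect_equal(forward_difference(t(u), k, "x"), t(A %*% u),
                     tolerance = 1e-12)
        v <- matrix(rnorm((m + k) * n), m + k, n)
        expect_equal(adjoint_difference(v, k, "y"), t(A) %*% v,
                     tolerance = 1e-12)
        expect_equal(adjoint_difference(forward_difference(u, k, "y"), k, "y"),
                     t(A) %*% (A %*% u), tolerance = 1e-12)
      }
    }
  }
})

test_that("adjoint identity <Du, v> == <u, D'v> holds to 1e-10 relative", {
  set.seed(12)
  for (k in c(1, 2, 3, 5)) {
    for (rep in 1:5) {
      m <- sample((k + 1):(k + 8), 1); n <- sample(1:6, 1)
      u <- matrix(rnorm(m * n), m, n)
      vy <- matrix(rnorm((m + k) * n), m + k, n)
      lhs <- sum(forward_difference(u, k, "y") * vy)
      rhs <- sum(u * adjoint_difference(vy, k, "y"))
      expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
      vx <- matrix(rnorm(m * (n + k)), m, n + k)
      lhs <- sum(forward_difference(u, k, "x") * vx)
      rhs <- sum(u * adjoint_difference(vx, k, "x"))
      expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
    }
  }
})

test_that("smooth penalty evaluates hand examples and degenerate extents", {
  expect_equal(smooth_penalty(matrix(3, 5, 5), 2), 0)
  # extent below k+1 along both axes contributes nothing
  expect_equal(smooth_penalty(matrix(c(1, 9), 1, 2), 2), 0)
  # 4x4 ramp along x, k = 2: 2 valid positions x 4 columns x 3^2 = 72
  ramp <- matrix(rep(1:4, times = 4), 4, 4, byrow = TRUE)
  expect_equal(smooth_penalty(ramp, 2), 72)
  # consistency with its own definition
  set.seed(13)
  u <- matrix(rnorm(30), 5, 6)
  expect_equal(smooth_penalty(u, 2),
               sum(forward_difference(u, 2, "y")^2) +
                 sum(forward_difference(u, 2, "x")^2))
})

test_that("largest eigenvalue of D'D stays below the closed-form bound", {
  expect_equal(operator_norm_bound(1), 4)
  expect_equal(operator_norm_bound(2), 36)
  expect_equal(operator_norm_bound(5), 900)
  for (k in c(1, 2, 5)) {
    for (m in c(k + 1, 9, 12)) {
      A <- oracle_diff_matrix(k, m)
      lam <- max(eigen(t(A) %*% A, symmetric = TRUE, only.values = TRUE)$values)
      expect_lte(lam, operator_norm_bound(k))
    }
  }
})
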