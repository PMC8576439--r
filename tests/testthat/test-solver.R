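test_that("floor threshold zeroes strictly-below entries only", {
  expect_equal(floor_threshold(c(2.9, 3, 5), 3), c(0, 3, 5))
  expect_equal(floor_threshold(matrix(0, 3, 3), 3), matrix(0, 3, 3))
  v <- matrix(c(0, 0.5, 2, 7), 2, 2)
  expect_equal(floor_threshold(v, 0), v)   # nothing below 0 after a clamp
  expect_error(floor_threshold(v, -1))
})

test_that("proximal step has the expected fixed points", {
  p <- rssm_params()
  Z <- matrix(0, 6, 6)
  st <- pgd_step(Z, Z, Z, p)
  expect_equal(st$Is, Z)
  expect_equal(st$B, Z)
  # constant decomposition above the floor with zero gradient is unchanged
  Is <- matrix(5, 6, 6); B <- matrix(100, 6, 6); Y <- Is + B
  st <- pgd_step(Y, Is, B, p)
  expect_equal(st$Is, Is)
  expect_equal(st$B, B)
})

test_that("one step from the initializer descends the objective", {
  Y <- bright_pixel_fixture()
  p <- rssm_params()
  ini <- rssm_init(Y)
  st <- pgd_step(Y, ini$Is0, ini$B0, p)
  expect_lt(rssm_objective(Y, st$Is, st$B, p),
            rssm_objective(Y, ini$Is0, ini$B0, p))
})

test_that("a constant image decomposes into zero foreground and flat background", {
  fit <- rssm(matrix(50, 32, 32), rssm_params(max_iter = 100))
  expect_s3_class(fit, "rssm")
  expect_true(fit$converged)
  expect_equal(max(fit$foreground), 0)
  expect_equal(mean(fit$background), 50, tolerance = 0.02)
})

test_that("a noiseless rectangle is recovered with high fidelity", {
  spec <- synthetic_spec(delta = 15, noise_range = 0, mean_filter = 1)
  sim <- simulate_image(spec, 1)
  fit <- rssm(sim$image)
  r <- cor(as.vector(fit$foreground), as.vector(sim$truth_foreground))
  expect_gte(r, 0.9)
})

test_that("decomposition conserves the input and stays nonnegative", {
  set.seed(41)
  for (mode in c("paper", "soft")) {
    Y <- matrix(runif(256, 0, 40), 16, 16)
    fit <- rssm(Y, rssm_params(prox_mode = mode, max_iter = 60))
    expect_true(all(fit$foreground >= 0))
    expect_true(all(fit$background >= 0))
    # residual is defined as Y - Is - B, so the sum telescopes back to Y
    expect_identical(fit$residual, Y - fit$foreground - fit$background)
    expect_equal(fit$foreground + fit$background + fit$residual, Y,
                 tolerance = 1e-12)
    expect_length(fit$objective_trace, fit$iterations + 1L)
  }
})

test_that("soft-prox traces are non-increasing on random images", {
  set.seed(42)
  for (rep in 1:10) {
    Y <- matrix(runif(256, 0, 30), 16, 16)
    fit <- rssm(Y, rssm_params(prox_mode = "soft", max_iter = 60))
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("the iteration converges and is bit-reproducible", {
  spec <- synthetic_spec(delta = 10, n_images = 1, seed = 5)
  Y <- simulate_image(spec, 1)$image
  f1 <- rssm(Y)
  f2 <- rssm(Y)
  expect_true(f1$converged)
  expect_lt(f1$reports[[1]]$final_rel_change, f1$params$tol)
  expect_identical(f1$foreground, f2$foreground)
  expect_identical(f1$background, f2$background)
})

test_that("ablation variants are valid and differ as the model predicts", {
  spec <- synthetic_spec(delta = 15, n_images = 1, seed = 7)
  sim <- simulate_image(spec, 1)
  off <- sim$truth_mask == 0
  fits <- lapply(c(none = "none", no_smooth = "no_smooth",
                   no_sparse = "no_sparse"),
                 function(m) rssm(sim$image, ablation = m))
  for (f in fits) {
    expect_true(all(f$foreground >= 0))
    expect_true(all(f$background >= 0))
    expect_identical(f$residual, sim$image - f$foreground - f$background)
  }
  # without the sparsity term, residual noise stays in the foreground
  expect_gt(sum(fits$no_sparse$foreground[off] > 0),
            sum(fits$none$foreground[off] > 0))
  expect_gt(sum(fits$no_smooth$foreground[off] > 0),
            sum(fits$none$foreground[off] > 0))
})

test_that("degenerate inputs are rejected", {
  expect_error(rssm(matrix(numeric(0), 0, 0)), "2 or 3 axes|extent")
  expect_error(solve_slice(matrix(numeric(0), 0, 1), rssm_params()))
})

test_that("print, summary, fitted and residuals methods are consistent", {
  Y <- bright_pixel_fixture()
  fit <- rssm(Y, rssm_params(max_iter = 30))
  expect_output(print(fit), "Sparse-smooth decomposition")
  s <- summary(fit)
  expect_s3_class(s, "summary.rssm")
  expect_output(print(s), "iterations")
  expect_equal(fitted(fit) + residuals(fit), Y)
})
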