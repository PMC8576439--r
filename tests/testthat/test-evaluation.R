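test_that("intensity profiles interpolate bilinearly", {
  expect_equal(intensity_profile(matrix(7, 5, 5), c(1, 1), c(5, 5), 9),
               rep(7, 9))
  # a linear field samples to an arithmetic progression
  ramp <- matrix(rep(1:6, times = 4), 4, 6, byrow = TRUE)
  expect_equal(intensity_profile(ramp, c(2, 1), c(2, 6), 11),
               seq(1, 6, length.out = 11))
  # hand-computed diagonal samples on a 3x3 image
  img <- matrix(c(2, 0, 1, 4, 8, 3, 1, 5, 7), 3, 3)
  expect_equal(intensity_profile(img, c(1, 1), c(3, 3), 4),
               c(2, 42 / 9, 55 / 9, 7))
  expect_error(intensity_profile(img, c(0, 1), c(3, 3), 4), "outside")
})

test_that("profile correlation follows the Pearson formula", {
  expect_equal(pearson_correlation(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(pearson_correlation(c(1, 5, 2), -c(1, 5, 2)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  expect_warning(r <- pearson_correlation(c(2, 2), c(3, 3)), "constant")
  expect_equal(r, 0)
  expect_error(pearson_correlation(1:3, 1:4), "length")
})

test_that("point matching implements the per-point radius rule", {
  gold <- rbind(c(0, 0), c(100, 0))
  # identical sets: perfect scores
  m <- match_points(gold, gold)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  # strict inequality at the 6 um radius
  expect_equal(match_points(rbind(c(0, 5.9)), rbind(c(0, 0)))$tp, 1L)
  expect_equal(match_points(rbind(c(0, 6.0)), rbind(c(0, 0)))$fp, 1L)
  # worked many-to-one example
  det <- rbind(c(0, 1), c(0, 2), c(50, 50))
  m <- match_points(det, gold)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 1L, 1L))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$f1, 4 / 7)
  # one-to-one mode: the duplicate detection becomes a false positive
  m1 <- match_points(det, gold, one_to_one = TRUE)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1L, 2L, 1L))
})

test_that("matching respects spacing, ordering and radius monotonicity", {
  set.seed(61)
  gold <- matrix(runif(30, 0, 50), 10, 3)
  det <- gold + matrix(rnorm(30, 0, 3), 10, 3)
  m <- match_points(det, gold)
  mshuf <- match_points(det[sample(10), ], gold[sample(10), ])
  expect_equal(m[c("tp", "fp", "fn")], mshuf[c("tp", "fp", "fn")])
  shift <- matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  mt <- match_points(det + shift, gold + shift)
  expect_equal(m[c("tp", "fp", "fn")], mt[c("tp", "fp", "fn")])
  tps <- sapply(c(1, 3, 6, 12), function(r) match_points(det, gold, r)$tp)
  expect_true(all(diff(tps) >= 0))
  # anisotropic spacing scales distances physically
  expect_equal(match_points(rbind(c(0, 2)), rbind(c(0, 0)),
                            spacing = c(1, 4))$fp, 1L)
  expect_equal(match_points(rbind(c(0, 2)), rbind(c(0, 0)),
                            spacing = c(1, 1))$tp, 1L)
  expect_error(match_points(rbind(c(1, 2)), rbind(c(1, 2, 3))),
               "dimensionality")
})

test_that("F1 is the harmonic mean with tabulated rounding", {
  expect_equal(round_report(f1_from_pr(0.90, 0.97)), 0.93)
  expect_equal(round_report(f1_from_pr(0.85, 0.83)), 0.84)
  expect_equal(f1_from_pr(0.7, 0.7), 0.7)
  expect_equal(f1_from_pr(0, 0), 0)
  expect_error(f1_from_pr(1.2, 0.5), "\\[0, 1\\]")
  # harmonic <= arithmetic and bounded by the components
  set.seed(62)
  p <- runif(50); r <- runif(50)
  f <- f1_from_pr(p, r)
  expect_true(all(f <= (p + r) / 2 + 1e-12))
  expect_true(all(f <= pmax(p, r) + 1e-12))
  expect_true(all(f <= 2 * pmin(p, r) + 1e-12))
  # display rounding is half away from zero
  expect_equal(round_report(0.935), 0.94)
  expect_equal(round_report(-0.935), -0.94)
})

test_that("point sets round-trip through tab-separated text", {
  pts <- cbind(y = c(1.5, 20, 3), x = c(2, 4.25, 6), z = c(0, 1, 2))
  f <- tempfile(fileext = ".tsv")
  write_points(pts, f, spacing = c(0.3, 0.3, 1))
  rt <- read_points(f)
  expect_equal(unname(rt$points), unname(pts))
  expect_equal(rt$spacing, c(0.3, 0.3, 1))
  expect_error(read_points(tempfile()), "not found")
})
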