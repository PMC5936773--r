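test_that("inverse Simpson matches hand values and vegan", {
  expect_equal(inverse_simpson(rep(10, 6)), 6.0)
  expect_equal(inverse_simpson(42), 1.0)
  counts <- c(90, 6, 1, 1, 1, 1)
  expect_equal(inverse_simpson(counts), 1 / (0.9^2 + 0.06^2 + 4 * 0.01^2))
  expect_error(inverse_simpson(c(0, 0)), "zero")

  skip_if_not_installed("vegan")
  set.seed(70)
  for (rep in 1:5) {
    x <- sample(0:50, 8, replace = TRUE)
    if (sum(x) == 0) next
    expect_equal(inverse_simpson(x),
                 unname(vegan::diversity(x, index = "invsimpson")))
  }
})

test_that("inverse Simpson is permutation- and scale-invariant", {
  set.seed(71)
  x <- c(5, 9, 1, 30, 2)
  expect_equal(inverse_simpson(sample(x)), inverse_simpson(x))
  expect_equal(inverse_simpson(7 * x), inverse_simpson(x))
})

test_that("bootstrap at equal depths reproduces the observed community", {
  counts <- matrix(c(40, 30, 30,
                     20, 50, 30), nrow = 3,
                   dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
  est <- bootstrap_diversity(counts, iterations = 50, seed = 5)
  expect_equal(est$subsample_depth, rep(100, 2))
  expect_equal(est$richness_mean, c(3, 3))
  expect_equal(est$richness_se, c(0, 0))
  expect_equal(est$inv_simpson_mean,
               c(inverse_simpson(counts[, 1]), inverse_simpson(counts[, 2])))
  expect_false(any(est$dropped))
})

test_that("bootstrap is seed-deterministic and drops shallow samples", {
  set.seed(72)
  counts <- matrix(rpois(40, 30), nrow = 5,
                   dimnames = list(paste0("OTU_", 1:5), paste0("s", 1:8)))
  counts[, 1] <- c(1, 0, 0, 1, 0)      # clearly the shallowest sample
  e1 <- bootstrap_diversity(counts, iterations = 30, seed = 9)
  e2 <- bootstrap_diversity(counts, iterations = 30, seed = 9)
  expect_identical(e1, e2)
  expect_true(e1$dropped[e1$sample_id == "s1"])
  expect_false(all(e1$dropped))
})

test_that("deep subsampling of an even two-OTU sample approaches 1/D = 2", {
  counts <- matrix(c(5000, 5000), nrow = 2,
                   dimnames = list(c("a", "b"), "s1"))
  est <- bootstrap_diversity(counts, iterations = 200, seed = 11)
  # the statistic at depth 10000 is exactly 2; subsampling to the full
  # depth keeps it there
  expect_equal(est$inv_simpson_mean, 2)
  # and at a forced lower depth the mean stays within 3 MC-se of 2
  sub <- matrix(c(5000, 5000, 500, 500), nrow = 2,
                dimnames = list(c("a", "b"), c("deep", "shallow")))
  est2 <- bootstrap_diversity(sub, iterations = 200, seed = 11)
  mc_se <- est2$inv_simpson_se[1] / sqrt(200)
  expect_lt(abs(est2$inv_simpson_mean[1] - 2), 3 * mc_se + 0.01)
})

test_that("standard curves recover slope, efficiency and copies", {
  copies <- 4.2 * 10^(1:7)
  cq <- 38 - 10 / 3 * log10(copies)    # slope exactly -10/3
  cv <- fit_standard_curve(copies, cq)
  expect_equal(cv$slope, -10 / 3)
  expect_equal(cv$r_squared, 1.0)
  expect_equal(cv$efficiency, 10^(3 / 10) - 1)

  # a slope of -1/log10(2) is a perfect doubling: efficiency 100%
  cq2 <- 40 + log2(1 / copies)
  cv2 <- fit_standard_curve(copies, cq2)
  expect_equal(cv2$efficiency, 1.0, tolerance = 1e-9)

  # quantification round-trip on exact-linear standards
  for (i in seq_along(copies))
    expect_equal(quantify(cv, cq[i]), copies[i], tolerance = 1e-9)
  expect_equal(quantify(cv, cv$intercept), 1.0)

  expect_error(fit_standard_curve(c(10, 10, 10), c(30, 30, 30)), "distinct")
})

test_that("slope recovery under Cq noise is within 0.05", {
  set.seed(73)
  copies <- 4.2 * 10^(1:7)
  cq <- 38 - 3.5 * log10(copies) + rnorm(7, sd = 0.1)
  cv <- fit_standard_curve(copies, cq)
  expect_lt(abs(cv$slope - (-3.5)), 0.05)
})

test_that("the nifH correction multiplies by the read fraction exactly", {
  expect_equal(correct_nifh_copies(1234, 1.0), 1234)
  expect_equal(correct_nifh_copies(1000, 0.1), 100)
  expect_equal(correct_nifh_copies(1000, 0), 0)
  expect_error(correct_nifh_copies(10, 1.5), "fraction")
})

test_that("evaluate_mock computes bias ratios and total variation distance", {
  spec <- mock_spec(paste0("m", 1:6), rep(1 / 6, 6))
  obs <- setNames(rep(100, 6), paste0("m", 1:6))
  ev <- evaluate_mock(obs, spec)
  expect_equal(ev$tvd, 0)
  expect_equal(ev$members$bias_ratio, rep(1, 6))

  # an even mock observed at 33/16/12/16/12/11 percent
  obs2 <- setNames(c(33, 16, 12, 16, 12, 11), paste0("m", 1:6))
  ev2 <- evaluate_mock(obs2, spec)
  manual <- 0.5 * sum(abs(c(33, 16, 12, 16, 12, 11) / 100 - 1 / 6))
  expect_equal(ev2$tvd, manual)
  expect_equal(round(ev2$tvd, 3), 0.163)

  # a missing member has bias ratio 0 and is flagged
  obs3 <- setNames(c(50, 50, 0, 0, 0, 0), paste0("m", 1:6))
  ev3 <- evaluate_mock(obs3[1:2], spec)
  expect_true(all(ev3$members$missing[3:6]))
  expect_equal(ev3$members$bias_ratio[3:6], rep(0, 4))

  # unknown members are reported as contaminants
  ev4 <- evaluate_mock(c(obs, geobacter = 1), spec)
  expect_equal(names(ev4$contaminants), "geobacter")

  expect_error(evaluate_mock(setNames(0, "m1"), spec), "zero total")
})
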