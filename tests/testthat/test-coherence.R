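test_that("profile difference agrees with the definitional-sums Pearson oracle", {
  set.seed(123)
  for (i in 1:1000) {
    a <- rnorm(5L)
    b <- rnorm(5L)
    expect_lt(abs(profile_difference(a, b) - (1 - abs(pearson_sums(a, b)))),
              1e-10)
  }
})

test_that("geometry identities: self, sign flip and hand-computed pairs", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(profile_difference(a, a), 0)
  expect_equal(profile_difference(a, -a), 0)
  b <- c(1, 2, 3, 4, 4)
  expect_equal(profile_difference(a, b), 1 - abs(pearson_sums(a, b)),
               tolerance = 1e-12)
  expect_lt(abs(profile_difference(a, b) - 0.0299), 1e-3)

  expect_equal(magnitude_difference(a, a), 0)
  expect_equal(magnitude_difference(c(3, 4), c(0, 0)), 5)
  expect_equal(magnitude_difference(a, b), sqrt(55) - sqrt(46),
               tolerance = 1e-12)
})

test_that("profile difference is invariant under affine maps of either profile", {
  set.seed(42)
  a <- rnorm(5L)
  b <- rnorm(5L)
  base <- profile_difference(a, b)
  for (i in 1:100) {
    alpha <- runif(1, -3, 3)
    if (abs(alpha) < 1e-3) alpha <- 1
    beta <- runif(1, -5, 5)
    expect_lt(abs(profile_difference(alpha * a + beta, b) - base), 1e-10)
    expect_lt(abs(profile_difference(a, alpha * b + beta) - base), 1e-10)
  }
})

test_that("magnitude difference scales linearly and obeys the reverse triangle bound", {
  set.seed(7)
  for (i in 1:100) {
    a <- rnorm(5L)
    b <- rnorm(5L)
    alpha <- runif(1, 0.1, 5)
    expect_equal(magnitude_difference(alpha * a, alpha * b),
                 alpha * magnitude_difference(a, b), tolerance = 1e-10)
    expect_lte(magnitude_difference(a, b), sqrt(sum((a - b)^2)) + 1e-12)
  }
})

test_that("degenerate profiles are excluded, not scored", {
  expect_warning(pd <- profile_difference(rep(1, 5), rnorm(5)),
                 "zero-variance")
  expect_true(is.na(pd))
  expect_error(profile_difference(1:4, 1:5), "length")
  expect_error(profile_difference(1:2, 2:1), ">= 3")
})

test_that("quadrant assignment follows the 2x2 partition", {
  expect_identical(quadrant_assign(0, 0, 0.5, 1), "C")
  expect_identical(quadrant_assign(1, 100, 0.5, 1), "B")
  expect_identical(quadrant_assign(0.1, 5, 0.5, 1), "A")
  expect_identical(quadrant_assign(0.9, 0.2, 0.5, 1), "D")
  expect_identical(quadrant_assign(c(0, 1), c(0, 2), 0.5, 1), c("C", "B"))
})

test_that("the coherence table separates planted coherent from divergent TFs", {
  ds <- std_dataset()
  ct <- std_coherence()
  expect_identical(nrow(ct), 16L)
  expect_identical(ct$tf, sort(ds$config$tf_names))
  coh <- ct$tf %in% ds$config$coherent_tfs
  expect_lt(mean(ct$profile_difference[coh]), 0.1)
  expect_gt(mean(ct$profile_difference[!coh]),
            mean(ct$profile_difference[coh]) + 0.3)
  # Table invariants
  expect_true(all(ct$profile_difference >= 0 & ct$profile_difference <= 1))
  expect_true(all(ct$magnitude_difference >= 0))
  expect_true(all(ct$mean_abs_corr >= 0 & ct$mean_abs_corr <= 1))
  expect_true(all(ct$sd_abs_corr <= 0.5))
  expect_identical(ct$x_err, ct$sd_abs_corr)
})

test_that("coherent TFs sit near the origin and quadrants reflect the split", {
  ds <- std_dataset()
  ct <- std_coherence()
  baer_like <- ct[ct$tf == ds$config$coherent_tfs[1L], ]
  expect_lt(baer_like$profile_difference, 0.1)
  expect_identical(baer_like$quadrant, "C")
  sp <- attr(ct, "splits")
  expect_identical(ct$quadrant,
                   quadrant_assign(ct$profile_difference,
                                   ct$magnitude_difference,
                                   sp[["x_split"]], sp[["y_split"]]))
})

test_that("coherence_point matches the table row and validates its inputs", {
  f <- std_fits()
  ct <- std_coherence()
  tf <- ct$tf[1L]
  pt <- coherence_point(f$A, f$B, tf, n_draws = 1000L, seed = 11L)
  expect_equal(pt$profile_difference,
               ct$profile_difference[ct$tf == tf], tolerance = 1e-12)
  expect_equal(pt$mean_abs_corr, ct$mean_abs_corr[ct$tf == tf],
               tolerance = 1e-12)
  expect_error(coherence_point(f$A, f$B, "NotATF"), "NotATF")
})

test_that("the coherence table is reproducible under a fixed seed", {
  f <- std_fits()
  t1 <- coherence_table(f$A, f$B, n_draws = 200L, seed = 3L)
  t2 <- coherence_table(f$A, f$B, n_draws = 200L, seed = 3L)
  expect_identical(t1, t2)
})

test_that("Monte-Carlo correlation spread is consistent across draw counts", {
  f <- std_fits()
  t1 <- coherence_table(f$A, f$B, n_draws = 1000L, seed = 21L)
  t4 <- coherence_table(f$A, f$B, n_draws = 4000L, seed = 22L)
  expect_true(all(abs(t1$sd_abs_corr - t4$sd_abs_corr) < 3 / sqrt(1000)))
})

test_that("vanishing posterior variance collapses the error bars", {
  f <- std_fits()
  shrunk <- lapply(f, function(fit) {
    fit$variance[] <- 1e-18
    fit
  })
  ct <- coherence_table(shrunk$A, shrunk$B, n_draws = 500L, seed = 2L)
  expect_true(all(ct$sd_abs_corr < 1e-6))
  expect_true(all(ct$x_err < 1e-6))
  same <- coherence_table(shrunk$A, shrunk$A, n_draws = 500L, seed = 2L)
  expect_true(all(same$profile_difference < 1e-12))
  expect_true(all(same$mean_abs_corr > 1 - 1e-6))
})

test_that("flat mean profiles are excluded from the table with a report", {
  f <- std_fits()
  flat <- f$A
  flat$mean[1L, ] <- 1
  flat$variance[1L, ] <- 1e-12
  expect_warning(ct <- coherence_table(flat, f$B, n_draws = 100L, seed = 1L),
                 "excluded")
  expect_identical(nrow(ct), 15L)
  expect_identical(attr(ct, "excluded"), flat$tf_names[1L])
})
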