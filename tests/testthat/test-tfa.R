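test_that("a noiseless single-TF system recovers the common gene profile", {
  profile <- c(1, -0.5, 0.25, 2, -1)
  n <- 20L
  Y <- matrix(rep(profile, each = n), n, 5L,
              dimnames = list(sprintf("g%02d", 1:n),
                              paste0("t", c(10, 20, 40, 60, 120))))
  X <- matrix(1L, n, 1L, dimnames = list(rownames(Y), "TF1"))
  fit <- tfa(Y, X, seed = 1L, max_iters = 2000L, elbo_rel_tol = 1e-12)
  # gauge: strengths have unit norm, so b = 1/sqrt(n) each and the activity
  # absorbs the common scale; the per-gene reconstruction is exact. The gene
  # baselines absorb a uniform offset of the profile, so the activity is
  # recovered up to that additive constant.
  expect_equal(unname(fitted(fit)), unname(Y), tolerance = 1e-6)
  rescaled <- fit$mean[1L, ] / sqrt(n)
  expect_equal(unname(rescaled - mean(rescaled)), profile - mean(profile),
               tolerance = 1e-6)
  expect_gt(cor(rescaled, profile), 1 - 1e-9)
  expect_true(all(fit$strengths_mean > 0))
  expect_equal(sum(fit$strengths_mean^2), 1, tolerance = 1e-9)
})

test_that("the fit recovers planted activities and the noise scale", {
  ds <- std_dataset()
  fit <- std_fits()$A
  rec <- vapply(fit$tf_names, function(tf)
    abs(cor(fit$mean[tf, ], ds$truth$activities_A[tf, ])), numeric(1L))
  expect_gte(median(rec), 0.9)
  expect_lt(abs(fit$noise_sd_hat - ds$config$noise_sd) / ds$config$noise_sd,
            0.2)
  expect_identical(dim(fit$mean), c(16L, 5L))
  expect_identical(dim(fit$variance), dim(fit$mean))
  expect_true(all(fit$variance > 0))
  expect_true(all(fit$strengths_mean[fit$connectivity == 0L] == 0))
})

test_that("the ELBO is non-decreasing on every fit of the standard fixture", {
  for (fit in std_fits())
    expect_gte(min(diff(fit$elbo_trace)), -1e-8)
})

test_that("the fit is deterministic given the seed", {
  cfg <- sim_config(n_genes = 60L, connectivity_density = 0.2, seed = 5L)
  ds <- simulate_dataset(cfg)
  f1 <- tfa(ds$expression$A, ds$connectivity, seed = 3L)
  f2 <- tfa(ds$expression$A, ds$connectivity, seed = 3L)
  expect_identical(f1$mean, f2$mean)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
})

test_that("recovery degrades gracefully as noise grows", {
  noise <- c(0.05, 0.1, 0.2, 0.4)
  med <- vapply(noise, function(ns) {
    cfg <- sim_config(n_genes = 200L, tf_names = paste0("TF", 1:6),
                      coherent_tfs = paste0("TF", 1:3),
                      connectivity_density = 0.1, noise_sd = ns, seed = 11L)
    ds <- simulate_dataset(cfg)
    fit <- tfa(ds$expression$A, ds$connectivity, seed = 1L,
               max_iters = 4000L)
    median(vapply(fit$tf_names, function(tf)
      abs(cor(fit$mean[tf, ], ds$truth$activities_A[tf, ])), numeric(1L)))
  }, numeric(1L))
  expect_gte(med[1L], 0.9)
  expect_true(all(diff(med) <= 0.02))
})

test_that("the gauge makes the optimum reproducible across initialisations", {
  ds <- std_dataset()
  fits <- lapply(1:5, function(s)
    tfa(ds$expression$A, ds$connectivity, seed = s, max_iters = 6000L,
        elbo_rel_tol = 1e-11))
  ref <- fits[[1L]]$mean
  for (f in fits[-1L])
    expect_lt(median(abs(f$mean - ref)), 1e-3)
})

test_that("TFs without measured targets are dropped with a warning", {
  cfg <- sim_config(n_genes = 40L, connectivity_density = 0.3, seed = 2L)
  ds <- simulate_dataset(cfg)
  X <- cbind(ds$connectivity, Ghost = 0L)
  expect_warning(
    expect_warning(fit <- tfa(ds$expression$A, X, seed = 1L, max_iters = 5L),
                   "Ghost"),
    "converge")
  expect_false("Ghost" %in% fit$tf_names)
  expect_identical(fit$dropped_tfs, "Ghost")

  Y2 <- ds$expression$A
  rownames(Y2) <- paste0("other_", rownames(Y2))
  expect_error(tfa(Y2, ds$connectivity), "no genes shared")
})

test_that("replicate time columns are averaged before fitting", {
  cfg <- sim_config(n_genes = 50L, connectivity_density = 0.3,
                    replicates = 2L, seed = 6L)
  ds <- simulate_dataset(cfg)
  fit <- suppressWarnings(tfa(ds$expression$A, ds$connectivity, seed = 1L,
                              max_iters = 10L))
  expect_identical(length(fit$time_points_min), 5L)
})

test_that("posterior sampling matches the marginal moments and the seed contract", {
  fit <- std_fits()$A
  s1 <- sample_activities(fit, 100L, seed = 5L)
  s2 <- sample_activities(fit, 100L, seed = 5L)
  expect_identical(unclass(s1), unclass(s2))

  big <- sample_activities(fit, 10000L, seed = 9L)
  emp_var <- apply(big, c(2L, 3L), var)
  expect_true(all(abs(emp_var - t(fit$variance)) / t(fit$variance) < 0.05))

  tiny <- fit
  tiny$variance[] <- 1e-20
  d <- sample_activities(tiny, 50L, seed = 1L)
  expect_true(all(abs(sweep(d, c(2L, 3L), t(tiny$mean))) < 1e-9))
})

test_that("fit methods expose coefficients, residuals and simulations coherently", {
  fit <- std_fits()$A
  expect_identical(coef(fit), fit$mean)
  expect_identical(coef(fit, "strengths"), fit$strengths_mean)
  expect_equal(residuals(fit), fit$expression - fitted(fit))
  expect_lt(sd(residuals(fit)), 2 * fit$noise_sd_hat)
  expect_identical(predict(fit, genes = fit$gene_ids[3:1]),
                   fitted(fit)[3:1, ])
  expect_error(predict(fit, genes = "nope"), "unknown gene")
  sims <- simulate(fit, nsim = 2L, seed = 1L)
  expect_length(sims, 2L)
  expect_identical(dim(sims[[1L]]), dim(fit$expression))
  expect_output(print(fit), "converged")
  expect_output(print(summary(fit)), "n_targets")
})
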