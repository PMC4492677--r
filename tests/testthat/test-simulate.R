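test_that("connectivity sampling honours shape, density and the two-target floor", {
  cfg <- sim_config(n_genes = 100L, tf_names = paste0("TF", 1:4),
                    connectivity_density = 0.1, coherent_tfs = "TF1",
                    seed = 1L)
  X <- generate_connectivity(cfg)
  expect_identical(dim(X), c(100L, 4L))
  expect_true(all(X %in% c(0L, 1L)))
  expect_true(all(colSums(X) >= 2))

  cfg1 <- sim_config(n_genes = 10L, tf_names = c("a", "b"),
                     connectivity_density = 1, coherent_tfs = "a", seed = 3L)
  expect_true(all(generate_connectivity(cfg1) == 1L))
})

test_that("connectivity nonzero count matches the binomial moments", {
  cfg <- sim_config(n_genes = 4598L, connectivity_density = 0.02, seed = 7L)
  X <- generate_connectivity(cfg)
  n <- 4598 * 16
  mu <- n * 0.02
  sdv <- sqrt(n * 0.02 * 0.98)
  expect_lt(abs(sum(X) - mu), 4 * sdv)
})

test_that("config validation names the offending field", {
  expect_error(sim_config(connectivity_density = 0), "connectivity_density")
  expect_error(sim_config(connectivity_density = 1.2), "connectivity_density")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(time_points_min = c(10, 10, 20)), "time_points_min")
  expect_error(sim_config(coherent_tfs = c("BaeR", "NoSuchTF")), "partition")
})

test_that("ground truth copies coherent TFs and masks strengths by connectivity", {
  cfg <- sim_config(n_genes = 60L, connectivity_density = 0.2, seed = 5L)
  X <- generate_connectivity(cfg)
  tr <- generate_truth(cfg, X)
  for (tf in cfg$coherent_tfs)
    expect_identical(tr$activities_A[tf, ], tr$activities_B[tf, ])
  for (tf in cfg$divergent_tfs)
    expect_false(identical(tr$activities_A[tf, ], tr$activities_B[tf, ]))
  expect_true(all(tr$strengths[X == 0L] == 0))
  expect_error(generate_truth(cfg, X[1:10, ]), "dimensions")
})

test_that("zero strength scale removes all TF signal", {
  cfg <- sim_config(n_genes = 40L, connectivity_density = 0.3,
                    strength_sd = 0, noise_sd = 0, baseline_sd = 0,
                    seed = 2L)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$truth$strengths == 0))
  expect_true(all(ds$expression$A == 0))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 50L, connectivity_density = 0.2, seed = 42L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$expression, d2$expression)
  d3 <- simulate_dataset(sim_config(n_genes = 50L,
                                    connectivity_density = 0.2, seed = 43L))
  expect_false(identical(d1$expression$A, d3$expression$A))
})

test_that("noiseless expression reproduces the bilinear reconstruction exactly", {
  cfg <- sim_config(n_genes = 50L, connectivity_density = 0.3, noise_sd = 0,
                    seed = 9L)
  ds <- simulate_dataset(cfg)
  recon <- ds$truth$baselines + ds$truth$strengths %*% ds$truth$activities_A
  expect_equal(unname(ds$expression$A), unname(recon), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("residual noise level matches the configured noise SD", {
  cfg <- sim_config(n_genes = 600L, connectivity_density = 0.05,
                    noise_sd = 0.1, seed = 7L)
  ds <- simulate_dataset(cfg)
  recon <- ds$truth$baselines + ds$truth$strengths %*% ds$truth$activities_A
  resid_sd <- sd(as.vector(ds$expression$A - recon))
  expect_lt(abs(resid_sd - cfg$noise_sd) / cfg$noise_sd, 0.1)
})

test_that("coherent TFs have exactly zero true profile and magnitude difference", {
  ds <- std_dataset()
  for (tf in ds$config$coherent_tfs) {
    expect_lt(profile_difference(ds$truth$activities_A[tf, ],
                                 ds$truth$activities_B[tf, ]), 1e-12)
    expect_identical(magnitude_difference(ds$truth$activities_A[tf, ],
                                          ds$truth$activities_B[tf, ]), 0)
  }
})

test_that("datasets round-trip through the TSV writers and readers", {
  cfg <- sim_config(n_genes = 30L, connectivity_density = 0.3, seed = 4L)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))

  back <- read_expression(paths[["expression_A"]])
  expect_equal(unname(back), unname(ds$expression$A), tolerance = 1e-12,
               ignore_attr = TRUE)
  Xback <- read_connectivity(paths[["connectivity"]])
  expect_identical(sort(colnames(Xback)), sort(cfg$tf_names))
  expect_equal(sum(Xback), sum(ds$connectivity))

  truth <- read.delim(paths[["truth"]])
  expect_setequal(unique(truth$label), c("coherent", "divergent"))
  expect_setequal(truth$tf[truth$label == "coherent"], cfg$coherent_tfs)
})

test_that("writing an empty TF panel is rejected before any file appears", {
  cfg <- sim_config(n_genes = 20L, tf_names = c("a", "b"),
                    coherent_tfs = "a", connectivity_density = 0.5, seed = 1L)
  ds <- simulate_dataset(cfg)
  ds$config$tf_names <- character(0)
  dir <- file.path(withr::local_tempdir(), "empty_panel")
  expect_error(write_dataset(ds, dir), "empty TF panel")
  expect_false(dir.exists(dir))
})

test_that("replicate columns are generated with shared signal", {
  cfg <- sim_config(n_genes = 30L, connectivity_density = 0.3,
                    replicates = 2L, noise_sd = 0, seed = 6L)
  ds <- simulate_dataset(cfg)
  expect_identical(ncol(ds$expression$A), 10L)
  expect_identical(ds$expression$A[, 1L], ds$expression$A[, 2L])
})
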