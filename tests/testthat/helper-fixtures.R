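# Shared fixtures. The "standard fixture" (500 genes, 16 TFs, 5 time points,
# density 0.05, noise SD 0.1, seed 7) and its two condition fits are computed
# once per test run and reused across files.

fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, compute) {
  if (!exists(name, envir = fixture_cache, inherits = FALSE))
    assign(name, compute(), envir = fixture_cache)
  get(name, envir = fixture_cache, inherits = FALSE)
}

std_config <- function() {
  sim_config(n_genes = 500L, connectivity_density = 0.05, noise_sd = 0.1,
             seed = 7L)
}

std_dataset <- function() cache_get("std_dataset",
                                    function() simulate_dataset(std_config()))

std_fits <- function() cache_get("std_fits", function() {
  ds <- std_dataset()
  list(A = tfa(ds$expression$A, ds$connectivity, seed = 1L,
               max_iters = 2000L),
       B = tfa(ds$expression$B, ds$connectivity, seed = 2L,
               max_iters = 2000L))
})

std_coherence <- function() cache_get("std_coherence", function() {
  f <- std_fits()
  coherence_table(f$A, f$B, n_draws = 1000L, seed = 11L)
})

# Independent Pearson oracle via the raw definitional sums (no stats::cor).
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# A tiny deterministic expression fixture: 3 genes x 5 times, log2 scale.
tiny_expression <- function() {
  m <- matrix(c(1, 2, 3, 4, 5,
                -1, -2, -1, 0, 1,
                0.5, 0.25, 0, -0.25, -0.5),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("geneA", "geneB", "geneC"),
                              paste0("t", c(10, 20, 40, 60, 120))))
  m
}
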