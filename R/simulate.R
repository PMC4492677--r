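#' Transcription factors of the default comparison panel
#'
#' The sixteen E. coli transcription factors used as the default panel of the
#' synthetic generator and of two-condition coherence comparisons: global and
#' stress-response regulators whose regulons respond to CO-releasing-molecule
#' exposure (envelope stress, iron and oxidative-stress regulons among them).
#'
#' @return Character vector of 16 TF names.
#' @export
default_tf_panel <- function() {
  c("BaeR", "CpxR", "CRP", "CysB", "Fis", "FNR", "Fur", "GadX",
    "H-NS", "IHF", "IscR", "NarL", "NarP", "NsrR", "OxyR", "SoxS")
}

# Default coherent subset: regulators whose activity is taken to respond
# near-identically to the active compound and its CO-depleted control
# (envelope-stress and housekeeping regulators); the remaining eight diverge.
default_coherent_tfs <- function() {
  c("BaeR", "CpxR", "CRP", "FNR", "GadX", "IHF", "NarL", "NsrR")
}

#' Configuration of the synthetic two-condition experiment
#'
#' Collects the parameters of the generative model used to produce paired
#' time-course differential-expression datasets with known ground truth. The
#' defaults emulate an anaerobic E. coli exposure experiment: 4,598 genes
#' sampled 10, 20, 40, 60 and 120 min after compound addition, a sparse
#' regulon connectivity over 16 transcription factors, and two conditions
#' (A, an active-compound analogue; B, an inactivated-control analogue) that
#' share regulatory strengths and baselines but may differ in TF activities.
#'
#' @param n_genes Number of genes (default 4598, a full-genome array).
#' @param tf_names Character vector of transcription-factor names.
#' @param time_points_min Strictly increasing sampling times in minutes.
#' @param connectivity_density Probability that a given gene belongs to a
#'   given TF's regulon; in (0, 1].
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise on log2 ratios (non-negative).
#' @param coherent_tfs TFs whose true activity profile is identical in the
#'   two conditions.
#' @param divergent_tfs TFs whose activities are drawn independently per
#'   condition. Together with `coherent_tfs` this must partition `tf_names`.
#' @param strength_sd Standard deviation of the Gaussian regulatory
#'   strengths on regulon edges (non-negative).
#' @param baseline_sd Standard deviation of per-gene baseline log2 ratios
#'   (non-negative; log-ratio data are centred near zero).
#' @param replicates Number of i.i.d. noise replicates per time point
#'   (default 1; replicates repeat columns with fresh noise).
#' @param seed Non-negative integer seed governing all random draws.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_connectivity()], [generate_truth()],
#'   [generate_expression()], [simulate_dataset()]
#' @export
sim_config <- function(n_genes = 4598L,
                       tf_names = default_tf_panel(),
                       time_points_min = c(10, 20, 40, 60, 120),
                       connectivity_density = 0.02,
                       noise_sd = 0.1,
                       coherent_tfs = intersect(default_coherent_tfs(), tf_names),
                       divergent_tfs = setdiff(tf_names, coherent_tfs),
                       strength_sd = 1,
                       baseline_sd = 0.1,
                       replicates = 1L,
                       seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  if (!is.character(tf_names) || length(tf_names) < 1L ||
      anyDuplicated(tf_names))
    stop("'tf_names' must be a non-empty character vector without duplicates",
         call. = FALSE)
  if (!is.numeric(time_points_min) || length(time_points_min) < 2L ||
      any(time_points_min <= 0) || any(diff(time_points_min) <= 0))
    stop("'time_points_min' must be >= 2 strictly increasing positive times",
         call. = FALSE)
  if (!is.numeric(connectivity_density) || length(connectivity_density) != 1L ||
      connectivity_density <= 0 || connectivity_density > 1)
    stop("'connectivity_density' must lie in (0, 1]", call. = FALSE)
  check_non_negative(noise_sd, "noise_sd")
  check_non_negative(strength_sd, "strength_sd")
  check_non_negative(baseline_sd, "baseline_sd")
  replicates <- check_count(replicates, "replicates")
  seed <- check_count(seed, "seed", min = 0L)
  if (length(intersect(coherent_tfs, divergent_tfs)) > 0L ||
      !setequal(union(coherent_tfs, divergent_tfs), tf_names))
    stop("'coherent_tfs' and 'divergent_tfs' must partition 'tf_names'",
         call. = FALSE)
  structure(list(n_genes = n_genes,
                 tf_names = tf_names,
                 time_points_min = as.numeric(time_points_min),
                 connectivity_density = connectivity_density,
                 noise_sd = noise_sd,
                 coherent_tfs = coherent_tfs,
                 divergent_tfs = divergent_tfs,
                 strength_sd = strength_sd,
                 baseline_sd = baseline_sd,
                 replicates = replicates,
                 seed = seed),
            class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))

#' Sample a regulon connectivity matrix
#'
#' Draws a binary gene x TF membership matrix with independent
#' Bernoulli(density) entries, resampling any TF column with fewer than two
#' targets so every regulon is informative.
#'
#' @param config A [sim_config()] object.
#' @return Binary matrix (genes x TFs) with gene and TF dimnames.
#' @export
generate_connectivity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  m <- length(config$tf_names)
  with_seed(config$seed, {
    X <- matrix(rbinom(n * m, 1L, config$connectivity_density), n, m)
    for (j in seq_len(m)) {
      tries <- 0L
      while (sum(X[, j]) < 2L) {
        tries <- tries + 1L
        if (tries > 10000L)
          stop("could not sample >= 2 targets for TF '",
               config$tf_names[j], "'; raise 'connectivity_density'",
               call. = FALSE)
        X[, j] <- rbinom(n, 1L, config$connectivity_density)
      }
    }
    dimnames(X) <- list(sim_gene_ids(n), config$tf_names)
    X
  })
}

# One Gaussian random-walk profile over the minute grid: unit diffusion from
# an implicit zero state at t = 0, increments scaled by sqrt(delta t).
rw_profile <- function(times) cumsum(rnorm(length(times),
                                           sd = sqrt(diff(c(0, times)))))

#' Draw the ground truth of a synthetic experiment
#'
#' Latent TF activities are Gaussian random walks over the minute grid (unit
#' diffusion); coherent TFs share one profile across both conditions while
#' divergent TFs get independent draws. Regulatory strengths are Gaussian on
#' regulon edges and exactly zero elsewhere; both conditions share strengths
#' and per-gene baselines.
#'
#' @param config A [sim_config()] object.
#' @param connectivity Matrix from [generate_connectivity()] (dimensions must
#'   match the config).
#' @return An object of class `ground_truth`: list with `activities_A`,
#'   `activities_B` (TF x time), `strengths` (gene x TF), `baselines`,
#'   `noise_sd`, and the coherent/divergent labels.
#' @export
generate_truth <- function(config, connectivity) {
  stopifnot(inherits(config, "sim_config"))
  m <- length(config$tf_names)
  tt <- config$time_points_min
  if (!is.matrix(connectivity) || nrow(connectivity) != config$n_genes ||
      ncol(connectivity) != m)
    stop("'connectivity' dimensions do not match 'config'", call. = FALSE)
  with_seed(config$seed + 1L, {
    cA <- t(vapply(seq_len(m), function(i) rw_profile(tt), numeric(length(tt))))
    cB <- cA
    for (j in which(config$tf_names %in% config$divergent_tfs))
      cB[j, ] <- rw_profile(tt)
    dimnames(cA) <- dimnames(cB) <- list(config$tf_names, time_colnames(tt))
    B <- matrix(0, config$n_genes, m, dimnames = dimnames(connectivity))
    nz <- which(connectivity == 1L)
    B[nz] <- rnorm(length(nz), sd = config$strength_sd)
    structure(list(activities_A = cA,
                   activities_B = cB,
                   strengths = B,
                   baselines = stats::setNames(
                     rnorm(config$n_genes, sd = config$baseline_sd),
                     rownames(connectivity)),
                   noise_sd = config$noise_sd,
                   coherent_tfs = config$coherent_tfs,
                   divergent_tfs = config$divergent_tfs),
              class = "ground_truth")
  })
}

#' Generate paired-condition expression matrices from a ground truth
#'
#' Applies the bilinear observation model
#' `y[n, t] = mu[n] + sum_m X[n, m] b[n, m] c[m, t] + eps[n, t]`
#' with i.i.d. Gaussian noise, independently for the two conditions (which
#' share X, b and mu but use their own activities).
#'
#' @param truth A `ground_truth` object.
#' @param connectivity The matching connectivity matrix.
#' @param config The [sim_config()] the truth was drawn under.
#' @return List with elements `A` and `B`: gene x time numeric matrices of
#'   log2 ratios with a `condition` attribute. With `replicates > 1` each
#'   time column is repeated with fresh noise.
#' @export
generate_expression <- function(truth, connectivity, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (!identical(dim(connectivity), dim(truth$strengths)))
    stop("'connectivity' and truth strengths dimensions differ", call. = FALSE)
  signal <- function(acts) truth$baselines + truth$strengths %*% acts
  with_seed(config$seed + 2L, {
    out <- lapply(list(A = truth$activities_A, B = truth$activities_B),
                  function(acts) {
                    mu <- signal(acts)
                    if (config$replicates > 1L)
                      mu <- mu[, rep(seq_len(ncol(mu)),
                                     each = config$replicates), drop = FALSE]
                    y <- mu + rnorm(length(mu), sd = config$noise_sd)
                    dimnames(y) <- dimnames(mu)
                    y
                  })
    attr(out$A, "condition") <- "A"
    attr(out$B, "condition") <- "B"
    out
  })
}

#' Simulate a complete two-condition dataset
#'
#' Convenience wrapper running [generate_connectivity()], [generate_truth()]
#' and [generate_expression()] under one configuration.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `sim_dataset`: list with `config`, `connectivity`,
#'   `truth` and `expression` (list `A`/`B`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  connectivity <- generate_connectivity(config)
  truth <- generate_truth(config, connectivity)
  expr <- generate_expression(truth, connectivity, config)
  structure(list(config = config, connectivity = connectivity,
                 truth = truth, expression = expr),
            class = "sim_dataset")
}

#' Write a simulated dataset to tab-delimited files
#'
#' Emits `expression_A.tsv` and `expression_B.tsv` (gene x time log2 ratios),
#' `connectivity.tsv` (edge list: tf, gene, sign) and `truth.tsv`
#' (tf, condition, time_min, activity, label) into `dir`. Values round-trip
#' through the package readers to better than 12 significant digits.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (length(dataset$config$tf_names) == 0L)
    stop("dataset has an empty TF panel; nothing to write", call. = FALSE)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory '", dir, "'", call. = FALSE)
  paths <- c(expression_A = file.path(dir, "expression_A.tsv"),
             expression_B = file.path(dir, "expression_B.tsv"),
             connectivity = file.path(dir, "connectivity.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(dataset$expression$A, paths[["expression_A"]])
  write_expression(dataset$expression$B, paths[["expression_B"]])

  X <- dataset$connectivity
  nz <- which(X == 1L, arr.ind = TRUE)
  nz <- nz[order(nz[, "col"], nz[, "row"]), , drop = FALSE]
  edges <- data.frame(tf = colnames(X)[nz[, "col"]],
                      gene = rownames(X)[nz[, "row"]],
                      sign = ifelse(dataset$truth$strengths[nz] >= 0, 1L, -1L))
  utils::write.table(edges, paths[["connectivity"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  tr <- dataset$truth
  tt <- dataset$config$time_points_min
  long <- do.call(rbind, lapply(c("A", "B"), function(cond) {
    acts <- if (cond == "A") tr$activities_A else tr$activities_B
    data.frame(tf = rep(rownames(acts), each = length(tt)),
               condition = cond,
               time_min = rep(tt, nrow(acts)),
               activity = as.vector(t(acts)),
               label = rep(ifelse(rownames(acts) %in% tr$coherent_tfs,
                                  "coherent", "divergent"),
                           each = length(tt)))
  }))
  utils::write.table(long, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
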