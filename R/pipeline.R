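#' Run the full two-condition analysis pipeline
#'
#' Orchestrates one reproducible comparison: read the two expression
#' matrices and the regulon connectivity, fit TF activities independently
#' per condition, compute the coherence table, classify fold changes and
#' (when a category map is given) the per-category and genome-fraction
#' summaries, and write every result as TSV plus a JSON run report.
#'
#' @param config Either a named list or the path of a YAML file with keys:
#'   `expression_a`, `expression_b`, `connectivity` (paths, required);
#'   `categories` (path, optional); `out_dir` (required); `genome_size`
#'   (default 4598); `n_draws` (default 1000); `seed` (default 1);
#'   `hyperparams` (optional list passed to [tfa()]).
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  required <- c("expression_a", "expression_b", "connectivity", "out_dir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0L)
    stop("config is missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  for (key in c("expression_a", "expression_b", "connectivity", "categories"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config path '", key, "' does not exist: ", config[[key]],
           call. = FALSE)
  genome_size <- config$genome_size %||% 4598L
  n_draws <- config$n_draws %||% 1000L
  seed <- config$seed %||% 1L
  hp <- config$hyperparams %||% list()
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)

  report <- list(package_version = as.character(utils::packageVersion("tfcoherence")),
                 seed = seed, n_draws = n_draws, genome_size = genome_size,
                 hyperparams = hp, warnings = character(0), stages = list())
  note <- function(w) report$warnings <<- c(report$warnings,
                                            conditionMessage(w))
  run_stage <- function(name, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    }), error = function(e) {
      report$stages[[name]] <<- "FAILED"
      writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA),
                 file.path(out_dir, "report.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- "ok"
    res
  }

  exprs <- run_stage("read", {
    list(A = read_expression(config$expression_a, "A"),
         B = read_expression(config$expression_b, "B"))
  })
  X <- run_stage("connectivity", read_connectivity(config$connectivity))
  cats <- if (!is.null(config$categories))
    run_stage("categories", read_categories(config$categories)) else NULL

  fits <- run_stage("fit", lapply(exprs, function(y)
    do.call(tfa, c(list(expression = y, connectivity = X,
                        seed = hp$seed %||% seed),
                   hp[setdiff(names(hp), "seed")]))))
  report$converged <- lapply(fits, `[[`, "converged")
  report$elbo_trace <- lapply(fits, `[[`, "elbo_trace")
  report$noise_sd_hat <- lapply(fits, `[[`, "noise_sd_hat")
  report$dropped_tfs <- lapply(fits, `[[`, "dropped_tfs")

  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  run_stage("posteriors", for (cond in names(fits)) {
    f <- fits[[cond]]
    tsv(data.frame(tf = rep(f$tf_names, each = length(f$time_points_min)),
                   time_min = rep(f$time_points_min, length(f$tf_names)),
                   mean = as.vector(t(f$mean)),
                   variance = as.vector(t(f$variance))),
        sprintf("posterior_%s.tsv", cond))
    nz <- which(f$connectivity == 1L, arr.ind = TRUE)
    nz <- nz[order(nz[, "col"], nz[, "row"]), , drop = FALSE]
    tsv(data.frame(gene = f$gene_ids[nz[, "row"]],
                   tf = f$tf_names[nz[, "col"]],
                   mean = f$strengths_mean[nz]),
        sprintf("strengths_%s.tsv", cond))
  })

  coh <- run_stage("coherence",
                   coherence_table(fits$A, fits$B, n_draws = n_draws,
                                   seed = seed))
  report$excluded_tfs <- attr(coh, "excluded")
  run_stage("write_coherence", tsv(as.data.frame(coh), "coherence.tsv"))

  run_stage("summaries", for (cond in names(exprs)) {
    fc <- classify_fold_changes(exprs[[cond]], cats)
    gf <- genome_fraction_altered(fc, genome_size)
    tsv(gf, sprintf("genome_fraction_%s.tsv", cond))
    if (!is.null(cats)) {
      cp <- category_percentages(fc)
      tsv(cp, sprintf("category_summary_%s.tsv", cond))
    }
  })

  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "report.json"))
  invisible(report)
}
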