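#' Classify per-gene fold changes by the 2-fold / 0.5-fold rule
#'
#' Converts log2 ratios to the ratio scale (`fold_change = 2^value`) and
#' classifies every (gene, time) observation: `up` when the fold change is
#' >= 2, `down` when <= 0.5, otherwise `unchanged`. Both thresholds are
#' inclusive.
#'
#' @param x Gene x time numeric matrix of log2 ratios (as returned by
#'   [read_expression()]).
#' @param categories Optional named character vector from
#'   [read_categories()]; adds a `category` column (NA when unmapped).
#' @return A data frame of class `fold_change_table` with columns `gene_id`,
#'   `time_min`, `fold_change`, `direction` (factor up/down/unchanged) and
#'   `category`.
#' @export
classify_fold_changes <- function(x, categories = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  times <- times_from_colnames(x)
  fc <- 2^as.vector(x)
  out <- data.frame(
    gene_id = rep(rownames(x), times = ncol(x)),
    time_min = rep(times, each = nrow(x)),
    fold_change = fc,
    direction = factor(ifelse(fc >= 2, "up",
                              ifelse(fc <= 0.5, "down", "unchanged")),
                       levels = c("up", "down", "unchanged")),
    category = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(categories))
    out$category <- unname(categories[out$gene_id])
  out <- out[order(out$time_min, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Percentage of genes altered per functional category and time
#'
#' For every functional category and sampling time, the percentage of that
#' category's (measured, categorised) genes classified up and down. Genes
#' without a category are excluded from these summaries and counted in a
#' message. Categories left empty after exclusion are absent from the
#' result, not reported as zero.
#'
#' @param table A `fold_change_table` from [classify_fold_changes()].
#' @param categories Optional named character vector; used to (re)assign the
#'   `category` column when given.
#' @return Data frame with columns `category`, `time_min`, `n_genes`,
#'   `pct_up`, `pct_down` (percentages of `n_genes`; `pct_up + pct_down`
#'   never exceeds 100).
#' @export
category_percentages <- function(table, categories = NULL) {
  stopifnot(inherits(table, "fold_change_table"))
  if (!is.null(categories))
    table$category <- unname(categories[table$gene_id])
  unmapped <- unique(table$gene_id[is.na(table$category)])
  if (length(unmapped) > 0L)
    message(length(unmapped), " uncategorised gene(s) excluded from ",
            "category summaries")
  tab <- table[!is.na(table$category), , drop = FALSE]
  if (nrow(tab) == 0L)
    return(data.frame(category = character(), time_min = numeric(),
                      n_genes = integer(), pct_up = numeric(),
                      pct_down = numeric()))
  key <- interaction(tab$category, tab$time_min, drop = TRUE)
  agg <- do.call(rbind, lapply(split(tab, key), function(d) {
    data.frame(category = d$category[1L], time_min = d$time_min[1L],
               n_genes = nrow(d),
               pct_up = 100 * sum(d$direction == "up") / nrow(d),
               pct_down = 100 * sum(d$direction == "down") / nrow(d))
  }))
  agg <- agg[order(agg$category, agg$time_min), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Genome-wide fraction of up- and downregulated genes per time
#'
#' Percentages are denominated on the full genome size, not on the number of
#' measured genes, so unmeasured genes count as unchanged.
#'
#' @param table A `fold_change_table`.
#' @param genome_size Total number of genes in the genome (default 4598);
#'   must be at least the number of distinct genes in `table`.
#' @return Data frame with columns `time_min`, `n_up`, `n_down`, `pct_up`,
#'   `pct_down`.
#' @export
genome_fraction_altered <- function(table, genome_size = 4598L) {
  stopifnot(inherits(table, "fold_change_table"))
  genome_size <- check_count(genome_size, "genome_size")
  n_obs <- length(unique(table$gene_id))
  if (genome_size < n_obs)
    stop("'genome_size' (", genome_size, ") is smaller than the number of ",
         "measured genes (", n_obs, ")", call. = FALSE)
  times <- sort(unique(table$time_min))
  if (length(times) == 0L)
    return(data.frame(time_min = numeric(), n_up = integer(),
                      n_down = integer(), pct_up = numeric(),
                      pct_down = numeric()))
  out <- do.call(rbind, lapply(times, function(tm) {
    d <- table[table$time_min == tm, , drop = FALSE]
    data.frame(time_min = tm,
               n_up = sum(d$direction == "up"),
               n_down = sum(d$direction == "down"))
  }))
  out$pct_up <- 100 * out$n_up / genome_size
  out$pct_down <- 100 * out$n_down / genome_size
  out
}

#' Heat-map values: natural logarithm of the fold change
#'
#' The heat-scale convention for expression heat maps: `ln(fold_change)`,
#' so downregulation is negative, no change is 0, and genes inside the
#' (0.5, 2) unchanged band fall in (-ln 2, ln 2).
#'
#' @param table A `fold_change_table` with strictly positive fold changes.
#' @return Gene x time numeric matrix of `ln(fold_change)` values, genes in
#'   first-appearance order, times ascending.
#' @export
heat_values <- function(table) {
  stopifnot(inherits(table, "fold_change_table"))
  if (any(table$fold_change <= 0))
    stop("fold changes must be strictly positive to take logarithms",
         call. = FALSE)
  genes <- unique(table$gene_id)
  times <- sort(unique(table$time_min))
  h <- matrix(NA_real_, length(genes), length(times),
              dimnames = list(genes, time_colnames(times)))
  h[cbind(match(table$gene_id, genes), match(table$time_min, times))] <-
    log(table$fold_change)
  h
}
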