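#' Read a gene x time expression matrix
#'
#' Parses a tab-delimited file whose first column is `gene` and whose
#' remaining columns are `t<minutes>` (e.g. `t10`, `t120`) holding log2
#' expression ratios of treated versus control. Genes containing any missing
#' value are dropped with a message; duplicate gene identifiers and
#' non-numeric cells are errors.
#'
#' @param path Path to the TSV file.
#' @param condition_label Optional free-text label attached as the
#'   `condition` attribute (defaults to the file name without extension).
#' @return Numeric matrix (genes x times) with gene rownames and `t<min>`
#'   colnames; time points are recoverable via the column names.
#' @export
read_expression <- function(path, condition_label = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L || names(df)[1L] != "gene")
    stop("expression file must have a 'gene' column followed by t<min> columns",
         call. = FALSE)
  genes <- df[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L)
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !is.na(vals) &
                 toupper(trimws(vals)) != "NA" & trimws(vals) != "",
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]),
         call. = FALSE)
  rownames(num) <- genes
  keep <- stats::complete.cases(num)
  if (any(!keep))
    message(sum(!keep), " gene", if (sum(!keep) > 1L) "s" else "",
            " removed (missing values)")
  num <- num[keep, , drop = FALSE]
  times_from_colnames(num)  # validates the t<min> header convention
  attr(num, "condition") <- condition_label %||%
    sub("\\.[^.]*$", "", basename(path))
  num
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an expression matrix in the package TSV format
#'
#' @param x Gene x time numeric matrix with `t<min>` column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  times_from_colnames(x)
  df <- data.frame(gene = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-to-gene regulon edge list into a connectivity matrix
#'
#' The file has columns `tf` and `gene` (one regulon edge per line) and an
#' optional `sign` column, which is retained as an attribute for provenance
#' but ignored by the activity model (strengths are free-signed). Duplicate
#' edges are collapsed with a warning.
#'
#' @param path Path to the TSV edge list.
#' @return Binary matrix (genes x TFs) with a `sign` attribute (data frame of
#'   the deduplicated edges, if a sign column was present).
#' @export
read_connectivity <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("connectivity file '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L]))
    stop("malformed connectivity line ", which(nf != nf[1L])[1L],
         ": expected ", nf[1L], " tab-separated fields", call. = FALSE)
  header <- fields[[1L]]
  if (!all(c("tf", "gene") %in% header))
    stop("connectivity file must have 'tf' and 'gene' columns", call. = FALSE)
  df <- as.data.frame(do.call(rbind, fields[-1L]), stringsAsFactors = FALSE)
  names(df) <- header
  ndup <- sum(duplicated(df[c("tf", "gene")]))
  if (ndup > 0L) {
    warning(ndup, " duplicated regulon edge(s) collapsed", call. = FALSE)
    df <- df[!duplicated(df[c("tf", "gene")]), , drop = FALSE]
  }
  genes <- unique(df$gene)
  tfs <- unique(df$tf)
  X <- matrix(0L, length(genes), length(tfs), dimnames = list(genes, tfs))
  X[cbind(match(df$gene, genes), match(df$tf, tfs))] <- 1L
  if ("sign" %in% names(df)) attr(X, "sign") <- df
  X
}

#' Read a gene-to-functional-category map
#'
#' Two-column TSV (`gene`, `category`). A gene listed under several
#' categories is assigned to the first one listed; the multiplicity is
#' reported with a warning.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping gene id to category name.
#' @export
read_categories <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("category file '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop("malformed category line ", which(nf != 2L)[1L],
         ": expected 2 tab-separated fields", call. = FALSE)
  header <- fields[[1L]]
  if (!identical(header, c("gene", "category")))
    stop("category file must have columns 'gene' and 'category'",
         call. = FALSE)
  df <- as.data.frame(do.call(rbind, fields[-1L]), stringsAsFactors = FALSE)
  names(df) <- header
  nmulti <- sum(duplicated(df$gene))
  if (nmulti > 0L)
    warning(nmulti, " gene(s) listed in multiple categories; ",
            "first listing kept", call. = FALSE)
  df <- df[!duplicated(df$gene), , drop = FALSE]
  stats::setNames(df$category, df$gene)
}
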