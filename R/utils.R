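# Internal helpers shared across the package.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never disturb user-level randomness.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Scalar validators; `what` names the offending field in error messages.
check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", what), call. = FALSE)
  invisible(x)
}

check_non_negative <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", what),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", what, min), call. = FALSE)
  invisible(as.integer(x))
}

# Time points are read from expression column names of the form t<minutes>.
times_from_colnames <- function(x) {
  cn <- colnames(x)
  if (is.null(cn) || !all(grepl("^t[0-9.]+$", cn)))
    stop("expression column names must have the form t<minutes>, e.g. 't10'",
         call. = FALSE)
  as.numeric(sub("^t", "", cn))
}

time_colnames <- function(times) paste0("t", format(times, trim = TRUE,
                                                    scientific = FALSE))
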