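#' Profile difference: 1 minus the absolute Pearson correlation
#'
#' The abscissa of the coherence plot. Two profiles whose shapes agree up
#' to an affine map (in particular up to a sign flip) score 0; shapes with
#' no linear association score 1.
#'
#' @param a,b Numeric activity profiles of equal length (>= 3) and nonzero
#'   variance.
#' @return A value in \[0, 1\], or `NA_real_` with a warning when either
#'   profile has zero variance (the Pearson correlation is then undefined
#'   and the TF should be excluded, not scored).
#' @export
profile_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  if (length(a) < 3L) stop("profiles must have length >= 3", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero-variance profile: profile difference undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - abs(stats::cor(a, b))
}

#' Magnitude difference: absolute difference of profile norms
#'
#' The ordinate of the coherence plot: `| ||a||_2 - ||b||_2 |` over the
#' shared time grid.
#'
#' @param a,b Numeric profiles of equal length.
#' @return Non-negative real.
#' @export
magnitude_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  abs(sqrt(sum(a^2)) - sqrt(sum(b^2)))
}

#' Assign coherence-plot quadrants
#'
#' The plot is partitioned at (`x_split`, `y_split`): quadrant C (similar
#' kinetics and magnitude) is low/low near the origin, B (different in both)
#' is high/high, A is low profile difference but high magnitude difference,
#' and D the reverse.
#'
#' @param x Profile differences (vectorised).
#' @param y Magnitude differences.
#' @param x_split,y_split Non-negative split points.
#' @return Character vector of labels in `c("A", "B", "C", "D")`.
#' @export
quadrant_assign <- function(x, y, x_split, y_split) {
  check_non_negative(x_split, "x_split")
  check_non_negative(y_split, "y_split")
  ifelse(x < x_split,
         ifelse(y < y_split, "C", "A"),
         ifelse(y < y_split, "D", "B"))
}

# Per-draw |Pearson| and magnitude-difference statistics for one TF given
# paired sample arrays (draw x time) from the two conditions.
draw_stats <- function(da, db) {
  va <- apply(da, 1L, stats::var)
  vb <- apply(db, 1L, stats::var)
  ok <- va > 0 & vb > 0
  rho <- rep(NA_real_, nrow(da))
  rho[ok] <- abs(vapply(which(ok), function(i) stats::cor(da[i, ], db[i, ]),
                        numeric(1L)))
  list(abs_corr = rho[ok],
       mag_diff = abs(sqrt(rowSums(da^2)) - sqrt(rowSums(db^2)))[ok])
}

#' Coherence statistics for one TF between two fitted conditions
#'
#' Point coordinates come from the posterior-mean profiles; the mean and SD
#' of the absolute Pearson correlation, and both error-bar half-widths, come
#' from Monte-Carlo draws from the two marginal posteriors ([sample_activities()],
#' independently seeded per condition). The horizontal half-width equals the
#' SD of the absolute correlation (since x = 1 - |rho|); the vertical one is
#' the SD of the draw-wise magnitude difference.
#'
#' @param fit_a,fit_b [tfa()] fits of the two conditions on identical time
#'   grids.
#' @param tf TF name present in both fits.
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed Seed; condition B uses `seed + 1`.
#' @param x_split,y_split Quadrant splits (defaults 0.5 and the point's own
#'   magnitude difference cannot define a median, so `y_split` defaults to
#'   `Inf`, i.e. no vertical split, when scoring a single TF).
#' @return One-row data frame with columns `tf`, `profile_difference`,
#'   `magnitude_difference`, `mean_abs_corr`, `sd_abs_corr`, `x_err`,
#'   `y_err`, `quadrant`, or `NULL` (with a warning) when the TF's mean
#'   profile has zero variance.
#' @export
coherence_point <- function(fit_a, fit_b, tf, n_draws = 1000L, seed = 1L,
                            x_split = 0.5, y_split = Inf) {
  stopifnot(inherits(fit_a, "tfa"), inherits(fit_b, "tfa"))
  if (!isTRUE(all.equal(fit_a$time_points_min, fit_b$time_points_min)))
    stop("the two fits use different time grids", call. = FALSE)
  for (f in list(fit_a, fit_b))
    if (!tf %in% f$tf_names)
      stop("TF '", tf, "' not present in both fits", call. = FALSE)
  a <- fit_a$mean[tf, ]
  b <- fit_b$mean[tf, ]
  pd <- profile_difference(a, b)
  if (is.na(pd)) {
    warning("TF '", tf, "' excluded: zero-variance mean profile",
            call. = FALSE)
    return(NULL)
  }
  da <- sample_activities(fit_a, n_draws, seed)[, , tf]
  db <- sample_activities(fit_b, n_draws, seed + 1L)[, , tf]
  st <- draw_stats(da, db)
  md <- magnitude_difference(a, b)
  data.frame(tf = tf,
             profile_difference = pd,
             magnitude_difference = md,
             mean_abs_corr = mean(st$abs_corr),
             sd_abs_corr = stats::sd(st$abs_corr),
             x_err = stats::sd(st$abs_corr),
             y_err = stats::sd(st$mag_diff),
             quadrant = quadrant_assign(pd, md, x_split,
                                        if (is.finite(y_split)) y_split
                                        else md + 1),
             stringsAsFactors = FALSE)
}

#' Coherence table comparing all shared TFs between two conditions
#'
#' One row per TF present in both fits, sorted by TF name: coherence-plot
#' coordinates, Monte-Carlo mean/SD of the absolute Pearson correlation,
#' error-bar half-widths and quadrant labels. TFs with a zero-variance mean
#' profile are excluded and listed in the `excluded` attribute.
#'
#' @param fit_a,fit_b [tfa()] fits of the two conditions.
#' @param n_draws Monte-Carlo draws per condition (default 1000).
#' @param seed Seed (condition B uses `seed + 1`).
#' @param x_split Profile-difference split for quadrant labels (default 0.5).
#' @param y_split Magnitude-difference split; default is the median
#'   magnitude difference over the plotted TFs.
#' @return Data frame of class `coherence_table` with attributes `excluded`
#'   (character vector) and `splits`.
#' @export
coherence_table <- function(fit_a, fit_b, n_draws = 1000L, seed = 1L,
                            x_split = 0.5, y_split = NULL) {
  stopifnot(inherits(fit_a, "tfa"), inherits(fit_b, "tfa"))
  if (!isTRUE(all.equal(fit_a$time_points_min, fit_b$time_points_min)))
    stop("the two fits use different time grids", call. = FALSE)
  shared <- sort(intersect(fit_a$tf_names, fit_b$tf_names))
  if (length(shared) == 0L)
    stop("no TFs shared between the two fits", call. = FALSE)
  n_draws <- check_count(n_draws, "n_draws", min = 2L)
  da <- sample_activities(fit_a, n_draws, seed)
  db <- sample_activities(fit_b, n_draws, seed + 1L)
  excluded <- character(0)
  rows <- list()
  for (tf in shared) {
    a <- fit_a$mean[tf, ]
    b <- fit_b$mean[tf, ]
    pd <- suppressWarnings(profile_difference(a, b))
    if (is.na(pd)) {
      excluded <- c(excluded, tf)
      next
    }
    st <- draw_stats(da[, , tf], db[, , tf])
    rows[[tf]] <- data.frame(tf = tf,
                             profile_difference = pd,
                             magnitude_difference = magnitude_difference(a, b),
                             mean_abs_corr = mean(st$abs_corr),
                             sd_abs_corr = stats::sd(st$abs_corr),
                             x_err = stats::sd(st$abs_corr),
                             y_err = stats::sd(st$mag_diff),
                             stringsAsFactors = FALSE)
  }
  if (length(excluded) > 0L)
    warning("TF(s) excluded (zero-variance profile): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  if (length(rows) == 0L)
    stop("all shared TFs were excluded", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(y_split)) y_split <- stats::median(out$magnitude_difference)
  out$quadrant <- quadrant_assign(out$profile_difference,
                                  out$magnitude_difference, x_split, y_split)
  attr(out, "excluded") <- excluded
  attr(out, "splits") <- c(x_split = x_split, y_split = y_split)
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  class(out) <- c("coherence_table", "data.frame")
  out
}

#' @export
print.coherence_table <- function(x, digits = 3, ...) {
  cat(sprintf("Coherence comparison of %d TF(s) (%d Monte-Carlo draws)\n",
              nrow(x), attr(x, "n_draws") %||% NA_integer_))
  print.data.frame(x, digits = digits, row.names = FALSE)
  excl <- attr(x, "excluded")
  if (length(excl) > 0L)
    cat("Excluded (zero-variance profile):", paste(excl, collapse = ", "),
        "\n")
  invisible(x)
}

#' Coherence plot
#'
#' Scatter of profile difference (x) against magnitude difference (y), one
#' point per TF with horizontal/vertical error bars and quadrant split
#' lines. TFs near the origin (quadrant C) respond with similar kinetics
#' and amplitude in the two conditions; quadrant B collects TFs that differ
#' in both.
#'
#' @param x A [coherence_table()].
#' @param labels Draw TF names next to the points (default TRUE).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coherence_table <- function(x, labels = TRUE, ...) {
  sp <- attr(x, "splits")
  xe <- x$x_err
  ye <- x$y_err
  graphics::plot(x$profile_difference, x$magnitude_difference,
                 xlim = c(0, max(1, x$profile_difference + xe)),
                 ylim = c(0, max(x$magnitude_difference + ye) * 1.05),
                 pch = 19, col = "steelblue4",
                 xlab = "Profile difference (1 - |Pearson r|)",
                 ylab = "Magnitude difference (| ||a|| - ||b|| |)", ...)
  graphics::segments(x$profile_difference - xe, x$magnitude_difference,
                     x$profile_difference + xe, x$magnitude_difference,
                     col = "grey60")
  graphics::segments(x$profile_difference, x$magnitude_difference - ye,
                     x$profile_difference, x$magnitude_difference + ye,
                     col = "grey60")
  if (!is.null(sp)) graphics::abline(v = sp["x_split"], h = sp["y_split"],
                                     lty = 3)
  if (labels)
    graphics::text(x$profile_difference, x$magnitude_difference, x$tf,
                   pos = 3, cex = 0.7)
  invisible(x)
}
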