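#' @export
print.tfa <- function(x, ...) {
  cat("Regulon-constrained TF activity model (variational Bayes)\n")
  if (!is.null(x$condition)) cat("Condition:", x$condition, "\n")
  cat(sprintf("%d genes, %d TFs, %d time points (%s min)\n",
              length(x$gene_ids), length(x$tf_names),
              length(x$time_points_min),
              paste(x$time_points_min, collapse = ", ")))
  cat(sprintf("ELBO %.3f after %d sweeps (%s); noise SD %.4g\n",
              utils::tail(x$elbo_trace, 1L), length(x$elbo_trace),
              if (x$converged) "converged" else "NOT converged",
              x$noise_sd_hat))
  if (length(x$dropped_tfs) > 0L)
    cat("Dropped TFs (no measured targets):",
        paste(x$dropped_tfs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tfa <- function(object, ...) {
  act <- object$mean
  out <- data.frame(tf = object$tf_names,
                    n_targets = colSums(object$connectivity),
                    activity_min = apply(act, 1L, min),
                    activity_max = apply(act, 1L, max),
                    activity_norm = sqrt(rowSums(act^2)),
                    mean_posterior_sd = rowMeans(sqrt(object$variance)),
                    row.names = NULL)
  structure(list(table = out, noise_sd_hat = object$noise_sd_hat,
                 converged = object$converged,
                 elbo = utils::tail(object$elbo_trace, 1L)),
            class = "summary.tfa")
}

#' @export
print.summary.tfa <- function(x, ...) {
  cat(sprintf("TF activity fit: ELBO %.3f (%s), noise SD %.4g\n\n",
              x$elbo, if (x$converged) "converged" else "not converged",
              x$noise_sd_hat))
  print(x$table, digits = 3)
  invisible(x)
}

#' Posterior mean coefficients of a TF activity fit
#'
#' @param object A [tfa()] fit.
#' @param type `"activities"` (TF x time posterior mean, the default) or
#'   `"strengths"` (gene x TF posterior mean regulatory strengths).
#' @param ... Unused.
#' @export
coef.tfa <- function(object, type = c("activities", "strengths"), ...) {
  switch(match.arg(type),
         activities = object$mean,
         strengths = object$strengths_mean)
}

#' @export
fitted.tfa <- function(object, ...) {
  object$baseline_mean + object$strengths_mean %*% object$mean
}

#' @export
residuals.tfa <- function(object, ...) {
  object$expression - fitted(object)
}

#' Predicted expression under the fitted model
#'
#' @param object A [tfa()] fit.
#' @param genes Optional subset of gene ids to predict for.
#' @param ... Unused.
#' @return Gene x time matrix of posterior-mean reconstructions.
#' @export
predict.tfa <- function(object, genes = NULL, ...) {
  yhat <- fitted(object)
  if (is.null(genes)) return(yhat)
  missing <- setdiff(genes, rownames(yhat))
  if (length(missing) > 0L)
    stop("unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  yhat[genes, , drop = FALSE]
}

#' Simulate expression data from a fitted activity model
#'
#' Parametric-bootstrap replicates: posterior-mean reconstruction plus
#' Gaussian noise at the fitted noise scale.
#'
#' @param object A [tfa()] fit.
#' @param nsim Number of replicate matrices.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` gene x time matrices.
#' @export
simulate.tfa <- function(object, nsim = 1, seed = NULL, ...) {
  yhat <- fitted(object)
  gen <- function() yhat + rnorm(length(yhat), sd = object$noise_sd_hat)
  sims <- if (is.null(seed)) replicate(nsim, gen(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
  lapply(sims, function(s) { dimnames(s) <- dimnames(yhat); s })
}

#' Plot inferred TF activity profiles
#'
#' One panel per TF: posterior mean across time with a +/- 2 SD band.
#'
#' @param x A [tfa()] fit.
#' @param tfs TFs to plot (default all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tfa <- function(x, tfs = x$tf_names, ...) {
  tfs <- intersect(tfs, x$tf_names)
  if (length(tfs) == 0L) stop("no matching TFs to plot", call. = FALSE)
  nc <- ceiling(sqrt(length(tfs)))
  nr <- ceiling(length(tfs) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  tt <- x$time_points_min
  for (tf in tfs) {
    mu <- x$mean[tf, ]
    sdv <- sqrt(x$variance[tf, ])
    ylim <- range(mu + 2 * sdv, mu - 2 * sdv)
    graphics::plot(tt, mu, type = "n", ylim = ylim, xlab = "", ylab = "",
                   main = tf, ...)
    graphics::polygon(c(tt, rev(tt)), c(mu + 2 * sdv, rev(mu - 2 * sdv)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(tt, mu, lwd = 2, col = "steelblue4")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
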