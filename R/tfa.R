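#' Infer transcription-factor activity profiles by variational Bayes
#'
#' Fits the regulon-constrained bilinear factor model
#' \deqn{y_{nt} = \mu_n + \sum_m X_{nm} b_{nm} c_{mt} + \epsilon_{nt},
#'   \qquad \epsilon_{nt} \sim N(0, \sigma^2)}
#' to a gene x time log-ratio expression matrix `y`, where `X` is a binary
#' regulon membership matrix, `b` are gene-specific regulatory strengths,
#' `mu` are gene baselines and `c` are the latent TF activity profiles of
#' interest. Priors: `b ~ N(0, strength_prior_sd^2)` on regulon edges,
#' `mu ~ N(0, baseline_prior_sd^2)`, and a Gaussian random walk on each
#' activity profile, `c[m, t] ~ N(c[m, t-1], rw_scale^2 * dt)` with
#' `c[m, 1] ~ N(0, 1)`. Inference is coordinate-ascent variational Bayes
#' with a Gaussian factor per activity profile, a joint Gaussian factor per
#' gene over its baseline and strengths, and a closed-form point update of
#' the shared noise scale; the evidence lower bound (ELBO) is monitored and
#' is non-decreasing across sweeps.
#'
#' The bilinear form is unidentifiable up to a per-TF sign/scale: rescaling
#' one TF's strengths by `a > 0` and its activities by `1/a` leaves the
#' likelihood unchanged. After convergence a deterministic gauge is applied:
#' each TF's strength vector is scaled to unit Euclidean norm (the activity
#' absorbs the scale, its variance the squared scale) and the sign is chosen
#' so the largest-magnitude strength entry is positive.
#'
#' @param expression Gene x time numeric matrix of log2 ratios with
#'   `t<min>` column names ([read_expression()] output). Replicate columns
#'   sharing a time label are averaged before fitting.
#' @param connectivity Binary gene x TF matrix ([read_connectivity()]
#'   output). Genes absent from `expression` are ignored; TFs with no
#'   measured target are dropped with a warning; measured genes without any
#'   regulator still inform the baseline and noise estimates.
#' @param strength_prior_sd,baseline_prior_sd Prior standard deviations of
#'   strengths and baselines (default 1).
#' @param rw_scale Random-walk prior scale of the activities per square-root
#'   minute (default 0.1).
#' @param noise_sd_init Initial noise standard deviation (default 0.5).
#' @param max_iters Maximum number of coordinate-ascent sweeps (default 500).
#' @param elbo_rel_tol Relative ELBO-change convergence tolerance, checked
#'   from the second sweep on (default 1e-6).
#' @param seed Seed for the (small, Gaussian) strength initialisation; the
#'   fit is deterministic given the seed.
#' @param verbose Print the ELBO each sweep.
#'
#' @return Object of class `tfa` with components `mean` and `variance`
#'   (TF x time posterior moments of the activities), `cov` (per-TF
#'   time x time posterior covariances), `strengths_mean` (gene x TF, zero
#'   off-regulon), `baseline_mean`, `noise_sd_hat`, `elbo_trace`,
#'   `converged`, `dropped_tfs`, plus the aligned inputs used.
#' @seealso [sample_activities()], [coherence_table()]
#' @export
tfa <- function(expression, connectivity,
                strength_prior_sd = 1, baseline_prior_sd = 1,
                rw_scale = 0.1, noise_sd_init = 0.5,
                max_iters = 500L, elbo_rel_tol = 1e-6,
                seed = 1L, verbose = FALSE) {
  check_positive(strength_prior_sd, "strength_prior_sd")
  check_positive(baseline_prior_sd, "baseline_prior_sd")
  check_positive(rw_scale, "rw_scale")
  check_positive(noise_sd_init, "noise_sd_init")
  max_iters <- check_count(max_iters, "max_iters")
  check_positive(elbo_rel_tol, "elbo_rel_tol")
  seed <- check_count(seed, "seed", min = 0L)
  stopifnot(is.matrix(expression), is.numeric(expression),
            is.matrix(connectivity))

  times_all <- times_from_colnames(expression)
  # Replicate arrays appear as repeated time columns: average them.
  if (anyDuplicated(times_all)) {
    ut <- sort(unique(times_all))
    Y <- vapply(ut, function(tm)
      rowMeans(expression[, times_all == tm, drop = FALSE]),
      numeric(nrow(expression)))
    dimnames(Y) <- list(rownames(expression), time_colnames(ut))
    expression <- Y
    times_all <- ut
  }
  tt <- times_all
  Tn <- length(tt)
  if (Tn < 2L) stop("need at least 2 time points", call. = FALSE)

  genes <- rownames(expression)
  if (is.null(genes) || is.null(rownames(connectivity)) ||
      is.null(colnames(connectivity)))
    stop("'expression' and 'connectivity' need gene/TF dimnames",
         call. = FALSE)
  if (length(intersect(genes, rownames(connectivity))) == 0L)
    stop("no genes shared between expression matrix and connectivity",
         call. = FALSE)
  X <- matrix(0L, length(genes), ncol(connectivity),
              dimnames = list(genes, colnames(connectivity)))
  common <- intersect(genes, rownames(connectivity))
  X[common, ] <- (connectivity[common, , drop = FALSE] != 0) + 0L
  dropped <- colnames(X)[colSums(X) == 0L]
  if (length(dropped) > 0L) {
    warning("dropping TF(s) with no measured targets: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, colSums(X) > 0L, drop = FALSE]
  }
  if (ncol(X) == 0L)
    stop("no TF has any measured target gene", call. = FALSE)
  tfs <- colnames(X)
  M <- ncol(X)
  N <- length(genes)
  Y <- expression

  # Random-walk prior precision over the time grid (tridiagonal).
  Q0 <- matrix(0, Tn, Tn)
  Q0[1L, 1L] <- 1
  dts <- diff(tt)
  for (t in 2:Tn) {
    w <- 1 / (rw_scale^2 * dts[t - 1L])
    Q0[t - 1L, t - 1L] <- Q0[t - 1L, t - 1L] + w
    Q0[t, t] <- Q0[t, t] + w
    Q0[t - 1L, t] <- Q0[t - 1L, t] - w
    Q0[t, t - 1L] <- Q0[t, t - 1L] - w
  }
  logdetQ0 <- 2 * sum(log(diag(chol(Q0))))

  # Group genes by regulon pattern: genes with the same active TF set share
  # the same posterior precision, so updates solve one small system per
  # pattern instead of one per gene.
  pat_key <- apply(X, 1L, function(r) paste(which(r == 1L), collapse = ","))
  groups <- split(seq_len(N), pat_key)
  patterns <- lapply(groups, function(idx) {
    active <- X[idx[1L], ] == 1L
    list(idx = idx,
         active = which(active),
         Y = Y[idx, , drop = FALSE])
  })
  P <- length(patterns)
  pats_with_tf <- lapply(seq_len(M), function(m)
    which(vapply(patterns, function(p) m %in% p$active, logical(1L))))

  # Variational state. Per pattern: mean matrix (|G| x (k+1), column 1 is
  # the baseline) and shared covariance S. Per TF: mean profile and T x T
  # covariance.
  state <- with_seed(seed, lapply(patterns, function(p) {
    k <- length(p$active)
    mean0 <- cbind(rowMeans(p$Y),
                   matrix(rnorm(length(p$idx) * k, sd = 0.1),
                          length(p$idx), k))
    P0 <- diag(c(1 / baseline_prior_sd^2, rep(1 / strength_prior_sd^2, k)),
               k + 1L)
    list(mean = mean0, S = diag(1 / diag(P0), k + 1L), P0 = P0,
         logdetP0 = sum(log(diag(P0))))
  }))
  cmean <- matrix(0, M, Tn, dimnames = list(tfs, time_colnames(tt)))
  cvar <- matrix(1, M, Tn, dimnames = dimnames(cmean))
  Vc <- rep(list(diag(1, Tn)), M)
  sigma2 <- noise_sd_init^2

  elbo_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iters)) {
    # --- update each activity profile q(c_m) ---
    for (m in seq_len(M)) {
      prec_add <- 0
      lin <- numeric(Tn)
      for (pi in pats_with_tf[[m]]) {
        p <- patterns[[pi]]
        st <- state[[pi]]
        j <- match(m, p$active) + 1L
        Ebm <- st$mean[, j]
        G <- length(p$idx)
        prec_add <- prec_add + sum(Ebm^2) + G * st$S[j, j]
        contrib <- drop(crossprod(p$Y, Ebm)) -
          (sum(Ebm * st$mean[, 1L]) + G * st$S[1L, j])
        for (m2 in p$active[p$active != m]) {
          j2 <- match(m2, p$active) + 1L
          coefm <- sum(Ebm * st$mean[, j2]) + G * st$S[j, j2]
          contrib <- contrib - coefm * cmean[m2, ]
        }
        lin <- lin + contrib
      }
      Lam <- Q0 + diag(prec_add / sigma2, Tn)
      R <- chol(Lam)
      V <- chol2inv(R)
      cmean[m, ] <- drop(V %*% (lin / sigma2))
      cvar[m, ] <- diag(V)
      Vc[[m]] <- V
    }

    # --- update each gene-block factor q(mu_n, b_n.) ---
    for (pi in seq_len(P)) {
      p <- patterns[[pi]]
      A <- p$active
      EZ <- rbind(1, cmean[A, , drop = FALSE])
      ZZ <- tcrossprod(EZ)
      if (length(A) > 0L) {
        d <- c(0, rowSums(cvar[A, , drop = FALSE]))
        ZZ <- ZZ + diag(d, length(d))
      }
      Lam <- state[[pi]]$P0 + ZZ / sigma2
      S <- chol2inv(chol(Lam))
      state[[pi]]$S <- (S + t(S)) / 2
      state[[pi]]$mean <- (p$Y %*% t(EZ)) %*% S / sigma2
    }

    # --- gauge rebalancing (parameter-expanded VB) ---
    # The likelihood is flat along per-TF scalings b -> b/alpha, c -> alpha*c,
    # which makes plain coordinate ascent crawl. Transferring scale between
    # the strength and activity factors with the ELBO-optimal alpha (closed
    # form below) leaves every likelihood expectation unchanged and exactly
    # maximises the prior + entropy terms over alpha, so the ELBO cannot
    # decrease.
    for (m in seq_len(M)) {
      Sc <- drop(cmean[m, ] %*% Q0 %*% cmean[m, ]) + sum(Q0 * Vc[[m]])
      Sb <- 0
      Gm <- 0L
      for (pi in pats_with_tf[[m]]) {
        p <- patterns[[pi]]
        st <- state[[pi]]
        j <- match(m, p$active) + 1L
        Sb <- Sb + sum(st$mean[, j]^2) + length(p$idx) * st$S[j, j]
        Gm <- Gm + length(p$idx)
      }
      if (Sc <= 0 || Sb <= 0) next
      dfree <- Tn - Gm
      u <- (dfree + sqrt(dfree^2 + 4 * Sc * Sb / strength_prior_sd^2)) /
        (2 * Sc)
      alpha <- sqrt(u)
      cmean[m, ] <- cmean[m, ] * alpha
      cvar[m, ] <- cvar[m, ] * u
      Vc[[m]] <- Vc[[m]] * u
      for (pi in pats_with_tf[[m]]) {
        j <- match(m, patterns[[pi]]$active) + 1L
        state[[pi]]$mean[, j] <- state[[pi]]$mean[, j] / alpha
        state[[pi]]$S[j, ] <- state[[pi]]$S[j, ] / alpha
        state[[pi]]$S[, j] <- state[[pi]]$S[, j] / alpha
      }
    }

    # --- expected sum of squared errors and noise update ---
    sse <- 0
    for (pi in seq_len(P)) {
      p <- patterns[[pi]]
      st <- state[[pi]]
      A <- p$active
      G <- length(p$idx)
      EZ <- rbind(1, cmean[A, , drop = FALSE])
      Eu <- st$mean %*% EZ
      sse <- sse + sum((p$Y - Eu)^2)
      # activity-variance term: sum_t var(c_mt) * E[b_nm^2]
      for (m in A) {
        j <- match(m, A) + 1L
        sse <- sse + sum(cvar[m, ]) *
          (sum(st$mean[, j]^2) + G * st$S[j, j])
      }
      # strength/baseline-covariance term: sum_t Ez' S Ez per gene
      sse <- sse + G * sum(EZ * (st$S %*% EZ))
    }
    sigma2 <- max(sse / (N * Tn), 1e-12)

    # --- ELBO ---
    elbo <- -N * Tn / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2)
    for (pi in seq_len(P)) {
      st <- state[[pi]]
      G <- nrow(st$mean)
      d <- ncol(st$mean)
      quad <- sum((st$mean %*% st$P0) * st$mean)
      logdetS <- 2 * sum(log(diag(chol(st$S))))
      elbo <- elbo - 0.5 * (G * sum(diag(st$P0 %*% st$S)) + quad -
                              G * d - G * logdetS - G * st$logdetP0)
    }
    for (m in seq_len(M)) {
      logdetV <- 2 * sum(log(diag(chol(Vc[[m]]))))
      elbo <- elbo - 0.5 * (sum(diag(Q0 %*% Vc[[m]])) +
                              drop(cmean[m, ] %*% Q0 %*% cmean[m, ]) -
                              Tn - logdetV - logdetQ0)
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (verbose)
      cat(sprintf("sweep %3d  ELBO %.6f\n", iter, elbo))
    if (iter >= 2L) {
      prev <- elbo_trace[iter - 1L]
      if (abs(elbo - prev) < elbo_rel_tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("variational fit did not converge in ", max_iters, " sweeps",
            call. = FALSE)

  # Assemble gene-level posterior means.
  Bmean <- matrix(0, N, M, dimnames = list(genes, tfs))
  mu_mean <- numeric(N)
  for (pi in seq_len(P)) {
    p <- patterns[[pi]]
    st <- state[[pi]]
    mu_mean[p$idx] <- st$mean[, 1L]
    if (length(p$active) > 0L)
      Bmean[p$idx, p$active] <- st$mean[, -1L, drop = FALSE]
  }
  names(mu_mean) <- genes

  # Gauge fixing: unit-norm strengths, dominant strength entry positive.
  for (m in seq_len(M)) {
    s <- sqrt(sum(Bmean[, m]^2))
    if (s > 0) {
      Bmean[, m] <- Bmean[, m] / s
      cmean[m, ] <- cmean[m, ] * s
      cvar[m, ] <- cvar[m, ] * s^2
      Vc[[m]] <- Vc[[m]] * s^2
    }
    jmax <- which.max(abs(Bmean[, m]))
    if (length(jmax) == 1L && Bmean[jmax, m] < 0) {
      Bmean[, m] <- -Bmean[, m]
      cmean[m, ] <- -cmean[m, ]
    }
  }

  structure(list(tf_names = tfs,
                 time_points_min = tt,
                 mean = cmean,
                 variance = cvar,
                 cov = stats::setNames(Vc, tfs),
                 strengths_mean = Bmean,
                 baseline_mean = mu_mean,
                 noise_sd_hat = sqrt(sigma2),
                 elbo_trace = elbo_trace,
                 converged = converged,
                 dropped_tfs = dropped,
                 gene_ids = genes,
                 connectivity = X,
                 expression = Y,
                 condition = attr(expression, "condition"),
                 hyperparams = list(strength_prior_sd = strength_prior_sd,
                                    baseline_prior_sd = baseline_prior_sd,
                                    rw_scale = rw_scale,
                                    noise_sd_init = noise_sd_init,
                                    max_iters = max_iters,
                                    elbo_rel_tol = elbo_rel_tol,
                                    seed = seed),
                 call = match.call()),
            class = "tfa")
}

#' Draw Monte-Carlo samples of TF activity profiles
#'
#' Independent Gaussian draws from the marginal posterior of each
#' (TF, time) activity, used to propagate inference uncertainty into
#' derived statistics such as coherence-plot error bars.
#'
#' @param fit A [tfa()] fit.
#' @param n_draws Number of draws (>= 2).
#' @param seed Seed making the draws reproducible.
#' @return Object of class `tfa_samples`: a 3-D array with dimensions
#'   (draw, time, TF) and a `seed` attribute.
#' @export
sample_activities <- function(fit, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "tfa"))
  n_draws <- check_count(n_draws, "n_draws", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  Tn <- length(fit$time_points_min)
  M <- length(fit$tf_names)
  draws <- with_seed(seed, {
    a <- array(rnorm(n_draws * Tn * M), dim = c(n_draws, Tn, M),
               dimnames = list(NULL, colnames(fit$mean), fit$tf_names))
    for (m in seq_len(M))
      a[, , m] <- a[, , m] * rep(sqrt(fit$variance[m, ]), each = n_draws) +
        rep(fit$mean[m, ], each = n_draws)
    a
  })
  attr(draws, "seed") <- seed
  class(draws) <- c("tfa_samples", class(draws))
  draws
}
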