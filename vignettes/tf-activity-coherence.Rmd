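---
title: "Methods: regulon-constrained TF activity inference and coherence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon-constrained TF activity inference and coherence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoherence)
```

# The problem

Genome-wide expression time courses are rich but hard to read gene by gene.
When the regulon structure of the organism is known — which genes each
transcription factor (TF) controls — the thousands of measured fold changes
can be explained by a much smaller number of latent *TF activity profiles*.
This package infers those profiles with calibrated uncertainty and then asks
a comparative question: given two stimuli (say, an active compound and its
inactivated control), do they drive the same regulators with the same
kinetics and amplitude?

# The observation model

For gene $n = 1..N$, TF $m = 1..M$ and time point $t = 1..T$:

$$y_{nt} = \mu_n + \sum_m X_{nm} b_{nm} c_{mt} + \varepsilon_{nt},
  \qquad \varepsilon_{nt} \sim N(0, \sigma^2)$$

* $y_{nt}$: measured log2 expression ratio (treated vs. control);
* $X_{nm} \in \{0,1\}$: regulon membership from a curated edge list. A sign
  column in the input, if present, is kept for provenance but not imposed:
  the strengths are free-signed and the data decide, since curated signs are
  incomplete and condition-dependent;
* $b_{nm}$: regulatory strength of TF $m$ on gene $n$, nonzero only on
  regulon edges;
* $\mu_n$: gene baseline (log-ratio data are centred near zero, but array
  effects leave per-gene offsets);
* $c_{mt}$: the latent activity of TF $m$ at time $t$;
* $\sigma$: a single noise scale shared across genes. A shared scale is the
  most stable variant for short series (five time points give little
  information for per-gene variances); this is a modelling assumption, not a
  fact about the data.

Priors: $b_{nm} \sim N(0, s_b^2)$, $\mu_n \sim N(0, s_\mu^2)$ and, per TF, a
Gaussian random walk over the actual minute grid,
$c_{m,t} \sim N(c_{m,t-1}, r^2 \Delta t)$ with $c_{m,1} \sim N(0,1)$.
The random walk encodes that regulator activity varies smoothly on the
scale of minutes; scaling the increment variance by $\Delta t$ makes the
prior consistent under refinement of the irregular 10–120-min grid.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `strength_prior_sd` ($s_b$) | 1 | log2 units per unit activity | regularises strengths; 1 matches strengths of order unity after gauging |
| `baseline_prior_sd` ($s_\mu$) | 1 | log2 units | weak shrinkage of per-gene offsets |
| `rw_scale` ($r$) | 0.1 | activity units per $\sqrt{\text{min}}$ | smoothness of activity profiles; 0.1 allows order-one activity changes over the 120-min course while damping point-to-point jitter |
| `noise_sd_init` | 0.5 | log2 units | starting noise scale only; $\sigma$ is re-estimated every sweep |
| `max_iters` | 500 | sweeps | cap on coordinate-ascent sweeps |
| `elbo_rel_tol` | 1e-6 | — | relative ELBO change declaring convergence (checked from sweep 2) |

None of these defaults is critical for point estimates on well-determined
problems (many targets per TF); they matter most for weakly connected TFs,
where the random-walk prior keeps profiles finite.

# Inference

The posterior is approximated by mean-field variational Bayes with factors

$$q(\text{everything}) \;=\; \prod_n q(\mu_n, b_{n\cdot})
  \;\prod_m q(c_{m\cdot}),$$

i.e. a *joint* Gaussian per gene over its baseline and strengths (their
posterior correlation is strong and is retained), and a full $T \times T$
Gaussian per TF activity profile (the random walk couples times). Updates
are closed-form; the noise variance is set each sweep to the expected mean
squared residual. Each step maximises the evidence lower bound (ELBO) over
one block, so the ELBO is analytically non-decreasing — the test suite
asserts this (tolerance $10^{-8}$) on every fit it runs.

Genes sharing a regulon pattern share their posterior precision, so updates
are solved once per *pattern* rather than once per gene; with realistic
sparse connectivities this reduces thousands of small linear solves per
sweep to a few dozen.

## The gauge, and why plain coordinate ascent crawls

The likelihood is invariant under $b_{\cdot m} \to b_{\cdot m}/\alpha$,
$c_{m\cdot} \to \alpha c_{m\cdot}$ for any $\alpha > 0$ (and under a joint
sign flip). Two consequences:

1. **Reported results need a convention.** After convergence each TF's
   strength vector is scaled to unit Euclidean norm — the activity absorbs
   the scale, its variance the squared scale — and the sign is chosen so the
   largest-magnitude strength entry is positive. Activities from separately
   fitted conditions are thereby on a common scale, which is what makes the
   magnitude axis of the coherence plot meaningful.
2. **Optimisation along the near-flat scale direction is slow.** The priors
   break the invariance only weakly, and alternating $b$/$c$ updates move
   along that valley in tiny steps. The fitter therefore interleaves a
   parameter-expansion move: after each sweep it transfers scale between
   the strength and activity factors with the closed-form $\alpha$ that
   exactly maximises the ELBO (the likelihood terms are invariant, and the
   prior-plus-entropy terms are maximised analytically). The move can never
   decrease the ELBO and removes the slow mode; in practice it cuts
   convergence from thousands of sweeps to a few hundred.

Remaining numerical choices: posterior covariances are computed via
Cholesky factorisations; the noise variance is floored at $10^{-12}$ so
noiseless test systems remain well-posed; convergence is declared on the
relative ELBO change to make the criterion insensitive to problem size.
Initialisation is deterministic given the seed: activities at zero, gene
baselines at row means, strengths at small seeded Gaussian draws (the small
random draws break the $c = 0$ symmetry; the multi-start test below shows
the optimum reached does not depend on them).

Non-convergence within `max_iters` returns the current state with
`converged = FALSE` and a warning rather than an error, since a
nearly-converged posterior is still informative.

# Coherence analysis

For each TF fitted in two conditions A and B:

* **profile difference** $x = 1 - |\rho(\bar c_A, \bar c_B)|$ using the
  posterior-*mean* profiles — the point coordinates describe the two
  profiles themselves;
* **magnitude difference** $y = |\,\lVert\bar c_A\rVert_2 -
  \lVert\bar c_B\rVert_2|$, unweighted over the shared time grid (no
  defensible time-weighting presents itself for a 5-point design);
* **uncertainty**: $n_{\text{draws}}$ (default 1000) independent Gaussian
  draws from each condition's marginal posterior give the Monte-Carlo mean
  and SD of $|\rho|$ and of the draw-wise magnitude difference. The
  horizontal error-bar half-width equals the SD of $|\rho|$ (since
  $x = 1-|\rho|$); the vertical one is the SD of the magnitude difference.
  The only uncertainty source propagated is the inference uncertainty of
  the activities; 1000 draws put the Monte-Carlo error of these SDs well
  below the quantities themselves, and the suite checks consistency between
  1000 and 4000 draws.

A TF whose posterior-mean profile has zero variance has an undefined
Pearson correlation; it is excluded and reported, never silently scored 0
or 1, because no value is defensible.

Quadrants partition the plot at configurable splits (`x_split = 0.5` by
default — half-way between perfect correlation and none — and `y_split` at
the median magnitude difference of the plotted TFs, since amplitude is
scale-dependent): C = similar kinetics and amplitude (near the origin),
B = different in both, A = similar kinetics but different amplitude, D the
reverse. D merely completes the $2\times2$ partition.

Open design points resolved here: the two conditions are fitted fully
independently (no sharing of strengths), which is the conservative choice
when the comparability of regulation between conditions is itself the
question; the gauge then re-aligns the scales.

# Fold-change bookkeeping

Expression is stored as log2 ratios; classification converts to the ratio
scale and applies the inclusive thresholds: up when the fold change is
$\ge 2$, down when $\le 0.5$, else unchanged. Downregulation is represented
as a ratio below 1 (never a negative "fold"), so heat-map values are the
single formula $\ln(\text{fold change})$ — negative for repression, zero
for no change. Category summaries report, per functional category and time,
the percentage of that category's genes up and down; genes without a
category are excluded from category summaries (and counted in a message)
but retained in genome-fraction summaries, which are denominated on the
full genome size so that unmeasured genes count as unchanged. A gene listed
in several categories is assigned to the first listing (with a warning);
genes with missing values are dropped, never imputed.

# The synthetic generator

The generator is the package's test bed: it emulates the target experiment
— two conditions sharing connectivity, strengths and baselines; five
sampling times at 10, 20, 40, 60, 120 min; 4,598 genes by default; a sparse
Bernoulli connectivity (density 0.02 by default, resampled so every TF
keeps at least two targets); activities as Gaussian random walks with unit
diffusion over the minute grid; strengths $N(0,1)$ on edges; baselines
$N(0, 0.1^2)$; i.i.d. Gaussian noise with SD 0.1, the scale of replicate
scatter on well-measured arrays. Half of the default 16-TF panel is planted
*coherent* (identical activity in both conditions) and half *divergent*
(independent draws), so both axes of the coherence plot are exercised; one
replicate per time point by default, as an optional count.

The generative form deliberately matches the inference model, which makes
parameter recovery a fair self-consistency test — and only that. Passing
these tests shows the estimator recovers truth under its own assumptions
with realistic dimensions and noise; it does not certify behaviour under
probe effects, dye bias, normalisation artefacts, heavy-tailed noise,
TF–TF interactions or nonlinear dose response, none of which are simulated.

# Problem sizes and verification

The standard fixture used throughout the tests is 500 genes, 16 TFs, 5 time
points, density 0.05, noise SD 0.1 — large enough that every TF has ~25
targets and recovery is well-determined, small enough for quick, repeated
fitting. On it the suite verifies: median per-TF $|\rho|$ between true and
inferred activities $\ge 0.9$ (observed ≈ 0.99999); fitted noise SD within
20% of truth; planted-coherent mean profile difference below 0.1 with the
divergent group at least 0.3 above it; ELBO monotonicity on every fit; and
agreement of the optimum across five random initialisations (median
absolute activity difference below $10^{-3}$ at a $10^{-11}$ ELBO
tolerance). The coherence geometry is cross-checked against a
definitional-sums Pearson implementation to $10^{-10}$ on 1000 random
profile pairs, and all bench-assay formulas against hand arithmetic.

# Known limitations

* Mean-field variational posteriors typically understate variance; error
  bars on the coherence plot are best read comparatively.
* The connectivity is trusted as given: wrong or missing regulon edges bias
  the affected TF's profile, and the model performs no edge selection.
* A TF whose regulon barely responds is only weakly identified; its profile
  shrinks toward the random-walk prior rather than reporting failure.
* With five time points the profile correlation is a coarse kinetic
  summary; a single outlying time point moves it substantially.
* The shared noise scale can be mis-calibrated for genes with atypical
  measurement variance (a per-gene variant is a possible extension, not
  currently exposed).
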