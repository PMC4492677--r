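# tfcoherence

Regulon-constrained inference of transcription-factor (TF) activities from
time-course expression data, and *coherence plots* for comparing those
activities between two experimental conditions with full propagation of the
inference uncertainty.

The package was built for the kind of experiment where a bacterial culture
(for example, anaerobic *E. coli* challenged with a CO-releasing compound and
with its inactivated counterpart) is profiled genome-wide at a handful of
time points after treatment, and the analyst wants to move from thousands of
per-gene fold changes to a small set of interpretable regulator activities:
which TFs responded, how strongly, and whether two stimuli drove the *same*
regulators with the *same* kinetics.

## The model

For gene $n$, TF $m$ and time $t$, observed log-ratio expression $y_{nt}$ is
modelled as

$$y_{nt} = \mu_n + \sum_m X_{nm}\, b_{nm}\, c_{mt} + \varepsilon_{nt},
  \qquad \varepsilon_{nt} \sim N(0, \sigma^2),$$

where $X$ is a binary regulon membership matrix (RegulonDB/EcoCyc-style
edges), $b_{nm}$ are free-signed gene-specific regulatory strengths,
$\mu_n$ are gene baselines, and $c_{mt}$ are the latent TF activity
profiles. Priors are Gaussian on $b$ and $\mu$ and a Gaussian random walk
over the (irregular) minute grid on each activity profile. The posterior is
approximated by coordinate-ascent variational Bayes with a monitored,
provably non-decreasing evidence lower bound (ELBO), and the bilinear
sign/scale non-identifiability is resolved by a deterministic gauge
(unit-norm strengths, dominant strength entry positive).

Two conditions fitted on the same TF panel are then compared per TF by

* **profile difference** $= 1 - |\rho|$, the absolute Pearson correlation
  between the two posterior-mean activity profiles (kinetic agreement), and
* **magnitude difference** $= \bigl|\,\lVert c_A\rVert_2 - \lVert
  c_B\rVert_2\,\bigr|$ (amplitude agreement),

with Monte-Carlo draws from the marginal posteriors supplying the mean and
SD of $|\rho|$ and both error bars. Supporting utilities cover the standard
microarray bookkeeping (inclusive $\ge 2$-fold / $\le 0.5$-fold
classification, per-category and genome-fraction percentages, natural-log
heat values) and common bench arithmetic (cytochrome quantitation from
difference spectra, CFU/ml, doubling times under linear growth kinetics).

A synthetic-data generator with known ground-truth activities, strengths
and noise makes every stage testable end to end.

## Worked example

```r
library(tfcoherence)

cfg <- sim_config(n_genes = 300, connectivity_density = 0.05,
                  noise_sd = 0.1, seed = 7)
ds  <- simulate_dataset(cfg)

fit_a <- tfa(ds$expression$A, ds$connectivity, seed = 1, max_iters = 2000)
fit_b <- tfa(ds$expression$B, ds$connectivity, seed = 2, max_iters = 2000)
fit_a
#> Regulon-constrained TF activity model (variational Bayes)
#> Condition: A
#> 300 genes, 16 TFs, 5 time points (10, 20, 40, 60, 120 min)
#> ELBO -4002.807 after 292 sweeps (converged); noise SD 0.09797

ct <- coherence_table(fit_a, fit_b, n_draws = 1000, seed = 11)
ct[c(1, 9), ]
#>    tf profile_difference magnitude_difference mean_abs_corr sd_abs_corr
#>  BaeR           0.000301                 0.13          1.00    0.000194
#>  H-NS           0.449607                 2.06          0.55    0.013274
#>     x_err y_err quadrant
#>  0.000194 0.109        C
#>  0.013274 0.138        A
```

The generator planted BaeR as *coherent* (identical activity in both
conditions) and H-NS as *divergent* (independent activities): the fitted
comparison recovers exactly that contrast. BaeR sits at the origin of the
coherence plot (profile difference ≈ 0, i.e. absolute correlation ≈ 1,
quadrant C: same kinetics, same amplitude), while H-NS shows a large profile
difference (mean $|\rho|$ only 0.55). `plot(ct)` draws the coherence plot
with error bars; `plot(fit_a)` shows the activity profiles with posterior
bands.

Fold-change bookkeeping on the same data:

```r
fc <- classify_fold_changes(ds$expression$A)
genome_fraction_altered(fc, genome_size = 300)
#>   time_min n_up n_down   pct_up pct_down
#> 1       10   49     60 16.33333 20.00000
#> ...
#> 5      120   68     76 22.66667 25.33333
```

i.e. after 120 min, 22.7% of this synthetic genome is up- and 25.3%
downregulated by the inclusive 2-fold / 0.5-fold rule.

`run_pipeline()` chains all of this (read → fit per condition → coherence →
summaries → TSV outputs + JSON run report) from one YAML or list config.

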