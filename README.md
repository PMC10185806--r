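# dfcstates

Dynamic functional connectivity (dFC) brain-state analysis for parcellated
resting-state fMRI, built for the question: *do patients with a deficit —
here, post-stroke spatial neglect — spend their scan time in different
whole-brain connectivity configurations than patients without it, and does
that temporal preference scale with symptom severity?*

The package implements the full pipeline as composable, pipe-friendly
functions over tibbles:

1. **Band-pass filtering** (0.029–0.15 Hz, zero-phase Butterworth) of
   ROI × time BOLD tables;
2. **Sliding-window connectivity**: Pearson correlation of all ROI pairs in
   20-TR windows moved by 1 TR, Fisher z-transformed
   (260 volumes → 241 windows per run);
3. **State identification**: k-means under the Manhattan distance
   (centroid = coordinate-wise median) over all subjects' pooled windows,
   with the number of states chosen at the peak of the *mixed performance
   criterion*
   `MPFC(k) = CS · AS · DI / DB`
   (average cluster size × average silhouette × Dunn index ÷
   Davies–Bouldin index, all under L1);
4. **State characterization**: signed-network Louvain **modularity** (Q,
   asymmetric positive/negative null models, so anti-correlations count)
   and Chan-style **system segregation**
   `S = mean over networks of (WNFC − BNFC)/WNFC`
   on per-subject state matrices;
5. **Temporal dynamics and statistics**: fraction time and dwell time per
   state, pooled two-sample t-tests between groups, Spearman correlations
   with Center-of-Cancellation (CoC) neglect severity, Benjamini–Hochberg
   FDR per metric family, and paired state contrasts on Q and S.

Because the clinical fMRI data this design targets are not public, the
package ships a first-class **synthetic cohort generator**: a
Markov-switching multivariate Gaussian model with two latent states (one
modular/segregated with task-positive/task-negative anti-correlation, one
weakly coupled/diffuse), group-specific state occupancy, severity scores
driven by diffuse-state dwell, and stored volume-level ground truth. Every
stage of the pipeline is tested end-to-end against that ground truth and
against brute-force oracles (exhaustive partition searches, loop-based
validity indices).

## Worked example

Simulate a small cohort (3 neglect-like, 3 control-like subjects, one
120-volume run) and run the whole-cohort analysis with k fixed at 2:

```r
library(dfcstates)

cohort <- simulate_cohort(cohort_spec(n_subjects = c(3, 3), n_volumes = 120, seed = 42))
run <- run_whole_cohort(
  cohort$timeseries, cohort$spec$parcellation, cohort$behavior,
  config = run_config(k_range = 2, n_init = 10, seed = 42, n_louvain = 25),
  tr_seconds = 1.714, filtered = TRUE   # simulated series emulate filtered residuals
)

tidy(run$model)
#> # A tibble: 2 × 4
#>   state n_windows occupancy mean_abs_z
#>   <int>     <int>     <dbl>      <dbl>
#> 1     1       430     0.710      0.186
#> 2     2       176     0.290      0.106
```

States are relabeled so state 1 is the more segregated configuration; here
it also carries the stronger connectivity (`mean_abs_z`). Per-subject
temporal and graph metrics come out of `tidy(run)`:

```r
head(tidy(run), 4)
#> # A tibble: 4 × 12
#>   subject state fraction_time fraction_pct dwell_windows n_visits dwell_seconds
#>   <chr>   <int>         <dbl>        <dbl>         <dbl>    <int>         <dbl>
#> 1 sub-01      1         0.802         80.2          40.5        2          69.4
#> 2 sub-01      2         0.198         19.8          10          2          17.1
#> 3 sub-02      1         0.238         23.8          24          1          41.1
#> 4 sub-02      2         0.762         76.2          38.5        2          66.0
```

`sub-01` (control-like) lives mostly in the segregated state 1; `sub-02`
(neglect-like) in the diffuse state 2. The group statistics quantify this
and its relation to severity:

```r
run$stats$severity
#> # A tibble: 4 × 6
#>   metric        state    rho      p      q     n
#>   <chr>         <int>  <dbl>  <dbl>  <dbl> <int>
#> 1 fraction_time     1 -0.820 0.0458 0.0458     6
#> 2 fraction_time     2  0.820 0.0458 0.0458     6
#> 3 dwell_windows     1 -0.820 0.0458 0.0917     6
#> 4 dwell_windows     2  0.516 0.295  0.295      6

run$stats$state_contrasts
#> # A tibble: 2 × 9
#>   metric       state_a state_b     t    df       p mean_diff n_dropped zero_variance
#>   <chr>          <int>   <int> <dbl> <dbl>   <dbl>     <dbl>     <int> <lgl>
#> 1 modularity         1       2  6.04     5 0.00179     0.228         0 FALSE
#> 2 segregation        1       2  3.04     5 0.0288      0.164         0 FALSE
```

Severity correlates positively with time spent in the diffuse state
(ρ = 0.82) and negatively with the segregated state, and the segregated
state has significantly higher modularity and segregation than the diffuse
one — the qualitative pattern the pipeline is designed to detect. (With six
subjects the group t-tests are underpowered; the default 20-subject cohort
detects the occupancy difference reliably.)

`plot_mpfc()`, `plot_fc_matrix()`, `plot_temporal()` and `autoplot()`
methods provide the standard figures; `run_subcohorts()` repeats the whole
analysis inside each group and aligns states across groups by centroid
correlation; `write_cohort()`/`write_run()` persist everything as
TSV/JSON with config and seed provenance.

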