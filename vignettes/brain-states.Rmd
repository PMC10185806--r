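---
title: "Dynamic brain states from sliding-window connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain states from sliding-window connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dfcstates` estimates recurring whole-brain connectivity configurations —
*brain states* — from parcellated resting-state BOLD time series, and tests
whether their temporal expression differs between clinical groups and scales
with symptom severity. This vignette explains the model and every design
choice that was genuinely open, so that results can be interpreted (and the
package modified) without reverse-engineering the code.

## The analysis model

The pipeline has five stages.

**1. Band-pass filtering.** Each ROI time series is filtered to
0.029–0.15 Hz. The lower edge matters for the sliding-window step: windowed
correlation of signals containing power at periods longer than the window
produces spurious fluctuations, so the shortest retained period (1/0.029 Hz
≈ 34 s) is matched to the window length. We use a 2nd-order Butterworth
applied forward and backward (`signal::filtfilt`), giving zero phase shift
and an effective 4th-order roll-off. The filter family and order are not
dictated by the estimation problem; Butterworth is the common choice in
resting-state work and its maximally flat pass-band avoids ripple in the
band of interest. Columns are demeaned before filtering (DC is outside the
band; removing it first avoids step transients at the record edges). No
padding is added, so roughly the first and last `1/low_hz` seconds are
attenuated; with 260-volume runs this affects about 20 volumes at each end.

**2. Sliding-window dynamic FC.** Windows of 20 TRs (34 s at TR = 1.714 s)
advance by 1 TR, giving `floor((260 - 20)/1) + 1 = 241` windows per run.
Within each window the Pearson correlation of every ROI pair is computed
and Fisher z-transformed (`atanh`), yielding a sequence of 30 × 30 symmetric
matrices per subject. Three conventions:

* the window is rectangular (no taper) — plain segmentation;
* the diagonal is stored as 0, not `atanh(1) = Inf` — self-connectivity is
  uninformative and infinities break L1 distances;
* correlations are clipped at `|r| = 1 - 1e-7` before `atanh`, so degenerate
  windows stay finite (`z ≈ ±8.4`).

A ROI with zero variance inside a window yields r = 0 for its pairs, with a
warning. Windows never cross run boundaries; a subject's window stream is
the run-wise concatenation in acquisition order, and dwell-time runs are
also terminated at run boundaries. This avoids windows that span an
acquisition gap, at the cost of `window_length - 1` fewer windows per
additional run.

**3. State identification.** The upper triangles of all subjects' windowed
matrices (241 × 20 = 4,820 vectors of length 435 for the default cohort)
are pooled and clustered by k-means under the Manhattan (cityblock)
distance. Under L1 the cost-minimizing centroid is the coordinate-wise
*median*, so the algorithm is a k-medians: assignment minimizes L1
distance, the update takes per-coordinate medians, and an emptied cluster
is re-seeded at the point farthest from its centroid. Initialization is
k-means++-style seeding adapted to L1 (new centers drawn with probability
proportional to the distance to the nearest chosen center); the best of
`n_init = 50` restarts by total cost is kept. All randomness flows from one
seed, so fits are exactly reproducible.

The number of states is chosen by the **mixed performance criterion**

$$\mathrm{MPFC}(k) = \mathrm{CS} \cdot \mathrm{AS} \cdot \mathrm{DI} / \mathrm{DB},$$

the product of average cluster size (CS), average silhouette (AS) and Dunn
index (DI), divided by the Davies–Bouldin index (DB); k is taken at the
peak. AS, DI and DB all use the same L1 metric as the clustering (internal
consistency; the choice is ours, the distance used inside the published
criterion is not stated). Because DB is a lower-is-better index it divides
rather than multiplies; the printed formula in the source literature is
typographically ambiguous ("CS\*AS\*DIDB") and we implement the reading
consistent with the criterion being a product of *performance* terms. CS
penalizes fragmenting the windows over many clusters, which makes large k
uncompetitive; we scan k = 2–6 by default. On structureless
high-dimensional data MPFC decays monotonically with k (tested), so the
criterion does not hallucinate structure.

**4. State characterization.** For every subject and state, the subject's
windows assigned to that state are averaged into a subject-level state
matrix (states a subject never visits are reported absent, not
zero-filled). Two graph metrics are computed on these signed weighted
matrices:

* **Modularity (Q)** via Louvain optimization of the *asymmetric signed*
  quality function: positive and negative weights get separate null models,
  the positive term normalized by total positive strength $v^+$ and the
  negative term by the combined strength $v^+ + v^-$. Anti-correlations are
  the defining feature of the segregated state, so they must inform Q —
  zeroing them (available via `negative_weights = "zero"`) would blind the
  metric to exactly the structure of interest; the asymmetric weighting
  keeps the negative null model from dominating. Q is reported as the best
  of 100 random-restart optimizations (node moves + community merges),
  which on ≤ 8-node problems provably attains the exhaustive-search optimum
  (tested against full partition enumeration).
* **System segregation (S)**: for each of the 7 networks,
  `(WNFC - BNFC) / WNFC` — within-network mean minus between-network mean,
  normalized by within — averaged over networks. Networks with non-positive
  WNFC have undefined segregation; they are excluded from the average with
  a warning and an exclusion count (the alternative, imputing 0, would pull
  S toward zero exactly when a state is most degenerate). S is computed on
  the Fisher-z values, the matrices' native units here.

**5. Temporal dynamics and statistics.** From the window label stream:
*fraction time* (share of a subject's windows in each state) and *dwell
time* (mean length of maximal same-state runs, in windows; seconds =
windows × step × TR). Dwell is the *mean* per-visit duration, the standard
reading in the dFC literature (the total would conflate occupancy with
persistence). Group comparisons use pooled-variance Student t-tests
(group 1 − group 2 with group 1 = neglect): a pooled test with
n = 11 + 9 gives df = 18, which is what the published static-FC
comparisons report, and it reproduces their printed t values from the
printed means/SDs to < 0.005. Severity analyses use Spearman rank
correlations of the mean of the two CoC cancellation scores against
fraction and dwell times. FDR correction is Benjamini–Hochberg, applied
per metric family (the k states' fraction-time tests form one family, the
dwell-time tests another, and likewise for the correlations) — the
published symmetric corrected p-values (0.036/0.036, 0.009/0.009) imply
exactly this family structure.

The whole-cohort orchestration (`run_whole_cohort()`) relabels states by
descending system segregation of the cohort centroids, so "state 1" is
always the most segregated state; sub-cohort runs (`run_subcohorts()`)
cluster each group independently and align states across groups by greedy
maximal Pearson correlation of centroid upper triangles — an operational
version of matching states "by visual similarity".

## The synthetic cohort: what it emulates and what it does not

The patient fMRI data behind this design are not public, so the package
ships a generator (`simulate_cohort()`) whose defaults define the study
conditions used by every end-to-end test:

* 20 subjects — 11 neglect-like, 9 control-like — with one 260-volume run
  at TR = 1.714 s over 30 ROIs in 7 networks (the acquisition protocol has
  three such runs; replicate-based power checks use `n_runs = 3`);
* two latent covariance states. The *segregated* state has within-network
  correlation 0.6, anti-correlation −0.3 between the task-positive set
  {DAN, SMN, CON} and the task-negative set {FPN, DMN}, and mild coupling
  0.2 between networks within each set. The *diffuse* state has weak
  within- (0.2) and between-network (0.1) correlation everywhere. Both are
  repaired to valid correlation matrices by eigenvalue clipping. By
  construction the segregated state scores higher modularity and
  segregation — the direction, not the magnitude, of the empirical
  contrast is the reproduction target, because the published absolute Q
  values (e.g. means above 1) are outside the standard signed-Q range and
  their exact normalization is unreported;
* a first-order Markov chain per subject assigns each volume a state.
  Transition matrices differ by group: stationary occupancy of the diffuse
  state is 0.65 for neglect-like and 0.35 for control-like subjects (a 0.3
  gap). Switch rates are 0.0325/0.0175, i.e. mean dwell ≈ 31 and 57
  volumes (53 and 98 s). The dwell scale is a design constraint, not a
  free dial: sliding-window state detection is only identifiable when
  states typically persist longer than the window (20 TRs), and these
  values sit in the range reported for resting-state connectivity states;
* volumes are drawn from zero-mean multivariate normals with the active
  state's covariance plus isotropic N(0, 0.4²) observation noise;
* behavioral CoC scores follow
  `max(0, -0.1 + 0.4 × diffuse fraction + N(0, 0.03²))`, so neglect-like
  subjects (fraction ≈ 0.65) mostly exceed the clinical cut-offs
  (0.081/0.083) and control-like subjects mostly do not, and severity is
  monotone in diffuse-state occupancy by construction;
* all randomness derives from one master seed through a documented
  per-subject/per-run map (`subject_seed()`), so any subject is
  reproducible in isolation.

The generated series emulate *post-denoising residuals*: the generator has
no temporal spectral model (volumes are conditionally independent given the
state sequence), so the band-pass stage is skipped for synthetic data
(`filtered = TRUE`). Filtering them anyway would only introduce temporal
autocorrelation — fewer effective samples per window — and smear state
boundaries with the filter's ~34-s impulse response, degrading the
volume-level ground truth without adding realism where it matters (the
spatial covariance structure). The band-pass itself is validated separately
on sinusoid fixtures with known frequency content.

What the generator deliberately does **not** model: hemodynamics, scanner
drift, motion artifacts, lesions, spatial smoothness, and any temporal
autocorrelation within a state. Passing tests therefore demonstrate that
the *estimation machinery* recovers known state structure and group
differences under realistic noise and occupancy dynamics — they cannot
certify behavior under preprocessing failures or exotic artifact regimes.

Ground truth for window-level labels is defined by majority vote of the
volume states inside the window, ties broken toward the earlier state;
windows containing any switch are flagged and excluded from label-accuracy
denominators (they have no uncontroversial true label), though not from
fraction-time comparisons.

## Numerical choices

* Correlation clipping bound `1 - 1e-7`; Dunn index capped at `1e6` when a
  cluster has zero diameter; Davies–Bouldin ratios capped at `1e6` for
  coincident centroids (with a warning).
* Median convention for even cluster sizes: mean of the two middle order
  statistics, matching `stats::median`.
* Assignment ties in k-means go to the lowest center index, so duplicated
  rows always share a label and fits are deterministic.
* Silhouette of a singleton-cluster member, and of a point with
  `max(a, b) = 0`, is 0.
* The Dunn index computes all pairwise distances; above 6,000 points it
  switches to a stratified subsample (flagged in the output). At the
  default cohort size (4,820 windows) the computation is exact.
* Louvain moves/merges require a gain > 1e-12; k-means stops on a label
  fixed point or a relative cost plateau below 1e-9.
* Markov chains start from their stationary distribution (computed from
  the transition matrix's left eigenvector), so occupancy needs no burn-in.

## Problem sizes used by the test-suite

Unit tests run on constructed examples of ≤ 60 points and cohorts of 4–8
subjects with 50–140 volumes. End-to-end acceptance checks use the full
default cohort (20 subjects, 4,820 windows, MPFC scan over k = 2–6 at 50
restarts) once, and 40 replicate cohorts at the three-run acquisition with
k fixed at 2 and 5 restarts — the two-state structure is strongly
identified, so extra restarts change runtime, not results. Brute-force
oracles (exhaustive 2-partitions for k-means, full partition enumeration
for Louvain, loop-based silhouette/Dunn/DB) are kept to ≤ 12 points and
≤ 8 nodes where enumeration is exact.

## Known limitations

* The MPFC scan is the only model-selection device; no information
  criteria or split-half stability checks are provided.
* Louvain restarts explore random node orders; for pathological
  near-degenerate matrices more restarts may be needed than the default
  100 (the ≤ 8-node optimality guarantee is empirical, verified against
  enumeration in the tests).
* Sub-cohort state matching by centroid correlation is greedy; with more
  than ~4 states of similar structure a global assignment (Hungarian)
  would be preferable.
* Dwell-time estimates from 241-window streams are coarse for very sticky
  chains (few visits per subject), which is visible as wide group-test
  p-values for dwell time on synthetic cohorts.
* Hidden-Markov-model state estimation and sparse inverse covariance FC
  are out of scope by design.
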