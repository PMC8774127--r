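---
title: "Structure-function coupling on connectomes: model, inference, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling on connectomes: model, inference, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocouple)
```

## The model

A subject's structural connectome is a weighted, undirected graph $A$
over $N$ cortical areas (here 360 areas in 12 intrinsic connectivity
networks), with edge weights summarizing white-matter tract counts
normalized by fiber length.  Resting-state BOLD after parcellation is a
sequence of graph signals $x_t \in \mathbb{R}^N$, one per TR.

The symmetric normalized graph Laplacian
$$L = I - D^{-1/2} A D^{-1/2}, \qquad D = \mathrm{diag}(A\mathbf{1}),$$
has spectrum in $[0, 2]$ and an orthonormal eigenbasis $L = U \Lambda
U^\top$ with eigenvalues sorted ascending.  Eigenvectors with small
eigenvalues are spatially smooth over the structural graph ("low graph
frequency", aligned with structure); large eigenvalues give rough
patterns.  Degree normalization makes $L$ — and everything downstream —
invariant to a global rescaling of the edge weights, which matters
because tract-count units are arbitrary.

The graph Fourier transform of a run is $\hat{X} = U^\top X$ for the
node-by-TR matrix $X$.  The energy spectral density of eigenmode $k$ is
$\mathrm{esd}_k = \mathrm{mean}_t\, \hat{X}_{kt}^2$.  The low/high cut
$C$ is the *median energy split*: the smallest number of ascending
eigenmodes whose cumulative ESD reaches half the total.  Ideal
band-projectors then split the signal,
$$X_{\mathrm{coupled}} = U_{1:C} U_{1:C}^\top X, \qquad
  X_{\mathrm{decoupled}} = U_{C+1:N} U_{C+1:N}^\top X,$$
and each area's structural coupling and decoupling are the temporal
L2 norms
$$S_C(i) = \lVert X_{\mathrm{coupled}}[i,\cdot] \rVert_2 / \sqrt{T},
  \qquad
  S_D(i) = \lVert X_{\mathrm{decoupled}}[i,\cdot] \rVert_2 / \sqrt{T}.$$

Two consequences of the median split are worth keeping in mind when
interpreting results.  First, by construction the *total* coupled energy
is close to half the total energy for every subject, so the informative
variation is spatial — which areas hold the low-band energy — not the
global magnitude.  Second, the band projectors are orthogonal
complements in node space, which guarantees
$\sum_i S_C(i)^2 + \sum_i S_D(i)^2 = \sum_{i,t} X_{it}^2 / T$
globally; the corresponding per-area identity does **not** hold, because
the cross term between an area's coupled and decoupled timeseries only
vanishes when summed over areas.  The test suite asserts the global
identity.

## Inference

**Behavior PLS.**  Each subject contributes an $S_C$ row and an $S_D$
row to a stacked brain matrix (conditions nested in groups; 19 + 14
subjects give $66 \times 360$).  Within each group-by-condition cell the
Pearson correlation between age and each area's value forms a
$K \times N$ matrix ($K = 4$ for two groups and two conditions — this is
also why the decomposition yields exactly four latent variables).  Its
SVD $R = U_d \,\mathrm{diag}(d)\, V^\top$ gives, per latent variable, a
design salience (the group/condition contrast), a brain salience (the
areal pattern), and a singular value.

*Permutation test*: subject ages are shuffled across the whole sample —
each subject's two rows keep their common shuffled age, group labels
stay put — and the p-value of LV $k$ is the fraction of permutations
whose $k$-th singular value strictly exceeds the observed one.  The
counting is deliberately strict and unsmoothed (no $+1$ in numerator or
denominator), so the smallest reportable p is 0, flagged as
`< 1/n_perm` in the written output.  The default is 10000 permutations.

*Bootstrap*: subjects are resampled with replacement within group (the
two rows of a subject travel together; draws leaving any cell with fewer
than three distinct subjects are redrawn).  Bootstrap saliences are
aligned to the observed ones by an orthogonal Procrustes rotation before
the standard deviation is taken — without alignment, axis reflections of
near-degenerate LVs inflate the spread and destroy the bootstrap ratio.
The bootstrap ratio (BSR) of area $i$ on LV $k$ is the observed salience
over that aligned bootstrap SD; a zero SD yields an `Inf` sentinel with
a warning rather than a silent `NaN`.  95% CIs are percentile intervals
of the aligned bootstrap areal correlation patterns
($R_b^\top U_{d,b}$).  The default is 1000 iterations.

Areas with $|\mathrm{BSR}| > 2.58$ (the two-sided 99% standard-normal
critical value) are averaged within network, separately for positive and
negative directions, to summarize which networks carry each latent
pattern.  A confirmatory motion check reports the correlation between
brain scores and mean framewise displacement per condition and LV; it is
reported, never enforced.

**Quadratic age regression.**  Per area and metric, OLS of
$y = \beta_0 + \beta_1\,\mathrm{age}_c + \beta_2\,\mathrm{age}_c^2 +
\varepsilon$ with ages centered on the pooled sample mean (centered
first, then squared).  The two-sided t-test p of $\beta_2$ is adjusted
by Benjamini–Hochberg, by default within each metric's family of $N$
tests because the two metrics are reported separately (a joint family
over $2N$ tests is available).  Note that BH adjustment is monotone in p
and dominates it, but it is *not* idempotent — re-adjusting adjusted
values can move plateaus upward — so no code should rely on that.

**Cohort statistics.**  The two-sample comparison of mean framewise
displacement uses the pooled-variance (Student) t with
$df = n_1 + n_2 - 2$; only this form reproduces the demographic table's
printed $t = 1.75$ for 19 vs 14 subjects.  The printed $t(32)$ is
inconsistent with $df = 31$ at these group sizes, and the printed
Cohen's $d = 0.113$ is inconsistent with the printed t (the table's FD
values give $d = 0.617$); the package reports the computed values.
Similarly, the 19 athlete ages in the table average to 31.8, not the
stated 32.1, and the table contains a 19-year-old control although the
stated control range starts at 20 — readers and the subjects validator
therefore do not range-check against the stated ranges.

## The synthetic cohort generator

No imaging data accompany the study, so every downstream stage is
exercised on simulated cohorts with known ground truth.

**Connectomes** are weighted block models: nodes are partitioned evenly
into the 12 networks, and edge weights are gamma draws (shape 4) with a
larger mean within blocks than between (defaults 1.0 vs 0.2).  Gamma
weights are strictly positive, so realized graphs are connected; a BFS
guard adds bridging edges at the between-block mean if a custom
configuration ever disconnects the graph.

**BOLD** is synthesized directly in the spectral domain, so the planted
coupling structure is analytically controlled rather than emergent from
a biophysical simulation — the point of the generator is parameter
recovery, not realism.  Graph Fourier coefficients are independent
zero-mean normals whose per-mode variance follows a geometric profile
$\sigma_k^2 = \rho^{\,k-1}$ with $\rho = R^{-2/N}$, where $R$ is the
configured low/high band energy ratio (default 2; BOLD energy on real
connectomes concentrates at low graph frequency).  This smooth profile
was chosen over a flat two-band profile because it has the right
limit: as $R \to \infty$, $\rho \to 0$ and all energy concentrates in
the single lowest eigenmode, so the decoupled component — whose band
always starts inside the occupied modes under any flat profile, by the
median-split construction — genuinely vanishes.  `Inf` is implemented as
that exact limit.

**The planted effect** multiplies the spectral amplitude of eigenmode
$k$ by $1 + s_g \,(\mathrm{age} - \bar{a}_g)\, w_k$, where $s_g$ is the
group's slope per year, $\bar{a}_g$ the midpoint of the group's age
range, and $w_k = \sum_{i \in T} U_{ik}^2$ the mode's support on the
target networks $T$ (frontoparietal and default by default).  The slope
acts on the low half of the modes for the coupling effect and the high
half for the decoupling effect.  Because the block structure gives a few
low-frequency modes nearly full support on each network, the boost
concentrates where intended.  The study reports no subject-level
coupling values, so the slope magnitude is a free parameter; the default
0.1/year was fixed once, by a design-time power probe at the study
conditions (60-node graphs, 19 + 14 subjects, 106 TRs, noise SD 0.2),
as the smallest round value giving an age-by-coupling correlation above
0.9 and unambiguous latent-variable recovery.  Ages are uniform within
each group's range by default (the demographic table's exact ages are
available via `study_subjects()` for reproduction runs), and mean FD is
lognormal around 0.08 mm.

What the generator does *not* emulate: hemodynamic response and temporal
autocorrelation (TRs are exchangeable), head-motion artifacts beyond a
scalar FD covariate, inter-subject registration error, and realistic
connectome topology beyond community structure (no distance dependence,
hubs, or hemispheric symmetry).  Passing recovery tests therefore show
that the estimator chain is correct and powerful under its own
assumptions, not that those assumptions hold in real data.

## Numerical choices and degenerate inputs

* Connectome symmetrization tolerance is 1e-8 (averaged below, error
  above); nonzero diagonals are zeroed with a warning.
* Eigenvector signs are fixed by making the first component above
  1e-10 in magnitude positive, so profiles and saliences are
  reproducible across LAPACK builds.  Repeated eigenvalues are fine:
  all downstream quantities depend on band projectors, which are
  basis-invariant.
* An isolated (zero-degree) node is a hard error naming the node, never
  silently dropped — node alignment across subjects must not shift.
* The median split is clipped to $N - 1$ (with a warning) when all
  energy is low-frequency, so the high band is never empty.  It is
  computed per subject by default; `split = "group_mean"` derives one
  cut from the cohort-average ESD, since the source description does not
  say which was used.
* Zero-variance areas within a correlation cell get correlation 0 with
  a warning (not `NaN`); zero age variance in a cell is a hard error.
* In the planted-effect recovery tests, "the planted LV" is identified
  as the one maximizing the singular-value-weighted magnitude of the
  athlete-$S_C$ design salience, $d_k |u_{k}|$ — salience alone can
  point to a minor LV because LV contributions scale with $d_k$.
* The per-TR normalization (`per_tr`, division by $\sqrt{T}$) is the
  default because it is the only normalization invariant to scan
  length; `none` is exposed for comparability with raw-norm outputs.

## Problem sizes in the test suite

Property tests run on random graphs with $N \in [4, 32]$ (200 cases);
null-uniformity uses 50 replicate 24-node cohorts at 500 permutations;
planted-effect recovery uses 20 replicate 60-node cohorts at 1000
permutations and 200 bootstrap iterations; the acceptance script runs
the full 360-area design at 10000 permutations and 1000 bootstrap
iterations.  These sizes were chosen so the whole suite exercises every
inferential path in a few minutes on one core while keeping Monte-Carlo
margins comfortable.

## Limitations

The pipeline analyzes a single behavioral variable (age) against two
conditions; task PLS variants, split-half reliability, and multivariate
behavior batteries are out of scope.  Graph filtering is ideal
(hard band split); tapered filters and graph wavelets are not
implemented.  The structural-decoupling ratio $S_D/S_C$ appears only as
a derived column in the per-subject output, since coupling and
decoupling are analyzed separately throughout.
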