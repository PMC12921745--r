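---
title: "Group-specific transferred FDR with spline-linear gamma regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-specific transferred FDR with spline-linear gamma regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistical model

Sequential closed search identifies peptide-spectrum matches (PSMs) for
one post-translational modification (PTM) at a time against a reduced
database. Filtering those results needs a *group-specific* FDR: the error
rate among the modified PSMs alone, not among all PSMs. Computing a
classical target–decoy FDR inside the modified subset (the *separate*
FDR) fails in practice because the subset contains few decoys — the
estimate is noisy, often degenerate, and discards true identifications.

The *transferred* FDR rescales the well-populated global statistics onto
the group. All PSMs — modified and unmodified, target and decoy — are
merged and sorted in ascending score order; the worst PSM gets rank 1 and
the best rank $N$. Scores enter only through ranks, which makes the
method insensitive to the score calibration of the upstream engine (any
monotone transformation of the score gives identical results). At a rank
threshold $x$ (counting PSMs with rank $\ge x$):

$$\widehat{FDR}_k(x) \;=\; \frac{N(x)}{N_k(x)}\;\gamma_k(x)\;FDR(x),$$

with $FDR(x) = D(x)/T(x)$ the global decoy/target ratio, $N(x)$ the
unmodified target count, $N_k(x)$ the modified target count, and
$\gamma_k(x)$ the proportion of $k$-modified PSMs among false
identifications, estimated from decoys as $\hat\gamma_k(x) =
D_k(x)/D(x)$. Intuitively, $\gamma_k(x) D(x)$ estimates the number of
false *modified* targets above the threshold, and the prefactor converts
the global rate into the group's rate.

The numerator convention follows the formulation in which $N(x)$ counts
targets *without* the modification; `transferred_fdr_curve()` exposes
`n_definition = "all_targets"` for the variant that uses all targets,
which differs only by the factor $N/T = 1 - N_k/T$ and is slightly more
conservative when the modified group is large.

### Why a spline for gamma

$\hat\gamma_k(x)$ is not linear in rank: the modified fraction of decoys
drifts as score quality increases, and a single straight line (the
original transferred-FDR choice) misfits both ends of the curve. We model
$\gamma_k(x)$ as a *continuous piecewise-linear* (spline-linear) function

$$\gamma_k(x) = a_i + b_i x, \qquad x_{i-1} \le x \le x_i,$$

fitted by least squares on a hinge basis
$\{1, x, (x-k_1)_+, \dots, (x-k_m)_+\}$, which enforces continuity at the
interior knots by construction. With zero interior knots the model
reduces exactly to ordinary least squares, so the linear transferred FDR
is nested inside the spline one and the two are comparable by their
$R^2$/RMSE on the same thresholds.

### Stabilizing device 1: Poisson error propagation

At high ranks decoys die out and $\hat\gamma_k = D_k/D$ becomes a ratio
of two small counts. Treating both counts as Poisson, its propagated
standard error is

$$\sigma(x, y) = \frac{x}{y}\sqrt{\frac1x + \frac1y},
\qquad x = D_k,\; y = D.$$

Thresholds with $\sigma > 0.01$ (the default `sigma_cutoff`) are masked
out before the regression; thresholds where either count is zero are
undefined and always masked. The mask is computed, never assumed: noise
can make $\sigma$ non-monotone, so every grid point is tested and the
fitted range ends at the largest stable rank. Note the cutoff couples to
decoy depth: $\sigma \approx \gamma\sqrt{(1+1/\gamma)/D}$, so with
$\gamma \approx 0.25$ a threshold needs roughly $D \gtrsim 4000$ decoys
above it to pass 0.01. This is exactly why the database builder pads
reduced databases with random (entrapment) sequences; analyses at
shallower decoy depth should raise `sigma_cutoff` accordingly (the
package's own small-study examples use 0.05).

### Stabilizing device 2: inflection-point knot anchoring

Where targets start outnumbering decoys the gamma observations change
character, and a knot placed arbitrarily in that region makes the last
segment — the one used for extrapolation — fluctuate between runs. The
anchor rule places one knot at the *inflection point* of the decoy/target
ratio $\rho(x) = D(x)/T(x)$: the first derivative of $\rho$ is taken by
central finite differences on the threshold grid, convolved with a
Gaussian kernel (reflect padding at the boundaries), and the anchor is
the grid rank attaining the global minimum of the smoothed derivative,
ties resolving to the smallest rank. The kernel width defaults to 2% of
the grid span; the smoothing exists to keep the argmin off isolated noise
spikes, and in the noiseless limit the anchor converges to the argmin of
the raw finite differences.

Knot layout: boundary nodes sit at the ends of the stable range;
`n_interior_knots` (default 3, anchor included) interior knots are
equally spaced, and the spaced knot nearest the anchor is replaced by the
anchor so that exactly one node is rooted there. If the anchor falls
outside the stable range — common when the ratio's steepest descent lies
beyond the masked region — the fit falls back to the spaced knots and
flags the model rather than extrapolating the anchor rule. A segment left
with fewer than two stable points drops its knot with a warning; a
collinear hinge column is likewise dropped.

Beyond the last node, $\gamma$ is extrapolated with the last segment's
coefficients (below the first node, with the first segment's), and the
result is clipped to $[0,1]$ since a proportion outside that range is
meaningless.

### From the FDR curve to decisions

$\widehat{FDR}_k$ is evaluated on a threshold grid. Counts only change at
ranks held by decoy PSMs, so the default grid is the decoy ranks plus the
range ends; `"all"` evaluates every rank. Thresholds with $N_k(x) = 0$
are skipped (there is nothing to accept), and thresholds where targets
vanish while decoys remain are flagged undefined. The raw curve is not
truncated; q-values monotonize it as the running minimum over more
permissive (lower-rank) thresholds, so a PSM's q-value is the smallest
FDR level at which any acceptance set containing it would pass. The
acceptance rule at level $\alpha$ (default 1%) is `rank >=
threshold_rank` with `threshold_rank` the smallest grid rank whose
q-value is at or below $\alpha$ — equivalently, q-value $\le \alpha$.

Boundary convention: "scores greater than $x$" is implemented as rank
$\ge x$ everywhere (at-or-above), consistent with the ranking
construction; ties in score keep the stable input order. The global FDR
uses the plain ratio $D/T$; the $+1$ decoy correction is available as
`plus_one = TRUE` in `count_curves()`.

## The reduced database builder

Each PTM is searched against a reduced FASTA: proteins identified in the
standard search that carry a matching annotation (UniProt `MOD_RES`
features or dbPTM records, normalized through a packaged vocabulary),
plus `n_random = 5000` random forward sequences, their 5000 reversals,
and reversed decoys of the real proteins. The 5000 default follows the
observation that smaller databases distort the q-value distribution
while larger ones only cost time; the sizing harness
(`search_space_experiment()`) reproduces that comparison on any inputs.

Two under-determined choices were made here and held fixed. First, the
random sequences are *composition- and length-matched* to the input
proteome (residues i.i.d. from the proteome's amino-acid frequencies,
lengths resampled from its empirical length distribution) so the random
peptide mass distribution resembles the real one; uniformly random
sequences would also work for rank statistics but give unrealistic
digests. Second, the "5000 reverse" entries are the reverses of the 5000
forwards — not independent randoms — mirroring the target/decoy pairing
of the real entries. Random hits are removed from results only *after*
the threshold is fixed (`strip_random_hits()`), and only PSMs mapping
exclusively to random entries are dropped.

## The synthetic data generator

`simulate_psm_set()` generates the merged population the estimators
consume, with hidden truth for calibration. Targets split into correct
matches and incorrect matches; decoys are generated in equal number to
the incorrect targets, and both draw scores from the same null
distribution — the exchangeability assumption of the target-decoy method,
here true by construction. Correct targets draw from a right-shifted
distribution. The defaults are hyperscore-like Gumbel families (null:
location 15, scale 3; correct: location 30, scale 5), chosen once for
realism; since the statistics are rank-based, the exact family is
irrelevant and configurable. Default mixture: 20,000 PSMs, 10% of correct
targets modified, 30% incorrect targets.

The modified/unmodified membership of *false* matches follows a
`gamma_profile` evaluated at the PSM's score quantile (not its raw
score), matching the rank domain of the regression; the default logistic
profile rises from 0.15 to 0.35 around the median. What the simulator
deliberately does not model: spectra and fragmentation, mass accuracy,
shared peptides across proteins, score miscalibration between engines,
and correlated duplicate spectra. Passing calibration on these
simulations therefore demonstrates the correctness of the statistical
chain under its stated assumptions — not the behaviour of any particular
search engine's score function on real data.

`simulate_gamma_observations()` generates binomially noised gamma curves
with known truth for the regression tests in isolation.

## Numerical choices and degenerate inputs

* Thresholds with $D = 0$ have undefined $\hat\gamma$; with $D_k = 0$ the
  error propagation is undefined; both are excluded from the stable mask.
  If *no* threshold is stable the estimation aborts with advice to add
  decoys or raise the cutoff; the pipeline catches this per PTM, warns,
  and continues with zero acceptances for that PTM.
* The inflection search requires at least five grid points.
* Continuity at interior knots holds to machine precision by the hinge
  parameterization; the spline/OLS nesting is exact.
* An empty acceptance is reported as a threshold of `NA`, never as rank 1.
* Spectrum keys use the annotated peptide string (sequence plus
  modification tokens), so differently modified forms of one sequence
  never collide. Both key profiles that appear in practice — (file, scan,
  modified peptide) and (file, scan, charge, peptide) — are supported and
  neither is canonical.

## Scales used by the tests

The packaged checks run simulations of 20,000 PSMs for calibration and
sensitivity (20 seeds each), 1,000 PSMs for brute-force oracle
equivalence (50 seeds), and 150–200-point gamma curves for the regression
comparisons (50 seeds); the pipeline fixtures use 3,000-PSM studies with
`sigma_cutoff = 0.05` to match their decoy depth, per the coupling noted
above. These sizes were chosen so that binomial noise is small relative
to the effects under test while a full run stays interactive.

## Known limitations

* Only singly-modified peptides are in scope (methionine oxidation may
  co-occur and is ignored for grouping); multiply-modified peptides are
  not modelled.
* Site positions are taken as reported upstream; no localization scoring.
* Protein counts report all mapped accessions; no shared-peptide
  inference or protein-level FDR.
* The transferred estimate inherits the assumptions of the target-decoy
  method itself — in particular that decoys mimic false targets in both
  score and modification propensity. Entrapment padding makes the second
  assumption safer but cannot enforce it.
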