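---
title: "Methods: mosaic-locus scanning and peptide dose-response models"
author: "mosaicscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic-locus scanning and peptide dose-response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscan)
```

# What the package computes

`mosaicscan` implements two statistical procedures used when studying
peptide-permease operons of the *Bacillus subtilis* group and the
quorum-sensing peptides they import:

* a **sliding-window phylogenetic incongruence scan** that locates
  horizontally transferred segments inside an operon, estimates their
  breakpoints and types the strains into alleles; and
* an **erf dose-response model** of reporter expression versus peptide
  concentration, with the companion geometric fold-change statistic for
  replicate sporulation efficiencies.

Both come with simulators that generate their inputs with known ground
truth, so every claim in the test suite is checked against a
constructed answer rather than eyeballed.

# The mosaic scan

## Window trees

The scan slides a window of `width` 500 bp advancing in `step` 50 bp
jumps along a gap-aware nucleotide alignment (coordinates are 0-based
and half-open; a trailing partial window is dropped, so an alignment of
length $L$ yields $\lfloor (L-\mathrm{width})/\mathrm{step}\rfloor + 1$
windows). Per window, pairwise distances use the Jukes–Cantor
correction $d = -\tfrac34 \log(1 - \tfrac43 p)$ with pairwise deletion:
$p$ counts mismatches only over sites where both sequences carry an
unambiguous base. The correction diverges at $p = 3/4$, so pairs with
$p \ge 0.74999$ are capped at $d = 5$ substitutions/site and flagged
saturated; a window in which some pair has fewer than 50% comparable
sites is skipped with a recorded reason, never silently dropped.

Window trees are built by neighbor joining: the downstream comparison
only needs trees with consistent branch lengths, not
maximum-likelihood topologies, and NJ is deterministic and fast enough
to run thousands of times. Two contracts make the output bit-reproducible across platforms:
exact ties in the Q criterion are broken by the lexicographically
smallest pair of cluster labels (a cluster is labeled by its smallest
leaf label), and negative branch-length estimates are clamped to zero
with a flag.

## Comparing trees

The K tree score rescales the comparison tree onto the reference before
measuring branch-length disagreement. Branches are matched by
bipartition; over the union of splits, with missing branches given
length zero,
$$K^\* = \frac{\sum b_c b_r}{\sum b_c^2}, \qquad
\mathrm{score} = \sqrt{\textstyle\sum (K^\* b_c - b_r)^2}.$$
The score is zero iff the trees agree up to a global scale factor — so
a window that merely evolves faster than average is *not* penalized —
and it is asymmetric in its arguments and not a metric (no triangle
inequality), which is documented rather than asserted. For the
window-by-window similarity matrix the two directed scores of a pair
are averaged into a single symmetric value. A topological companion,
the Robinson–Foulds distance, counts internal splits present in exactly
one tree; internal branches of length zero are treated as polytomies.

## Flagging incongruent windows

Each window tree is scored against the reference species tree. A window
is flagged incongruent only when two independent signals fire:

* **branch-length signal** — robust z of the K score above
  `zThreshold` (default 2.0), and
* **topological signal** — RF distance above `rfThresholdFraction`
  (default 0.4) of its maximum $2(n-3)$.

The z baseline is estimated by quantile matching on the *lower tail* of
the K-score distribution: the 5th and 25th percentiles are mapped to
their standard-normal positions, giving a location and scale. Because
the K score is anchored at zero for windows that agree with the
reference, congruent windows always form the lowest part of the
distribution. A median/MAD baseline over all windows fails here: a
transferred operon segment can easily cover close to half of the
scanned windows (the default simulated locus puts ~45% of windows on
the donor history), and the median then absorbs the incongruent mode —
we measured donor-window z values of ~0.6 under median/MAD where the
lower-tail estimator gives z > 20. Under a homogeneous locus the
lower-tail estimator simply matches the full distribution, so the
nominal meaning of the threshold is kept.

## Segmentation, calls and breakpoints

Windows are grouped into contiguous segments by agglomerative merging
on the similarity matrix: repeatedly merge the adjacent pair of
segments with the smallest mean between-segment K score, and stop when
the next merge's score exceeds the mean + 2 SD of all already-accepted
merge scores (a jump marks a region boundary), or at one segment; a cap
of `maxSegments` (default 8) bounds fragmentation.

A segment is called *incongruent* when more than 80% of its windows are
flagged, *congruent* below 20%, and *mixed* in between — the mixed
state is exactly what a recombination transition zone inside a gene
produces. An incongruent call additionally requires a run of at least
`minRun` 3 consecutive flagged windows, so an isolated noisy window can
never create a transferred-segment call. Breakpoints follow the
window-level convention: the bp midpoint between the centers of the two
adjacent windows where the flags flip, reported for the flanks of every
supported flagged run. Because a window overlapping the true boundary
by as little as ~10% of its width already carries enough foreign signal
to be flagged, these breakpoints are biased *outward* by a fraction of
a window; at the default geometry the bias stays within half a window
(±250 bp) of the truth, which the acceptance suite checks over 20
simulation seeds.

## Allele typing

Within the called region, strains are clustered on a whole-region
Jukes–Cantor distance matrix (region-level distances use every site,
unlike the windowed trees) by average-linkage hierarchical clustering.
The number of clusters comes from a scale-free *deep-split* rule:
scanning merge heights from the top, a merge counts as an allele split
while it stands at least `heightRatio` (default 2) times higher than
the next merge below it. A divergent donor split towers over the
within-group tree depth (measured height ratios ≥ 2.3 at the default
divergence of 0.3 subs/site), whereas a vertically inherited region
produces a graded continuum of merge heights (measured ratios ≤ 1.8
across null simulations). An absolute-gap criterion (largest height gap
versus the median gap) was rejected: genuine clade structure in the
species tree produces large absolute gaps in null regions, and that
statistic did not separate the two cases in simulation. `scanAlignment`
types alleles on the *core* of the called region (shrunk by one window
width per side), since the called region overstates the transferred
segment by up to a window per side and the flanking vertical sequence
dilutes the between-allele signal.

# The dose-response model

Reporter expression at peptide concentration $c$ is
$$Y(c) = E_{\min} + (E_{\max} - E_{\min})
  \frac{1 + \mathrm{erf}\!\left(\log_{10}(c/K)/n\right)}{2},$$
the default `halfmax` convention, under which $Y(0) = E_{\min}$,
$Y(K) = (E_{\min}+E_{\max})/2$ and $Y(\infty) = E_{\max}$ — i.e. $K$
really is the half-maximal concentration. A `literal` convention,
$Y = E_{\min} + (E_{\max}-E_{\min})\,\mathrm{erf}(\log_{10}(c/K)/n)$,
is provided as a first-class alternative because the two forms differ
in what happens at $c = K$ (the literal form pins $Y(K) = E_{\min}$ and
reaches its floor $2E_{\min}-E_{\max}$ only as $c \to 0$). On data
sampling both plateaus the two conventions fit identically up to the
remapping $E_{\min}' = (E_{\min}+E_{\max})/2$, which the test suite
asserts on noiseless fixtures. Parameters and units: $E_{\min}, E_{\max}$
in arbitrary fluorescence units (with the background convention that
wild-type autofluorescence ≈ 1 AU), $K$ in µM, $n$ dimensionless
(log10-decades of curve width; $n = 1$ unless stated — the slope is
rarely reported in experimental work).

Fitting is least squares of per-concentration replicate means against
$\log_{10} c$ (experimental figures display mean ± sem of biological
repeats, and fitting means avoids giving dense concentrations extra
weight; an inverse-variance weighting option exists but is off by
default). Rows at $c = 0$ are pinned to the analytic limit rather than
dropped. The optimizer works on
$(E_{\min},\ E_{\max}-E_{\min},\ \log_{10} K,\ \log n)$ with the first
two bounded below by zero, Levenberg–Marquardt with objective tolerance
$10^{-8}$, and five starts placing $\log_{10} K$ on a grid spanning the
positive concentration range — multi-start plus the transform makes the
fit reproducible and keeps the invariants $E_{\max} \ge E_{\min} \ge 0$,
$K, n > 0$ without penalty terms. Standard errors come from the
Jacobian at the optimum; a fit is flagged as poorly identified when the
fitted $K$ leaves the sampled concentration range or
$\mathrm{SE}(\log_{10} K) > 1$. `compareK()` propagates log-scale
errors into a fold ratio of two fitted $K$s with the geometric interval
$\mathrm{ratio}\cdot 10^{\pm SE}$. The ON-cell readout
(`thresholdFraction()`) is deliberately simple: the fraction of cells
whose expression reaches `fold` (default 10) times background.

# Fold-change statistics

Replicate efficiencies are ratio-scale, noisy on the log scale, so the
group comparison is the ratio of geometric means,
$\mathrm{ratio} = 10^{\overline{\log_{10} a} - \overline{\log_{10} b}}$,
with $\mathrm{SE}_{\log_{10}} = \sqrt{s_a^2/n_a + s_b^2/n_b}$ computed
from the log10 replicates and the geometric ±1 SE interval
$\mathrm{ratio}\cdot 10^{\pm SE}$ — an interval of the published form
"30 (18–48)". Welch's unequal-variance t-test on the log10 values
supplies the significance test (groups of biological repeats have no
reason to share a variance). Base-10 logarithms are used throughout to
match how such intervals are printed. On log-normal data this estimator
is median-unbiased, and its ±1 SE interval covers the true ratio at
close to the nominal ~68% — the calibration test observes 60–75%
coverage over 500 simulations at $n = 4$, SD 0.2.

# The simulators

`simulateSpeciesTree()` draws a pure-birth (Yule) tree and rescales it
to a mean root-to-tip depth of 0.1 substitutions/site — shallow enough
to mimic within-species-group divergence while leaving phylogenetic
signal in a 500 bp window. `deriveDonorTree()` grafts the two allele
groups onto opposite sides of a single internal branch of length
`donorDivergence` (default 0.3 subs/site, a deeply divergent donor
pair), preserving the species subtopology within each group (a
`random` within-group mode exists). `evolveAlignment()` evolves each
layout segment site-independently under Jukes–Cantor along its assigned
tree — root base uniform, substitution probability
$\tfrac34(1-e^{-4t/3})$ per branch of length $t$, uniform choice among
the three alternative bases — and concatenates segments, emitting
pre-aligned, gap-free sequences. The default layout emulates a
permease operon (appD 1000, appF 900, appC 900, appA 1600, appB 900,
yjbA 500 bp) with appA+appB (2500 bp) on the donor tree: gene order and
the qualitative pattern are what matters; the lengths are illustrative
and configurable. Breakpoints are sharp; no indels, codon structure or
rate heterogeneity are simulated — so passing tests demonstrate
recovery under clean JC evolution, not robustness to alignment error,
rate variation or gapped data (real alignments enter through the same
gap-aware distance code, but their alignment quality is the user's
responsibility).

Dose-response data are simulated as $Y(c)\,(1+\varepsilon)$ with
$\varepsilon \sim N(0, \mathrm{noiseCV})$, floored at zero —
flow-cytometry means are scale-noisy, hence multiplicative noise
(default CV 10%, 3 replicates per concentration, 8 concentrations
log-spaced over $K \cdot 10^{\pm 1.75}$ so both plateaus are sampled).
Efficiency replicates are log-normal with a configurable true ratio
(default baseline: 50% wild-type sporulation efficiency). Every
generator takes a mandatory seed and is bit-reproducible.

# Numerical choices and problem sizes

* JC saturation: $p_{cap} = 0.74999$, $d_{max} = 5.0$.
* NJ ties: lexicographic; negative branches clamped to 0 and flagged.
* Identical window trees produce floating-point fuzz of order
  $10^{-17}$ in the quadratic-form K score; scores below
  $10^{-10}\times$ the branch-length scale are snapped to zero so the
  segmentation stop rule is not tripped by rounding noise.
* Optimizer: `minpack.lm`, ftol = ptol = $10^{-8}$, 200 iterations,
  5 starts.
* Degenerate inputs: windows shorter than the width yield an empty
  window list; an all-identical region yields one allele cluster with
  zero merge heights; zero-variance replicate groups give a degenerate
  t statistic (0 or ±∞) rather than an error.

The test and acceptance suites run the full pipeline at 24 strains ×
5.8 kb × 20 seeds, the dose-response recovery at 200 simulations per
parameter set, and the fold-change calibration at 500 simulations —
sizes at which the stochastic checks are stable from seed to seed while
the whole suite stays fast.

# Known limitations

* The scan assumes a shared, correct alignment and a trustworthy
  reference tree; it detects *that* and *where* histories differ, not
  the transfer direction or the donor's identity.
* The K score is not a metric; the similarity matrix is a symmetrized
  summary, appropriate for segmentation but not for embedding.
* Breakpoint estimates are window-center midpoints with a known
  outward bias of a fraction of a window width; sub-window breakpoint
  refinement is out of scope.
* The deep-split allele rule targets the regime of a divergent donor
  (between-allele divergence well above within-group depth); alleles
  barely deeper than the species tree will not be separated.
* The erf curve is a phenomenological dose-response description;
  mechanistic transport kinetics and single-cell distribution modeling
  are out of scope.
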