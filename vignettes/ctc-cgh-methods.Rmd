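---
title: "Copy-number analysis of rare sorted tumor cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of rare sorted tumor cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcCGH)
```

# Scope

`ctcCGH` analyzes genome-wide BAC array CGH profiles of rare,
flow-sorted tumor cell pools — on the order of twenty circulating tumor
cells (CTCs) — hybridized as male test DNA against a female normal
reference. The package covers the dry half of such a study: a
spot-level simulator that stands in for hybridization data, replicate
summarization and clone QC, segmentation, five-state copy-number
calling with the X-chromosome sex-mismatch adjustment, cohort
recurrence, and a weighted Pearson statistic for profile concordance.
Wet-lab stages (cell sorting, whole-genome amplification, image
quantification) are out of scope; the package consumes spot-level log2
ratios.

# The measurement model

Each of the 2,464 BAC clones on the simulated array (printed in
triplicate; counts and replication configurable) measures the log2
ratio of test to reference copy number at its genomic position. The
test channel is modelled as a mixture of tumor cells and contaminating
normal leukocytes. With tumor fraction $f$, tumor copy number $c$ at
the clone, germline copy number $g$ (2 on autosomes; 1 on X and Y for
a male), and reference copy number $r$, the expected ratio is

$$\mu = \log_2\frac{\max\{(1-f)\,g + f\,c,\ \varepsilon\}}{\max\{r,\ \varepsilon\}},$$

where $\varepsilon$ (`floor_copies`, default 0.05 copies) emulates the
array's dynamic-range floor so a homozygous deletion in a pure sample
does not produce $-\infty$. Admixture pulls $\mu$ toward 0 — the
"dampened dynamic range" of contaminated isolates — monotonically in
$1-f$, which is what the dilution analyses in `analysis/05` and the
concordance property tests exercise.

On chromosome X, a male-versus-female hybridization has a
copy-number-neutral expectation of $\log_2(1/2) = -1$ (one X copy
against two). The denominator floor also covers Y clones against a
female reference (0 copies); chromosome Y is carried through the
simulator for realism but always excluded from analysis.

Noise has three components, applied to each clone's expected value: a
clone-level Gaussian offset shared by its replicate spots
(`sigma_clone`, default 0.08 log2 units), independent per-spot Gaussian
noise (`sigma_spot`, default 0.05), and an additive outlier of SD
`outlier_sigma` (default 0.6) hitting each spot independently with
probability `outlier_prob` (default 0.01). The platform's noise
magnitudes are not published; these defaults were chosen once as
plausible for a two-color BAC array with ~600 ng labelled input, and
the outlier component is sized so that a single hit in a triplicate
usually pushes the replicate SD past the 0.2 QC threshold — which is
the scenario the QC filter exists for. What the generator does *not*
model: amplification bias or locus dropout from whole-genome
amplification, GC waves, spatial artefacts, or two-color intensity
calculations (ratios are generated directly).

Preset truth profiles (`preset_truth()`) encode aberration patterns of
the kind reported for the prostate lines used in spiked-cell
validation — 8p loss and 8q gain with a focal AR-region amplification
on X for `vcap_like`, a PTEN-region homozygous deletion for
`pc3_like` — plus a patient-like CTC profile with an 11q13 focal
amplification (`patient9_like`) and an aberration-free male leukocyte
control. Aberrations are assigned to clones by midpoint containment,
so truth states are unambiguous at clone resolution.

# Replicate summarization and clone QC

`summarize_replicates()` reduces each clone's spots to their arithmetic
mean and sample standard deviation ($n-1$ denominator — the
conventional choice for triplicate spot QC; a single-spot clone gets
SD 0). `qc_filter()` flags clones whose replicate SD exceeds 0.2
strictly; an SD of exactly 0.2 is retained. Failed clones are flagged
rather than deleted so that concordance can later intersect QC-passing
clones across samples, and QC is applied *before* segmentation (the
alternative ordering is defensible but one had to be fixed).

# Segmentation

`segment_profile()` partitions each chromosome's ordered QC-passing
clone means by circular binary segmentation: the maximal-|t| circular
arc (pooled two-sample t between arc members and non-members, both
pieces at least `min_width = 2` clones) is tested by permutation, and
a significant window splits at the arc boundaries, recursing on the
pieces. P-values use the add-one convention
$p = (1 + \#\{T^* \ge T_{obs}\})/(B+1)$ with $B = 1000$ shuffles, so
$p$ is never exactly zero and the attainable floor $1/1001$ lies below
the default $\alpha = 0.01$. After recursion, adjacent segments whose
means differ by less than `merge_tol = 0.05` log2 units are fused,
closest pair first. $\alpha$, $B$, `min_width` and `merge_tol` are not
published for the original analysis; the defaults here are
conventional for CBS-family methods and all configurable.

## The rank variant

The original analysis used a proprietary "rank segmentation" variant
of CBS whose mechanism is undocumented. The obvious reading — compute
the arc statistic on within-window ranks — turned out, on measurement,
to be structurally unable to detect the very signal this assay is
about: for a 4-clone high-level amplification among 124 X-chromosome
clones, the rank-scale arc t is capped near 3.6–4.2 (ranks discard
magnitude, so an amplification of log2 ratio 3 scores no higher than
one of 0.3), while the 99th percentile of the permutation null's
maximal arc t is about 4.4. No significance level short of accepting
massive false-positive rates detects it, yet focal AR amplification is
exactly what the assay must find.

The package therefore implements the rank variant as a two-scale test:
each window is examined on the within-window-rank scale *and* on the
original scale, each at $\alpha/2$ (Bonferroni, keeping the overall
level at $\alpha$), and the more significant split wins. The rank
scale contributes robustness to heavy-tailed noise for broad,
low-amplitude changes; the original scale retains magnitude and
detects short high-level amplicons. Setting `use_ranks = FALSE` gives
classic single-scale CBS on the original values. Two consequences are
documented and tested: split decisions of the hybrid are invariant
under affine transforms of the profile (t statistics are
location-scale invariant and ranks are monotone invariant), and the
pure monotone-transform invariance that a rank-only method would enjoy
holds for the rank component alone. Ranks are recomputed per recursion
window; whether the original implementation ranked globally or per
window is unknowable, and per-window ranking keeps the statistic
self-contained.

## Numerical choices

The arc scan enumerates each two-piece partition exactly once (an
edge-touching partition is represented by its suffix arc), because an
arc and its contiguous complement have *identical* t and would
otherwise tie with the winner decided by floating-point rounding. Ties
are real, not hypothetical: same-length arcs with equal mean
difference tie exactly since the within-group sum of squares equals
the total minus the between-group term, and on the rank scale such
coincidences are common. A candidate arc must beat the incumbent by a
$10^{-9}$ relative margin, so exact ties resolve deterministically to
the earliest arc — and the compiled scan agrees arc-for-arc with an
exhaustive R enumeration in the tests. A numerically constant window
(total SS below $10^{-12}$ of the total sum of squares) returns
$T = 0$; a perfectly separated arc returns $T = \infty$, which
compares correctly against permuted statistics. A flank shorter than
`min_width` left at a window edge by the chosen arc is absorbed into
the arc rather than vetoing the split. The scan is $O(m^2)$ per window
with incremental sums, implemented in C++; permutations re-use R's
RNG, so a single `seed` in `segmentation_config()` makes whole-genome
segmentation reproducible.

# Copy-number calling

Segment means are thresholded into five states: gains and losses at
$\pm 0.2$ and high-level gains / homozygous deletions at $\pm 0.6$
log2 units. Thresholds are exclusive — a mean of exactly 0.2 is
neutral — because the published rule names the values without
specifying boundary behavior and a strict reading is the conservative
one; `strict = FALSE` switches to inclusive comparisons. On chromosome
X the neutral baseline for the sex-mismatched design is subtracted
first (equivalently: all four thresholds are shifted by the baseline —
the equivalence is a tested property), so a normal male X reads
NEUTRAL rather than as a chromosome-wide loss. With integer tumor
copies in a pure male sample, any X gain clears the high-level
threshold (adjusted mean $\log_2 c \ge 1$); low-level X gains arise in
admixed samples, which is how the simulated cohort produces them.
Locus queries (`call_locus()`, e.g. the AR region on Xq) return the
covering segment's state; a query spanning several segments resolves
to the most extreme state, with larger |adjusted mean| breaking a
gain-versus-loss tie, because a single per-sample locus call is
needed.

# Cohort recurrence

`build_cohort()` maps each sample's clone to its covering segment's
state; a clone QC-failed in a sample is missing for that sample (the
segment bridges its position, so the QC record — not coverage — must
mark it). Frequencies are computed over non-missing samples per clone;
how the original analysis handled per-sample QC dropouts is unstated,
and per-clone denominators waste the least data. A gain or loss is
recurrent when its frequency strictly exceeds 0.5 — with nine samples,
5/9 qualifies and exactly half would not — and recurrent clones are
reported as maximal runs at clone resolution (cytoband annotation is
out of scope). Whether high- and low-level gains were pooled in the
original recurrence rule is unstated; both count as "gain" here, and
likewise for losses.

# Weighted Pearson concordance

Unweighted correlation between two aCGH profiles is dominated by the
mass of near-normal clones, so clones are weighted by local deviation
from normal. With $x_{ref}, y_{ref}$ the medians over all $n$ shared
clones,

$$w_i = \tfrac12\Big(\mathrm{median}_{j \in \{i, i+1\}}|x_j - x_{ref}| +
\mathrm{median}_{j \in \{i, i+1\}}|y_j - y_{ref}|\Big),
\qquad i = 1, \dots, n-1,$$

and $r_w = \mathrm{cov}(x, y; w) \,/\,
\sqrt{\mathrm{cov}(x, x; w)\,\mathrm{cov}(y, y; w)}$ with
$\Sigma w$-normalized weighted covariances (no small-sample
correction; none is published). Three conventions are made explicit:
the median of the two values $j \in \{i, i+1\}$ is their midpoint; the
weight index stops at $n-1$, so the weighted sums run over
observations $1..n-1$ and the last clone contributes only through its
neighbor's weight (the alternative of a one-sided weight for clone
$n$ was noted and not implemented); and only autosomal clones that
pass QC in *both* samples enter the statistic — pairwise, not
listwise, exclusion. The statistic is computed on clone-level means,
not segmented values, since the formula indexes clones. If every
weight is zero or either weighted variance vanishes (both profiles
flat at their medians), the correlation is undefined and returned as
`NA` with `weights_degenerate` set — uniform weights are *not*
silently substituted. Coefficients are binned as $[0, 0.2)$
uncorrelated, $[0.2, 0.4)$ lowly, $[0.4, 0.6)$ fairly, $[0.6, 0.8)$
moderately, $[0.8, 1]$ highly correlated; negative values fall outside
that scale and are labelled "anticorrelated" rather than folded into
"uncorrelated".

# What the tests do and do not show

The simulation suite validates the pipeline under its own measurement
model: Gaussian clone and spot noise, additive outliers, ideal
mixture attenuation, evenly spaced clones. Zero-noise end-to-end runs
must reproduce truth states exactly; noisy runs (clone and spot SD
0.05 each, ten seeds) must recover at least 90% of true breakpoints
within one clone and keep aberration-free chromosomes free of
threshold-exceeding segments; statistics are checked against
independently coded brute-force oracles (exhaustive arc enumeration on
windows up to 50 clones; direct evaluation of the weighted correlation
formula at $10^{-12}$). Problem sizes — the full 2,464-clone design
for end-to-end checks, 200 oracle windows, 100 random correlation
pairs — keep the default suite under a minute of segmentation work
while still exercising every chromosome-scale code path. Passing these
tests shows the algorithms are implemented correctly under the stated
model; it does not certify performance on real arrays, whose dominant
failure modes (WGA bias, GC waves, spatial gradients) the generator
deliberately omits.

# Known limitations

* No integer copy-number estimation or allele-specific analysis;
  states are threshold calls on log2 ratios.
* No GC-wave or wave-artefact correction and no multi-sample joint
  segmentation.
* Recurrence is descriptive (frequency runs), with no significance
  model for recurrent regions.
* The two-scale rank variant is this package's reconstruction of an
  undocumented proprietary method; it is calibrated (overall level
  $\alpha$) but not numerically identical to the original software's
  output.
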