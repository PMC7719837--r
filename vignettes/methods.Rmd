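---
title: "Methods: gaze-bias analysis for tool viewing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-bias analysis for tool viewing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toolgaze)
```

## The scientific problem

When people look at an elongated tool whose functional end and grip are
separated along its long axis, the distribution of their gaze between the
two ends indexes *technical reasoning* — the inference of how the tool is
used from its mechanical structure. The standard design contrasts familiar
everyday tools with unfamiliar novel ones under different action demands
(free viewing, a pantomimed lift, a pantomimed use), with cumulative
fixation time on the functional part as the quantitative outcome.
`toolgaze` implements the complete analysis chain for such experiments —
fixation classification, consensus ROI construction, standardized gaze
coordinates, gaze metrics, and the within-subjects statistical battery —
together with a synthetic-data generator that emulates the full design with
known ground truth, so every stage is testable without access to raw
recordings.

## Screen geometry and units

All gaze coordinates are screen pixels, origin top-left, x rightward,
y downward — the convention of commercial tracker exports. Conversion to
visual angle assumes square pixels and uses the symmetric formula
$\theta = 2\arctan\!\big(\tfrac{p \cdot \mathrm{pitch}}{2d}\big)$, where
pitch is the physical pixel size (diagonal length over pixel diagonal) and
$d$ the viewing distance. At the default geometry (17.3-inch 1920 × 1080
display at 60 cm), 100 px subtends 1.90°, i.e. roughly 2°, which motivates
the default velocity threshold below.

## Fixation classification (I-VT at the native period)

The classifier is a velocity-threshold scheme operating on consecutive
valid samples at the native 60 Hz period:

* **velocity threshold** — 100 px per 16.7 ms sample period. A pair of
  consecutive valid samples stays within one fixation candidate iff their
  Euclidean displacement, divided by the number of elapsed periods, is at
  or below threshold.
* **minimum duration** — 100 ms. A fixation's duration covers one sampling
  period per member sample (`end` = last member's timestamp + one period),
  so a 300-sample stationary trial is a single 5,000 ms fixation. The
  duration comparison carries a 1 µs tolerance because 6 × (1000/60) is
  not exactly representable in binary floating point.
* **gap bridging** — up to `max_gap_samples` (default 1) consecutive
  invalid samples may be bridged if the displacement across the gap, per
  elapsed period, stays under threshold; longer gaps split candidates.
  Tracker documentation for the original filter is proprietary, so only
  the published parameterization is implemented; single-sample dropouts
  are routine at 60 Hz, hence the default of 1.

Centroids are unweighted means of member positions (sampling is uniform,
so time weighting would be redundant), and a fixation is attributed to an
ROI by centroid containment. No post-hoc merging of near-adjacent
fixations is performed.

## ROI construction and the standardized coordinate

Subjects draw rectangles around each tool's functional and grasping parts;
the consensus ROI per part is the plain edgewise mean over all subjects
(no outlier rejection — the procedure is a stated plain average). The tool
center is the midpoint of the two rectangle centers. The standardized
horizontal coordinate $u$ is piecewise linear: 0 at the center, +100 at
the *outer* (right) edge of the functional ROI, −100 at the outer (left)
edge of the grasping ROI. Only the horizontal axis enters $u$; missingness
is decided separately by 2-D containment, and samples outside both
rectangles — including the central gap between them, where the tool center
itself lies — are missing for all standardized analyses. Containment is
half-open (closed at minimum edges, open at maximum edges) so boundary
points classify deterministically; a consequence is that $u = +100$ is
attainable only as a limit, while $u = -100$ is attainable at the grasp
ROI's left edge. The histogram's last bin is closed at +100 so the anchor
remains countable.

## Gaze metrics

* **Cell table** — per trial, the summed duration of fixations whose
  centroid lies in the functional rectangle; per
  subject × condition × familiarity cell, the **mean** across the cell's
  six tools. A mean (rather than a sum) keeps per-trial units
  interpretable; a `sum` switch is exposed for sensitivity runs. Under a
  balanced design the two differ by a constant factor, so F statistics and
  degrees of freedom are unaffected.
* **Time-binned trace** — a two-stage mean of $u$ in 250 ms bins tiling
  [0, 5000) ms: per-subject means over non-missing samples first, then
  mean and SD across subjects. A sample at exactly 5,000 ms would be
  post-offset and is excluded.
* **Position histograms** — 10 equal-width bins over [−100, +100], counts
  of non-missing samples. Published figure captions are ambiguous about
  whether counts were pooled over subjects or averaged per subject, so
  both are emitted (`count`, `mean_count_per_subject`); neither is
  asserted as the original.
* **Density grid** — each fixation adds its duration to the grid cell
  containing its centroid (off-screen centroids clamp to border cells so
  mass is conserved). This is the quantitative substrate of a heat map;
  rendering is out of scope.

Traces and histograms use *all* valid samples, not only fixation samples:
they summarize "gaze data", which the source analyses treat as distinct
from the fixation-based cumulative time.

## Statistical battery

**Two-way repeated-measures ANOVA.** The cell table is decomposed as a
fully within-subjects two-factor design; each effect is tested against its
own subject-interaction error term. With $a=3$ conditions, $b=2$
familiarity levels and $n=14$ subjects the degrees of freedom are
$(2, 26)$, $(1, 13)$ and $(2, 26)$. No sphericity correction is applied by
default because the reference analyses report uncorrected df; the
familiarity factor has two levels, for which sphericity is trivial, and
the condition factor's correction is available to users by applying
epsilon adjustments externally. Zero error variance yields a flagged
degenerate result (F reported as `NA`) rather than an exception.

**Shaffer's sequentially rejective procedure.** For all pairwise
comparisons of $k$ means, step $i$ uses critical value $\alpha/t_i$, where
$t_i$ is the maximum number of pairwise-equality hypotheses that can be
simultaneously true once $i-1$ are false. The achievable counts of true
hypotheses depend only on the block sizes of the equality partition, so
the package enumerates integer partitions of $k$ and computes
$\sum_j \binom{b_j}{2}$ exactly; for $k = 4$ this gives the sequence
$(6, 3, 3, 3, 2, 1)$. Rejection proceeds in ascending p order and stops at
the first failure.

**Follow-up families.** Simple effects use paired t tests on
subject-level cell values — the assumption-light choice given that a
pooled-error variant would lean on sphericity: (i) within each familiarity
level, the three condition comparisons, Shaffer-corrected with $k=3$;
(ii) within each condition, the single familiar-vs-unfamiliar comparison
(family of one); (iii) the condition main-effect comparisons on
subject-level condition means, Shaffer-corrected with $k=3$. All tests are
two-sided at $\alpha = 0.05$.

**Mann–Whitney U** (familiarity manipulation check) counts pairwise wins
with half credit for ties. With both $n \le 8$ and no ties the p-value is
exact by full enumeration of group assignments; otherwise a normal
approximation with tie-corrected variance and continuity correction is
used. Ratings are heavily tied, so the 6-vs-6 per-tool-median comparison
typically takes the approximate branch; both per-tool-median and
all-ratings units are implemented since the original unit of analysis is
not stated.

**Variance-gated t test** (ROI-area comparability): a two-sided F test of
equal variances at $\alpha = 0.05$ first; Welch's t with Satterthwaite df
if it rejects, pooled-variance Student's t otherwise, with the branch
recorded.

## The synthetic generator

The generator emulates the study conditions: 14 subjects, 6 familiar + 6
unfamiliar tools, 3 conditions in the fixed block order (free viewing,
lift, use — recorded in the manifest but generatively inert, since the
fixed order is a design confound, not a modeled effect), tools shown once
per condition in per-subject random order, 5,000 ms trials at 60 Hz
(300 samples), tool images spanning 13.69° horizontally with centers
5.15° above the screen center and the grip on the left. The tool bounding
box is split 45% / 10% / 45% into grasp part, central gap, and functional
part; per-tool pixel rectangles are not published, so this
geometry-derived split is the shared truth for all tools.

Each trial is a renewal process alternating fixations and 2-sample
transits:

* **Fixation durations** are Gamma(shape 4, scale 75 ms; mean 300 ms),
  truncated below at 120 ms so every injected fixation clears the 100 ms
  classifier minimum with margin. No quantitative duration statistics are
  published for the original subjects; these are conventional values for
  scene viewing at 60 Hz. The trial's last fixation absorbs the remaining
  samples when too few remain to fit another saccade-plus-fixation.
* **Fixation targets** are drawn from a (functional, grasp, center)
  mixture whose weights depend on condition × familiarity; centroids are
  Gaussian (SD 25 px) around the region center, clamped inside the
  region.
* **Sample noise** is isotropic Gaussian, SD 8 px; the within-fixation
  consecutive-sample displacement then exceeds the 100 px threshold with
  probability $\exp(-100^2/(4\sigma^2)) \approx 10^{-17}$ per step, so
  clean recovery is a property, not luck.
* **Transits** interpolate linearly between consecutive centroids *plus an
  alternating vertical excursion* of ±250 px. A purely linear 2-sample
  transit between two nearby centroids (same-region refixations are
  legitimate draws) would have sub-threshold hops and merge neighbouring
  fixations; the excursion guarantees every transit displacement exceeds
  the threshold for any centroid pair, making the injected segmentation
  the unique correct grouping. No main-sequence saccade dynamics, drift or
  tremor are modeled, and validity dropouts (default rate 0) are the only
  blink surrogate — passing recovery tests therefore demonstrates
  correctness of the segmentation logic, not robustness to oculomotor
  noise in real recordings.

**Default mixture weights** (functional / grasp / center): free viewing
0.50/0.30/0.20 for both familiarity levels; lift 0.30/0.50/0.20 familiar,
0.15/0.65/0.20 unfamiliar; use 0.55/0.25/0.20 familiar, 0.70/0.10/0.20
unfamiliar. These were fixed a priori by two constraints: (i) the
hypothesized ordering — functional-part time use > free viewing > lift,
unfamiliar-use maximal, lift showing the reverse familiarity bias — and
(ii) exact balance of the familiar/unfamiliar marginal means (both 0.45),
so the familiarity main effect is null by construction while the
interaction is real. A noncentrality calculation at these weights (≈ 6
trials per cell, ≈ 14 fixations per trial) puts the interaction's
noncentrality parameter near 80 at $n = 14$, i.e. power ≈ 1, so the
probability of reproducing the full qualitative significance pattern in a
seed is dominated by the ~95% chance that the null familiarity effect
stays above $\alpha = 0.05$.

Drawn rectangles are the true rectangles with independent uniform edge
jitter (half-width 10 px), redrawn (bounded retries) if an edge crossing
degenerates a rectangle or swaps the part order. Ratings are drawn per
subject × tool from categorical distributions with medians 5 (familiar)
and 1 (unfamiliar), matching the reported medians.

All randomness flows from a single integer seed through R's default RNG,
so identical configurations reproduce bit-identical bundles.

## Numerical and interface choices

* Gaze coordinates are generated and stored to 3 decimals, timestamps at
  full double precision (`%.17g`), which makes write-then-read the exact
  identity and files-mode runs byte-identical to in-memory runs.
* On-disk formats are plain text (TSV/CSV/YAML), documented in the reader
  help pages; gzip-compressed variants are handled transparently. Readers
  validate closed vocabularies, timestamp monotonicity, key uniqueness
  and file references, and every rejection names the first offending row.
* The pipeline's run manifest records a hash over the semantically
  meaningful configuration fields (the output directory is excluded),
  per-stage row counts, and timings.
* Problem sizes in the shipped test-suite: unit oracles run on toy inputs;
  calibration uses 2,000 null tables (type-I error) and 1,000 null
  families (family-wise error); design-level checks run the full
  504-trial experiment, and the pattern-recovery property uses 100
  independent seeds. These sizes give Monte-Carlo standard errors well
  inside the asserted bounds.

## Known limitations

* The generator's renewal scanpath has no temporal structure within a
  trial (no early center bias, no drift toward the grasp part late in
  use trials), so time-binned traces from synthetic data are flat per
  cell; the trace machinery is validated by oracle, not by emulating
  published trajectories.
* Raw recordings for the original study are not deposited, so the
  reference F values are not reproducible; the pipeline validates
  structure (degrees of freedom, design counts) and behaviour on
  synthetic data with known truth instead.
* The inter-ROI gap rule follows the literal missing-value definition:
  samples between the rectangles are missing even though the tool center
  lies there; whether the original analyses did the same is not stated.
* Only binocular-averaged, single-stream gaze is handled; no smooth
  pursuit, no eye-specific processing.
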