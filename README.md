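# toolgaze

Analysis pipeline for screen-based eye-tracking experiments on **gaze bias
toward the functional part of tools**. In these designs, observers view
elongated tools (functional end right, grip left) under different action
demands — free viewing, a pantomimed *lift*, a pantomimed *use* — with
familiar and unfamiliar tools crossed within subjects. The cumulative
fixation time on the tool's functional part indexes *technical reasoning*:
the inference of how a tool is used from its mechanical structure.

The package implements the full chain for such experiments, plus a
synthetic-data generator with known ground truth so the entire chain is
testable without raw recordings:

* **I-VT fixation classification** at the native 60 Hz period
  (velocity threshold 100 px / 16.7 ms ≈ 2° of visual angle; minimum
  duration 100 ms; single-sample gap bridging).
* **Consensus ROIs** per tool part as the edgewise mean of subject-drawn
  rectangles; the tool center is the midpoint of the two ROI centers.
* **Standardized horizontal coordinate** *u*: piecewise linear with the
  tool center at 0, the outer edge of the functional ROI at +100, the
  outer edge of the grasping ROI at −100; samples outside both ROIs are
  missing.
* **Gaze metrics**: per-cell cumulative functional-part fixation time
  (the ANOVA input), 250 ms time-binned mean *u*, 10-bin position
  histograms, and a duration-weighted fixation density grid.
* **Statistics**: balanced two-way repeated-measures ANOVA (each effect
  against its own subject-interaction error term; df (2, 26) / (1, 13) /
  (2, 26) at *n* = 14), Shaffer's sequentially rejective pairwise
  procedure with exactly enumerated critical denominators, paired-*t*
  simple effects, Mann–Whitney *U* (exact by enumeration for small
  tie-free samples), and the variance-ratio-gated Student/Welch *t* test.

See `vignettes/methods.Rmd` for the model, parameter and design choices.

## Worked example

The `analysis/` scripts run the workflow end to end on a simulated
experiment (bulky raw gaze streams go to `scratch/`, tables to
`results/`):

```sh
Rscript analysis/01_simulate.R     # 14 subjects x 3 conditions x 12 tools
Rscript analysis/02_fixations.R    # I-VT classification + recovery check
Rscript analysis/03_roi_metrics.R  # consensus ROIs, cell table, traces
Rscript analysis/04_stats.R        # ANOVA + Shaffer follow-ups
```

Output from a run (seed 20):

```
Classified 7589 fixations over 504 trials (injected: 7589 )
Cell means of cumulative functional fixation time (ms):
             familiar unfamiliar
free_viewing   2254.4     2366.7
lift           1344.4      616.9
use            2594.4     3209.9

  condition    F(2, 26) = 626.9746, p = 1.003e-22
  familiarity  F(1, 13) = 0.0000, p = 0.9988
  interaction  F(2, 26) = 88.1759, p = 2.602e-12
```

Every injected fixation was recovered exactly (7,589 of 7,589). The cell
means show the generated gaze-bias structure: functional-part time is
highest under *use* (maximal for unfamiliar tools), intermediate under
free viewing, lowest under *lift* — and the ANOVA finds the condition main
effect and the condition × familiarity interaction with no familiarity
main effect, the qualitative signature this design probes. The
Shaffer-corrected follow-ups (printed by `04_stats.R`) reject every
condition pair, reject familiar-vs-unfamiliar under *lift* and *use* (in
opposite directions), and retain it under free viewing.

The same chain runs in-process:

```r
library(toolgaze)
res <- run_pipeline(run_config(generation = generation_config(seed = 20)))
res$anova            # repeated-measures ANOVA
res$pairwise         # Shaffer-corrected decision families
```

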