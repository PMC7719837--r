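#!/usr/bin/env Rscript
# Step 4: the statistical battery. Mann-Whitney U on familiarity ratings,
# variance-gated t on functional ROI areas, the two-way repeated-measures
# ANOVA on cumulative functional fixation time, and Shaffer-corrected
# pairwise follow-ups.

library(toolgaze)

bundle <- read_bundle("scratch/bundle")
ct <- read.csv("results/03_cell_table.csv")
roi_report <- read.csv("results/03_roi_report.csv")

# Familiarity manipulation check: per-tool rating medians, 6 vs 6
med <- aggregate(rating ~ tool + familiarity, data = bundle$ratings, median)
mw <- mann_whitney_u(med$rating[med$familiarity == "familiar"],
                     med$rating[med$familiarity == "unfamiliar"])
cat(sprintf("Ratings Mann-Whitney: U = %.1f, p = %.4g (%s)\n",
            mw$U_a, mw$p, mw$method))

# ROI-area comparability: F-test gate, then Student or Welch
areas <- roi_report[roi_report$part == "functional", ]
at <- variance_gated_t_test(areas$area_px2[areas$familiarity == "familiar"],
                            areas$area_px2[areas$familiarity == "unfamiliar"])
cat(sprintf("Functional ROI area t test (%s branch): t(%.2f) = %.3f, p = %.4f\n",
            at$branch, at$df, at$t, at$p))

an <- rm_anova_2way(ct)
print(an)
write.csv(an$effects, "results/04_anova.csv", row.names = FALSE)

se <- simple_effects(ct)
pw <- do.call(rbind, se)
rownames(pw) <- NULL
write.csv(pw, "results/04_pairwise.csv", row.names = FALSE)
cat("\nShaffer-corrected decisions:\n")
print(pw[c("family", "comparison", "p_raw", "critical_alpha", "reject")])
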