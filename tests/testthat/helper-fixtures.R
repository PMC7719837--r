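# Shared fixtures, built in code. Small configs keep each file fast; the
# full 14-subject design is exercised where a test is about the design.

small_config <- function(seed = 1L, n_subjects = 3L, n_tools = 2L, ...) {
  generation_config(n_subjects = n_subjects,
                    n_tools_per_familiarity = n_tools, seed = seed, ...)
}

# A recording with known structure: two stationary episodes separated by a
# large jump, at the 60 Hz period.
two_fixation_samples <- function(n1 = 18, n_sacc = 2, n2 = 279,
                                 p1 = c(300, 300), p2 = c(1200, 300)) {
  n <- n1 + n_sacc + n2
  x <- c(rep(p1[1], n1),
         p1[1] + seq_len(n_sacc) / (n_sacc + 1) * (p2[1] - p1[1]),
         rep(p2[1], n2))
  y <- c(rep(p1[2], n1),
         p1[2] + c(-250, 250)[seq_len(n_sacc)],
         rep(p2[2], n2))
  data.frame(trial_id = "t1", t_ms = (seq_len(n) - 1) * (1000 / 60),
             x_px = x, y_px = y, valid = TRUE)
}

constant_samples <- function(n = 300, x = 500, y = 400) {
  data.frame(trial_id = "t1", t_ms = (seq_len(n) - 1) * (1000 / 60),
             x_px = rep(x, n), y_px = rep(y, n), valid = TRUE)
}

# A valid ROI set: functional on the right, grasp on the left, with a gap.
demo_roiset <- function() {
  build_roi_set(functional = roi_rect(1000, 200, 1300, 350),
                grasp = roi_rect(600, 200, 900, 350),
                tool = "demo", familiarity = "familiar")
}

# Null cell table: pure noise plus a subject effect, no true effects.
null_cell_table <- function(n_subjects = 14, sd_noise = 1, sd_subject = 1) {
  grid <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                      condition = c("free_viewing", "lift", "use"),
                      familiarity = c("familiar", "unfamiliar"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  subj_eff <- stats::rnorm(n_subjects, sd = sd_subject)
  grid$value_ms <- subj_eff[match(grid$subject, unique(grid$subject))] +
    stats::rnorm(nrow(grid), sd = sd_noise)
  grid
}

# Independent oracle for the achievable numbers of true pairwise-equality
# hypotheses among k means: enumerate ALL labelings of k items with k
# possible labels (every set partition arises) and count within-block pairs.
brute_true_counts <- function(k) {
  labelings <- do.call(expand.grid, rep(list(seq_len(k)), k))
  counts <- apply(as.matrix(labelings), 1, function(lab) {
    sum(choose(table(lab), 2))
  })
  sort(unique(counts))
}

brute_shaffer <- function(k) {
  m <- k * (k - 1) / 2
  counts <- brute_true_counts(k)
  vapply(seq_len(m), function(i) max(counts[counts <= m - i + 1]), numeric(1))
}
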