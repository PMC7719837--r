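test_that("identical config and seed reproduce a bit-identical bundle", {
  cfg <- small_config(seed = 7, dropout_prob = 0.01)
  b1 <- generate_experiment(cfg)
  b2 <- generate_experiment(cfg)
  expect_identical(b1, b2)
  b3 <- generate_experiment(small_config(seed = 8, dropout_prob = 0.01))
  expect_false(identical(b1$samples, b3$samples))
})

test_that("the default design yields 36 trials per subject, 504 in total", {
  cfg <- generation_config(seed = 3)
  b <- generate_experiment(cfg)
  expect_equal(nrow(b$manifest), 504)
  expect_true(all(table(b$manifest$subject) == 36))
  expect_true(all(table(b$manifest$subject, b$manifest$condition) == 12))
  # every recording has exactly round(5000 * 60 / 1000) = 300 samples
  expect_true(all(table(b$samples$trial_id) == 300))
  expect_equal(nrow(b$samples), 504 * 300)
})

test_that("tool geometry follows the stimulus description (grip on the left)", {
  cfg <- generation_config(seed = 3)
  tr <- generate_experiment(cfg)$ground_truth$true_rects
  geom <- cfg$geometry
  one <- tr[tr$tool == tr$tool[1], ]
  g <- one[one$part == "grasp", ]
  f <- one[one$part == "functional", ]
  expect_lt(g$x_max, f$x_min)
  # horizontal extent spans 13.69 degrees
  width <- f$x_max - g$x_min
  expect_equal(px_to_visual_angle(width, geom), 13.69, tolerance = 1e-3)
  # tool center sits 5.15 degrees above the screen center
  cy <- (g$y_min + g$y_max) / 2
  offset <- geom$height_px / 2 - cy
  expect_equal(offset, visual_angle_to_px(5.15, geom), tolerance = 1e-3)
})

test_that("a degenerate all-functional mixture with zero noise stays in the functional part", {
  w <- c(functional = 1, grasp = 0, center = 0)
  weights <- lapply(setNames(nm = c("free_viewing", "lift", "use")),
                    function(cond) list(familiar = w, unfamiliar = w))
  cfg <- small_config(seed = 17, n_subjects = 2, mixture_weights = weights,
                      sample_noise_px = 0)
  b <- generate_experiment(cfg)
  truth <- b$ground_truth
  f <- truth$true_rects[truth$true_rects$part == "functional", ][1, ]
  expect_true(all(truth$fixations$region == "functional"))
  expect_true(all(truth$fixations$centroid_x_px >= f$x_min &
                    truth$fixations$centroid_x_px <= f$x_max &
                    truth$fixations$centroid_y_px >= f$y_min &
                    truth$fixations$centroid_y_px <= f$y_max))
})

test_that("with zero noise every within-fixation sample equals its centroid", {
  cfg <- small_config(seed = 19, n_subjects = 1, sample_noise_px = 0)
  b <- generate_experiment(cfg)
  fx <- b$ground_truth$fixations
  period <- 1000 / cfg$sampling_hz
  for (tid in unique(fx$trial_id)[1:4]) {
    s <- b$samples[b$samples$trial_id == tid, ]
    f <- fx[fx$trial_id == tid, ]
    for (i in seq_len(nrow(f))) {
      idx <- which(s$t_ms >= f$onset_ms[i] - 1e-9 &
                     s$t_ms < f$offset_ms[i] - 1e-9)
      expect_true(all(s$x_px[idx] == f$centroid_x_px[i]))
      expect_true(all(s$y_px[idx] == f$centroid_y_px[i]))
    }
    # injected fixations are ordered and non-overlapping
    expect_true(all(f$offset_ms[-nrow(f)] <= f$onset_ms[-1] + 1e-9))
  }
})

test_that("ratings follow the 1-5 scale with the configured medians", {
  cfg <- generation_config(seed = 23)
  r <- generate_ratings(cfg)
  expect_true(all(r$rating %in% 1:5))
  expect_gte(median(r$rating[r$familiarity == "familiar"]), 4)
  expect_equal(median(r$rating[r$familiarity == "unfamiliar"]), 1)

  # degenerate distributions: familiar always 5, unfamiliar always 1
  dg <- generation_config(seed = 23, rating_probs = list(
    familiar = c(0, 0, 0, 0, 1), unfamiliar = c(1, 0, 0, 0, 0)))
  rd <- generate_ratings(dg)
  expect_equal(median(rd$rating[rd$familiarity == "familiar"]), 5)
  expect_equal(median(rd$rating[rd$familiarity == "unfamiliar"]), 1)

  # Monte-Carlo check of the empirical medians at scale
  big <- generation_config(seed = 29, n_subjects = 84) # 84 x 12 ratings
  rb <- generate_ratings(big)
  expect_equal(median(rb$rating[rb$familiarity == "familiar"]), 5)
  expect_equal(median(rb$rating[rb$familiarity == "unfamiliar"]), 1)
})

test_that("drawn rectangles jitter around the truth without swapping sides", {
  cfg0 <- generation_config(seed = 31, drawn_rect_jitter_px = 0)
  d0 <- generate_drawn_rects(cfg0)
  truth <- generate_experiment(cfg0)$ground_truth$true_rects
  m <- merge(d0, truth, by = c("tool", "part"), suffixes = c("", ".true"))
  expect_equal(m$x_min, m$x_min.true)
  expect_equal(m$y_max, m$y_max.true)

  cfg <- generation_config(seed = 37, drawn_rect_jitter_px = 10)
  d <- generate_drawn_rects(cfg)
  m <- merge(d, truth, by = c("tool", "part"), suffixes = c("", ".true"))
  # law of large numbers at jitter 10 px (uniform, sd ~5.8): the mean over
  # 14 subjects x 12 tools per part/edge is within 3 px of truth (>6 SE);
  # per-tool means over 14 subjects stay within a 4.5-SE envelope (~7 px)
  for (edge in c("x_min", "y_min", "x_max", "y_max")) {
    dev <- m[[edge]] - m[[paste0(edge, ".true")]]
    expect_true(all(abs(tapply(dev, m$part, mean)) < 3))
    expect_true(all(abs(tapply(dev, paste(m$tool, m$part), mean)) < 7))
  }
  # grasp stays left of functional for every subject and tool
  g <- d[d$part == "grasp", ]
  f <- d[d$part == "functional", ]
  key <- function(x) paste(x$subject, x$tool)
  f <- f[match(key(g), key(f)), ]
  expect_true(all((g$x_min + g$x_max) / 2 < (f$x_min + f$x_max) / 2))
})

test_that("invalid configurations are rejected", {
  expect_error(generation_config(n_subjects = 0), "positive integers")
  bad_w <- default_mixture_weights()
  bad_w$lift$familiar <- c(0.5, 0.4, 0.2) # sums to 1.1
  expect_error(generation_config(mixture_weights = bad_w), "summing to 1")
  expect_error(generation_config(rating_probs = list(
    familiar = c(1, 0, 0, 0, 0), unfamiliar = c(2, 0, 0, 0, 0))),
    "probability")
  expect_error(generation_config(trial_duration_ms = -5), "positive")
})
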