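# Most tests run on one small generated bundle; brute-force oracles
# recompute each metric with naive loops.

metrics_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- generate_experiment(small_config(seed = 201, n_subjects = 3))
      fx <- classify_fixations_batch(b$samples, b$manifest)
      roi <- derive_roisets(b$drawn_rects)
      std <- standardize_samples(b$samples, b$manifest, roi$roisets)
      cache <<- list(b = b, fx = fx, roi = roi, std = std)
    }
    cache
  }
})

test_that("per-cell cumulative fixation time matches a brute-force recomputation", {
  fix <- metrics_fixture()
  ct <- cell_cumulative_fixation_time(fix$fx, fix$b$manifest,
                                      fix$roi$roisets)
  expect_equal(nrow(ct), 3 * 3 * 2)
  # brute force: per-trial filtered sums, then per-cell means
  brute <- sapply(seq_len(nrow(ct)), function(i) {
    trials <- fix$b$manifest[
      fix$b$manifest$subject == ct$subject[i] &
        fix$b$manifest$condition == ct$condition[i] &
        fix$b$manifest$familiarity == ct$familiarity[i], ]
    mean(sapply(trials$trial_id, function(tid) {
      f <- fix$fx[fix$fx$trial_id == tid, ]
      rect <- fix$roi$roisets[[trials$tool[match(tid, trials$trial_id)]]]$functional
      if (nrow(f) == 0) return(0)
      sum(f$duration_ms[point_in_rect(f$centroid_x_px, f$centroid_y_px, rect)])
    }))
  })
  expect_equal(ct$value_ms, brute)

  # permuting trial order never changes a cell value
  perm <- sample(nrow(fix$fx))
  ct2 <- cell_cumulative_fixation_time(fix$fx[perm, ], fix$b$manifest,
                                       fix$roi$roisets)
  expect_equal(ct2, ct)

  # sum aggregation = mean * tools per cell under balance
  ct_sum <- cell_cumulative_fixation_time(fix$fx, fix$b$manifest,
                                          fix$roi$roisets, aggregate = "sum")
  expect_equal(ct_sum$value_ms, ct$value_ms * 2)
})

test_that("trials without fixations contribute zero and missing cells error", {
  fix <- metrics_fixture()
  no_fx <- fix$fx[0, ]
  ct <- cell_cumulative_fixation_time(no_fx, fix$b$manifest,
                                      fix$roi$roisets)
  expect_true(all(ct$value_ms == 0))

  broken <- fix$b$manifest[fix$b$manifest$condition != "lift" |
                             fix$b$manifest$subject != "S01", ]
  expect_error(
    cell_cumulative_fixation_time(fix$fx, broken, fix$roi$roisets),
    "missing cell")
})

test_that("enlarging the functional rectangle never decreases any cell value", {
  fix <- metrics_fixture()
  ct <- cell_cumulative_fixation_time(fix$fx, fix$b$manifest,
                                      fix$roi$roisets)
  grown <- lapply(fix$roi$roisets, function(rs) {
    f <- rs$functional
    build_roi_set(roi_rect(f$x_min - 50, f$y_min - 50,
                           f$x_max + 50, f$y_max + 50),
                  rs$grasp, rs$tool, rs$familiarity)
  })
  ct2 <- cell_cumulative_fixation_time(fix$fx, fix$b$manifest, grown)
  expect_true(all(ct2$value_ms >= ct$value_ms - 1e-9))
})

test_that("time-binned traces are two-stage means over non-missing samples", {
  fix <- metrics_fixture()
  tr <- time_binned_mean_position(fix$std)
  expect_equal(nrow(tr), 3 * 2 * 20)
  expect_true(all(tr$bin_end_ms - tr$bin_start_ms == 250))

  # brute force one (condition, familiarity, bin) with data
  row <- tr[which(tr$n_subjects > 0)[5], ]
  d <- fix$std[!is.na(fix$std$u) &
                 fix$std$condition == row$condition &
                 fix$std$familiarity == row$familiarity &
                 fix$std$t_ms >= row$bin_start_ms &
                 fix$std$t_ms < row$bin_end_ms, ]
  subj_means <- tapply(d$u, d$subject, mean)
  expect_equal(row$mean_u, mean(subj_means))
  expect_equal(row$sd_u, sd(subj_means))
  expect_equal(row$n_samples, nrow(d))
})

test_that("constant and fully-missing gaze produce the forced trace values", {
  fix <- metrics_fixture()
  std <- fix$std
  rs1 <- fix$roi$roisets[[1]]
  # park every sample of one tool's trials just inside the functional outer
  # edge: u close to +100 in every bin
  idx <- std$tool == rs1$tool
  std$u[idx] <- 100
  std$region[idx] <- "functional"
  one <- std[idx, ]
  tr <- time_binned_mean_position(one)
  with_data <- tr[tr$n_subjects > 0, ]
  expect_true(all(with_data$mean_u == 100))

  # all samples outside both ROIs: every bin missing
  none <- std
  none$u <- NA_real_
  tr2 <- time_binned_mean_position(none)
  expect_true(all(is.na(tr2$mean_u)))
  expect_true(all(tr2$n_samples == 0))
})

test_that("position histograms conserve the non-missing sample count", {
  fix <- metrics_fixture()
  h <- position_histogram(fix$std)
  expect_equal(nrow(h), 3 * 2 * 10)
  expect_equal(sum(h$count), sum(!is.na(fix$std$u)))

  # brute-force binning for one cell
  one <- h[h$condition == "use" & h$familiarity == "unfamiliar", ]
  u <- fix$std$u[!is.na(fix$std$u) & fix$std$condition == "use" &
                   fix$std$familiarity == "unfamiliar"]
  brute <- sapply(seq_len(10), function(k) {
    lo <- -100 + (k - 1) * 20; hi <- lo + 20
    if (k < 10) sum(u >= lo & u < hi) else sum(u >= lo & u <= hi)
  })
  expect_equal(one$count, as.integer(brute))

  # point mass: all samples in the first bin
  pm <- fix$std[1:100, ]
  pm$u <- -90
  pm$condition <- "lift"; pm$familiarity <- "familiar"
  hp <- position_histogram(pm)
  cell <- hp[hp$condition == "lift" & hp$familiarity == "familiar", ]
  expect_equal(cell$count, c(100L, rep(0L, 9)))
  # the +100 anchor lands in the last (closed) bin
  pm$u <- 100
  hp2 <- position_histogram(pm)
  cell2 <- hp2[hp2$condition == "lift" & hp2$familiarity == "familiar", ]
  expect_equal(cell2$count[10], 100L)
})

test_that("fixation density grids conserve duration mass", {
  fix <- metrics_fixture()
  g <- fixation_density_grid(fix$fx)
  expect_equal(sum(g), sum(fix$fx$duration_ms))

  one <- data.frame(centroid_x_px = 70, centroid_y_px = 50,
                    duration_ms = 500)
  g1 <- fixation_density_grid(one, nx = 48, ny = 27)
  expect_equal(sum(g1), 500)
  expect_equal(g1[2, 2], 500) # 70/40 -> col 2, 50/40 -> row 2

  # brute-force accumulation
  set.seed(211)
  fx <- data.frame(centroid_x_px = runif(200, -50, 2000),
                   centroid_y_px = runif(200, -50, 1100),
                   duration_ms = runif(200, 100, 600))
  g2 <- fixation_density_grid(fx, nx = 10, ny = 5)
  brute <- matrix(0, 5, 10)
  for (i in 1:200) {
    cx <- min(max(floor(fx$centroid_x_px[i] / 1920 * 10), 0), 9) + 1
    cy <- min(max(floor(fx$centroid_y_px[i] / 1080 * 5), 0), 4) + 1
    brute[cy, cx] <- brute[cy, cx] + fx$duration_ms[i]
  }
  expect_equal(g2, brute)
})
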