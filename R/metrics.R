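# Quantitative gaze surfaces: the per-cell cumulative fixation time on the
# functional ROI (the ANOVA input), 250 ms time-binned mean standardized
# position, 10-bin position histograms, and a duration-weighted 2-D
# fixation density grid. Histograms and traces use all valid samples
# ("gaze data"); the cumulative time uses classified fixations.

#' Derive consensus ROI sets from subject-drawn rectangles
#'
#' For each tool and part, edges are averaged across subjects
#' ([average_rois()]); each tool's averaged functional and grasp rectangles
#' then define its center and standardization anchors ([build_roi_set()]).
#'
#' @param drawn_rects Data frame `subject`, `tool`, `part`, `x_min`,
#'   `y_min`, `x_max`, `y_max` (e.g. from [generate_drawn_rects()] or
#'   [read_roi_file()]).
#' @param familiarity_of Optional named character vector mapping tool id to
#'   familiarity; by default inferred from tool-id prefixes
#'   (`familiar_*` / `unfamiliar_*`).
#' @return List with `roisets` (named list of [build_roi_set()] objects,
#'   one per tool) and `report` (audit data frame: tool, part, averaged
#'   edges, area, tool center).
#' @export
derive_roisets <- function(drawn_rects, familiarity_of = NULL) {
  tools <- unique(drawn_rects$tool)
  roisets <- list()
  report <- list()
  for (tool in tools) {
    fam <- if (!is.null(familiarity_of)) {
      unname(familiarity_of[tool])
    } else if (grepl("^unfamiliar", tool)) "unfamiliar" else if
    (grepl("^familiar", tool)) "familiar" else NA_character_
    parts <- list()
    for (part in tg_parts()) {
      rows <- drawn_rects[drawn_rects$tool == tool &
                            drawn_rects$part == part, ]
      if (nrow(rows) == 0L) {
        stop("derive_roisets: no drawn rectangles for tool ", tool,
             " part ", part)
      }
      rects <- lapply(seq_len(nrow(rows)), function(i) {
        roi_rect(rows$x_min[i], rows$y_min[i], rows$x_max[i], rows$y_max[i])
      })
      parts[[part]] <- average_rois(rects)
    }
    rs <- build_roi_set(parts$functional, parts$grasp, tool, fam)
    roisets[[tool]] <- rs
    for (part in tg_parts()) {
      r <- parts[[part]]
      report[[length(report) + 1L]] <- data.frame(
        tool = tool, familiarity = fam, part = part,
        x_min = r$x_min, y_min = r$y_min, x_max = r$x_max, y_max = r$y_max,
        area_px2 = roi_area(r),
        center_x_px = rs$center_x_px, center_y_px = rs$center_y_px,
        stringsAsFactors = FALSE)
    }
  }
  list(roisets = roisets, report = do.call(rbind, report))
}

tg_check_cells <- function(df, subjects, what) {
  expected <- expand.grid(subject = subjects, condition = tg_conditions(),
                          familiarity = tg_familiarity(),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$condition, d$familiarity, sep = "\r")
  missing <- setdiff(key(expected), key(df))
  if (length(missing)) {
    stop(what, ": incomplete design, missing cell(s): ",
         paste(gsub("\r", "/", utils::head(missing, 5)), collapse = ", "))
  }
}

#' Per-cell cumulative fixation time on the functional ROI
#'
#' For every trial, sums the durations of fixations whose centroid falls in
#' the tool's functional rectangle (trials with no qualifying fixation
#' contribute 0), then aggregates the per-trial values within each
#' subject x condition x familiarity cell.
#'
#' @param fixations Fixation table from [classify_fixations_batch()].
#' @param manifest Trial manifest (defines the complete design; every trial
#'   contributes, including fixation-free ones).
#' @param roisets Named list of ROI sets from [derive_roisets()].
#' @param aggregate `"mean"` (default; per-trial units are preserved) or
#'   `"sum"` across each cell's tools.
#' @return Data frame `subject`, `condition`, `familiarity`, `value_ms`,
#'   complete and balanced; errors if any design cell is missing.
#' @export
cell_cumulative_fixation_time <- function(fixations, manifest, roisets,
                                          aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  missing_roi <- setdiff(unique(manifest$tool), names(roisets))
  if (length(missing_roi)) {
    stop("cell_cumulative_fixation_time: no ROI set for tool(s): ",
         paste(missing_roi, collapse = ", "))
  }
  per_trial <- stats::setNames(numeric(nrow(manifest)), manifest$trial_id)
  fixations <- fixations[fixations$trial_id %in% manifest$trial_id, ,
                         drop = FALSE] # the manifest defines the design
  if (nrow(fixations) > 0L) {
    f_rects <- lapply(roisets, `[[`, "functional")
    tool_of <- manifest$tool[match(fixations$trial_id, manifest$trial_id)]
    xmin <- vapply(f_rects, `[[`, numeric(1), "x_min")[tool_of]
    xmax <- vapply(f_rects, `[[`, numeric(1), "x_max")[tool_of]
    ymin <- vapply(f_rects, `[[`, numeric(1), "y_min")[tool_of]
    ymax <- vapply(f_rects, `[[`, numeric(1), "y_max")[tool_of]
    inside <- fixations$centroid_x_px >= xmin & fixations$centroid_x_px < xmax &
      fixations$centroid_y_px >= ymin & fixations$centroid_y_px < ymax
    if (any(inside)) {
      sums <- rowsum(fixations$duration_ms[inside],
                     fixations$trial_id[inside])
      per_trial[rownames(sums)] <- sums[, 1]
    }
  }
  df <- data.frame(subject = manifest$subject,
                   condition = manifest$condition,
                   familiarity = manifest$familiarity,
                   value_ms = unname(per_trial[manifest$trial_id]),
                   stringsAsFactors = FALSE)
  agg_fun <- if (aggregate == "mean") mean else sum
  out <- stats::aggregate(value_ms ~ subject + condition + familiarity,
                          data = df, FUN = agg_fun)
  tg_check_cells(out, unique(manifest$subject),
                 "cell_cumulative_fixation_time")
  out <- out[order(out$subject, out$condition, out$familiarity), ]
  rownames(out) <- NULL
  out
}

#' Standardize all valid gaze samples against their tool's ROI set
#'
#' Joins design labels onto the samples, classifies each valid sample
#' against the tool's rectangles (half-open containment) and computes the
#' standardized horizontal coordinate `u`. Samples outside both ROIs, and
#' invalid samples, get `u = NA` (missing).
#'
#' @param samples All trials' gaze samples (with `trial_id`).
#' @param manifest Trial manifest.
#' @param roisets Named list of ROI sets from [derive_roisets()].
#' @return The samples data frame with added `subject`, `condition`,
#'   `familiarity`, `tool`, `region`, `u`.
#' @export
standardize_samples <- function(samples, manifest, roisets) {
  m <- match(samples$trial_id, manifest$trial_id)
  if (anyNA(m)) {
    stop("standardize_samples: sample trial_id absent from manifest: ",
         samples$trial_id[which(is.na(m))[1]])
  }
  out <- samples
  out$subject <- manifest$subject[m]
  out$condition <- manifest$condition[m]
  out$familiarity <- manifest$familiarity[m]
  out$tool <- manifest$tool[m]
  out$region <- NA_character_
  out$u <- NA_real_
  for (tool in unique(out$tool)) {
    rs <- roisets[[tool]]
    if (is.null(rs)) stop("standardize_samples: no ROI set for tool ", tool)
    idx <- which(out$tool == tool & out$valid &
                   is.finite(out$x_px) & is.finite(out$y_px))
    if (!length(idx)) next
    reg <- classify_sample(out$x_px[idx], out$y_px[idx], rs)
    out$region[idx] <- reg
    hit <- reg != "outside"
    out$u[idx[hit]] <- standardize_x(out$x_px[idx[hit]], rs)
  }
  out
}

#' Time-binned mean standardized gaze position
#'
#' Two-stage mean per (condition, familiarity): within each time bin, the
#' mean `u` over each subject's non-missing samples, then the mean and SD
#' of those per-subject means across subjects. Bins tile
#' `[0, trial_duration_ms)` in `bin_ms` steps; a sample at exactly the
#' trial offset is post-stimulus and excluded.
#'
#' @param std_samples Output of [standardize_samples()].
#' @param bin_ms Bin width (default 250 ms).
#' @param trial_duration_ms Trial length (default 5000 ms).
#' @return Data frame `condition`, `familiarity`, `bin_index` (0-based),
#'   `bin_start_ms`, `bin_end_ms`, `mean_u`, `sd_u`, `n_subjects`,
#'   `n_samples`; bins with no data have `NA` means and zero counts.
#' @export
time_binned_mean_position <- function(std_samples, bin_ms = 250,
                                      trial_duration_ms = 5000) {
  n_bins <- ceiling(trial_duration_ms / bin_ms)
  keep <- !is.na(std_samples$u) & std_samples$t_ms < trial_duration_ms
  d <- std_samples[keep, c("subject", "condition", "familiarity", "t_ms", "u")]
  grid <- expand.grid(condition = tg_conditions(),
                      familiarity = tg_familiarity(),
                      bin_index = seq_len(n_bins) - 1L,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) {
    out <- grid[order(grid$condition, grid$familiarity, grid$bin_index), ]
    out$bin_start_ms <- out$bin_index * bin_ms
    out$bin_end_ms <- pmin(out$bin_start_ms + bin_ms, trial_duration_ms)
    out$mean_u <- NA_real_; out$sd_u <- NA_real_
    out$n_subjects <- 0L; out$n_samples <- 0L
    rownames(out) <- NULL
    return(out[c("condition", "familiarity", "bin_index", "bin_start_ms",
                 "bin_end_ms", "mean_u", "sd_u", "n_subjects", "n_samples")])
  }
  d$bin_index <- floor(d$t_ms / bin_ms)
  per_subj <- stats::aggregate(
    u ~ subject + condition + familiarity + bin_index, data = d, FUN = mean)
  n_samp <- stats::aggregate(
    u ~ condition + familiarity + bin_index, data = d, FUN = length)
  names(n_samp)[names(n_samp) == "u"] <- "n_samples"
  stats_df <- stats::aggregate(
    u ~ condition + familiarity + bin_index, data = per_subj,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  stats_df <- cbind(stats_df[c("condition", "familiarity", "bin_index")],
                    as.data.frame(stats_df$u))
  out <- merge(grid, stats_df, all.x = TRUE, sort = FALSE)
  out <- merge(out, n_samp, all.x = TRUE, sort = FALSE)
  out$n[is.na(out$n)] <- 0
  out$n_samples[is.na(out$n_samples)] <- 0
  out$bin_start_ms <- out$bin_index * bin_ms
  out$bin_end_ms <- pmin(out$bin_start_ms + bin_ms, trial_duration_ms)
  out <- out[order(out$condition, out$familiarity, out$bin_index),
             c("condition", "familiarity", "bin_index", "bin_start_ms",
               "bin_end_ms", "mean", "sd", "n", "n_samples")]
  names(out) <- c("condition", "familiarity", "bin_index", "bin_start_ms",
                  "bin_end_ms", "mean_u", "sd_u", "n_subjects", "n_samples")
  out$n_subjects <- as.integer(out$n_subjects)
  out$n_samples <- as.integer(out$n_samples)
  rownames(out) <- NULL
  out
}

#' Histogram of standardized gaze position
#'
#' Equal-width bins over `[-100, +100]`; interior bins are half-open and
#' the last bin is closed at +100 so the anchor point is countable. For
#' each (condition, familiarity) the pooled count over all subjects and
#' the mean per-subject count are both reported; counts cover exactly the
#' non-missing samples.
#'
#' @param std_samples Output of [standardize_samples()].
#' @param n_bins Number of bins (default 10).
#' @return Data frame `condition`, `familiarity`, `bin_index` (1-based),
#'   `bin_lo`, `bin_hi`, `count`, `mean_count_per_subject`.
#' @export
position_histogram <- function(std_samples, n_bins = 10) {
  width <- 200 / n_bins
  keep <- !is.na(std_samples$u)
  d <- std_samples[keep, c("subject", "condition", "familiarity", "u")]
  d <- d[d$u >= -100 & d$u <= 100, ]
  d$bin_index <- pmin(floor((d$u + 100) / width), n_bins - 1) + 1L
  subjects <- unique(std_samples$subject)
  grid <- expand.grid(condition = tg_conditions(),
                      familiarity = tg_familiarity(),
                      bin_index = seq_len(n_bins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(d)) {
    pooled <- stats::aggregate(cnt ~ condition + familiarity + bin_index,
                               data = cbind(d, cnt = 1), FUN = sum)
  } else {
    pooled <- data.frame(condition = character(0), familiarity = character(0),
                         bin_index = integer(0), cnt = numeric(0))
  }
  out <- merge(grid, pooled, all.x = TRUE, sort = FALSE)
  out$cnt[is.na(out$cnt)] <- 0
  out$bin_lo <- -100 + (out$bin_index - 1L) * width
  out$bin_hi <- -100 + out$bin_index * width
  out$mean_count_per_subject <- out$cnt / length(subjects)
  out <- out[order(out$condition, out$familiarity, out$bin_index),
             c("condition", "familiarity", "bin_index", "bin_lo", "bin_hi",
               "cnt", "mean_count_per_subject")]
  names(out)[names(out) == "cnt"] <- "count"
  out$count <- as.integer(out$count)
  rownames(out) <- NULL
  out
}

#' Duration-weighted 2-D fixation density grid
#'
#' Each fixation adds its duration to the grid cell containing its
#' centroid; centroids off-screen are clamped into the border cell so total
#' mass always equals total fixation time. This is the quantitative base
#' of a fixation heat map (rendering is out of scope).
#'
#' @param fixations Fixation table with `centroid_x_px`, `centroid_y_px`,
#'   `duration_ms`.
#' @param nx,ny Grid resolution.
#' @param geometry A [screen_geometry()] defining the screen extent.
#' @return `ny` x `nx` numeric matrix (rows = screen y, top to bottom).
#' @export
fixation_density_grid <- function(fixations, nx = 48, ny = 27,
                                  geometry = screen_geometry()) {
  grid <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(fixations) == 0L) return(grid)
  ix <- pmin(pmax(floor(fixations$centroid_x_px / geometry$width_px * nx),
                  0), nx - 1) + 1L
  iy <- pmin(pmax(floor(fixations$centroid_y_px / geometry$height_px * ny),
                  0), ny - 1) + 1L
  for (i in seq_along(ix)) {
    grid[iy[i], ix[i]] <- grid[iy[i], ix[i]] + fixations$duration_ms[i]
  }
  grid
}
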