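# Synthetic experiment generator. Emulates the study design end to end:
# 14 subjects x 3 conditions (free viewing, lift, use) x 12 tools (6
# familiar, 6 unfamiliar), 60 Hz gaze sampled over 5 s trials, an
# alternating fixation/saccade renewal structure, subject-drawn ROI
# rectangles with edge jitter, and 1-5 familiarity ratings. Every trial
# carries ground truth (injected fixations) so the classifier and all
# downstream metrics can be checked against a known answer.

#' Default condition x familiarity gaze-mixture weights
#'
#' Probability that a fixation targets the functional part, the grasping
#' part, or the central gap, per (condition, familiarity) cell. The
#' defaults encode the hypothesised gaze-bias structure: functional-part
#' weight ordered use > free viewing > lift, maximal for unfamiliar tools
#' under the use demand, and with familiar/unfamiliar marginal means exactly
#' equal so there is no familiarity main effect.
#'
#' @return Nested list `weights[[condition]][[familiarity]]`, each a
#'   3-vector `(functional, grasp, center)` summing to 1.
#' @export
default_mixture_weights <- function() {
  w <- function(f, g, c) c(functional = f, grasp = g, center = c)
  list(
    free_viewing = list(familiar = w(0.50, 0.30, 0.20),
                        unfamiliar = w(0.50, 0.30, 0.20)),
    lift = list(familiar = w(0.30, 0.50, 0.20),
                unfamiliar = w(0.15, 0.65, 0.20)),
    use = list(familiar = w(0.55, 0.25, 0.20),
               unfamiliar = w(0.70, 0.10, 0.20))
  )
}

#' Configuration for the synthetic experiment generator
#'
#' Defaults reproduce the study conditions: 14 subjects, 6 tools per
#' familiarity level, 5,000 ms trials at 60 Hz, tool images spanning
#' 13.69 degrees horizontally with their center 5.15 degrees above the
#' screen center and the grip on the left.
#'
#' @param n_subjects Number of subjects.
#' @param n_tools_per_familiarity Tools per familiarity level.
#' @param trial_duration_ms Stimulus presentation time.
#' @param sampling_hz Tracker sampling rate.
#' @param mixture_weights See [default_mixture_weights()].
#' @param fixation_duration_shape,fixation_duration_scale_ms Gamma
#'   parameters for fixation durations (default mean 300 ms).
#' @param min_fixation_duration_ms Lower truncation for injected fixation
#'   durations; kept above the classifier's 100 ms minimum so every
#'   injected fixation is recoverable.
#' @param fixation_scatter_px SD of fixation centroids around their target
#'   region center (centroids are clamped inside the region).
#' @param sample_noise_px Per-sample isotropic noise SD around the fixation
#'   centroid. The default (8 px) keeps the within-fixation
#'   consecutive-sample displacement below the 100 px classifier threshold
#'   with probability `1 - exp(-100^2 / (4 * 8^2))` > 1 - 1e-16 per step.
#' @param saccade_samples Transit samples inserted between fixations.
#' @param saccade_excursion_px Vertical excursion of transit samples;
#'   guarantees every transit displacement exceeds the velocity threshold
#'   regardless of how close consecutive fixation centroids are.
#' @param drawn_rect_jitter_px Half-width of the uniform edge jitter applied
#'   to the true rectangles to emulate subject drawings.
#' @param rating_probs List with elements `familiar` and `unfamiliar`: the
#'   probability over ratings 1..5 (default medians 5 and 1).
#' @param dropout_prob Per-sample probability of an invalid (validity-flag)
#'   dropout; default 0 (clean recordings).
#' @param seed Integer seed; identical config + seed reproduces a
#'   bit-identical bundle.
#' @param geometry A [screen_geometry()].
#' @param tool_width_deg,tool_height_deg Tool image extent in visual angle.
#' @param tool_elevation_deg Elevation of the tool center above the screen
#'   center.
#' @param grasp_frac,gap_frac Fractions of the tool width assigned to the
#'   grasping part and the central gap (the functional part takes
#'   `1 - grasp_frac - gap_frac`, on the right).
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(n_subjects = 14L,
                              n_tools_per_familiarity = 6L,
                              trial_duration_ms = 5000,
                              sampling_hz = 60,
                              mixture_weights = default_mixture_weights(),
                              fixation_duration_shape = 4,
                              fixation_duration_scale_ms = 75,
                              min_fixation_duration_ms = 120,
                              fixation_scatter_px = 25,
                              sample_noise_px = 8,
                              saccade_samples = 2L,
                              saccade_excursion_px = 250,
                              drawn_rect_jitter_px = 10,
                              rating_probs = list(
                                familiar = c(0, 0, 0.05, 0.35, 0.60),
                                unfamiliar = c(0.70, 0.20, 0.10, 0, 0)),
                              dropout_prob = 0,
                              seed = 1L,
                              geometry = screen_geometry(),
                              tool_width_deg = 13.69,
                              tool_height_deg = 3,
                              tool_elevation_deg = 5.15,
                              grasp_frac = 0.45,
                              gap_frac = 0.10) {
  counts <- c(n_subjects = n_subjects,
              n_tools_per_familiarity = n_tools_per_familiarity,
              saccade_samples = saccade_samples)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("generation_config: counts must be positive integers")
  }
  pos <- c(trial_duration_ms = trial_duration_ms, sampling_hz = sampling_hz,
           fixation_duration_shape = fixation_duration_shape,
           fixation_duration_scale_ms = fixation_duration_scale_ms,
           min_fixation_duration_ms = min_fixation_duration_ms,
           saccade_excursion_px = saccade_excursion_px,
           tool_width_deg = tool_width_deg, tool_height_deg = tool_height_deg)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("generation_config: ", paste(names(pos)[!is.finite(pos) | pos <= 0],
                                      collapse = ", "),
         " must be finite and positive")
  }
  nonneg <- c(fixation_scatter_px, sample_noise_px, drawn_rect_jitter_px,
              dropout_prob)
  if (any(!is.finite(nonneg)) || any(nonneg < 0) || dropout_prob >= 1) {
    stop("generation_config: noise/jitter/dropout parameters out of range")
  }
  if (grasp_frac <= 0 || gap_frac < 0 || grasp_frac + gap_frac >= 1) {
    stop("generation_config: grasp_frac/gap_frac must leave room for the functional part")
  }
  for (cond in tg_conditions()) {
    for (fam in tg_familiarity()) {
      w <- mixture_weights[[cond]][[fam]]
      if (is.null(w) || length(w) != 3L || any(!is.finite(w)) || any(w < 0) ||
          abs(sum(w) - 1) > 1e-9) {
        stop("generation_config: mixture weights for (", cond, ", ", fam,
             ") must be a non-negative 3-vector summing to 1")
      }
    }
  }
  for (fam in tg_familiarity()) {
    p <- rating_probs[[fam]]
    if (is.null(p) || length(p) != 5L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      stop("generation_config: rating_probs$", fam,
           " must be a probability 5-vector")
    }
  }
  n_samples <- round(trial_duration_ms * sampling_hz / 1000)
  if (n_samples < ceiling(min_fixation_duration_ms * sampling_hz / 1000)) {
    stop("generation_config: trial too short for a single fixation")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_tools_per_familiarity = as.integer(n_tools_per_familiarity),
         trial_duration_ms = trial_duration_ms, sampling_hz = sampling_hz,
         mixture_weights = mixture_weights,
         fixation_duration_shape = fixation_duration_shape,
         fixation_duration_scale_ms = fixation_duration_scale_ms,
         min_fixation_duration_ms = min_fixation_duration_ms,
         fixation_scatter_px = fixation_scatter_px,
         sample_noise_px = sample_noise_px,
         saccade_samples = as.integer(saccade_samples),
         saccade_excursion_px = saccade_excursion_px,
         drawn_rect_jitter_px = drawn_rect_jitter_px,
         rating_probs = rating_probs, dropout_prob = dropout_prob,
         seed = as.integer(seed), geometry = geometry,
         tool_width_deg = tool_width_deg, tool_height_deg = tool_height_deg,
         tool_elevation_deg = tool_elevation_deg,
         grasp_frac = grasp_frac, gap_frac = gap_frac),
    class = "generation_config"
  )
}

# Serialize a generation_config to a plain nested list (for YAML) and back.
config_to_list <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  out <- unclass(config)
  out$geometry <- unclass(out$geometry)[c("width_px", "height_px",
                                          "diagonal_mm",
                                          "viewing_distance_mm")]
  out$mixture_weights <- lapply(out$mixture_weights,
                                function(by_fam) lapply(by_fam, as.numeric))
  out
}

config_from_list <- function(lst) {
  lst$geometry <- do.call(screen_geometry, lst$geometry)
  lst$mixture_weights <- lapply(lst$mixture_weights, function(by_fam) {
    lapply(by_fam, function(w) {
      w <- as.numeric(w)
      names(w) <- c("functional", "grasp", "center")
      w
    })
  })
  do.call(generation_config, lst)
}

# True tool layout in screen pixels, derived from the stimulus geometry:
# horizontal extent subtending tool_width_deg, vertical center
# tool_elevation_deg above the screen center, grip on the left. The bounding
# box is split grasp_frac / gap_frac / functional_frac from left to right.
tool_layout <- function(config) {
  geom <- config$geometry
  width_px <- visual_angle_to_px(config$tool_width_deg, geom)
  height_px <- visual_angle_to_px(config$tool_height_deg, geom)
  elev_px <- visual_angle_to_px(config$tool_elevation_deg, geom)
  cx <- geom$width_px / 2
  cy <- geom$height_px / 2 - elev_px
  x0 <- cx - width_px / 2
  y0 <- cy - height_px / 2
  y1 <- cy + height_px / 2
  g_x1 <- x0 + config$grasp_frac * width_px
  f_x0 <- g_x1 + config$gap_frac * width_px
  list(
    grasp = roi_rect(x0, y0, g_x1, y1),
    center = roi_rect(g_x1, y0, f_x0, y1),
    functional = roi_rect(f_x0, y0, x0 + width_px, y1)
  )
}

tg_tool_ids <- function(config) {
  n <- config$n_tools_per_familiarity
  c(sprintf("familiar_%02d", seq_len(n)),
    sprintf("unfamiliar_%02d", seq_len(n)))
}

tg_tool_table <- function(config) {
  n <- config$n_tools_per_familiarity
  data.frame(tool = tg_tool_ids(config),
             familiarity = rep(tg_familiarity(), each = n),
             stringsAsFactors = FALSE)
}

# True rectangles as a data frame. Every tool shares the geometry-derived
# layout: no per-tool pixel rectangles exist to emulate, so the split of
# the stimulus bounding box is the shared truth.
tg_true_rects <- function(config) {
  layout <- tool_layout(config)
  tools <- tg_tool_table(config)
  do.call(rbind, lapply(seq_len(nrow(tools)), function(i) {
    do.call(rbind, lapply(c("functional", "grasp"), function(part) {
      r <- layout[[part]]
      data.frame(tool = tools$tool[i], familiarity = tools$familiarity[i],
                 part = part,
                 x_min = round(r$x_min, 3), y_min = round(r$y_min, 3),
                 x_max = round(r$x_max, 3), y_max = round(r$y_max, 3),
                 stringsAsFactors = FALSE)
    }))
  }))
}

tg_subject_ids <- function(config) sprintf("S%02d", seq_len(config$n_subjects))

# --- RNG-consuming internals (callers own the seed) -------------------------

tg_gen_drawn_rects <- function(config) {
  truth <- tg_true_rects(config)
  j <- config$drawn_rect_jitter_px
  out <- list()
  for (subj in tg_subject_ids(config)) {
    for (tool in unique(truth$tool)) {
      rows <- truth[truth$tool == tool, ]
      for (attempt in seq_len(100L)) {
        jit <- matrix(stats::runif(8, -j, j), nrow = 2)
        cand <- rows
        edges <- c("x_min", "y_min", "x_max", "y_max")
        cand[, edges] <- round(as.matrix(rows[, edges]) + jit, 3)
        widths_ok <- all(cand$x_max - cand$x_min > 1 &
                           cand$y_max - cand$y_min > 1)
        g <- cand[cand$part == "grasp", ]
        f <- cand[cand$part == "functional", ]
        no_swap <- (g$x_min + g$x_max) / 2 < (f$x_min + f$x_max) / 2
        if (widths_ok && no_swap) break
        if (attempt == 100L) {
          stop("generate_drawn_rects: jitter repeatedly produced degenerate rectangles")
        }
      }
      cand$subject <- subj
      out[[length(out) + 1L]] <- cand
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("subject", "tool", "part", "x_min", "y_min", "x_max", "y_max")]
}

tg_gen_ratings <- function(config) {
  tools <- tg_tool_table(config)
  subjects <- tg_subject_ids(config)
  grid <- expand.grid(subject = subjects, tool = tools$tool,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$subject, subjects),
                     match(grid$tool, tools$tool)), ]
  grid$familiarity <- tools$familiarity[match(grid$tool, tools$tool)]
  grid$rating <- NA_integer_
  for (fam in tg_familiarity()) {
    idx <- grid$familiarity == fam
    grid$rating[idx] <- sample(1:5, sum(idx), replace = TRUE,
                               prob = config$rating_probs[[fam]])
  }
  rownames(grid) <- NULL
  grid[c("subject", "tool", "familiarity", "rating")]
}

# Simulate one trial: alternating fixations (Gamma durations truncated at
# min_fixation_duration_ms) and short transit bursts. Transit sample i sits
# on the line between consecutive centroids plus an alternating vertical
# excursion, so every transit displacement exceeds any plausible velocity
# threshold and the injected segmentation is the unique correct grouping.
tg_sim_trial <- function(config, layout, weights, trial_id) {
  period <- 1000 / config$sampling_hz
  n_total <- round(config$trial_duration_ms * config$sampling_hz / 1000)
  min_n <- ceiling(config$min_fixation_duration_ms / period - 1e-9)
  k <- config$saccade_samples
  regions <- c("functional", "grasp", "center")

  starts <- integer(0); lens <- integer(0)
  region_of <- character(0); cx <- numeric(0); cy <- numeric(0)
  pos <- 1L
  repeat {
    remaining <- n_total - pos + 1L
    dur <- stats::rgamma(1, shape = config$fixation_duration_shape,
                         scale = config$fixation_duration_scale_ms)
    n_fix <- max(min_n, round(dur / period))
    if (remaining < n_fix + k + min_n) n_fix <- remaining
    region <- sample(regions, 1, prob = weights)
    r <- layout[[region]]
    rcx <- (r$x_min + r$x_max) / 2
    rcy <- (r$y_min + r$y_max) / 2
    cxy <- c(rcx, rcy) + stats::rnorm(2, sd = config$fixation_scatter_px)
    cxy[1] <- min(max(cxy[1], r$x_min + 1), r$x_max - 1)
    cxy[2] <- min(max(cxy[2], r$y_min + 1), r$y_max - 1)
    starts <- c(starts, pos); lens <- c(lens, n_fix)
    region_of <- c(region_of, region); cx <- c(cx, cxy[1]); cy <- c(cy, cxy[2])
    pos <- pos + n_fix
    if (pos > n_total) break
    pos <- pos + k
  }

  x <- numeric(n_total); y <- numeric(n_total)
  n_fixes <- length(starts)
  for (i in seq_len(n_fixes)) {
    idx <- starts[i]:(starts[i] + lens[i] - 1L)
    if (config$sample_noise_px > 0) {
      x[idx] <- cx[i] + stats::rnorm(lens[i], sd = config$sample_noise_px)
      y[idx] <- cy[i] + stats::rnorm(lens[i], sd = config$sample_noise_px)
    } else {
      x[idx] <- cx[i]; y[idx] <- cy[i]
    }
    if (i < n_fixes) {
      tstart <- starts[i] + lens[i]
      for (s in seq_len(k)) {
        frac <- s / (k + 1)
        x[tstart + s - 1L] <- cx[i] + frac * (cx[i + 1] - cx[i])
        y[tstart + s - 1L] <- cy[i] + frac * (cy[i + 1] - cy[i]) +
          config$saccade_excursion_px * (-1)^s
      }
    }
  }

  valid <- rep(TRUE, n_total)
  if (config$dropout_prob > 0) {
    valid <- stats::runif(n_total) >= config$dropout_prob
  }
  samples <- data.frame(trial_id = trial_id,
                        t_ms = (seq_len(n_total) - 1) * period,
                        x_px = round(x, 3), y_px = round(y, 3),
                        valid = valid, stringsAsFactors = FALSE)
  fixations <- data.frame(trial_id = trial_id,
                          onset_ms = (starts - 1) * period,
                          offset_ms = (starts + lens - 1) * period,
                          region = region_of,
                          centroid_x_px = round(cx, 3),
                          centroid_y_px = round(cy, 3),
                          stringsAsFactors = FALSE)
  list(samples = samples, fixations = fixations)
}

#' Generate a complete synthetic experiment with ground truth
#'
#' Produces everything the pipeline consumes — trial manifest, 60 Hz gaze
#' streams, subject-drawn ROI rectangles, familiarity ratings — plus the
#' injected ground truth (fixation list, true rectangles, mixture weights).
#' Identical config (including seed) reproduces a bit-identical bundle.
#'
#' @param config A [generation_config()].
#' @return An object of class `gaze_bundle`: a list with `manifest`,
#'   `samples` (one data frame over all trials), `drawn_rects`, `ratings`,
#'   `ground_truth` (list: `fixations`, `true_rects`, `mixture_weights`)
#'   and `config`.
#' @export
generate_experiment <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(config$seed)
  layout <- tool_layout(config)
  tools <- tg_tool_table(config)
  subjects <- tg_subject_ids(config)

  drawn <- tg_gen_drawn_rects(config)
  ratings <- tg_gen_ratings(config)

  # Block order is fixed (free viewing, lift, use); tools are shown once per
  # condition in a per-subject random order. Recorded, not modelled.
  rows <- list()
  for (subj in subjects) {
    for (cond in tg_conditions()) {
      order_idx <- sample.int(nrow(tools))
      for (pos in seq_along(order_idx)) {
        tl <- tools[order_idx[pos], ]
        tid <- paste(subj, cond, tl$tool, sep = "_")
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, condition = cond, tool = tl$tool,
          familiarity = tl$familiarity, trial_id = tid,
          gaze_file = file.path("gaze", paste0(tid, ".tsv")),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL

  sample_list <- vector("list", nrow(manifest))
  fix_list <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    w <- config$mixture_weights[[manifest$condition[i]]][[manifest$familiarity[i]]]
    trial <- tg_sim_trial(config, layout, w, manifest$trial_id[i])
    sample_list[[i]] <- trial$samples
    fix_list[[i]] <- trial$fixations
  }
  samples <- do.call(rbind, sample_list)
  rownames(samples) <- NULL
  truth_fix <- do.call(rbind, fix_list)
  rownames(truth_fix) <- NULL

  structure(
    list(manifest = manifest, samples = samples, drawn_rects = drawn,
         ratings = ratings,
         ground_truth = list(fixations = truth_fix,
                             true_rects = tg_true_rects(config),
                             mixture_weights = config$mixture_weights),
         config = config),
    class = "gaze_bundle"
  )
}

#' Generate familiarity ratings alone
#'
#' Standalone version of the rating stage of [generate_experiment()]
#' (which uses the same distributions under the experiment-level seed).
#'
#' @param config A [generation_config()].
#' @return Data frame `subject`, `tool`, `familiarity`, `rating` (1-5).
#' @export
generate_ratings <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(config$seed)
  tg_gen_ratings(config)
}

#' Generate subject-drawn ROI rectangles alone
#'
#' Each drawn rectangle is the tool's true rectangle with independent
#' uniform edge jitter of half-width `drawn_rect_jitter_px`; draws that
#' degenerate (non-positive extent) or swap the grasp/functional sides are
#' redrawn up to a bounded retry count.
#'
#' @param config A [generation_config()].
#' @return Data frame `subject`, `tool`, `part`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @export
generate_drawn_rects <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(config$seed)
  tg_gen_drawn_rects(config)
}
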