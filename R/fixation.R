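# I-VT fixation classification at the native sampling period. The velocity
# criterion is a displacement threshold between consecutive valid samples
# (default 100 px per 60 Hz period, i.e. 100 px / 16.6 ms); maximal runs of
# sub-threshold displacements lasting at least the minimum duration become
# fixations.

#' Fixation-classifier parameters
#'
#' @param velocity_threshold_px Maximum displacement (px) between
#'   consecutive samples, per elapsed sample period, for the pair to stay
#'   within one fixation.
#' @param min_fixation_ms Minimum fixation duration.
#' @param max_gap_samples Maximum run of consecutive invalid samples that
#'   may be bridged inside a fixation (the displacement across the gap,
#'   scaled per elapsed period, must still be under threshold).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(velocity_threshold_px = 100,
                          min_fixation_ms = 100,
                          max_gap_samples = 1L) {
  if (!is.finite(velocity_threshold_px) || velocity_threshold_px <= 0) {
    stop("filter_params: velocity_threshold_px must be positive")
  }
  if (!is.finite(min_fixation_ms) || min_fixation_ms <= 0) {
    stop("filter_params: min_fixation_ms must be positive")
  }
  if (max_gap_samples < 0) stop("filter_params: max_gap_samples must be >= 0")
  structure(list(velocity_threshold_px = velocity_threshold_px,
                 min_fixation_ms = min_fixation_ms,
                 max_gap_samples = as.integer(max_gap_samples)),
            class = "filter_params")
}

#' Displacements between consecutive valid gaze samples
#'
#' @param samples One trial's gaze samples (`t_ms`, `x_px`, `y_px`,
#'   `valid`), time-ordered.
#' @return Data frame with one row per consecutive valid pair: sample
#'   indices `from`/`to`, Euclidean `displacement_px`, the number of sample
#'   periods spanned (`n_periods`), and `bridges_invalid` flagging intervals
#'   that cross invalid samples. Empty when fewer than 2 valid samples.
#' @export
sample_displacements <- function(samples) {
  v <- which(samples$valid & is.finite(samples$x_px) &
               is.finite(samples$y_px))
  if (length(v) < 2L) {
    return(data.frame(from = integer(0), to = integer(0),
                      displacement_px = numeric(0), n_periods = integer(0),
                      bridges_invalid = logical(0)))
  }
  dx <- diff(samples$x_px[v]); dy <- diff(samples$y_px[v])
  data.frame(from = v[-length(v)], to = v[-1],
             displacement_px = sqrt(dx^2 + dy^2),
             n_periods = diff(v),
             bridges_invalid = diff(v) > 1L)
}

#' Classify gaze samples into fixations (I-VT)
#'
#' Maximal runs of consecutive valid samples whose successive displacements
#' are all at or below `velocity_threshold_px` (per elapsed sample period)
#' form candidate groups; groups spanning at least `min_fixation_ms` are
#' emitted as fixations. A fixation's duration covers one sampling period
#' per member sample: `end_ms` is the last member's timestamp plus one
#' period, so a full 300-sample 60 Hz trial at one position yields a single
#' 5,000 ms fixation. Centroids are unweighted means of member positions.
#'
#' @param samples One trial's gaze samples (`t_ms`, `x_px`, `y_px`,
#'   `valid`), time-ordered.
#' @param params A [filter_params()].
#' @param sampling_hz Nominal sampling rate (sets the sample period used
#'   for durations and for scaling displacements across bridged gaps).
#' @return Data frame of fixations: `start_ms`, `end_ms`, `duration_ms`,
#'   `centroid_x_px`, `centroid_y_px`, `first_idx`, `last_idx`,
#'   `n_samples`; zero rows when nothing qualifies.
#' @export
classify_fixations <- function(samples, params = filter_params(),
                               sampling_hz = 60) {
  stopifnot(inherits(params, "filter_params"))
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      duration_ms = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), first_idx = integer(0),
                      last_idx = integer(0), n_samples = integer(0))
  v <- which(samples$valid & is.finite(samples$x_px) &
               is.finite(samples$y_px))
  if (length(v) == 0L) return(empty)
  period <- 1000 / sampling_hz
  if (length(v) == 1L) {
    grp <- 1L
  } else {
    dx <- diff(samples$x_px[v]); dy <- diff(samples$y_px[v])
    disp <- sqrt(dx^2 + dy^2)
    span <- diff(v) # elapsed sample periods (1 = adjacent)
    break_here <- (span - 1L) > params$max_gap_samples |
      disp > params$velocity_threshold_px * span
    grp <- cumsum(c(1L, as.integer(break_here)))
  }
  first <- v[!duplicated(grp)]
  last <- v[!duplicated(grp, fromLast = TRUE)]
  n_mem <- tabulate(grp)
  cx <- as.numeric(rowsum(samples$x_px[v], grp)) / n_mem
  cy <- as.numeric(rowsum(samples$y_px[v], grp)) / n_mem
  start_ms <- samples$t_ms[first]
  end_ms <- samples$t_ms[last] + period
  duration <- end_ms - start_ms
  keep <- duration >= params$min_fixation_ms - 1e-6
  if (!any(keep)) return(empty)
  out <- data.frame(start_ms = start_ms[keep], end_ms = end_ms[keep],
                    duration_ms = duration[keep],
                    centroid_x_px = cx[keep], centroid_y_px = cy[keep],
                    first_idx = first[keep], last_idx = last[keep],
                    n_samples = n_mem[keep])
  rownames(out) <- NULL
  out
}

#' Classify fixations for every trial in a bundle
#'
#' @param samples All trials' gaze samples (with `trial_id`).
#' @param manifest Trial manifest; subject/condition/tool/familiarity are
#'   joined onto the output.
#' @inheritParams classify_fixations
#' @return Fixation table with one row per fixation, carrying the trial's
#'   design labels.
#' @export
classify_fixations_batch <- function(samples, manifest,
                                     params = filter_params(),
                                     sampling_hz = 60) {
  idx <- split(seq_len(nrow(samples)), samples$trial_id)
  out <- lapply(manifest$trial_id, function(tid) {
    rows <- idx[[tid]]
    if (is.null(rows)) return(NULL)
    fx <- classify_fixations(samples[rows, , drop = FALSE], params,
                             sampling_hz)
    if (nrow(fx) == 0L) return(NULL)
    fx$trial_id <- tid
    fx
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      duration_ms = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), first_idx = integer(0),
                      last_idx = integer(0), n_samples = integer(0),
                      trial_id = character(0))
  }
  m <- match(out$trial_id, manifest$trial_id)
  out$subject <- manifest$subject[m]
  out$condition <- manifest$condition[m]
  out$tool <- manifest$tool[m]
  out$familiarity <- manifest$familiarity[m]
  rownames(out) <- NULL
  out
}

#' Total duration of fixations satisfying a spatial predicate
#'
#' @param fixations A fixation table from [classify_fixations()].
#' @param predicate Function of `(x, y)` centroid vectors returning a
#'   logical vector; e.g. containment in an ROI rectangle.
#' @return Summed `duration_ms` over matching fixations; 0 when empty.
#' @export
cumulative_duration <- function(fixations, predicate) {
  if (nrow(fixations) == 0L) return(0)
  hit <- predicate(fixations$centroid_x_px, fixations$centroid_y_px)
  sum(fixations$duration_ms[hit])
}
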