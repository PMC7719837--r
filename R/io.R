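# On-disk dialects. No tracker-export format is assumed; these are the
# package's documented plain-text formats. All readers validate and report
# the location of the first offending row; none silently drops data.
# Paths ending in ".gz" are read and written through a gzip connection
# (reading any compressed file also works transparently via file()).

tg_gaze_cols <- c("trial_id", "t_ms", "x_px", "y_px", "valid")

tg_open_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  file(path, "rt") # file() decompresses gz/bz2/xz transparently
}

tg_open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

tg_fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

tg_check_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "))
  }
}

tg_check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad)) {
    stop(what, ": value(s) outside the closed vocabulary {",
         paste(vocab, collapse = ", "), "}: ", paste(bad, collapse = ", "))
  }
}

#' Write and read gaze sample logs (tab-separated)
#'
#' Columns: `trial_id`, `t_ms` (time since stimulus onset, written at full
#' double precision), `x_px`, `y_px` (written to 3 decimals), `valid` (0/1).
#' Invalid samples keep their coordinate fields (possibly `NA`); no sentinel
#' values are used. Writing then reading is the identity at the stated
#' precision.
#'
#' @param samples Data frame with the columns above (`valid` logical).
#' @param path File path; a `.gz` suffix enables gzip compression.
#' @export
write_gaze_tsv <- function(samples, path) {
  tg_check_cols(samples, tg_gaze_cols, "write_gaze_tsv")
  con <- tg_open_write(path)
  on.exit(close(con))
  lines <- paste(samples$trial_id,
                 sprintf("%.17g", samples$t_ms),
                 tg_fmt3(samples$x_px),
                 tg_fmt3(samples$y_px),
                 as.integer(samples$valid),
                 sep = "\t")
  writeLines(c(paste(tg_gaze_cols, collapse = "\t"), lines), con)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @param sampling_hz If supplied, inter-sample intervals are checked to be
#'   within 20% of the nominal period, except across runs of invalid samples.
#' @return `read_gaze_tsv` returns the samples data frame (`valid` logical).
#' @export
read_gaze_tsv <- function(path, sampling_hz = NULL) {
  con <- tg_open_read(path)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, sep = "\t",
                          colClasses = c(trial_id = "character"),
                          na.strings = "NA", check.names = TRUE)
  tg_check_cols(df, tg_gaze_cols, "read_gaze_tsv")
  df <- df[tg_gaze_cols]
  df$valid <- df$valid != 0L
  if (any(is.na(df$t_ms)) || any(df$t_ms < 0)) {
    stop("read_gaze_tsv: timestamps must be present and non-negative (row ",
         which(is.na(df$t_ms) | df$t_ms < 0)[1], ")")
  }
  if (any(df$valid & (!is.finite(df$x_px) | !is.finite(df$y_px)))) {
    stop("read_gaze_tsv: valid sample with non-finite coordinates (row ",
         which(df$valid & (!is.finite(df$x_px) | !is.finite(df$y_px)))[1], ")")
  }
  for (tid in unique(df$trial_id)) {
    idx <- which(df$trial_id == tid)
    t <- df$t_ms[idx]
    if (length(t) > 1) {
      bad <- which(diff(t) <= 0)
      if (length(bad)) {
        stop("read_gaze_tsv: non-monotone timestamps in trial ", tid,
             " at row ", idx[bad[1] + 1L])
      }
      if (!is.null(sampling_hz)) {
        period <- 1000 / sampling_hz
        dt <- diff(t)
        # gaps across invalid samples are allowed to exceed the nominal period
        across_invalid <- !df$valid[idx[-length(idx)]] | !df$valid[idx[-1]]
        bad <- which(!across_invalid & abs(dt - period) > 0.2 * period)
        if (length(bad)) {
          stop("read_gaze_tsv: inter-sample interval off-nominal in trial ",
               tid, " at row ", idx[bad[1] + 1L])
        }
      }
    }
  }
  df
}

#' Write and read the trial manifest (CSV)
#'
#' Columns: `subject`, `condition`, `tool`, `familiarity`, `trial_id`,
#' `gaze_file` (path to the trial's gaze TSV, relative to the manifest's
#' directory). Conditions and familiarity come from closed vocabularies;
#' `(subject, condition, tool)` must be unique.
#'
#' @param manifest Data frame with the columns above.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("subject", "condition", "tool", "familiarity", "trial_id",
            "gaze_file")
  tg_check_cols(manifest, cols, "write_manifest")
  utils::write.csv(manifest[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_files Verify every referenced gaze file exists.
#' @param base_dir Directory gaze-file references are resolved against
#'   (defaults to the manifest's directory).
#' @export
read_manifest <- function(path, check_files = TRUE,
                          base_dir = dirname(path)) {
  con <- tg_open_read(path)
  on.exit(close(con))
  df <- utils::read.csv(con, colClasses = "character")
  cols <- c("subject", "condition", "tool", "familiarity", "trial_id",
            "gaze_file")
  tg_check_cols(df, cols, "read_manifest")
  df <- df[cols]
  tg_check_vocab(df$condition, tg_conditions(), "read_manifest: condition")
  tg_check_vocab(df$familiarity, tg_familiarity(),
                 "read_manifest: familiarity")
  key <- paste(df$subject, df$condition, df$tool, sep = "\r")
  if (anyDuplicated(key)) {
    stop("read_manifest: duplicate (subject, condition, tool) at row ",
         which(duplicated(key))[1])
  }
  if (check_files) {
    paths <- file.path(base_dir, df$gaze_file)
    missing <- !file.exists(paths)
    if (any(missing)) {
      stop("read_manifest: referenced gaze file(s) not found: ",
           paste(utils::head(df$gaze_file[missing], 5), collapse = ", "))
    }
  }
  df
}

#' Write and read subject-drawn ROI rectangles (tab-separated)
#'
#' One row per subject x tool x part, keyed by `subject`, `tool`, `part`
#' (`functional` or `grasp`), with edges `x_min`, `y_min`, `x_max`, `y_max`
#' in screen pixels (3 decimals on disk).
#'
#' @param rects Data frame with the columns above.
#' @param path File path.
#' @export
write_roi_file <- function(rects, path) {
  cols <- c("subject", "tool", "part", "x_min", "y_min", "x_max", "y_max")
  tg_check_cols(rects, cols, "write_roi_file")
  out <- rects[cols]
  for (nm in c("x_min", "y_min", "x_max", "y_max")) {
    out[[nm]] <- tg_fmt3(out[[nm]])
  }
  con <- tg_open_write(path)
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_file
#' @export
read_roi_file <- function(path) {
  con <- tg_open_read(path)
  on.exit(close(con))
  df <- utils::read.delim(con, colClasses = c(subject = "character",
                                              tool = "character",
                                              part = "character"))
  cols <- c("subject", "tool", "part", "x_min", "y_min", "x_max", "y_max")
  tg_check_cols(df, cols, "read_roi_file")
  df <- df[cols]
  tg_check_vocab(df$part, tg_parts(), "read_roi_file: part")
  bad <- which(!(df$x_min < df$x_max & df$y_min < df$y_max))
  if (length(bad)) {
    stop("read_roi_file: degenerate rectangle at row ", bad[1])
  }
  df
}

#' Write and read tool-familiarity ratings (CSV)
#'
#' Columns: `subject`, `tool`, `familiarity`, `rating` (integer 1-5 on the
#' post-experiment familiarity scale).
#'
#' @param ratings Data frame with the columns above.
#' @param path File path.
#' @export
write_ratings <- function(ratings, path) {
  cols <- c("subject", "tool", "familiarity", "rating")
  tg_check_cols(ratings, cols, "write_ratings")
  utils::write.csv(ratings[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  con <- tg_open_read(path)
  on.exit(close(con))
  df <- utils::read.csv(con, colClasses = c(subject = "character",
                                            tool = "character",
                                            familiarity = "character"))
  cols <- c("subject", "tool", "familiarity", "rating")
  tg_check_cols(df, cols, "read_ratings")
  df <- df[cols]
  tg_check_vocab(df$familiarity, tg_familiarity(), "read_ratings: familiarity")
  bad <- which(!(df$rating %in% 1:5))
  if (length(bad)) {
    stop("read_ratings: rating outside 1..5 at row ", bad[1])
  }
  df$rating <- as.integer(df$rating)
  df
}

# Ground-truth fixation log (generator output; recovery-test oracle).
tg_truth_cols <- c("trial_id", "onset_ms", "offset_ms", "region",
                   "centroid_x_px", "centroid_y_px")

#' @rdname write_gaze_tsv
#' @param truth Ground-truth fixation data frame
#'   (`trial_id`, `onset_ms`, `offset_ms`, `region`, `centroid_x_px`,
#'   `centroid_y_px`).
#' @export
write_ground_truth <- function(truth, path) {
  tg_check_cols(truth, tg_truth_cols, "write_ground_truth")
  out <- truth[tg_truth_cols]
  out$onset_ms <- sprintf("%.17g", out$onset_ms)
  out$offset_ms <- sprintf("%.17g", out$offset_ms)
  out$centroid_x_px <- tg_fmt3(out$centroid_x_px)
  out$centroid_y_px <- tg_fmt3(out$centroid_y_px)
  con <- tg_open_write(path)
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_ground_truth <- function(path) {
  con <- tg_open_read(path)
  on.exit(close(con))
  df <- utils::read.delim(con, colClasses = c(trial_id = "character",
                                              region = "character"))
  tg_check_cols(df, tg_truth_cols, "read_ground_truth")
  df[tg_truth_cols]
}

#' Write a generated experiment bundle to a directory
#'
#' Lays out the bundle in the package's on-disk dialects: per-trial gaze
#' TSVs under `gaze/`, `manifest.csv`, `rois_drawn.tsv`, `ratings.csv`,
#' `true_rois.tsv`, `ground_truth.tsv` and `config.yaml`.
#'
#' @param bundle A bundle from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "gaze"), recursive = TRUE, showWarnings = FALSE)
  split_idx <- split(seq_len(nrow(bundle$samples)), bundle$samples$trial_id)
  for (i in seq_len(nrow(bundle$manifest))) {
    tid <- bundle$manifest$trial_id[i]
    write_gaze_tsv(bundle$samples[split_idx[[tid]], , drop = FALSE],
                   file.path(dir, bundle$manifest$gaze_file[i]))
  }
  write_manifest(bundle$manifest, file.path(dir, "manifest.csv"))
  write_roi_file(bundle$drawn_rects, file.path(dir, "rois_drawn.tsv"))
  write_ratings(bundle$ratings, file.path(dir, "ratings.csv"))
  true_rects <- bundle$ground_truth$true_rects
  true_rects$subject <- "truth"
  write_roi_file(true_rects, file.path(dir, "true_rois.tsv"))
  write_ground_truth(bundle$ground_truth$fixations,
                     file.path(dir, "ground_truth.tsv"))
  yaml::write_yaml(config_to_list(bundle$config),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @return `read_bundle` returns a bundle equal (at on-disk precision, which
#'   the generator also uses in memory) to the one that was written.
#' @export
read_bundle <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  samples <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    read_gaze_tsv(file.path(dir, manifest$gaze_file[i]))
  }))
  rownames(samples) <- NULL
  drawn <- read_roi_file(file.path(dir, "rois_drawn.tsv"))
  ratings <- read_ratings(file.path(dir, "ratings.csv"))
  truth_path <- file.path(dir, "ground_truth.tsv")
  true_roi_path <- file.path(dir, "true_rois.tsv")
  config_path <- file.path(dir, "config.yaml")
  ground_truth <- NULL
  if (file.exists(truth_path) && file.exists(true_roi_path)) {
    tr <- read_roi_file(true_roi_path)
    tr$subject <- NULL
    fam <- rep(NA_character_, nrow(tr))
    fam[grepl("^familiar", tr$tool)] <- "familiar"
    fam[grepl("^unfamiliar", tr$tool)] <- "unfamiliar"
    tr$familiarity <- fam
    ground_truth <- list(fixations = read_ground_truth(truth_path),
                         true_rects = tr[c("tool", "familiarity", "part",
                                           "x_min", "y_min", "x_max",
                                           "y_max")])
  }
  config <- if (file.exists(config_path)) {
    config_from_list(yaml::read_yaml(config_path))
  }
  structure(list(manifest = manifest, samples = samples,
                 drawn_rects = drawn, ratings = ratings,
                 ground_truth = ground_truth, config = config),
            class = "gaze_bundle")
}
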