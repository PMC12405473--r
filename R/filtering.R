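#' Frame-selection configuration
#'
#' Parameters of the quality-filtering cascade that turns raw landmark
#' time series into per-subject analysis sets: detector-confidence
#' threshold, percentile for head-pose outlier removal, minimum
#' inter-sample interval (to decorrelate successive expressions), minimum
#' number of surviving sets per condition for a subject to be retained, and
#' the per-subject per-condition top-k selection by confidence.
#'
#' @param conf_threshold confidence threshold in \[0, 1\]; sets with
#'   confidence `>=` the threshold are kept.
#' @param outlier_percentile percentile in (0, 100\] above which head tilt
#'   or rotation asymmetry marks a set as a pose outlier.
#' @param min_interval_s minimum spacing between retained sets, seconds.
#' @param min_sets_per_condition subject-inclusion threshold.
#' @param top_k sets retained per subject per condition.
#' @param pool_outliers compute the outlier percentile over all videos
#'   pooled (`TRUE`, default) or per video.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(conf_threshold = 0.6, outlier_percentile = 95,
                          min_interval_s = 1.0,
                          min_sets_per_condition = 10L, top_k = 10L,
                          pool_outliers = TRUE) {
  if (conf_threshold < 0 || conf_threshold > 1)
    stop("conf_threshold must lie in [0, 1]", call. = FALSE)
  if (outlier_percentile <= 0 || outlier_percentile > 100)
    stop("outlier_percentile must lie in (0, 100]", call. = FALSE)
  if (min_interval_s < 0) stop("min_interval_s must be >= 0", call. = FALSE)
  if (min_sets_per_condition < 0 || top_k < 1)
    stop("invalid set-count parameters", call. = FALSE)
  if (top_k > min_sets_per_condition)
    warning("top_k exceeds min_sets_per_condition; ",
            "retained subjects may contribute unequal set counts")
  structure(list(conf_threshold = conf_threshold,
                 outlier_percentile = outlier_percentile,
                 min_interval_s = min_interval_s,
                 min_sets_per_condition = as.integer(min_sets_per_condition),
                 top_k = as.integer(top_k),
                 pool_outliers = isTRUE(pool_outliers)),
            class = "filter_config")
}

#' Head tilt of one landmark set
#'
#' The absolute acute angle, in degrees, between the segment joining the
#' inner eye corners and the image x-axis; 0 for a level head, 90 for a
#' fully rolled one. Used (with [head_rotation_asym()]) to discard frames
#' in which the head is strongly tilted or turned.
#'
#' @param shape L x 2 coordinate matrix.
#' @param scheme the `landmark_scheme` in force.
#' @return angle in degrees, in \[0, 90\].
#' @export
head_tilt_deg <- function(shape, scheme) {
  e1 <- shape[scheme_role(scheme, "inner_eye_left"), ]
  e2 <- shape[scheme_role(scheme, "inner_eye_right"), ]
  d <- e2 - e1
  if (all(d == 0))
    stop("degenerate geometry: inner eye corners coincide", call. = FALSE)
  atan2(abs(d[2L]), abs(d[1L])) * 180 / pi
}

#' Head rotation asymmetry of one landmark set
#'
#' The absolute difference between the eye-to-nose distances of the two
#' inner eye corners, in the coordinate units of the input (pixels for raw
#' data). Zero for a frontal face; grows as the head turns.
#'
#' @inheritParams head_tilt_deg
#' @return a nonnegative scalar.
#' @export
head_rotation_asym <- function(shape, scheme) {
  e1 <- shape[scheme_role(scheme, "inner_eye_left"), ]
  e2 <- shape[scheme_role(scheme, "inner_eye_right"), ]
  nose <- shape[scheme_role(scheme, "nose_centre"), ]
  abs(sqrt(sum((e1 - nose)^2)) - sqrt(sum((e2 - nose)^2)))
}

# Vectorized pose metrics over a time series.
ts_pose_metrics <- function(ts, scheme) {
  n <- n_sets(ts)
  tilt <- numeric(n)
  rot <- numeric(n)
  for (i in seq_len(n)) {
    tilt[i] <- head_tilt_deg(ts$coords[i, , ], scheme)
    rot[i] <- head_rotation_asym(ts$coords[i, , ], scheme)
  }
  data.frame(tilt = tilt, rot = rot)
}

#' Confidence filter
#'
#' Keeps landmark sets whose detector confidence is at or above the
#' threshold (boundary inclusive), preserving order.
#'
#' @param ts a `landmark_ts`.
#' @param cfg a `filter_config`.
#' @return the filtered `landmark_ts`.
#' @export
filter_by_confidence <- function(ts, cfg) {
  subset_ts(ts, which(ts$confidence >= cfg$conf_threshold))
}

#' Pose-outlier filter
#'
#' Computes the `outlier_percentile`-th percentile (linear interpolation
#' between order statistics) of head tilt and of rotation asymmetry over
#' the supplied sets, and removes any set strictly exceeding either
#' threshold. With fewer than two sets the input is returned unchanged.
#' Applied to the pooled post-confidence sample across all videos by
#' default; see [run_filter_cascade()].
#'
#' @param ts a `landmark_ts`.
#' @param cfg a `filter_config`.
#' @param scheme the scheme in force.
#' @param thresholds optional precomputed `c(tilt, rot)` thresholds (used
#'   for pooled filtering); when `NULL` they are computed from `ts` itself.
#' @return the filtered `landmark_ts`.
#' @export
remove_pose_outliers <- function(ts, cfg, scheme, thresholds = NULL) {
  if (n_sets(ts) < 2L && is.null(thresholds)) return(ts)
  pm <- ts_pose_metrics(ts, scheme)
  if (is.null(thresholds)) {
    p <- cfg$outlier_percentile / 100
    thresholds <- c(stats::quantile(pm$tilt, p, type = 7, names = FALSE),
                    stats::quantile(pm$rot, p, type = 7, names = FALSE))
  }
  keep <- pm$tilt <= thresholds[1L] & pm$rot <= thresholds[2L]
  subset_ts(ts, which(keep))
}

#' Minimum inter-sample interval filter
#'
#' Greedy earliest-first thinning: the first set is kept, and each later
#' set is kept iff its timestamp is at least `min_interval_s` after the
#' last kept one. Decorrelates successive dynamic expressions.
#'
#' @param ts a `landmark_ts` (timestamps nondecreasing).
#' @param cfg a `filter_config`.
#' @return the thinned `landmark_ts`.
#' @export
enforce_min_interval <- function(ts, cfg) {
  n <- n_sets(ts)
  if (n <= 1L || cfg$min_interval_s <= 0) return(ts)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (ts$timestamp[i] >= last + cfg$min_interval_s) {
      keep[i] <- TRUE
      last <- ts$timestamp[i]
    }
  }
  subset_ts(ts, which(keep))
}

#' Subject-inclusion filter
#'
#' Retains only subjects with at least `min_sets_per_condition` surviving
#' sets in both conditions, and returns the exclusion log.
#'
#' @param dataset a `landmark_dataset`.
#' @param cfg a `filter_config`.
#' @return list with `dataset` (retained videos) and `excluded`
#'   (data frame: subject, control/fireworks set counts).
#' @export
select_subjects <- function(dataset, cfg) {
  man <- dataset$manifest
  counts <- vapply(dataset$tables, n_sets, integer(1L))
  subj <- unique(man$subject_id)
  per <- t(vapply(subj, function(s) c(
    control = sum(counts[man$subject_id == s & man$condition == "control"]),
    fireworks = sum(counts[man$subject_id == s &
                             man$condition == "fireworks"])),
    integer(2L)))
  ok <- per[, "control"] >= cfg$min_sets_per_condition &
        per[, "fireworks"] >= cfg$min_sets_per_condition
  keep_vid <- man$subject_id %in% subj[ok]
  excluded <- data.frame(subject_id = subj[!ok],
                         control = per[!ok, "control"],
                         fireworks = per[!ok, "fireworks"],
                         row.names = NULL)
  ds <- if (any(keep_vid))
    landmark_dataset(dataset$tables[keep_vid], man[keep_vid, , drop = FALSE])
  else structure(list(tables = list(),
                      manifest = man[0L, , drop = FALSE]),
                 class = "landmark_dataset")
  list(dataset = ds, excluded = excluded)
}

#' Top-k selection by confidence
#'
#' Keeps the `top_k` highest-confidence sets of a series (applied per
#' subject per condition). Ties are broken by earlier timestamp, then by
#' input order, so selection is fully deterministic. If fewer than `top_k`
#' sets are available, all are kept. Output preserves timestamp order.
#'
#' @param ts a `landmark_ts`.
#' @param cfg a `filter_config`.
#' @return the selected `landmark_ts`.
#' @export
select_top_k <- function(ts, cfg) {
  n <- n_sets(ts)
  if (n <= cfg$top_k) return(ts)
  ord <- order(-ts$confidence, ts$timestamp, seq_len(n))
  subset_ts(ts, sort(ord[seq_len(cfg$top_k)]))
}

#' Run the full frame-selection cascade
#'
#' Applies, in order: ear-pinna landmark removal, confidence filtering,
#' head-pose outlier removal (percentile thresholds pooled across all
#' videos by default), per-video minimum-interval thinning, subject
#' inclusion, and per-subject per-condition top-k selection by confidence.
#'
#' @param dataset a `landmark_dataset` on the raw (full) scheme.
#' @param cfg a `filter_config`.
#' @param scheme the raw `landmark_scheme`; the cascade works on
#'   `reduce_scheme(scheme)` after pinna removal.
#' @param drop_ears set `FALSE` if `dataset` is already on the reduced
#'   scheme.
#' @return list with `dataset` (the analysis sets), `report` (a
#'   `filter_report`: per-stage counts) and `excluded` (subject log).
#' @export
run_filter_cascade <- function(dataset, cfg = filter_config(),
                               scheme = default_scheme(),
                               drop_ears = TRUE) {
  stopifnot(inherits(dataset, "landmark_dataset"),
            inherits(cfg, "filter_config"))
  count_all <- function(ds) sum(vapply(ds$tables, n_sets, integer(1L)))
  stages <- character()
  counts <- integer()
  note <- function(stage, ds) {
    stages <<- c(stages, stage)
    counts <<- c(counts, count_all(ds))
  }
  note("input", dataset)
  if (drop_ears) {
    dataset <- drop_ear_landmarks(dataset, scheme)
    scheme <- reduce_scheme(scheme)
  }
  note("ear_removal", dataset)

  dataset$tables <- lapply(dataset$tables, filter_by_confidence, cfg = cfg)
  note("confidence", dataset)
  n_after_conf <- counts[length(counts)]

  if (cfg$pool_outliers) {
    pm <- do.call(rbind, lapply(dataset$tables, ts_pose_metrics,
                                scheme = scheme))
    if (!is.null(pm) && nrow(pm) >= 2L) {
      p <- cfg$outlier_percentile / 100
      thr <- c(stats::quantile(pm$tilt, p, type = 7, names = FALSE),
               stats::quantile(pm$rot, p, type = 7, names = FALSE))
      dataset$tables <- lapply(dataset$tables, remove_pose_outliers,
                               cfg = cfg, scheme = scheme, thresholds = thr)
    }
  } else {
    dataset$tables <- lapply(dataset$tables, remove_pose_outliers,
                             cfg = cfg, scheme = scheme)
  }
  note("pose_outliers", dataset)

  dataset$tables <- lapply(dataset$tables, enforce_min_interval, cfg = cfg)
  note("min_interval", dataset)

  sel <- select_subjects(dataset, cfg)
  dataset <- sel$dataset
  note("subject_inclusion", dataset)

  dataset$tables <- lapply(dataset$tables, select_top_k, cfg = cfg)
  note("top_k", dataset)

  report <- structure(list(
    counts = data.frame(stage = stages, n_sets = counts),
    confidence_retention = if (counts[1L] > 0)
      n_after_conf / counts[1L] else NA_real_
  ), class = "filter_report")
  list(dataset = dataset, report = report, excluded = sel$excluded)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter cascade:\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("confidence retention: %.1f%%\n",
              100 * x$confidence_retention))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(list(counts = report$counts,
                            confidence_retention =
                              report$confidence_retention),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Stack a dataset's landmark sets for analysis
#'
#' Collects every landmark set of a (filtered) dataset into one
#' `n x L x 2` coordinate array with parallel subject / condition / video
#' / timestamp / confidence vectors, the form the alignment and statistics
#' functions consume.
#'
#' @param dataset a `landmark_dataset`.
#' @return list with `coords`, `subject`, `condition`, `video`,
#'   `timestamp`, `confidence`.
#' @export
stack_dataset <- function(dataset) {
  tabs <- dataset$tables
  ns <- vapply(tabs, n_sets, integer(1L))
  n <- sum(ns)
  if (n == 0L) stop("dataset has no landmark sets", call. = FALSE)
  L <- n_landmarks_ts(tabs[[which(ns > 0)[1L]]])
  coords <- array(0, dim = c(n, L, 2L))
  subject <- character(n)
  condition <- character(n)
  video <- character(n)
  timestamp <- numeric(n)
  confidence <- numeric(n)
  at <- 0L
  for (t in tabs) {
    k <- n_sets(t)
    if (k == 0L) next
    idx <- at + seq_len(k)
    coords[idx, , ] <- t$coords
    subject[idx] <- t$subject_id
    condition[idx] <- t$condition
    video[idx] <- t$video_id
    timestamp[idx] <- t$timestamp
    confidence[idx] <- t$confidence
    at <- at + k
  }
  list(coords = coords, subject = subject, condition = condition,
       video = video, timestamp = timestamp, confidence = confidence)
}
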