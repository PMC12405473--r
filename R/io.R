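#' Landmark time series
#'
#' One video's landmark detections: for each retained frame, a timestamp in
#' seconds, the detector confidence in \[0, 1\] and an L x 2 matrix of image
#' coordinates in pixels (x rightward, y downward). Stored as an object of
#' class `landmark_ts` with an `n x L x 2` coordinate array.
#'
#' @param video_id video identifier.
#' @param subject_id subject identifier.
#' @param condition `"control"` or `"fireworks"`.
#' @param timestamp numeric vector of frame timestamps, seconds,
#'   nondecreasing.
#' @param confidence numeric vector in \[0, 1\], same length.
#' @param coords numeric array `n x L x 2`.
#' @return an object of class `landmark_ts`.
#' @export
landmark_ts <- function(video_id, subject_id, condition,
                        timestamp, confidence, coords) {
  condition <- match.arg(condition, c("control", "fireworks"))
  timestamp <- as.numeric(timestamp)
  confidence <- as.numeric(confidence)
  n <- length(timestamp)
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3L] != 2L)
    stop("coords must be an n x L x 2 array", call. = FALSE)
  if (dim(coords)[1L] != n || length(confidence) != n)
    stop("timestamp, confidence and coords disagree on the number of sets",
         call. = FALSE)
  if (n > 0) {
    if (any(!is.finite(timestamp)) || any(timestamp < 0))
      stop("timestamps must be finite and >= 0", call. = FALSE)
    if (is.unsorted(timestamp))
      stop("timestamps must be nondecreasing", call. = FALSE)
    if (any(confidence < 0 | confidence > 1))
      stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(video_id = video_id, subject_id = subject_id,
                 condition = condition, timestamp = timestamp,
                 confidence = confidence, coords = coords),
            class = "landmark_ts")
}

#' @export
print.landmark_ts <- function(x, ...) {
  cat("Landmark time series", x$video_id, "(subject", x$subject_id,
      "/", x$condition, "):", length(x$timestamp), "sets x",
      dim(x$coords)[2L], "landmarks\n")
  invisible(x)
}

n_sets <- function(ts) length(ts$timestamp)

n_landmarks_ts <- function(ts) dim(ts$coords)[2L]

# Subset a time series by row index, keeping metadata.
subset_ts <- function(ts, idx) {
  landmark_ts(ts$video_id, ts$subject_id, ts$condition,
              ts$timestamp[idx], ts$confidence[idx],
              ts$coords[idx, , , drop = FALSE])
}

#' Read a landmark time-series CSV
#'
#' Wide CSV layout, UTF-8, comma separated: columns `timestamp`,
#' `x1 ... xL`, `y1 ... yL`, `confidence`, one landmark set per row. The
#' coordinate count is validated against `scheme`.
#'
#' @param path CSV file path.
#' @param scheme the `landmark_scheme` in force (46-point raw or 36-point
#'   reduced).
#' @param video_id,subject_id,condition metadata attached to the returned
#'   series (normally supplied by the manifest).
#' @return a `landmark_ts`.
#' @export
read_landmark_timeseries <- function(path, scheme, video_id = basename(path),
                                     subject_id = NA_character_,
                                     condition = "control") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  L <- scheme$n_landmarks
  want <- c("timestamp", paste0("x", seq_len(L)), paste0("y", seq_len(L)),
            "confidence")
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column(s) ",
         paste(utils::head(missing_cols, 3L), collapse = ", "),
         if (length(missing_cols) > 3L) " ...", call. = FALSE)
  extra <- setdiff(names(df), want)
  if (length(extra))
    stop("schema error in ", path, ": unexpected column(s) ",
         paste(utils::head(extra, 3L), collapse = ", "), call. = FALSE)
  num <- suppressWarnings(
    vapply(df[want], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, want))
  if (nrow(df) > 0L) {
    bad <- which(apply(is.na(num), 1L, any))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric value in data row ",
           bad[1L], call. = FALSE)
    conf <- num[, "confidence"]
    if (any(conf < 0 | conf > 1))
      stop("validation error in ", path, ": confidence outside [0, 1] ",
           "in data row ", which(conf < 0 | conf > 1)[1L], call. = FALSE)
  }
  n <- nrow(df)
  coords <- array(0, dim = c(n, L, 2L))
  if (n > 0L) {
    coords[, , 1L] <- num[, paste0("x", seq_len(L)), drop = FALSE]
    coords[, , 2L] <- num[, paste0("y", seq_len(L)), drop = FALSE]
  }
  landmark_ts(video_id, subject_id, condition,
              timestamp = if (n) num[, "timestamp"] else numeric(),
              confidence = if (n) num[, "confidence"] else numeric(),
              coords = coords)
}

#' Write a landmark time-series CSV
#'
#' Inverse of [read_landmark_timeseries()]; coordinates are written with
#' full double precision (17 significant digits) so that a read/write round
#' trip is bit-stable.
#'
#' @param ts a `landmark_ts`.
#' @param path output file path.
#' @export
write_landmark_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "landmark_ts"))
  L <- n_landmarks_ts(ts)
  n <- n_sets(ts)
  header <- c("timestamp", paste0("x", seq_len(L)), paste0("y", seq_len(L)),
              "confidence")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (n > 0L) {
    m <- cbind(ts$timestamp, ts$coords[, , 1L, drop = TRUE],
               ts$coords[, , 2L, drop = TRUE], ts$confidence)
    if (n == 1L) m <- matrix(m, nrow = 1L)
    rows <- apply(m, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Study datasets: a manifest plus one time series per video
#'
#' @param tables list of `landmark_ts`, one per video.
#' @param manifest data frame with columns `video_id`, `subject_id`,
#'   `condition`, `path` (path may be `NA` for in-memory data).
#' @return an object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(tables, manifest) {
  need <- c("video_id", "subject_id", "condition", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(manifest$condition %in% c("control", "fireworks")))
    stop("manifest conditions must be control or fireworks", call. = FALSE)
  ids <- vapply(tables, function(t) t$video_id, character(1L))
  if (!setequal(ids, manifest$video_id))
    stop("manifest video_ids do not match the supplied tables",
         call. = FALSE)
  tables <- tables[match(manifest$video_id, ids)]
  structure(list(tables = tables, manifest = manifest),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", nrow(x$manifest), "videos,",
      length(unique(x$manifest$subject_id)), "subjects,",
      sum(vapply(x$tables, n_sets, integer(1L))), "landmark sets\n")
  invisible(x)
}

#' Read / write a study manifest
#'
#' CSV with columns `video_id`, `subject_id`, `condition`
#' (`control`|`fireworks`) and `path` (landmark table location, relative to
#' the manifest's directory unless absolute).
#'
#' @param path manifest CSV path.
#' @return `read_manifest` returns a data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("video_id", "subject_id", "condition", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a full dataset from a manifest
#'
#' @param manifest_path manifest CSV path.
#' @param scheme `landmark_scheme` the tables must conform to.
#' @return a `landmark_dataset`.
#' @export
read_dataset <- function(manifest_path, scheme) {
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  tables <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_landmark_timeseries(p, scheme, video_id = man$video_id[i],
                             subject_id = man$subject_id[i],
                             condition = man$condition[i])
  })
  landmark_dataset(tables, man)
}

#' Write a dataset to a directory
#'
#' Writes one time-series CSV per video plus `manifest.csv`.
#'
#' @param dataset a `landmark_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$path <- paste0(man$video_id, ".csv")
  for (i in seq_along(dataset$tables))
    write_landmark_timeseries(dataset$tables[[i]],
                              file.path(dir, man$path[i]))
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Remove ear-pinna landmarks from a time series or dataset
#'
#' Ear pinnae vary strongly between breeds and move passively (inertia), so
#' the pinna landmarks are discarded before shape analysis, leaving only the
#' ear-base landmarks. Retained landmarks keep their relative order and
#' coordinates; the matching reduced scheme is obtained with
#' [reduce_scheme()].
#'
#' @param x a `landmark_ts` or `landmark_dataset`.
#' @param scheme the scheme describing `x`.
#' @return object of the same class with `length(ear_pinna_indices)` fewer
#'   landmarks per set.
#' @export
drop_ear_landmarks <- function(x, scheme) UseMethod("drop_ear_landmarks")

#' @export
drop_ear_landmarks.landmark_ts <- function(x, scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  if (n_landmarks_ts(x) != scheme$n_landmarks)
    stop("scheme error: series has ", n_landmarks_ts(x),
         " landmarks but scheme declares ", scheme$n_landmarks,
         call. = FALSE)
  drop <- scheme$ear_pinna_indices
  if (!length(drop)) return(x)
  keep <- setdiff(seq_len(scheme$n_landmarks), drop)
  landmark_ts(x$video_id, x$subject_id, x$condition, x$timestamp,
              x$confidence, x$coords[, keep, , drop = FALSE])
}

#' @export
drop_ear_landmarks.landmark_dataset <- function(x, scheme) {
  x$tables <- lapply(x$tables, drop_ear_landmarks, scheme = scheme)
  x
}
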