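#' Synthetic study configuration
#'
#' Parameters of the synthetic landmark-video generator. Defaults emulate
#' the target study design: 11 subjects filmed once per condition, videos of
#' about 4.4 minutes at 25 fps with 12-15 landmark sets sampled per second.
#' Shape units are fractions of centroid size of the canonical template;
#' pixel-space nuisance (scale, translation) is applied on top.
#'
#' @param n_subjects number of subjects (each filmed in both conditions).
#' @param fps video frame rate; must be at least `sampling_rate`.
#' @param sampling_rate landmark sets per second, in \[12, 15\].
#' @param duration_s video length in seconds.
#' @param delta_ear medial ear-base displacement magnitude under the
#'   fireworks condition, as a fraction of centroid size.
#' @param delta_mouth mouth-region displacement magnitude (dorsal upper
#'   muzzle / nose, ventral lower muzzle, lateral lip corners), same units.
#' @param sigma_subject SD of the smoothed per-subject deviation from the
#'   template, per coordinate.
#' @param sigma_frame SD of per-frame landmark jitter, per coordinate.
#' @param pose_sigma_tilt SD of the head roll angle, degrees.
#' @param pose_sigma_yaw SD of the yaw proxy (one-sided x-compression
#'   fraction).
#' @param scale_log_sd SD of log image scale.
#' @param translation_sd SD of image translation, pixels.
#' @param conf_base,conf_pose_slope,conf_noise_slope,conf_jitter_sd
#'   parameters of the linear-with-clipping detector-confidence model.
#' @param base_scale_px mean image scale (pixels per unit centroid size).
#' @param centre_px length-2 image-centre offset, pixels.
#' @param seed RNG seed used by [simulate_dataset()].
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 11L, fps = 25, sampling_rate = 13,
                             duration_s = 264, delta_ear = 0.03,
                             delta_mouth = 0.015, sigma_subject = 0.02,
                             sigma_frame = 0.005, pose_sigma_tilt = 8,
                             pose_sigma_yaw = 0.15, scale_log_sd = 0.08,
                             translation_sd = 20, conf_base = 0.85,
                             conf_pose_slope = 0.08, conf_noise_slope = 0.5,
                             conf_jitter_sd = 0.02, base_scale_px = 120,
                             centre_px = c(320, 240), seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), fps = fps,
              sampling_rate = sampling_rate, duration_s = duration_s,
              delta_ear = delta_ear, delta_mouth = delta_mouth,
              sigma_subject = sigma_subject, sigma_frame = sigma_frame,
              pose_sigma_tilt = pose_sigma_tilt,
              pose_sigma_yaw = pose_sigma_yaw,
              scale_log_sd = scale_log_sd, translation_sd = translation_sd,
              conf_base = conf_base, conf_pose_slope = conf_pose_slope,
              conf_noise_slope = conf_noise_slope,
              conf_jitter_sd = conf_jitter_sd,
              base_scale_px = base_scale_px, centre_px = centre_px,
              seed = as.integer(seed))
  mags <- c("duration_s", "delta_ear", "delta_mouth", "sigma_subject",
            "sigma_frame", "pose_sigma_tilt", "pose_sigma_yaw",
            "scale_log_sd", "translation_sd", "conf_jitter_sd")
  if (any(unlist(cfg[mags]) < 0))
    stop("config error: magnitudes must be >= 0", call. = FALSE)
  if (cfg$sampling_rate < 12 || cfg$sampling_rate > 15)
    stop("config error: sampling_rate must lie in [12, 15]", call. = FALSE)
  if (cfg$fps < cfg$sampling_rate)
    stop("config error: fps must be >= sampling_rate", call. = FALSE)
  if (cfg$duration_s <= 0 || cfg$sampling_rate <= 0)
    stop("config error: duration and sampling rate must be positive",
         call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Canonical frontal face template
#'
#' A fixed, bilaterally symmetric 36-landmark frontal configuration:
#' centroid at the origin, unit centroid size, inter-eye line horizontal,
#' midline along x = 0 (image convention: x rightward, y downward, so the
#' forehead has negative y). It stands in for a frontal dog face; only its
#' role geometry (eyes above nose, ear bases lateral-dorsal, mouth ventral)
#' matters to the statistics.
#'
#' @param scheme reduced (36-landmark) `landmark_scheme`.
#' @return a 36 x 2 matrix.
#' @export
make_template <- function(scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  if (scheme$n_landmarks != 36L)
    stop("scheme error: template requires the reduced 36-landmark scheme",
         call. = FALSE)
  left <- list(
    # eye ring (left), then inner corner 6; dog eyes are wide set, so the
    # inner corners sit well off the midline
    `1` = c(-0.80, -0.16), `2` = c(-0.68, -0.25), `3` = c(-0.56, -0.21),
    `4` = c(-0.68, -0.05), `5` = c(-0.56, -0.08), `6` = c(-0.52, -0.13),
    # temple, cheek, jaw, brow
    `13` = c(-0.85, -0.38), `15` = c(-0.85, 0.05), `17` = c(-0.58, 0.40),
    `19` = c(-0.42, -0.36),
    # nostril
    `23` = c(-0.07, 0.20),
    # muzzle: upper ridge 25, side 26, upper lip 27
    `25` = c(-0.13, 0.08), `26` = c(-0.24, 0.18), `27` = c(-0.12, 0.28),
    # lower lip 31, lip corner 33, ear base 35
    `31` = c(-0.08, 0.42), `33` = c(-0.28, 0.36), `35` = c(-0.75, -0.58)
  )
  mid <- list(`21` = c(0, -0.48), `22` = c(0, 0.18))
  X <- matrix(NA_real_, 36L, 2L)
  mp <- scheme$mirror_pairs
  for (nm in names(left)) {
    i <- as.integer(nm)
    X[i, ] <- left[[nm]]
    j <- mp[mp[, 1L] == i, 2L]
    X[j, ] <- c(-left[[nm]][1L], left[[nm]][2L])
  }
  for (nm in names(mid)) X[as.integer(nm), ] <- mid[[nm]]
  X <- sweep(X, 2L, colMeans(X))
  X / centroid_size(X)
}

#' Condition displacement field
#'
#' The ground-truth facial-shape change applied under the fireworks
#' condition: ear bases move medially (toward the midline) with magnitude
#' `delta_ear`; the nose centre and upper-muzzle landmarks move dorsally
#' (negative y), the lower-muzzle landmarks ventrally (positive y) and the
#' lip corners laterally (outward x), each with magnitude `delta_mouth`.
#' All other landmarks are unaffected.
#'
#' @param scheme reduced `landmark_scheme` (mirror-pair column 1 = left).
#' @param delta_ear,delta_mouth displacement magnitudes, fractions of
#'   centroid size, `>= 0`.
#' @return a 36 x 2 displacement matrix.
#' @export
condition_displacement <- function(scheme, delta_ear = 0.03,
                                   delta_mouth = 0.015) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  if (delta_ear < 0 || delta_mouth < 0)
    stop("displacement magnitudes must be >= 0", call. = FALSE)
  D <- matrix(0, scheme$n_landmarks, 2L)
  mp <- scheme$mirror_pairs
  side <- function(i) {
    if (i %in% mp[, 1L]) -1 else if (i %in% mp[, 2L]) 1 else 0
  }
  for (i in scheme$ear_base_indices)          # medial: toward x = 0
    D[i, 1L] <- -side(i) * delta_ear
  for (i in c(scheme_role(scheme, "nose_centre"),
              scheme_role(scheme, "upper_muzzle")))
    D[i, 2L] <- -delta_mouth                  # dorsal
  for (i in scheme_role(scheme, "lower_muzzle"))
    D[i, 2L] <- delta_mouth                   # ventral
  for (i in scheme_role(scheme, "lip_corners"))
    D[i, 1L] <- side(i) * delta_mouth         # lateral
  D
}

# One frame's pose + similarity nuisance, vectorized over frames.
# shapes: n x L x 2 array in face units; returns pixel coordinates.
apply_pose <- function(shapes, roll_deg, yaw, scale_px, tx, ty) {
  n <- dim(shapes)[1L]
  out <- shapes
  for (f in seq_len(n)) {
    S <- shapes[f, , ]
    # yaw proxy: compress x-offsets on the side of the midline sign(yaw)
    # points to, by factor (1 - |yaw|)
    if (yaw[f] != 0) {
      onside <- sign(S[, 1L]) == sign(yaw[f])
      S[onside, 1L] <- S[onside, 1L] * (1 - min(abs(yaw[f]), 0.9))
    }
    th <- roll_deg[f] * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    S <- S %*% t(R)
    out[f, , ] <- S * scale_px[f] + rep(c(tx[f], ty[f]), each = nrow(S))
  }
  out
}

#' Simulate one landmark video
#'
#' Generates `floor(duration_s * sampling_rate)` landmark sets at uniform
#' timestamps. Each frame is a similarity transform (random rotation =
#' head roll, log-normal scale, Gaussian translation) of the subject's face
#' shape, plus the condition displacement field under fireworks, per-frame
#' Gaussian landmark jitter, and a one-sided x-compression standing in for
#' head yaw. Detector confidence decreases linearly in normalized pose
#' magnitude and jitter norm, with a small Gaussian disturbance, clipped to
#' \[0, 1\]. Draws from the current RNG stream; seed externally (or use
#' [simulate_dataset()], which seeds from its config).
#'
#' @param subject_shape 36 x 2 base face shape (template units).
#' @param condition `"control"` or `"fireworks"`.
#' @param cfg a `synthetic_config`.
#' @param scheme reduced `landmark_scheme`.
#' @param video_id,subject_id identifiers for the returned series.
#' @return list with the `landmark_ts` (`$table`) and per-frame nuisance
#'   parameters (`$pose`: roll, yaw, scale, tx, ty).
#' @export
simulate_video <- function(subject_shape, condition, cfg, scheme,
                           video_id = "video", subject_id = "subject") {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- floor(cfg$duration_s * cfg$sampling_rate)
  if (n < 1L) stop("config error: no frames to simulate", call. = FALSE)
  timestamp <- (seq_len(n) - 1L) / cfg$sampling_rate
  L <- nrow(subject_shape)
  D <- condition_displacement(scheme, cfg$delta_ear, cfg$delta_mouth)
  base <- subject_shape + if (condition == "fireworks") D else 0
  noise <- array(stats::rnorm(n * L * 2L, sd = cfg$sigma_frame),
                 dim = c(n, L, 2L))
  shapes <- noise + rep(1, n) %o% base
  roll <- stats::rnorm(n, sd = cfg$pose_sigma_tilt)
  yaw <- stats::rnorm(n, sd = cfg$pose_sigma_yaw)
  scale_px <- cfg$base_scale_px * exp(stats::rnorm(n, sd = cfg$scale_log_sd))
  tx <- cfg$centre_px[1L] + stats::rnorm(n, sd = cfg$translation_sd)
  ty <- cfg$centre_px[2L] + stats::rnorm(n, sd = cfg$translation_sd)
  px <- apply_pose(shapes, roll, yaw, scale_px, tx, ty)
  noise_norm <- sqrt(apply(noise^2, 1L, sum))
  pose_pen <- (if (cfg$pose_sigma_tilt > 0)
                 abs(roll) / cfg$pose_sigma_tilt else numeric(n)) +
              (if (cfg$pose_sigma_yaw > 0)
                 abs(yaw) / cfg$pose_sigma_yaw else numeric(n))
  conf <- cfg$conf_base - cfg$conf_pose_slope * pose_pen -
    cfg$conf_noise_slope * noise_norm +
    stats::rnorm(n, sd = cfg$conf_jitter_sd)
  conf <- pmin(pmax(conf, 0), 1)
  list(table = landmark_ts(video_id, subject_id, condition,
                           timestamp, conf, px),
       pose = data.frame(roll = roll, yaw = yaw, scale = scale_px,
                         tx = tx, ty = ty))
}

#' Simulate a full two-condition study
#'
#' Draws `n_subjects` subject face shapes (template plus a spatially
#' smoothed Gaussian deviation field) and simulates one control and one
#' fireworks video per subject. Fully reproducible: the RNG is seeded from
#' `cfg$seed`, so identical configs give identical datasets.
#'
#' @param cfg a `synthetic_config`.
#' @param scheme reduced 36-landmark scheme; defaults to
#'   `reduce_scheme(default_scheme())`.
#' @return list with `dataset` (a `landmark_dataset`) and `ground_truth`
#'   (template, subject shapes, displacement field, per-video pose tables).
#' @export
simulate_dataset <- function(cfg = synthetic_config(),
                             scheme = reduce_scheme(default_scheme())) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_subjects < 1L)
    stop("config error: n_subjects must be >= 1", call. = FALSE)
  set.seed(cfg$seed)
  template <- make_template(scheme)
  nbrs <- template_neighbours(template)
  subjects <- sprintf("s%02d", seq_len(cfg$n_subjects))
  subject_shapes <- lapply(subjects, function(s)
    template + smooth_deviation(template, cfg$sigma_subject, nbrs))
  names(subject_shapes) <- subjects
  tables <- list()
  pose <- list()
  man <- NULL
  for (i in seq_along(subjects)) {
    for (cond in c("control", "fireworks")) {
      vid <- paste0(subjects[i], "_", cond)
      sim <- simulate_video(subject_shapes[[i]], cond, cfg, scheme,
                            video_id = vid, subject_id = subjects[i])
      tables[[vid]] <- sim$table
      pose[[vid]] <- sim$pose
      man <- rbind(man, data.frame(video_id = vid,
                                   subject_id = subjects[i],
                                   condition = cond, path = NA_character_))
    }
  }
  list(
    dataset = landmark_dataset(unname(tables), man),
    ground_truth = list(template = template,
                        subject_shapes = subject_shapes,
                        displacement = condition_displacement(
                          scheme, cfg$delta_ear, cfg$delta_mouth),
                        pose = pose)
  )
}

# Indices of each landmark's two nearest template neighbours.
template_neighbours <- function(template) {
  d <- as.matrix(stats::dist(template))
  diag(d) <- Inf
  t(apply(d, 1L, function(r) order(r)[1:2]))
}

# i.i.d. Gaussian per-landmark deviations, averaged with the two nearest
# template neighbours for crude spatial coherence.
smooth_deviation <- function(template, sigma, nbrs) {
  L <- nrow(template)
  dev <- matrix(stats::rnorm(L * 2L, sd = sigma), L, 2L)
  (dev + dev[nbrs[, 1L], ] + dev[nbrs[, 2L], ]) / 3
}

#' Serialize ground truth to JSON
#'
#' @param ground_truth the `ground_truth` element of [simulate_dataset()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- list(
    template = ground_truth$template,
    subject_shapes = ground_truth$subject_shapes,
    displacement = ground_truth$displacement,
    pose = ground_truth$pose
  )
  jsonlite::write_json(gt, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
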