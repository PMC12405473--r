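test_that("head tilt is the acute inter-eye angle in degrees", {
  red <- test_reduced()
  shape <- make_template(red)
  place_eyes <- function(e1, e2) {
    s <- shape
    s[6, ] <- e1; s[7, ] <- e2
    s
  }
  expect_equal(head_tilt_deg(place_eyes(c(0, 0), c(1, 0)), red), 0)
  expect_equal(head_tilt_deg(place_eyes(c(0, 0), c(1, 1)), red), 45)
  expect_equal(head_tilt_deg(place_eyes(c(0, 0), c(0, 2)), red), 90)
  # folding: swapping the eyes or negating y gives the same acute angle
  expect_equal(head_tilt_deg(place_eyes(c(1, 1), c(0, 0)), red), 45)
  expect_equal(head_tilt_deg(place_eyes(c(0, 0), c(1, -1)), red), 45)
  expect_error(head_tilt_deg(place_eyes(c(1, 1), c(1, 1)), red),
               "degenerate")
})

test_that("rotation asymmetry is the |eye-nose| distance difference", {
  red <- test_reduced()
  shape <- make_template(red)
  shape[6, ] <- c(0, 0); shape[7, ] <- c(2, 0); shape[22, ] <- c(1, 1)
  expect_equal(head_rotation_asym(shape, red), 0)
  shape[22, ] <- c(0, 1)
  expect_equal(head_rotation_asym(shape, red), sqrt(5) - 1)
  # isometry invariance: rigid motion leaves both pose metrics unchanged
  set.seed(3)
  rot <- similarity_transform(shape, scale = 1)
  expect_equal(head_rotation_asym(rot, red),
               head_rotation_asym(shape, red), tolerance = 1e-9)
  shifted <- shape + 17.3
  expect_equal(head_tilt_deg(shifted, red), head_tilt_deg(shape, red))
  expect_equal(head_rotation_asym(shifted, red),
               head_rotation_asym(shape, red))
})

test_that("the confidence filter keeps the inclusive boundary", {
  cfgf <- filter_config()
  ts <- toy_ts(c(0.5, 0.6, 0.7))
  kept <- filter_by_confidence(ts, cfgf)
  expect_equal(kept$confidence, c(0.6, 0.7))
  expect_equal(length(filter_by_confidence(toy_ts(numeric(0)),
                                           cfgf)$confidence), 0L)
  all_kept <- filter_by_confidence(ts, filter_config(conf_threshold = 0))
  expect_equal(all_kept$confidence, ts$confidence)
})

test_that("pose-outlier removal uses the interpolated 95th percentile", {
  red <- test_reduced()
  base <- make_template(red)
  # 100 sets whose rotation asymmetry runs 1..100 with constant (zero)
  # tilt: eyes pinned horizontal, nose slid between them
  n <- 100L
  coords <- array(0, dim = c(n, 36, 2))
  for (i in seq_len(n)) {
    s <- base
    s[6, ] <- c(0, 0); s[7, ] <- c(200, 0)
    s[22, ] <- c(100 + i / 2, 0)
    coords[i, , ] <- s
  }
  ts <- landmark_ts("v", "s", "control", seq_len(n) - 1, rep(0.9, n),
                    coords)
  pm <- facegmm:::ts_pose_metrics(ts, red)
  expect_equal(pm$rot, as.numeric(1:100), tolerance = 1e-9)
  expect_equal(pm$tilt, rep(0, n))
  out <- remove_pose_outliers(ts, filter_config(), red)
  # interpolated P95 of 1..100 is 95.05, so values 96..100 are removed;
  # the constant tilt sample removes nothing (no value exceeds its own
  # percentile)
  expect_equal(length(out$timestamp), 95L)
  expect_equal(max(facegmm:::ts_pose_metrics(out, red)$rot), 95,
               tolerance = 1e-9)
})

test_that("outlier removal obeys the either-metric union rule", {
  red <- test_reduced()
  ts <- toy_ts(rep(0.9, 5))
  # constant pose: nothing exceeds the percentile of a constant sample
  expect_equal(length(remove_pose_outliers(ts, filter_config(),
                                           red)$timestamp), 5L)
  # explicit thresholds: a set over only the rotation threshold goes
  shape_turned <- make_template(red)
  shape_turned[22, 1] <- shape_turned[22, 1] + 0.3  # breaks symmetry
  ts2 <- toy_ts(rep(0.9, 3))
  ts2$coords[2, , ] <- shape_turned
  out <- remove_pose_outliers(ts2, filter_config(), red,
                              thresholds = c(Inf, 0.1))
  expect_equal(out$timestamp, c(0, 2))
})

test_that("interval thinning is greedy earliest-first", {
  ts <- toy_ts(rep(0.9, 5), timestamp = c(0.0, 0.5, 1.0, 1.4, 2.2))
  out <- enforce_min_interval(ts, filter_config(min_interval_s = 1.0))
  expect_equal(out$timestamp, c(0.0, 1.0, 2.2))
  expect_equal(enforce_min_interval(toy_ts(0.9), filter_config())$timestamp,
               0)
  expect_equal(enforce_min_interval(ts, filter_config(min_interval_s = 0)
                                    )$timestamp, ts$timestamp)
})

test_that("subject inclusion requires the minimum in both conditions", {
  mk <- function(subject, condition, n)
    toy_ts(rep(0.9, n), subject = subject, condition = condition)
  tabs <- list(mk("a", "control", 10), mk("a", "fireworks", 10),
               mk("b", "control", 9), mk("b", "fireworks", 50))
  man <- data.frame(
    video_id = vapply(tabs, function(t) t$video_id, character(1)),
    subject_id = c("a", "a", "b", "b"),
    condition = c("control", "fireworks", "control", "fireworks"),
    path = NA_character_)
  sel <- select_subjects(landmark_dataset(tabs, man), filter_config())
  expect_setequal(unique(sel$dataset$manifest$subject_id), "a")
  expect_equal(sel$excluded$subject_id, "b")
  expect_equal(sel$excluded$control, 9L)
})

test_that("top-k selection ranks by confidence with timestamp tie-breaks", {
  set.seed(8)
  conf <- round(runif(15), 3)
  ts <- toy_ts(conf)
  out <- select_top_k(ts, filter_config(top_k = 10))
  expect_equal(sort(out$confidence, decreasing = TRUE),
               sort(conf, decreasing = TRUE)[1:10])
  expect_false(is.unsorted(out$timestamp))

  # tie at the k-th rank: earlier timestamp wins
  conf2 <- c(0.9, 0.8, 0.8, 0.7)
  out2 <- select_top_k(toy_ts(conf2), filter_config(top_k = 2))
  expect_equal(out2$timestamp, c(0, 1))

  # fewer available than k: all kept
  out3 <- select_top_k(toy_ts(conf2), filter_config(top_k = 10))
  expect_equal(length(out3$timestamp), 4L)
})

test_that("the cascade is a shrinking filter with a faithful report", {
  sim <- simulate_dataset(fast_config(seed = 21, duration_s = 25))
  res <- run_filter_cascade(sim$dataset, filter_config(), test_scheme(),
                            drop_ears = FALSE)
  counts <- res$report$counts$n_sets
  expect_true(all(diff(counts) <= 0))
  expect_equal(res$report$counts$stage[1], "input")
  st <- stack_dataset(res$dataset)
  # retained sets are a subset of the simulated ones (match on timestamp
  # within each video)
  for (t in res$dataset$tables) {
    orig <- sim$dataset$tables[[
      which(sim$dataset$manifest$video_id == t$video_id)]]
    expect_true(all(t$timestamp %in% orig$timestamp))
  }
  # maximal confidence threshold empties the cascade
  res0 <- run_filter_cascade(sim$dataset, filter_config(conf_threshold = 1),
                             test_scheme(), drop_ears = FALSE)
  expect_equal(res0$report$counts$n_sets[res0$report$counts$stage ==
                                           "confidence"], 0L)
})

test_that("filter reports serialize to JSON", {
  sim <- simulate_dataset(fast_config(seed = 2, duration_s = 12))
  res <- run_filter_cascade(sim$dataset, filter_config(), test_scheme(),
                            drop_ears = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_report(res$report, path)
  j <- jsonlite::read_json(path)
  expect_equal(length(j$counts), nrow(res$report$counts))
})
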