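#' Run configuration
#'
#' Assembles a full pipeline run: where the data comes from (a manifest of
#' landmark CSVs, or the synthetic generator), the filter cascade
#' parameters, superimposition tolerances, the analysis knobs and the
#' output directory. Unknown keys are rejected.
#'
#' @param manifest path to a study manifest CSV, or `NULL` to simulate.
#' @param scheme a `landmark_scheme` or path to a scheme file; default the
#'   packaged 46-point scheme.
#' @param synthetic a `synthetic_config` (used when `manifest` is `NULL`).
#' @param filter a `filter_config`.
#' @param gpa_tol,gpa_max_iter superimposition convergence controls.
#' @param variance_target cumulative-variance fraction selecting tested
#'   PCs.
#' @param alpha significance level.
#' @param n_pose_pcs number of leading PCs treated as head pose in the
#'   residualization step.
#' @param out_dir output directory.
#' @param seed global seed; overrides `synthetic$seed`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(manifest = NULL, scheme = NULL,
                       synthetic = synthetic_config(),
                       filter = filter_config(), gpa_tol = 1e-8,
                       gpa_max_iter = 100L, variance_target = 0.90,
                       alpha = 0.05, n_pose_pcs = 3L,
                       out_dir = "facegmm_run", seed = NULL) {
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  if (is.null(scheme)) scheme <- default_scheme()
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  structure(list(manifest = manifest, scheme = scheme,
                 synthetic = synthetic, filter = filter,
                 gpa_tol = gpa_tol, gpa_max_iter = gpa_max_iter,
                 variance_target = variance_target, alpha = alpha,
                 n_pose_pcs = as.integer(n_pose_pcs), out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys: `manifest`, `scheme` (path), `synthetic`, `filter`,
#' `gpa_tol`, `gpa_max_iter`, `variance_target`, `alpha`, `n_pose_pcs`,
#' `out_dir`, `seed`; `synthetic` and `filter` take the corresponding
#' constructor arguments. Unknown keys anywhere raise an error.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("manifest", "scheme", "synthetic", "filter", "gpa_tol",
             "gpa_max_iter", "variance_target", "alpha", "n_pose_pcs",
             "out_dir", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  check_args <- function(lst, fn, what) {
    bad <- setdiff(names(lst), names(formals(fn)))
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    lst
  }
  args <- y[setdiff(names(y), c("synthetic", "filter"))]
  args$synthetic <- do.call(synthetic_config,
                            check_args(y$synthetic %||% list(),
                                       synthetic_config, "synthetic"))
  args$filter <- do.call(filter_config,
                         check_args(y$filter %||% list(),
                                    filter_config, "filter"))
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences data acquisition (manifest or synthetic generation), the
#' frame-selection cascade, generalised Procrustes superimposition, shape
#' PCA, per-PC condition ANOVA under FDR control, the subject-level paired
#' effect and power computation (on the PC with the smallest adjusted p),
#' head-pose residualization, two-group CVA with Wilks' Lambda, the mean
#' shape difference, and figure/report serialization. Every numeric output
#' is reproducible for a fixed config (including seed).
#'
#' @param config a `run_config` or path to a YAML config.
#' @return the summary list, invisibly; side effect: files under
#'   `config$out_dir` (`summary.json`, `filter_report.json`,
#'   `condition_tests.csv`, `pc_scores.csv`, `effect.json`, `cva.json`,
#'   `mean_shape_difference.csv`, figures).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- config$scheme

  if (is.null(config$manifest)) {
    sim <- stage("simulate", simulate_dataset(config$synthetic,
                                              reduce_scheme(scheme)))
    dataset <- sim$dataset
    drop_ears <- FALSE   # generator emits the reduced scheme
  } else {
    dataset <- stage("load", read_dataset(config$manifest, scheme))
    drop_ears <- TRUE
  }

  filt <- stage("filter",
                run_filter_cascade(dataset, config$filter, scheme,
                                   drop_ears = drop_ears))
  write_filter_report(filt$report,
                      file.path(config$out_dir, "filter_report.json"))
  stacked <- stage("filter", stack_dataset(filt$dataset))
  if (length(unique(stacked$condition)) < 2L)
    stop("[stage filter] fewer than two conditions survive filtering",
         call. = FALSE)

  ali <- stage("align", gpa(stacked$coords, tol = config$gpa_tol,
                            max_iter = config$gpa_max_iter))
  pcm <- stage("analyse", pca_fit(ali, config$variance_target))
  tests <- stage("analyse", anova_per_pc(pcm, stacked$condition))
  utils::write.csv(as.data.frame(tests),
                   file.path(config$out_dir, "condition_tests.csv"),
                   row.names = FALSE)
  scores_df <- data.frame(subject = stacked$subject,
                          condition = stacked$condition,
                          video = stacked$video,
                          timestamp = stacked$timestamp,
                          pcm$scores[, pcm$tested_pcs, drop = FALSE])
  utils::write.csv(scores_df, file.path(config$out_dir, "pc_scores.csv"),
                   row.names = FALSE)

  best_pc <- tests$pc[which.min(tests$p_adj)]
  effect <- stage("analyse",
                  subject_level_effect(pcm, stacked$condition,
                                       stacked$subject, best_pc,
                                       config$alpha))
  jsonlite::write_json(list(pc = best_pc, paired_d = effect$paired_d,
                            power = effect$power,
                            n_subjects = effect$n_subjects),
                       file.path(config$out_dir, "effect.json"),
                       digits = NA, auto_unbox = TRUE)

  flat <- flatten_aligned(ali)
  pose_pcs <- seq_len(min(config$n_pose_pcs, ncol(pcm$scores)))
  resid <- stage("analyse",
                 pooled_within_group_regression(
                   flat, pcm$scores[, pose_pcs, drop = FALSE],
                   stacked$condition))
  resid_field <- fold_shape(
    colMeans(resid$residual_shapes[stacked$condition == "fireworks", ,
                                   drop = FALSE]) -
    colMeans(resid$residual_shapes[stacked$condition == "control", ,
                                   drop = FALSE]))
  write_displacement_field(resid_field,
                           file.path(config$out_dir,
                                     "residual_shape_difference.csv"))

  cva <- stage("analyse",
               cva_two_group(pcm$scores[, pcm$tested_pcs, drop = FALSE],
                             stacked$condition, loadings = pcm$loadings))
  jsonlite::write_json(list(wilks_lambda = cva$wilks_lambda,
                            F_approx = cva$F_approx, df1 = cva$df1,
                            df2 = cva$df2, p = cva$p),
                       file.path(config$out_dir, "cva.json"),
                       digits = NA, auto_unbox = TRUE)

  msd <- stage("analyse", mean_shape_difference(ali, stacked$condition))
  write_displacement_field(msd$field,
                           file.path(config$out_dir,
                                     "mean_shape_difference.csv"))

  stage("report", {
    render_mean_shape_comparison(msd, file.path(config$out_dir,
                                                "mean_shapes.png"))
    render_pc_deformation(pcm, best_pc,
                          file.path(config$out_dir,
                                    sprintf("pc%d_deformation.png",
                                            best_pc)))
    render_cva_scatter(cva, stacked$condition,
                       file.path(config$out_dir, "cva_scatter.png"))
  })

  red_scheme <- if (scheme$n_landmarks == 36L) scheme
                else reduce_scheme(scheme)
  ear_idx <- red_scheme$ear_base_indices
  summary <- list(
    n_sets_retained = nrow(pcm$scores),
    n_subjects = length(unique(stacked$subject)),
    filter_counts = stats::setNames(as.list(filt$report$counts$n_sets),
                                    filt$report$counts$stage),
    confidence_retention = filt$report$confidence_retention,
    tested_pcs = pcm$tested_pcs,
    explained_variance_ratio =
      pcm$explained_variance_ratio[pcm$tested_pcs],
    significant_pcs = tests$pc[tests$p_adj < config$alpha],
    best_pc = best_pc,
    best_pc_F = tests$F[tests$pc == best_pc],
    best_pc_p_adj = tests$p_adj[tests$pc == best_pc],
    paired_d = effect$paired_d,
    power = effect$power,
    wilks_lambda = cva$wilks_lambda,
    cva_F = cva$F_approx,
    max_displacement_landmark = which.max(msd$norms),
    max_displacement_is_ear_base =
      which.max(msd$norms) %in% ear_idx,
    gpa_converged = ali$converged
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(summary)
}
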