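#' Principal component analysis of Procrustes coordinates
#'
#' Centers the flattened aligned coordinates and eigendecomposes their
#' covariance. `tested_pcs` is the smallest prefix of components whose
#' cumulative explained-variance ratio reaches `variance_target`; these are
#' the components carried into the condition tests and the CVA.
#'
#' @param aligned an `aligned_dataset` from [gpa()], or an `n x 2L` matrix
#'   of flattened shapes.
#' @param variance_target cumulative-variance fraction for selecting the
#'   tested components.
#' @return an object of class `pc_model`: `mean_vector`, `loadings`
#'   (k x 2L, orthonormal rows), `scores` (n x k), `sdev`,
#'   `explained_variance_ratio`, `tested_pcs`.
#' @export
pca_fit <- function(aligned, variance_target = 0.90) {
  X <- if (inherits(aligned, "aligned_dataset")) flatten_aligned(aligned)
       else as.matrix(aligned)
  if (nrow(X) < 3L)
    stop("insufficient data: PCA needs at least 3 shapes", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- length(pc$sdev)
  tested <- seq_len(which(cumsum(evr) >= variance_target - 1e-12)[1L])
  structure(list(mean_vector = pc$center,
                 loadings = t(pc$rotation),   # k x 2L
                 scores = pc$x,
                 sdev = pc$sdev,
                 explained_variance_ratio = evr,
                 tested_pcs = tested,
                 variance_target = variance_target),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("Shape PCA:", ncol(x$scores), "components over",
      nrow(x$scores), "shapes\n")
  cat(sprintf("  tested PCs: 1-%d (%.1f%% cumulative variance)\n",
              max(x$tested_pcs),
              100 * sum(x$explained_variance_ratio[x$tested_pcs])))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, stable under
#' input permutation (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Per-component condition tests
#'
#' One-way two-group ANOVA of each tested principal component's scores
#' against condition, with a Shapiro-Wilk normality check on each
#' component's residuals and Benjamini-Hochberg adjustment across the
#' tested components.
#'
#' @param scores n x k PC score matrix (or `pc_model`).
#' @param condition length-n condition labels (two levels).
#' @param tested_pcs components to test; defaults to the model's
#'   cumulative-variance prefix when `scores` is a `pc_model`.
#' @return an object of class `condition_tests`: data frame with columns
#'   `pc`, `F`, `p`, `p_adj`, `shapiro_W`, `shapiro_p`.
#' @export
anova_per_pc <- function(scores, condition, tested_pcs = NULL) {
  if (inherits(scores, "pc_model")) {
    if (is.null(tested_pcs)) tested_pcs <- scores$tested_pcs
    scores <- scores$scores
  }
  if (is.null(tested_pcs)) tested_pcs <- seq_len(ncol(scores))
  condition <- factor(condition)
  if (nlevels(condition) != 2L)
    stop("exactly two condition labels required", call. = FALSE)
  if (any(table(condition) < 2L))
    stop("each condition needs at least 2 landmark sets", call. = FALSE)
  res <- lapply(tested_pcs, function(j) {
    s <- scores[, j]
    fit <- stats::aov(s ~ condition)
    tab <- summary(fit)[[1L]]
    r <- stats::residuals(fit)
    sw <- tryCatch(stats::shapiro.test(r),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    data.frame(pc = j, F = tab$`F value`[1L], p = tab$`Pr(>F)`[1L],
               shapiro_W = unname(sw$statistic),
               shapiro_p = unname(sw$p.value))
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_fdr(out$p)
  out <- out[, c("pc", "F", "p", "p_adj", "shapiro_W", "shapiro_p")]
  structure(out, class = c("condition_tests", "data.frame"))
}

#' Power of a two-sided paired t-test
#'
#' Computed from the noncentral t distribution with noncentrality
#' `|d| * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param d paired Cohen's d (mean of paired differences over their
#'   sample SD).
#' @param n number of pairs.
#' @param alpha two-sided significance level.
#' @return power in \[alpha, 1\] (equals `alpha` at `d = 0`).
#' @export
paired_t_power <- function(d, n, alpha = 0.05) {
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  df <- n - 1
  ncp <- abs(d) * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

#' Subject-level paired effect size and post-hoc power
#'
#' Averages the scores of one principal component per subject per
#' condition (restoring statistical independence across frames), forms the
#' paired fireworks-minus-control differences, and reports paired Cohen's
#' d (mean over sample SD of the differences) and the post-hoc power of a
#' two-sided paired t-test at `alpha`.
#'
#' @param scores n x k PC score matrix (or `pc_model`).
#' @param condition,subject length-n labels.
#' @param pc_index which component to analyse.
#' @param alpha significance level for the power computation.
#' @return an object of class `effect_report`: `subject_means` (data
#'   frame), `paired_d`, `power`, `n_subjects`.
#' @export
subject_level_effect <- function(scores, condition, subject, pc_index,
                                 alpha = 0.05) {
  if (inherits(scores, "pc_model")) scores <- scores$scores
  s <- scores[, pc_index]
  condition <- as.character(condition)
  subj <- unique(subject)
  if (length(subj) < 2L) stop("need at least 2 subjects", call. = FALSE)
  means <- do.call(rbind, lapply(subj, function(id) {
    ctrl <- s[subject == id & condition == "control"]
    fire <- s[subject == id & condition == "fireworks"]
    if (!length(ctrl) || !length(fire))
      stop("subject ", id, " lacks sets in one condition", call. = FALSE)
    data.frame(subject_id = id, control = mean(ctrl),
               fireworks = mean(fire))
  }))
  diffs <- means$fireworks - means$control
  sdd <- stats::sd(diffs)
  if (sdd == 0)
    stop("paired differences have zero variance; d undefined",
         call. = FALSE)
  d <- mean(diffs) / sdd
  structure(list(subject_means = means, paired_d = d,
                 power = paired_t_power(d, length(subj), alpha),
                 n_subjects = length(subj), alpha = alpha),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf(
    "Subject-level paired effect: d = %.3f over %d subjects, power = %.1f%%\n",
    x$paired_d, x$n_subjects, 100 * x$power))
  invisible(x)
}

#' Pooled within-group regression of shape on head-pose components
#'
#' The first few principal components of facial shape predominantly encode
#' residual head pose (turning, nodding). This residualizes the shapes
#' against those components: predictors and responses are centered by
#' their condition means, a common slope matrix is fit by least squares on
#' the pooled centered data, and the condition means are added back to the
#' residuals, so between-condition differences survive while within-group
#' pose covariation is removed.
#'
#' @param shapes_flat n x 2L flattened aligned coordinates.
#' @param predictors n x q score matrix (typically the first three PCs).
#' @param condition length-n group labels.
#' @return list with `coefficients` (q x 2L) and `residual_shapes`
#'   (n x 2L).
#' @export
pooled_within_group_regression <- function(shapes_flat, predictors,
                                           condition) {
  Y <- as.matrix(shapes_flat)
  X <- as.matrix(predictors)
  g <- factor(condition)
  if (any(table(g) <= ncol(X) + 1L))
    stop("each group needs more sets than predictors", call. = FALSE)
  gm_X <- apply(X, 2L, function(v) tapply(v, g, mean))
  gm_Y <- apply(Y, 2L, function(v) tapply(v, g, mean))
  Xc <- X - gm_X[g, , drop = FALSE]
  Yc <- Y - gm_Y[g, , drop = FALSE]
  XtX <- crossprod(Xc)
  if (rcond_sym(XtX) < 1e-12)
    stop("rank-deficient predictors: within-group design is singular",
         call. = FALSE)
  B <- solve(XtX, crossprod(Xc, Yc))
  resid <- Yc - Xc %*% B
  list(coefficients = B,
       residual_shapes = resid + gm_Y[g, , drop = FALSE])
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else min(ev) / max(ev)
}

#' Two-group canonical variates analysis with Wilks' Lambda
#'
#' Fisher's discriminant over `q` variables for two groups: CV1 is the
#' direction maximizing between- over within-group variance, Wilks'
#' Lambda is `det(W) / det(W + B)` over the q variables, and for two
#' groups the exact F transform is
#' `F = ((1 - Lambda) / Lambda) * (n - q - 1) / q` with `df1 = q`,
#' `df2 = n - q - 1`. Run on the tested-PC scores by default (a
#' nonsingular within-group covariance is then guaranteed for n > q + 1).
#'
#' @param X n x q data matrix (e.g. tested-PC scores).
#' @param condition length-n labels, two levels, each with >= 2 members.
#' @param loadings optional k x 2L PC loading matrix (rows >= q); when
#'   supplied, the unit CV1 step is mapped back to an L x 2 landmark
#'   displacement field.
#' @return an object of class `cva_result`: `cv1_scores` (centered at the
#'   grand mean), `cv1_direction` (unit q-vector), `wilks_lambda`,
#'   `F_approx`, `df1`, `df2`, `p`, `group_means`, `cv1_deformation`.
#' @export
cva_two_group <- function(X, condition, loadings = NULL) {
  X <- as.matrix(X)
  g <- factor(condition)
  if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
  n <- nrow(X)
  q <- ncol(X)
  cnt <- table(g)
  if (any(cnt < 2L)) stop("each group needs >= 2 members", call. = FALSE)
  if (q >= n - 1L)
    stop("q must be < n - 1; reduce dimension (run on PC scores)",
         call. = FALSE)
  m <- colMeans(X)
  m1 <- colMeans(X[g == levels(g)[1L], , drop = FALSE])
  m2 <- colMeans(X[g == levels(g)[2L], , drop = FALSE])
  W <- matrix(0, q, q)
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2L, colMeans(Xi)))
  }
  B <- cnt[1L] * tcrossprod(m1 - m) + cnt[2L] * tcrossprod(m2 - m)
  if (rcond_sym(W) < 1e-12)
    stop("singular within-group covariance: reduce the dimension ",
         "(e.g. run on the tested PC scores)", call. = FALSE)
  a <- solve(W, m2 - m1)
  a <- a / sqrt(sum(a^2))
  lambda <- det(W) / det(W + B)
  F_approx <- ((1 - lambda) / lambda) * (n - q - 1) / q
  p <- stats::pf(F_approx, q, n - q - 1, lower.tail = FALSE)
  deformation <- NULL
  if (!is.null(loadings)) {
    deformation <- fold_shape(as.vector(
      t(loadings[seq_len(q), , drop = FALSE]) %*% a))
  }
  structure(list(cv1_scores = as.vector((X - rep(1, n) %o% m) %*% a),
                 cv1_direction = a,
                 wilks_lambda = as.numeric(lambda),
                 F_approx = as.numeric(F_approx),
                 df1 = q, df2 = n - q - 1L, p = as.numeric(p),
                 group_means = rbind(m1, m2),
                 group_labels = levels(g),
                 cv1_deformation = deformation),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf(
    "Two-group CVA: Wilks' Lambda = %.4g, F(%d, %d) = %.3f, p = %.3g\n",
    x$wilks_lambda, x$df1, x$df2, x$F_approx, x$p))
  invisible(x)
}

#' Mean-shape difference between conditions
#'
#' Per-landmark difference of the fireworks and control mean
#' configurations of aligned shapes, with per-landmark displacement norms.
#'
#' @param aligned an `aligned_dataset` or `n x L x 2` array.
#' @param condition length-n labels containing both `"control"` and
#'   `"fireworks"`.
#' @return list with `field` (L x 2, fireworks minus control), `norms`
#'   (length L), `control_mean` and `fireworks_mean` (L x 2).
#' @export
mean_shape_difference <- function(aligned, condition) {
  arr <- if (inherits(aligned, "aligned_dataset")) aligned$aligned
         else aligned
  if (!all(c("control", "fireworks") %in% condition))
    stop("both conditions must be present", call. = FALSE)
  cm <- apply(arr[condition == "control", , , drop = FALSE],
              c(2L, 3L), mean)
  fm <- apply(arr[condition == "fireworks", , , drop = FALSE],
              c(2L, 3L), mean)
  field <- fm - cm
  list(field = field, norms = sqrt(rowSums(field^2)),
       control_mean = cm, fireworks_mean = fm)
}

#' Shape deformation along one principal component
#'
#' The mean shape displaced by plus and minus `magnitude_sd` standard
#' deviations along one component, refolded to landmark coordinates; the
#' standard visualisation of what a component encodes.
#'
#' @param pc_model a `pc_model`.
#' @param pc_index component number.
#' @param magnitude_sd displacement in units of that component's SD.
#' @return list with `shape_plus` and `shape_minus` (L x 2 matrices).
#' @export
pc_deformation <- function(pc_model, pc_index, magnitude_sd = 1) {
  if (pc_index < 1L || pc_index > nrow(pc_model$loadings))
    stop("invalid component index", call. = FALSE)
  v <- magnitude_sd * pc_model$sdev[pc_index] *
    pc_model$loadings[pc_index, ]
  list(shape_plus = fold_shape(pc_model$mean_vector + v),
       shape_minus = fold_shape(pc_model$mean_vector - v))
}
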