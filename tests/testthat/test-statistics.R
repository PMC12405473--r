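test_that("shape PCA satisfies its algebraic contracts", {
  set.seed(1)
  n <- 30; L <- 8
  X <- matrix(rnorm(n * 2 * L), n)
  pcm <- pca_fit(X)
  # loadings orthonormal
  expect_equal(tcrossprod(pcm$loadings), diag(nrow(pcm$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # ratios sum to 1 at full rank and are nonincreasing
  expect_equal(sum(pcm$explained_variance_ratio), 1, tolerance = 1e-12)
  expect_true(all(diff(pcm$explained_variance_ratio) <= 1e-12))
  # full-rank reconstruction
  rec <- pcm$scores %*% pcm$loadings +
    rep(1, n) %o% pcm$mean_vector
  expect_equal(rec, X, tolerance = 1e-9, ignore_attr = TRUE)
  # tested prefix reaches the variance target
  expect_gte(sum(pcm$explained_variance_ratio[pcm$tested_pcs]), 0.90)
  expect_lt(sum(pcm$explained_variance_ratio[
    utils::head(pcm$tested_pcs, -1)]), 0.90)

  # rank-1 data loads entirely on PC1
  v <- rnorm(2 * L)
  X1 <- outer(rnorm(n), v)
  pcm1 <- pca_fit(X1)
  expect_equal(pcm1$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_error(pca_fit(X[1:2, ]), "insufficient")
})

test_that("per-PC ANOVA reproduces hand-computed F and the F = t^2 identity", {
  scores <- cbind(c(1, 2, 3, 4, 5, 6))
  cond <- c("control", "control", "control",
            "fireworks", "fireworks", "fireworks")
  res <- anova_per_pc(scores, cond, tested_pcs = 1L)
  # SSB = 13.5, MSW = 1 for groups {1,2,3} vs {4,5,6}
  expect_equal(res$F, 13.5, tolerance = 1e-12)

  # identical groups: F = 0, p = 1
  res0 <- anova_per_pc(cbind(rep(c(1, 2, 3), 2)),
                       rep(c("control", "fireworks"), each = 3),
                       tested_pcs = 1L)
  expect_equal(res0$F, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)

  # F equals the squared pooled-variance t statistic on random data
  set.seed(2)
  for (rep in 1:10) {
    y <- rnorm(24)
    g <- rep(c("control", "fireworks"), each = 12)
    res <- anova_per_pc(cbind(y), g, tested_pcs = 1L)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand-stepped oracle and is stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  # independent step-up oracle and permutation invariance
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (k in m:1) {
      prev <- min(prev, m * p[o[k]] / k)
      adj[o[k]] <- prev
    }
    adj
  }
  set.seed(3)
  for (rep in 1:10) {
    p <- runif(12)^2
    expect_equal(bh_fdr(p), step_up(p), tolerance = 1e-12)
    perm <- sample(12)
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
})

test_that("per-PC tests assemble F, Shapiro and BH columns coherently", {
  set.seed(4)
  n <- 40
  scores <- cbind(rnorm(n), rnorm(n), rnorm(n))
  scores[, 2] <- scores[, 2] + rep(c(0, 1.5), each = n / 2)
  cond <- rep(c("control", "fireworks"), each = n / 2)
  res <- anova_per_pc(scores, cond, tested_pcs = 1:3)
  expect_equal(res$pc, 1:3)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_equal(res$p_adj, bh_fdr(res$p))
  for (j in 1:3) {
    sw <- shapiro.test(residuals(aov(scores[, j] ~ factor(cond))))
    expect_equal(res$shapiro_W[j], unname(sw$statistic), tolerance = 1e-9)
  }
  expect_error(anova_per_pc(scores, rep("control", n)), "two condition")
})

test_that("paired power follows the noncentral t distribution", {
  # closed anchors: null effect gives alpha; huge effect gives ~1
  expect_equal(paired_t_power(0, 11), 0.05, tolerance = 1e-12)
  expect_gt(paired_t_power(5, 11), 0.999)
  # monotone in d and n
  expect_gt(paired_t_power(1.2, 11), paired_t_power(0.8, 11))
  expect_gt(paired_t_power(0.8, 20), paired_t_power(0.8, 10))
  # simulation oracle: empirical rejection rate of the paired t-test
  set.seed(5)
  d_true <- 1.0; n <- 15; reps <- 4000
  rej <- mean(replicate(reps, {
    x <- rnorm(n, mean = d_true)
    t.test(x)$p.value < 0.05
  }))
  expect_equal(paired_t_power(d_true, n), rej, tolerance = 0.03)
})

test_that("subject-level effect reports paired d and power", {
  # subjects with per-condition means differing by [0, 1, 2]: d = 1
  subj <- rep(c("a", "b", "c"), each = 4)
  cond <- rep(rep(c("control", "fireworks"), each = 2), 3)
  base <- c(0, 0, 0, 0,  1, 1, 2, 2,  2, 2, 4, 4)
  eff <- subject_level_effect(cbind(base), cond, subj, 1)
  expect_equal(eff$paired_d, 1, tolerance = 1e-12)
  expect_equal(eff$power, paired_t_power(1, 3), tolerance = 1e-12)
  expect_equal(eff$n_subjects, 3L)

  # zero-variance differences: d undefined
  expect_error(subject_level_effect(cbind(rep(c(0, 1), 3)),
                                    rep(c("control", "fireworks"), 3),
                                    rep(c("a", "b", "c"), each = 2), 1),
               "zero variance")
})

test_that("pooled within-group regression removes pose covariation only", {
  set.seed(6)
  n <- 60; q <- 3; p <- 10
  g <- rep(c("control", "fireworks"), each = n / 2)
  X <- matrix(rnorm(n * q), n)
  B_true <- matrix(rnorm(q * p), q)
  gmeans <- rbind(rnorm(p), rnorm(p) + 2)
  Y <- gmeans[as.integer(factor(g)), ] + X %*% B_true
  fit <- pooled_within_group_regression(Y, X, g)
  # perfect linear dependence: residual shapes collapse onto the group
  # means of the responses
  expected <- apply(Y, 2, function(v) tapply(v, g, mean))
  for (i in seq_len(n))
    expect_equal(fit$residual_shapes[i, ],
                 expected[g[i], ], tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("regression recovers zero slopes for independent data", {
  set.seed(7)
  n <- 200; q <- 3; p <- 6
  g <- rep(c("control", "fireworks"), each = n / 2)
  X <- matrix(rnorm(n * q), n)
  Y <- matrix(rnorm(n * p), n)
  fit <- pooled_within_group_regression(Y, X, g)
  # direct least-squares oracle on group-centered data
  gm_X <- apply(X, 2, function(v) tapply(v, g, mean))
  gm_Y <- apply(Y, 2, function(v) tapply(v, g, mean))
  Xc <- X - gm_X[factor(g), ]
  Yc <- Y - gm_Y[factor(g), ]
  B_ref <- qr.solve(Xc, Yc)
  expect_equal(fit$coefficients, B_ref, tolerance = 1e-9,
               ignore_attr = TRUE)
  # coefficients shrink toward zero: |B| < 3 SE elementwise
  se <- sqrt(diag(solve(crossprod(Xc)))) %o%
    apply(Yc - Xc %*% B_ref, 2, sd)
  expect_true(all(abs(fit$coefficients) < 3 * se))
  # residual-predictor orthogonality within groups
  resid_c <- fit$residual_shapes - gm_Y[factor(g), ]
  expect_equal(max(abs(crossprod(Xc, resid_c))), 0, tolerance = 1e-9)
  expect_error(pooled_within_group_regression(Y, cbind(X[, 1], X[, 1]), g),
               "rank")
})

test_that("two-group CVA reproduces the analytic 1-D case", {
  X <- cbind(c(1, 2, 10, 11))
  g <- c("control", "control", "fireworks", "fireworks")
  res <- cva_two_group(X, g)
  expect_equal(res$wilks_lambda, 1 / 82, tolerance = 1e-12)
  expect_equal(res$F_approx, 162, tolerance = 1e-9)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 2L)
  # cross-check F = t^2 with the pooled t statistic
  tt <- t.test(X[, 1] ~ g, var.equal = TRUE)
  expect_equal(res$F_approx, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("Wilks' Lambda matches an independent Hotelling T^2 oracle", {
  set.seed(8)
  for (rep in 1:6) {
    n1 <- 15; n2 <- 18; q <- 4
    X <- rbind(matrix(rnorm(n1 * q), n1),
               matrix(rnorm(n2 * q), n2) + 0.8)
    g <- rep(c("control", "fireworks"), c(n1, n2))
    res <- cva_two_group(X, g)
    # Hotelling T^2 from scratch
    m1 <- colMeans(X[1:n1, ]); m2 <- colMeans(X[-(1:n1), ])
    S <- (crossprod(sweep(X[1:n1, ], 2, m1)) +
            crossprod(sweep(X[-(1:n1), ], 2, m2))) / (n1 + n2 - 2)
    T2 <- (n1 * n2 / (n1 + n2)) *
      as.numeric(t(m1 - m2) %*% solve(S, m1 - m2))
    expect_equal(res$wilks_lambda, 1 / (1 + T2 / (n1 + n2 - 2)),
                 tolerance = 1e-9)
  }
})

test_that("CVA degenerates correctly and is invariant to linear maps", {
  # identical group means and covariances: Lambda = 1, F = 0
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  X <- rbind(tri, tri)
  g <- rep(c("control", "fireworks"), each = 3)
  res <- cva_two_group(X, g)
  expect_equal(res$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(res$F_approx, 0, tolerance = 1e-12)

  set.seed(9)
  X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40), 20) + 1)
  g <- rep(c("control", "fireworks"), each = 20)
  r1 <- cva_two_group(X, g)
  A <- matrix(c(2, 0.5, -1, 3), 2)
  r2 <- cva_two_group(X %*% A + 5, g)
  # scores agree up to sign and affine scale
  s1 <- r1$cv1_scores; s2 <- r2$cv1_scores
  expect_equal(abs(cor(s1, s2)), 1, tolerance = 1e-9)
  expect_equal(r1$wilks_lambda, r2$wilks_lambda, tolerance = 1e-9)

  expect_error(cva_two_group(matrix(rnorm(16), 4),
                             rep(c("control", "fireworks"), each = 2)),
               "q must be")
  skip_if_not_installed("MASS")
  # direction matches MASS::lda's discriminant up to scale
  l <- MASS::lda(X, grouping = g)
  expect_equal(abs(cor(X %*% l$scaling, X %*% r1$cv1_direction)),
               matrix(1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mean shape difference is the antisymmetric condition field", {
  set.seed(10)
  n <- 12; L <- 5
  arr <- array(rnorm(n * L * 2), dim = c(n, L, 2))
  cond <- rep(c("control", "fireworks"), each = n / 2)
  msd <- mean_shape_difference(arr, cond)
  expect_equal(msd$field, msd$fireworks_mean - msd$control_mean)
  expect_equal(msd$norms, sqrt(rowSums(msd$field^2)))
  flipped <- mean_shape_difference(
    arr, rep(c("fireworks", "control"), each = n / 2))
  expect_equal(flipped$field, -msd$field)
  # identical samples: zero field
  arr2 <- arr
  arr2[7:12, , ] <- arr[1:6, , ]
  expect_equal(mean_shape_difference(arr2, cond)$field, matrix(0, L, 2))
  expect_error(mean_shape_difference(arr, rep("control", n)),
               "both conditions")
})

test_that("PC deformations are linear displacements along a loading", {
  set.seed(11)
  X <- matrix(rnorm(60 * 8), 60)
  pcm <- pca_fit(X)
  def <- pc_deformation(pcm, 2, magnitude_sd = 1)
  diff_vec <- facegmm:::flatten_shape(def$shape_plus - def$shape_minus)
  expect_equal(diff_vec,
               2 * pcm$sdev[2] * pcm$loadings[2, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  def0 <- pc_deformation(pcm, 2, magnitude_sd = 0)
  expect_equal(def0$shape_plus, facegmm:::fold_shape(pcm$mean_vector))
  expect_equal(def0$shape_plus, def0$shape_minus)
  expect_error(pc_deformation(pcm, 99), "invalid")
})
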