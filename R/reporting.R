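#' Thin-plate spline interpolation of scalar landmark values
#'
#' Fits the 2-D thin-plate spline (kernel `U(r) = r^2 log r` with an
#' affine part) through `values` at `points` and evaluates it on a grid
#' covering the points plus a margin. Falls back to nearest-neighbour
#' interpolation with a warning if the TPS system is numerically singular
#' (e.g. duplicated landmarks).
#'
#' @param points L x 2 landmark coordinates.
#' @param values length-L scalar values (e.g. displacement norms).
#' @param grid_n grid resolution per axis.
#' @param margin fractional bounding-box margin.
#' @return list with `x`, `y` (grid axes) and `z` (grid_n x grid_n matrix).
#' @export
tps_interpolate <- function(points, values, grid_n = 120L, margin = 0.1) {
  P <- as.matrix(points)
  L <- nrow(P)
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  D2 <- as.matrix(stats::dist(P))^2
  K <- U(D2)
  Pm <- cbind(1, P)
  A <- rbind(cbind(K, Pm), cbind(t(Pm), matrix(0, 3L, 3L)))
  rhs <- c(values, 0, 0, 0)
  w <- tryCatch(solve(A, rhs), error = function(e) NULL)
  rng_x <- range(P[, 1L]); rng_y <- range(P[, 2L])
  mx <- margin * diff(rng_x); my <- margin * diff(rng_y)
  gx <- seq(rng_x[1L] - mx, rng_x[2L] + mx, length.out = grid_n)
  gy <- seq(rng_y[1L] - my, rng_y[2L] + my, length.out = grid_n)
  z <- matrix(0, grid_n, grid_n)
  if (is.null(w)) {
    warning("degenerate TPS system; falling back to nearest neighbour")
    for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
      d2 <- (P[, 1L] - gx[i])^2 + (P[, 2L] - gy[j])^2
      z[i, j] <- values[which.min(d2)]
    }
  } else {
    for (j in seq_len(grid_n)) {
      d2 <- outer(gx, P[, 1L], function(a, b) (a - b)^2) +
        matrix((P[, 2L] - gy[j])^2, grid_n, L, byrow = TRUE)
      z[, j] <- U(d2) %*% w[seq_len(L)] +
        w[L + 1L] + w[L + 2L] * gx + w[L + 3L] * gy
    }
  }
  list(x = gx, y = gy, z = z)
}

#' Condition mean-shape comparison figure
#'
#' Overlays the control and fireworks mean configurations on a
#' thin-plate-spline heatmap of the per-landmark displacement norms.
#' Rendering is deterministic given identical inputs.
#'
#' @param msd result of [mean_shape_difference()].
#' @param path output PNG path.
#' @param grid_n heatmap grid resolution.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_mean_shape_comparison <- function(msd, path, grid_n = 120L,
                                         width = 800L, height = 800L) {
  cm <- msd$control_mean
  fm <- msd$fireworks_mean
  mid <- (cm + fm) / 2
  surf <- tps_interpolate(mid, msd$norms, grid_n = grid_n)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  zlim <- c(0, max(msd$norms, 1e-12))
  graphics::image(surf$x, surf$y, pmax(surf$z, 0), zlim = zlim,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "x", ylab = "y", useRaster = TRUE,
                  ylim = rev(range(surf$y)),  # image y axis points down
                  main = "Condition mean shapes and displacement heatmap")
  graphics::points(cm, pch = 19, col = "red3", cex = 1.2)
  graphics::points(fm, pch = 17, col = "blue3", cex = 1.2)
  graphics::arrows(cm[, 1L], cm[, 2L], fm[, 1L], fm[, 2L],
                   length = 0.05, col = "grey25")
  graphics::legend("topright",
                   legend = c("control mean", "fireworks mean"),
                   pch = c(19, 17), col = c("red3", "blue3"), bty = "n")
  invisible(path)
}

#' PC deformation figure
#'
#' Mean shape with the plus / minus deformation along one component
#' overlaid (the standard +/- SD visualisation).
#'
#' @param pc_model a `pc_model`.
#' @param pc_index component to display.
#' @param path output PNG path.
#' @param magnitude_sd displacement magnitude in component SDs.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_pc_deformation <- function(pc_model, pc_index, path,
                                  magnitude_sd = 1, width = 800L,
                                  height = 800L) {
  def <- pc_deformation(pc_model, pc_index, magnitude_sd)
  mean_shape <- fold_shape(pc_model$mean_vector)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  allp <- rbind(mean_shape, def$shape_plus, def$shape_minus)
  graphics::plot(allp, type = "n", xlab = "x", ylab = "y",
                 ylim = rev(range(allp[, 2L])),
                 main = sprintf("Shape change along PC%d (+/- %g SD)",
                                pc_index, magnitude_sd))
  graphics::points(mean_shape, pch = 19, col = "grey40")
  graphics::points(def$shape_plus, pch = 17, col = "red3")
  graphics::points(def$shape_minus, pch = 25, col = "blue3",
                   bg = "blue3")
  graphics::legend("topright",
                   legend = c("mean", "+1 SD", "-1 SD"),
                   pch = c(19, 17, 25),
                   col = c("grey40", "red3", "blue3"), bty = "n")
  invisible(path)
}

#' CVA score figure
#'
#' Distribution of CV1 scores per condition with Gaussian confidence
#' intervals (normal quantile in one dimension) and arrows from the grand
#' mean to each condition mean. Groups with fewer than 3 points get no
#' interval (warning).
#'
#' @param cva a `cva_result`.
#' @param condition length-n labels matching `cva$cv1_scores`.
#' @param path output PNG path.
#' @param ci confidence level for the interval.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_cva_scatter <- function(cva, condition, path, ci = 0.9,
                               width = 900L, height = 500L) {
  s <- cva$cv1_scores
  g <- factor(condition)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  cols <- c("red3", "blue3")
  ypos <- c(1, 2)
  graphics::plot(range(s), c(0.5, 2.5), type = "n", yaxt = "n",
                 xlab = "CV1 score", ylab = "",
                 main = sprintf("CVA separation (%.0f%% CI)", 100 * ci))
  graphics::axis(2, at = ypos, labels = levels(g), las = 1)
  zq <- stats::qnorm(1 - (1 - ci) / 2)
  for (k in seq_along(levels(g))) {
    sk <- s[g == levels(g)[k]]
    graphics::points(sk, rep(ypos[k], length(sk)), col = cols[k],
                     pch = 19)
    if (length(sk) >= 3L) {
      m <- mean(sk); half <- zq * stats::sd(sk)
      graphics::segments(m - half, ypos[k] + 0.25, m + half,
                         ypos[k] + 0.25, col = cols[k], lwd = 3)
    } else {
      warning("group ", levels(g)[k],
              " has fewer than 3 points; interval skipped")
    }
    graphics::arrows(mean(s), 1.5, mean(s[g == levels(g)[k]]), ypos[k],
                     length = 0.08, col = cols[k])
  }
  invisible(path)
}

#' Write a displacement field to CSV
#'
#' Columns `landmark`, `dx`, `dy`, `norm`.
#'
#' @param field L x 2 displacement matrix.
#' @param path output CSV path.
#' @export
write_displacement_field <- function(field, path) {
  df <- data.frame(landmark = seq_len(nrow(field)),
                   dx = field[, 1L], dy = field[, 2L],
                   norm = sqrt(rowSums(field^2)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
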