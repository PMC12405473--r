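#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks to
#' their centroid; the scale measure removed during superimposition.
#'
#' @param shape an L x 2 coordinate matrix, L >= 2.
#' @return a positive scalar.
#' @export
centroid_size <- function(shape) {
  shape <- as.matrix(shape)
  if (nrow(shape) < 2L) stop("need at least two landmarks", call. = FALSE)
  cs <- sqrt(sum(sweep(shape, 2L, colMeans(shape))^2))
  if (cs == 0) stop("degenerate shape: all landmarks coincident",
                    call. = FALSE)
  cs
}

# Center and scale a configuration to unit centroid size.
normalize_shape <- function(shape) {
  shape <- sweep(as.matrix(shape), 2L, colMeans(shape))
  shape / sqrt(sum(shape^2))
}

#' Optimal rotation between two centered unit-size shapes
#'
#' Finds the proper (determinant +1) rotation `R` minimizing the Frobenius
#' norm of `A %*% R - B`. Reflections are disallowed so that left/right
#' anatomy cannot flip.
#'
#' @param A,B centered, unit-centroid-size L x 2 matrices.
#' @return list with `rotation` (2 x 2) and `distance` (the minimized
#'   Frobenius residual, the partial Procrustes distance).
#' @export
align_pair <- function(A, B) {
  M <- crossprod(A, B)
  if (!all(is.finite(M)) || sum(M^2) == 0)
    stop("degenerate configuration: cannot align", call. = FALSE)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  list(rotation = R, distance = sqrt(sum((A %*% R - B)^2)))
}

#' Generalised Procrustes Analysis
#'
#' Iterative superimposition: every configuration is centered and scaled to
#' unit centroid size, then repeatedly rotated onto the running consensus
#' (the renormalized coordinate-wise mean) until the consensus moves less
#' than `tol` in Frobenius norm or `max_iter` is reached. The consensus is
#' initialized from the normalized mean of the centered, scaled shapes,
#' which makes the procedure a fixed point on its own output (re-running
#' on aligned coordinates converges in one iteration) and is fully
#' deterministic.
#'
#' @param shapes an `n x L x 2` array (or list of L x 2 matrices), n >= 2.
#' @param tol consensus-movement convergence tolerance (Frobenius norm).
#' @param max_iter maximum number of consensus updates.
#' @return an object of class `aligned_dataset`: `aligned` (`n x L x 2`),
#'   `consensus` (L x 2, unit size), `centroid_sizes`, `n_iterations`,
#'   `converged`.
#' @export
gpa <- function(shapes, tol = 1e-8, max_iter = 100L) {
  if (is.list(shapes)) {
    n <- length(shapes)
    L <- nrow(shapes[[1L]])
    arr <- array(0, dim = c(n, L, 2L))
    for (i in seq_len(n)) arr[i, , ] <- shapes[[i]]
    shapes <- arr
  }
  stopifnot(length(dim(shapes)) == 3L, dim(shapes)[3L] == 2L)
  n <- dim(shapes)[1L]
  if (n < 2L) stop("need at least two shapes", call. = FALSE)
  sizes <- numeric(n)
  aligned <- shapes
  for (i in seq_len(n)) {
    sizes[i] <- centroid_size(shapes[i, , ])
    aligned[i, , ] <- normalize_shape(shapes[i, , ])
  }
  consensus <- normalize_shape(apply(aligned, c(2L, 3L), mean))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      fit <- align_pair(aligned[i, , ], consensus)
      aligned[i, , ] <- aligned[i, , ] %*% fit$rotation
    }
    new_consensus <- normalize_shape(apply(aligned, c(2L, 3L), mean))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = sizes, n_iterations = iter,
                 converged = converged),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Procrustes-aligned dataset:", dim(x$aligned)[1L], "shapes x",
      dim(x$aligned)[2L], "landmarks;",
      x$n_iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Centers and scales both configurations to unit centroid size, rotates
#' one optimally onto the other (proper rotations only) and returns the
#' residual Frobenius distance (partial Procrustes distance). Symmetric in
#' its arguments.
#'
#' @param A,B L x 2 coordinate matrices with the same L.
#' @return a nonnegative scalar.
#' @export
procrustes_distance <- function(A, B) {
  align_pair(normalize_shape(A), normalize_shape(B))$distance
}

#' Flatten aligned coordinates
#'
#' Turns `n x L x 2` aligned coordinates into the `n x 2L` matrix
#' (`x1, y1, x2, y2, ...` per row) consumed by the PCA and regression
#' functions.
#'
#' @param aligned an `aligned_dataset` or `n x L x 2` array.
#' @return an `n x 2L` matrix.
#' @export
flatten_aligned <- function(aligned) {
  arr <- if (inherits(aligned, "aligned_dataset")) aligned$aligned
         else aligned
  n <- dim(arr)[1L]
  t(vapply(seq_len(n), function(i) flatten_shape(arr[i, , ]),
           numeric(dim(arr)[2L] * 2L)))
}
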