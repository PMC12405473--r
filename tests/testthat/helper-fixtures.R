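# Shared fixtures: small schemes, shapes and fast synthetic configs.

test_scheme <- function() default_scheme()

test_reduced <- function() reduce_scheme(default_scheme())

# Short videos keep simulation cheap; all structural defaults untouched.
fast_config <- function(seed = 1L, duration_s = 30, ...) {
  synthetic_config(duration_s = duration_s, seed = seed, ...)
}

random_shape <- function(L, scale = 1) {
  matrix(stats::rnorm(L * 2, sd = scale), L, 2)
}

# A landmark_ts with given per-set confidences/timestamps around a fixed
# frontal shape (reduced scheme).
toy_ts <- function(confidence, timestamp = seq_along(confidence) - 1,
                   subject = "s01", condition = "control",
                   shape = make_template(test_reduced())) {
  n <- length(confidence)
  coords <- array(0, dim = c(n, nrow(shape), 2))
  for (i in seq_len(n)) coords[i, , ] <- shape
  landmark_ts(paste0(subject, "_", condition), subject, condition,
              timestamp, confidence, coords)
}

# Random similarity transform of a shape.
similarity_transform <- function(shape, angle = stats::runif(1, 0, 2 * pi),
                                 scale = exp(stats::rnorm(1, 0, 0.3)),
                                 shift = stats::rnorm(2, 0, 5)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  scale * shape %*% t(R) + rep(shift, each = nrow(shape))
}

# Brute-force partial Procrustes distance: normalize both shapes, scan a
# fine rotation grid. Independent of align_pair's SVD route.
grid_procrustes <- function(A, B, n_grid = 20000L) {
  norm1 <- function(S) {
    S <- sweep(S, 2, colMeans(S))
    S / sqrt(sum(S^2))
  }
  A <- norm1(A); B <- norm1(B)
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = n_grid)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    best <- min(best, sum((A %*% R - B)^2))
  }
  sqrt(best)
}
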