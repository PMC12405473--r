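#' Landmark schemes
#'
#' A landmark scheme declares how many landmarks a detector emits, which
#' landmark numbers play named anatomical roles (inner eye corners, nose
#' centre, muzzle and lip points), which landmarks sit on the ear pinnae
#' (discarded before analysis because pinna geometry is highly breed
#' dependent) and which mark the ear bases (retained so that ear carriage
#' still enters the analysis). Scheme numbering is 1-based, matching how
#' landmark numbers are cited in figures and config files.
#'
#' @param n_landmarks total number of landmarks in the scheme.
#' @param roles named list mapping role names to landmark numbers
#'   (integer vectors, 1-based).
#' @param ear_pinna_indices landmark numbers on the ear pinnae.
#' @param ear_base_indices landmark numbers at the ear bases.
#' @param mirror_pairs two-column integer matrix of bilaterally paired
#'   landmarks; column 1 holds the subject-left member (negative x in the
#'   canonical frontal template), column 2 the subject-right member.
#' @param midline_indices landmark numbers lying on the facial midline.
#'
#' @return an object of class `landmark_scheme`.
#' @export
landmark_scheme <- function(n_landmarks, roles, ear_pinna_indices,
                            ear_base_indices, mirror_pairs = NULL,
                            midline_indices = integer()) {
  n_landmarks <- as.integer(n_landmarks)
  if (length(n_landmarks) != 1L || is.na(n_landmarks) || n_landmarks < 1L)
    stop("n_landmarks must be a single positive integer", call. = FALSE)
  roles <- lapply(roles, as.integer)
  ear_pinna_indices <- sort(unique(as.integer(ear_pinna_indices)))
  ear_base_indices <- sort(unique(as.integer(ear_base_indices)))
  all_idx <- c(unlist(roles, use.names = FALSE), ear_pinna_indices,
               ear_base_indices, as.integer(mirror_pairs),
               as.integer(midline_indices))
  if (length(all_idx) && (any(all_idx < 1L) || any(all_idx > n_landmarks)))
    stop("scheme indices must lie in [1, ", n_landmarks, "]", call. = FALSE)
  if (length(intersect(ear_pinna_indices, ear_base_indices)))
    stop("ear pinna and ear base index sets must be disjoint", call. = FALSE)
  if (!is.null(mirror_pairs)) {
    mirror_pairs <- matrix(as.integer(mirror_pairs), ncol = 2L)
    if (anyDuplicated(as.integer(mirror_pairs)))
      stop("mirror_pairs must not repeat a landmark", call. = FALSE)
  }
  structure(list(
    n_landmarks = n_landmarks,
    roles = roles,
    ear_pinna_indices = ear_pinna_indices,
    ear_base_indices = ear_base_indices,
    mirror_pairs = mirror_pairs,
    midline_indices = as.integer(midline_indices)
  ), class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", x$n_landmarks, "landmarks\n")
  cat("  roles:", paste(names(x$roles), collapse = ", "), "\n")
  cat("  ear pinna:", length(x$ear_pinna_indices),
      " ear base:", length(x$ear_base_indices), "\n")
  invisible(x)
}

#' Canonical 46-point dog-face landmark scheme
#'
#' The full detector scheme: 46 landmarks of which ten (five per ear) lie on
#' the ear pinnae and are discarded before morphometric analysis, leaving 36.
#' The named roles follow the numbering used throughout the analysis:
#' landmarks 6 and 7 are the inner eye corners, 22 the nose centre, 25 and 28
#' the upper-muzzle pair, 31 and 32 the lower-muzzle pair, 33 and 34 the lip
#' corners, 35 and 36 the ear bases.
#'
#' @return a `landmark_scheme` with 46 landmarks.
#' @export
default_scheme <- function() {
  landmark_scheme(
    n_landmarks = 46L,
    roles = list(
      inner_eye_left = 6L, inner_eye_right = 7L,
      nose_centre = 22L,
      upper_muzzle = c(25L, 28L),
      lower_muzzle = c(31L, 32L),
      lip_corners = c(33L, 34L)
    ),
    ear_pinna_indices = 37:46,
    ear_base_indices = c(35L, 36L),
    mirror_pairs = rbind(
      c(1L, 8L), c(2L, 9L), c(3L, 10L), c(4L, 11L), c(5L, 12L),
      c(6L, 7L),
      c(13L, 14L), c(15L, 16L), c(17L, 18L), c(19L, 20L),
      c(23L, 24L),
      c(25L, 28L), c(26L, 29L), c(27L, 30L),
      c(31L, 32L), c(33L, 34L), c(35L, 36L),
      c(37L, 42L), c(38L, 43L), c(39L, 44L), c(40L, 45L), c(41L, 46L)
    ),
    midline_indices = c(21L, 22L)
  )
}

#' Reduce a scheme by removing the ear-pinna landmarks
#'
#' Drops `ear_pinna_indices` and renumbers the remaining landmarks
#' consecutively, preserving their relative order; all role, ear-base,
#' mirror-pair and midline indices are remapped consistently.
#'
#' @param scheme a `landmark_scheme`.
#' @return the reduced `landmark_scheme` (empty pinna set).
#' @export
reduce_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  drop <- scheme$ear_pinna_indices
  if (!length(drop)) return(scheme)
  keep <- setdiff(seq_len(scheme$n_landmarks), drop)
  remap <- integer(scheme$n_landmarks)
  remap[keep] <- seq_along(keep)
  map_idx <- function(i) remap[i]
  mp <- scheme$mirror_pairs
  if (!is.null(mp)) {
    ok <- !(mp[, 1L] %in% drop | mp[, 2L] %in% drop)
    mp <- matrix(map_idx(mp[ok, , drop = FALSE]), ncol = 2L)
  }
  landmark_scheme(
    n_landmarks = length(keep),
    roles = lapply(scheme$roles, map_idx),
    ear_pinna_indices = integer(),
    ear_base_indices = map_idx(setdiff(scheme$ear_base_indices, drop)),
    mirror_pairs = mp,
    midline_indices = map_idx(setdiff(scheme$midline_indices, drop))
  )
}

#' Resolve a named role to landmark numbers
#'
#' @param scheme a `landmark_scheme`.
#' @param role role name, e.g. `"nose_centre"`.
#' @return integer landmark numbers.
#' @export
scheme_role <- function(scheme, role) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  idx <- scheme$roles[[role]]
  if (is.null(idx)) stop("unknown role: ", role, call. = FALSE)
  idx
}

#' Read / write a scheme file
#'
#' Schemes are stored as YAML (or JSON, which YAML subsumes) with fields
#' `n_landmarks`, `roles`, `ear_pinna_indices`, `ear_base_indices` and
#' optionally `mirror_pairs` (list of two-element pairs) and
#' `midline_indices`.
#'
#' @param path file path.
#' @return `read_scheme` returns a `landmark_scheme`; `write_scheme` is
#'   called for its side effect and returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  mp <- y$mirror_pairs
  if (!is.null(mp)) mp <- do.call(rbind, lapply(mp, as.integer))
  landmark_scheme(
    n_landmarks = y$n_landmarks,
    roles = y$roles,
    ear_pinna_indices = y$ear_pinna_indices,
    ear_base_indices = y$ear_base_indices,
    mirror_pairs = mp,
    midline_indices = if (is.null(y$midline_indices)) integer()
                      else y$midline_indices
  )
}

#' @rdname read_scheme
#' @param scheme a `landmark_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  y <- list(
    n_landmarks = scheme$n_landmarks,
    roles = scheme$roles,
    ear_pinna_indices = scheme$ear_pinna_indices,
    ear_base_indices = scheme$ear_base_indices,
    midline_indices = scheme$midline_indices
  )
  if (!is.null(scheme$mirror_pairs))
    y$mirror_pairs <- apply(scheme$mirror_pairs, 1L, identity,
                            simplify = FALSE)
  yaml::write_yaml(y, path)
  invisible(path)
}

# Flatten an L x 2 shape to (x1, y1, x2, y2, ...) and back.  All matrix
# statistics in the package use this interleaved convention.
flatten_shape <- function(m) as.vector(t(m))

fold_shape <- function(v) matrix(v, ncol = 2L, byrow = TRUE)
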