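#' Define an atom group
#'
#' @param indices integer atom indices (1-based rows of the coordinate
#'   matrix), unique and non-empty.
#' @param weights optional per-atom weights (default uniform).
#' @return an `atom_group`.
#' @export
atom_group <- function(indices, weights = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("atom group must be non-empty")
  if (anyDuplicated(indices) || any(indices < 1L))
    stop("atom group indices must be unique positive integers")
  if (is.null(weights)) weights <- rep(1, length(indices))
  if (length(weights) != length(indices) || any(weights <= 0))
    stop("weights must be positive and match the group length")
  structure(list(idx = indices, w = weights / sum(weights)), class = "atom_group")
}

.as_group <- function(g) {
  if (inherits(g, "atom_group")) g else atom_group(g)
}

.group_coords <- function(g, coords) {
  if (max(g$idx) > nrow(coords)) stop("atom group index out of range")
  coords[g$idx, , drop = FALSE]
}

.centroid <- function(g, coords) {
  x <- .group_coords(g, coords)
  colSums(x * g$w)
}

#' Distance between the centroids of two atom groups
#'
#' On a C-alpha model "center of mass" means the (uniformly or
#' user-weighted) centroid; no masses exist in the model.
#'
#' @param group_a,group_b atom groups (or bare index vectors).
#' @param coords N x 3 coordinate matrix.
#' @return non-negative distance; symmetric in its group arguments.
#' @export
com_distance <- function(group_a, group_b, coords) {
  ca <- .centroid(.as_group(group_a), coords)
  cb <- .centroid(.as_group(group_b), coords)
  sqrt(sum((ca - cb)^2))
}

#' Radius of gyration of an atom group
#'
#' Root-mean-square distance of the group atoms from their centroid, with
#' uniform weights.
#'
#' @param group atom group (or bare index vector).
#' @param coords N x 3 coordinate matrix.
#' @return non-negative radius of gyration.
#' @export
radius_of_gyration <- function(group, coords) {
  g <- .as_group(group)
  x <- .group_coords(g, coords)
  xc <- sweep(x, 2, colMeans(x))
  sqrt(sum(xc^2) / nrow(x))
}

.check_nondegenerate <- function(xc, what = "fit group") {
  if (nrow(xc) < 3L) stop(sprintf("%s needs >= 3 atoms", what))
  s <- svd(xc, nu = 0, nv = 0)$d
  if (s[2] < 1e-8 * max(s[1], 1))
    stop(sprintf("%s is collinear/degenerate; superposition is ill-defined", what))
  invisible(TRUE)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Returns the proper rotation `R` (det = +1) and translation `t` minimizing
#' the RMSD of the fit group, such that `mobile %*% t(R) + t` superposes onto
#' the reference.
#'
#' @param mobile_coords,ref_coords congruent N x 3 coordinate matrices.
#' @param fit_group atom group used for the fit (>= 3 non-collinear atoms).
#' @return list with `R` (3 x 3) and `t` (length 3).
#' @export
kabsch_align <- function(mobile_coords, ref_coords, fit_group) {
  g <- .as_group(fit_group)
  xm <- .group_coords(g, mobile_coords)
  xr <- .group_coords(g, ref_coords)
  cm <- colMeans(xm); cr <- colMeans(xr)
  xm_c <- sweep(xm, 2, cm); xr_c <- sweep(xr, 2, cr)
  .check_nondegenerate(xm_c)
  .check_nondegenerate(xr_c, "reference fit group")
  S <- t(xm_c) %*% xr_c
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cr - R %*% cm))
}

#' Apply a rigid transform returned by [kabsch_align()]
#'
#' @param coords N x 3 matrix.
#' @param transform list with `R` and `t`.
#' @return transformed coordinates.
#' @export
apply_transform <- function(coords, transform) {
  sweep(coords %*% t(transform$R), 2, -transform$t)
}

#' Root-mean-square deviation, with optional superposition
#'
#' If `fit_group` is given, the mobile coordinates are first rigidly
#' superposed onto the reference on that group, then the RMSD is measured on
#' `measure_group`; with `fit_group = NULL` no superposition is performed.
#' Fitting on the measured group itself can never give a larger RMSD than
#' fitting on any other group.
#'
#' @param mobile_coords,ref_coords congruent N x 3 coordinate matrices.
#' @param measure_group atoms the RMSD is computed over.
#' @param fit_group atoms used for superposition, or `NULL` for none.
#' @return non-negative RMSD.
#' @export
rmsd <- function(mobile_coords, ref_coords, measure_group, fit_group = NULL) {
  if (!all(dim(mobile_coords) == dim(ref_coords)))
    stop("mobile and reference coordinate sets differ in size")
  if (!is.null(fit_group)) {
    tr <- kabsch_align(mobile_coords, ref_coords, fit_group)
    mobile_coords <- apply_transform(mobile_coords, tr)
  }
  g <- .as_group(measure_group)
  dd <- .group_coords(g, mobile_coords) - .group_coords(g, ref_coords)
  sqrt(sum(dd^2) / length(g$idx))
}

#' Orientation quaternion of a group relative to a reference
#'
#' Solves the optimal-rotation problem (after centroid removal) through the
#' standard 4 x 4 key-matrix eigenproblem and returns the unit quaternion of
#' the rotation taking the reference group onto the current group,
#' canonicalized to `w >= 0` (q and -q encode the same rotation).
#'
#' @param group atom group (>= 3 non-collinear atoms).
#' @param coords current N x 3 coordinates.
#' @param ref_coords reference N x 3 coordinates.
#' @return a `quaternion` (named numeric: w, x, y, z).
#' @export
orientation_quaternion <- function(group, coords, ref_coords) {
  g <- .as_group(group)
  y <- .group_coords(g, coords)
  x <- .group_coords(g, ref_coords)
  yc <- sweep(y, 2, colMeans(y)); xc <- sweep(x, 2, colMeans(x))
  .check_nondegenerate(yc, "orientation group")
  .check_nondegenerate(xc, "orientation reference group")
  S <- t(xc) %*% yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  if (q[1] < 0) q <- -q
  q <- q / sqrt(sum(q^2))
  structure(stats::setNames(q, c("w", "x", "y", "z")), class = "quaternion")
}

#' Orientation angle (degrees) of a group relative to a reference
#'
#' The rotation angle of the optimal superposition rotation,
#' `2 * acos(|w|)` in degrees, in `[0, 180]`.
#'
#' @inheritParams orientation_quaternion
#' @return angle in degrees.
#' @export
orientation_angle <- function(group, coords, ref_coords) {
  q <- orientation_quaternion(group, coords, ref_coords)
  2 * acos(min(1, abs(q[["w"]]))) * 180 / pi
}

#' Declarative collective-variable specification
#'
#' @param kind one of `"com_distance"`, `"radius_of_gyration"`,
#'   `"orientation_angle"`, `"rmsd"`.
#' @param group main atom group.
#' @param group_b second group (`com_distance` only).
#' @param ref reference coordinates (`orientation_angle`, `rmsd`).
#' @param fit_group superposition group for `rmsd`; the default `NULL` means
#'   superpose on `group` itself (the standard convention for an RMSD
#'   collective variable).
#' @param name optional label.
#' @return a `cv_spec`.
#' @export
cv_spec <- function(kind, group, group_b = NULL, ref = NULL, fit_group = NULL,
                    name = kind) {
  if (!kind %in% names(.cv_kind_codes)) stop(sprintf("unknown CV kind '%s'", kind))
  group <- .as_group(group)
  if (kind == "com_distance" && is.null(group_b))
    stop("com_distance requires group_b")
  if (kind %in% c("orientation_angle", "rmsd") && is.null(ref))
    stop(sprintf("%s requires reference coordinates", kind))
  structure(list(kind = kind, group = group,
                 group_b = if (!is.null(group_b)) .as_group(group_b),
                 ref = ref,
                 fit_group = if (!is.null(fit_group)) .as_group(fit_group),
                 name = name), class = "cv_spec")
}

#' Evaluate a collective variable on a coordinate frame
#'
#' Pure function of the coordinates: dispatches to [com_distance()],
#' [radius_of_gyration()], [orientation_angle()] or [rmsd()].
#'
#' @param spec a `cv_spec`.
#' @param coords N x 3 coordinate matrix.
#' @return the scalar CV value.
#' @export
evaluate_cv <- function(spec, coords) {
  stopifnot(inherits(spec, "cv_spec"))
  switch(spec$kind,
    com_distance = com_distance(spec$group, spec$group_b, coords),
    radius_of_gyration = radius_of_gyration(spec$group, coords),
    orientation_angle = orientation_angle(spec$group, coords, spec$ref),
    rmsd = rmsd(coords, spec$ref, spec$group,
                if (is.null(spec$fit_group)) spec$group else spec$fit_group),
    stop(sprintf("unknown CV kind '%s'", spec$kind))
  )
}

# engine form of a cv_spec (kind codes shared with src/core.cpp)
.cv_engine_def <- function(spec) {
  ref <- NULL
  if (spec$kind %in% c("orientation_angle", "rmsd"))
    ref <- spec$ref[spec$group$idx, , drop = FALSE]
  if (spec$kind == "rmsd" && !is.null(spec$fit_group) &&
      !identical(spec$fit_group$idx, spec$group$idx))
    stop("the dynamics engine supports rmsd CVs superposed on their own group only")
  list(kind_code = .cv_kind_codes[[spec$kind]],
       idx = spec$group$idx,
       idx_b = if (!is.null(spec$group_b)) spec$group_b$idx,
       ref = ref)
}

#' Gradient of a collective variable (engine route)
#'
#' Gradient of the CV with respect to all coordinates as computed by the
#' dynamics core: analytic for distances, radii of gyration and RMSD, central
#' finite differences (step 1e-5) through the quaternion eigenproblem for
#' orientation angles. Exposed for gradient-check tests.
#'
#' @inheritParams evaluate_cv
#' @return N x 3 gradient matrix.
#' @export
cv_gradient <- function(spec, coords) {
  cg_cv_gradient(as.matrix(coords), .cv_engine_def(spec))
}

#' Pairwise RMSD map over trajectory frames
#'
#' @param traj a `cg_trajectory`.
#' @param measure_group atoms the RMSD is computed over.
#' @param fit_group superposition group (or `NULL` for none).
#' @param stride keep every `stride`-th frame.
#' @return symmetric matrix of pairwise RMSDs with zero diagonal.
#' @export
pairwise_rmsd_map <- function(traj, measure_group, fit_group = NULL, stride = 1L) {
  frames <- traj_frames(traj)
  keep <- seq(1L, length(frames), by = as.integer(stride))
  frames <- frames[keep]
  f <- length(frames)
  if (f < 2L) stop("need >= 2 frames after striding")
  m <- matrix(0, f, f)
  for (i in seq_len(f - 1L)) {
    for (j in (i + 1L):f) {
      m[i, j] <- m[j, i] <- rmsd(frames[[i]], frames[[j]], measure_group, fit_group)
    }
  }
  m
}
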