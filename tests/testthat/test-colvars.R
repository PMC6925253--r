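test_that("com_distance matches closed forms and a longhand centroid oracle", {
  x <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_identical(com_distance(1L, 2L, x), 5)
  expect_identical(com_distance(1L, 1L, x), 0)

  set.seed(5)
  y <- matrix(stats::rnorm(24), 8, 3)
  ga <- 1:4; gb <- 5:8
  oracle <- sqrt(sum((colMeans(y[ga, ]) - colMeans(y[gb, ]))^2))
  expect_equal(com_distance(ga, gb, y), oracle, tolerance = 1e-12)
  expect_equal(com_distance(gb, ga, y), com_distance(ga, gb, y))
  expect_error(com_distance(integer(0), gb, y), "non-empty")
})

test_that("radius of gyration matches symmetry cases and the direct formula", {
  expect_equal(radius_of_gyration(1L, matrix(c(1, 2, 3), 1)), 0)
  a <- 2.7  # equilateral triangle, side a: Rg = a / sqrt(3)
  tri <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0))
  expect_equal(radius_of_gyration(1:3, tri), a / sqrt(3), tolerance = 1e-12)

  set.seed(9)
  p <- matrix(stats::rnorm(15), 5, 3)
  direct <- sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
  expect_equal(radius_of_gyration(1:5, p), direct, tolerance = 1e-12)
})

test_that("kabsch alignment recovers known transforms with a proper rotation", {
  set.seed(3)
  x <- matrix(stats::rnorm(30), 10, 3)
  tr <- kabsch_align(x, x, 1:10)
  expect_equal(tr$R, diag(3), tolerance = 1e-10)
  expect_equal(tr$t, rep(0, 3), tolerance = 1e-10)

  R0 <- rotation_about(c(1, 2, -1), 37)
  t0 <- c(4, -2, 1)
  y <- sweep(x %*% t(R0), 2, -t0)  # y = R0 x + t0
  tr <- kabsch_align(y, x, 1:10)   # must recover the inverse transform
  expect_lt(max(abs(tr$R %*% R0 - diag(3))), 1e-8)
  expect_lt(max(abs(apply_transform(y, tr) - x)), 1e-8)

  # reflection-only relation still yields det +1 and nonzero residual
  y_ref <- x %*% diag(c(-1, 1, 1))
  tr <- kabsch_align(y_ref, x, 1:10)
  expect_equal(det(tr$R), 1, tolerance = 1e-10)
  expect_gt(rmsd(y_ref, x, 1:10, 1:10), 0.1)

  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_align(line, line, 1:5), "collinear")
})

test_that("rmsd closed forms: identity, translation with/without alignment", {
  set.seed(4)
  x <- matrix(stats::rnorm(21), 7, 3)
  expect_equal(rmsd(x, x, 1:7), 0)
  t0 <- c(1, -2, 2)
  y <- sweep(x, 2, -t0)
  expect_equal(rmsd(y, x, 1:7), sqrt(sum(t0^2)), tolerance = 1e-10)
  expect_equal(rmsd(y, x, 1:7, fit_group = 1:7), 0, tolerance = 1e-10)
  expect_error(rmsd(x[1:5, ], x, 1:5), "size")
})

test_that("bundle-1 rmsd under bundle-2 alignment equals the rocking displacement", {
  tw <- fix_toy()
  r <- tw$refs
  b1 <- atom_indices(tw$structure, bundle = 1)
  b2 <- atom_indices(tw$structure, bundle = 2)
  # oracle: bundle 2 aligns exactly, so the measured RMSD must equal the raw
  # displacement of bundle-1 atoms under the known rocking rotation
  oracle <- sqrt(mean(rowSums((r$if_coords[b1, ] - r$of_coords[b1, ])^2)))
  expect_equal(rmsd(r$if_coords, r$of_coords, b1, b2), oracle, tolerance = 1e-8)
  # fit-on-self never exceeds fit-on-other
  expect_lte(rmsd(r$if_coords, r$of_coords, b1, b1),
             rmsd(r$if_coords, r$of_coords, b1, b2))
})

test_that("orientation quaternion: identity, known rotations, canonical sign", {
  set.seed(6)
  x <- matrix(stats::rnorm(18), 6, 3)
  q <- orientation_quaternion(1:6, x, x)
  expect_equal(q[["w"]], 1, tolerance = 1e-9)
  expect_equal(orientation_angle(1:6, x, x), 0, tolerance = 1e-6)

  y <- x %*% t(rotation_about(c(0, 0, 1), 30))
  expect_equal(orientation_angle(1:6, y, x), 30, tolerance = 1e-6)
  q <- orientation_quaternion(1:6, y, x)
  axis <- c(q[["x"]], q[["y"]], q[["z"]]) / sin(acos(q[["w"]]))
  expect_equal(abs(axis[3]), 1, tolerance = 1e-6)
  expect_gte(q[["w"]], 0)

  # q and -q: the canonical form always has w >= 0
  y2 <- x %*% t(rotation_about(c(1, 1, 0), 170))
  expect_gte(orientation_quaternion(1:6, y2, x)[["w"]], 0)
})

test_that("orientation angle matches the rotation-matrix oracle over random rotations", {
  set.seed(77)
  x <- matrix(stats::rnorm(24), 8, 3)
  worst <- 0
  for (k in 1:100) {
    R <- random_rotation()
    t <- stats::rnorm(3, 0, 5)
    y <- sweep(x %*% t(R), 2, -t)
    worst <- max(worst, abs(orientation_angle(1:8, y, x) - rotation_angle_deg(R)))
  }
  expect_lt(worst, 1e-6)
})

test_that("evaluate_cv dispatches to the primitive operations", {
  tw <- fix_toy()
  r <- tw$refs
  s <- tw$structure
  b1 <- atom_indices(s, bundle = 1)
  b2 <- atom_indices(s, bundle = 2)

  spec_d <- cv_spec("com_distance", b1, group_b = b2)
  expect_identical(evaluate_cv(spec_d, r$of_coords), com_distance(b1, b2, r$of_coords))

  spec_r <- cv_spec("rmsd", b1, ref = r$of_coords)
  expect_equal(evaluate_cv(spec_r, r$of_coords), 0, tolerance = 1e-10)

  # orientation of the moving bundle helix between the references recovers
  # the rocking angle by construction
  tm8 <- atom_indices(s, helix = s$meta$site_helices[["moving"]])
  spec_o <- cv_spec("orientation_angle", tm8, ref = r$of_coords)
  expect_equal(evaluate_cv(spec_o, r$if_coords), r$angle_deg, tolerance = 1e-6)

  expect_error(cv_spec("torsion", b1), "unknown CV kind")
  expect_error(cv_spec("com_distance", b1), "group_b")
})

test_that("engine CV values agree with the pure-R implementations", {
  tw <- fix_toy()
  s <- tw$structure; r <- tw$refs
  set.seed(12)
  x <- r$of_coords + matrix(stats::rnorm(length(r$of_coords), 0, 0.3),
                            nrow(r$of_coords))
  b1 <- atom_indices(s, bundle = 1)
  specs <- list(
    cv_spec("com_distance", b1, group_b = atom_indices(s, bundle = 2)),
    cv_spec("radius_of_gyration", b1),
    cv_spec("orientation_angle", b1, ref = r$if_coords),
    cv_spec("rmsd", b1, ref = r$if_coords))
  for (sp in specs) {
    eng <- rockbundle:::cg_cv_value(x, rockbundle:::.cv_engine_def(sp))
    expect_equal(eng, evaluate_cv(sp, x), tolerance = 1e-10)
  }
})

test_that("engine CV gradients pass a finite-difference check", {
  tw <- fix_toy()
  s <- tw$structure; r <- tw$refs
  set.seed(13)
  x <- r$of_coords + matrix(stats::rnorm(length(r$of_coords), 0, 0.2),
                            nrow(r$of_coords))
  b1 <- atom_indices(s, bundle = 1)
  specs <- list(
    cv_spec("com_distance", b1, group_b = atom_indices(s, bundle = 2)),
    cv_spec("radius_of_gyration", b1),
    cv_spec("orientation_angle", b1, ref = r$if_coords),
    cv_spec("rmsd", b1, ref = r$if_coords))
  h <- 1e-6
  for (sp in specs) {
    g <- cv_gradient(sp, x)
    for (probe in list(c(b1[2], 1), c(b1[5], 3))) {
      x2 <- x; x2[probe[1], probe[2]] <- x2[probe[1], probe[2]] + h
      fd <- (evaluate_cv(sp, x2) - evaluate_cv(sp, x)) / h
      expect_equal(g[probe[1], probe[2]], fd, tolerance = 1e-3)
    }
  }
})

test_that("CVs are invariant under global rigid motion of coords and references", {
  tw <- fix_toy()
  s <- tw$structure; r <- tw$refs
  set.seed(21)
  x <- r$of_coords + matrix(stats::rnorm(length(r$of_coords), 0, 0.2),
                            nrow(r$of_coords))
  b1 <- atom_indices(s, bundle = 1)
  R <- random_rotation(); t0 <- stats::rnorm(3, 0, 8)
  move <- function(m) sweep(m %*% t(R), 2, -t0)
  specs <- list(
    cv_spec("com_distance", b1, group_b = atom_indices(s, bundle = 2)),
    cv_spec("radius_of_gyration", b1),
    cv_spec("orientation_angle", b1, ref = r$if_coords),
    cv_spec("rmsd", b1, ref = r$if_coords))
  for (sp in specs) {
    sp2 <- sp
    if (!is.null(sp$ref)) sp2$ref <- move(sp$ref)
    expect_lt(abs(evaluate_cv(sp2, move(x)) - evaluate_cv(sp, x)), 1e-8)
  }
})

test_that("perturbing one atom changes a centroid distance by at most delta/n", {
  set.seed(30)
  x <- matrix(stats::rnorm(30), 10, 3)
  ga <- 1:5; gb <- 6:10
  d0 <- com_distance(ga, gb, x)
  delta <- 0.37
  for (k in 1:10) {
    x2 <- x
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    x2[3, ] <- x2[3, ] + delta * u
    expect_lte(abs(com_distance(ga, gb, x2) - d0), delta / length(ga) + 1e-12)
  }
})

test_that("pairwise RMSD maps are symmetric, zero-diagonal and consistent", {
  tw <- fix_toy()
  s <- tw$structure; r <- tw$refs
  b1 <- atom_indices(s, bundle = 1)

  const <- as_trajectory(list(r$of_coords, r$of_coords, r$of_coords))
  expect_lt(max(pairwise_rmsd_map(const, b1, b1)), 1e-12)

  two <- as_trajectory(list(r$of_coords, r$if_coords))
  m2 <- pairwise_rmsd_map(two, b1, atom_indices(s, bundle = 2))
  expect_equal(m2[1, 2], rmsd(r$if_coords, r$of_coords, b1, atom_indices(s, bundle = 2)),
               tolerance = 1e-12)

  set.seed(8)
  frames <- lapply(1:5, function(i)
    r$of_coords + matrix(stats::rnorm(length(r$of_coords), 0, 0.3), nrow(r$of_coords)))
  m <- pairwise_rmsd_map(as_trajectory(frames), b1, b1)
  expect_lt(max(abs(m - t(m))), 1e-10)
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))
})
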