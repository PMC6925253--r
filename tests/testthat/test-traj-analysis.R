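# synthetic trajectories for the correlation analyses: a static 4-atom
# anchor (non-collinear, so alignment is well-posed) plus probe atoms
.anchor <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))

.make_traj <- function(probe_frames) {
  frames <- lapply(probe_frames, function(p) rbind(.anchor, p))
  as_trajectory(frames)
}

test_that("correlation matrix: perfect correlation, anti-correlation, diagonal", {
  set.seed(2)
  disp <- stats::rnorm(20, 0, 0.5)
  frames <- lapply(disp, function(d)
    rbind(c(20, 0, 0) + c(d, 0, 0), c(25, 0, 0) + c(d, 0, 0),
          c(20, 5, 0) - c(d, 0, 0)))
  # probes are nodes 5:7; the static anchor (1:4) only serves the alignment
  C <- correlation_matrix(.make_traj(frames), 1:4, nodes = 5:7)
  expect_equal(diag(C), rep(1, 3))
  expect_equal(C[1, 2], 1, tolerance = 1e-10)   # in-phase pair
  expect_equal(C[1, 3], -1, tolerance = 1e-10)  # anti-phase pair
  expect_lt(max(abs(C - t(C))), 1e-12)
})

test_that("correlation matrix matches a longhand covariance oracle", {
  set.seed(7)
  frames <- lapply(1:25, function(i) matrix(stats::rnorm(15, sd = 0.4), 5, 3) +
                     rbind(c(20, 0, 0), c(24, 0, 0), c(20, 4, 0), c(16, 0, 4), c(20, -4, 0)))
  traj <- .make_traj(frames)
  nodes <- 5:9  # the five probe atoms behind the four-atom anchor
  C <- correlation_matrix(traj, 1:4, nodes = nodes)

  # brute-force oracle, frame by frame, after the same alignment
  fr <- traj_frames(traj)
  ref <- fr[[1]]
  aligned <- lapply(fr, function(f)
    apply_transform(f, kabsch_align(f, ref, 1:4))[nodes, , drop = FALSE])
  n <- length(nodes)
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  oracle <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- mean(vapply(aligned, function(f)
      sum((f[i, ] - mean_xyz[i, ]) * (f[j, ] - mean_xyz[j, ])), 0))
    vi <- mean(vapply(aligned, function(f) sum((f[i, ] - mean_xyz[i, ])^2), 0))
    vj <- mean(vapply(aligned, function(f) sum((f[j, ] - mean_xyz[j, ])^2), 0))
    oracle[i, j] <- num / sqrt(vi * vj)
  }
  diag(oracle) <- 1
  expect_lt(max(abs(C - oracle)), 1e-10)
})

test_that("a zero-variance node is reported by index", {
  set.seed(44)
  frames <- lapply(1:12, function(i)
    rbind(c(20, 0, 0) + stats::rnorm(3, 0, 0.1), c(25, 0, 0)))
  # node 6 (the second probe) never moves
  expect_error(correlation_matrix(.make_traj(frames), 1:4, nodes = 5:6), "node 6")
  expect_error(correlation_matrix(.make_traj(frames[1:5]), 1:4, nodes = 5:6),
               ">= 10 frames")
})

test_that("contact mask thresholds on occupancy", {
  near <- rbind(c(0, 0, 0), c(3, 0, 0))
  far <- rbind(c(0, 0, 0), c(30, 0, 0))
  # pair in contact in 60% and another in 100% of frames
  frames <- c(rep(list(near), 6), rep(list(far), 4))
  traj <- as_trajectory(frames)
  expect_false(contact_mask(traj, cutoff = 8, occupancy = 0.75)[1, 2])
  expect_true(contact_mask(traj, cutoff = 8, occupancy = 0.5)[1, 2])
  expect_true(all(contact_mask(as_trajectory(rep(list(near), 4)), 8, 0.75)[1, 2]))
  # engineered occupancies 0.6 vs 0.8 against a hand count
  f2 <- c(rep(list(near), 8), rep(list(far), 2))
  expect_true(contact_mask(as_trajectory(f2), 8, 0.75)[1, 2])
  expect_false(contact_mask(as_trajectory(frames), 8, 0.75)[1, 2])
})

test_that("network construction validates inputs and weights", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.9
  C[2, 3] <- C[3, 2] <- -0.5
  C[3, 4] <- C[4, 3] <- 0.2
  M <- matrix(TRUE, 4, 4)
  net <- build_network(C, M)
  expect_true(all(net$edges$w >= 0))
  expect_false(any(net$edges$i == net$edges$j))
  # strongest edges sorted by |C| descending (anti-correlation counts)
  se <- strongest_edges(net, 2)
  expect_equal(se$c[1], 0.9)
  expect_equal(abs(se$c[2]), 0.5)
  expect_error(build_network(C + 0.5, M), "symmetric")
})

test_that("allosteric paths: chain, disconnection, brute-force oracle", {
  # chain with perfect correlations: path weight 0 along the chain
  n <- 4
  C <- diag(n); M <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) {
    C[i, i + 1] <- C[i + 1, i] <- 1
    M[i, i + 1] <- M[i + 1, i] <- TRUE
  }
  net <- build_network(C, M)
  p <- allosteric_path(net, 1, 4)
  expect_true(p$found)
  expect_identical(p$path, 1:4)
  expect_equal(p$weight, 0)

  # two components: explicit no-path result
  C2 <- diag(4); M2 <- matrix(FALSE, 4, 4)
  C2[1, 2] <- C2[2, 1] <- 0.8; M2[1, 2] <- M2[2, 1] <- TRUE
  C2[3, 4] <- C2[4, 3] <- 0.8; M2[3, 4] <- M2[4, 3] <- TRUE
  p2 <- allosteric_path(build_network(C2, M2), 1, 4)
  expect_false(p2$found)

  # 6-node random weighted graph vs exhaustive enumeration over simple paths
  set.seed(31)
  for (rep in 1:5) {
    n <- 6
    C <- diag(n)
    M <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.7) {
        C[i, j] <- C[j, i] <- stats::runif(1, 0.05, 0.99)
        M[i, j] <- M[j, i] <- TRUE
      }
    }
    net <- build_network(C, M)
    W <- matrix(Inf, n, n)
    for (r in seq_len(nrow(net$edges)))
      W[net$edges$i[r], net$edges$j[r]] <- W[net$edges$j[r], net$edges$i[r]] <- net$edges$w[r]
    best <- Inf
    enumerate <- function(path, cost) {
      u <- path[length(path)]
      if (u == n) { best <<- min(best, cost); return(invisible()) }
      for (v in setdiff(which(is.finite(W[u, ])), path))
        enumerate(c(path, v), cost + W[u, v])
    }
    enumerate(1L, 0)
    p <- allosteric_path(net, 1, n)
    if (is.finite(best)) {
      expect_true(p$found)
      expect_equal(p$weight, best, tolerance = 1e-12)
    } else {
      expect_false(p$found)
    }
  }
})

test_that("adding edges never lengthens the shortest path", {
  set.seed(41)
  n <- 6
  C <- diag(n); M <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) {  # start from a chain
    C[i, i + 1] <- C[i + 1, i] <- stats::runif(1, 0.2, 0.9)
    M[i, i + 1] <- M[i + 1, i] <- TRUE
  }
  w0 <- allosteric_path(build_network(C, M), 1, n)$weight
  C[1, 4] <- C[4, 1] <- 0.5; M[1, 4] <- M[4, 1] <- TRUE
  w1 <- allosteric_path(build_network(C, M), 1, n)$weight
  expect_lte(w1, w0 + 1e-12)
})

test_that("inter-bundle coupling score: perfect motion and block-diagonal limits", {
  tw <- fix_toy()
  s <- tw$structure
  n <- nrow(s$coords)
  # all-identical motion: every correlation 1 -> score 1
  C1 <- matrix(1, n, n)
  M1 <- matrix(TRUE, n, n); diag(M1) <- FALSE
  expect_equal(interbundle_coupling_score(build_network(C1, M1), s), 1)

  # independent bundles: exact zero cross-block correlations drop the edges,
  # leaving no qualifying edge -> score 0 with a warning
  b1 <- !is.na(s$atoms$bundle_id) & s$atoms$bundle_id == 1
  C0 <- matrix(0, n, n)
  C0[b1, b1] <- 0.8; C0[!b1, !b1] <- 0.8
  diag(C0) <- 1
  expect_warning(sc <- interbundle_coupling_score(build_network(C0, M1), s),
                 "no contact edges")
  expect_equal(sc, 0)
})

test_that("bundle-relative RMSD separates rigid rocking from internal distortion", {
  tw <- fix_toy()
  s <- tw$structure; r <- tw$refs

  # repeated reference: all zeros
  const <- as_trajectory(rep(list(r$of_coords), 4))
  expect_equal(bundle_relative_rmsd(const, s, r, 1, 2), rep(0, 4))

  # pure bundle-1 rocking frames: self-fit sees no internal distortion,
  # other-fit sees the full rigid displacement
  frames <- list(r$of_coords, r$if_coords, r$of_coords)
  tr <- as_trajectory(frames)
  self_fit <- bundle_relative_rmsd(tr, s, r, 1, 1)
  other_fit <- bundle_relative_rmsd(tr, s, r, 1, 2)
  expect_lt(max(self_fit), 1e-8)
  expect_gt(other_fit[2], 1)

  # superposition optimality on noisy frames: mean(self) <= mean(other)
  set.seed(19)
  noisy <- lapply(1:6, function(i)
    r$of_coords + matrix(stats::rnorm(length(r$of_coords), 0, 0.4), nrow(r$of_coords)))
  tn <- as_trajectory(noisy)
  expect_lte(mean(bundle_relative_rmsd(tn, s, r, 1, 1)),
             mean(bundle_relative_rmsd(tn, s, r, 1, 2)))
})

test_that("ensemble summaries have unit histogram mass and track references", {
  tw <- fix_toy()
  s <- tw$structure; r <- tw$refs
  b1 <- atom_indices(s, bundle = 1)
  specs <- list(rg = cv_spec("radius_of_gyration", b1))

  const <- as_trajectory(rep(list(r$of_coords), 5))
  es <- ensemble_summary(const, specs,
                         c(rg = radius_of_gyration(b1, r$of_coords)))
  expect_equal(es$cvs$rg$sd, 0)
  expect_equal(sum(es$cvs$rg$mass), 1)
  expect_equal(es$cvs$rg$abs_dev_from_ref, 0, tolerance = 1e-12)

  set.seed(23)
  noisy <- lapply(1:40, function(i)
    r$of_coords + matrix(stats::rnorm(length(r$of_coords), 0, 0.3), nrow(r$of_coords)))
  es2 <- ensemble_summary(as_trajectory(noisy), specs)
  expect_equal(sum(es2$cvs$rg$mass), 1, tolerance = 1e-12)
  expect_length(es2$cvs$rg$series, 40L)
  expect_gt(es2$cvs$rg$sd, 0)
})
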