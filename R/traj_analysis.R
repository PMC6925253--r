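#' Residue-residue dynamical correlation matrix
#'
#' After superposing every frame on `fit_group` (onto the first frame), the
#' normalized cross-correlation of the per-particle displacements from the
#' mean structure is \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j
#' \rangle / \sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta
#' r_j|^2\rangle}.} The diagonal is exactly 1. The ion row, when present, is
#' dropped: nodes are the protein C-alpha particles.
#'
#' @param traj a `cg_trajectory` with >= 10 frames.
#' @param fit_group alignment group (e.g. the held-fixed bundle, so that the
#'   rocking motion does not contaminate the fluctuations). Fit atoms may be
#'   excluded from `nodes`: a static anchor used only for alignment is fine.
#' @param nodes atom indices the correlation is computed over (default: all
#'   protein particles).
#' @return correlation matrix over `nodes` (row/column order follows
#'   `nodes`).
#' @export
correlation_matrix <- function(traj, fit_group, nodes = NULL) {
  frames <- traj_protein_frames(traj)
  if (length(frames) < 10L) stop("need >= 10 frames for a correlation matrix")
  ref <- frames[[1]]
  if (is.null(nodes)) nodes <- seq_len(nrow(ref))
  aligned <- lapply(frames, function(f)
    apply_transform(f, kabsch_align(f, ref, fit_group))[nodes, , drop = FALSE])
  n <- length(nodes)
  f <- length(aligned)
  flat <- vapply(aligned, function(x) as.numeric(x), numeric(3L * n))
  mu <- rowMeans(flat)
  dev <- flat - mu
  dx <- dev[seq_len(n), , drop = FALSE]
  dy <- dev[n + seq_len(n), , drop = FALSE]
  dz <- dev[2L * n + seq_len(n), , drop = FALSE]
  cov <- (dx %*% t(dx) + dy %*% t(dy) + dz %*% t(dz)) / f
  v <- diag(cov)
  if (any(v <= 1e-14)) {
    bad <- nodes[which(v <= 1e-14)[1]]
    stop(sprintf("node %d has zero displacement variance; correlation undefined", bad))
  }
  C <- cov / sqrt(outer(v, v))
  diag(C) <- 1
  C
}

#' Contact mask from trajectory occupancies
#'
#' `M[i, j]` is `TRUE` when particles i and j are within `cutoff` in at
#' least an `occupancy` fraction of frames.
#'
#' @param traj a `cg_trajectory` with >= 2 frames.
#' @param cutoff contact distance (model units).
#' @param occupancy minimal fraction of frames in contact.
#' @return symmetric logical matrix (diagonal `FALSE`).
#' @export
contact_mask <- function(traj, cutoff = 8.0, occupancy = 0.75) {
  frames <- traj_protein_frames(traj)
  if (length(frames) < 2L) stop("need >= 2 frames for a contact mask")
  n <- nrow(frames[[1]])
  acc <- matrix(0, n, n)
  for (f in frames) acc <- acc + (as.matrix(stats::dist(f)) <= cutoff)
  M <- acc / length(frames) >= occupancy
  diag(M) <- FALSE
  M
}

#' Build the contact-filtered correlation network
#'
#' Edges connect contact pairs (`M[i, j]` true, i != j) and carry weights
#' \eqn{w_{ij} = -\ln |C_{ij}|}, so strong (anti)correlation means short
#' edges; using `|C|` lets anti-correlated pairs couple too. Contact pairs
#' with `C_ij == 0` would have infinite weight and are dropped.
#'
#' @param C correlation matrix (symmetric, unit diagonal, entries in
#'   `[-1, 1]`).
#' @param M logical contact mask.
#' @return a `correlation_network`: the matrices, an edge data frame
#'   (i, j, c, w) and an [igraph][igraph::graph_from_data_frame] graph.
#' @export
build_network <- function(C, M) {
  n <- nrow(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)) || any(abs(C) > 1 + 1e-8))
    stop("C must be symmetric with entries in [-1, 1]")
  if (any(dim(M) != dim(C))) stop("contact mask does not match C")
  idx <- which(M & upper.tri(M), arr.ind = TRUE)
  cvals <- C[idx]
  keep <- abs(cvals) > 0
  edges <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                      c = cvals[keep], w = -log(pmin(1, abs(cvals[keep]))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j, weight = edges$w),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  structure(list(C = C, M = M, edges = edges, graph = g, n = n),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Strongest correlation edges of a network
#'
#' @param net a `correlation_network`.
#' @param k number of edges.
#' @return edge data frame sorted by `|c|` descending.
#' @export
strongest_edges <- function(net, k = 10L) {
  e <- net$edges
  e <- e[order(-abs(e$c), e$i, e$j), ]
  utils::head(e, k)
}

#' Shortest (allosteric) path between two nodes
#'
#' Dijkstra shortest path under the `-ln|C|` edge weights, with
#' deterministic tie-breaking: among equal-cost relaxations the smaller
#' predecessor node index wins, so repeated calls give the same path.
#'
#' @param net a `correlation_network`.
#' @param from,to node indices.
#' @return list with `found`, `path` (node vector, empty when disconnected)
#'   and `weight`.
#' @export
allosteric_path <- function(net, from, to) {
  n <- net$n
  adj <- vector("list", n)
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$i[r]; j <- net$edges$j[r]; w <- net$edges$w[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  dist <- rep(Inf, n); prev <- rep(NA_integer_, n); done <- rep(FALSE, n)
  dist[from] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]  # which.min takes the first = smallest index
    done[u] <- TRUE
    if (u == to) break
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
        nd <- dist[u] + w
        if (nd < dist[v] - 1e-15 ||
            (abs(nd - dist[v]) <= 1e-15 && !is.na(prev[v]) && u < prev[v])) {
          dist[v] <- nd; prev[v] <- u
        }
      }
    }
  }
  if (!is.finite(dist[to])) return(list(found = FALSE, path = integer(0), weight = Inf))
  path <- as.integer(to)
  while (path[1] != from) path <- c(prev[path[1]], path)
  list(found = TRUE, path = path, weight = dist[to])
}

#' Inter-bundle coupling score
#'
#' Mean `|C_ij|` over contact edges whose endpoints lie on the ion-site
#' bearing helices of *different* bundles (the TM1/TM8 analogues). Reported
#' per condition, the bound-vs-apo contrast quantifies how ion binding
#' couples the motion of the two bundles.
#'
#' @param net a `correlation_network`.
#' @param structure the `toy_structure`.
#' @return scalar score in `[0, 1]`; 0 with a warning when no contact edge
#'   qualifies.
#' @export
interbundle_coupling_score <- function(net, structure) {
  tm8 <- structure$meta$site_helices[["moving"]]
  tm1 <- structure$meta$site_helices[["fixed"]]
  a <- atom_indices(structure, helix = tm8)
  b <- atom_indices(structure, helix = tm1)
  e <- net$edges
  qual <- (e$i %in% a & e$j %in% b) | (e$i %in% b & e$j %in% a)
  if (!any(qual)) {
    warning("no contact edges between the site helices of the two bundles; score 0")
    return(0)
  }
  mean(abs(e$c[qual]))
}

#' Bundle-relative RMSD series
#'
#' Per-frame RMSD of one bundle against a reference after superposing either
#' on the other bundle (reporting rigid-body motion of the bundles relative
#' to each other) or on the bundle itself (reporting internal distortion
#' only). By superposition optimality the self-fit series mean never exceeds
#' the other-fit mean.
#'
#' @param traj a `cg_trajectory`.
#' @param structure the `toy_structure`.
#' @param refs the `reference_pair`.
#' @param measure_bundle bundle whose RMSD is measured (1 or 2).
#' @param fit_bundle bundle used for superposition.
#' @param ref_state reference state, `"of"` or `"if"`.
#' @return numeric vector, one RMSD per frame.
#' @export
bundle_relative_rmsd <- function(traj, structure, refs, measure_bundle = 1L,
                                 fit_bundle = 2L, ref_state = c("of", "if")) {
  ref_state <- match.arg(ref_state)
  ref <- if (ref_state == "of") refs$of_coords else refs$if_coords
  m_idx <- atom_indices(structure, bundle = measure_bundle)
  f_idx <- atom_indices(structure, bundle = fit_bundle)
  vapply(traj_protein_frames(traj), function(f) rmsd(f, ref, m_idx, f_idx), 0)
}

#' Ensemble summary of collective variables over a trajectory
#'
#' Per CV: the frame-by-frame series, mean, standard deviation, a
#' unit-mass histogram (Freedman-Diaconis bin rule, fixed so outputs are
#' reproducible) and the absolute deviation of the ensemble mean from a
#' reference value when one is supplied.
#'
#' @param traj a `cg_trajectory`.
#' @param cv_specs named list of [cv_spec()]s.
#' @param reference_values optional named numeric of reference overlays.
#' @param condition optional condition label carried into the summary.
#' @return an `ensemble_summary` (named list, one entry per CV).
#' @export
ensemble_summary <- function(traj, cv_specs, reference_values = NULL,
                             condition = NA_character_) {
  frames <- traj_frames(traj)
  out <- lapply(names(cv_specs), function(nm) {
    series <- vapply(frames, function(f) evaluate_cv(cv_specs[[nm]], f), 0)
    if (stats::sd(series) == 0) {
      breaks <- series[1] + c(-0.5, 0.5)
      mass <- 1
    } else {
      h <- graphics::hist(series, breaks = "FD", plot = FALSE)
      breaks <- h$breaks
      mass <- h$counts / sum(h$counts)
    }
    ref <- if (!is.null(reference_values) && nm %in% names(reference_values))
      reference_values[[nm]] else NA_real_
    list(series = series, mean = mean(series), sd = stats::sd(series),
         breaks = breaks, mass = mass, reference = ref,
         abs_dev_from_ref = if (is.na(ref)) NA_real_ else abs(mean(series) - ref))
  })
  names(out) <- names(cv_specs)
  structure(list(cvs = out, condition = condition,
                 n_frames = length(frames)), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary (%s), %d frames:\n",
              x$condition, x$n_frames))
  for (nm in names(x$cvs)) {
    cv <- x$cvs[[nm]]
    cat(sprintf("  %s: mean %.3f sd %.3f%s\n", nm, cv$mean, cv$sd,
                if (is.na(cv$reference)) "" else
                  sprintf(" |mean - ref| %.3f", cv$abs_dev_from_ref)))
  }
  invisible(x)
}
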