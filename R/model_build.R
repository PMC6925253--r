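#' Build the coarse two-bundle transporter and its OF/IF reference pair
#'
#' Constructs a C-alpha-level toy transporter with the architecture shared by
#' LeuT-fold carriers: two helical bundles related by a pseudo-two-fold axis,
#' an ion pseudo-particle bound at the bundle interface, cytoplasmic and
#' periplasmic gating residues, and a pair of substrate-site distance probes.
#' The outward-facing (OF) reference is the as-built geometry; the
#' inward-facing (IF) reference is generated by a rigid-body rocking rotation
#' of bundle 1 (the moving bundle) about an in-plane axis through the protein
#' center while bundle 2 is held fixed.
#'
#' Each bundle carries one "site helix" placed close to the central axis (the
#' TM8 analogue on bundle 1, the TM1 analogue on bundle 2); the five ion-site
#' atoms sit on these two helices (3 + 2, mirroring the two-helix composition
#' of the Na2 site) and all lie within `site_radius` of the ion position in
#' the OF reference. Gate tag sets are chosen as the most inward-facing
#' residues in the bottom (cytoplasmic) and top (periplasmic) thirds of the
#' site helices, so that the rocking closes the periplasmic gate and opens
#' the cytoplasmic one. Loops between consecutive helices of a bundle are
#' represented by jittered particles that belong to no bundle.
#'
#' @param n_helices_per_bundle integer >= 2, helices per bundle.
#' @param residues_per_helix integer >= 6, C-alpha beads per helix.
#' @param rocking_angle_deg positive rotation (degrees) taking OF to IF.
#' @param seed integer seed controlling the loop jitter.
#' @param site_radius maximal OF distance (model units) between the ion and
#'   any of the five site atoms.
#' @param pivot_height z position of the rocking axis (model units above the
#'   membrane midplane); the axis runs along y through `(0, 0, pivot_height)`.
#'   Axes further above the ion site break the site open more strongly along
#'   the transition. The default (`NULL`) places the axis 1.9 model units
#'   below the periplasmic helix ends (2.5 for the default 12-residue
#'   helices), which keeps both gates responsive to the rocking while the
#'   site opens substantially.
#' @return a list with elements `structure` (a `toy_structure`) and
#'   `refs` (a `reference_pair`).
#' @examples
#' tw <- build_toy_transporter(2, 10, 25, seed = 1)
#' table(tw$structure$atoms$role)
#' @export
build_toy_transporter <- function(n_helices_per_bundle = 2L,
                                  residues_per_helix = 12L,
                                  rocking_angle_deg = 25,
                                  seed = 1L,
                                  site_radius = 3.0,
                                  pivot_height = NULL) {
  H <- as.integer(n_helices_per_bundle)
  R <- as.integer(residues_per_helix)
  if (H < 2L) stop("n_helices_per_bundle must be >= 2")
  if (R < 6L) stop("residues_per_helix must be >= 6")
  if (rocking_angle_deg < 0) stop("rocking_angle_deg must be non-negative")

  # geometry constants (model length units, "Angstrom-like")
  helix_radius <- 1.6   # C-alpha wiggle radius about the helix axis
  rise <- 0.8           # rise per residue
  twist <- 100          # degrees per residue
  r_site <- 3.2         # axis radius of the two central site helices
  r_outer <- 9.0        # axis radius of the peripheral helices
  min_clearance <- 2.2  # build-time lower bound on pairwise distances

  # helix axis placements: helix 1 of each bundle is the site helix; bundle 2
  # is bundle 1 rotated by 180 degrees about z (pseudo-two-fold)
  az1 <- if (H == 2L) 0 else seq(-60, 60, length.out = H - 1L)
  hel <- data.frame(
    helix_id = seq_len(2L * H),
    bundle_id = rep(1:2, each = H),
    azimuth = c(0, az1, 180, az1 + 180),
    axis_radius = rep(c(r_site, rep(r_outer, H - 1L)), 2L)
  )

  site_res_moving <- max(1L, floor(R / 2) - 2L)  # i, i+3, i+4 pattern
  # phase so that the first site residue points inward (toward the z axis)
  hel$phase0 <- (hel$azimuth + 180) - (site_res_moving - 1L) * twist

  half_len <- (R - 1L) * rise / 2
  if (is.null(pivot_height)) pivot_height <- max(0, half_len - 1.9)
  ideal_helix <- function(h) {
    j <- seq_len(R) - 1L
    ang <- (h$phase0 + j * twist) * pi / 180
    cx <- h$axis_radius * cos(h$azimuth * pi / 180)
    cy <- h$axis_radius * sin(h$azimuth * pi / 180)
    cbind(cx + helix_radius * cos(ang),
          cy + helix_radius * sin(ang),
          j * rise - half_len)
  }

  coords <- do.call(rbind, lapply(seq_len(nrow(hel)), function(k) ideal_helix(hel[k, ])))
  atoms <- data.frame(
    index = seq_len(2L * H * R),
    residue_id = seq_len(2L * H * R),
    helix_id = rep(hel$helix_id, each = R),
    bundle_id = rep(hel$bundle_id, each = R),
    role = "plain",
    stringsAsFactors = FALSE
  )

  # loop particles: 2 between the helix tops of consecutive helices of a
  # bundle, jittered; bundle "none" (NA), not rotated into the IF reference
  set.seed(as.integer(seed))
  loop_xyz <- NULL
  loop_parent <- integer(0)  # bundle whose helices the loop bridges
  for (b in 1:2) {
    hb <- hel$helix_id[hel$bundle_id == b]
    for (k in seq_len(length(hb) - 1L)) {
      a_top <- coords[max(atoms$index[atoms$helix_id == hb[k]]), ]
      b_top <- coords[max(atoms$index[atoms$helix_id == hb[k + 1L]]), ]
      for (f in c(1 / 3, 2 / 3)) {
        p <- (1 - f) * a_top + f * b_top
        p[3] <- p[3] + 1.4
        loop_xyz <- rbind(loop_xyz, p + stats::rnorm(3, 0, 0.35))
        loop_parent <- c(loop_parent, b)
      }
    }
  }
  n_hel_atoms <- nrow(coords)
  n_loops <- if (is.null(loop_xyz)) 0L else nrow(loop_xyz)
  if (n_loops > 0L) {
    coords <- rbind(coords, loop_xyz)
    atoms <- rbind(atoms, data.frame(
      index = n_hel_atoms + seq_len(n_loops),
      residue_id = n_hel_atoms + seq_len(n_loops),
      helix_id = NA_integer_, bundle_id = NA_integer_,
      role = "plain", stringsAsFactors = FALSE
    ))
  }
  rownames(coords) <- NULL

  # deterministic clearance fix-up: push loop particles away from any
  # too-close neighbour so the OF reference has zero excluded-volume energy
  for (it in seq_len(50L)) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    bad <- which(d < min_clearance, arr.ind = TRUE)
    bad <- bad[bad[, 1] > n_hel_atoms & bad[, 1] > bad[, 2], , drop = FALSE]
    if (nrow(bad) == 0L) break
    i <- bad[1, 1]; j <- bad[1, 2]
    u <- coords[i, ] - coords[j, ]
    u <- u / sqrt(sum(u^2))
    coords[i, ] <- coords[j, ] + u * (min_clearance + 0.1)
  }

  helix_atom_idx <- function(h) atoms$index[!is.na(atoms$helix_id) & atoms$helix_id == h]
  tm8 <- 1L            # moving site helix (bundle 1)
  tm1 <- H + 1L        # fixed site helix (bundle 2)

  # ion-binding site: i, i+3, i+4 on the moving helix; i, i+3 on the fixed
  # (one-turn spacings keep all five C-alphas on the interface-facing side)
  m <- site_res_moving
  if (m + 4L > R) m <- R - 4L
  site_local <- list(c(m, m + 3L, m + 4L), c(m, m + 3L))
  na_site <- c(helix_atom_idx(tm8)[site_local[[1]]], helix_atom_idx(tm1)[site_local[[2]]])
  atoms$role[na_site] <- "na_site"

  # ion position: minimax distance to the five site atoms
  site_xyz <- coords[na_site, , drop = FALSE]
  obj <- function(p) max(sqrt(rowSums(sweep(site_xyz, 2, p)^2)))
  opt <- stats::optim(colMeans(site_xyz), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  ion_pos <- unname(opt$par)
  if (obj(ion_pos) > site_radius)
    stop(sprintf("ion-site construction failed: max OF site distance %.3f > site radius %.3f",
                 obj(ion_pos), site_radius))
  if (min(sqrt(rowSums(sweep(coords, 2, ion_pos)^2))) < 2.0)
    stop("ion-site construction failed: ion clashes with a protein particle")

  # gates: most inward-facing residues of the bottom (cyto) / top (peri)
  # thirds of the two site helices (2 on the moving helix, 1 on the fixed)
  rho <- sqrt(coords[, 1]^2 + coords[, 2]^2)
  pick_inward <- function(h, zone, n, used) {
    idx <- helix_atom_idx(h)
    for (width in c(max(2L, ceiling(R / 3)), ceiling(R / 2), R)) {
      zone_idx <- if (zone == "bottom") idx[seq_len(width)] else idx[(R - width + 1L):R]
      cand <- setdiff(zone_idx, used)
      if (length(cand) >= n) return(cand[order(rho[cand])][seq_len(n)])
    }
    stop("geometric failure: not enough untagged residues on a site helix")
  }
  used <- na_site
  cyto <- c(pick_inward(tm8, "bottom", 2L, used), pick_inward(tm1, "bottom", 1L, used))
  used <- c(used, cyto)
  peri <- c(pick_inward(tm8, "top", 2L, used), pick_inward(tm1, "top", 1L, used))
  used <- c(used, peri)
  atoms$role[cyto] <- "cyto_gate"
  atoms$role[peri] <- "peri_gate"

  # substrate-site probes: two cross-bundle pairs on the site helices just
  # above the ion site — the toy's core, where ion binding holds the
  # geometry; pairing with the peripheral helices would probe the floppy
  # rim. Short helices can exhaust a site helix's untagged residues, in
  # which case the probe falls back to the next helix of the same bundle.
  pick_sub <- function(bundle, used) {
    helices <- c(if (bundle == 1L) tm8 else tm1,
                 setdiff(hel$helix_id[hel$bundle_id == bundle],
                         c(tm8, tm1)))
    for (h in helices) {
      res <- tryCatch(pick_inward(h, "top", 1L, used), error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    stop("geometric failure: no residue available for a substrate probe")
  }
  sub1 <- c(pick_sub(1L, used), pick_sub(2L, used))
  used <- c(used, sub1)
  sub2 <- c(pick_sub(1L, used), pick_sub(2L, used))
  used <- c(used, sub2)
  atoms$role[c(sub1, sub2)] <- "substrate_site"

  # IF reference: rotate bundle-1 helix atoms about a y-direction axis
  # passing just above the ion site, so the periplasmic ends of the moving
  # bundle swing toward bundle 2 (outward lumen closes), the cytoplasmic
  # ends swing away (inward lumen opens), and the ion site itself is pulled
  # apart (site breakage along the transition)
  z_pivot <- pivot_height
  ang <- -rocking_angle_deg * pi / 180
  Ry <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)),
               3, 3, byrow = TRUE)
  # moving set: bundle-1 helix atoms plus the loop particles bridging
  # bundle-1 helices (they ride along, but keep bundle tag "none")
  moving <- !is.na(atoms$bundle_id) & atoms$bundle_id == 1L
  if (n_loops > 0L)
    moving[n_hel_atoms + which(loop_parent == 1L)] <- TRUE
  pivot <- c(0, 0, z_pivot)
  if_coords <- coords
  if (rocking_angle_deg > 0)  # identity rocking leaves the references equal
    if_coords[moving, ] <- sweep(sweep(coords[moving, , drop = FALSE], 2, pivot) %*% t(Ry),
                                 2, -pivot)

  structure <- structure(list(
    atoms = atoms,
    coords = coords,
    ion = list(present = TRUE, position = ion_pos),
    meta = list(
      n_helices_per_bundle = H, residues_per_helix = R,
      site_helices = c(moving = tm8, fixed = tm1),
      substrate_pairs = list(sub1, sub2),
      helices = hel, rise = rise, helix_radius = helix_radius,
      min_clearance = min_clearance, seed = as.integer(seed),
      loop_parent = loop_parent,
      n_helix_atoms = n_hel_atoms, n_loop_particles = n_loops
    )
  ), class = "toy_structure")

  refs <- structure(list(
    of_coords = coords, if_coords = if_coords,
    axis = c(0, -1, 0), angle_deg = rocking_angle_deg,
    axis_point = pivot
  ), class = "reference_pair")

  # construction postcondition: gate radii of gyration must order correctly
  # (periplasmic lumen closes, cytoplasmic lumen opens) unless degenerate
  if (rocking_angle_deg > 0) {
    rg <- function(x, idx) {
      xc <- sweep(x[idx, , drop = FALSE], 2, colMeans(x[idx, , drop = FALSE]))
      sqrt(sum(xc^2) / length(idx))
    }
    ok <- rg(if_coords, cyto) > rg(coords, cyto) && rg(if_coords, peri) < rg(coords, peri)
    if (!ok)
      stop("geometric failure: gate radius-of-gyration ordering not satisfied; model unusable for completion detection")
  }

  list(structure = structure, refs = refs)
}

#' Atom indices of a structure by role, helix, or bundle
#'
#' @param structure a `toy_structure`.
#' @param role,helix,bundle optional filters; non-NULL filters are combined.
#' @return integer atom indices.
#' @export
atom_indices <- function(structure, role = NULL, helix = NULL, bundle = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(helix)) keep <- keep & !is.na(a$helix_id) & a$helix_id %in% helix
  if (!is.null(bundle)) keep <- keep & !is.na(a$bundle_id) & a$bundle_id %in% bundle
  a$index[keep]
}

#' Split a helix into extracellular / intracellular segments
#'
#' The helix residue list is split evenly, with the extra residue assigned to
#' the extracellular (periplasmic, high-z) half.
#'
#' @param structure a `toy_structure`.
#' @param helix helix id.
#' @param segment `"e"` (extracellular) or `"i"` (intracellular).
#' @return integer atom indices of the segment.
#' @export
helix_segment <- function(structure, helix, segment = c("e", "i")) {
  segment <- match.arg(segment)
  idx <- atom_indices(structure, helix = helix)
  n <- length(idx)
  n_e <- ceiling(n / 2)
  if (segment == "e") idx[(n - n_e + 1L):n] else idx[seq_len(n - n_e)]
}

#' @export
print.toy_structure <- function(x, ...) {
  cat(sprintf("toy_structure: %d particles (%d helix, %d loop), %d helices, ion %s\n",
              nrow(x$atoms), x$meta$n_helix_atoms, x$meta$n_loop_particles,
              2L * x$meta$n_helices_per_bundle,
              if (x$ion$present) "present" else "absent"))
  print(table(x$atoms$role))
  invisible(x)
}
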