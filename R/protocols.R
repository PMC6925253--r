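#' Steering-protocol catalogue for the OF to IF transition
#'
#' Builds the biasing protocols explored for the rocking transition,
#' analogous to driving different structural elements of the two ion-site
#' helices (the TM1/TM8 analogues):
#'
#' * `d_theta` — the two ion-site C-alpha pair distances plus the four
#'   per-segment orientation angles of the two site helices (TM8e, TM8i,
#'   TM1e, TM1i). The distance schedules run from their OF to their IF
#'   values; each orientation schedule runs from 0 to the angle that segment
#'   turns through in the IF reference.
#' * `theta_only` — the four orientation angles alone (no distance drive).
#' * `d_only` — the two ion-site distances alone.
#' * `rmsd_18` — RMSD of the two site helices to the IF reference, driven
#'   from its OF value to 0 (superposed on the driven atoms).
#' * `rg_theta` — radius of gyration of the five ion-site atoms plus the
#'   four orientation angles.
#'
#' Orientation CVs measure the rotation-angle magnitude of a segment away
#' from its OF reference. The angle fixes how far a segment has turned but
#' not about which axis, so an orientation-only drive can be satisfied by
#' local compliance that never carries the bundle into the IF basin — which
#' is exactly the failure mode that distinguishes the protocols. Each
#' protocol ends with a restrained hold at the final centers and a
#' bias-free relaxation segment, over which completion is judged.
#'
#' @param structure a `toy_structure`.
#' @param refs the matching `reference_pair`.
#' @param duration steering steps.
#' @param hold post-steering restrained hold steps.
#' @param relax post-hold unrestrained relaxation steps.
#' @param k_dist,k_theta,k_rmsd,k_rg force constants (reduced energy per
#'   squared CV unit; degrees for orientation angles). The distance drive
#'   must out-pull the k = 200 ion restraints for the ion-bound arm, hence
#'   the stiff default.
#' @param which protocol names to build (default all).
#' @return named list of `steering_protocol`s.
#' @export
protocol_catalog <- function(structure, refs, duration = 20000L, hold = 36000L,
                             relax = 12000L,
                             k_dist = 300, k_theta = 0.3, k_rmsd = 15, k_rg = 300,
                             which = c("d_theta", "theta_only", "d_only",
                                       "rmsd_18", "rg_theta")) {
  tm8 <- structure$meta$site_helices[["moving"]]
  tm1 <- structure$meta$site_helices[["fixed"]]
  of <- refs$of_coords
  ifc <- refs$if_coords

  site8 <- intersect(atom_indices(structure, role = "na_site"),
                     atom_indices(structure, helix = tm8))
  site1 <- intersect(atom_indices(structure, role = "na_site"),
                     atom_indices(structure, helix = tm1))

  # the ion-site "distance" is two C-alpha pair distances spanning the site
  # (low pair and high pair), which pin the relative placement of the two
  # site helices, not just their mean separation
  d_specs <- list(
    site_d1 = cv_spec("com_distance", site8[1], group_b = site1[1],
                      name = "site_d1"),
    site_d2 = cv_spec("com_distance", site8[2], group_b = site1[2],
                      name = "site_d2"))
  d_terms <- lapply(d_specs, function(sp)
    list(spec = sp, start = evaluate_cv(sp, of),
         end = evaluate_cv(sp, ifc), k = k_dist))

  theta_specs <- list()
  for (h in c(tm8, tm1)) {
    for (seg in c("e", "i")) {
      idx <- helix_segment(structure, h, seg)
      theta_specs[[sprintf("theta_h%d%s", h, seg)]] <-
        cv_spec("orientation_angle", idx, ref = of,
                name = sprintf("theta_h%d%s", h, seg))
    }
  }
  theta_terms <- lapply(names(theta_specs), function(nm) {
    sp <- theta_specs[[nm]]
    list(spec = sp, start = 0,
         end = orientation_angle(sp$group, ifc, of), k = k_theta)
  })

  helix18 <- c(atom_indices(structure, helix = tm8), atom_indices(structure, helix = tm1))
  rmsd_spec <- cv_spec("rmsd", helix18, ref = ifc, name = "rmsd_to_if")
  rmsd_term <- list(spec = rmsd_spec, start = evaluate_cv(rmsd_spec, of),
                    end = 0, k = k_rmsd)

  site_all <- atom_indices(structure, role = "na_site")
  rg_spec <- cv_spec("radius_of_gyration", site_all, name = "site_rg")
  rg_term <- list(spec = rg_spec, start = evaluate_cv(rg_spec, of),
                  end = evaluate_cv(rg_spec, ifc), k = k_rg)

  catalog <- list(
    d_theta = steering_protocol(c(d_terms, theta_terms),
                                duration, hold, relax, name = "d_theta"),
    theta_only = steering_protocol(theta_terms, duration, hold, relax,
                                   name = "theta_only"),
    d_only = steering_protocol(d_terms, duration, hold, relax, name = "d_only"),
    rmsd_18 = steering_protocol(list(rmsd_term), duration, hold, relax,
                                name = "rmsd_18"),
    rg_theta = steering_protocol(c(list(rg_term), theta_terms),
                                 duration, hold, relax, name = "rg_theta")
  )
  catalog[which]
}
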