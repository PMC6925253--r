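#' Build the double-basin elastic-network energy model
#'
#' The potential is
#' \deqn{V(x) = -\frac{1}{\beta}\ln\left(e^{-\beta V_{OF}(x)} + e^{-\beta V_{IF}(x)}\right)
#'  + V_{excl}(x) + V_{ion}(x)}
#' where each basin term is a harmonic elastic network built on that basin's
#' reference (springs between particle pairs within `enm_cutoff`, rest
#' lengths equal to the reference distances, so each basin is exactly zero at
#' its own reference), \eqn{V_{excl}} is a soft pairwise repulsion active
#' below `r_excl`, and \eqn{V_{ion}} comprises five harmonic distance
#' restraints between the ion pseudo-particle and the five ion-site atoms
#' with rest lengths taken from the OF reference. The mixing parameter
#' `beta_mix` controls the barrier between the basins. All terms depend only
#' on interparticle distances, so the energy is invariant under global rigid
#' motion.
#'
#' Simulation coordinates for a bound model are the protein coordinates with
#' the ion appended as the last row (see [start_coords()]).
#'
#' @param structure a `toy_structure`.
#' @param refs the matching `reference_pair`.
#' @param enm_cutoff spring cutoff (model units).
#' @param k_spring elastic-network spring constant (reduced energy / length^2).
#' @param beta_mix basin-mixing parameter (> 0); larger values sharpen the
#'   basin switch and raise the barrier.
#' @param k_ion ion-restraint force constant; the default 200 echoes the
#'   restraint stiffness used for the Na2 site in atomistic work, as a label
#'   in reduced units.
#' @param r_excl soft excluded-volume radius; 0 disables the term.
#' @param k_excl excluded-volume stiffness.
#' @param ion logical; `TRUE` builds the ion-bound model (ion particle plus
#'   restraints), `FALSE` the apo model (no ion particle at all).
#' @return an `energy_model`.
#' @export
build_energy_model <- function(structure, refs, enm_cutoff = 8, k_spring = 1,
                               beta_mix = 2, k_ion = 200, r_excl = 2.0,
                               k_excl = 25, ion = structure$ion$present) {
  stopifnot(inherits(structure, "toy_structure"), inherits(refs, "reference_pair"))
  if (!all(dim(refs$of_coords) == dim(structure$coords)) ||
      !all(dim(refs$if_coords) == dim(structure$coords)))
    stop("reference pair is not congruent with the structure")
  if (enm_cutoff <= 0 || k_spring <= 0 || beta_mix <= 0 || k_ion < 0)
    stop("enm_cutoff, k_spring, beta_mix must be positive and k_ion non-negative")

  pair_list <- function(x, cutoff) {
    d <- as.matrix(stats::dist(x))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    list(pairs = cbind(idx[, 1], idx[, 2]), r0 = d[idx])
  }
  pof <- pair_list(refs$of_coords, enm_cutoff)
  pif <- pair_list(refs$if_coords, enm_cutoff)
  if (any(pof$r0 <= 0) || any(pif$r0 <= 0))
    stop("degenerate reference: coincident particles produce zero rest lengths")

  # each bundle must form a connected spring network in both basins
  for (b in 1:2) {
    idx <- atom_indices(structure, bundle = b)
    for (pl in list(pof, pif)) {
      keep <- pl$pairs[, 1] %in% idx & pl$pairs[, 2] %in% idx
      g <- igraph::graph_from_edgelist(
        matrix(match(as.vector(t(pl$pairs[keep, , drop = FALSE])), idx), ncol = 2, byrow = TRUE),
        directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
      if (igraph::components(g)$no != 1L)
        stop(sprintf("enm_cutoff %.2f leaves the spring network of bundle %d disconnected", enm_cutoff, b))
    }
  }

  n_protein <- nrow(structure$coords)
  site <- atom_indices(structure, role = "na_site")
  ion_r0 <- if (ion) sqrt(rowSums(sweep(refs$of_coords[site, , drop = FALSE],
                                        2, structure$ion$position)^2)) else numeric(0)

  structure(list(
    pairs_of = pof$pairs, r0_of = pof$r0,
    pairs_if = pif$pairs, r0_if = pif$r0,
    k_spring = k_spring, beta_mix = beta_mix,
    r_excl = r_excl, k_excl = k_excl,
    k_ion = if (ion) k_ion else 0,
    ion = ion,
    ion_row = if (ion) n_protein + 1L else 0L,
    site_rows = site, ion_r0 = ion_r0,
    n_protein = n_protein,
    n_particles = n_protein + as.integer(ion),
    enm_cutoff = enm_cutoff
  ), class = "energy_model")
}

.enm_list <- function(model) {
  list(pairs_of = model$pairs_of, r0_of = model$r0_of,
       pairs_if = model$pairs_if, r0_if = model$r0_if,
       k_spring = model$k_spring, beta_mix = model$beta_mix,
       r_excl = model$r_excl, k_excl = model$k_excl,
       k_ion = model$k_ion, ion_row = model$ion_row,
       site_rows = if (model$ion) model$site_rows else integer(0),
       ion_r0 = model$ion_r0)
}

#' Evaluate the model energy and its components
#'
#' @param model an `energy_model`.
#' @param coords simulation coordinates (`model$n_particles` x 3; the ion is
#'   the last row for a bound model).
#' @return list with `total`, `of`, `if`, `mix`, `excl`, `ion` energies.
#' @export
model_energy <- function(model, coords) {
  stopifnot(inherits(model, "energy_model"))
  if (nrow(coords) != model$n_particles)
    stop(sprintf("coords must have %d rows (ion last when bound)", model$n_particles))
  cg_energy(coords, .enm_list(model))
}

#' Gradient of the model energy
#'
#' @inheritParams model_energy
#' @return `n_particles` x 3 matrix of dV/dx.
#' @export
model_gradient <- function(model, coords) {
  stopifnot(inherits(model, "energy_model"))
  cg_gradient(coords, .enm_list(model))
}

#' Simulation start coordinates for a reference state
#'
#' Returns the protein coordinates of the requested reference with, for a
#' bound model, the ion appended as the last row at its OF binding position.
#'
#' @param model an `energy_model`.
#' @param structure the `toy_structure` the model was built from.
#' @param refs the matching `reference_pair`.
#' @param state `"of"` or `"if"`.
#' @return `n_particles` x 3 coordinate matrix.
#' @export
start_coords <- function(model, structure, refs, state = c("of", "if")) {
  state <- match.arg(state)
  x <- if (state == "of") refs$of_coords else refs$if_coords
  if (model$ion) x <- rbind(x, structure$ion$position)
  unname(as.matrix(x))
}

#' Free-particle energy model
#'
#' An energy model with no springs, no excluded volume and no ion term; every
#' particle diffuses freely. Used to validate the integrator, the bias-work
#' bookkeeping and the Jarzynski estimator on analytically solvable systems
#' (e.g. a dragged harmonic trap).
#'
#' @param n_particles number of free particles.
#' @return an `energy_model`.
#' @export
free_particle_model <- function(n_particles) {
  structure(list(
    pairs_of = matrix(integer(0), 0, 2), r0_of = numeric(0),
    pairs_if = matrix(integer(0), 0, 2), r0_if = numeric(0),
    k_spring = 1, beta_mix = 1, r_excl = 0, k_excl = 0,
    k_ion = 0, ion = FALSE, ion_row = 0L,
    site_rows = integer(0), ion_r0 = numeric(0),
    n_protein = as.integer(n_particles),
    n_particles = as.integer(n_particles),
    enm_cutoff = 0
  ), class = "energy_model")
}
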