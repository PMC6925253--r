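#' Construct a trajectory object
#'
#' @param frames list of N x 3 coordinate matrices, or an N x 3 x F array.
#' @param dt integration timestep (reduced time units).
#' @param stride save stride in steps.
#' @param seed RNG seed the frames were generated with (NA if synthetic).
#' @param ion_present logical; when `TRUE` the last row of each frame is the
#'   ion pseudo-particle.
#' @param frame_steps integer step index of each frame (0 = initial state).
#' @param provenance free-form provenance list.
#' @return a `cg_trajectory`.
#' @export
as_trajectory <- function(frames, dt = 0.002, stride = 1L, seed = NA_integer_,
                          ion_present = FALSE, frame_steps = NULL,
                          provenance = list()) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of coordinate matrices")
  n <- nrow(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L || !all(is.finite(f)))
      stop("all frames must be finite N x 3 matrices with constant N")
  }
  if (is.null(frame_steps)) frame_steps <- (seq_along(frames) - 1L) * as.integer(stride)
  structure(list(frames = frames, frame_steps = as.integer(frame_steps),
                 dt = dt, stride = as.integer(stride), seed = seed,
                 ion_present = isTRUE(ion_present), provenance = provenance),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames x %d particles, dt = %g, stride = %d, ion %s\n",
              n_frames(x), nrow(x$frames[[1]]), x$dt, x$stride,
              if (x$ion_present) "present" else "absent"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' List of coordinate frames
#' @param traj a `cg_trajectory`.
#' @export
traj_frames <- function(traj) traj$frames

#' Single coordinate frame
#' @param traj a `cg_trajectory`.
#' @param i frame number (1-based).
#' @export
traj_frame <- function(traj, i) traj$frames[[i]]

#' Protein-only frames (ion row dropped)
#' @param traj a `cg_trajectory`.
#' @export
traj_protein_frames <- function(traj) {
  if (!traj$ion_present) return(traj$frames)
  lapply(traj$frames, function(f) f[-nrow(f), , drop = FALSE])
}

.run_engine <- function(model, start, cvdefs, c_start, c_end, k_cv,
                        steer_steps, hold_steps, relax_steps, dt, friction,
                        temperature, seed, save_stride, abort_energy) {
  if (nrow(start) != model$n_particles)
    stop(sprintf("start coordinates must have %d rows", model$n_particles))
  set.seed(as.integer(seed))
  cg_run(as.matrix(start), .enm_list(model), cvdefs,
         c_start, c_end, k_cv, as.integer(steer_steps), as.integer(hold_steps),
         as.integer(relax_steps), dt, friction, temperature,
         as.integer(save_stride), abort_energy)
}

#' Run unbiased overdamped Langevin dynamics
#'
#' First-order (Euler-Maruyama) overdamped Langevin integration of the
#' energy model at the given reduced temperature. Deterministic for a given
#' seed. Aborts with the offending step index if the energy diverges.
#'
#' @param model an `energy_model`.
#' @param start starting coordinates (`model$n_particles` x 3).
#' @param n_steps number of integration steps.
#' @param dt timestep (reduced time); the default is stable for the default
#'   model stiffness (including the k = 200 ion restraints).
#' @param friction friction coefficient.
#' @param temperature reduced temperature (kT).
#' @param seed RNG seed.
#' @param save_stride store every `save_stride`-th frame.
#' @param abort_energy divergence threshold.
#' @return a `cg_trajectory` (per-frame potential energy in
#'   `$provenance$energy`).
#' @export
run_equilibrium <- function(model, start, n_steps, dt = 0.002, friction = 1,
                            temperature = 1, seed = 1L, save_stride = 50L,
                            abort_energy = 1e8) {
  out <- .run_engine(model, start, list(), numeric(0), numeric(0), numeric(0),
                     n_steps, 0L, 0L, dt, friction, temperature, seed,
                     save_stride, abort_energy)
  as_trajectory(out$frames, dt = dt, stride = save_stride, seed = seed,
                ion_present = model$ion, frame_steps = out$frame_steps,
                provenance = list(kind = "equilibrium", n_steps = n_steps,
                                  temperature = temperature, friction = friction,
                                  energy = as.numeric(out$energy)))
}

#' Define a steering protocol
#'
#' A time-dependent harmonic bias \eqn{U(x,t) = \sum_q \tfrac12 k_q
#' (CV_q(x) - c_q(t))^2} whose centers move linearly from their start to
#' their end values over `duration` steps, followed by `hold` steps at the
#' final centers (restrained relaxation).
#'
#' @param cvs list of terms, each a list with elements `spec` (a
#'   [cv_spec()]), `start`, `end` (center schedule endpoints) and `k`
#'   (force constant, >= 0).
#' @param duration steering steps (>= 1).
#' @param hold post-steering hold steps (restrained relaxation at the final
#'   centers).
#' @param relax post-hold steps with the bias switched off entirely
#'   (unrestrained relaxation; no work is accumulated).
#' @param name protocol label.
#' @return a `steering_protocol`.
#' @export
steering_protocol <- function(cvs, duration, hold = 0L, relax = 0L,
                              name = "protocol") {
  if (length(cvs) < 1L) stop("protocol needs at least one CV term")
  for (term in cvs) {
    if (!inherits(term$spec, "cv_spec")) stop("each term needs a cv_spec in $spec")
    if (!is.finite(term$start) || !is.finite(term$end)) stop("start/end must be finite")
    if (term$k < 0) stop("force constants must be >= 0")
  }
  if (duration < 1L) stop("duration must be >= 1")
  structure(list(cvs = cvs, duration = as.integer(duration),
                 hold = as.integer(hold), relax = as.integer(relax),
                 name = name),
            class = "steering_protocol")
}

#' Run a steered simulation and record the nonequilibrium work
#'
#' The bias centers follow the protocol's linear schedule; the work is
#' accumulated at each center update as \eqn{W \mathrel{+}= U(x_t, c_{t+1})
#' - U(x_t, c_t)}, an identity that is exact for stepwise schedules. Hold
#' steps keep the centers fixed and add no work; relax steps run free of
#' any bias (unrestrained relaxation at the target state).
#'
#' @inheritParams run_equilibrium
#' @param protocol a `steering_protocol`.
#' @return list with `trajectory` (a `cg_trajectory`) and `work` (a
#'   `work_profile`: cumulative work, per-step CV values, center schedule,
#'   total work at the end of steering).
#' @export
run_steered <- function(model, start, protocol, dt = 0.002, friction = 1,
                        temperature = 1, seed = 1L, save_stride = 50L,
                        abort_energy = 1e8) {
  stopifnot(inherits(protocol, "steering_protocol"))
  cvdefs <- lapply(protocol$cvs, function(term) .cv_engine_def(term$spec))
  c_start <- vapply(protocol$cvs, function(term) term$start, 0)
  c_end <- vapply(protocol$cvs, function(term) term$end, 0)
  k_cv <- vapply(protocol$cvs, function(term) term$k, 0)
  out <- .run_engine(model, start, cvdefs, c_start, c_end, k_cv,
                     protocol$duration, protocol$hold, protocol$relax,
                     dt, friction, temperature, seed, save_stride,
                     abort_energy)
  traj <- as_trajectory(out$frames, dt = dt, stride = save_stride, seed = seed,
                        ion_present = model$ion, frame_steps = out$frame_steps,
                        provenance = list(kind = "steered", protocol = protocol$name,
                                          duration = protocol$duration,
                                          hold = protocol$hold,
                                          relax = protocol$relax,
                                          temperature = temperature,
                                          friction = friction,
                                          energy = as.numeric(out$energy)))
  work <- structure(list(
    work = as.numeric(out$work),
    total = as.numeric(out$work)[protocol$duration + 1L],
    cv_series = out$cv_series, centers = out$centers,
    k = k_cv, duration = protocol$duration, hold = protocol$hold,
    relax = protocol$relax, protocol = protocol$name
  ), class = "work_profile")
  list(trajectory = traj, work = work)
}

#' @export
print.work_profile <- function(x, ...) {
  cat(sprintf("work_profile: protocol '%s', %d + %d steps, W_total = %.3f kT\n",
              x$protocol, x$duration, x$hold, x$total))
  invisible(x)
}

#' Recompute the steering work post hoc from a saved trajectory
#'
#' Re-evaluates every CV with the pure-R collective-variable implementations
#' on the stored frames and re-applies the incremental bookkeeping rule to
#' the schedule. Requires a trajectory saved with stride 1 covering the
#' steering phase. Serves as an independent cross-check of the work
#' accumulated online by the dynamics core.
#'
#' @param traj the `cg_trajectory` returned by [run_steered()] (stride 1).
#' @param protocol the `steering_protocol` that produced it.
#' @return total recomputed work.
#' @export
recompute_work <- function(traj, protocol) {
  if (traj$stride != 1L)
    stop("post-hoc work recomputation requires a stride-1 trajectory")
  dur <- protocol$duration
  if (n_frames(traj) < dur + 1L)
    stop("trajectory does not cover the steering phase")
  c_start <- vapply(protocol$cvs, function(term) term$start, 0)
  c_end <- vapply(protocol$cvs, function(term) term$end, 0)
  k_cv <- vapply(protocol$cvs, function(term) term$k, 0)
  centers <- function(t) c_start + (c_end - c_start) * min(1, t / dur)
  W <- 0
  for (t in 0:(dur - 1L)) {
    x <- traj_frame(traj, t + 1L)  # state before step t -> t+1
    v <- vapply(protocol$cvs, function(term) evaluate_cv(term$spec, x), 0)
    c0 <- centers(t); c1 <- centers(t + 1L)
    W <- W + sum(0.5 * k_cv * ((v - c1)^2 - (v - c0)^2))
  }
  W
}

#' Jarzynski free-energy estimate from nonequilibrium work values
#'
#' \eqn{\Delta F = -kT \ln \langle e^{-W/kT} \rangle}, evaluated with a
#' log-sum-exp guard, plus a bootstrap standard error. By Jensen's
#' inequality the estimate never exceeds the sample mean work.
#'
#' @param works numeric vector of total work values (>= 2).
#' @param temperature reduced temperature kT.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return list with `delta_F`, `se`, `mean_work`, `n`.
#' @export
jarzynski_estimate <- function(works, temperature = 1, n_boot = 200L, seed = 1L) {
  if (length(works) < 2L) stop("need at least two work values")
  est <- function(w) {
    a <- -w / temperature
    m <- max(a)
    -temperature * (m + log(mean(exp(a - m))))
  }
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(i) est(sample(works, replace = TRUE)), 0)
  list(delta_F = est(works), se = stats::sd(boots),
       mean_work = mean(works), n = length(works))
}

#' Judge completion of the OF to IF transition from gate radii of gyration
#'
#' Averaged over the final unrestrained-relaxation segment (falling back to
#' the restrained hold segment, and failing that to the last 10% of frames),
#' the transition is `complete` when
#' both gate radii of gyration are within `tol_fraction` of their IF
#' reference values and the gates moved in the right directions relative to
#' the OF reference (cytoplasmic gate opened, periplasmic gate closed);
#' `partial` when exactly one gate satisfies its tolerance; `none` otherwise.
#'
#' @param traj a `cg_trajectory`.
#' @param structure the `toy_structure` (provides the gate tags).
#' @param refs the `reference_pair`.
#' @param tol_fraction relative tolerance on the IF gate values.
#' @return list with `verdict` ("complete", "partial" or "none") and a
#'   `gates` data frame of measured vs reference values.
#' @export
check_completion <- function(traj, structure, refs, tol_fraction = 0.1) {
  cyto <- atom_indices(structure, role = "cyto_gate")
  peri <- atom_indices(structure, role = "peri_gate")
  if (length(cyto) == 0L || length(peri) == 0L) stop("gate tags missing")
  frames <- traj_protein_frames(traj)
  hold <- traj$provenance$hold
  relax <- traj$provenance$relax
  dur <- traj$provenance$duration
  keep <- integer(0)
  if (!is.null(relax) && relax > 0L && !is.null(dur) && !is.null(hold))
    keep <- which(traj$frame_steps > dur + hold)
  if (length(keep) == 0L && !is.null(hold) && hold > 0L && !is.null(dur))
    keep <- which(traj$frame_steps > dur)
  if (length(keep) == 0L)
    keep <- seq(max(1L, ceiling(0.9 * length(frames))), length(frames))
  rg_mean <- function(idx) mean(vapply(frames[keep], function(f)
    radius_of_gyration(idx, f), 0))
  g <- data.frame(
    gate = c("cyto", "peri"),
    measured = c(rg_mean(cyto), rg_mean(peri)),
    of_ref = c(radius_of_gyration(cyto, refs$of_coords),
               radius_of_gyration(peri, refs$of_coords)),
    if_ref = c(radius_of_gyration(cyto, refs$if_coords),
               radius_of_gyration(peri, refs$if_coords))
  )
  g$within_tol <- abs(g$measured - g$if_ref) <= tol_fraction * g$if_ref
  ordering <- g$measured[1] > g$of_ref[1] && g$measured[2] < g$of_ref[2]
  verdict <- if (all(g$within_tol) && ordering) "complete"
             else if (sum(g$within_tol) == 1L) "partial" else "none"
  list(verdict = verdict, gates = g)
}

#' Run a steered-protocol suite over conditions and replicas
#'
#' For every protocol x condition (ion-bound, apo) x replica, runs the
#' steered transition from the OF state, records the total work and the
#' completion verdict, and aggregates the results per cell. Seeds are paired
#' across conditions (replica r uses `seed_base + r` in both arms) for
#' variance reduction. Per-replica failures are recorded as `failed` rows
#' without aborting the suite.
#'
#' @param model_bound,model_apo energy models with and without the ion.
#' @param structure,refs the toy structure and reference pair.
#' @param protocols named list of `steering_protocol`s.
#' @param replicas replicas per cell.
#' @param seed_base base seed.
#' @param dt,friction,temperature,save_stride integrator settings.
#' @param tol_fraction completion tolerance (see [check_completion()]).
#' @return list with `results` (per-replica data frame) and `summary`
#'   (per protocol x condition: copies, transition verdict, mean and sd of
#'   the work over completed copies).
#' @export
run_protocol_suite <- function(model_bound, model_apo, structure, refs,
                               protocols, replicas = 3L, seed_base = 1000L,
                               dt = 0.002, friction = 1, temperature = 1,
                               save_stride = 100L, tol_fraction = 0.1) {
  if (length(protocols) < 1L) stop("need at least one protocol")
  if (is.null(names(protocols)))
    names(protocols) <- vapply(protocols, function(p) p$name, "")
  rows <- list()
  for (pname in names(protocols)) {
    for (cond in c("bound", "apo")) {
      model <- if (cond == "bound") model_bound else model_apo
      start <- start_coords(model, structure, refs, "of")
      for (r in seq_len(replicas)) {
        seed <- as.integer(seed_base) + r
        row <- tryCatch({
          out <- run_steered(model, start, protocols[[pname]], dt = dt,
                             friction = friction, temperature = temperature,
                             seed = seed, save_stride = save_stride)
          comp <- check_completion(out$trajectory, structure, refs, tol_fraction)
          data.frame(protocol = pname, condition = cond, replica = r,
                     seed = seed, work = out$work$total,
                     verdict = comp$verdict, stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(protocol = pname, condition = cond, replica = r,
                     seed = seed, work = NA_real_, verdict = "failed",
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  cells <- unique(results[, c("protocol", "condition")])
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$protocol == cells$protocol[i] &
                   results$condition == cells$condition[i], ]
    n_complete <- sum(sub$verdict == "complete")
    transition <- if (n_complete == nrow(sub)) "yes"
                  else if (n_complete > 0L || any(sub$verdict == "partial")) "partial"
                  else "no"
    wc <- sub$work[sub$verdict == "complete"]
    data.frame(protocol = cells$protocol[i], condition = cells$condition[i],
               copies = nrow(sub), n_complete = n_complete,
               transition = transition,
               mean_work = if (length(wc)) mean(wc) else NA_real_,
               sd_work = if (length(wc) > 1L) stats::sd(wc) else NA_real_,
               n_cvs = length(protocols[[cells$protocol[i]]]$cvs),
               stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary)
}
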