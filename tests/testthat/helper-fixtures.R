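# Shared fixtures, built once per test run and cached.

.fix_env <- new.env(parent = emptyenv())

fix_toy <- function() {
  if (is.null(.fix_env$toy))
    .fix_env$toy <- build_toy_transporter(seed = 1L)  # the default study model
  .fix_env$toy
}

fix_models <- function() {
  if (is.null(.fix_env$models)) {
    tw <- fix_toy()
    .fix_env$models <- list(
      bound = build_energy_model(tw$structure, tw$refs, ion = TRUE),
      apo = build_energy_model(tw$structure, tw$refs, ion = FALSE))
  }
  .fix_env$models
}

# uniform random rotation matrix (quaternion method), deterministic per call
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# angle (degrees) of a rotation matrix -- independent oracle for the
# quaternion-based orientation angle
rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# dragged harmonic trap on the separation of two free particles: returns the
# steered result for given duration/k/seed
dragged_trap <- function(duration, k = 2, d_start = 2, d_end = 5, seed = 1,
                         hold = 0L, temperature = 1, save_stride = 1000L) {
  model <- free_particle_model(2L)
  start <- rbind(c(0, 0, 0), c(d_start, 0, 0))
  spec <- cv_spec("com_distance", 1L, group_b = 2L, name = "sep")
  prot <- steering_protocol(
    list(list(spec = spec, start = d_start, end = d_end, k = k)),
    duration = duration, hold = hold, name = "trap")
  run_steered(model, start, prot, seed = seed, temperature = temperature,
              save_stride = save_stride)
}
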