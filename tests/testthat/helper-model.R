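# Shared fixtures. The anchor calibration is deterministic but takes a few
# seconds, so it is computed once per session and memoized.

.katytw_cache <- new.env(parent = emptyenv())

calibrated_result <- function() {
  if (is.null(.katytw_cache$calib))
    .katytw_cache$calib <- calibrate(calibration_problem())
  .katytw_cache$calib
}

calibrated_model <- function(mode = "no_ca") {
  res <- calibrated_result()
  do.call(build_ear_model,
          utils::modifyList(res$model_args, list(ablation = mode)))
}

# a minimal hand-specified segment network (x-uniform, three nodes) used by
# the impedance oracles
toy_network <- function(m_dw = 5e-3, k_dw = 2e8, k_ca = 1.5e8,
                        m_tm = 4e-3, k_tm = 3e8,
                        materials = material_set()) {
  n <- 3L
  structure(list(
    x = c(0, 1, 2), m_dw = rep(m_dw, n), k_dw = rep(k_dw, n),
    k_ca = rep(k_ca, n), m_tm = rep(m_tm, n), k_tm = rep(k_tm, n),
    materials = materials, ablation_mode = "intact", E_dw_used = NA
  ), class = "segment_network")
}

# total mechanical energy of a free-decay time solution (two fluid-loaded
# faces per unit plan area, consistent with the line's 2iw p/Z source term)
mechanical_energy <- function(ts, network, every = 20) {
  h <- diff(ts$x)[1] * 1e-6
  H <- network$profile$duct_height * 1e-6
  rho <- network$materials$rho_fluid
  cum_trap <- function(v) cumsum(c(0, (v[-1] + v[-length(v)]) / 2))
  vapply(seq(1, length(ts$times), by = every), function(k) {
    x <- ts$snapshots[, k]
    v <- ts$velocity[, k]
    u <- -2 * cum_trap(v) * h / H          # fluid velocity, u(drive end) = 0
    sum(2 * (0.5 * network$m_dw * v^2 + 0.5 * network$k_dw * x^2) +
          0.5 * rho * H * u^2) * h
  }, numeric(1))
}

# synthetic time_solution with a prescribed separable field
separable_time_solution <- function(x, A, f = 20e3, n_cycles = 5,
                                    samples_per_cycle = 80) {
  dt <- 1 / (f * samples_per_cycle)
  times <- seq(0, n_cycles / f, by = dt)
  snapshots <- outer(A, sin(2 * pi * f * times))
  structure(list(
    frequency = f, times = times, snapshots = snapshots,
    velocity = outer(A * 2 * pi * f, cos(2 * pi * f * times)),
    steady_state_mask = rep(TRUE, length(times)), dt = dt,
    n_cycles = n_cycles, ramp_cycles = 0, x = x,
    drive_end = "distal", d0 = 10
  ), class = "time_solution")
}

# synthetic frequency_solution carrying a prescribed complex field
synthetic_frequency_solution <- function(x, x_dw, f = 20e3) {
  structure(list(
    frequency = f, omega = 2 * pi * f, x = x,
    p = x_dw, x_dw = x_dw, x_tm = 0 * x_dw,
    drive_end = "distal", d0 = 10
  ), class = "frequency_solution")
}
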