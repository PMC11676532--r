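#' Drive specification
#'
#' The inner ear is excited through the tympanal plates with a prescribed
#' fluid acceleration of magnitude `d0 * omega^2` um/s^2 (default d0 = 10,
#' i.e. 10 omega^2 um/s^2), applied as a flux boundary condition at the
#' driven end of the transect. The opposite end is the pressure-release
#' facilitator (p = 0). Frequencies default to the published sweep,
#' 10-80 kHz in 10 kHz steps.
#'
#' The default driven end is distal: in a one-dimensional incompressible
#' transmission line, energy can only propagate through the region where the
#' partition is stiffness-dominated, so the drive must enter at the stiff
#' (distal, narrow, thick) end of the tapering dorsal wall - exactly as the
#' stapes drives the stiff base of the cochlea. See the methods vignette.
#'
#' @param d0 displacement scale, um (> 0)
#' @param frequencies Hz, positive and sorted
#' @param drive_end `"distal"` or `"proximal"`
#' @return object of class `drive_spec`
#' @export
drive_spec <- function(d0 = 10, frequencies = seq(10e3, 80e3, by = 10e3),
                       drive_end = c("distal", "proximal")) {
  drive_end <- match.arg(drive_end)
  if (d0 < 0) stop("drive_spec: d0 must be >= 0", call. = FALSE)
  if (length(frequencies) == 0 || any(frequencies <= 0) ||
      is.unsorted(frequencies))
    stop("drive_spec: frequencies must be positive and sorted",
         call. = FALSE)
  structure(list(d0 = d0, frequencies = frequencies, drive_end = drive_end),
            class = "drive_spec")
}

#' Complex tridiagonal solve (Thomas algorithm)
#' @param dl,dd,du sub-, main and super-diagonal (lengths n-1, n, n-1)
#' @param b right-hand side
#' @return solution vector
#' @keywords internal
thomas_solve <- function(dl, dd, du, b) {
  n <- length(dd)
  cp <- complex(length.out = n)
  bp <- complex(length.out = n)
  cp[1] <- du[1] / dd[1]
  bp[1] <- b[1] / dd[1]
  for (i in 2:n) {
    denom <- dd[i] - dl[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- du[i] / denom
    bp[i] <- (b[i] - dl[i - 1] * bp[i - 1]) / denom
  }
  x <- complex(length.out = n)
  x[n] <- bp[n]
  for (i in (n - 1):1) x[i] <- bp[i] - cp[i] * x[i + 1]
  x
}

# Face-averaged H/rho coefficients and boundary indices for the line.
line_coefficients <- function(profile, network, drive_end) {
  n <- profile$n_segments
  h <- diff(profile$x) * um
  if (diff(range(h)) > 1e-9 * h[1])
    stop("solve requires a uniform grid", call. = FALSE)
  h <- h[1]
  g <- profile$duct_height * um / network$materials$rho_fluid
  gf <- (g[-1] + g[-n]) / 2                     # faces i+1/2
  d_idx <- if (drive_end == "distal") 1L else n
  o_idx <- if (drive_end == "distal") n else 1L
  list(n = n, h = h, g = g, gf = gf, d_idx = d_idx, o_idx = o_idx)
}

#' Solve the fluid-coupled line in the frequency domain
#'
#' Second-order finite differences for the long-wave line
#' \deqn{\frac{d}{dx}\Big(\frac{H(x)}{\rho}\frac{dp}{dx}\Big) =
#'   \frac{2 i \omega}{Z(x,\omega)} p}
#' with a prescribed-flux condition `dp/dx = -rho * a0(omega)` at the driven
#' end and `p = 0` at the pressure-release end. Dorsal-wall displacement is
#' `x_dw = p / (i omega Z)` and the tectorial-membrane displacement follows
#' from the two-degree-of-freedom transfer ratio.
#'
#' @param profile geometry profile
#' @param network matching [assemble_network()] object
#' @param drive a [drive_spec()]
#' @param f frequency, Hz (> 0)
#' @return object of class `frequency_solution` with complex fields `p`
#'   (Pa), `x_dw`, `x_tm` (m) along `x` (um)
#' @export
solve_frequency <- function(profile, network, drive, f) {
  stopifnot(inherits(profile, "geometry_profile"),
            inherits(network, "segment_network"),
            inherits(drive, "drive_spec"))
  if (f <= 0) stop("solve_frequency: f must be positive", call. = FALSE)
  if (length(network$x) != profile$n_segments)
    stop("network grid does not match profile", call. = FALSE)
  omega <- 2 * pi * f
  lc <- line_coefficients(profile, network, drive$drive_end)
  n <- lc$n; h <- lc$h; gf <- lc$gf
  imp <- segment_impedance(network, omega)
  s <- 2i * omega / imp$Z

  dl <- complex(length.out = n - 1)
  du <- complex(length.out = n - 1)
  dd <- complex(length.out = n)
  # interior rows
  for (i in 2:(n - 1)) {
    dl[i - 1] <- gf[i - 1] / h^2
    du[i]     <- gf[i] / h^2
    dd[i]     <- -(gf[i - 1] + gf[i]) / h^2 - s[i]
  }
  rhs <- complex(length.out = n)
  a0 <- drive$d0 * um * omega^2          # prescribed acceleration, m/s^2
  rho <- network$materials$rho_fluid
  if (lc$d_idx == 1L) {
    dd[1] <- -2 * gf[1] / h^2 - s[1]
    du[1] <- 2 * gf[1] / h^2
    rhs[1] <- -(2 / h) * lc$g[1] * rho * a0
    dd[n] <- 1; dl[n - 1] <- 0; rhs[n] <- 0
  } else {
    dd[n] <- -2 * gf[n - 1] / h^2 - s[n]
    dl[n - 1] <- 2 * gf[n - 1] / h^2
    rhs[n] <- -(2 / h) * lc$g[n] * rho * a0
    dd[1] <- 1; du[1] <- 0; rhs[1] <- 0
  }
  p <- thomas_solve(dl, dd, du, rhs)
  if (any(!is.finite(Re(p)) | !is.finite(Im(p))))
    stop("numerical-singularity: the line is singular at this frequency ",
         "(possible only with r_visc = 0 on an exact resonance); use a ",
         "nonzero fluid viscosity", call. = FALSE)
  x_dw <- p / (1i * omega * imp$Z)
  x_tm <- x_dw * imp$tm_transfer
  structure(list(
    frequency = f, omega = omega, x = profile$x,
    p = p, x_dw = x_dw, x_tm = x_tm,
    drive_end = drive$drive_end, d0 = drive$d0,
    h = h, impedance = imp, network = network, profile = profile
  ), class = "frequency_solution")
}

#' @export
print.frequency_solution <- function(x, ...) {
  cat(sprintf("frequency_solution at %.3g kHz (%d points)\n",
              x$frequency / 1e3, length(x$x)))
  cat(sprintf("  max |x_dw| = %.3g m at %.0f um from the distal end\n",
              max(Mod(x$x_dw)), x$x[which.max(Mod(x$x_dw))]))
  invisible(x)
}

#' Viscous power dissipated along the transect
#'
#' Time-averaged viscous intensity absorbed at each position,
#' `0.5 * r_visc * omega^2 * |x_dw|^2` (W/m^2), the per-face intensity of
#' the Stokes boundary layer. The line couples two fluid-loaded faces per
#' unit plan area, so the total absorbed power (per unit duct width) is
#' twice the integral of this profile over x - which balances the boundary
#' input power, see [input_power()].
#'
#' @param solution a [solve_frequency()] result
#' @return non-negative vector, W/m^2 per grid point
#' @export
dissipated_power <- function(solution) {
  stopifnot(inherits(solution, "frequency_solution"))
  0.5 * solution$impedance$r_visc * solution$omega^2 * Mod(solution$x_dw)^2
}

#' Net acoustic power entering at the driven boundary
#'
#' Time-averaged product of boundary pressure and inward volume flux per
#' unit duct width, `0.5 * Re(p_d * conj(H_d * u_in))` with
#' `u_in = a0 / (i omega)` the prescribed inward fluid velocity.
#'
#' @param solution a [solve_frequency()] result
#' @return scalar, W per unit duct width (W/m)
#' @export
input_power <- function(solution) {
  stopifnot(inherits(solution, "frequency_solution"))
  omega <- solution$omega
  d_idx <- if (solution$drive_end == "distal") 1L
           else length(solution$x)
  a0 <- solution$d0 * um * omega^2
  u_in <- a0 / (1i * omega)
  H_d <- solution$profile$duct_height[d_idx] * um
  0.5 * Re(solution$p[d_idx] * Conj(H_d * u_in))
}

#' Solve the fluid-coupled line in the time domain
#'
#' Method-of-lines integration of the same spatial operator with the full
#' per-segment two-degree-of-freedom state, stepped with the A-stable
#' Crank-Nicolson rule. The drive acceleration `d0 omega^2 sin(omega t)` is
#' ramped on with a half-Hann window over `ramp_cycles` to suppress the
#' transient. The viscous resistance is frozen at the drive frequency
#' (each run is monochromatic, so the frequency-dependent boundary-layer
#' resistance is evaluated where the energy is).
#'
#' @inheritParams solve_frequency
#' @param f drive frequency, Hz
#' @param n_cycles total simulated drive cycles (default 30)
#' @param ramp_cycles cycles over which the drive ramps on (default 10)
#' @param dt time step, s; must satisfy `dt <= 1/(40 f)`; default `1/(80 f)`
#' @param steady_cycles how many final cycles to flag as steady state
#'   (default 8)
#' @param initial_displacement optional dorsal-wall displacement at t = 0
#'   (m, one value per grid point); useful for free-decay runs
#' @return object of class `time_solution`: `times` (s), `snapshots`
#'   (matrix, grid x time, dorsal-wall displacement in m), matching
#'   `velocity` snapshots, optional `snapshots_tm`/`velocity_tm`, and
#'   `steady_state_mask`
#' @export
solve_time <- function(profile, network, drive, f, n_cycles = 30,
                       ramp_cycles = 10, dt = NULL, steady_cycles = 8,
                       initial_displacement = NULL) {
  stopifnot(inherits(profile, "geometry_profile"),
            inherits(network, "segment_network"),
            inherits(drive, "drive_spec"))
  if (f <= 0) stop("solve_time: f must be positive", call. = FALSE)
  if (n_cycles <= ramp_cycles)
    stop("solve_time: n_cycles must exceed ramp_cycles", call. = FALSE)
  period <- 1 / f
  if (is.null(dt)) dt <- period / 80
  if (dt > period / 40 + 1e-15)
    stop("solve_time: dt must resolve at least 40 samples per period",
         call. = FALSE)
  omega <- 2 * pi * f
  lc <- line_coefficients(profile, network, drive$drive_end)
  n <- lc$n; h <- lc$h; gf <- lc$gf
  rho <- network$materials$rho_fluid
  r <- viscous_resistance(omega, network$materials)

  # spatial operator A (rows: flux balance; release row = Dirichlet p = 0)
  A <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- gf[i - 1] / h^2
    A[i, i + 1] <- gf[i] / h^2
    A[i, i]     <- -(gf[i - 1] + gf[i]) / h^2
  }
  if (lc$d_idx == 1L) {
    A[1, 1] <- -2 * gf[1] / h^2; A[1, 2] <- 2 * gf[1] / h^2
  } else {
    A[n, n] <- -2 * gf[n - 1] / h^2; A[n, n - 1] <- 2 * gf[n - 1] / h^2
  }
  drive_coeff <- (2 / h) * lc$g[lc$d_idx] * rho   # times a0(t), on drive row

  m_dw <- network$m_dw
  has_ca <- any(network$k_ca > 0)
  Dm <- diag(1 / m_dw)
  # pressure solve: (A - 2 D) p = -2 D F - e_d * drive_coeff * a0(t),
  # with the release row forced to p = 0.
  B <- A - 2 * Dm
  B[lc$o_idx, ] <- 0; B[lc$o_idx, lc$o_idx] <- 1
  Binv <- solve(B)
  E2 <- 2 * Dm; E2[lc$o_idx, ] <- 0
  SF <- Binv %*% E2                      # p = SF %*% F + gvec * a0(t)
  gvec <- -Binv[, lc$d_idx] * drive_coeff
  SI <- Dm %*% (SF + diag(n))            # a_dw = SI %*% F + Dm gvec a0
  ga <- (1 / m_dw) * gvec

  C1 <- network$k_dw + network$k_ca
  C2 <- network$k_ca
  nb <- if (has_ca) 4L else 2L
  N <- nb * n
  M <- matrix(0, N, N)
  ix <- 1:n; iv <- n + 1:n
  M[ix, iv] <- diag(n)
  M[iv, ix] <- -SI %*% diag(C1)
  M[iv, iv] <- -SI %*% diag(rep(r, n))
  if (has_ca) {
    ixt <- 2 * n + 1:n; ivt <- 3 * n + 1:n
    M[iv, ixt] <- SI %*% diag(C2)
    M[ixt, ivt] <- diag(n)
    M[ivt, ix] <- diag(C2 / network$m_tm)
    M[ivt, ixt] <- -diag((C2 + network$k_tm) / network$m_tm)
  }
  bdir <- numeric(N); bdir[iv] <- ga     # times a0(t)

  n_steps <- ceiling(n_cycles * period / dt)
  times <- (0:n_steps) * dt
  a0_amp <- drive$d0 * um * omega^2
  ramp_T <- ramp_cycles * period
  a0_t <- a0_amp * sin(omega * times) *
    ifelse(times < ramp_T, 0.5 * (1 - cos(pi * times / ramp_T)), 1)

  I_N <- diag(N)
  T_step <- solve(I_N - (dt / 2) * M, I_N + (dt / 2) * M)
  b_step <- solve(I_N - (dt / 2) * M, bdir) * (dt / 2)

  y <- numeric(N)
  if (!is.null(initial_displacement)) {
    stopifnot(length(initial_displacement) == n)
    y[ix] <- initial_displacement
    if (has_ca) y[2 * n + 1:n] <- initial_displacement
  }
  snapshots <- matrix(0, n, n_steps + 1)
  velocity <- matrix(0, n, n_steps + 1)
  snapshots[, 1] <- y[ix]
  if (has_ca) {
    snapshots_tm <- matrix(0, n, n_steps + 1)
    velocity_tm <- matrix(0, n, n_steps + 1)
    snapshots_tm[, 1] <- y[2 * n + 1:n]
  } else snapshots_tm <- velocity_tm <- NULL
  for (k in seq_len(n_steps)) {
    y <- T_step %*% y + b_step * (a0_t[k] + a0_t[k + 1])
    snapshots[, k + 1] <- y[ix]
    velocity[, k + 1] <- y[iv]
    if (has_ca) {
      snapshots_tm[, k + 1] <- y[2 * n + 1:n]
      velocity_tm[, k + 1] <- y[3 * n + 1:n]
    }
  }
  if (any(!is.finite(y)))
    stop("stability error: the time integration diverged; reduce dt ",
         "(estimated stable maximum ", signif(period / 40, 3), " s)",
         call. = FALSE)
  steady_cycles <- min(steady_cycles, n_cycles - ramp_cycles)
  mask <- times >= (n_cycles - steady_cycles) * period - 1e-12 * period
  structure(list(
    frequency = f, times = times, snapshots = snapshots,
    velocity = velocity, snapshots_tm = snapshots_tm,
    velocity_tm = velocity_tm,
    steady_state_mask = mask, dt = dt, n_cycles = n_cycles,
    ramp_cycles = ramp_cycles, x = profile$x,
    drive_end = drive$drive_end, d0 = drive$d0,
    network = network, profile = profile
  ), class = "time_solution")
}

#' @export
print.time_solution <- function(x, ...) {
  cat(sprintf(
    "time_solution at %.3g kHz: %d steps, %d grid points, %d steady samples\n",
    x$frequency / 1e3, length(x$times) - 1, nrow(x$snapshots),
    sum(x$steady_state_mask)))
  invisible(x)
}
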