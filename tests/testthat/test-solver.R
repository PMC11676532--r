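make_model <- function(n = 101, mode = "no_ca", ...) {
  build_ear_model(ablation = mode, n_segments = n, ...)
}

test_that("zero drive gives identically zero fields", {
  m <- make_model()
  d0 <- drive_spec(d0 = 0, frequencies = 20e3)
  fs <- solve_frequency(m$profile, m$network, d0, 20e3)
  expect_true(all(fs$p == 0))
  expect_true(all(fs$x_dw == 0))
  expect_true(all(fs$x_tm == 0))
})

test_that("the discrete system is linear in the drive to machine precision", {
  m <- make_model()
  f <- 30e3
  fs10 <- solve_frequency(m$profile, m$network, drive_spec(d0 = 10), f)
  fs1 <- solve_frequency(m$profile, m$network, drive_spec(d0 = 1), f)
  expect_equal(fs10$p, 10 * fs1$p, tolerance = 1e-14)
  expect_equal(fs10$x_dw, 10 * fs1$x_dw, tolerance = 1e-14)
  expect_equal(fs10$x_tm, 10 * fs1$x_tm, tolerance = 1e-14)
})

test_that("pressure vanishes exactly at the release end", {
  m <- make_model()
  fs <- solve_frequency(m$profile, m$network, m$drive, 40e3)
  expect_identical(fs$p[length(fs$p)], 0 + 0i)   # drive distal, release prox
  d2 <- drive_spec(drive_end = "proximal")
  fs2 <- solve_frequency(m$profile, m$network, d2, 40e3)
  expect_identical(fs2$p[1], 0 + 0i)
})

test_that("tridiagonal solution equals a dense direct solve at n = 5", {
  m <- make_model(n = 5)
  f <- 25e3
  omega <- 2 * pi * f
  fs <- solve_frequency(m$profile, m$network, m$drive, f)

  # independent dense assembly of the same discrete operator
  prof <- m$profile
  n <- 5L
  h <- diff(prof$x)[1] * 1e-6
  g <- prof$duct_height * 1e-6 / 1000
  gf <- (g[-1] + g[-n]) / 2
  s <- 2i * omega / segment_impedance(m$network, omega)$Z
  A <- matrix(0 + 0i, n, n)
  rhs <- complex(length.out = n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- gf[i - 1] / h^2
    A[i, i + 1] <- gf[i] / h^2
    A[i, i] <- -(gf[i - 1] + gf[i]) / h^2 - s[i]
  }
  a0 <- 10e-6 * omega^2
  A[1, 1] <- -2 * gf[1] / h^2 - s[1]
  A[1, 2] <- 2 * gf[1] / h^2
  rhs[1] <- -(2 / h) * g[1] * 1000 * a0
  A[n, n] <- 1
  p_dense <- solve(A, rhs)
  expect_equal(fs$p, p_dense, tolerance = 1e-12)

  # reciprocity: the interior block of the operator is symmetric
  expect_equal(A[2:(n - 1), 2:(n - 1)], t(A[2:(n - 1), 2:(n - 1)]))
})

test_that("halving the grid spacing barely moves the peak", {
  coarse <- make_model(n = 101)
  fine <- make_model(n = 201)
  f <- 20e3
  fsc <- solve_frequency(coarse$profile, coarse$network, coarse$drive, f)
  fsf <- solve_frequency(fine$profile, fine$network, fine$drive, f)
  pk_c <- as.numeric(peak_distance_from_distal(fsc))
  pk_f <- as.numeric(peak_distance_from_distal(fsf))
  expect_lt(abs(pk_c - pk_f), 6)                       # one coarse cell
  expect_lt(abs(max(Mod(fsc$x_dw)) - max(Mod(fsf$x_dw))) /
              max(Mod(fsf$x_dw)), 0.02)
})

test_that("time-domain steady state matches the frequency domain at 20 kHz", {
  m <- make_model()
  f <- 20e3
  ts <- solve_time(m$profile, m$network, m$drive, f)
  env <- envelope(ts)
  ref <- Mod(solve_frequency(m$profile, m$network, m$drive, f)$x_dw)
  ok <- ref > 1e-9 * max(ref)   # the release node is exactly zero
  expect_lt(max(abs(env - ref)[ok] / ref[ok]), 0.02)
  expect_lt(max(abs(env - ref)[!ok]) / max(ref), 0.02)
})

test_that("extending the run beyond steady state leaves the envelope alone", {
  m <- make_model()
  f <- 20e3
  e1 <- envelope(solve_time(m$profile, m$network, m$drive, f,
                            n_cycles = 30, ramp_cycles = 10))
  e2 <- envelope(solve_time(m$profile, m$network, m$drive, f,
                            n_cycles = 60, ramp_cycles = 10))
  ok <- e2 > 1e-9 * max(e2)
  expect_lt(max(abs(e1 - e2)[ok] / e2[ok]), 1e-3)
})

test_that("free decay with viscous fluid dissipates mechanical energy", {
  # n = 201: the test-side fluid-velocity reconstruction (trapezoidal
  # integration of wall velocity) needs the fine grid to track the
  # scheme's discrete energy balance
  m <- make_model(n = 201)
  x0 <- 1e-8 * exp(-((m$profile$x - 300) / 80)^2)
  d0 <- drive_spec(d0 = 0, frequencies = 20e3)
  ts <- solve_time(m$profile, m$network, d0, 20e3, n_cycles = 12,
                   ramp_cycles = 2, initial_displacement = x0)
  energy <- mechanical_energy(ts, m$network)
  expect_true(all(diff(energy) <= 1e-9 * energy[1]))
  expect_lt(energy[length(energy)], 0.8 * energy[1])
})

test_that("time stepping rejects an unresolved step and bad cycle counts", {
  m <- make_model(n = 21)
  expect_error(solve_time(m$profile, m$network, m$drive, 20e3,
                          dt = 1 / (10 * 20e3)), "40 samples")
  expect_error(solve_time(m$profile, m$network, m$drive, 20e3,
                          n_cycles = 5, ramp_cycles = 10), "exceed")
})

test_that("dissipated power is non-negative, zero without viscosity, and
           balances the boundary input power", {
  m <- make_model()
  f <- 20e3
  fs <- solve_frequency(m$profile, m$network, m$drive, f)
  dp <- dissipated_power(fs)
  expect_true(all(dp >= 0))

  # lossless fluid: no dissipation anywhere
  mats0 <- material_set(mu_fluid = 0)
  prof <- m$profile
  net0 <- assemble_network(prof, mats0, ablation_spec("no_ca"))
  fs0 <- solve_frequency(prof, net0, m$drive, f)
  expect_true(all(dissipated_power(fs0) == 0))

  # energy balance: the line couples two fluid-loaded faces per unit plan
  # area, so twice the integral of the per-face intensity equals the
  # boundary input power
  h <- diff(prof$x)[1] * 1e-6
  expect_equal(2 * sum(dp) * h, input_power(fs), tolerance = 0.01)
})

test_that("driving from the proximal end pins the response near the drive", {
  # with the drive on the compliant (proximal) side every frequency at or
  # above the local resonance is evanescent from the start, so the
  # displacement maximum stays in the proximal half at high frequency -
  # the configuration cannot reproduce distal high-frequency peaks
  m <- make_model()
  d <- drive_spec(drive_end = "proximal", frequencies = 80e3)
  fs <- solve_frequency(m$profile, m$network, d, 80e3)
  expect_gt(as.numeric(peak_distance_from_distal(fs)), 300)
})

test_that("drive_spec validates its fields", {
  expect_error(drive_spec(d0 = -1), "d0")
  expect_error(drive_spec(frequencies = c(2e4, 1e4)), "sorted")
  expect_error(drive_spec(frequencies = numeric(0)), "frequencies")
  d <- drive_spec()
  expect_equal(d$frequencies, seq(10e3, 80e3, by = 10e3))
  expect_equal(d$d0, 10)
})
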