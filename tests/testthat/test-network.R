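test_that("plate stiffness follows the cubic-thickness / quartic-width laws", {
  base <- build_profile(n_segments = 11, thickness_endpoints = c(4.5, 4.5),
                        width_endpoints = c(80, 80))
  thick <- build_profile(n_segments = 11, thickness_endpoints = c(9, 9),
                         width_endpoints = c(80, 80))
  wide <- build_profile(n_segments = 11, thickness_endpoints = c(4.5, 4.5),
                        width_endpoints = c(160, 160))
  k0 <- plate_stiffness(base, E = 3e6)
  expect_equal(plate_stiffness(thick, E = 3e6), 8 * k0)
  expect_equal(plate_stiffness(wide, E = 3e6), k0 / 16)
  # direct arithmetic: E = 3 MPa, t = 4.5 um, w = 80 um, nu = 0.3, beta = 32
  expect_equal(k0[1],
               (384 / 12) * 3e6 * (4.5e-6)^3 / ((1 - 0.3^2) * (80e-6)^4))
  expect_error(plate_stiffness(base, E = 0), "positive")
})

test_that("areal masses are density times thickness with the printed TM taper", {
  gp <- build_profile(n_segments = 11)
  mats <- material_set(rho_cuticle = 1200)
  am <- areal_masses(gp, mats, tm_thickness_endpoints = c(3.47, 3.08))
  expect_equal(am$m_dw[1], 1200 * 4.84e-6)   # 5.808e-3 kg/m^2
  expect_equal(am$m_dw[1], 5.808e-3)
  # endpoint TM masses in the printed 3.47 : 3.08 ratio
  expect_equal(am$m_tm[1] / am$m_tm[11], 3.47 / 3.08)
  # zero-thickness hypothetical: mass scales to zero with thickness
  expect_equal(1200 * 0, 0)
})

test_that("viscous resistance is the Stokes boundary-layer value", {
  mats <- material_set()   # water at 20 C
  omega <- 2 * pi * 20e3
  expect_equal(viscous_resistance(omega, mats),
               2 * sqrt(1000 * 1.002e-3 * omega / 2))
  # lossless limit and square-root scaling
  expect_equal(viscous_resistance(omega, material_set(mu_fluid = 0)), 0)
  expect_equal(viscous_resistance(4 * omega, mats),
               2 * viscous_resistance(omega, mats))
  expect_error(viscous_resistance(-1, mats), "non-negative")
})

test_that("assemble_network implements the three ablation modes", {
  gp <- build_profile(n_segments = 21)
  mats <- material_set()

  noca <- assemble_network(gp, mats, ablation_spec("no_ca"))
  expect_true(all(noca$k_ca == 0))
  expect_true(all(noca$k_tm == 0))
  expect_true(all(noca$m_tm == 0))
  expect_equal(noca$E_dw_used, 1.3e7)

  udw <- assemble_network(gp, mats, ablation_spec("uniform_dw"))
  expect_equal(max(udw$profile$thickness) - min(udw$profile$thickness), 0)
  expect_equal(udw$profile$thickness[1], 15)
  expect_equal(udw$E_dw_used, mats$E_av_wall)
  expect_true(all(udw$k_ca > 0))   # crista retained

  # intact with k_ca = 0 is parameter-equivalent to no_ca at the default E
  intact0 <- assemble_network(gp, mats, ablation_spec("intact"),
                              k_ca_profile = 0)
  noca_default <- assemble_network(
    gp, mats, ablation_spec("no_ca", E_dw_override = mats$E_dw))
  expect_equal(intact0$k_dw, noca_default$k_dw)
  expect_equal(intact0$m_dw, noca_default$m_dw)
  expect_true(all(intact0$k_ca == 0))

  expect_error(assemble_network(gp, mats, list(mode = "nope")),
               "configuration error")
})

test_that("segment impedance: branch decoupling, resonance and passivity", {
  omega <- 2 * pi * 30e3
  mats <- material_set()
  r <- viscous_resistance(omega, mats)

  # k_ca = 0 reduces to the single-oscillator line
  single <- toy_network(k_ca = 0, m_tm = 0, k_tm = 0)
  Z <- segment_impedance(single, omega)$Z[1]
  expect_equal(Z, (2e8 - omega^2 * 5e-3) / (1i * omega) + r)

  # at resonance with r = 0 the impedance vanishes
  lossless <- toy_network(k_ca = 0, m_tm = 0, k_tm = 0,
                          materials = material_set(mu_fluid = 0))
  w0 <- sqrt(2e8 / 5e-3)
  expect_equal(Mod(segment_impedance(lossless, w0)$Z[1]), 0)

  # passivity: Re(Z) equals r_visc at any frequency
  net <- toy_network()
  for (f in c(5e3, 20e3, 60e3)) {
    om <- 2 * pi * f
    expect_equal(Re(segment_impedance(net, om)$Z[1]),
                 viscous_resistance(om, mats))
  }
  expect_error(segment_impedance(net, 0), "positive")
})

test_that("stiff-coupling limit collapses to the single oscillator", {
  # k_ca -> infinity with m_tm = k_tm = 0: series spring disappears
  net <- toy_network(k_ca = 1e6 * 2e8, m_tm = 0, k_tm = 0)
  ref <- toy_network(k_ca = 0, m_tm = 0, k_tm = 0)
  for (f in c(10e3, 40e3, 80e3)) {
    om <- 2 * pi * f
    Z1 <- segment_impedance(net, om)$Z[1]
    Z0 <- segment_impedance(ref, om)$Z[1]
    expect_lt(Mod(Z1 - Z0) / Mod(Z0), 1e-3)
  }
})

test_that("two-DOF reactance has exactly two zero crossings", {
  net <- toy_network()   # two distinct resonances inside the sweep
  freqs <- seq(2e3, 120e3, by = 250)
  omegas <- 2 * pi * freqs
  reactance <- vapply(omegas, function(om)
    Im(segment_impedance(net, om)$Z[1]), numeric(1))
  # the reactance also flips sign discontinuously at the tectorial-branch
  # antiresonance (a pole, not a zero); multiplying by the branch
  # denominator removes the pole and leaves the two true zeros
  denom <- net$k_ca[1] + net$k_tm[1] - omegas^2 * net$m_tm[1]
  zeros <- sum(diff(sign(reactance * denom)) != 0)
  expect_identical(zeros, 2L)
  # and the raw reactance changes sign once more, at the pole
  expect_identical(sum(diff(sign(reactance)) != 0), 3L)
})

test_that("impedance agrees with brute-force integration of the 2-DOF ODEs", {
  skip_if_not_installed("deSolve")
  omega <- 2 * pi * 30e3
  net <- toy_network()
  r <- viscous_resistance(omega, net$materials)
  imp <- segment_impedance(net, omega)
  Z <- imp$Z[1]

  p0 <- 1
  deriv <- function(t, y, parms) {
    a1 <- (p0 * cos(omega * t) - 2e8 * y[1] - 1.5e8 * (y[1] - y[3]) -
             r * y[2]) / 5e-3
    a2 <- (1.5e8 * (y[1] - y[3]) - 3e8 * y[3]) / 4e-3
    list(c(y[2], a1, y[4], a2))
  }
  Tp <- 2 * pi / omega
  out <- deSolve::ode(c(0, 0, 0, 0), seq(0, 40 * Tp, by = Tp / 400),
                      deriv, NULL, method = "ode45",
                      rtol = 1e-9, atol = 1e-13)
  sel <- out[, 1] >= 35 * Tp
  tt <- out[sel, 1]
  v1 <- out[sel, 3]
  V <- complex(real = 2 * mean(v1 * cos(omega * tt)),
               imaginary = -2 * mean(v1 * sin(omega * tt)))
  Z_ode <- p0 / V
  expect_lt(abs(Mod(Z_ode) - Mod(Z)) / Mod(Z), 0.01)
  expect_lt(abs(Arg(Z_ode) - Arg(Z)), 0.01)

  # the TM transfer ratio from the same run
  x2 <- out[sel, 4]; x1 <- out[sel, 2]
  expect_lt(abs(max(abs(x2)) / max(abs(x1)) - abs(imp$tm_transfer[1])), 0.01)
})

test_that("material_set validates its invariants", {
  expect_error(material_set(E_dw = -1), "positive")
  expect_error(material_set(nu = 0.5), "nu")
  expect_error(material_set(mu_fluid = -1e-3), "mu_fluid")
  m <- material_set()
  expect_equal(m$E_dw, 3e6)        # dorsal wall, 0.003 GPa
  expect_equal(m$E_av_wall, 15e9)  # vesicle wall, 15 GPa
  expect_equal(m$E_tm, 5e7)        # tectorial membrane, 0.05 GPa
})
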