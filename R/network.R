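#' Material constants of the inner-ear model
#'
#' Default Young's moduli follow the published table for the *Mimetica* sp.
#' model (values in Pa): dorsal wall 3 MPa, auditory-vesicle wall 15 GPa,
#' cap cell 0.01 GPa, dendrite 0.02 GPa, tectorial membrane 0.05 GPa,
#' tympanal plate 1 GPa, pressure-release facilitator 0.025 GPa. The
#' auditory-vesicle fluid is water-like (density 1000 kg/m^3, viscosity
#' 1.002 mPa s at 20 C). Cuticle density is not printed for this species;
#' 1200 kg/m^3 is a typical insect-cuticle value and is configurable, as is
#' the Poisson ratio (0.3).
#'
#' @param E_dw,E_av_wall,E_capcell,E_dendrite,E_tm,E_tp,E_prf Young's
#'   moduli, Pa
#' @param rho_cuticle cuticle density, kg/m^3
#' @param rho_fluid fluid density, kg/m^3
#' @param mu_fluid fluid dynamic viscosity, Pa s
#' @param nu Poisson ratio (0 <= nu < 0.5)
#' @return object of class `material_set`
#' @export
material_set <- function(E_dw = 3e6, E_av_wall = 15e9, E_capcell = 1e7,
                         E_dendrite = 2e7, E_tm = 5e7, E_tp = 1e9,
                         E_prf = 2.5e7, rho_cuticle = 1200,
                         rho_fluid = 1000, mu_fluid = 1.002e-3, nu = 0.3) {
  m <- list(E_dw = E_dw, E_av_wall = E_av_wall, E_capcell = E_capcell,
            E_dendrite = E_dendrite, E_tm = E_tm, E_tp = E_tp,
            E_prf = E_prf, rho_cuticle = rho_cuticle,
            rho_fluid = rho_fluid, mu_fluid = mu_fluid, nu = nu)
  moduli <- unlist(m[1:7])
  if (any(moduli <= 0) || rho_cuticle <= 0 || rho_fluid <= 0)
    stop("material_set: moduli and densities must be positive", call. = FALSE)
  if (mu_fluid < 0)
    stop("material_set: mu_fluid must be >= 0", call. = FALSE)
  if (nu < 0 || nu >= 0.5)
    stop("material_set: need 0 <= nu < 0.5", call. = FALSE)
  structure(m, class = "material_set")
}

#' Ablation specification
#'
#' The two in-silico manipulations used to identify the driver of tonotopy:
#' \describe{
#'   \item{intact}{full network.}
#'   \item{no_ca}{crista acustica removed; the dorsal-wall modulus is raised
#'     to 13 MPa, compensating the stiffening the dendrite coupling provides
#'     in the intact system.}
#'   \item{uniform_dw}{the dorsal-wall thickness taper is removed (uniform
#'     15 um) and its modulus set to that of the remaining vesicle wall
#'     (15 GPa); the crista acustica stays in place.}
#' }
#'
#' @param mode one of `"intact"`, `"no_ca"`, `"uniform_dw"`
#' @param E_dw_override Pa; only used for `no_ca` (default 13 MPa)
#' @param uniform_thickness um; only used for `uniform_dw` (default 15)
#' @return object of class `ablation_spec`
#' @export
ablation_spec <- function(mode = c("intact", "no_ca", "uniform_dw"),
                          E_dw_override = NULL, uniform_thickness = 15) {
  mode <- match.arg(mode)
  if (mode == "no_ca" && is.null(E_dw_override)) E_dw_override <- 13e6
  structure(list(mode = mode, E_dw_override = E_dw_override,
                 uniform_thickness = uniform_thickness),
            class = "ablation_spec")
}

um <- 1e-6  # geometry profiles are in um; mechanics in SI

#' Areal bending stiffness of a clamped plate strip
#'
#' Reduction of the shell formulation to a beam-strip areal stiffness:
#' `k(x) = beta * E * t(x)^3 / ((1 - nu^2) * w(x)^4)` in N/m^3, with
#' `beta = 384/12` for a clamped-clamped strip under uniform load (the
#' 384/(12) factor is the uniform-load midspan coefficient of E*I per unit
#' width, I = t^3/12). `scale` is the dimensionless stiffness multiplier the
#' calibration adjusts.
#'
#' @param profile a [build_profile()] geometry (um units)
#' @param E Young's modulus, Pa
#' @param nu Poisson ratio
#' @param beta geometric constant (default 384/12)
#' @param scale calibration stiffness scale (default 1)
#' @return areal stiffness k(x), N/m^3, one value per grid point
#' @export
plate_stiffness <- function(profile, E, nu = 0.3, beta = 384 / 12,
                            scale = 1) {
  stopifnot(inherits(profile, "geometry_profile"))
  if (E <= 0) stop("plate_stiffness: E must be positive", call. = FALSE)
  w <- profile$width * um
  t <- profile$thickness * um
  if (any(w == 0))
    stop("invalid-geometry: zero width in profile", call. = FALSE)
  scale * beta * E * t^3 / ((1 - nu^2) * w^4)
}

#' Areal masses of the dorsal wall and tectorial membrane
#'
#' `m_dw = rho_cuticle * t(x)`, `m_tm = rho_cuticle * t_tm(x)` with the
#' tectorial-membrane thickness interpolated linearly between its printed
#' endpoints (3.47 um distal, 3.08 um proximal).
#'
#' @param profile geometry profile (um)
#' @param materials a [material_set()]
#' @param tm_thickness_endpoints `(distal, proximal)` tectorial-membrane
#'   thickness, um
#' @return list with `m_dw`, `m_tm` (kg/m^2) and `t_tm` (um)
#' @export
areal_masses <- function(profile, materials,
                         tm_thickness_endpoints = c(3.47, 3.08)) {
  stopifnot(inherits(profile, "geometry_profile"),
            inherits(materials, "material_set"))
  t_tm <- tm_thickness_endpoints[1] +
    (tm_thickness_endpoints[2] - tm_thickness_endpoints[1]) *
    profile$x / profile$length
  list(m_dw = materials$rho_cuticle * profile$thickness * um,
       m_tm = materials$rho_cuticle * t_tm * um,
       t_tm = t_tm)
}

#' Viscous areal resistance of the fluid boundary layers
#'
#' Stokes oscillatory boundary layer on the two wetted faces of a segment:
#' `r_visc = 2 * sqrt(rho_fluid * mu_fluid * omega / 2)` (N s/m^3). This is
#' the only loss channel in the model: the published model has no material
#' damping, viscous fluid losses only.
#'
#' @param omega angular frequency, rad/s (>= 0)
#' @param materials a [material_set()]
#' @return r_visc, N s/m^3
#' @export
viscous_resistance <- function(omega, materials) {
  if (any(omega < 0))
    stop("viscous_resistance: omega must be non-negative", call. = FALSE)
  2 * sqrt(materials$rho_fluid * materials$mu_fluid * omega / 2)
}

#' Default crista-acustica coupling stiffness
#'
#' The dendrite and cap cell act as springs in series between the dorsal
#' wall and the tectorial membrane. The printed moduli are bulk values; the
#' scolopidia are discrete, sparse structures, so the areal stiffness
#' carries an effective area-fraction factor `fill`. Neither the fill nor
#' the spring geometry is printed; the default (4e-4) is set by a
#' qualitative parametric sweep - the same procedure the original study
#' used for its moduli - constrained by the published intact-organ
#' behaviour: a monotone tonotopic map that flattens at high frequency,
#' crista displacement no larger than dorsal-wall displacement, and a
#' crista contribution that stays below the stiffening compensated by the
#' 13 MPa crista-removed override. Heights default to 15 um each over the
#' nominal 30 um organ height. The level is exposed as a calibratable
#' profile (`kca_scale`, `k_ca_profile`).
#'
#' @param materials a [material_set()]
#' @param fill effective plan-area fraction of the scolopidial springs
#' @param h_dendrite,h_capcell spring heights, um
#' @return scalar areal stiffness, N/m^3
#' @export
ca_coupling_stiffness <- function(materials, fill = 4e-4,
                                  h_dendrite = 15, h_capcell = 15) {
  fill / (h_dendrite * um / materials$E_dendrite +
            h_capcell * um / materials$E_capcell)
}

#' Assemble the per-segment mechanical network
#'
#' Builds the lumped parameters of the segment network at every grid point:
#' dorsal-wall areal mass `m_dw` and stiffness `k_dw`, crista-acustica
#' coupling stiffness `k_ca`, tectorial-membrane mass `m_tm` and grounded
#' stiffness `k_tm`. Ablation modes:
#' \itemize{
#'   \item `no_ca`: `k_ca = k_tm = m_tm = 0`, dorsal-wall modulus raised to
#'     the override (13 MPa by default).
#'   \item `uniform_dw`: thickness replaced by a uniform 15 um and modulus
#'     by the vesicle-wall value; the triangular width planform is retained
#'     (only the thickness gradient was removed in the original experiment)
#'     and the crista parameters stay.
#' }
#'
#' @param profile geometry profile
#' @param materials a [material_set()]
#' @param ablation an [ablation_spec()]
#' @param k_ca_profile optional areal stiffness profile (N/m^3, recycled);
#'   default from [ca_coupling_stiffness()]
#' @param k_tm_profile optional tectorial-membrane areal stiffness profile;
#'   default from [plate_stiffness()] with `E_tm`, the TM thickness taper
#'   and the TM span
#' @param tm_thickness_endpoints `(distal, proximal)` um
#' @param tm_width_fraction the tectorial membrane is slung between its two
#'   support bands and spans only the crista band, a fraction of the
#'   dorsal-wall width (default 0.5); its plate stiffness uses this
#'   narrower span
#' @param beta plate geometric constant
#' @param stiffness_scale calibration multiplier applied to the plate
#'   stiffnesses (dorsal wall and tectorial membrane)
#' @return object of class `segment_network`
#' @export
assemble_network <- function(profile, materials = material_set(),
                             ablation = ablation_spec("intact"),
                             k_ca_profile = NULL, k_tm_profile = NULL,
                             tm_thickness_endpoints = c(3.47, 3.08),
                             tm_width_fraction = 0.5,
                             beta = 384 / 12, stiffness_scale = 1) {
  stopifnot(inherits(profile, "geometry_profile"),
            inherits(materials, "material_set"))
  if (!inherits(ablation, "ablation_spec"))
    stop("configuration error: ablation must be an ablation_spec",
         call. = FALSE)
  mode <- ablation$mode
  if (!mode %in% c("intact", "no_ca", "uniform_dw"))
    stop("configuration error: unknown ablation mode '", mode, "'",
         call. = FALSE)

  n <- profile$n_segments
  dw_profile <- profile
  E_dw <- materials$E_dw
  if (mode == "no_ca") {
    E_dw <- ablation$E_dw_override %||% 13e6
  } else if (mode == "uniform_dw") {
    dw_profile <- new_geometry_profile(
      profile$x, profile$width,
      rep(ablation$uniform_thickness, n), profile$duct_height)
    E_dw <- materials$E_av_wall
  }

  masses <- areal_masses(dw_profile, materials, tm_thickness_endpoints)
  k_dw <- plate_stiffness(dw_profile, E_dw, materials$nu, beta,
                          stiffness_scale)

  if (mode == "no_ca") {
    k_ca <- k_tm <- m_tm <- rep(0, n)
  } else {
    k_ca <- if (is.null(k_ca_profile))
      rep(ca_coupling_stiffness(materials), n)
    else rep_len(k_ca_profile, n)
    k_tm <- if (is.null(k_tm_profile)) {
      tm_geo <- new_geometry_profile(
        profile$x, profile$width * tm_width_fraction,
        tm_thickness_endpoints[1] +
          diff(tm_thickness_endpoints) * profile$x / profile$length,
        profile$duct_height)
      plate_stiffness(tm_geo, materials$E_tm, materials$nu, beta,
                      stiffness_scale)
    } else rep_len(k_tm_profile, n)
    m_tm <- masses$m_tm
  }
  if (any(c(k_dw, k_ca, k_tm, masses$m_dw, m_tm) < 0))
    stop("segment_network: negative mass or stiffness", call. = FALSE)

  structure(list(
    x = profile$x,
    profile = dw_profile,
    m_dw = masses$m_dw, k_dw = k_dw,
    k_ca = k_ca, m_tm = m_tm, k_tm = k_tm,
    materials = materials,
    ablation_mode = mode,
    E_dw_used = E_dw
  ), class = "segment_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.segment_network <- function(x, ...) {
  cat(sprintf("segment_network (%s): %d segments\n", x$ablation_mode,
              length(x$x)))
  cat(sprintf("  E_dw used: %.3g Pa\n", x$E_dw_used))
  cat(sprintf("  k_dw: %.3g .. %.3g N/m^3\n", min(x$k_dw), max(x$k_dw)))
  if (any(x$k_ca > 0))
    cat(sprintf("  k_ca: %.3g, k_tm: %.3g .. %.3g N/m^3\n",
                x$k_ca[1], min(x$k_tm), max(x$k_tm)))
  invisible(x)
}

#' Complex areal impedance of a segment
#'
#' Harmonic balance of the two-degree-of-freedom segment network (pressure
#' drives the dorsal wall; the wall drives the tectorial membrane through
#' the crista spring; the membrane is restrained by its own grounded
#' spring):
#' \deqn{Z(\omega) = \frac{k_{dw} + k_{ca} - \omega^2 m_{dw} -
#'   k_{ca}^2 / (k_{ca} + k_{tm} - \omega^2 m_{tm})}{i\omega} + r_{visc}}
#' The tectorial-membrane transfer ratio
#' `x_tm / x_dw = k_ca / (k_ca + k_tm - omega^2 m_tm)` is returned
#' alongside.
#'
#' @param network a [assemble_network()] object
#' @param omega angular frequency, rad/s (> 0)
#' @return list with complex vector `Z` (N s/m^3), real/complex vector
#'   `tm_transfer`, and `r_visc`
#' @export
segment_impedance <- function(network, omega) {
  stopifnot(inherits(network, "segment_network"))
  if (omega <= 0)
    stop("segment_impedance: omega must be positive", call. = FALSE)
  r <- viscous_resistance(omega, network$materials)
  denom <- network$k_ca + network$k_tm - omega^2 * network$m_tm
  branch <- numeric(length(denom))
  active <- network$k_ca > 0
  if (any(active & denom == 0))
    stop("resonance-singularity: the tectorial-membrane branch is exactly ",
         "at resonance (k_ca + k_tm = omega^2 m_tm); in practice r_visc > 0 ",
         "keeps the assembled line regular - perturb omega or the profile",
         call. = FALSE)
  branch[active] <- network$k_ca[active]^2 / denom[active]
  reactance <- network$k_dw + network$k_ca - omega^2 * network$m_dw - branch
  Z <- reactance / (1i * omega) + r
  transfer <- numeric(length(denom))
  transfer[active] <- network$k_ca[active] / denom[active]
  list(Z = Z, tm_transfer = transfer, r_visc = r)
}

#' Dump a segment network as CSV
#'
#' Columns: `x_um, m_dw, k_dw, k_ca, m_tm, k_tm`.
#' @param network a `segment_network`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_network_csv <- function(network, path) {
  utils::write.csv(data.frame(
    x_um = network$x, m_dw = network$m_dw, k_dw = network$k_dw,
    k_ca = network$k_ca, m_tm = network$m_tm, k_tm = network$k_tm
  ), path, row.names = FALSE)
  invisible(path)
}
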