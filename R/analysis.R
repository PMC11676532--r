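#' Steady-state displacement envelope from a time solution
#'
#' The envelope is the smooth curve outlining the extremes of the
#' displacement oscillations: at each grid point, the maximum of
#' `|x_dw(x, t)|` over the steady-state samples.
#'
#' @param ts a [solve_time()] result whose steady-state mask covers at
#'   least 3 drive cycles
#' @return non-negative envelope, m, one value per grid point
#' @export
envelope <- function(ts) {
  stopifnot(inherits(ts, "time_solution"))
  n_steady <- sum(ts$steady_state_mask)
  if (n_steady * ts$dt < 3 / ts$frequency - 1e-12 / ts$frequency)
    stop("insufficient-simulation: need at least 3 steady-state cycles ",
         "for an envelope; increase n_cycles", call. = FALSE)
  apply(abs(ts$snapshots[, ts$steady_state_mask, drop = FALSE]), 1, max)
}

#' Peak distance from the distal end
#'
#' Position of the envelope (or frequency-domain magnitude) maximum,
#' refined by 3-point parabolic interpolation around the discrete argmax,
#' reported in um from the distal end (x = 0).
#'
#' @param env numeric envelope over the grid, or a `frequency_solution`
#'   (in which case the magnitude of the selected displacement field is
#'   used)
#' @param x grid positions, um (not needed for a `frequency_solution`)
#' @param field for a `frequency_solution`: `"dw"` (dorsal wall, default)
#'   or `"tm"` (tectorial membrane / crista surface)
#' @return distance, um. If the maximum sits on a grid boundary the
#'   (unrefined) boundary position is returned with attribute
#'   `boundary = TRUE`.
#' @export
peak_distance_from_distal <- function(env, x = NULL,
                                      field = c("dw", "tm")) {
  field <- match.arg(field)
  if (inherits(env, "frequency_solution")) {
    x <- env$x
    env <- if (field == "tm") Mod(env$x_tm) else Mod(env$x_dw)
  }
  stopifnot(length(env) == length(x))
  if (diff(range(env)) == 0)
    stop("ambiguous-peak: envelope is flat", call. = FALSE)
  i <- which.max(env)
  n <- length(env)
  if (i == 1L || i == n) {
    out <- x[i]
    attr(out, "boundary") <- TRUE
    return(out)
  }
  # parabola through (x[i-1..i+1], env[i-1..i+1]); vertex offset in cells
  y1 <- env[i - 1]; y2 <- env[i]; y3 <- env[i + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 0.5), -0.5)
  out <- x[i] + delta * (x[i + 1] - x[i])
  attr(out, "boundary") <- FALSE
  out
}

#' Envelope asymmetry ratio about the peak
#'
#' Average dB-per-um slope magnitude over the first `window_db` decibels of
#' drop on either side of the peak, reported as
#' `leading / trailing`, where "leading" is the side of the peak facing the
#' driven end (the side the wave arrives from) and "trailing" is the far
#' side. For a travelling wave the envelope builds up gradually on the
#' arrival side and cuts off sharply beyond the best place, so the
#' travelling-wave signature is a ratio below 1. A symmetric envelope gives
#' exactly 1.
#'
#' @param env envelope over the grid (linear amplitude)
#' @param x grid positions, um
#' @param peak_position um; defaults to [peak_distance_from_distal()]
#' @param window_db evaluation window below the peak, dB (default 10)
#' @param drive_end `"distal"` or `"proximal"`: which side the wave
#'   arrives from
#' @return dimensionless ratio; `NA` with a warning if the peak sits on the
#'   transect boundary, and attribute `one_sided = TRUE` if the envelope
#'   drops by less than `window_db` on one side
#' @export
asymmetry_ratio <- function(env, x, peak_position = NULL, window_db = 10,
                            drive_end = c("distal", "proximal")) {
  drive_end <- match.arg(drive_end)
  if (is.null(peak_position)) peak_position <- peak_distance_from_distal(env, x)
  i <- which.min(abs(x - peak_position))
  n <- length(env)
  if (i == 1L || i == n) {
    warning("boundary-peak: peak at the transect boundary, ",
            "asymmetry ratio undefined")
    return(NA_real_)
  }
  env_db <- 20 * log10(pmax(env, .Machine$double.xmin))
  peak_db <- env_db[i]
  side_slope <- function(idx) {
    # mean |dB/um| over the window from the peak to the first sample
    # window_db below it (or the last available sample)
    if (length(idx) == 0) return(list(slope = NA_real_, complete = FALSE))
    drop <- peak_db - env_db[idx]
    hit <- which(drop >= window_db)
    complete <- length(hit) > 0
    j <- if (complete) idx[hit[1]] else idx[length(idx)]
    d <- abs(peak_db - env_db[j]) / abs(x[j] - x[i])
    list(slope = d, complete = complete)
  }
  left <- side_slope(seq(i - 1, 1))
  right <- side_slope(seq(i + 1, n))
  leading <- if (drive_end == "distal") left else right
  trailing <- if (drive_end == "distal") right else left
  out <- leading$slope / trailing$slope
  if (!leading$complete || !trailing$complete)
    attr(out, "one_sided") <- TRUE
  out
}

#' Unwrapped phase profile of the dorsal-wall displacement
#'
#' Phase of `x_dw` along the transect, unwrapped so no adjacent jump
#' exceeds 180 degrees, between the measurement points `P1` and `P2`
#' (default: the transect endpoints).
#'
#' @param fs a [solve_frequency()] result
#' @param P1,P2 positions, um, `P1 < P2` within the grid
#' @return object of class `phase_profile`: `x` (um), `phase_unwrapped`
#'   (degrees), `P1`, `P2`, `frequency`
#' @export
phase_profile <- function(fs, P1 = NULL, P2 = NULL) {
  stopifnot(inherits(fs, "frequency_solution"))
  if (is.null(P1)) P1 <- fs$x[1]
  if (is.null(P2)) P2 <- fs$x[length(fs$x)]
  if (!(P1 < P2))
    stop("phase_profile: need P1 < P2", call. = FALSE)
  sel <- which(fs$x >= P1 - 1e-9 & fs$x <= P2 + 1e-9)
  # the displacement is exactly zero at the pressure-release node (p = 0
  # there by construction) and Arg(0) is meaningless; the pressure varies
  # linearly through zero at that end, so the correct limiting phase is the
  # phase of the nearest interior node. Degenerate nodes are therefore
  # carried with the nearest valid phase.
  amp <- Mod(fs$x_dw[sel])
  valid <- amp > 0
  if (!any(valid))
    stop("phase_profile: zero field has no phase", call. = FALSE)
  ph_valid <- signal::unwrap(Arg(fs$x_dw[sel][valid])) * 180 / pi
  idx <- findInterval(seq_along(sel), which(valid))
  idx[idx == 0] <- 1L
  ph <- ph_valid[idx]
  structure(list(frequency = fs$frequency, x = fs$x[sel],
                 phase_unwrapped = ph, P1 = P1, P2 = P2),
            class = "phase_profile")
}

#' Accumulated phase lag between P1 and P2
#'
#' `phase(P1) - phase(P2)` in degrees. With the wave travelling away from
#' the driven end, phase decreases along the propagation direction, so the
#' lag accumulated between the near-drive point and the far point is
#' positive.
#'
#' @param pp a [phase_profile()]
#' @return lag, degrees
#' @export
phase_accumulation <- function(pp) {
  stopifnot(inherits(pp, "phase_profile"))
  ph <- pp$phase_unwrapped
  ph[1] - ph[length(ph)]
}

#' Tonotopic map: frequency to peak place
#'
#' Per-frequency peak distances from the distal end, with a monotonicity
#' flag (distances non-increasing with frequency, the signature of
#' tonotopy). Frequencies whose envelope peak is ambiguous are recorded as
#' `NA`, never fabricated.
#'
#' @param solutions list of `frequency_solution` objects (>= 3 frequencies),
#'   or a list with elements `env` + `x` + `frequency`
#' @param source label: `"intact"`, `"no_ca"` or `"uniform_dw"`
#' @param field displacement field for the peak, `"dw"` or `"tm"`; the
#'   uniform-DW experiment reports the maximum on the crista surface, so
#'   use `"tm"` there
#' @return object of class `tonotopic_map`: data frame `frequency_hz`,
#'   `peak_um`, plus `monotone` flag
#' @export
tonotopic_map <- function(solutions, source = "intact",
                          field = c("dw", "tm")) {
  field <- match.arg(field)
  if (length(solutions) < 3)
    stop("tonotopic_map: need at least 3 frequencies", call. = FALSE)
  freq <- vapply(solutions, function(s) s$frequency, numeric(1))
  peak <- vapply(solutions, function(s) {
    p <- tryCatch(
      if (inherits(s, "frequency_solution"))
        peak_distance_from_distal(s, field = field)
      else peak_distance_from_distal(s$env, s$x),
      error = function(e) NA_real_)
    as.numeric(p)
  }, numeric(1))
  ord <- order(freq)
  freq <- freq[ord]; peak <- peak[ord]
  ok <- !is.na(peak)
  monotone <- all(diff(peak[ok]) <= 1e-9)
  structure(list(
    map = data.frame(frequency_hz = freq, peak_um = peak),
    source = source, monotone = monotone
  ), class = "tonotopic_map")
}

#' @export
print.tonotopic_map <- function(x, ...) {
  cat(sprintf("tonotopic_map (%s), monotone decreasing: %s\n",
              x$source, x$monotone))
  print(x$map, row.names = FALSE)
  invisible(x)
}

#' Linearity of the tonotopic map
#'
#' Ordinary least-squares R^2 of peak distance versus frequency. The
#' crista-removed map is expected to be closer to linear than the intact
#' one (the crista components bend the intact map at high frequencies).
#'
#' @param map a [tonotopic_map()] with >= 4 usable frequencies
#' @return R^2 in [0, 1]; `NA` with a warning for a degenerate
#'   (constant) map
#' @export
map_linearity <- function(map) {
  stopifnot(inherits(map, "tonotopic_map"))
  d <- map$map[!is.na(map$map$peak_um), ]
  if (nrow(d) < 4)
    stop("map_linearity: need at least 4 frequencies", call. = FALSE)
  if (diff(range(d$peak_um)) == 0) {
    warning("degenerate map: constant peak position, R^2 undefined")
    return(NA_real_)
  }
  summary(stats::lm(peak_um ~ frequency_hz, data = d))$r.squared
}
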