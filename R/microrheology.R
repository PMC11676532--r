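kB <- 1.380649e-23  # Boltzmann constant, J/K

#' Bead and imaging specification for microrheology
#'
#' Defaults follow the published recordings: 1.02 um fluorescent
#' microspheres (radius 0.51 um) observed at 50 Hz (frame interval 0.02 s)
#' at room temperature. `localization_noise_sd` is the static localization
#' error of the tracking step (default 20 nm, a typical value for
#' epifluorescence centroid tracking); it inflates the measured MSD by an
#' additive `4 sigma^2`, which the viscosity fitter absorbs with its offset
#' term.
#'
#' @param radius bead radius, m
#' @param temperature K
#' @param frame_interval s
#' @param localization_noise_sd m
#' @return object of class `bead_spec`
#' @export
bead_spec <- function(radius = 0.51e-6, temperature = 293.15,
                      frame_interval = 0.02, localization_noise_sd = 20e-9) {
  if (radius <= 0 || temperature <= 0 || frame_interval <= 0)
    stop("bead_spec: radius, temperature and frame_interval must be ",
         "positive", call. = FALSE)
  if (localization_noise_sd < 0)
    stop("bead_spec: localization_noise_sd must be >= 0", call. = FALSE)
  structure(list(radius = radius, temperature = temperature,
                 frame_interval = frame_interval,
                 localization_noise_sd = localization_noise_sd),
            class = "bead_spec")
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB T / (6 pi eta a)`.
#'
#' @param bead a [bead_spec()]
#' @param viscosity Pa s
#' @return D, m^2/s
#' @export
diffusion_coefficient <- function(bead, viscosity) {
  stopifnot(inherits(bead, "bead_spec"))
  if (viscosity <= 0)
    stop("viscosity must be positive", call. = FALSE)
  kB * bead$temperature / (6 * pi * viscosity * bead$radius)
}

# fractional Gaussian noise by Davies-Harte circulant embedding;
# increments of fBm with Hurst H, unit variance per step at lag 1
fgn <- function(n, H) {
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  m <- 2 * n
  row1 <- c(g(0:(n - 1)), g(n), g((n - 1):1))
  lambda <- Re(stats::fft(row1))
  lambda[lambda < 0] <- 0   # clip tiny negatives from roundoff
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  w <- stats::fft(sqrt(lambda / (2 * m)) * z)
  Re(w)[1:n]
}

#' Simulate 2D Brownian bead trajectories
#'
#' Per-axis Gaussian increments with variance `2 D dt`,
#' `D = kB T / (6 pi eta a)`; optional additive localization noise on the
#' observed positions. Setting `alpha < 1` produces subdiffusive fractional
#' Brownian motion with `msd = 4 D dt^(1-alpha) tau^alpha` at lag 1 scaled
#' to match the Brownian step variance (used to test the Newtonian check).
#' Seeded and bit-reproducible.
#'
#' @param n_particles,n_frames counts (>= 1)
#' @param bead a [bead_spec()]
#' @param viscosity Pa s (> 0)
#' @param seed integer RNG seed
#' @param alpha MSD power-law exponent of the generated motion (default 1,
#'   Newtonian)
#' @param start_positions optional n x 2 matrix of starting positions (m);
#'   defaults to the origin for every particle
#' @return object of class `trajectory_set`: data frame `tracks`
#'   (`track_id`, `frame`, `x_m`, `y_m`) plus metadata (`seed`,
#'   `true_viscosity`, `bead`)
#' @export
simulate_trajectories <- function(n_particles, n_frames, bead = bead_spec(),
                                  viscosity = 1.002e-3, seed = 1,
                                  alpha = 1, start_positions = NULL) {
  stopifnot(inherits(bead, "bead_spec"))
  if (n_particles < 1 || n_frames < 1)
    stop("n_particles and n_frames must be >= 1", call. = FALSE)
  D <- diffusion_coefficient(bead, viscosity)
  step_sd <- sqrt(2 * D * bead$frame_interval)
  if (is.null(start_positions))
    start_positions <- matrix(0, n_particles, 2)
  set.seed(as.integer(seed))
  tracks <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    n_inc <- n_frames - 1L
    if (n_inc > 0) {
      if (alpha == 1) {
        dx <- stats::rnorm(n_inc, sd = step_sd)
        dy <- stats::rnorm(n_inc, sd = step_sd)
      } else {
        dx <- step_sd * fgn(n_inc, alpha / 2)
        dy <- step_sd * fgn(n_inc, alpha / 2)
      }
      x <- start_positions[i, 1] + c(0, cumsum(dx))
      y <- start_positions[i, 2] + c(0, cumsum(dy))
    } else {
      x <- start_positions[i, 1]; y <- start_positions[i, 2]
    }
    if (bead$localization_noise_sd > 0) {
      x <- x + stats::rnorm(n_frames, sd = bead$localization_noise_sd)
      y <- y + stats::rnorm(n_frames, sd = bead$localization_noise_sd)
    }
    tracks[[i]] <- data.frame(track_id = i, frame = seq_len(n_frames),
                              x_m = x, y_m = y)
  }
  structure(list(tracks = do.call(rbind, tracks), seed = seed,
                 true_viscosity = viscosity, bead = bead,
                 frame_interval = bead$frame_interval),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d tracks, %d rows%s\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks),
              if (!is.null(x$true_viscosity))
                sprintf(" (synthetic, eta = %.3g Pa s)", x$true_viscosity)
              else ""))
  invisible(x)
}

#' Render trajectories as synthetic fluorescence frames
#'
#' Gaussian spots of constant intensity on a zero background, one frame per
#' trajectory time point. The pixel at row r / column c spans
#' `[(c-1), c] x [(r-1), r] * pixel_size` with its center at
#' `(c - 0.5, r - 0.5) * pixel_size`; x maps to columns, y to rows.
#' Particles whose center leaves the field of view are clipped (a warning
#' reports the count).
#'
#' @param ts a `trajectory_set`
#' @param image_size pixels, scalar or `c(ncol, nrow)`
#' @param psf_sd point-spread-function standard deviation, px
#' @param pixel_size m per pixel
#' @param intensity peak spot intensity (arbitrary units)
#' @return list of numeric matrices (one per frame), with attributes
#'   `pixel_size` and `n_clipped`
#' @export
render_frames <- function(ts, image_size = 96, psf_sd = 2,
                          pixel_size = 0.25e-6, intensity = 1000) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  ncol_px <- image_size[1]; nrow_px <- image_size[2]
  frames_idx <- sort(unique(ts$tracks$frame))
  half <- ceiling(4 * psf_sd)
  n_clipped <- 0L
  frames <- lapply(frames_idx, function(f) {
    img <- matrix(0, nrow_px, ncol_px)
    pts <- ts$tracks[ts$tracks$frame == f, ]
    for (k in seq_len(nrow(pts))) {
      cx <- pts$x_m[k] / pixel_size   # in px units, 0 at the left edge
      cy <- pts$y_m[k] / pixel_size
      if (cx < 0 || cx > ncol_px || cy < 0 || cy > nrow_px) {
        n_clipped <<- n_clipped + 1L
        next
      }
      cols <- max(1, floor(cx - half)):min(ncol_px, ceiling(cx + half))
      rows <- max(1, floor(cy - half)):min(nrow_px, ceiling(cy + half))
      gx <- exp(-((cols - 0.5) - cx)^2 / (2 * psf_sd^2))
      gy <- exp(-((rows - 0.5) - cy)^2 / (2 * psf_sd^2))
      img[rows, cols] <- img[rows, cols] + intensity * outer(gy, gx)
    }
    img
  })
  if (n_clipped > 0)
    warning(n_clipped, " particle positions fell outside the frame and ",
            "were clipped")
  attr(frames, "pixel_size") <- pixel_size
  attr(frames, "n_clipped") <- n_clipped
  frames
}

#' Localize particles in an image stack
#'
#' Intensity-weighted centroid of every above-threshold connected region
#' (8-connectivity, labelled with `EBImage::bwlabel`), giving sub-pixel
#' positions. A frame with no detections yields an empty set, not an error.
#'
#' @param frames list of numeric matrices (as from [render_frames()])
#' @param threshold absolute intensity threshold
#' @param pixel_size m per pixel (defaults to the attribute set by
#'   [render_frames()], else 1)
#' @return list of data frames (`frame`, `x_m`, `y_m`, `mass`), one per
#'   frame
#' @export
localize <- function(frames, threshold, pixel_size = NULL) {
  if (length(frames) == 0) stop("localize: empty frame list", call. = FALSE)
  if (is.null(pixel_size))
    pixel_size <- attr(frames, "pixel_size") %||% 1
  lapply(seq_along(frames), function(f) {
    img <- frames[[f]]
    mask <- img > threshold
    if (!any(mask))
      return(data.frame(frame = integer(0), x_m = numeric(0),
                        y_m = numeric(0), mass = numeric(0)))
    labels <- EBImage::bwlabel(mask)
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[idx]
    w <- img[idx]
    xs <- (idx[, "col"] - 0.5) * w
    ys <- (idx[, "row"] - 0.5) * w
    mass <- tapply(w, lab, sum)
    data.frame(frame = f,
               x_m = as.numeric(tapply(xs, lab, sum) / mass) * pixel_size,
               y_m = as.numeric(tapply(ys, lab, sum) / mass) * pixel_size,
               mass = as.numeric(mass))
  })
}

#' Link per-frame positions into trajectories
#'
#' Greedy mutual-nearest-neighbour linking gated at `max_step`. A link is
#' made only when it is unambiguous: the track end and the detection are
#' mutual nearest neighbours and neither has any other candidate within the
#' gate. Ambiguous situations (e.g. two particles crossing within the gate)
#' terminate the tracks involved rather than guessing; unmatched detections
#' start new tracks.
#'
#' @param positions list of per-frame data frames with columns `x_m`, `y_m`
#'   (as from [localize()])
#' @param max_step gate distance, m
#' @param frame_interval s (stored in the result; default 0.02)
#' @param bead optional [bead_spec()] carried through to the result
#' @return a `trajectory_set`
#' @export
link_tracks <- function(positions, max_step, frame_interval = 0.02,
                        bead = NULL) {
  if (length(positions) < 2)
    stop("link_tracks: need at least 2 frames", call. = FALSE)
  next_id <- 0L
  open_id <- integer(0)       # track ids open at the previous frame
  open_xy <- matrix(numeric(0), 0, 2)
  rows <- list()
  add_row <- function(id, f, xy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = id, frame = f, x_m = xy[1], y_m = xy[2])
  }
  for (f in seq_along(positions)) {
    det <- positions[[f]]
    det_xy <- cbind(det$x_m, det$y_m)
    nd <- nrow(det_xy); nt <- length(open_id)
    linked_det <- rep(FALSE, nd)
    new_open_id <- integer(0)
    new_open_xy <- matrix(numeric(0), 0, 2)
    if (nt > 0 && nd > 0) {
      dmat <- sqrt(outer(open_xy[, 1], det_xy[, 1], "-")^2 +
                     outer(open_xy[, 2], det_xy[, 2], "-")^2)
      in_gate <- dmat <= max_step
      cand_t <- rowSums(in_gate)   # candidates per open track
      cand_d <- colSums(in_gate)   # candidates per detection
      for (i in seq_len(nt)) {
        if (cand_t[i] != 1L) next            # none or ambiguous: terminate
        j <- which(in_gate[i, ])
        if (cand_d[j] != 1L) next            # contested detection
        add_row(open_id[i], f, det_xy[j, ])
        linked_det[j] <- TRUE
        new_open_id <- c(new_open_id, open_id[i])
        new_open_xy <- rbind(new_open_xy, det_xy[j, , drop = FALSE])
      }
    }
    for (j in seq_len(nd)) {
      if (linked_det[j]) next
      next_id <- next_id + 1L
      add_row(next_id, f, det_xy[j, ])
      new_open_id <- c(new_open_id, next_id)
      new_open_xy <- rbind(new_open_xy, det_xy[j, , drop = FALSE])
    }
    open_id <- new_open_id; open_xy <- new_open_xy
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, seed = NULL, true_viscosity = NULL,
                 bead = bead, frame_interval = frame_interval),
            class = "trajectory_set")
}

#' Time-and-ensemble averaged mean squared displacement
#'
#' For each lag, the 2D squared displacement averaged over all start times
#' within each track and then over tracks (weighted by the number of
#' pairs). Standard errors come from the spread of per-track MSD values.
#' Lags with no pairs are omitted; tracks shorter than two points are
#' skipped.
#'
#' @param ts a `trajectory_set`
#' @param max_lag_frames largest lag, frames (default 25)
#' @return object of class `msd_curve`: data frame `tau_s`, `msd_m2`,
#'   `n_pairs`, `se`
#' @export
msd <- function(ts, max_lag_frames = 25) {
  stopifnot(inherits(ts, "trajectory_set"))
  dt <- ts$frame_interval
  split_tracks <- split(ts$tracks, ts$tracks$track_id)
  split_tracks <- Filter(function(d) nrow(d) >= 2, split_tracks)
  if (length(split_tracks) == 0)
    stop("msd: no usable tracks (need >= 2 points)", call. = FALSE)
  max_len <- max(vapply(split_tracks, nrow, integer(1)))
  lags <- seq_len(min(max_lag_frames, max_len - 1))
  per_lag <- lapply(lags, function(L) {
    vals <- vapply(split_tracks, function(d) {
      n <- nrow(d)
      if (n <= L) return(c(NA_real_, 0))
      dx <- d$x_m[(1 + L):n] - d$x_m[1:(n - L)]
      dy <- d$y_m[(1 + L):n] - d$y_m[1:(n - L)]
      c(mean(dx^2 + dy^2), n - L)
    }, numeric(2))
    m_i <- vals[1, ]; w_i <- vals[2, ]
    ok <- w_i > 0
    if (!any(ok)) return(NULL)
    m_i <- m_i[ok]; w_i <- w_i[ok]
    mbar <- sum(w_i * m_i) / sum(w_i)
    se <- if (length(m_i) > 1)
      sqrt(sum(w_i * (m_i - mbar)^2) / sum(w_i) / (length(m_i) - 1))
    else mbar / sqrt(2 * w_i)   # single track: chi^2 approximation
    c(msd = mbar, n_pairs = sum(w_i), se = unname(se))
  })
  keep <- !vapply(per_lag, is.null, logical(1))
  out <- do.call(rbind, per_lag[keep])
  structure(list(curve = data.frame(
    tau_s = lags[keep] * dt,
    msd_m2 = out[, "msd"],
    n_pairs = out[, "n_pairs"],
    se = out[, "se"])), class = "msd_curve")
}

#' Fit viscosity and power-law exponent from an MSD curve
#'
#' Weighted linear fit `msd = offset + 4 D tau` over the lag window
#' corresponding to the probed frequency band (default 10^-2 to 25 Hz,
#' i.e. `tau` in `[1/(2 pi 25), 1/(2 pi 10^-2)]` s, inclusive rounding to
#' the available lags). The additive offset absorbs the static localization
#' error `4 sigma^2` and is included by default. Viscosity follows from
#' Stokes-Einstein, `eta = kB T / (6 pi a D)`. The power-law exponent
#' `alpha` is the log-log slope of the raw MSD over the window (subtracting
#' the fitted intercept would masquerade genuine anomalous curvature as a
#' static offset; with realistic localization noise the raw slope is biased
#' low by only a few percent). `newtonian` is `TRUE` when
#' `|alpha - 1| <= 0.1`.
#'
#' @param curve an [msd()] result with at least 5 usable lags
#' @param bead a [bead_spec()]
#' @param freq_range_hz probed frequency band, Hz (default `c(1e-2, 25)`)
#' @param offset include the static-error offset term (default TRUE)
#' @return object of class `rheology_result`: `viscosity` (Pa s) with 95%
#'   CI, `powerlaw_exponent` with 95% CI, `newtonian`,
#'   `frequency_range_probed`, `offset_m2`, `D`
#' @export
fit_viscosity <- function(curve, bead = bead_spec(),
                          freq_range_hz = c(1e-2, 25), offset = TRUE) {
  stopifnot(inherits(curve, "msd_curve"), inherits(bead, "bead_spec"))
  d <- curve$curve
  tau_min <- 1 / (2 * pi * max(freq_range_hz))
  tau_max <- 1 / (2 * pi * min(freq_range_hz))
  sel <- d$tau_s >= tau_min * (1 - 1e-9) & d$tau_s <= tau_max * (1 + 1e-9)
  if (sum(sel) < 5) sel <- rep(TRUE, nrow(d))  # inclusive fallback
  d <- d[sel, ]
  if (nrow(d) < 5)
    stop("fit_viscosity: need at least 5 lags", call. = FALSE)
  w <- if (all(is.finite(d$se)) && all(d$se > 0)) 1 / d$se^2
       else rep(1, nrow(d))
  fit <- if (offset)
    stats::lm(msd_m2 ~ tau_s, data = d, weights = w)
  else
    stats::lm(msd_m2 ~ tau_s + 0, data = d, weights = w)
  co <- summary(fit)$coefficients
  slope <- co["tau_s", "Estimate"]
  slope_se <- co["tau_s", "Std. Error"]
  if (slope <= 0)
    stop("physically-invalid: non-positive MSD slope; no diffusive motion ",
         "to invert", call. = FALSE)
  D <- slope / 4
  eta <- kB * bead$temperature / (6 * pi * bead$radius * D)
  eta_ci <- kB * bead$temperature /
    (6 * pi * bead$radius * (slope + c(1.96, -1.96) * slope_se) / 4)
  c0 <- if (offset) stats::coef(fit)[["(Intercept)"]] else 0
  ok <- d$msd_m2 > 0
  alpha <- NA_real_; alpha_ci <- c(NA_real_, NA_real_)
  if (sum(ok) >= 3) {
    lfit <- stats::lm(log(d$msd_m2[ok]) ~ log(d$tau_s[ok]))
    lsum <- summary(lfit)$coefficients
    alpha <- lsum[2, "Estimate"]
    alpha_ci <- alpha + c(-1.96, 1.96) * lsum[2, "Std. Error"]
  }
  structure(list(
    viscosity = eta, viscosity_ci = sort(eta_ci),
    D = D, offset_m2 = c0,
    powerlaw_exponent = alpha, powerlaw_ci = alpha_ci,
    newtonian = is.finite(alpha) && abs(alpha - 1) <= 0.1,
    frequency_range_probed = c(1 / (2 * pi * max(d$tau_s)),
                               1 / (2 * pi * min(d$tau_s)))
  ), class = "rheology_result")
}

#' @export
print.rheology_result <- function(x, ...) {
  cat(sprintf("rheology_result: eta = %.4g Pa s (95%% CI %.3g-%.3g)\n",
              x$viscosity, x$viscosity_ci[1], x$viscosity_ci[2]))
  cat(sprintf("  alpha = %.3f (95%% CI %.3f-%.3f), newtonian: %s\n",
              x$powerlaw_exponent, x$powerlaw_ci[1], x$powerlaw_ci[2],
              x$newtonian))
  invisible(x)
}

#' Fluid density from weight and volume
#'
#' The published density measurement drew the vesicle fluid into a
#' capillary, weighed it, and imaged the volume; density is weight/volume.
#' Retrieved volumes ranged 4-80 nL; a note flags inputs outside that
#' regime.
#'
#' @param weight kg (> 0... the withdrawn fluid mass)
#' @param volume m^3 (> 0); 1 nL = 1e-12 m^3
#' @return density, kg/m^3, with attribute `in_regime`
#' @export
density_from_weight_volume <- function(weight, volume) {
  if (volume <= 0)
    stop("density_from_weight_volume: volume must be positive",
         call. = FALSE)
  out <- weight / volume
  in_regime <- volume >= 4e-12 && volume <= 80e-12
  if (!in_regime)
    message("note: volume ", signif(volume / 1e-12, 3),
            " nL is outside the 4-80 nL regime of the reference procedure")
  attr(out, "in_regime") <- in_regime
  out
}

#' Write rendered frames as a TIFF stack
#'
#' @param frames list of matrices from [render_frames()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_frames_tiff <- function(frames, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_frames_tiff requires the 'tiff' package", call. = FALSE)
  mx <- max(unlist(lapply(frames, max)), 1)
  tiff::writeTIFF(lapply(frames, function(f) f / mx), path)
  invisible(path)
}
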