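#' Discretized dorsal-wall / duct geometry
#'
#' A `geometry_profile` discretizes the ~600 um transect of the katydid
#' dorsal wall (DW) onto a regular grid. The coordinate convention follows
#' the experimental reporting: `x = 0` at the DISTAL end of the transect,
#' increasing toward the proximal end, so that peak positions are "distances
#' from the distal end". The DW is triangular: it narrows and thickens
#' toward the distal end, which is what produces the stiffness gradient
#' (stiff distal, compliant proximal) underlying tonotopy.
#'
#' Fields (all per grid point unless scalar):
#' \describe{
#'   \item{n_segments}{number of grid points}
#'   \item{x}{position grid, um from the distal end, `x[1] = 0`,
#'     `x[n] = length`}
#'   \item{length}{transect length, um}
#'   \item{width}{DW width w(x), um (non-decreasing distal to proximal)}
#'   \item{thickness}{DW thickness t(x), um (non-increasing distal to
#'     proximal)}
#'   \item{duct_height}{fluid duct height H(x), um}
#'   \item{segment_area}{plan area of each segment, um^2 (cell length x
#'     local width)}
#' }
#'
#' @param x numeric grid (um)
#' @param width,thickness,duct_height numeric vectors (um), same length as x
#' @return object of class `geometry_profile`
#' @keywords internal
new_geometry_profile <- function(x, width, thickness, duct_height) {
  n <- length(x)
  stopifnot(length(width) == n, length(thickness) == n,
            length(duct_height) == n)
  if (n < 3L)
    stop("invalid-geometry: need at least 3 grid points", call. = FALSE)
  if (any(diff(x) <= 0) || x[1] != 0)
    stop("invalid-geometry: x must be strictly increasing with x[1] = 0",
         call. = FALSE)
  if (any(width <= 0) || any(thickness <= 0) || any(duct_height <= 0))
    stop("invalid-geometry: width, thickness and duct height must be positive",
         call. = FALSE)
  if (thickness[1] < thickness[n] - 1e-12 * thickness[1])
    stop("orientation error: thickness must not increase from the distal ",
         "end (x = 0) to the proximal end; distal thickness >= proximal ",
         "thickness is required", call. = FALSE)
  h <- diff(x)
  cell <- c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
  structure(list(
    n_segments   = n,
    x            = x,
    length       = x[n],
    width        = width,
    thickness    = thickness,
    duct_height  = duct_height,
    segment_area = cell * width
  ), class = "geometry_profile")
}

#' Build a tapered dorsal-wall geometry profile
#'
#' Interpolates the printed endpoint tapers onto a regular grid. Thickness
#' runs 4.84 um (distal) to 4.10 um (proximal) by default; width increases
#' distal to proximal. Tapers are linear in x by default; an exponential
#' taper (endpoint-matching geometric interpolation) is available via
#' `taper = "exponential"`.
#'
#' @param n_segments number of grid points (>= 3)
#' @param length transect length, um (default 600)
#' @param thickness_endpoints numeric length-2, `(distal, proximal)` um;
#'   distal must be >= proximal
#' @param width_endpoints numeric length-2, `(distal, proximal)` um
#' @param duct_height fluid duct height, um (scalar)
#' @param taper `"linear"` (default) or `"exponential"`
#' @return a [new_geometry_profile()] object
#' @export
#' @examples
#' gp <- build_profile(101)
#' gp$thickness[1]    # 4.84 um at the distal end
build_profile <- function(n_segments = 201L, length = 600,
                          thickness_endpoints = c(4.84, 4.10),
                          width_endpoints = c(40, 120),
                          duct_height = 100,
                          taper = c("linear", "exponential")) {
  taper <- match.arg(taper)
  if (n_segments < 3L)
    stop("invalid-geometry: n_segments must be >= 3", call. = FALSE)
  if (length <= 0 || any(thickness_endpoints <= 0) ||
      any(width_endpoints <= 0) || duct_height <= 0)
    stop("invalid-geometry: all dimensions must be positive", call. = FALSE)
  if (thickness_endpoints[1] < thickness_endpoints[2])
    stop("orientation error: thickness_endpoints must be ordered ",
         "(distal, proximal) with distal >= proximal (the dorsal wall ",
         "thins toward the proximal end)", call. = FALSE)
  x <- seq(0, length, length.out = n_segments)
  interp <- function(ends) {
    if (taper == "linear") {
      ends[1] + (ends[2] - ends[1]) * x / length
    } else {
      ends[1] * (ends[2] / ends[1])^(x / length)
    }
  }
  new_geometry_profile(
    x           = x,
    width       = interp(width_endpoints),
    thickness   = interp(thickness_endpoints),
    duct_height = rep(duct_height, n_segments)
  )
}

#' Build a uniform (taper-free) geometry profile
#'
#' Constant thickness and width along the transect. Used by the uniform-DW
#' ablation, in which the dorsal wall is given the 15 um thickness of the
#' remainder of the auditory-vesicle wall.
#'
#' @inheritParams build_profile
#' @param thickness constant thickness, um (default 15)
#' @param width constant width, um
#' @return a [new_geometry_profile()] object
#' @export
uniform_profile <- function(n_segments = 201L, length = 600,
                            thickness = 15, width = 80, duct_height = 100) {
  if (thickness <= 0)
    stop("invalid-geometry: thickness must be positive", call. = FALSE)
  build_profile(n_segments, length,
                thickness_endpoints = c(thickness, thickness),
                width_endpoints = c(width, width),
                duct_height = duct_height)
}

#' @export
print.geometry_profile <- function(x, ...) {
  cat(sprintf(
    "geometry_profile: %d points over %.0f um (distal -> proximal)\n",
    x$n_segments, x$length))
  cat(sprintf("  thickness: %.3g -> %.3g um\n",
              x$thickness[1], x$thickness[x$n_segments]))
  cat(sprintf("  width:     %.3g -> %.3g um\n",
              x$width[1], x$width[x$n_segments]))
  cat(sprintf("  duct height: %.3g um\n", x$duct_height[1]))
  invisible(x)
}

#' Write / read a geometry profile as CSV
#'
#' Columns: `x_um, width_um, thickness_um, duct_height_um`.
#'
#' @param profile a `geometry_profile`
#' @param path file path
#' @return `read_geometry_csv` returns a `geometry_profile`;
#'   `write_geometry_csv` returns `path` invisibly.
#' @export
write_geometry_csv <- function(profile, path) {
  stopifnot(inherits(profile, "geometry_profile"))
  utils::write.csv(data.frame(
    x_um = profile$x,
    width_um = profile$width,
    thickness_um = profile$thickness,
    duct_height_um = profile$duct_height
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_um", "width_um", "thickness_um", "duct_height_um")
  if (!all(need %in% names(d)))
    stop("geometry CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  new_geometry_profile(d$x_um, d$width_um, d$thickness_um, d$duct_height_um)
}
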