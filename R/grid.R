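#' Stem slice geometry
#'
#' Describes the horizontal cross-section of a stem to be discretized: overall
#' diameter, bark layer thicknesses and the resolution of the polar grid.
#'
#' @param diameter Stem diameter (m), including bark.
#' @param outer_bark_thickness Outer (dead) bark thickness (m).
#' @param inner_bark_thickness Inner (live) bark thickness (m).
#' @param n_wedges Number of uniform angular wedges (>= 4).
#' @param radial_spacing Radial distance between node centers (m).
#'
#' @return An object of class `stem_geometry`.
#' @export
#' @examples
#' stem_geometry(0.14, 0.0015, 0.0015, n_wedges = 16, radial_spacing = 0.001)
stem_geometry <- function(diameter, outer_bark_thickness, inner_bark_thickness,
                          n_wedges = 16L, radial_spacing = 0.001) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter > 0)
  if (outer_bark_thickness < 0 || inner_bark_thickness < 0)
    stop("bark thicknesses must be >= 0")
  if (outer_bark_thickness + inner_bark_thickness >= diameter / 2)
    stop("total bark thickness must be < stem radius")
  n_wedges <- as.integer(n_wedges)
  if (n_wedges < 4L) stop("n_wedges must be >= 4")
  if (radial_spacing <= 0) stop("radial_spacing must be > 0")
  if (radial_spacing > diameter / 2)
    stop("radial_spacing exceeds the stem radius")
  structure(list(diameter = diameter,
                 outer_bark_thickness = outer_bark_thickness,
                 inner_bark_thickness = inner_bark_thickness,
                 n_wedges = n_wedges,
                 radial_spacing = radial_spacing),
            class = "stem_geometry")
}

#' Build the polar finite-volume grid of a stem slice
#'
#' Discretizes a circular stem cross-section into `n_wedges` uniform angular
#' wedges, each holding a column of radial nodes at the control-volume centers.
#' The outermost node sits exactly at the bark surface so the surface flux
#' boundary condition applies at a node; interior faces lie midway between
#' nodes; the innermost control volume extends to the geometric center, which
#' is not itself a node (no-flux inner boundary: heat crosses the center only
#' by diffusing around the innermost ring).
#'
#' Bark thickness is rounded to an integer number of radial nodes (nearest,
#' minimum one node for any strictly positive thickness). All quantities are
#' per unit stem height.
#'
#' @param geometry A [stem_geometry()] object.
#'
#' @return An object of class `polar_grid` with elements
#'   `node_radii` (outermost first, m), `wedge_angles` (wedge-center bearings,
#'   rad clockwise from north), `face_radii` (length `n_radial + 1`, from the
#'   bark surface down to 0), `cv_volumes` (`n_radial x n_wedges` matrix,
#'   m^3 per m height), `zone` (factor vector: outer_bark / inner_bark / wood),
#'   plus scalars `n_radial`, `n_wedges`, `dr`, `dtheta`, `radius`.
#' @export
build_grid <- function(geometry) {
  stopifnot(inherits(geometry, "stem_geometry"))
  R <- geometry$diameter / 2
  dr <- geometry$radial_spacing
  nw <- geometry$n_wedges
  n <- as.integer(round(R / dr))
  if (n < 3L) stop("fewer than 3 radial nodes; reduce radial_spacing")

  bark_total <- geometry$outer_bark_thickness + geometry$inner_bark_thickness
  if (bark_total > 0 && dr > bark_total)
    warning("radial_spacing exceeds total bark thickness: bark is under-resolved")

  n_nodes_for <- function(th) if (th <= 0) 0L else max(1L, as.integer(round(th / dr)))
  n_ob <- n_nodes_for(geometry$outer_bark_thickness)
  n_ib <- n_nodes_for(geometry$inner_bark_thickness)
  if (n_ob + n_ib >= n) stop("bark occupies the whole radius at this spacing")

  node_radii <- R - (seq_len(n) - 1) * dr
  # faces: surface at the outermost node, midway between nodes, center closes
  # the innermost cell so that total volume is exactly pi R^2 per unit height
  face_radii <- c(R, R - (seq_len(n - 1) - 0.5) * dr, 0)
  dtheta <- 2 * pi / nw
  cv_col <- dtheta / 2 * (face_radii[-(n + 1)]^2 - face_radii[-1]^2)
  cv_volumes <- matrix(cv_col, nrow = n, ncol = nw)

  zone <- factor(c(rep("outer_bark", n_ob), rep("inner_bark", n_ib),
                   rep("wood", n - n_ob - n_ib)),
                 levels = c("outer_bark", "inner_bark", "wood"))

  structure(list(node_radii = node_radii,
                 wedge_angles = (seq_len(nw) - 0.5) * dtheta,
                 face_radii = face_radii,
                 cv_volumes = cv_volumes,
                 zone = zone,
                 n_radial = n, n_wedges = nw,
                 dr = dr, dtheta = dtheta, radius = R,
                 n_outer_bark = n_ob, n_inner_bark = n_ib),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("polar_grid: %d radial nodes x %d wedges (R = %.4g m, dr = %.4g m)\n",
              x$n_radial, x$n_wedges, x$radius, x$dr))
  cat(sprintf("  zones: %d outer bark, %d inner bark, %d wood\n",
              x$n_outer_bark, x$n_inner_bark,
              x$n_radial - x$n_outer_bark - x$n_inner_bark))
  invisible(x)
}

#' Wedge index of a compass bearing
#'
#' Wedge 1 spans the first `2*pi/n_wedges` radians clockwise from north
#' (bearing 0); indices increase clockwise. Bearings are wrapped modulo
#' `2*pi`.
#'
#' @param grid A [build_grid()] object.
#' @param bearing Angle (rad) clockwise from north.
#' @return Integer wedge index in `1:n_wedges`.
#' @export
wedge_of_angle <- function(grid, bearing) {
  stopifnot(inherits(grid, "polar_grid"))
  b <- bearing %% (2 * pi)
  idx <- as.integer(floor(b / grid$dtheta)) + 1L
  # guard against floating wrap at exactly 2*pi
  pmin(idx, grid$n_wedges)
}

#' Index of the cambium (bark/wood interface) node
#'
#' The cambium probe is taken at the first wood node beneath the inner bark,
#' matching thermocouple placement at the cambium layer between bark and wood.
#'
#' @param grid A [build_grid()] object.
#' @return Integer radial node index.
#' @export
cambium_index <- function(grid) {
  stopifnot(inherits(grid, "polar_grid"))
  min(grid$n_outer_bark + grid$n_inner_bark + 1L, grid$n_radial)
}
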