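#' Spherical head model
#'
#' A single homogeneous sphere standing in for a realistic volume conductor.
#' The beamformer algebra is independent of the conductor model, and the
#' sphere admits a closed-form forward solution that can be tested exactly.
#'
#' @param radius Sphere radius in meters (default 0.09, an adult head).
#' @param center Sphere center, length-3 numeric in meters (head-centered
#'   coordinates; default the origin).
#' @return An object of class `head_model` with fields `center` and `radius`.
#' @export
head_model <- function(radius = 0.09, center = c(0, 0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1, length(center) == 3)
  if (radius <= 0) stop("head model radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "head_model")
}

#' Sensor array on a spherical cap
#'
#' Places magnetometers on a spherical cap above the head (helmet geometry)
#' using a Fibonacci lattice, with radial (outward) coil orientations.
#'
#' @param n Number of sensors (default 275, a whole-head system; >= 2).
#' @param head A [head_model()].
#' @param radius_factor Sensor shell radius as a multiple of the head radius
#'   (default 1.2).
#' @param cap_fraction Fraction of the full sphere covered by the cap,
#'   measured from the top (default 0.6, covering down past the "ears").
#' @return A `sensor_array` with `positions` (n x 3, meters), `orientations`
#'   (n x 3 unit vectors), `names`, and `count`.
#' @export
sensor_array <- function(n = 275, head = head_model(), radius_factor = 1.2,
                         cap_fraction = 0.6) {
  stopifnot(n >= 2, radius_factor > 1, cap_fraction > 0, cap_fraction <= 1)
  r <- head$radius * radius_factor
  # Fibonacci lattice on the cap z/r in [1 - 2*cap_fraction, 1]
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * cap_fraction * i / n
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  unit <- cbind(s * cos(phi), s * sin(phi), z)
  pos <- sweep(unit * r, 2, head$center, `+`)
  structure(list(
    positions = pos,
    orientations = unit,  # radial, outward
    names = sprintf("MEG%03d", seq_len(n)),
    count = n
  ), class = "sensor_array")
}

#' Regular volumetric source grid inside the head
#'
#' Builds a regular 3D lattice aligned to the head center and keeps the
#' points strictly inside the head sphere. These are the candidate source
#' positions for beamforming.
#'
#' @param head A [head_model()].
#' @param spacing Lattice spacing in meters (default 0.01, i.e. 1 cm).
#' @return A `source_grid` with `positions` (nodes x 3), `spacing`,
#'   `inside_mask` (logical over the full lattice) and `node_index`
#'   (contiguous ids of retained nodes).
#' @export
build_source_grid <- function(head, spacing = 0.01) {
  stopifnot(inherits(head, "head_model"))
  if (spacing <= 0) stop("grid spacing must be > 0")
  r <- head$radius
  k <- floor(r / spacing)
  if (spacing >= 2 * r && k < 0) stop("empty grid: spacing exceeds head size")
  ax <- seq(-k, k) * spacing
  lattice <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  lattice <- sweep(lattice, 2, head$center, `+`)
  d2 <- rowSums(sweep(lattice, 2, head$center)^2)
  inside <- d2 < r^2
  if (!any(inside)) stop("empty grid: no lattice point falls inside the head sphere")
  pos <- lattice[inside, , drop = FALSE]
  dimnames(pos) <- NULL
  structure(list(
    positions = pos,
    spacing = spacing,
    inside_mask = inside,
    node_index = seq_len(nrow(pos))
  ), class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d nodes, spacing %.3g m\n",
              nrow(x$positions), x$spacing))
  invisible(x)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors\n", x$count))
  invisible(x)
}
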