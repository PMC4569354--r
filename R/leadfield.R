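#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form (Sarvas) solution for the field outside a spherically
#' symmetric volume conductor. Radial dipoles are magnetically silent, and
#' the field does not depend on the conductivity profile.
#'
#' @param r_sensor Sensor position, length-3 (meters), relative to the
#'   sphere center.
#' @param r_dipole Dipole position, length-3 (meters), relative to the
#'   sphere center.
#' @param q Dipole moment, length-3 (A*m).
#' @return Magnetic field vector (tesla), length 3.
#' @keywords internal
sarvas_field <- function(r_sensor, r_dipole, q) {
  drop(sarvas_field_multi(matrix(r_sensor, 1), r_dipole, q))
}

# Vectorized over sensors: pos_s is n x 3 (center-relative), returns n x 3.
sarvas_field_multi <- function(pos_s, r_dipole, q) {
  mu0_4pi <- 1e-7
  a_mat <- sweep(pos_s, 2, r_dipole)          # a = r - r0
  a <- sqrt(rowSums(a_mat^2))
  r <- sqrt(rowSums(pos_s^2))
  r0_dot_r <- drop(pos_s %*% r_dipole)
  f <- a * (r * a + r^2 - r0_dot_r)
  a_dot_r <- rowSums(a_mat * pos_s)
  c1 <- a^2 / r + a_dot_r / a + 2 * a + 2 * r
  c2 <- a + 2 * r + a_dot_r / a
  grad_f <- c1 * pos_s - outer(c2, r_dipole)
  qxr0 <- c(q[2] * r_dipole[3] - q[3] * r_dipole[2],
            q[3] * r_dipole[1] - q[1] * r_dipole[3],
            q[1] * r_dipole[2] - q[2] * r_dipole[1])
  qxr0_dot_r <- drop(pos_s %*% qxr0)
  b <- mu0_4pi / f^2 * (f * matrix(qxr0, nrow(pos_s), 3, byrow = TRUE) -
                          qxr0_dot_r * grad_f)
  b[!is.finite(f) | f == 0, ] <- 0
  b
}

#' Lead field for a source grid and sensor array
#'
#' Computes the gain matrix mapping unit current dipoles at each grid node
#' (three Cartesian orientations per node) to the projection of the magnetic
#' field on each sensor's coil orientation, using the spherical-conductor
#' closed form. A node placed exactly at the sphere center has no external
#' field in any orientation; such nodes get zero gain and a warning.
#'
#' @param grid A [build_source_grid()] result.
#' @param sensors A [sensor_array()].
#' @param head The [head_model()] the grid was built in.
#' @return A `lead_field` with `matrix` (sensors x (3*nodes), tesla per A*m),
#'   ordered node-major (columns 3k-2..3k belong to node k).
#' @export
compute_leadfield <- function(grid, sensors, head) {
  stopifnot(inherits(grid, "source_grid"), inherits(sensors, "sensor_array"),
            inherits(head, "head_model"))
  pos_s <- sweep(sensors$positions, 2, head$center)   # center-relative
  pos_d <- sweep(grid$positions, 2, head$center)
  ds <- sqrt(rowSums(pos_s^2))
  if (any(ds <= head$radius))
    stop("all sensors must lie outside the head sphere")
  n_sens <- nrow(pos_s)
  n_node <- nrow(pos_d)
  lf <- matrix(0, n_sens, 3L * n_node)
  center_nodes <- which(rowSums(pos_d^2) == 0)
  if (length(center_nodes))
    warning(sprintf("%d node(s) at the sphere center are magnetically silent; gain set to 0",
                    length(center_nodes)))
  eye <- diag(3)
  for (k in seq_len(n_node)) {
    if (k %in% center_nodes) next
    for (o in 1:3) {
      b <- sarvas_field_multi(pos_s, pos_d[k, ], eye[o, ])
      lf[, 3L * (k - 1L) + o] <- rowSums(b * sensors$orientations)
    }
  }
  structure(list(matrix = lf, n_nodes = n_node, n_sensors = n_sens),
            class = "lead_field")
}

#' Extract the sensors x 3 gain block of one node
#' @param lf A `lead_field`.
#' @param node Node index.
#' @return sensors x 3 matrix.
#' @export
leadfield_node <- function(lf, node) {
  stopifnot(inherits(lf, "lead_field"), node >= 1, node <= lf$n_nodes)
  lf$matrix[, (3L * (node - 1L) + 1L):(3L * node), drop = FALSE]
}
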