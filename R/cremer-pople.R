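#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the puckering amplitude and phase angles of a six-membered ring
#' from its Cartesian coordinates, following the Cremer-Pople construction:
#' a mean plane is placed through the geometric centre of the six atoms such
#' that the out-of-plane displacements \eqn{z_j} satisfy
#' \eqn{\sum_j z_j = 0} and the two first-moment constraints
#' \eqn{\sum_j z_j \cos(2\pi (j-1)/6) = \sum_j z_j \sin(2\pi (j-1)/6) = 0}.
#' The displacements are then decomposed into an \eqn{m = 2} Fourier
#' component of amplitude \eqn{q_2} and phase \eqn{\phi_2}, and an
#' alternating chair component \eqn{q_3 = 6^{-1/2} \sum_j (-1)^{j-1} z_j}.
#' The spherical-polar form is \eqn{Q = \sqrt{q_2^2 + q_3^2}},
#' \eqn{\cos\theta = q_3 / Q}, \eqn{\phi = \phi_2}.
#'
#' With atoms ordered O5, C1, ..., C5 the \eqn{^4C_1} chair sits at
#' \eqn{\theta = 0} and \eqn{^1C_4} at \eqn{\theta = 180}; boats and
#' skew-boats populate the equator \eqn{\theta = 90} and envelopes /
#' half-chairs the two tropics.
#'
#' The result is invariant under rigid-body rotation and translation of the
#' input coordinates.
#'
#' @param ring a [ring_coords()] object, or any numeric 6 x 3 matrix of ring
#'   coordinates in ring order.
#' @param Q_min planarity threshold in Angstrom: below this total amplitude
#'   the angles \eqn{\theta, \phi} are numerically meaningless and the
#'   `planar` flag is set (angles are still returned as computed).
#'
#' @return An object of class `pucker`: a list with elements `Q`, `theta`,
#'   `phi` (degrees, \eqn{\phi} wrapped to `[0, 360)`), `q2`, `q3`, `phi2`,
#'   and logical `planar`.
#' @seealso [classify_pucker()], [ideal_ring()]
#' @export
#' @examples
#' chair <- ideal_ring(Q = 0.57, theta = 0, phi = 0)
#' cremer_pople(chair)
cremer_pople <- function(ring, Q_min = 0.1) {
  pos <- unclass(as.matrix(ring))
  if (!identical(dim(pos), c(6L, 3L)))
    stop("'ring' must contain exactly 6 atoms in 3-D")
  if (any(!is.finite(pos))) stop("non-finite ring coordinates")

  centred <- sweep(pos, 2, colMeans(pos))
  j <- 0:5
  psi <- 2 * pi * j / 6

  # mean-plane normal from the two first-moment vectors; the cross-product
  # order fixes the sign convention so that a ring traversed O5, C1..C5
  # with displacements z_j = (-1)^(j-1) h (O5 up) is the north-pole chair
  Rp <- colSums(centred * sin(psi))
  Rpp <- colSums(centred * cos(psi))
  n <- c(Rpp[2] * Rp[3] - Rpp[3] * Rp[2],
         Rpp[3] * Rp[1] - Rpp[1] * Rp[3],
         Rpp[1] * Rp[2] - Rpp[2] * Rp[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12)
    stop("degenerate ring geometry: mean plane undefined ",
         "(coincident or collinear atoms)")
  n <- n / nn

  z <- as.numeric(centred %*% n)

  # m = 2 Fourier component
  q2cos <- sqrt(1 / 3) * sum(z * cos(2 * psi))
  q2sin <- -sqrt(1 / 3) * sum(z * sin(2 * psi))
  q2 <- sqrt(q2cos^2 + q2sin^2)
  phi2 <- (atan2(q2sin, q2cos) * 180 / pi) %% 360

  # alternating chair component
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)

  Q <- sqrt(q2^2 + q3^2)
  theta <- if (Q > 0) acos(max(-1, min(1, q3 / Q))) * 180 / pi else NA_real_

  structure(list(Q = Q, theta = theta, phi = phi2,
                 q2 = q2, q3 = q3, phi2 = phi2,
                 planar = Q < Q_min),
            class = "pucker")
}

#' Construct a pucker object directly from spherical coordinates
#'
#' @param Q total puckering amplitude in Angstrom (>= 0).
#' @param theta polar angle in degrees, in `[0, 180]`.
#' @param phi meridian angle in degrees; wrapped to `[0, 360)`.
#' @param Q_min planarity threshold (Angstrom).
#' @return A `pucker` object (see [cremer_pople()]).
#' @export
pucker <- function(Q, theta, phi, Q_min = 0.1) {
  stopifnot(Q >= 0, theta >= 0, theta <= 180)
  phi <- phi %% 360
  th <- theta * pi / 180
  structure(list(Q = Q, theta = theta, phi = phi,
                 q2 = Q * sin(th), q3 = Q * cos(th), phi2 = phi,
                 planar = Q < Q_min),
            class = "pucker")
}

#' @export
print.pucker <- function(x, digits = 4, ...) {
  cat(sprintf("Cremer-Pople pucker: Q = %.*f A, theta = %s, phi = %s%s\n",
              digits, x$Q,
              if (is.na(x$theta)) "undef" else sprintf("%.*f deg", digits, x$theta),
              sprintf("%.*f deg", digits, x$phi),
              if (x$planar) "  [below planarity threshold]" else ""))
  invisible(x)
}

#' @export
format.pucker <- function(x, ...) {
  sprintf("(Q=%.3f, theta=%.1f, phi=%.1f)", x$Q, x$theta, x$phi)
}

#' Mercator-map representation of a puckering series
#'
#' Projects a series of puckering coordinates onto the standard planar
#' Mercator chart of the Cremer-Pople sphere: x is the meridian angle
#' \eqn{\phi} in `[0, 360)`, y the polar angle \eqn{\theta} in `[0, 180]`.
#' Input order and length are preserved, so trajectories can be drawn as
#' paths over the chart.
#'
#' @param pucker_series a list of `pucker` objects (or a single one).
#' @return A data.frame with columns `phi`, `theta`, `Q` (one row per
#'   element; zero rows for an empty series).
#' @export
mercator <- function(pucker_series) {
  if (inherits(pucker_series, "pucker")) pucker_series <- list(pucker_series)
  if (length(pucker_series) == 0)
    return(data.frame(phi = numeric(0), theta = numeric(0), Q = numeric(0)))
  data.frame(phi = vapply(pucker_series, `[[`, numeric(1), "phi"),
             theta = vapply(pucker_series, `[[`, numeric(1), "theta"),
             Q = vapply(pucker_series, `[[`, numeric(1), "Q"))
}
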