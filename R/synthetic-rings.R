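#' Construct an ideal six-membered ring at given puckering coordinates
#'
#' Inverse of the Cremer-Pople decomposition: places the six ring atoms on
#' a regular hexagon scaled to the target bond length and adds the
#' out-of-plane displacements
#' \deqn{z_j = \sqrt{1/3}\, q_2 \cos(\phi_2 + 4\pi (j-1)/6)
#'       + \sqrt{1/6}\, q_3 (-1)^{j-1}}
#' with \eqn{q_2 = Q\sin\theta}, \eqn{q_3 = Q\cos\theta},
#' \eqn{\phi_2 = \phi}. The displacement pattern satisfies the mean-plane
#' constraints by construction, so [cremer_pople()] recovers
#' \eqn{(Q, \theta, \phi)} to machine precision.
#'
#' @param Q total puckering amplitude in Angstrom (0 gives a planar
#'   hexagon). Amplitudes above 1.5 A degenerate the ring geometry and are
#'   rejected.
#' @param theta,phi spherical puckering angles in degrees.
#' @param bond_length target in-plane atom spacing in Angstrom.
#' @param frame_index,residue_id passed to [ring_coords()].
#' @return A [ring_coords()] object (atom order O5, C1, ..., C5).
#' @export
#' @examples
#' s3 <- ideal_ring(0.6, 90, 210)           # ideal 1S3 skew-boat
#' classify_pucker(cremer_pople(s3))$conformer
ideal_ring <- function(Q, theta, phi, bond_length = 1.54,
                       frame_index = 0L, residue_id = "-1") {
  stopifnot(Q >= 0, bond_length > 0)
  if (Q > 1.5)
    stop("puckering amplitude Q = ", Q,
         " A exceeds 1.5 A; ring geometry degenerates")
  j <- 0:5
  psi <- 2 * pi * j / 6
  th <- theta * pi / 180
  ph <- phi * pi / 180
  q2 <- Q * sin(th)
  q3 <- Q * cos(th)
  z <- sqrt(1 / 3) * q2 * cos(ph + 2 * psi) + sqrt(1 / 6) * q3 * (-1)^j
  # in-plane polygon: hexagonal directions with each side shortened to
  # compensate its out-of-plane gap, then re-closed, so 3-D bonds stay
  # near the target length; the planar arrangement never enters the
  # puckering decomposition (only the z pattern does), so the round trip
  # through cremer_pople() stays exact
  dz <- z[c(2:6, 1)] - z
  s <- sqrt(pmax(bond_length^2 - dz^2, (0.5 * bond_length)^2))
  u <- cbind(cos(psi + 2 * pi / 3), sin(psi + 2 * pi / 3))
  e <- colSums(s * u) / 6
  steps <- s * u - matrix(e, 6, 2, byrow = TRUE)
  xy <- apply(rbind(c(0, 0), steps[-6, ]), 2, cumsum)
  xy <- sweep(xy, 2, colMeans(xy))
  pos <- cbind(xy, z)
  ring_coords(pos, frame_index = frame_index, residue_id = residue_id)
}

#' Ideal ring for a named canonical conformer
#'
#' Convenience wrapper looking up \eqn{(\theta_{ref}, \phi_{ref})} in the
#' conformer library and calling [ideal_ring()].
#'
#' @param label canonical conformer symbol, e.g. `"1S3"`, `"1,4B"`.
#' @param Q puckering amplitude (Angstrom).
#' @param library conformer library (built when omitted).
#' @param ... passed to [ideal_ring()].
#' @export
conformer_ring <- function(label, Q = 0.6,
                           library = build_conformer_library(), ...) {
  i <- match(label, library$label)
  if (is.na(i)) stop("unknown conformer label: ", label)
  ideal_ring(Q, library$theta_ref[i], library$phi_ref[i], ...)
}

#' Specification of a stochastic puckering path
#'
#' Describes a synthetic subsite -1 ring trajectory as a sequence of
#' waypoints on the Cremer-Pople sphere with dwell fractions, emulating the
#' statistical structure of MD conformer streams: long residence in the
#' ground-state chair punctuated by excursions toward tropic and equatorial
#' conformers.
#'
#' @param waypoints character vector of conformer labels, or a list mixing
#'   labels and numeric `c(Q, theta, phi)` triples.
#' @param dwell_fractions non-negative per-waypoint fractions summing to 1.
#' @param n_frames number of recorded frames (default 1000, one frame per
#'   20 ps of a 20 ns-equivalent run).
#' @param angular_noise_sigma s.d. of Gaussian angular noise, degrees,
#'   applied in the tangent plane of each waypoint.
#' @param Q_noise_sigma s.d. of Gaussian amplitude noise, Angstrom.
#' @param Q amplitude used for labelled waypoints (Angstrom).
#' @param transition_frames frames of great-circle interpolation inserted
#'   between consecutive dwell blocks (taken out of the following block's
#'   allocation; 0 keeps blocks pure so occupancies match dwell fractions
#'   in expectation).
#' @param seed integer seed making the trajectory reproducible.
#' @return An object of class `pucker_path_spec`.
#' @export
pucker_path_spec <- function(waypoints, dwell_fractions = NULL,
                             n_frames = 1000L,
                             angular_noise_sigma = 3,
                             Q_noise_sigma = 0.02,
                             Q = 0.6,
                             transition_frames = 0L,
                             seed = 1L) {
  if (is.character(waypoints)) waypoints <- as.list(waypoints)
  k <- length(waypoints)
  stopifnot(k >= 1L, n_frames >= 1L)
  if (is.null(dwell_fractions)) dwell_fractions <- rep(1 / k, k)
  stopifnot(length(dwell_fractions) == k, all(dwell_fractions >= 0))
  if (abs(sum(dwell_fractions) - 1) > 1e-8)
    stop("dwell fractions must sum to 1")
  structure(list(waypoints = waypoints,
                 dwell_fractions = dwell_fractions,
                 n_frames = as.integer(n_frames),
                 angular_noise_sigma = angular_noise_sigma,
                 Q_noise_sigma = Q_noise_sigma,
                 Q = Q,
                 transition_frames = as.integer(transition_frames),
                 seed = as.integer(seed)),
            class = "pucker_path_spec")
}

# resolve a waypoint (label or c(Q, theta, phi)) to numeric coordinates
resolve_waypoint <- function(w, Q, library) {
  if (is.character(w)) {
    i <- match(w, library$label)
    if (is.na(i)) stop("unknown conformer label in waypoints: ", w)
    c(Q = Q, theta = library$theta_ref[i], phi = library$phi_ref[i])
  } else {
    stopifnot(is.numeric(w), length(w) == 3)
    c(Q = w[[1]], theta = w[[2]], phi = w[[3]])
  }
}

# apportion n frames over fractions so the total is exact (largest
# remainder method; every positive fraction gets >= 1 frame when possible)
apportion_frames <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a stochastic ring trajectory along a programmed puckering path
#'
#' Allocates frames to waypoints by dwell fraction, holds each dwell block
#' at its waypoint (optionally inserting great-circle interpolation frames
#' between blocks), perturbs every frame with Gaussian noise on the tangent
#' plane angles and on the amplitude, and realises each frame as an ideal
#' ring via [ideal_ring()]. Polar angles are reflected at \eqn{\theta = 0}
#' and \eqn{180} so noise never leaves the sphere; amplitudes are floored
#' at 0.15 A so classification stays defined.
#'
#' @param spec a [pucker_path_spec()].
#' @param library conformer library used to resolve labelled waypoints.
#' @return An object of class `ring_trajectory`: list with `frames` (list
#'   of [ring_coords()]), `time_step` (ps), `truth` (data.frame of the
#'   intended waypoint label per frame; interpolation frames are labelled
#'   `"transition"`), and the spec.
#' @export
#' @examples
#' spec <- pucker_path_spec(c("4C1", "1S3"), c(0.9, 0.1), n_frames = 200)
#' traj <- simulate_pucker_path(spec)
#' occupancy(per_frame_conformers(traj))
simulate_pucker_path <- function(spec, library = build_conformer_library()) {
  stopifnot(inherits(spec, "pucker_path_spec"))
  set.seed(spec$seed)
  wp <- lapply(spec$waypoints, resolve_waypoint, Q = spec$Q, library = library)
  labels <- vapply(spec$waypoints, function(w)
    if (is.character(w)) w else sprintf("(%g,%g,%g)", w[1], w[2], w[3]),
    character(1))
  counts <- apportion_frames(spec$n_frames, spec$dwell_fractions)

  target <- matrix(NA_real_, spec$n_frames, 3,
                   dimnames = list(NULL, c("Q", "theta", "phi")))
  truth <- character(spec$n_frames)
  pos <- 1L
  for (b in seq_along(wp)) {
    nb <- counts[b]
    if (nb == 0L) next
    nt <- if (b > 1L) min(spec$transition_frames, nb - 1L) else 0L
    if (nt > 0L) {
      prev <- wp[[b - 1L]]
      cur <- wp[[b]]
      frac <- seq_len(nt) / (nt + 1)
      for (t in seq_len(nt)) {
        target[pos, ] <- slerp_pucker(prev, cur, frac[t])
        truth[pos] <- "transition"
        pos <- pos + 1L
      }
      nb <- nb - nt
    }
    idx <- pos:(pos + nb - 1L)
    target[idx, ] <- matrix(wp[[b]], nb, 3, byrow = TRUE)
    truth[idx] <- labels[b]
    pos <- pos + nb
  }

  n <- spec$n_frames
  sig <- spec$angular_noise_sigma
  dtheta <- stats::rnorm(n, 0, sig)
  # tangent-plane azimuthal displacement: scale by sin(theta) so the noise
  # is isotropic on the sphere and phi stays well-defined near the poles
  dphi_t <- stats::rnorm(n, 0, sig)
  theta <- target[, "theta"] + dtheta
  # reflect at the poles
  theta <- abs(theta)
  theta <- ifelse(theta > 180, 360 - theta, theta)
  s <- pmax(sin(pmin(pmax(theta, 2), 178) * pi / 180), 0.05)
  phi <- (target[, "phi"] + dphi_t / s) %% 360
  Qv <- pmax(target[, "Q"] + stats::rnorm(n, 0, spec$Q_noise_sigma), 0.15)

  frames <- lapply(seq_len(n), function(i)
    ideal_ring(Qv[i], theta[i], phi[i], frame_index = i - 1L))

  structure(list(frames = frames,
                 time_step = 20,
                 run_length_label = sprintf("%g ns", n * 20 / 1000),
                 truth = data.frame(frame = seq_len(n) - 1L,
                                    waypoint = truth,
                                    stringsAsFactors = FALSE),
                 spec = spec),
            class = "ring_trajectory")
}

# great-circle interpolation between two (Q, theta, phi) points
slerp_pucker <- function(a, b, frac) {
  va <- sph_to_unit(a["theta"], a["phi"])
  vb <- sph_to_unit(b["theta"], b["phi"])
  omega <- acos(max(-1, min(1, sum(va * vb))))
  v <- if (omega < 1e-9) va else
    (sin((1 - frac) * omega) * va + sin(frac * omega) * vb) / sin(omega)
  v <- v / sqrt(sum(v^2))
  c(Q = unname((1 - frac) * a["Q"] + frac * b["Q"]),
    theta = acos(max(-1, min(1, v[3]))) * 180 / pi,
    phi = (atan2(v[2], v[1]) * 180 / pi) %% 360)
}

sph_to_unit <- function(theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' @export
print.ring_trajectory <- function(x, ...) {
  cat("Ring trajectory:", length(x$frames), "frames,",
      x$time_step, "ps/frame (", x$run_length_label, ")\n")
  invisible(x)
}
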