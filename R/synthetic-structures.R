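#' Synthetic Calpha-trace structures for structural-comparison tests
#'
#' `random_ca_structure` generates a self-avoiding-ish random walk with
#' the canonical 3.8 Angstrom Calpha-Calpha step, a minimal stand-in for
#' a protein fold when only pairwise geometry matters.
#' `perturb_structure` adds isotropic Gaussian coordinate noise and an
#' optional random rigid motion, producing structural "family members" at
#' a controlled noise level.
#'
#' @param n_res number of residues.
#' @param seed integer seed.
#' @param step Calpha-Calpha step length (Angstrom).
#' @return An `n_res` x 3 coordinate matrix.
#' @export
random_ca_structure <- function(n_res, seed = 1L, step = 3.8) {
  set.seed(seed)
  # biased random walk: correlated directions give an extended, fold-like
  # trace instead of a dense blob
  dirs <- matrix(stats::rnorm(n_res * 3), ncol = 3)
  for (i in 2:n_res) dirs[i, ] <- 0.7 * dirs[i - 1, ] + 0.3 * dirs[i, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coords <- apply(dirs * step, 2, cumsum)
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' @rdname random_ca_structure
#' @param coords coordinate matrix to perturb.
#' @param noise_sigma s.d. of per-atom Gaussian noise (Angstrom).
#' @param rigid also apply a random rotation + translation (which the
#'   superposition search must undo).
#' @export
perturb_structure <- function(coords, noise_sigma = 0.5, seed = 1L,
                              rigid = TRUE) {
  set.seed(seed)
  out <- coords + matrix(stats::rnorm(length(coords), 0, noise_sigma),
                         nrow(coords))
  if (rigid) {
    R <- random_rotation()
    out <- out %*% t(R) +
      matrix(stats::runif(3, -20, 20), nrow(out), 3, byrow = TRUE)
  }
  out
}

#' Uniform random 3-D rotation matrix
#'
#' Drawn via QR decomposition of a Gaussian matrix, sign-corrected to a
#' proper rotation (det = +1). Uses the current RNG stream.
#'
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
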