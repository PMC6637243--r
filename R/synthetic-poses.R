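#' Generate a synthetic docking ensemble around a reference complex
#'
#' Produces a ranked list of poses emulating the output of a carbohydrate
#' docking run: each pose is the reference ligand displaced by a random
#' rigid motion of controlled magnitude, with a dock score loosely
#' anti-correlated with displacement (better fits tend to score better,
#' with noise, as in real docking ensembles). Useful for exercising the
#' MD-seed selection rules without a docking engine.
#'
#' @param reference reference complex ligand: named list of residue
#'   coordinate matrices.
#' @param n number of poses (<= 30, the retained-ensemble convention).
#' @param displacement_range range (Angstrom) of per-pose translation
#'   magnitudes, sampled uniformly.
#' @param rotation_sigma s.d. (degrees) of a small random rotation about
#'   the ligand centroid.
#' @param score_noise s.d. of Gaussian noise on the score-displacement
#'   relation.
#' @param seed integer seed.
#' @return A list of [dock_pose()] objects ranked by dock score (rank 1 =
#'   most negative score).
#' @export
synthetic_dock_poses <- function(reference, n = 30L,
                                 displacement_range = c(0, 4),
                                 rotation_sigma = 5,
                                 score_noise = 0.5,
                                 seed = 1L) {
  stopifnot(n >= 1L, n <= 30L)
  set.seed(seed)
  all_ref <- do.call(rbind, reference)
  ctr <- colMeans(all_ref)
  mags <- stats::runif(n, displacement_range[1], displacement_range[2])
  ligs <- vector("list", n)
  for (i in seq_len(n)) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    shift <- mags[i] * dir
    ang <- stats::rnorm(1, 0, rotation_sigma) * pi / 180
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- rotation_about_axis(ax, ang)
    ligs[[i]] <- lapply(reference, function(pos)
      sweep(sweep(as.matrix(pos), 2, ctr) %*% t(R), 2, ctr + shift, "+"))
  }
  # scores: roughly -9 for perfect fits rising with displacement
  scores <- -9 + 0.8 * mags + stats::rnorm(n, 0, score_noise)
  ord <- order(scores)
  out <- vector("list", n)
  for (r in seq_len(n))
    out[[r]] <- dock_pose(ligs[[ord[r]]], dock_score = scores[ord[r]],
                          pose_rank = r)
  out
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) * c + s * K + (1 - c) * tcrossprod(u)
}
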