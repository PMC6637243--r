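# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (svd-Kabsch, vectorised Fourier sums) so that
# agreement is evidence, not tautology.

# random proper rigid-body transform applied to an n x 3 matrix
random_rigid_transform <- function(coords, translation_scale = 10) {
  R <- random_rotation()
  t <- stats::runif(3, -translation_scale, translation_scale)
  sweep(as.matrix(coords) %*% t(R), 2, t, "+")
}

# Horn's quaternion method for optimal superposition: an independent
# route to the least-squares rotation (eigen problem, not SVD)
quaternion_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(as.matrix(mobile), 2, cm)
  Q <- sweep(as.matrix(target), 2, ct)
  S <- crossprod(P, Q)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  list(apply = function(m) sweep(sweep(as.matrix(m), 2, cm) %*% t(R), 2,
                                 ct, "+"))
}

# superposed RMSD via the quaternion route
quaternion_rmsd <- function(a, b) {
  fit <- quaternion_superpose(a, b)
  sqrt(mean(rowSums((fit$apply(a) - b)^2)))
}

# brute-force Cremer-Pople via explicit per-atom loops and a nullspace
# normal (no cross product): n spans the nullspace of the two
# first-moment constraint rows
brute_force_cp <- function(coords) {
  r <- sweep(as.matrix(coords), 2, colMeans(coords))
  psi <- 2 * pi * (0:5) / 6
  C <- rbind(colSums(r * cos(psi)), colSums(r * sin(psi)))
  n <- svd(C, nv = 3)$v[, 3]
  # orient n along the polygon area vector: the ring traversed in atom
  # order must appear counterclockwise from the +n side
  area <- c(0, 0, 0)
  for (j in 1:6) {
    k <- if (j == 6) 1 else j + 1
    area <- area + c(r[j, 2] * r[k, 3] - r[j, 3] * r[k, 2],
                     r[j, 3] * r[k, 1] - r[j, 1] * r[k, 3],
                     r[j, 1] * r[k, 2] - r[j, 2] * r[k, 1])
  }
  if (sum(area * n) < 0) n <- -n
  z <- as.numeric(r %*% n)
  q2c <- 0; q2s <- 0; q3 <- 0
  for (j in 1:6) {
    q2c <- q2c + z[j] * cos(2 * psi[j])
    q2s <- q2s - z[j] * sin(2 * psi[j])
    q3 <- q3 + z[j] * (-1)^(j - 1)
  }
  q2c <- sqrt(1 / 3) * q2c; q2s <- sqrt(1 / 3) * q2s
  q3 <- sqrt(1 / 6) * q3
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  list(Q = Q, theta = acos(q3 / Q) * 180 / pi,
       phi = (atan2(q2s, q2c) * 180 / pi) %% 360,
       q2 = q2, q3 = q3)
}

# run-length oracle for excursion segmentation
runs_oracle <- function(labels, ground = "4C1") {
  away <- labels != ground
  out <- list()
  i <- 1L
  while (i <= length(labels)) {
    if (away[i]) {
      j <- i
      while (j < length(labels) && away[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(start = i - 1L, end = j - 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# brute-force MaxSub on tiny structures: exhaustively score every subset
# reachable from contiguous seeds is infeasible; instead check the bound
# via all subsets of size >= 4 on <= 12 residues
brute_force_maxsub <- function(a, b, d_threshold = 3.5) {
  n <- nrow(a)
  stopifnot(n <= 12)
  best <- 0
  idx_all <- seq_len(n)
  for (size in n:4) {
    combs <- utils::combn(idx_all, size)
    for (c_i in seq_len(ncol(combs))) {
      M <- combs[, c_i]
      fit <- quaternion_superpose(a[M, , drop = FALSE], b[M, , drop = FALSE])
      d_M <- sqrt(rowSums((fit$apply(a[M, , drop = FALSE]) -
                             b[M, , drop = FALSE])^2))
      if (all(d_M < d_threshold)) {
        d_all <- sqrt(rowSums((fit$apply(a) - b)^2))
        keep <- d_all < d_threshold
        sc <- sum(1 / (1 + (d_all[keep] / d_threshold)^2)) / n
        if (sc > best) best <- sc
      }
    }
    if (best > 0) break  # largest feasible subset found at this size
  }
  best
}

# standard two-residue mock complex used by several files
basic_mock <- function(n_frames = 60, waypoints = "4C1",
                       dwell = NULL, noise = 0, seed = 1) {
  build_mock_complex(mock_complex_spec(
    ligand_subsites = c("-1", "+1"),
    pucker_spec = pucker_path_spec(waypoints, dwell, n_frames = n_frames,
                                   angular_noise_sigma = noise,
                                   Q_noise_sigma = if (noise == 0) 0 else 0.02,
                                   seed = seed),
    seed = seed))
}

# apply one random rigid motion to a whole complex frame
random_rigid_frame <- function(f) {
  R <- random_rotation()
  t <- stats::runif(3, -6, 6)
  complex_frame(sweep(f$protein %*% t(R), 2, t, "+"),
                lapply(f$ligand, function(m) sweep(m %*% t(R), 2, t, "+")),
                f$frame_index)
}
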