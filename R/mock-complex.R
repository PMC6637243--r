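#' Specification of a mock enzyme:ligand complex trajectory
#'
#' Describes the synthetic stand-in for an MD run of a glycosidase:
#' oligosaccharide Michaelis complex: a rigid dummy protein scaffold plus a
#' short ligand whose subsite -1 sugar ring follows a programmed puckering
#' path while the other residues stay rigid (optionally jittered). The
#' geometry is idealised -- rings carry a single glycosidic-oxygen stub,
#' no substituents -- because the analytics under test only read ring
#' geometry and relative motion.
#'
#' @param n_protein_residues number of scaffold residues (4 backbone heavy
#'   atoms each).
#' @param ligand_subsites ordered subsite labels, one sugar residue each;
#'   must contain exactly one `"-1"`.
#' @param pucker_spec a [pucker_path_spec()] driving the -1 ring.
#' @param rigid_jitter_sigma s.d. (Angstrom) of Gaussian jitter applied to
#'   the non--1 residues; 0 keeps them strictly rigid.
#' @param seed integer seed (also reseeds the pucker path).
#' @return An object of class `mock_complex_spec`.
#' @export
mock_complex_spec <- function(n_protein_residues = 20L,
                              ligand_subsites = c("-1", "+1"),
                              pucker_spec = pucker_path_spec("4C1",
                                                             n_frames = 100L),
                              rigid_jitter_sigma = 0,
                              seed = 1L) {
  if (sum(ligand_subsites == "-1") != 1L)
    stop("exactly one ligand residue must sit at subsite -1")
  structure(list(n_protein_residues = as.integer(n_protein_residues),
                 ligand_subsites = ligand_subsites,
                 pucker_spec = pucker_spec,
                 rigid_jitter_sigma = rigid_jitter_sigma,
                 seed = as.integer(seed)),
            class = "mock_complex_spec")
}

# rigid dummy protein scaffold: GLY backbone heavy atoms on a coarse helix
protein_scaffold <- function(n_res) {
  res <- seq_len(n_res)
  ang <- res * 100 * pi / 180
  base <- cbind(8 * cos(ang), 8 * sin(ang), 1.5 * res)
  atoms <- rbind(c(-0.5, 0.8, 0), c(0, 0, 0), c(1.2, -0.4, 0.4),
                 c(1.6, -1.5, 0.2))
  coords <- do.call(rbind, lapply(res, function(i)
    sweep(atoms, 2, base[i, ], "+")))
  rownames(coords) <- as.vector(t(outer(res, c("N", "CA", "C", "O"),
                                        function(i, a) paste0(a, ":", i))))
  coords
}

# ring + glycosidic-oxygen stub for one ligand residue, shifted to its site
place_residue <- function(ring, offset) {
  pos <- unclass(ring)
  ctr <- colMeans(pos)
  o1 <- pos["C1", ] + 1.43 * (pos["C1", ] - ctr) / sqrt(sum((pos["C1", ] - ctr)^2))
  out <- rbind(pos, O1 = o1)
  sweep(out, 2, offset, "+")
}

# fixed site offsets: subsites strung 5 A apart along x, clear of scaffold
subsite_offsets <- function(labels) {
  k <- seq_along(labels)
  off <- cbind(14 + 5 * (k - 1), 0, 15)
  rownames(off) <- labels
  off
}

#' Build a mock enzyme:ligand complex trajectory
#'
#' Realises a [mock_complex_spec()]: the -1 ring follows its programmed
#' puckering path (via [simulate_pucker_path()]), every other sugar
#' residue is an ideal \eqn{^4C_1} ring held rigid (plus optional
#' jitter), and the protein scaffold is rigid throughout. Residue ids are
#' the 1-based ligand residue numbers, in `ligand_subsites` order.
#'
#' @param spec a [mock_complex_spec()].
#' @return An object of class `complex_trajectory`: list with `frames`
#'   (list of [complex_frame()]), `subsite_map` (named character vector,
#'   residue id -> subsite label), `truth` (the pucker path's intended
#'   waypoint per frame) and `spec`.
#' @export
#' @examples
#' spec <- mock_complex_spec(
#'   ligand_subsites = c("-1", "+1"),
#'   pucker_spec = pucker_path_spec(c("4C1", "1S3"), c(0.8, 0.2),
#'                                  n_frames = 50))
#' traj <- build_mock_complex(spec)
#' rmsd_series(traj, traj$subsite_map)
build_mock_complex <- function(spec) {
  stopifnot(inherits(spec, "mock_complex_spec"))
  labels <- spec$ligand_subsites
  n_res <- length(labels)
  resids <- as.character(seq_len(n_res))
  subsite_map <- stats::setNames(labels, resids)
  offsets <- subsite_offsets(labels)

  path <- simulate_pucker_path(spec$pucker_spec)
  n_frames <- length(path$frames)

  protein <- protein_scaffold(spec$n_protein_residues)
  rigid_ring <- ideal_ring(0.57, 0, 0)   # ground-state chair
  set.seed(spec$seed + 1L)               # jitter stream, separate from path
  jit <- spec$rigid_jitter_sigma

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    ligand <- vector("list", n_res)
    names(ligand) <- resids
    for (r in seq_len(n_res)) {
      if (labels[r] == "-1") {
        ligand[[r]] <- place_residue(path$frames[[f]], offsets[r, ])
      } else {
        res <- place_residue(rigid_ring, offsets[r, ])
        if (jit > 0)
          res <- res + matrix(stats::rnorm(length(res), 0, jit), nrow(res))
        ligand[[r]] <- res
      }
    }
    frames[[f]] <- complex_frame(protein, ligand, frame_index = f - 1L)
  }
  structure(list(frames = frames,
                 subsite_map = subsite_map,
                 truth = path$truth,
                 time_step = path$time_step,
                 spec = spec),
            class = "complex_trajectory")
}

#' @export
print.complex_trajectory <- function(x, ...) {
  cat("Complex trajectory:", length(x$frames), "frames;",
      nrow(x$frames[[1]]$protein), "protein atoms;",
      length(x$subsite_map), "ligand residues at subsites",
      paste(x$subsite_map, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the subsite -1 ring trajectory from a complex trajectory
#'
#' @param traj a `complex_trajectory`.
#' @param subsite subsite label of the residue to follow (default `"-1"`).
#' @return A `ring_trajectory` usable with [per_frame_conformers()].
#' @export
ring_trajectory <- function(traj, subsite = "-1") {
  stopifnot(inherits(traj, "complex_trajectory"))
  rid <- names(traj$subsite_map)[traj$subsite_map == subsite]
  if (length(rid) != 1L)
    stop("subsite ", subsite, " does not identify exactly one residue")
  ring_atoms <- c("O5", "C1", "C2", "C3", "C4", "C5")
  frames <- lapply(traj$frames, function(f) {
    pos <- f$ligand[[rid]]
    if (!all(ring_atoms %in% rownames(pos)))
      stop("frame ", f$frame_index, ": residue ", rid,
           " lacks ring atoms ",
           paste(setdiff(ring_atoms, rownames(pos)), collapse = ","))
    ring_coords(pos[ring_atoms, , drop = FALSE],
                frame_index = f$frame_index, residue_id = rid)
  })
  structure(list(frames = frames,
                 time_step = if (!is.null(traj$time_step)) traj$time_step else 20,
                 run_length_label = sprintf("%g ns",
                                            length(frames) * 20 / 1000),
                 truth = traj$truth),
            class = "ring_trajectory")
}
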