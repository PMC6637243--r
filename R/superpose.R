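#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the RMSD between two
#' matched coordinate sets and returns the transform, so it can be applied
#' to atoms that were not part of the fit (the trajectory protocol holds
#' the protein heavy atoms during alignment and carries the ligand along).
#'
#' @param mobile,target numeric n x 3 matrices of matched coordinates.
#' @return A list with `R` (3 x 3 rotation), `center_mobile`,
#'   `center_target`, and `apply(x)` mapping any m x 3 matrix into the
#'   target frame.
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)) || ncol(mobile) != 3L)
    stop("'mobile' and 'target' must be matched n x 3 matrices")
  if (nrow(mobile) < 3L) stop("at least 3 matched atoms required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  force(R); force(cm); force(ct)
  list(R = R, center_mobile = cm, center_target = ct,
       apply = function(x) sweep(sweep(as.matrix(x), 2, cm) %*% t(R), 2, ct, "+"))
}

#' Root-mean-square deviation between matched coordinate sets
#'
#' Plain RMSD in the current frame, with no re-superposition: use
#' [kabsch()] first if alignment is wanted.
#'
#' @param a,b matched n x 3 coordinate matrices.
#' @return RMSD in the input units (Angstrom).
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("coordinate sets differ in size: ", nrow(a), " vs ", nrow(b), " atoms")
  sqrt(mean(rowSums((a - b)^2)))
}

#' A single frame of an enzyme:ligand complex
#'
#' Heavy-atom coordinates of one trajectory frame, split into the protein
#' moiety and the individual ligand sugar residues. Hydrogens and waters
#' are expected to be excluded upstream.
#'
#' @param protein numeric n x 3 matrix of protein heavy-atom coordinates
#'   (rownames = atom identifiers).
#' @param ligand named list mapping ligand residue id to its heavy-atom
#'   coordinate matrix.
#' @param frame_index integer frame number.
#' @return An object of class `complex_frame`.
#' @export
complex_frame <- function(protein, ligand, frame_index = 0L) {
  protein <- as.matrix(protein)
  stopifnot(ncol(protein) == 3L, is.list(ligand), length(ligand) >= 1L)
  ligand <- lapply(ligand, as.matrix)
  structure(list(protein = protein, ligand = ligand,
                 frame_index = as.integer(frame_index)),
            class = "complex_frame")
}

# check two complex frames carry identical atom books
check_matching_atoms <- function(frame, reference) {
  if (nrow(frame$protein) != nrow(reference$protein))
    stop("protein atom sets differ: ", nrow(frame$protein), " vs ",
         nrow(reference$protein), " atoms")
  if (!identical(names(frame$ligand), names(reference$ligand)))
    stop("ligand residue sets differ: [",
         paste(names(frame$ligand), collapse = ","), "] vs [",
         paste(names(reference$ligand), collapse = ","), "]")
  for (r in names(frame$ligand))
    if (nrow(frame$ligand[[r]]) != nrow(reference$ligand[[r]]))
      stop("ligand residue ", r, " atom count differs between frames")
  invisible(TRUE)
}

#' Superpose a complex frame onto a reference via its protein heavy atoms
#'
#' Fits the frame's protein heavy atoms onto the reference's by
#' least-squares and applies the same rigid transform to every ligand
#' residue -- the protein is held steady, the ligand is never re-fitted,
#' so ligand RMSD reports genuine motion relative to the protein frame.
#'
#' @param frame,reference `complex_frame` objects with matching atom sets.
#' @return The transformed `complex_frame`.
#' @export
superpose <- function(frame, reference) {
  stopifnot(inherits(frame, "complex_frame"),
            inherits(reference, "complex_frame"))
  check_matching_atoms(frame, reference)
  fit <- kabsch(frame$protein, reference$protein)
  complex_frame(fit$apply(frame$protein),
                lapply(frame$ligand, fit$apply),
                frame$frame_index)
}

#' Per-subsite flexibility profile of a complex trajectory
#'
#' For every frame: superpose on the protein heavy atoms of the reference
#' (frame 0), then record the RMSD of (i) the protein itself, (ii) the
#' complete ligand scaffold and (iii) each individual sugar residue,
#' labelled by its subsite. Higher per-frame RMSD at subsite -1 than at
#' +1 is the flexibility signature of the lytic subsite.
#'
#' @param frames list of `complex_frame` objects (>= 2), or a
#'   `complex_trajectory`.
#' @param subsite_map named character vector mapping ligand residue id to
#'   subsite label (`"-1"`, `"+1"`, ...); must cover all ligand residues
#'   and contain `-1`.
#' @param reference reference frame; default the first frame.
#' @return An object of class `flexibility_profile`: data.frame with one
#'   row per frame and one RMSD column (Angstrom) per entity
#'   (`protein`, `ligand`, then one per subsite).
#' @export
rmsd_series <- function(frames, subsite_map, reference = NULL) {
  if (inherits(frames, "complex_trajectory")) frames <- frames$frames
  stopifnot(length(frames) >= 2L)
  if (length(subsite_map) == 0L) stop("empty subsite map")
  if (!"-1" %in% subsite_map)
    stop("subsite map must label one residue as subsite -1")
  if (is.null(reference)) reference <- frames[[1L]]
  resids <- names(reference$ligand)
  missing <- setdiff(resids, names(subsite_map))
  if (length(missing) > 0L)
    stop("subsite map does not cover ligand residues: ",
         paste(missing, collapse = ", "))
  full_lig <- function(f) do.call(rbind, f$ligand[resids])

  rows <- lapply(frames, function(f) {
    sup <- superpose(f, reference)
    ent <- c(protein = rmsd(sup$protein, reference$protein),
             ligand = rmsd(full_lig(sup), full_lig(reference)))
    per_res <- vapply(resids, function(r)
      rmsd(sup$ligand[[r]], reference$ligand[[r]]), numeric(1))
    names(per_res) <- unname(subsite_map[resids])
    c(ent, per_res)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(frame = vapply(frames, `[[`, integer(1), "frame_index"), out)
  rownames(out) <- NULL
  attr(out, "reference_frame") <- reference$frame_index
  class(out) <- c("flexibility_profile", "data.frame")
  out
}

#' @export
print.flexibility_profile <- function(x, ...) {
  ent <- setdiff(names(x), "frame")
  cat("Flexibility profile:", nrow(x), "frames, entities:",
      paste(ent, collapse = ", "), "\n")
  m <- colMeans(x[ent])
  cat("Mean RMSD (A):",
      paste(sprintf("%s %.3f", ent, m), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format export of a flexibility profile
#'
#' @param profile a `flexibility_profile`.
#' @return data.frame with columns `frame`, `entity`, `rmsd`.
#' @export
flexibility_long <- function(profile) {
  ent <- setdiff(names(profile), "frame")
  do.call(rbind, lapply(ent, function(e)
    data.frame(frame = profile$frame, entity = e, rmsd = profile[[e]],
               stringsAsFactors = FALSE)))
}
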