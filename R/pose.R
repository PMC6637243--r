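#' A docking pose of an oligosaccharide ligand
#'
#' Ligand heavy-atom coordinates in the receptor frame, with the affinity
#' score and rank the docking engine reported. Poses and reference
#' complexes share the receptor coordinate system, so pose geometry is
#' compared without re-superposition.
#'
#' @param ligand named list mapping ligand residue id to its heavy-atom
#'   coordinate matrix (rownames = atom names).
#' @param dock_score affinity value; more negative is better.
#' @param pose_rank integer rank within the docking run (1 = best score).
#' @return An object of class `dock_pose`.
#' @export
dock_pose <- function(ligand, dock_score, pose_rank) {
  stopifnot(is.list(ligand), length(ligand) >= 1L,
            is.numeric(dock_score), pose_rank >= 1L)
  structure(list(ligand = lapply(ligand, as.matrix),
                 dock_score = dock_score,
                 pose_rank = as.integer(pose_rank)),
            class = "dock_pose")
}

ring_atom_names <- c("O5", "C1", "C2", "C3", "C4", "C5")

# pull the six ring atoms of one residue, by name, in ring order
residue_ring <- function(ligand, residue_id) {
  pos <- ligand[[residue_id]]
  if (is.null(pos)) stop("residue ", residue_id, " absent from ligand")
  missing <- setdiff(ring_atom_names, rownames(pos))
  if (length(missing) > 0L)
    stop("residue ", residue_id, " lacks ring atoms: ",
         paste(missing, collapse = ", "))
  pos[ring_atom_names, , drop = FALSE]
}

#' Ring RMSD of a docking pose against a reference pyranose ring
#'
#' RMSD over the six ring atoms of the subsite -1 residue, computed in
#' the shared receptor frame (no re-superposition). A pose is an optimal
#' fit when this RMSD is below 0.5 Angstrom relative to the
#' crystallographic reference.
#'
#' @param pose a [dock_pose()] (or a bare ligand list).
#' @param reference reference complex ligand: named list of residue
#'   coordinate matrices, or a 6 x 3 ring matrix with ring-atom rownames.
#' @param residue_id id of the -1 residue in both pose and reference.
#' @return RMSD in Angstrom.
#' @export
ring_rmsd <- function(pose, reference, residue_id = "1") {
  lig <- if (inherits(pose, "dock_pose")) pose$ligand else pose
  ring_p <- residue_ring(lig, residue_id)
  ring_r <- if (is.matrix(reference))
    reference[ring_atom_names, , drop = FALSE]
  else residue_ring(reference, residue_id)
  rmsd(ring_p, ring_r)
}

#' Cutoffs for docking-pose evaluation
#'
#' @param ring_rmsd optimal-fit threshold on the -1 pyranose ring RMSD
#'   (Angstrom).
#' @param ligand_rmsd threshold on whole matched-ligand RMSD vs the
#'   reference complex (Angstrom).
#' @param nucleophile_dist max distance nucleophile carboxylate O to the
#'   anomeric C1 (Angstrom).
#' @param acidbase_dist max distance acid/base carboxylate O to the
#'   glycosidic O (Angstrom).
#' @param hbond_dist donor-acceptor distance counted as an H-bond contact
#'   (Angstrom).
#' @param min_hbonds minimum number of -1-subsite H-bond contacts required
#'   by the interaction criterion (0 disables the contact count).
#' @return A list of class `pose_cutoffs`.
#' @export
pose_cutoffs <- function(ring_rmsd = 0.5, ligand_rmsd = 2.0,
                         nucleophile_dist = 3.5, acidbase_dist = 3.5,
                         hbond_dist = 3.4, min_hbonds = 0L) {
  structure(list(ring_rmsd = ring_rmsd, ligand_rmsd = ligand_rmsd,
                 nucleophile_dist = nucleophile_dist,
                 acidbase_dist = acidbase_dist,
                 hbond_dist = hbond_dist, min_hbonds = as.integer(min_hbonds)),
            class = "pose_cutoffs")
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Evaluate docking poses and select the MD starting coordinates
#'
#' Applies the four selection criteria used to pick the initial
#' coordinates of an MD run from a docking ensemble: (i) the best dock
#' score, (ii) superimposition with the reference complex (whole
#' matched-ligand RMSD below cutoff), (iii) best-fit conformation of the
#' substrate non-reducing end in subsite -1 (ring RMSD below the
#' 0.5 Angstrom optimal-fit threshold), and (iv) the fundamental active
#' site interactions for nucleophilic and acid/base catalysis (catalytic
#' carboxylate oxygens within cutoff of the anomeric carbon and the
#' glycosidic oxygen, plus an optional minimum H-bond contact count).
#' The selected pose is the best dock score among poses passing criteria
#' (ii)-(iv); when no pose passes, the run is reported as having no
#' productive pose rather than silently falling back.
#'
#' @param poses list of [dock_pose()] objects (>= 1).
#' @param reference reference complex ligand (named list of residue
#'   coordinate matrices) defining the optimal geometry.
#' @param catalytic_atoms list with 3-vectors `nucleophile_O` and
#'   `acidbase_O` (receptor-frame coordinates of the two conserved
#'   glutamate carboxylate oxygens), and optionally `polar` (m x 3 matrix
#'   of receptor polar atoms for the H-bond contact count).
#' @param cutoffs a [pose_cutoffs()].
#' @param residue_id id of the -1 residue (default `"1"`).
#' @return An object of class `pose_selection`: data.frame of per-pose
#'   evaluations ordered by pose rank (columns `pose_rank`, `dock_score`,
#'   `ring_rmsd`, `optimal_fit`, `ligand_rmsd`, `nucleophile_distance`,
#'   `acidbase_distance`, `n_hbonds`, `crit_score`, `crit_superposition`,
#'   `crit_subsite_fit`, `crit_interactions`, `selected`) with attributes
#'   `selected_rank` (`NA` for a no-productive-pose run) and `productive`.
#' @export
select_md_seed <- function(poses, reference, catalytic_atoms,
                           cutoffs = pose_cutoffs(), residue_id = "1") {
  stopifnot(length(poses) >= 1L)
  if (!all(c("nucleophile_O", "acidbase_O") %in% names(catalytic_atoms)))
    stop("catalytic_atoms must name 'nucleophile_O' and 'acidbase_O'")
  ranks <- vapply(poses, `[[`, integer(1), "pose_rank")
  if (anyDuplicated(ranks)) stop("pose ranks must be unique within a run")
  poses <- poses[order(ranks)]           # order invariance

  ref_all <- do.call(rbind, reference)
  rows <- lapply(poses, function(p) {
    lig <- p$ligand
    lig_all <- do.call(rbind, lig[names(reference)])
    rr <- ring_rmsd(p, reference, residue_id)
    lr <- rmsd(lig_all, ref_all)
    ring <- residue_ring(lig, residue_id)
    c1 <- ring["C1", ]
    o1 <- if ("O1" %in% rownames(lig[[residue_id]]))
      lig[[residue_id]]["O1", ] else c1
    nd <- dist3(catalytic_atoms$nucleophile_O, c1)
    ad <- dist3(catalytic_atoms$acidbase_O, o1)
    nhb <- if (!is.null(catalytic_atoms$polar)) {
      res <- lig[[residue_id]]
      polar_lig <- res[grepl("^O", rownames(res)), , drop = FALSE]
      sum(apply(catalytic_atoms$polar, 1, function(a)
        any(sqrt(colSums((t(polar_lig) - a)^2)) <= cutoffs$hbond_dist)))
    } else 0L
    data.frame(pose_rank = p$pose_rank,
               dock_score = p$dock_score,
               ring_rmsd = rr,
               optimal_fit = rr < cutoffs$ring_rmsd,
               ligand_rmsd = lr,
               nucleophile_distance = nd,
               acidbase_distance = ad,
               n_hbonds = nhb)
  })
  ev <- do.call(rbind, rows)
  ev$crit_score <- ev$dock_score == min(ev$dock_score)
  ev$crit_superposition <- ev$ligand_rmsd <= cutoffs$ligand_rmsd
  ev$crit_subsite_fit <- ev$optimal_fit
  ev$crit_interactions <-
    ev$nucleophile_distance <= cutoffs$nucleophile_dist &
    ev$acidbase_distance <= cutoffs$acidbase_dist &
    ev$n_hbonds >= cutoffs$min_hbonds
  pass <- ev$crit_superposition & ev$crit_subsite_fit & ev$crit_interactions
  ev$selected <- FALSE
  if (any(pass)) {
    cand <- which(pass)
    best <- cand[order(ev$dock_score[cand], ev$pose_rank[cand])][1L]
    ev$selected[best] <- TRUE
  }
  rownames(ev) <- NULL
  structure(ev,
            selected_rank = if (any(ev$selected))
              ev$pose_rank[ev$selected] else NA_integer_,
            productive = any(pass),
            cutoffs = cutoffs,
            class = c("pose_selection", "data.frame"))
}

#' @export
print.pose_selection <- function(x, ...) {
  if (isTRUE(attr(x, "productive"))) {
    cat("MD seed: pose rank", attr(x, "selected_rank"),
        sprintf("(score %.2f, ring RMSD %.2f A)\n",
                x$dock_score[x$selected], x$ring_rmsd[x$selected]))
  } else {
    cat("No productive pose: every pose fails the geometry criteria",
        "(dislocated poses; fit to the catalytic pocket suboptimal)\n")
  }
  cat(nrow(x), "poses evaluated;", sum(x$optimal_fit),
      "with ring RMSD below", attr(x, "cutoffs")$ring_rmsd, "A\n")
  invisible(x)
}

#' JSON report of a pose selection
#'
#' @param selection a `pose_selection`.
#' @param file optional output path.
#' @return JSON string (invisibly when written to `file`).
#' @export
pose_selection_report <- function(selection, file = NULL) {
  rep <- list(productive = isTRUE(attr(selection, "productive")),
              selected_rank = attr(selection, "selected_rank"),
              n_poses = nrow(selection),
              n_optimal_fit = sum(selection$optimal_fit),
              cutoffs = unclass(attr(selection, "cutoffs")),
              poses = selection)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
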