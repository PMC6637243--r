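#' Write a complex trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame: protein scaffold as chain A glycine
#' backbone records, ligand sugar residues as chain B `GAL` residues with
#' PDB carbohydrate atom names (O5, C1..C5, O1). Occupancy 1.00, B-factor
#' 0.00, no hydrogens. Output is byte-deterministic given the trajectory.
#'
#' @param traj a `complex_trajectory` (see [build_mock_complex()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_complex_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "complex_trajectory"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("REMARK   1 SYNTHETIC MOCK ENZYME:LIGAND COMPLEX TRAJECTORY", con)
  for (f in traj$frames) {
    writeLines(sprintf("MODEL     %4d", f$frame_index + 1L), con)
    serial <- 1L
    # protein: rownames are "<atom>:<resno>"
    pn <- strsplit(rownames(f$protein), ":", fixed = TRUE)
    for (i in seq_len(nrow(f$protein))) {
      writeLines(pdb_atom_line(serial, pn[[i]][1], "GLY", "A",
                               as.integer(pn[[i]][2]), f$protein[i, ]), con)
      serial <- serial + 1L
    }
    for (rid in names(f$ligand)) {
      pos <- f$ligand[[rid]]
      for (i in seq_len(nrow(pos))) {
        writeLines(pdb_atom_line(serial, rownames(pos)[i], "GAL", "B",
                                 as.integer(rid), pos[i, ]), con)
        serial <- serial + 1L
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

pdb_atom_line <- function(serial, name, resn, chain, resno, xyz) {
  elem <- substr(name, 1, 1)
  name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, resn, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, elem)
}

#' Read a multi-model PDB file into a complex trajectory
#'
#' Parses trajectory frames (MODEL blocks) via \pkg{bio3d}, keeping heavy
#' atoms only and splitting each frame into the protein moiety and the
#' individual ligand residues.
#'
#' @param file path to a multi-model PDB.
#' @param ligand_chain chain id holding the ligand (default `"B"`); all
#'   other chains are treated as protein.
#' @param subsite_map optional named character vector (residue id ->
#'   subsite label) attached to the result.
#' @return A `complex_trajectory`.
#' @export
read_complex_pdb <- function(file, ligand_chain = "B", subsite_map = NULL) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  heavy <- at$elesy != "H" & !(at$resid %in% c("HOH", "WAT"))
  is_lig <- heavy & at$chain == ligand_chain
  is_prot <- heavy & at$chain != ligand_chain
  xyz <- pdb$xyz                         # n_frames x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- nrow(xyz)

  coords_of <- function(frame_row, idx) {
    m <- matrix(frame_row[as.vector(t(cbind(3 * idx - 2, 3 * idx - 1,
                                            3 * idx)))],
                ncol = 3, byrow = TRUE)
    m
  }
  prot_idx <- which(is_prot)
  prot_names <- paste0(at$elety[prot_idx], ":", at$resno[prot_idx])
  lig_idx_by_res <- split(which(is_lig), at$resno[which(is_lig)])
  # preserve file order of ligand residues
  lig_order <- as.character(unique(at$resno[which(is_lig)]))
  lig_idx_by_res <- lig_idx_by_res[lig_order]

  frames <- lapply(seq_len(n_frames), function(f) {
    row <- xyz[f, ]
    protein <- coords_of(row, prot_idx)
    rownames(protein) <- prot_names
    ligand <- lapply(lig_idx_by_res, function(idx) {
      m <- coords_of(row, idx)
      rownames(m) <- at$elety[idx]
      m
    })
    complex_frame(protein, ligand, frame_index = f - 1L)
  })
  structure(list(frames = frames,
                 subsite_map = subsite_map,
                 truth = NULL,
                 time_step = 20,
                 spec = NULL),
            class = "complex_trajectory")
}

#' Write / read a residue-to-subsite map as two-column TSV
#'
#' @param subsite_map named character vector (residue id -> subsite label).
#' @param file path.
#' @return `write_subsite_map`: `file` invisibly; `read_subsite_map`: the
#'   named character vector.
#' @export
write_subsite_map <- function(subsite_map, file) {
  utils::write.table(data.frame(residue_id = names(subsite_map),
                                subsite = unname(subsite_map)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_subsite_map
#' @export
read_subsite_map <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE, quote = "",
                         colClasses = "character")  # labels may hold "'"
  stats::setNames(d$subsite, d$residue_id)
}

#' Export a per-frame pucker/conformer table as TSV
#'
#' Writes the per-frame record `(frame, Q, theta, phi, conformer)` for a
#' classified trajectory, the standard flat-file form of a puckering
#' analysis.
#'
#' @param assignments a `conformer_series` (see [per_frame_conformers()]).
#' @param file path; when `NULL` the data.frame is returned only.
#' @return The data.frame, invisibly when written.
#' @export
pucker_table <- function(assignments, file = NULL) {
  d <- data.frame(
    frame = seq_along(assignments) - 1L,
    Q = vapply(assignments, function(a) a$pucker$Q, numeric(1)),
    theta = vapply(assignments, function(a) a$pucker$theta, numeric(1)),
    phi = vapply(assignments, function(a) a$pucker$phi, numeric(1)),
    conformer = conformer_labels(assignments),
    stringsAsFactors = FALSE)
  if (!is.null(file)) {
    utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(d))
  }
  d
}

#' Render occupancy tables in the families-by-conformers layout
#'
#' Binds one row per run into a wide table whose columns are the union of
#' observed conformers (ordered by the canonical library), with absent
#' conformers rendered as an em dash -- the conventional presentation of
#' per-run puckering distributions.
#'
#' @param tables named list of `occupancy_table` objects (names = run ids).
#' @param file optional TSV output path.
#' @param digits rounding for percentages.
#' @return A character data.frame (runs x conformers), invisibly when
#'   written.
#' @export
occupancy_wide <- function(tables, file = NULL, digits = 1) {
  lib <- build_conformer_library()
  all_conf <- unique(unlist(lapply(tables, function(t) names(t$percent))))
  ord <- c(intersect(lib$label, all_conf), setdiff(all_conf, lib$label))
  rows <- lapply(tables, function(t) {
    v <- vapply(ord, function(cf)
      if (cf %in% names(t$percent))
        formatC(round(t$percent[[cf]], digits), format = "f",
                digits = digits)
      else "—", character(1))
    as.data.frame(as.list(v), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(tables)
  out <- cbind(run = names(tables), out)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a subsite -1 ring trajectory straight from a multi-model PDB
#'
#' Convenience wrapper: parses the file with [read_complex_pdb()] and
#' extracts the six ring atoms of one ligand residue per frame.
#'
#' @param file multi-model PDB path.
#' @param ligand_chain chain id of the ligand (default `"B"`).
#' @param residue_id ligand residue id to follow (default the first).
#' @return A `ring_trajectory`.
#' @export
read_ring_trajectory <- function(file, ligand_chain = "B",
                                 residue_id = NULL) {
  ct <- read_complex_pdb(file, ligand_chain = ligand_chain)
  resids <- names(ct$frames[[1]]$ligand)
  if (is.null(residue_id)) residue_id <- resids[1L]
  ct$subsite_map <- stats::setNames(
    ifelse(resids == residue_id, "-1", paste0("+", seq_along(resids) - 1L)),
    resids)
  ring_trajectory(ct, "-1")
}
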