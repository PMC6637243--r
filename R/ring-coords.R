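#' Ordered six-atom ring coordinates for one trajectory frame
#'
#' Container for the six ring atoms of a pyranose residue in a single frame.
#' The atom order fixes the puckering convention: for D-pyranoses the ring is
#' traversed O5, C1, C2, C3, C4, C5, which places the ground-state
#' \eqn{^4C_1} chair at the north pole (\eqn{\theta = 0}) of the
#' Cremer-Pople sphere.
#'
#' @param positions numeric 6 x 3 matrix of coordinates in Angstrom, one row
#'   per ring atom in ring order.
#' @param atom_labels character vector of six atom names; default the
#'   standard pyranose ring `O5, C1, ..., C5`.
#' @param frame_index integer frame number (>= 0).
#' @param residue_id identifier of the residue the ring belongs to
#'   (e.g. `"A:401"` or a subsite label).
#'
#' @return An object of class `ring_coords`: the coordinate matrix with the
#'   labels as rownames and `frame_index` / `residue_id` attributes.
#' @export
#' @examples
#' r <- ideal_ring(Q = 0.6, theta = 0, phi = 0)
#' cremer_pople(r)
ring_coords <- function(positions,
                        atom_labels = c("O5", "C1", "C2", "C3", "C4", "C5"),
                        frame_index = 0L,
                        residue_id = "-1") {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || !identical(dim(positions), c(6L, 3L)))
    stop("'positions' must be a numeric 6 x 3 matrix")
  if (any(!is.finite(positions)))
    stop("ring coordinates must be finite")
  if (length(atom_labels) != 6L)
    stop("exactly 6 atom labels required")
  d <- ring_bond_lengths(positions)
  if (any(d <= 0.5) || any(d >= 3.0))
    stop("consecutive ring-atom distances outside (0.5, 3.0) Angstrom; ",
         "not a valid six-membered ring (bonds: ",
         paste(sprintf("%.2f", d), collapse = ", "), ")")
  dimnames(positions) <- list(atom_labels, c("x", "y", "z"))
  structure(positions,
            frame_index = as.integer(frame_index),
            residue_id = residue_id,
            class = c("ring_coords", "matrix", "array"))
}

# consecutive bond lengths around the ring (6 values, closing 6 -> 1)
ring_bond_lengths <- function(positions) {
  nxt <- positions[c(2:6, 1), , drop = FALSE]
  sqrt(rowSums((positions - nxt)^2))
}

#' @export
print.ring_coords <- function(x, ...) {
  cat("Ring coordinates (frame ", attr(x, "frame_index"),
      ", residue ", attr(x, "residue_id"), ")\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}
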