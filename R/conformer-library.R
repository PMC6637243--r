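#' Reference library of the 38 canonical pyranose ring conformers
#'
#' Builds the canonical conformer set used to classify Cremer-Pople
#' coordinates: 2 chairs at the poles, 6 boats and 6 skew-boats alternating
#' at 30-degree phi intervals on the equator, and 12 half-chairs plus 12
#' envelopes alternating at 30-degree intervals on the two tropics.
#'
#' Each reference position \eqn{(\theta_{ref}, \phi_{ref})} is derived from
#' the conformer's ideal geometry rather than tabulated: the IUPAC symbol
#' names the ring atoms displaced above (superscript) and below (subscript)
#' the reference plane, the corresponding out-of-plane displacement pattern
#' is constructed, and the forward Cremer-Pople decomposition of that
#' pattern yields the reference angles. Under the O5, C1..C5 atom ordering
#' this puts \eqn{^4C_1} at \eqn{\theta = 0}, \eqn{^1S_3} at
#' \eqn{(90, 210)}, \eqn{^{1,4}B} at \eqn{(90, 240)}, \eqn{^1S_5} at
#' \eqn{(90, 270)}, half-chairs at \eqn{\theta = 50.77} / \eqn{129.23} and
#' envelopes at \eqn{\theta = 54.74} / \eqn{125.26}.
#'
#' @return A data.frame of class `conformer_library` with columns `label`,
#'   `family` (chair / boat / skew-boat / half-chair / envelope),
#'   `theta_ref`, `phi_ref` (degrees) and `band` (pole / tropic-N /
#'   equator / tropic-S).
#' @export
#' @examples
#' lib <- build_conformer_library()
#' nrow(lib)           # 38
#' subset(lib, band == "equator")
build_conformer_library <- function() {
  specs <- conformer_atom_patterns()
  ref <- t(vapply(seq_len(nrow(specs)), function(i) {
    z <- displacement_pattern(specs$up[[i]], specs$down[[i]])
    pucker_angles_from_z(z)
  }, numeric(2)))
  # poles: phi is degenerate, report 0; snap float dust on the grid angles
  ref[, 2] <- round(ref[, 2], 9) %% 360
  ref[specs$family == "chair", 2] <- 0
  band <- ifelse(specs$family == "chair",
                 "pole",
          ifelse(specs$family %in% c("boat", "skew-boat"),
                 "equator",
                 ifelse(ref[, 1] < 90, "tropic-N", "tropic-S")))
  lib <- data.frame(label = specs$label,
                    family = specs$family,
                    theta_ref = ref[, 1],
                    phi_ref = ref[, 2],
                    band = band,
                    stringsAsFactors = FALSE)
  stopifnot(nrow(lib) == 38L, !anyDuplicated(lib$label))
  class(lib) <- c("conformer_library", "data.frame")
  lib
}

# Ring atoms are indexed 1..6 = O5, C1, C2, C3, C4, C5; in conformer symbols
# O5 is written "O" and carbons by number.
ring_atom_index <- function(sym) {
  i <- match(sym, c("O", "1", "2", "3", "4", "5"))
  if (anyNA(i)) stop("unknown ring atom symbol: ", paste(sym[is.na(i)], collapse = ","))
  i
}

# unit-amplitude out-of-plane displacement pattern for atoms flagged
# above/below the ring reference plane (already centred: mean removed)
displacement_pattern <- function(up, down) {
  z <- numeric(6)
  z[ring_atom_index(up)] <- 1
  z[ring_atom_index(down)] <- -1
  z - mean(z)
}

# forward Cremer-Pople decomposition applied directly to a displacement
# pattern; returns c(theta, phi) in degrees
pucker_angles_from_z <- function(z) {
  j <- 0:5
  psi <- 2 * pi * j / 6
  q2cos <- sqrt(1 / 3) * sum(z * cos(2 * psi))
  q2sin <- -sqrt(1 / 3) * sum(z * sin(2 * psi))
  q2 <- sqrt(q2cos^2 + q2sin^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  phi <- (atan2(q2sin, q2cos) * 180 / pi) %% 360
  theta <- acos(max(-1, min(1, q3 / sqrt(q2^2 + q3^2)))) * 180 / pi
  c(theta, phi)
}

# the 38 canonical conformers as displaced-atom sets
conformer_atom_patterns <- function() {
  entry <- function(label, family, up, down)
    list(label = label, family = family, up = up, down = down)
  e <- list(
    # chairs: full alternation
    entry("4C1", "chair", c("O", "2", "4"), c("1", "3", "5")),
    entry("1C4", "chair", c("1", "3", "5"), c("O", "2", "4")),
    # boats: para pair same side
    entry("3,OB", "boat", c("3", "O"), character(0)),
    entry("B1,4", "boat", character(0), c("1", "4")),
    entry("2,5B", "boat", c("2", "5"), character(0)),
    entry("B3,O", "boat", character(0), c("3", "O")),
    entry("1,4B", "boat", c("1", "4"), character(0)),
    entry("B2,5", "boat", character(0), c("2", "5")),
    # skew-boats: 1,3-pair opposite sides
    entry("3S1", "skew-boat", "3", "1"),
    entry("5S1", "skew-boat", "5", "1"),
    entry("2SO", "skew-boat", "2", "O"),
    entry("1S3", "skew-boat", "1", "3"),
    entry("1S5", "skew-boat", "1", "5"),
    entry("OS2", "skew-boat", "O", "2"),
    # half-chairs: adjacent pair opposite sides
    entry("OH1", "half-chair", "O", "1"),
    entry("2H1", "half-chair", "2", "1"),
    entry("2H3", "half-chair", "2", "3"),
    entry("4H3", "half-chair", "4", "3"),
    entry("4H5", "half-chair", "4", "5"),
    entry("OH5", "half-chair", "O", "5"),
    entry("1HO", "half-chair", "1", "O"),
    entry("1H2", "half-chair", "1", "2"),
    entry("3H2", "half-chair", "3", "2"),
    entry("3H4", "half-chair", "3", "4"),
    entry("5H4", "half-chair", "5", "4"),
    entry("5HO", "half-chair", "5", "O"),
    # envelopes: a single displaced atom
    entry("OE", "envelope", "O", character(0)),
    entry("E1", "envelope", character(0), "1"),
    entry("2E", "envelope", "2", character(0)),
    entry("E3", "envelope", character(0), "3"),
    entry("4E", "envelope", "4", character(0)),
    entry("E5", "envelope", character(0), "5"),
    entry("EO", "envelope", character(0), "O"),
    entry("1E", "envelope", "1", character(0)),
    entry("E2", "envelope", character(0), "2"),
    entry("3E", "envelope", "3", character(0)),
    entry("E4", "envelope", character(0), "4"),
    entry("5E", "envelope", "5", character(0))
  )
  data.frame(label = vapply(e, `[[`, character(1), "label"),
             family = vapply(e, `[[`, character(1), "family"),
             up = I(lapply(e, `[[`, "up")),
             down = I(lapply(e, `[[`, "down")),
             stringsAsFactors = FALSE)
}

#' Great-circle angular distance on the puckering sphere
#'
#' @param theta1,phi1,theta2,phi2 spherical angles in degrees.
#' @return Angular distance in degrees, in `[0, 180]`. Vectorised over the
#'   second point.
#' @export
puckering_distance <- function(theta1, phi1, theta2, phi2) {
  t1 <- theta1 * pi / 180; t2 <- theta2 * pi / 180
  dphi <- (phi1 - phi2) * pi / 180
  cd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dphi)
  acos(pmax(-1, pmin(1, cd))) * 180 / pi
}

#' Classify puckering coordinates against the canonical conformer library
#'
#' Assigns a `pucker` object to the nearest canonical conformer by
#' great-circle angular distance on the unit puckering sphere. Rings whose
#' total amplitude falls below the planarity threshold are reported as
#' `UNDEFINED` (a flat ring has no meaningful \eqn{\theta, \phi}). Exact
#' ties are broken by lexicographic label order.
#'
#' @param pucker a `pucker` object (see [cremer_pople()]).
#' @param library a `conformer_library`; built on the fly when omitted.
#' @return An object of class `conformer_assignment`: list with `conformer`
#'   (label or `"UNDEFINED"`), `family`, `angular_distance` (degrees, `NA`
#'   when undefined) and the input `pucker`.
#' @export
#' @examples
#' classify_pucker(pucker(Q = 0.57, theta = 0, phi = 123))   # 4C1
classify_pucker <- function(pucker, library = build_conformer_library()) {
  stopifnot(inherits(pucker, "pucker"))
  if (is.null(library) || nrow(library) == 0L)
    stop("empty conformer library")
  if (isTRUE(pucker$planar) || is.na(pucker$theta)) {
    return(structure(list(conformer = "UNDEFINED", family = NA_character_,
                          angular_distance = NA_real_, pucker = pucker),
                     class = "conformer_assignment"))
  }
  d <- puckering_distance(pucker$theta, pucker$phi,
                          library$theta_ref, library$phi_ref)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[order(library$label[best])][1L]
  structure(list(conformer = library$label[best],
                 family = library$family[best],
                 angular_distance = d[best],
                 pucker = pucker),
            class = "conformer_assignment")
}

#' @export
print.conformer_assignment <- function(x, ...) {
  if (identical(x$conformer, "UNDEFINED")) {
    cat("Conformer: UNDEFINED (near-planar ring, Q =",
        sprintf("%.3f", x$pucker$Q), "A)\n")
  } else {
    cat(sprintf("Conformer: %s (%s), %.2f deg from reference, %s\n",
                x$conformer, x$family, x$angular_distance, format(x$pucker)))
  }
  invisible(x)
}

# label sets used throughout the trajectory layer
equatorial_labels <- function(library = build_conformer_library())
  library$label[library$band == "equator"]

#' @export
print.conformer_library <- function(x, ...) {
  cat("Canonical pyranose conformer library:", nrow(x), "entries\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
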