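#' Per-frame conformer assignments for a ring trajectory
#'
#' Runs the Cremer-Pople decomposition and canonical-conformer
#' classification on every frame of a ring trajectory, preserving frame
#' order. This is the stream every downstream occupancy, excursion and
#' itinerary computation consumes.
#'
#' @param traj a `ring_trajectory` (from [simulate_pucker_path()] or
#'   [read_ring_trajectory()]), or a plain list of [ring_coords()].
#' @param library conformer library (built when omitted).
#' @param Q_min planarity threshold passed to [cremer_pople()].
#' @return A list of `conformer_assignment` objects, one per frame, with
#'   class `conformer_series`.
#' @export
per_frame_conformers <- function(traj, library = build_conformer_library(),
                                 Q_min = 0.1) {
  frames <- if (inherits(traj, "ring_trajectory")) traj$frames else traj
  if (length(frames) == 0L) stop("empty trajectory")
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    p <- tryCatch(cremer_pople(frames[[i]], Q_min = Q_min),
                  error = function(e)
                    stop("ring extraction failed at frame ", i - 1L, ": ",
                         conditionMessage(e), call. = FALSE))
    out[[i]] <- classify_pucker(p, library)
  }
  class(out) <- "conformer_series"
  out
}

#' @export
print.conformer_series <- function(x, ...) {
  tab <- sort(table(conformer_labels(x)), decreasing = TRUE)
  cat("Conformer series:", length(x), "frames;",
      paste(names(tab), sprintf("(%d)", tab), collapse = " "), "\n")
  invisible(x)
}

#' Extract the label vector from a conformer series
#' @param assignments a `conformer_series` or list of assignments.
#' @return Character vector of conformer labels.
#' @export
conformer_labels <- function(assignments) {
  if (is.character(assignments)) return(assignments)
  vapply(assignments, `[[`, character(1), "conformer")
}

#' Conformer occupancy table of a trajectory
#'
#' Tabulates the percentage of frames assigned to each conformer,
#' reproducing the layout of per-run puckering distribution tables:
#' conformers never observed are omitted (rendered as an em dash on
#' export), percentages sum to 100 and the dominant conformer is flagged.
#'
#' @param assignments a `conformer_series`, list of assignments, or plain
#'   character vector of labels.
#' @return An object of class `occupancy_table`: list with `percent`
#'   (named numeric, descending), `n_frames` and `dominant`.
#' @export
#' @examples
#' occupancy(rep(c("4C1", "1S3"), c(900, 100)))
occupancy <- function(assignments) {
  labels <- conformer_labels(assignments)
  if (length(labels) == 0L) stop("at least one assignment required")
  counts <- table(labels)
  pct <- 100 * as.numeric(counts) / length(labels)
  names(pct) <- names(counts)
  pct <- sort(pct, decreasing = TRUE)
  structure(list(percent = pct,
                 n_frames = length(labels),
                 dominant = names(pct)[1L]),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, digits = 1, ...) {
  cat("Occupancy over", x$n_frames, "frames (dominant:", x$dominant, ")\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Segment a conformer stream into excursions from the ground-state chair
#'
#' An excursion is a maximal contiguous run of frames whose conformer is
#' not the ground-state chair (default \eqn{^4C_1}); the intermediate
#' envelope and half-chair forms a ring passes through on its way to the
#' equator are counted inside the excursion. Each excursion records
#' whether it reached an equatorial (boat / skew-boat) conformer --
#' equatorial states may be attained in short bursts or held for extended
#' periods, and this segmentation makes that distinction measurable.
#'
#' @param assignments conformer stream (series, list, or label vector).
#' @param equator_labels labels counted as equatorial; defaults to the 12
#'   boat/skew-boat conformers of the library.
#' @param ground ground-state label closing an excursion (default `"4C1"`).
#' @return A data.frame of class `excursion_table` with columns
#'   `start_frame`, `end_frame` (0-based, inclusive), `n_frames`,
#'   `reached_equator`, and `conformers_visited` (comma-joined labels).
#'   Zero rows when the stream never leaves the ground state.
#' @export
excursions <- function(assignments,
                       equator_labels = equatorial_labels(),
                       ground = "4C1") {
  labels <- conformer_labels(assignments)
  away <- labels != ground
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      n_frames = integer(0), reached_equator = logical(0),
                      conformers_visited = character(0),
                      stringsAsFactors = FALSE)
  if (!any(away)) {
    class(empty) <- c("excursion_table", "data.frame")
    return(empty)
  }
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    vis <- unique(labels[idx])
    data.frame(start_frame = starts[k] - 1L,
               end_frame = ends[k] - 1L,
               n_frames = length(idx),
               reached_equator = any(vis %in% equator_labels),
               conformers_visited = paste(vis, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("excursion_table", "data.frame")
  out
}

#' The three family-type conformational itineraries
#'
#' Returns the catalytic itinerary definitions used for assignment. Each
#' itinerary is anchored by the equatorial pre-transition-state conformer
#' it starts from, passes through a tropic transition-state conformer
#' (possibly a hybrid of two adjacent canonical forms) and relaxes to the
#' \eqn{^4C_1} chair:
#' \itemize{
#'   \item GH2-type: \eqn{^1S_3 \to {}^4H_3{}^\ddagger \to {}^4C_1}
#'   \item GH1/GH35-type: \eqn{^{1,4}B \to {}^4H_3/{}^4E^\ddagger \to {}^4C_1}
#'   \item GH42-type: \eqn{^1S_5 \to {}^4E/{}^4H_5{}^\ddagger \to {}^4C_1}
#' }
#' All three are compatible with the antiperiplanar lone pair hypothesis
#' (ALPH) for hydrolysis of beta-glycosides.
#'
#' @return A data.frame with columns `itinerary`, `anchor` (the equatorial
#'   skew-boat/boat conformer), `ts_labels` (transition-state canonical
#'   labels, comma-joined) and `path` (display string).
#' @export
itinerary_definitions <- function() {
  data.frame(
    itinerary = c("GH2-type", "GH1/GH35-type", "GH42-type"),
    anchor = c("1S3", "1,4B", "1S5"),
    ts_labels = c("4H3", "4H3,4E", "4E,4H5"),
    path = c("1S3 -> 4H3* -> 4C1",
             "1,4B -> 4H3/4E* -> 4C1",
             "1S5 -> 4E/4H5* -> 4C1"),
    stringsAsFactors = FALSE)
}

#' Assign an ALPH conformational itinerary from an occupancy table
#'
#' Decides which of the three family-type itineraries a trajectory's
#' conformer inventory supports. An itinerary is supported when its
#' equatorial anchor conformer (\eqn{^1S_3}, \eqn{^{1,4}B} or
#' \eqn{^1S_5}) has nonzero occupancy; its support is that anchor's share
#' of the total anchor (equatorial pre-transition-state) occupancy. The
#' reported itinerary is the argmax over supports; `NONE` when no anchor
#' was ever observed. The assignment is a pure function of the occupancy
#' table.
#'
#' @param occ an `occupancy_table` (or named percentage vector).
#' @return An object of class `itinerary_assignment`: list with
#'   `itinerary` (`"NONE"` or a type label), `support` (named fractions in
#'   `[0, 1]` over the three itineraries), `supported` (character vector of
#'   all itineraries with nonzero support) and `alph_compatible`.
#' @export
#' @examples
#' assign_itinerary(occupancy(rep(c("4C1", "4H3", "1S3"),
#'                                c(980, 5, 15))))   # GH2-type
assign_itinerary <- function(occ) {
  pct <- if (inherits(occ, "occupancy_table")) occ$percent else occ
  stopifnot(is.numeric(pct), !is.null(names(pct)))
  defs <- itinerary_definitions()
  anchor_pct <- vapply(defs$anchor, function(a)
    if (a %in% names(pct)) unname(pct[[a]]) else 0, numeric(1))
  names(anchor_pct) <- defs$itinerary
  total <- sum(anchor_pct)
  support <- if (total > 0) anchor_pct / total else anchor_pct * 0
  supported <- defs$itinerary[anchor_pct > 0]
  itinerary <- if (total == 0) "NONE" else
    defs$itinerary[which.max(anchor_pct)]
  structure(list(itinerary = itinerary,
                 support = support,
                 supported = supported,
                 anchor_percent = anchor_pct,
                 alph_compatible = total > 0),
            class = "itinerary_assignment")
}

#' @export
print.itinerary_assignment <- function(x, ...) {
  if (identical(x$itinerary, "NONE")) {
    cat("Itinerary: NONE (no equatorial anchor conformer observed;",
        "not ALPH-diagnostic)\n")
  } else {
    defs <- itinerary_definitions()
    cat("Itinerary:", x$itinerary,
        sprintf("[%s]", defs$path[defs$itinerary == x$itinerary]), "\n")
    cat("Support:",
        paste(sprintf("%s %.2f", names(x$support), x$support),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export excursions as a BED-like interval table
#'
#' Frame coordinates written 0-based half-open (`end = end_frame + 1`),
#' the interval convention of BED-style tooling; the in-memory
#' `excursion_table` keeps inclusive ends.
#'
#' @param ex an `excursion_table` (see [excursions()]).
#' @param file output TSV path.
#' @param name interval name prefix.
#' @return The exported data.frame, invisibly.
#' @export
write_excursions_bed <- function(ex, file, name = "excursion") {
  bed <- data.frame(start = ex$start_frame,
                    end = ex$end_frame + 1L,
                    name = if (nrow(ex))
                      paste0(name, "_", seq_len(nrow(ex))) else character(0),
                    reached_equator = ex$reached_equator,
                    conformers_visited = ex$conformers_visited,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bed)
}
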