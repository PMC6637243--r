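#' MaxSub structural similarity score
#'
#' Seed-extension search for the largest subset of corresponded residues
#' superimposable within a distance threshold, scored in `[0, 1]`. Every
#' contiguous window of `seed_length` correspondence pairs seeds a
#' least-squares superposition; the matched set is grown over four
#' iterations with a threshold ramping up to `d_threshold`, re-fitting on
#' the matched set each round. The best final set M scores
#' \deqn{S = \frac{1}{N} \sum_{i \in M} \frac{1}{1 + (d_i/d)^2}}
#' with N the residue count of the *first* structure -- which is why the
#' score is not symmetric in its arguments; an identical pair under the
#' identity correspondence scores exactly 1.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (one representative
#'   atom per residue, e.g. Calpha, or flattened backbone sets).
#' @param correspondence two-column integer matrix of matched residue
#'   indices (into a and b); defaults to the identity correspondence when
#'   the structures have equal length. At least 4 pairs required.
#' @param d_threshold distance threshold d in Angstrom (default 3.5).
#' @param seed_length length of the seed windows (default 4).
#' @return Score in `[0, 1]`.
#' @seealso [structure_distance_matrix()]
#' @export
#' @examples
#' s <- random_ca_structure(30, seed = 7)
#' maxsub_score(s, s)   # 1: self-identity bound
maxsub_score <- function(coords_a, coords_b, correspondence = NULL,
                         d_threshold = 3.5, seed_length = 4L) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3L, ncol(coords_b) == 3L, d_threshold > 0)
  if (is.null(correspondence)) {
    if (nrow(coords_a) != nrow(coords_b))
      stop("structures differ in length; an explicit correspondence is required")
    correspondence <- cbind(seq_len(nrow(coords_a)), seq_len(nrow(coords_a)))
  }
  correspondence <- as.matrix(correspondence)
  L <- nrow(correspondence)
  if (L < 4L) stop("correspondence must map at least 4 residue pairs")
  A <- coords_a[correspondence[, 1], , drop = FALSE]
  B <- coords_b[correspondence[, 2], , drop = FALSE]

  pair_dists <- function(fit) sqrt(rowSums((fit$apply(A) - B)^2))

  best_score <- 0
  for (s in seq_len(L - seed_length + 1L)) {
    M <- s:(s + seed_length - 1L)
    for (iter in 1:4) {
      thr <- d_threshold * iter / 4
      fit <- kabsch(A[M, , drop = FALSE], B[M, , drop = FALSE])
      d <- pair_dists(fit)
      M_new <- which(d < thr)
      if (length(M_new) >= 3L) M <- M_new
    }
    fit <- kabsch(A[M, , drop = FALSE], B[M, , drop = FALSE])
    d <- pair_dists(fit)
    final <- d < d_threshold
    score <- sum(1 / (1 + (d[final] / d_threshold)^2)) / nrow(coords_a)
    if (score > best_score) best_score <- score
  }
  min(best_score, 1)
}

#' Symmetrized 1-MaxSubAverage structural distance matrix
#'
#' MaxSub scores are not symmetrical, so the two reciprocal scores of
#' each ordered structure pair are computed and averaged into a single
#' MaxSubAverage value; the structural distance for the pair is
#' 1 - MaxSubAverage. The result is symmetric with a zero diagonal and
#' entries in `[0, 1]`, ready for distance-based tree inference.
#'
#' @param structures named list of coordinate matrices (ids become matrix
#'   dimnames and, downstream, tree leaf labels).
#' @param correspondences optional list of two-column index matrices keyed
#'   `"idA|idB"`; identity correspondence (equal lengths) when absent.
#' @param d_threshold MaxSub distance threshold (Angstrom).
#' @return A symmetric matrix of class `structure_distance_matrix`.
#' @export
structure_distance_matrix <- function(structures, correspondences = NULL,
                                      d_threshold = 3.5) {
  ids <- names(structures)
  if (is.null(ids) || any(ids == ""))
    stop("'structures' must be a fully named list")
  n <- length(structures)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i >= k) next
      corr_ik <- correspondences[[paste(ids[i], ids[k], sep = "|")]]
      corr_ki <- if (!is.null(corr_ik)) corr_ik[, 2:1, drop = FALSE] else NULL
      ms_ik <- tryCatch(
        maxsub_score(structures[[i]], structures[[k]], corr_ik, d_threshold),
        error = function(e) stop("pair ", ids[i], "|", ids[k], ": ",
                                 conditionMessage(e), call. = FALSE))
      ms_ki <- tryCatch(
        maxsub_score(structures[[k]], structures[[i]], corr_ki, d_threshold),
        error = function(e) stop("pair ", ids[k], "|", ids[i], ": ",
                                 conditionMessage(e), call. = FALSE))
      D[i, k] <- D[k, i] <- 1 - (ms_ik + ms_ki) / 2
    }
  }
  class(D) <- c("structure_distance_matrix", "matrix", "array")
  D
}

#' Neighbor-joining tree from a structural distance matrix
#'
#' Standard Saitou-Nei neighbor-joining over a symmetric distance matrix;
#' on an additive matrix the generating topology and branch lengths are
#' reconstructed exactly. Negative branch lengths, an occasional NJ
#' artefact on non-additive input, are clamped to zero with a warning.
#'
#' @param D a `structure_distance_matrix` or any symmetric numeric matrix
#'   with ids as dimnames (>= 3 leaves).
#' @param clamp_negative clamp negative branch lengths to 0 (default TRUE).
#' @return An unrooted `phylo` tree (leaf labels = structure ids).
#' @export
nj_tree <- function(D, clamp_negative = TRUE) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("'D' must be a square distance matrix")
  if (max(abs(D - t(D))) > 1e-8) stop("'D' must be symmetric")
  if (nrow(D) < 3L) stop("at least 3 structures required for a tree")
  tree <- ape::nj(stats::as.dist(D))
  if (clamp_negative && any(tree$edge.length < 0)) {
    warning(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Write a tree in Newick format / a distance matrix in PHYLIP format
#'
#' @param tree a `phylo` tree.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_newick <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' @rdname write_newick
#' @param D a square distance matrix with ids as dimnames.
#' @export
write_phylip_matrix <- function(D, file) {
  D <- unclass(D)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  invisible(file)
}
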