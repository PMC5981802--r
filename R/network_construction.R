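# Single-subject similarity network construction. The edge statistic is a
# scaled two-sample energy distance between the per-vertex feature multisets
# of two regions, min-max normalised over the subject's off-diagonal entries
# and mapped through exp(-x) to a similarity in (0, 1].

#' Split a vertex table into per-region feature sets
#'
#' Groups the vertices of one subject by atlas region, returning one numeric
#' n_r x d matrix per region in atlas-index order.
#'
#' @param table A `vertex_table` from [read_vertex_features()].
#' @param parcellation A `parcellation` from [read_parcellation()].
#' @param feature_names Feature columns to use (default all six).
#' @return Named list of matrices (one per region, atlas order).
#' @export
region_feature_sets <- function(table, parcellation,
                                feature_names = surface_features()) {
  missing_cols <- setdiff(feature_names, names(table))
  if (length(missing_cols) > 0L)
    stop("column not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(table$region_label), parcellation$region_label)
  if (length(unknown) > 0L)
    stop("vertex labels absent from parcellation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  absent <- setdiff(parcellation$region_label, table$region_label)
  if (length(absent) > 0L)
    stop("regions with no vertices: ", paste(absent, collapse = ", "),
         call. = FALSE)
  feat <- as.matrix(table[, feature_names, drop = FALSE])
  if (!all(is.finite(feat))) stop("non-finite feature values", call. = FALSE)
  lapply(setNames(parcellation$region_label, parcellation$region_label),
         function(lab) {
           m <- feat[table$region_label == lab, , drop = FALSE]
           rownames(m) <- NULL
           m
         })
}

#' Z-score features pooled over a subject's vertices
#'
#' Each feature column is centred and scaled by the mean and standard
#' deviation pooled over every vertex of the subject (all regions together),
#' so that millimetre-, square-millimetre- and dimensionless-scaled features
#' contribute comparably to the Euclidean norm.
#'
#' @param subject_regions List of per-region feature matrices
#'   ([region_feature_sets()]).
#' @return List of the same shape with standardized columns.
#' @export
standardize_features <- function(subject_regions) {
  pooled <- do.call(rbind, subject_regions)
  mu <- colMeans(pooled)
  sigma <- apply(pooled, 2L, sd)
  zero <- which(sigma == 0 | !is.finite(sigma))
  if (length(zero) > 0L)
    stop("zero-variance feature: ",
         paste(colnames(pooled)[zero], collapse = ", "), call. = FALSE)
  lapply(subject_regions, function(m)
    sweep(sweep(m, 2L, mu, "-"), 2L, sigma, "/"))
}

# Sums of pairwise Euclidean norms, computed from coordinate differences
# (stats::dist) rather than the Gram expansion: the latter loses enough
# precision to near-duplicate vertex pairs to spoil 1e-10 agreement with a
# naive double loop. Summation order is fixed, so results are reproducible.

# Sum over unordered within-set pairs {i < j}.
.sum_within_norms <- function(A) sum(stats::dist(A))

# Sum over the n1 x n2 cross pairs (each once).
.sum_cross_norms <- function(A, B) {
  sum(stats::dist(rbind(A, B))) - .sum_within_norms(A) - .sum_within_norms(B)
}

#' Combined (energy) Euclidean distance between two regions
#'
#' For regions A (n1 vertices) and B (n2 vertices) with d-dimensional
#' feature vectors, computes
#' \deqn{e(A,B) = \frac{n_1 n_2}{n_1+n_2}\Big(\frac{2}{n_1 n_2}\sum_{ij}
#'   \|a_i-b_j\| - \frac{1}{n_1^2}\sum_{ij}\|a_i-a_j\| -
#'   \frac{1}{n_2^2}\sum_{ij}\|b_i-b_j\|\Big)}
#' a scaled two-sample energy distance: non-negative, symmetric, and zero
#' exactly when the two empirical feature distributions coincide.
#'
#' @param A,B Numeric matrices (vertices x features) with equal column count.
#' @return A non-negative scalar (values within -1e-10 of zero are clipped).
#' @export
combined_euclidean_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("feature dimension mismatch", call. = FALSE)
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 1L || n2 < 1L) stop("empty region", call. = FALSE)
  between <- .sum_cross_norms(A, B)
  within_a <- 2 * .sum_within_norms(A)   # ordered within-pair sum
  within_b <- 2 * .sum_within_norms(B)
  e <- n1 * n2 / (n1 + n2) *
    (2 / (n1 * n2) * between - within_a / n1^2 - within_b / n2^2)
  if (e < -1e-10)
    stop("energy distance negative beyond rounding: ", e, call. = FALSE)
  max(e, 0)
}

#' All-pairs regional dissimilarity matrix
#'
#' Applies [combined_euclidean_distance()] to every unordered pair of a
#' subject's regions. The result is symmetric with a zero diagonal and is
#' invariant to vertex order within regions.
#'
#' @param subject_regions List of per-region feature matrices in atlas order.
#' @return V x V symmetric numeric matrix with region labels as dimnames.
#' @export
pairwise_dissimilarity <- function(subject_regions) {
  V <- length(subject_regions)
  if (V < 2L) stop("need at least two regions", call. = FALSE)
  d <- unique(vapply(subject_regions, ncol, integer(1L)))
  if (length(d) != 1L) stop("feature dimension mismatch", call. = FALSE)
  ns <- vapply(subject_regions, nrow, integer(1L))
  if (any(ns < 1L)) stop("empty region", call. = FALSE)
  # within-region sums depend on one region only; compute each once
  within_half <- vapply(subject_regions, .sum_within_norms, numeric(1L))
  D <- matrix(0, V, V,
              dimnames = list(names(subject_regions), names(subject_regions)))
  for (i in seq_len(V - 1L)) {
    for (j in (i + 1L):V) {
      n1 <- ns[i]; n2 <- ns[j]
      between <- sum(stats::dist(rbind(subject_regions[[i]],
                                       subject_regions[[j]]))) -
        within_half[i] - within_half[j]
      e <- n1 * n2 / (n1 + n2) *
        (2 / (n1 * n2) * between -
           2 * within_half[i] / n1^2 - 2 * within_half[j] / n2^2)
      if (e < -1e-10)
        stop("energy distance negative beyond rounding: ", e, call. = FALSE)
      e <- max(e, 0)
      D[i, j] <- e
      D[j, i] <- e
    }
  }
  D
}

#' Min-max normalise a dissimilarity matrix
#'
#' Rescales the off-diagonal entries affinely so their minimum is 0 and
#' maximum 1, removing per-subject range differences. The minimum and
#' maximum are taken over off-diagonal (upper-triangle) entries only; the
#' structural zero diagonal is left untouched.
#'
#' @param D Symmetric non-negative dissimilarity matrix, zero diagonal.
#' @return Matrix of the same shape with off-diagonal range exactly [0, 1].
#' @export
minmax_normalize <- function(D) {
  off <- D[upper.tri(D)]
  e_min <- min(off); e_max <- max(off)
  if (e_max == e_min)
    stop("degenerate dissimilarity matrix: all off-diagonal values equal",
         call. = FALSE)
  Dn <- (D - e_min) / (e_max - e_min)
  diag(Dn) <- 0
  attr(Dn, "e_min") <- e_min
  attr(Dn, "e_max") <- e_max
  Dn
}

#' Convert normalised dissimilarity to similarity
#'
#' Maps each normalised off-diagonal dissimilarity e through c = exp(-e),
#' a strictly decreasing transform, and pins the diagonal to 1 (a region is
#' identical to itself). Off-diagonal similarities therefore lie in
#' [exp(-1), 1].
#'
#' @param Dn Min-max normalised dissimilarity matrix ([minmax_normalize()]).
#' @return Similarity matrix; diagonal 1, off-diagonal in [exp(-1), 1].
#' @export
to_similarity <- function(Dn) {
  off <- Dn[upper.tri(Dn)]
  if (any(off < 0 | off > 1))
    stop("normalised dissimilarities must lie in [0, 1]", call. = FALSE)
  C <- exp(-Dn)
  diag(C) <- 1
  C
}

#' Build one subject's morphological similarity network
#'
#' Full construction pipeline: optional pooled z-scoring of features,
#' all-pairs energy distance, per-subject min-max normalisation, and the
#' exponential similarity map. Provenance (features used, standardization
#' flag, method id, observed distance range) is attached as attributes.
#'
#' @param table A `vertex_table` for one subject.
#' @param parcellation A `parcellation`; default the bundled 68-region
#'   Desikan-Killiany atlas.
#' @param feature_names Features to use; default all six.
#' @param standardize Z-score features before the distance? Default `TRUE`
#'   when more than one feature is used (mixed units would otherwise let the
#'   largest-scaled feature dominate the norm), `FALSE` for one feature.
#' @return A `similarity_matrix`: V x V symmetric numeric matrix, diagonal 1,
#'   with `provenance` attribute.
#' @export
build_individual_network <- function(table,
                                     parcellation = dk_parcellation(),
                                     feature_names = surface_features(),
                                     standardize = length(feature_names) > 1L) {
  regions <- region_feature_sets(table, parcellation, feature_names)
  if (standardize) regions <- standardize_features(regions)
  D <- pairwise_dissimilarity(regions)
  Dn <- minmax_normalize(D)
  C <- to_similarity(Dn)
  structure(C, class = c("similarity_matrix", "matrix", "array"),
            provenance = list(method = "energy",
                              features = feature_names,
                              standardized = standardize,
                              e_min = attr(Dn, "e_min"),
                              e_max = attr(Dn, "e_max")))
}
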