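# Binary graph analysis of similarity networks: sparsity thresholding,
# small-world indices against null ensembles, betweenness hubs.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Binarise a similarity matrix at a given sparsity
#'
#' Retains the `round(S * p)` strongest of the `p = V(V-1)/2` possible
#' edges, where sparsity S is the fraction of edges kept. Ties at the cutoff
#' weight are broken by fixed lexicographic (row, column) order, so the
#' result is deterministic.
#'
#' @param W Symmetric weight matrix (e.g. a `similarity_matrix`).
#' @param S Sparsity in (0, 1]: fraction of strongest edges retained.
#' @param rank_abs Rank edges by absolute weight (for signed similarity
#'   measures)? Default `FALSE`.
#' @return A `binary_graph`: list with `adjacency` (0/1 symmetric matrix,
#'   zero diagonal), `sparsity`, and `n_edges`.
#' @export
threshold_by_sparsity <- function(W, S, rank_abs = FALSE) {
  if (!is.numeric(S) || length(S) != 1L || S <= 0 || S > 1)
    stop("sparsity S must lie in (0, 1]", call. = FALSE)
  V <- nrow(W)
  p <- V * (V - 1L) / 2L
  k <- round(S * p)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  # row-major lexicographic (i, j) order for deterministic tie-breaks
  lex <- order(ut[, 1L], ut[, 2L])
  ut <- ut[lex, , drop = FALSE]
  w <- W[ut]
  if (rank_abs) w <- abs(w)
  keep <- order(-w)[seq_len(k)]
  A <- matrix(0L, V, V, dimnames = dimnames(W))
  sel <- ut[keep, , drop = FALSE]
  A[sel] <- 1L
  A[sel[, c(2L, 1L), drop = FALSE]] <- 1L
  structure(list(adjacency = A, sparsity = S, n_edges = k),
            class = "binary_graph")
}

#' Construct a binary_graph directly from an adjacency matrix
#'
#' @param A 0/1 symmetric matrix with zero diagonal.
#' @return A `binary_graph`.
#' @export
binary_graph <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  if (any(A != t(A))) stop("adjacency must be symmetric", call. = FALSE)
  diag(A) <- 0L
  if (is.null(rownames(A))) {
    labs <- sprintf("n%02d", seq_len(nrow(A)))
    dimnames(A) <- list(labs, labs)
  }
  k <- sum(A[upper.tri(A)])
  structure(list(adjacency = A, sparsity = k / (nrow(A) * (nrow(A) - 1) / 2),
                 n_edges = k), class = "binary_graph")
}

.as_igraph <- function(G) {
  igraph::graph_from_adjacency_matrix(G$adjacency, mode = "undirected",
                                      diag = FALSE)
}

.from_igraph <- function(g, template) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  dimnames(A) <- dimnames(template$adjacency)
  binary_graph(A)
}

#' Clustering coefficient (Watts-Strogatz)
#'
#' Per-node ratio of realised to possible triangles; nodes of degree < 2
#' contribute 0. Cp is the unweighted mean over all nodes.
#'
#' @param G A `binary_graph`.
#' @return List with `nodal` (per-node values) and `Cp` (mean).
#' @export
clustering_coefficient <- function(G) {
  g <- .as_igraph(G)
  nodal <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(nodal) <- rownames(G$adjacency)
  list(nodal = nodal, Cp = mean(nodal))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all reachable ordered node pairs;
#' unreachable pairs are excluded and counted.
#'
#' @param G A `binary_graph`.
#' @return List with `Lp` and `n_unreachable` (ordered pairs excluded).
#' @export
characteristic_path_length <- function(G) {
  if (G$n_edges == 0L) stop("graph has no edges", call. = FALSE)
  d <- igraph::distances(.as_igraph(G))
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  list(Lp = mean(off[finite]), n_unreachable = sum(!finite))
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomises a graph by repeated double-edge swaps, preserving every
#' node's degree exactly while destroying higher-order structure such as
#' clustering. Used to build matched null ensembles.
#'
#' @param G A `binary_graph`.
#' @param n_swaps Number of attempted swaps; default `10 * n_edges`.
#' @param seed Integer seed for reproducibility.
#' @return A rewired `binary_graph` with identical degree sequence.
#' @export
rewire_degree_preserving <- function(G, n_swaps = 10L * G$n_edges, seed = 1L) {
  g <- .as_igraph(G)
  g2 <- .with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps)))
  .from_igraph(g2, G)
}

# Erdos-Renyi G(n, m) null with the same node and edge counts.
.er_null <- function(G, seed) {
  g2 <- .with_seed(seed, igraph::sample_gnm(nrow(G$adjacency), G$n_edges))
  .from_igraph(g2, G)
}

#' Small-world indices against a null ensemble
#'
#' Computes gamma = Cp / mean(Cp_null), lambda = Lp / mean(Lp_null) and
#' sigma = gamma / lambda, where the null ensemble consists of `n_null`
#' graphs with the same number of nodes and edges. The default null
#' additionally preserves the degree sequence (Maslov-Sneppen rewiring);
#' an Erdos-Renyi null matching only node/edge counts is available.
#' gamma > 1 with lambda close to 1 (hence sigma > 1) indicates small-world
#' organisation.
#'
#' @param G A `binary_graph`.
#' @param n_null Number of null graphs (default 100).
#' @param n_swaps Rewiring attempts per null graph (default `10 * n_edges`).
#' @param seed Integer seed.
#' @param null Null family: `"rewire"` (degree-preserving, default) or
#'   `"er"`.
#' @return List with `Cp`, `Lp`, `gamma`, `lambda_sw`, `sigma_sw`, `n_null`,
#'   and `null_summaries` (means/sds of the null Cp and Lp).
#' @export
small_world <- function(G, n_null = 100L, n_swaps = 10L * G$n_edges,
                        seed = 1L, null = c("rewire", "er")) {
  null <- match.arg(null)
  if (n_null < 1L) stop("n_null must be >= 1", call. = FALSE)
  Cp <- clustering_coefficient(G)$Cp
  Lp <- characteristic_path_length(G)$Lp
  cp_null <- numeric(n_null)
  lp_null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    Gb <- if (null == "rewire")
      rewire_degree_preserving(G, n_swaps, seed = seed + b)
    else .er_null(G, seed = seed + b)
    cp_null[b] <- clustering_coefficient(Gb)$Cp
    lp_null[b] <- characteristic_path_length(Gb)$Lp
  }
  gamma <- Cp / mean(cp_null)
  lambda_sw <- Lp / mean(lp_null)
  list(Cp = Cp, Lp = Lp, gamma = gamma, lambda_sw = lambda_sw,
       sigma_sw = gamma / lambda_sw, n_null = n_null,
       null_summaries = list(Cp_null_mean = mean(cp_null),
                             Cp_null_sd = sd(cp_null),
                             Lp_null_mean = mean(lp_null),
                             Lp_null_sd = sd(lp_null)))
}

#' Betweenness centrality and hub detection
#'
#' Exact betweenness (shortest paths through a node, equal-length paths
#' split evenly) per node; hubs are nodes whose betweenness exceeds the
#' network mean plus one population standard deviation.
#'
#' @param G A `binary_graph`.
#' @return List with `bc` (named per-node values) and `hubs` (node names).
#' @export
betweenness_hubs <- function(G) {
  g <- .as_igraph(G)
  bc <- igraph::betweenness(g, directed = FALSE)
  names(bc) <- rownames(G$adjacency)
  sd_pop <- sqrt(mean((bc - mean(bc))^2))
  list(bc = bc, hubs = names(bc)[bc > mean(bc) + sd_pop])
}

#' Evaluate one graph property of a thresholded network
#'
#' Convenience accessor used by the reliability and report layers.
#'
#' @param G A `binary_graph`.
#' @param property `"Cp"`, `"Lp"`, or `"BC"` (per-node betweenness vector).
#' @return Scalar for Cp/Lp; named numeric vector for BC.
#' @export
graph_property <- function(G, property = c("Cp", "Lp", "BC")) {
  property <- match.arg(property)
  switch(property,
         Cp = clustering_coefficient(G)$Cp,
         Lp = characteristic_path_length(G)$Lp,
         BC = betweenness_hubs(G)$bc)
}
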