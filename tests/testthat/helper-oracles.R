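# Independent brute-force oracles and small fixture builders used across
# the test files. Oracles deliberately share no code with the package
# implementation.

# Energy distance by literal double loops over vertex pairs.
naive_energy_distance <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  sab <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2))
    sab <- sab + sqrt(sum((A[i, ] - B[j, ])^2))
  saa <- 0
  for (i in seq_len(n1)) for (j in seq_len(n1))
    saa <- saa + sqrt(sum((A[i, ] - A[j, ])^2))
  sbb <- 0
  for (i in seq_len(n2)) for (j in seq_len(n2))
    sbb <- sbb + sqrt(sum((B[i, ] - B[j, ])^2))
  n1 * n2 / (n1 + n2) *
    (2 / (n1 * n2) * sab - saa / n1^2 - sbb / n2^2)
}

# Watts-Strogatz clustering by enumerating all node triples.
naive_clustering <- function(A) {
  V <- nrow(A)
  nodal <- numeric(V)
  for (v in seq_len(V)) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) { nodal[v] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && A[nb[a], nb[b]] == 1) links <- links + 1
    nodal[v] <- 2 * links / (k * (k - 1))
  }
  nodal
}

# All-pairs shortest path lengths by breadth-first search.
naive_distances <- function(A) {
  V <- nrow(A)
  D <- matrix(Inf, V, V); diag(D) <- 0
  for (s in seq_len(V)) {
    frontier <- s; depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1))))
      nxt <- nxt[D[s, nxt] == Inf & nxt != s]
      D[s, nxt] <- depth
      frontier <- nxt
    }
  }
  D
}

# Betweenness by exhaustive enumeration of all shortest paths (small V).
naive_betweenness <- function(A) {
  V <- nrow(A)
  D <- naive_distances(A)
  bc <- numeric(V)
  all_shortest <- function(s, t) {
    # enumerate vertex sequences s..t of length D[s,t] stepping down distance
    paths <- list()
    grow <- function(path) {
      v <- path[length(path)]
      if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (u in which(A[v, ] == 1))
        if (is.finite(D[u, t]) && D[u, t] == D[v, t] - 1) grow(c(path, u))
    }
    if (is.finite(D[s, t])) grow(s)
    paths
  }
  for (s in seq_len(V - 1)) for (t in (s + 1):V) {
    ps <- all_shortest(s, t)
    if (length(ps) == 0) next
    for (p in ps) {
      interior <- setdiff(p, c(s, t))
      for (v in interior) bc[v] <- bc[v] + 1 / length(ps)
    }
  }
  bc
}

# Soft-threshold lasso solution for orthonormal designs.
soft_threshold_fit <- function(X, y, lambda) {
  beta <- drop(crossprod(X, y))
  sign(beta) * pmax(abs(beta) - lambda, 0)
}

# Toy parcellation with V regions, alternating hemispheres.
toy_parcellation <- function(V, labels = sprintf("region_%02d", seq_len(V) - 1)) {
  structure(data.frame(region_label = labels,
                       hemisphere = rep_len(c("L", "R"), V),
                       index = seq_len(V) - 1L,
                       region_name = labels,
                       stringsAsFactors = FALSE),
            class = c("parcellation", "data.frame"), V = V)
}

# Parcellation matching a cohort_spec's labels.
spec_parcellation <- function(spec) toy_parcellation(spec$V, spec$region_labels)

# A deterministic random binary graph as adjacency matrix.
random_adjacency <- function(V, p, seed) {
  set.seed(seed)
  A <- matrix(0L, V, V)
  A[upper.tri(A)] <- as.integer(runif(V * (V - 1) / 2) < p)
  A + t(A)
}
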