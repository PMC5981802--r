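# Energy-distance network construction: closed forms, brute-force oracle
# equivalence, invariances, and the normalisation/similarity maps.

test_that("combined Euclidean distance matches closed forms", {
  # identical multisets give zero
  A <- matrix(c(0, 2, 1, 3), 2)
  expect_equal(combined_euclidean_distance(A, A), 0)

  # singletons reduce to the plain Euclidean distance
  expect_equal(combined_euclidean_distance(matrix(c(0, 0), 1),
                                           matrix(c(3, 4), 1)), 5)

  # 1-D worked case: A = {0, 2}, B = {1} -> (2/3) * (2 - 1 - 0) = 2/3
  expect_equal(combined_euclidean_distance(matrix(c(0, 2)), matrix(1)),
               2 / 3)

  expect_error(combined_euclidean_distance(matrix(1, 1, 2), matrix(1, 1, 3)),
               "dimension mismatch")
  expect_error(combined_euclidean_distance(matrix(0, 0, 1), matrix(1)),
               "empty region")
})

test_that("energy distance equals the naive double-loop oracle", {
  set.seed(11)
  for (rep in 1:25) {
    d <- sample(1:6, 1)
    A <- matrix(rnorm(sample(2:30, 1) * d), ncol = d)
    B <- matrix(rnorm(sample(2:30, 1) * d), ncol = d)
    expect_equal(combined_euclidean_distance(A, B),
                 naive_energy_distance(A, B), tolerance = 1e-10)
  }
})

test_that("energy distance is symmetric, translation-invariant, scales linearly, non-negative", {
  set.seed(12)
  for (rep in 1:20) {
    d <- sample(1:4, 1)
    A <- matrix(rnorm(sample(2:15, 1) * d), ncol = d)
    B <- matrix(rnorm(sample(2:15, 1) * d), ncol = d)
    e <- combined_euclidean_distance(A, B)
    expect_gte(e, 0)
    expect_equal(combined_euclidean_distance(B, A), e)
    shift <- matrix(rnorm(d), nrow(A), d, byrow = TRUE)
    expect_equal(combined_euclidean_distance(
      A + shift[rep(1, nrow(A)), , drop = FALSE],
      B + shift[rep(1, nrow(B)), , drop = FALSE]), e, tolerance = 1e-9)
    cc <- runif(1, 0.5, 3)
    expect_equal(combined_euclidean_distance(cc * A, cc * B), cc * e,
                 tolerance = 1e-9)
  }
})

test_that("standardization pools moments over the subject and is idempotent", {
  regions <- list(r1 = matrix(1), r2 = matrix(2), r3 = matrix(3))
  z <- standardize_features(regions)
  pooled <- do.call(rbind, z)
  expect_lt(abs(mean(pooled)), 1e-10)
  expect_equal(sd(pooled), 1, tolerance = 1e-10)
  z2 <- standardize_features(z)
  expect_equal(z2, z, tolerance = 1e-10)

  spec <- cohort_spec(V = 10, vertex_count_range = c(5, 15), seed = 8)
  tab <- generate_subject(spec, seed = 2)
  r <- region_feature_sets(tab, spec_parcellation(spec))
  zr <- standardize_features(r)
  pooled <- do.call(rbind, zr)
  expect_true(all(abs(colMeans(pooled)) < 1e-10))
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 6), tolerance = 1e-10)

  const <- list(a = matrix(c(1, 1)), b = matrix(c(1, 1)))
  expect_error(standardize_features(const), "zero-variance")
})

test_that("pairwise dissimilarity matches per-pair evaluation and handles degenerate input", {
  spec <- cohort_spec(V = 5, vertex_count_range = c(3, 12), seed = 13)
  tab <- generate_subject(spec, seed = 4)
  r <- region_feature_sets(tab, spec_parcellation(spec))
  D <- pairwise_dissimilarity(r)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], naive_energy_distance(r[[i]], r[[j]]),
                 tolerance = 1e-10)

  # identical regions give a zero matrix
  m <- matrix(rnorm(8), 4)
  expect_equal(unname(pairwise_dissimilarity(list(a = m, b = m))),
               matrix(0, 2, 2))

  # singleton regions reduce to plain pairwise Euclidean distances
  pts <- list(a = matrix(c(0, 0), 1), b = matrix(c(3, 4), 1),
              c = matrix(c(0, 1), 1))
  D3 <- pairwise_dissimilarity(pts)
  expect_equal(D3["a", "b"], 5)
  expect_equal(D3["a", "c"], 1)
})

test_that("min-max normalisation maps off-diagonal range to [0,1], preserving order", {
  D <- matrix(0, 3, 3)
  D[upper.tri(D)] <- c(1, 2, 3)
  D <- D + t(D)
  Dn <- minmax_normalize(D)
  expect_equal(sort(Dn[upper.tri(Dn)]), c(0, 0.5, 1))
  expect_equal(unname(diag(Dn)), rep(0, 3))

  set.seed(14)
  M <- matrix(0, 8, 8)
  M[upper.tri(M)] <- runif(28, 1, 9)
  M <- M + t(M)
  Mn <- minmax_normalize(M)
  off <- Mn[upper.tri(Mn)]
  expect_equal(range(off), c(0, 1))
  expect_equal(cor(off, M[upper.tri(M)], method = "spearman"), 1)

  flat <- matrix(1, 3, 3); diag(flat) <- 0
  expect_error(minmax_normalize(flat), "degenerate")
})

test_that("similarity map is exp(-e) with pinned diagonal and bounded range", {
  Dn <- matrix(0, 3, 3)
  Dn[upper.tri(Dn)] <- c(0, 0.5, 1)
  Dn <- Dn + t(Dn)
  C <- to_similarity(Dn)
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_equal(sort(C[upper.tri(C)]), c(exp(-1), exp(-0.5), 1))

  bad <- Dn; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(to_similarity(bad), "\\[0, 1\\]")
})

test_that("full construction is symmetric, bounded, feature-sensitive, and vertex-order invariant", {
  spec <- cohort_spec(V = 12, vertex_count_range = c(8, 20), seed = 21)
  parc <- spec_parcellation(spec)
  tab <- generate_subject(spec, seed = 5)
  W <- build_individual_network(tab, parc)
  expect_equal(dim(W), c(12L, 12L))
  expect_equal(unname(W), unname(t(W)))
  off <- W[upper.tri(W)]
  expect_true(all(off >= exp(-1) - 1e-12 & off <= 1))
  expect_equal(unname(diag(W)), rep(1, 12))
  expect_true(attr(W, "provenance")$standardized)

  W1 <- build_individual_network(tab, parc, feature_names = "thickness")
  expect_gt(max(abs(W - W1)), 1e-6)
  expect_false(attr(W1, "provenance")$standardized)

  # permuting vertex rows leaves the network bit-identical
  perm <- tab[sample(nrow(tab)), ]
  Wp <- build_individual_network(perm, parc)
  expect_identical(unname(as.matrix(W)), unname(as.matrix(Wp)))

  # similarity rank order is exactly the reverse of dissimilarity order
  r <- standardize_features(region_feature_sets(tab, parc))
  D <- pairwise_dissimilarity(r)
  expect_equal(cor(W[upper.tri(W)], D[upper.tri(D)], method = "spearman"),
               -1)
})

test_that("doubling vertex samples stabilises the energy distance", {
  # subsampling sanity: e(A,B) computed from n and 2n draws of the same
  # distributions should agree more closely as n grows (loose bound)
  set.seed(30)
  draw <- function(n, mu) matrix(rnorm(n * 2, mean = mu), n, 2)
  e_inf <- combined_euclidean_distance(draw(3000, 0), draw(3000, 0.8))
  err <- sapply(c(50, 400), function(n) {
    mean(replicate(8, abs(combined_euclidean_distance(
      draw(n, 0), draw(n, 0.8)) - e_inf)))
  })
  expect_lt(err[2], err[1])
})
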