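# Five alternative single-feature (cortical thickness) edge-similarity
# formulas from the individual-morphological-network literature, exposed so
# the same thresholding/classification pipeline can run on each.

#' Summarise one region's thickness distribution
#'
#' @param values Numeric vector of per-vertex thickness values.
#' @return A `region_summary` list: `values`, `T` (mean), `sd` (sample
#'   standard deviation), `mad` (mean absolute deviation from the mean),
#'   `n`.
#' @export
region_summary <- function(values) {
  if (length(values) < 1L || !all(is.finite(values)))
    stop("region values must be non-empty and finite", call. = FALSE)
  Tm <- mean(values)
  structure(list(values = values, T = Tm,
                 sd = if (length(values) > 1L) sd(values) else 0,
                 mad = mean(abs(values - Tm)), n = length(values)),
            class = "region_summary")
}

# Gaussian KDE evaluated on a fixed grid; Silverman's rule bandwidth.
.kde_on_grid <- function(values, grid, bandwidth) {
  f <- vapply(grid, function(x) mean(dnorm(x, mean = values,
                                           sd = bandwidth)), numeric(1L))
  pmax(f, 1e-12)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)

#' Distribution-based similarity (symmetric KL of thickness densities)
#'
#' Estimates each region's thickness density by Gaussian kernel density
#' estimation (Silverman bandwidth) on a shared grid, computes the
#' symmetric Kullback-Leibler divergence
#' `KL(i,j) = integral i(x) log(i/j) + j(x) log(j/i) dx`, and maps it to a
#' similarity `c = exp(-KL)`. Densities are floored at 1e-12 before logs.
#'
#' @param i,j `region_summary` objects.
#' @param bandwidth Optional common KDE bandwidth; default Silverman's rule
#'   per region.
#' @param grid_n Number of shared grid points (default 512), spanning the
#'   pooled range plus three bandwidths on each side.
#' @return Similarity in (0, 1], with the symmetric KL attached as
#'   attribute `"kl"`.
#' @export
kong_similarity <- function(i, j, bandwidth = NULL, grid_n = 512L) {
  if (i$sd == 0 || j$sd == 0)
    stop("zero-variance region: density estimate undefined", call. = FALSE)
  bw_i <- if (is.null(bandwidth)) stats::bw.nrd0(i$values) else bandwidth
  bw_j <- if (is.null(bandwidth)) stats::bw.nrd0(j$values) else bandwidth
  pad <- 3 * max(bw_i, bw_j)
  rng <- range(c(i$values, j$values))
  grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = grid_n)
  fi <- .kde_on_grid(i$values, grid, bw_i)
  fj <- .kde_on_grid(j$values, grid, bw_j)
  kl <- .trapz(grid, fi * log(fi / fj) + fj * log(fj / fi))
  structure(exp(-kl), kl = kl)
}

#' Mean-thickness z-score similarity
#'
#' `Z(i,j) = (T(i) - T(j)) / sd_j`; the edge value is the average
#' `(Z(i,j) + Z(j,i)) / 2`. The two Z terms exchange under swapping (i, j),
#' so the edge value is symmetric, but it is signed and may be negative;
#' downstream sparsity ranking uses its magnitude.
#'
#' @param i,j `region_summary` objects with positive standard deviations.
#' @return Signed similarity value.
#' @export
kim_similarity <- function(i, j) {
  if (i$sd == 0 || j$sd == 0)
    stop("zero standard deviation in region", call. = FALSE)
  z_ij <- (i$T - j$T) / j$sd
  z_ji <- (j$T - i$T) / i$sd
  (z_ij + z_ji) / 2
}

#' Gaussian similarity of mean thickness, spread-scaled
#'
#' `d(i,j) = (T(i) - T(j))^2`, `sigma = sd_i + sd_j`,
#' `c = exp(-d / (2 sigma^2))`.
#'
#' @param i,j `region_summary` objects; `sd_i + sd_j > 0`.
#' @return Similarity in (0, 1].
#' @export
wee_similarity <- function(i, j) {
  s <- i$sd + j$sd
  if (s == 0) stop("both regions have zero spread", call. = FALSE)
  exp(-(i$T - j$T)^2 / (2 * s^2))
}

#' Gaussian similarity of mean thickness with free scale
#'
#' `d(i,j) = (T(i) - T(j))^2`, `c = exp(-d / eta)`, with the scale `eta`
#' an input parameter.
#'
#' @param i,j `region_summary` objects.
#' @param eta Positive scale parameter.
#' @return Similarity in (0, 1].
#' @export
dai_similarity <- function(i, j, eta) {
  if (!is.numeric(eta) || eta <= 0) stop("eta must be > 0", call. = FALSE)
  exp(-(i$T - j$T)^2 / eta)
}

#' Dispersion-ratio and squared-mean-difference similarity pair
#'
#' `c_precision(i,j)` is the ratio of the two regions' mean absolute
#' deviations (so `c_precision(j,i) = 1/c_precision(i,j)`);
#' `c_rough(i,j) = |T(i) - T(j)|^2` is a symmetric distance-like statistic.
#'
#' @param i,j `region_summary` objects.
#' @return List with `c_precision` (`NA` with attribute `flagged = TRUE`
#'   when region j has zero dispersion) and `c_rough`.
#' @export
zheng_similarity <- function(i, j) {
  cp <- if (j$mad == 0) structure(NA_real_, flagged = TRUE)
        else i$mad / j$mad
  list(c_precision = cp, c_rough = (i$T - j$T)^2)
}

#' Build a subject's network with a chosen edge-similarity method
#'
#' Runs any of the six construction methods on one subject's thickness
#' (or other single-feature) data: `"proposed"` is the multivariate energy
#' construction restricted to the chosen feature; the others are the
#' single-feature formulas above applied to every region pair. For
#' `"zheng"`, the default edge weight is the min-max-normalised `c_rough`
#' passed through the exponential similarity map, with the `c_precision`
#' matrix attached as attribute `"c_precision"`. For `"kim"` the matrix is
#' signed (diagonal 0); rank edges by magnitude when thresholding.
#'
#' @param table A `vertex_table`.
#' @param parcellation A `parcellation` (default bundled 68-region atlas).
#' @param method One of `"proposed"`, `"kong"`, `"kim"`, `"wee"`, `"dai"`,
#'   `"zheng"`.
#' @param feature Feature column to use (default `"thickness"`).
#' @param eta Scale for `"dai"`; default the median of the squared
#'   mean-thickness differences over all region pairs (self-tuning).
#' @return A `similarity_matrix` with method provenance.
#' @export
build_network_with_method <- function(table,
                                      parcellation = dk_parcellation(),
                                      method = c("proposed", "kong", "kim",
                                                 "wee", "dai", "zheng"),
                                      feature = "thickness", eta = NULL) {
  method <- match.arg(method)
  if (method == "proposed")
    return(build_individual_network(table, parcellation,
                                    feature_names = feature,
                                    standardize = FALSE))
  regions <- region_feature_sets(table, parcellation, feature)
  summ <- lapply(regions, function(m) region_summary(m[, 1L]))
  V <- length(summ)
  labs <- names(summ)
  C <- matrix(0, V, V, dimnames = list(labs, labs))
  aux <- NULL
  if (method == "dai" && is.null(eta)) {
    Tm <- vapply(summ, `[[`, numeric(1L), "T")
    d2 <- outer(Tm, Tm, "-")^2
    eta <- stats::median(d2[upper.tri(d2)])
    if (!is.finite(eta) || eta <= 0)
      stop("self-tuned eta degenerate; supply eta explicitly", call. = FALSE)
  }
  if (method == "zheng")
    aux <- matrix(NA_real_, V, V, dimnames = list(labs, labs))
  for (a in seq_len(V - 1L)) for (b in (a + 1L):V) {
    val <- switch(method,
      kong = as.numeric(kong_similarity(summ[[a]], summ[[b]])),
      kim = kim_similarity(summ[[a]], summ[[b]]),
      wee = wee_similarity(summ[[a]], summ[[b]]),
      dai = dai_similarity(summ[[a]], summ[[b]], eta),
      zheng = {
        z <- zheng_similarity(summ[[a]], summ[[b]])
        aux[a, b] <- as.numeric(z$c_precision)
        aux[b, a] <- as.numeric(zheng_similarity(summ[[b]],
                                                 summ[[a]])$c_precision)
        z$c_rough
      })
    C[a, b] <- val
    C[b, a] <- val
  }
  if (method == "zheng") {
    C <- to_similarity(minmax_normalize(C))
  } else if (method != "kim") {
    diag(C) <- 1
  }
  structure(C, class = c("similarity_matrix", "matrix", "array"),
            provenance = c(list(method = method, features = feature,
                                standardized = FALSE),
                           if (method == "dai") list(eta = eta)),
            c_precision = aux)
}
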