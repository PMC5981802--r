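# Test-retest reliability of graph properties via the one-way
# random-effects intraclass correlation (single-rater, ICC(1,1)):
# ICC = sigma2_between / (sigma2_between + sigma2_within).

#' One-way random-effects ICC
#'
#' Estimates the intraclass correlation of a repeated measurement from the
#' one-way ANOVA decomposition over subjects: with n subjects measured in k
#' sessions, `sigma2_within = MSW`, `sigma2_between = (MSB - MSW)/k`, and
#' `icc = (MSB - MSW) / (MSB + (k-1) MSW)`. Values above 0.75 are
#' conventionally rated excellent, 0.59-0.75 good. Negative estimates
#' (sampling noise when the true between-subject variance is near zero) are
#' reported as computed and flagged, not truncated.
#'
#' @param M Numeric matrix, subjects x sessions (no missing cells).
#' @return List with `icc`, `sigma2_between`, `sigma2_within`, `f_stat`,
#'   `p_value`, `negative` flag, and `quality_band`
#'   (`"excellent"`/`"good"`/`"other"`).
#' @export
icc_one_way <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 sessions",
                             call. = FALSE)
  if (anyNA(M)) stop("missing cells in repeated measures", call. = FALSE)
  grand <- mean(M)
  if (sum((M - grand)^2) == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)
  row_means <- rowMeans(M)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((M - row_means)^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f <- msb / msw
  p <- if (msw == 0) 0 else pf(f, n - 1, n * (k - 1), lower.tail = FALSE)
  band <- if (icc > 0.75) "excellent" else if (icc >= 0.59) "good" else "other"
  list(icc = icc,
       sigma2_between = (msb - msw) / k,
       sigma2_within = msw,
       f_stat = f, p_value = p,
       negative = icc < 0,
       quality_band = band)
}

#' ICC of a graph property across a sparsity sweep
#'
#' For paired test-retest cohorts (one similarity matrix per subject per
#' session), thresholds every network at each sparsity, evaluates the chosen
#' property, and estimates its ICC across subjects. For per-node betweenness
#' the node-wise ICCs are averaged to one value per sparsity (the per-node
#' table is returned alongside).
#'
#' @param session1,session2 Lists of `similarity_matrix` objects, paired by
#'   position (same subjects, same order).
#' @param property `"Cp"`, `"Lp"`, or `"BC"`.
#' @param sparsities Numeric vector of sparsity fractions
#'   (default `seq(0.20, 0.40, by = 0.01)`).
#' @return Data frame with one row per sparsity: `sparsity`, `icc`,
#'   `p_value`, `significant` (p < 0.05), `quality_band`; for BC an
#'   additional attribute `per_node` holds the node x sparsity ICC matrix.
#' @export
icc_over_sparsity <- function(session1, session2,
                              property = c("Cp", "Lp", "BC"),
                              sparsities = seq(0.20, 0.40, by = 0.01)) {
  property <- match.arg(property)
  n <- length(session1)
  if (length(session2) != n || n < 2L)
    stop("sessions must be paired lists of >= 2 subjects", call. = FALSE)
  per_node <- NULL
  rows <- lapply(sparsities, function(S) {
    v1 <- lapply(session1, function(W)
      graph_property(threshold_by_sparsity(W, S), property))
    v2 <- lapply(session2, function(W)
      graph_property(threshold_by_sparsity(W, S), property))
    if (property == "BC") {
      B1 <- do.call(rbind, v1)   # subjects x nodes
      B2 <- do.call(rbind, v2)
      node_icc <- vapply(seq_len(ncol(B1)), function(j) {
        res <- tryCatch(icc_one_way(cbind(B1[, j], B2[, j])),
                        error = function(e) list(icc = NA_real_,
                                                 p_value = NA_real_))
        res$icc
      }, numeric(1L))
      per_node <<- cbind(per_node, node_icc)
      icc <- mean(node_icc, na.rm = TRUE)
      data.frame(sparsity = S, icc = icc, p_value = NA_real_,
                 significant = NA,
                 quality_band = if (icc > 0.75) "excellent"
                                else if (icc >= 0.59) "good" else "other")
    } else {
      res <- icc_one_way(cbind(unlist(v1), unlist(v2)))
      data.frame(sparsity = S, icc = res$icc, p_value = res$p_value,
                 significant = res$p_value < 0.05,
                 quality_band = res$quality_band)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (property == "BC") {
    colnames(per_node) <- as.character(sparsities)
    rownames(per_node) <- rownames(session1[[1L]])
    attr(out, "per_node") <- per_node
  }
  out
}
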