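# Seeded generator of FreeSurfer-like surface cohorts with the statistical
# structure the pipeline assumes: region-specific feature distributions,
# between-subject variation, test-retest session noise, group effects, and
# clinical scores coupled to disease severity.

#' Specify a synthetic surface cohort
#'
#' Fixes every distributional parameter of the generator. Per-vertex
#' features are Gaussian with region-specific means and spreads at
#' realistic scales (thickness about 2.5 +/- 0.3 mm, surface area about
#' 0.6 +/- 0.2 mm^2, gray matter volume about 1.5 +/- 0.5 mm^3, sulcal
#' depth / metric distortion / curvature dimensionless), so the mixed-unit
#' standardization question in network construction is genuinely exercised.
#' Region means are drawn once (deterministically from `seed`) around those
#' bases; subject, session and group effects shift regional means in units
#' of the typical per-vertex spread of each feature.
#'
#' @param V Number of regions (default 68; the bundled atlas labels are
#'   used when V = 68).
#' @param vertex_count_range Integer (min, max) vertices per region,
#'   drawn uniformly (default c(40, 120), a down-sampled surface).
#' @param d Number of features, 1..6 (default 6).
#' @param n_per_group Subjects per group for two-group cohorts (default 20).
#' @param between_subject_sd Subject random-effect scale (default 0.2).
#' @param within_subject_sd Test-retest session noise scale (default 0.1).
#' @param group_effect List with `regions` (1-based region indices) and
#'   `shift` (scalar or length-d mean shift, in per-vertex-sd units)
#'   applied to the +1 group. Default: the first `min(12, V)` regions,
#'   shift 0 (a null cohort).
#' @param seed Integer seed fixing the region parameter draw.
#' @return A `cohort_spec` list (region means/sds filled in).
#' @export
cohort_spec <- function(V = 68L, vertex_count_range = c(40L, 120L), d = 6L,
                        n_per_group = 20L, between_subject_sd = 0.2,
                        within_subject_sd = 0.1,
                        group_effect = NULL, seed = 1L) {
  if (is.null(group_effect))
    group_effect <- list(regions = seq_len(min(12L, V)), shift = 0)
  stopifnot(V >= 2L, d >= 1L, d <= 6L,
            vertex_count_range[1L] >= 2L,
            vertex_count_range[2L] >= vertex_count_range[1L],
            within_subject_sd >= 0, between_subject_sd >= 0)
  if (any(group_effect$regions < 1L) || any(group_effect$regions > V))
    stop("affected regions out of range", call. = FALSE)
  feature_names <- surface_features()[seq_len(d)]
  base_mean <- c(thickness = 2.5, area = 0.6, volume = 1.5, sulc = 0,
                 metric_distortion = 0, curvature = 0)[feature_names]
  base_sd <- c(thickness = 0.3, area = 0.2, volume = 0.5, sulc = 1,
               metric_distortion = 0.3, curvature = 0.15)[feature_names]
  labels <- if (V == 68L) dk_parcellation()$region_label
            else sprintf("region_%02d", seq_len(V) - 1L)
  region_means <- .with_seed(seed, {
    m <- matrix(rnorm(V * d, mean = rep(base_mean, each = V),
                      sd = rep(base_sd / 2, each = V)), V, d)
    dimnames(m) <- list(labels, feature_names)
    m
  })
  feature_sds <- matrix(rep(base_sd, each = V), V, d,
                        dimnames = list(labels, feature_names))
  shift <- group_effect$shift
  if (length(shift) == 1L) shift <- rep(shift, d)
  structure(list(V = V, vertex_count_range = as.integer(vertex_count_range),
                 d = d, feature_names = feature_names,
                 region_labels = labels,
                 region_means = region_means, feature_sds = feature_sds,
                 base_sd = base_sd,
                 n_per_group = as.integer(n_per_group),
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 group_effect = list(regions = as.integer(group_effect$regions),
                                     shift = shift),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# One subject's latent realization: vertex counts and standard-normal
# deviates, reusable across sessions so session noise perturbs parameters,
# not the sampled vertices.
.draw_realization <- function(spec, seed) {
  .with_seed(seed, {
    lo <- spec$vertex_count_range[1L]; hi <- spec$vertex_count_range[2L]
    n_r <- lo + sample.int(hi - lo + 1L, spec$V, replace = TRUE) - 1L
    z <- lapply(n_r, function(n) matrix(rnorm(n * spec$d), n, spec$d))
    list(n_r = n_r, z = z)
  })
}

# Assemble a vertex table from a realization and per-region mean shifts
# (V x d, in raw feature units).
.assemble_table <- function(spec, realization, mean_shift) {
  rows <- lapply(seq_len(spec$V), function(r) {
    mu <- spec$region_means[r, ] + mean_shift[r, ]
    sg <- spec$feature_sds[r, ]
    feat <- sweep(sweep(realization$z[[r]], 2L, sg, "*"), 2L, mu, "+")
    colnames(feat) <- spec$feature_names
    data.frame(region_label = spec$region_labels[r], feat,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(vertex_id = seq_len(nrow(out)) - 1L, out)
  rownames(out) <- NULL
  structure(out, class = c("vertex_table", "data.frame"))
}

# Subject random effect: V x d mean shifts in raw units.
.subject_shift <- function(spec, seed) {
  .with_seed(seed, matrix(rnorm(spec$V * spec$d, sd = rep(
    spec$between_subject_sd * spec$base_sd, each = spec$V)),
    spec$V, spec$d))
}

#' Generate one synthetic subject
#'
#' Draws per-region vertex counts uniformly from the spec's range, then
#' i.i.d. Gaussian vertex features around the region means (plus any
#' supplied per-region mean shift). Fully deterministic under (spec, seed).
#'
#' @param spec A `cohort_spec`.
#' @param subject_effect Optional V x d matrix of mean shifts in raw
#'   feature units (default none).
#' @param seed Integer seed.
#' @return A `vertex_table`.
#' @export
generate_subject <- function(spec, subject_effect = NULL, seed = 1L) {
  if (!inherits(spec, "cohort_spec")) stop("invalid spec", call. = FALSE)
  if (is.null(subject_effect))
    subject_effect <- matrix(0, spec$V, spec$d)
  .assemble_table(spec, .draw_realization(spec, seed), subject_effect)
}

#' Generate a test-retest session pair for one subject
#'
#' Both sessions share the subject's vertex realization (counts and
#' standardized deviates); each session perturbs the regional mean
#' parameters by independent Gaussian noise of scale `within_subject_sd`
#' (in per-vertex-sd units). With `within_subject_sd = 0` the two tables
#' are identical, so any deterministic network property has ICC exactly 1.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed (one subject per seed).
#' @return List of two `vertex_table`s (`session1`, `session2`).
#' @export
generate_test_retest_pair <- function(spec, seed = 1L) {
  realization <- .draw_realization(spec, seed)
  subj <- .subject_shift(spec, seed + 500000L)
  session_noise <- function(s)
    .with_seed(seed + 600000L + s, matrix(rnorm(spec$V * spec$d, sd = rep(
      spec$within_subject_sd * spec$base_sd, each = spec$V)),
      spec$V, spec$d))
  noise <- if (spec$within_subject_sd == 0)
    list(matrix(0, spec$V, spec$d), matrix(0, spec$V, spec$d))
  else list(session_noise(1L), session_noise(2L))
  list(session1 = .assemble_table(spec, realization, subj + noise[[1L]]),
       session2 = .assemble_table(spec, realization, subj + noise[[2L]]))
}

#' Generate a two-group synthetic cohort
#'
#' Builds `2 * n_per_group` subjects: the +1 (patient) group receives the
#' spec's group-effect mean shifts in the affected regions, scaled per
#' subject by a positive severity factor; the -1 (control) group does not.
#' Clinical scores are coupled to severity (MMSE-like, higher = healthier,
#' clipped to [0, 30]; CDR-like, snapped to {0, 0.5, 1, 2, 3}) so that
#' affected-edge values correlate with the scores. The `truth` element
#' records the planted structure.
#'
#' @param spec A `cohort_spec` with a nonzero `group_effect` for a real
#'   signal (zero shift gives a null cohort).
#' @param seed Integer seed.
#' @return A `synthetic_cohort` list: `subjects` (vertex tables), `labels`
#'   (+1/-1), `scores` (data.frame `mmse`, `cdr`), `truth` (affected
#'   regions, affected edges as region-pair indices, severities, spec).
#' @export
generate_two_group_cohort <- function(spec, seed = 1L) {
  if (spec$n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  n <- 2L * spec$n_per_group
  labels <- rep(c(1, -1), each = spec$n_per_group)
  affected <- spec$group_effect$regions
  shift_raw <- spec$group_effect$shift * spec$base_sd  # d-vector, raw units
  severity <- .with_seed(seed + 900000L,
                         ifelse(labels == 1,
                                abs(rnorm(n, mean = 1, sd = 0.3)), 0))
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    eff <- matrix(0, spec$V, spec$d)
    if (labels[s] == 1)
      eff[affected, ] <- matrix(rep(severity[s] * shift_raw,
                                    each = length(affected)),
                                length(affected), spec$d)
    subj <- .subject_shift(spec, seed + 700000L + s)
    subjects[[s]] <- .assemble_table(spec,
                                     .draw_realization(spec, seed + s),
                                     subj + eff)
  }
  scores <- .with_seed(seed + 800000L, {
    mmse <- pmin(pmax(29 - 3 * severity + rnorm(n, sd = 0.8), 0), 30)
    cdr_raw <- pmax(severity + rnorm(n, sd = 0.25), 0)
    cdr <- vapply(cdr_raw, function(x)
      c(0, 0.5, 1, 2, 3)[which.min(abs(c(0, 0.5, 1, 2, 3) - x))],
      numeric(1L))
    data.frame(mmse = mmse, cdr = cdr)
  })
  pair_has_affected <- function(i, j) (i %in% affected) || (j %in% affected)
  V <- spec$V
  ii <- rep(seq_len(V - 1L), times = (V - 1L):1L)
  jj <- unlist(lapply(seq_len(V - 1L), function(i) (i + 1L):V))
  affected_edges <- which(mapply(pair_has_affected, ii, jj))
  structure(list(subjects = subjects, labels = labels, scores = scores,
                 truth = list(affected_regions = affected,
                              affected_edges = affected_edges,
                              severity = severity,
                              spec = spec)),
            class = "synthetic_cohort")
}
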