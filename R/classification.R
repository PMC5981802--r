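# Edge-based classification: vectorised upper-triangle edge features,
# per-fold Lasso selection (L1-penalised least squares), RBF-SVM with
# leave-one-out cross-validation and grid search, confusion/ROC metrics,
# discriminative-edge aggregation and clinical-score correlation.

#' Vectorise similarity networks into an edge feature matrix
#'
#' Flattens the upper triangle (i < j, row-major) of each subject's V x V
#' similarity matrix into one row of m = V(V-1)/2 edge features, with a
#' fixed edge ordering shared across subjects.
#'
#' @param networks List of `similarity_matrix` objects with identical
#'   dimension and labels.
#' @param labels Numeric class labels in {+1, -1}, one per subject (+1 is
#'   the patient class). Optional (`NULL` for unlabeled data).
#' @return An `edge_features` list: `X` (n x m matrix), `y`, `edge_index`
#'   (data.frame mapping column position to region pair), `region_labels`.
#' @export
vectorize_edges <- function(networks, labels = NULL) {
  V <- nrow(networks[[1L]])
  rl <- rownames(networks[[1L]])
  for (W in networks)
    if (nrow(W) != V || ncol(W) != V)
      stop("all networks must share dimension", call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != length(networks))
      stop("one label per network required", call. = FALSE)
    if (!all(labels %in% c(-1, 1)))
      stop("labels must be +1/-1", call. = FALSE)
  }
  ii <- rep(seq_len(V - 1L), times = (V - 1L):1L)
  jj <- unlist(lapply(seq_len(V - 1L), function(i) (i + 1L):V))
  X <- t(vapply(networks, function(W) W[cbind(ii, jj)],
                numeric(length(ii))))
  edge_index <- data.frame(position = seq_along(ii), i = ii, j = jj,
                           region_i = rl[ii], region_j = rl[jj],
                           stringsAsFactors = FALSE)
  structure(list(X = X, y = labels, edge_index = edge_index,
                 region_labels = rl),
            class = "edge_features")
}

#' Restore a vectorised edge row to a symmetric matrix
#'
#' @param x Numeric vector of length V(V-1)/2 in the [vectorize_edges()]
#'   ordering.
#' @param region_labels Region labels defining V.
#' @return Symmetric V x V matrix, diagonal 1.
#' @export
devectorize_edges <- function(x, region_labels) {
  V <- length(region_labels)
  W <- matrix(0, V, V, dimnames = list(region_labels, region_labels))
  ii <- rep(seq_len(V - 1L), times = (V - 1L):1L)
  jj <- unlist(lapply(seq_len(V - 1L), function(i) (i + 1L):V))
  W[cbind(ii, jj)] <- x
  W <- W + t(W)
  diag(W) <- 1
  W
}

#' L1-penalised least-squares (Lasso) edge selection
#'
#' Minimises `0.5 * ||X w - y||^2 + lambda * ||w||_1` (no intercept) and
#' returns the coefficient vector and its nonzero support. Feature columns
#' are expected already standardized (done per training fold by
#' [loocv_classify()]).
#'
#' @param X n x m numeric matrix.
#' @param y Numeric response (class labels +1/-1 for selection use).
#' @param lambda_reg Penalty `lambda >= 0` on the objective above, or
#'   `"auto"` to choose it by inner 5-fold cross-validation over a
#'   logarithmic path.
#' @param seed Seed for the inner CV fold assignment (only used with
#'   `"auto"`).
#' @return A `lasso_fit` list: `w`, `lambda_reg`, `selected` (nonzero
#'   column indices).
#' @export
lasso_select <- function(X, y, lambda_reg = "auto", seed = 1L) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in Lasso input", call. = FALSE)
  n <- nrow(X)
  if (identical(lambda_reg, "auto")) {
    cv <- .with_seed(seed, glmnet::cv.glmnet(
      X, y, alpha = 1, nfolds = 5L, standardize = FALSE, intercept = FALSE))
    lam_g <- cv$lambda.min
    lambda_reg <- lam_g * n
  } else {
    if (lambda_reg < 0) stop("lambda_reg must be >= 0", call. = FALSE)
    lam_g <- lambda_reg / n
  }
  if (lam_g == 0) {
    # unpenalised limit: ordinary least squares
    w <- qr.coef(qr(X), y)
    w[is.na(w)] <- 0
  } else {
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam_g,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14, maxit = 1e7)
    w <- as.numeric(fit$beta)
  }
  names(w) <- colnames(X)
  structure(list(w = w, lambda_reg = lambda_reg,
                 selected = which(w != 0)),
            class = "lasso_fit")
}

#' Gaussian radial basis function kernel
#'
#' `K(x1, x2) = exp(-||x1 - x2||^2 / (2 sigma^2))`, the similarity kernel
#' used by the SVM; `sigma` is the kernel width.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param sigma_rbf Kernel width, > 0.
#' @return Scalar in (0, 1].
#' @export
rbf_kernel <- function(x1, x2, sigma_rbf) {
  if (sigma_rbf <= 0) stop("sigma_rbf must be > 0", call. = FALSE)
  exp(-sum((x1 - x2)^2) / (2 * sigma_rbf^2))
}

# Fit an RBF SVM and return oriented decision values for new rows:
# positive decision value favors the +1 class.
.svm_decision <- function(X_train, y_train, X_test, C, sigma_rbf) {
  fit <- e1071::svm(X_train, factor(y_train, levels = c(-1, 1)),
                    scale = FALSE, kernel = "radial",
                    gamma = 1 / (2 * sigma_rbf^2), cost = C)
  pr <- predict(fit, X_test, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  flip <- identical(colnames(dv), "-1/1")
  d <- as.numeric(dv)
  if (flip) d <- -d
  list(pred = as.numeric(as.character(pr)), decision = d)
}

#' Leave-one-out Lasso + RBF-SVM classification
#'
#' For each left-out subject: standardize edge columns on the training rows,
#' select edges by Lasso on the training rows only, restrict both sets to
#' the selected columns, train a soft-margin RBF-SVM, and record the
#' held-out prediction and decision value. A grid search over (C, sigma)
#' selects, in the default `"literal"` protocol, the pair maximising the
#' LOOCV accuracy itself (optimistic, but matches common practice in the
#' source literature); `"nested"` chooses (C, sigma) per fold by inner
#' 5-fold cross-validation on the training set only, giving an unbiased
#' estimate.
#'
#' @param F An `edge_features` object with labels.
#' @param lambda_reg Lasso penalty or `"auto"` (per-fold inner CV).
#' @param C_grid SVM cost grid (default `2^seq(-5, 15, by = 4)`).
#' @param sigma_grid Kernel width grid (default `2^seq(-15, 3, by = 4)`).
#' @param seed Integer seed (inner CV fold assignment).
#' @param mode `"literal"` or `"nested"` (see above).
#' @return A `classification_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `roc`, `hyperparams`, `protocol`, `folds`
#'   (per-fold records: selected edges, prediction, decision value,
#'   fallback flag), `edge_index`, `y`.
#' @export
loocv_classify <- function(F, lambda_reg = "auto",
                           C_grid = 2^seq(-5, 15, by = 4),
                           sigma_grid = 2^seq(-15, 3, by = 4),
                           seed = 1L, mode = c("literal", "nested")) {
  mode <- match.arg(mode)
  X <- F$X; y <- F$y
  n <- nrow(X)
  if (n < 4L || sum(y == 1) < 2L || sum(y == -1) < 2L)
    stop("need >= 4 subjects with >= 2 per class", call. = FALSE)

  # Per-fold standardization + Lasso selection (independent of C, sigma).
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2L, sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu, "-"), 2L, sg, "/")
    xte <- (X[i, ] - mu) / sg
    fit <- lasso_select(Xtr, y[tr], lambda_reg, seed = seed + i)
    sel <- fit$selected
    fallback <- length(sel) == 0L
    if (fallback) sel <- seq_len(ncol(X))
    folds[[i]] <- list(train = tr, test = i, selected = sel,
                       fallback = fallback, lambda_reg = fit$lambda_reg,
                       Xtr = Xtr[, sel, drop = FALSE],
                       xte = matrix(xte[sel], nrow = 1L))
  }

  run_loocv <- function(C, sigma_rbf) {
    pred <- numeric(n); dec <- numeric(n)
    for (i in seq_len(n)) {
      f <- folds[[i]]
      res <- .svm_decision(f$Xtr, y[f$train], f$xte, C, sigma_rbf)
      pred[i] <- res$pred; dec[i] <- res$decision
    }
    list(pred = pred, dec = dec, accuracy = mean(pred == y))
  }

  if (mode == "literal") {
    grid <- expand.grid(C = C_grid, sigma = sigma_grid)
    best <- NULL; best_acc <- -Inf; best_hp <- grid[1L, ]
    for (r in seq_len(nrow(grid))) {
      res <- run_loocv(grid$C[r], grid$sigma[r])
      if (res$accuracy > best_acc) {
        best <- res; best_acc <- res$accuracy; best_hp <- grid[r, ]
      }
    }
    pred <- best$pred; dec <- best$dec
    hyper <- list(C = best_hp$C, sigma_rbf = best_hp$sigma)
  } else {
    pred <- numeric(n); dec <- numeric(n)
    hp_per_fold <- vector("list", n)
    for (i in seq_len(n)) {
      f <- folds[[i]]
      ytr <- y[f$train]
      ntr <- length(ytr)
      assign_folds <- .with_seed(seed + 1000L + i,
                                 sample(rep_len(1:5, ntr)))
      best_hp <- c(C = C_grid[1L], sigma = sigma_grid[1L]); best_acc <- -Inf
      for (C in C_grid) for (sg in sigma_grid) {
        correct <- 0L
        for (v in 1:5) {
          va <- which(assign_folds == v)
          if (length(va) == 0L || length(unique(ytr[-va])) < 2L) next
          res <- .svm_decision(f$Xtr[-va, , drop = FALSE], ytr[-va],
                               f$Xtr[va, , drop = FALSE], C, sg)
          correct <- correct + sum(res$pred == ytr[va])
        }
        if (correct / ntr > best_acc) {
          best_acc <- correct / ntr; best_hp <- c(C = C, sigma = sg)
        }
      }
      res <- .svm_decision(f$Xtr, ytr, f$xte, best_hp["C"], best_hp["sigma"])
      pred[i] <- res$pred; dec[i] <- res$decision
      hp_per_fold[[i]] <- best_hp
    }
    hyper <- list(per_fold = hp_per_fold)
  }

  cm <- confusion_metrics(y, pred)
  roc <- roc_auc(y, dec)
  fold_records <- lapply(seq_len(n), function(i)
    list(test = i, selected = folds[[i]]$selected,
         fallback = folds[[i]]$fallback,
         lambda_reg = folds[[i]]$lambda_reg,
         prediction = pred[i], decision_value = dec[i]))
  structure(list(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, auc = roc$auc,
                 roc = roc$roc, hyperparams = hyper, protocol = mode,
                 folds = fold_records, edge_index = F$edge_index, y = y),
            class = "classification_report")
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (true-positive rate on the +1 patient class) and
#' specificity (true-negative rate on the -1 class).
#'
#' @param y_true,y_pred Numeric vectors of +1/-1 labels, equal length.
#' @return List with `accuracy`, `sensitivity`, `specificity` (the latter
#'   two `NA` with a warning when their class is absent from `y_true`).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch", call. = FALSE)
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  sens <- if (tp + fn == 0) { warning("no positive cases: sensitivity undefined"); NA_real_ } else tp / (tp + fn)
  spec <- if (tn + fp == 0) { warning("no negative cases: specificity undefined"); NA_real_ } else tn / (tn + fp)
  list(accuracy = (tp + tn) / length(y_true),
       sensitivity = sens, specificity = spec)
}

#' ROC curve and AUC from decision values
#'
#' Sweeps a threshold over the decision values to build the ROC curve and
#' computes the AUC as the Mann-Whitney pair-counting statistic (ties
#' count one half).
#'
#' @param y_true +1/-1 labels.
#' @param decision_values Continuous scores, larger favouring +1.
#' @return List with `roc` (data.frame of `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(y_true, decision_values) {
  pos <- decision_values[y_true == 1]
  neg <- decision_values[y_true == -1]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes required for ROC", call. = FALSE)
  if (length(unique(decision_values)) == 1L) {
    warning("constant decision values: AUC = 0.5")
    return(list(roc = data.frame(fpr = c(0, 1), tpr = c(0, 1)), auc = 0.5))
  }
  thr <- c(Inf, sort(unique(decision_values), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1L))
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = mean(cmp))
}

#' Discriminative edges: selected in every LOOCV fold
#'
#' The strict intersection of the per-fold Lasso selections; an edge must
#' be selected in every iteration of the leave-one-out loop to count as
#' discriminative. Edges are mapped back to region-pair names and tagged by
#' hemisphere (intra-left, intra-right, inter-hemispheric) when the
#' parcellation covers the network's labels.
#'
#' @param report A `classification_report`.
#' @param parcellation A `parcellation` for hemisphere tags; default the
#'   bundled 68-region atlas. Labels absent from it are tagged `NA`.
#' @return Data.frame of discriminative edges (`position`, `region_i`,
#'   `region_j`, `hemisphere_tag`), with attribute `counts` =
#'   c(intra_L, intra_R, inter).
#' @export
discriminative_edges <- function(report, parcellation = dk_parcellation()) {
  sel <- Reduce(intersect, lapply(report$folds, `[[`, "selected"))
  ei <- report$edge_index[report$edge_index$position %in% sel, , drop = FALSE]
  hemi <- setNames(parcellation$hemisphere, parcellation$region_label)
  h1 <- unname(hemi[ei$region_i]); h2 <- unname(hemi[ei$region_j])
  tag <- ifelse(is.na(h1) | is.na(h2), NA_character_,
                ifelse(h1 == "L" & h2 == "L", "intra-L",
                       ifelse(h1 == "R" & h2 == "R", "intra-R", "inter")))
  ei$hemisphere_tag <- tag
  rownames(ei) <- NULL
  attr(ei, "counts") <- c(intra_L = sum(tag == "intra-L", na.rm = TRUE),
                          intra_R = sum(tag == "intra-R", na.rm = TRUE),
                          inter = sum(tag == "inter", na.rm = TRUE))
  ei
}

#' Correlate edge features with clinical scores
#'
#' Pearson correlation (two-sided test) of each listed edge's values across
#' subjects with a per-subject clinical score (e.g. MMSE or CDR);
#' significance is flagged at unadjusted p < 0.05.
#'
#' @param F An `edge_features` object.
#' @param edges Edge positions (columns of `F$X`) to test.
#' @param scores Numeric per-subject clinical values aligned to rows of
#'   `F$X`.
#' @return Data.frame with `position`, `region_i`, `region_j`, `r`, `p`,
#'   `significant`, `skipped` (zero-variance edge or score).
#' @export
correlate_edges_with_scores <- function(F, edges, scores) {
  if (length(scores) != nrow(F$X))
    stop("scores must align with subjects", call. = FALSE)
  const_score <- sd(scores) == 0
  rows <- lapply(edges, function(e) {
    x <- F$X[, e]
    if (const_score || sd(x) == 0)
      return(data.frame(position = e, r = NA_real_, p = NA_real_,
                        significant = NA, skipped = TRUE))
    ct <- cor.test(x, scores, method = "pearson")
    data.frame(position = e, r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < 0.05, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  ei <- F$edge_index[match(out$position, F$edge_index$position), ]
  out$region_i <- ei$region_i
  out$region_j <- ei$region_j
  rownames(out) <- NULL
  out[, c("position", "region_i", "region_j", "r", "p", "significant",
          "skipped")]
}
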