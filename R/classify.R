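#' Grouped repeated cross-validation scheme
#'
#' Five outer folds (~80:20 split by patient count), stratified at the
#' patient level, repeated 10 times for 50 test folds in total. All samples
#' of a patient (baseline and follow-up) stay on the same side of every
#' split, so no patient leaks between train and test; inner model tuning
#' uses stratified 5-fold splits of the training patients.
#'
#' @param outer_folds number of outer folds (default 5).
#' @param inner_folds number of inner tuning folds (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed master seed for all fold draws.
#' @param group_samples if FALSE, samples are assigned to folds independently
#'   of their patient (for comparison only; leaks repeated patients).
#' @return a `cv_scheme` list.
#' @export
cv_scheme <- function(outer_folds = 5L, inner_folds = 5L, repeats = 10L,
                      seed = 1L, group_samples = TRUE) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, repeats >= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 group_samples = isTRUE(group_samples)),
            class = "cv_scheme")
}

# stratified assignment of groups (patients) to k folds: within each class,
# shuffle patients and deal them round-robin from a random starting fold
.assign_groups <- function(group_class, k) {
  folds <- integer(length(group_class))
  for (cl in unique(group_class)) {
    idx <- which(group_class == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- 1L + (sample.int(k, 1L) + seq_along(idx) - 2L) %% k
  }
  folds
}

#' Build grouped, stratified fold assignments
#'
#' @param labels character vector ("cancer"/"control"), one per sample.
#' @param patient_ids character vector, one per sample.
#' @param scheme a [cv_scheme()].
#' @return list of length `repeats`; each element is an integer vector of
#'   outer-fold ids (1..outer_folds), one per sample. Deterministic given the
#'   scheme seed.
#' @export
make_splits <- function(labels, patient_ids, scheme = cv_scheme()) {
  stopifnot(length(labels) == length(patient_ids), length(labels) >= 10)
  if (length(unique(labels)) < 2L)
    stop("input error: both classes must be present")
  # patient-level class: a patient with any cancer sample counts as cancer
  pts <- unique(patient_ids)
  pclass <- vapply(pts, function(p)
    if (any(labels[patient_ids == p] == "cancer")) "cancer" else "control",
    character(1))
  lapply(seq_len(scheme$repeats), function(r) {
    with_seed(derive_seed(scheme$seed, paste0("split/", r)), {
      for (try in 1:25) {
        if (scheme$group_samples) {
          pf <- .assign_groups(pclass, scheme$outer_folds)
          f <- pf[match(patient_ids, pts)]
        } else {
          f <- .assign_groups(labels, scheme$outer_folds)
        }
        ok <- all(vapply(seq_len(scheme$outer_folds), function(k)
          length(unique(labels[f != k])) == 2L && any(f == k), logical(1)))
        if (ok) return(f)
      }
      stop("could not build folds with both classes in every training set")
    })
  })
}

.standardize <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  keep <- sd > 0
  if (!all(keep))
    warning("dropping constant feature(s): ",
            paste(colnames(train)[!keep], collapse = ", "))
  train <- scale(train[, keep, drop = FALSE], mu[keep], sd[keep])
  test <- scale(test[, keep, drop = FALSE], mu[keep], sd[keep])
  list(train = train, test = test)
}

#' Model specification
#'
#' @param family one of "LR" (logistic regression), "RF" (random forest),
#'   "SVM" (radial-kernel support vector machine), "GLMEN" (binomial GLM with
#'   elastic-net regularization).
#' @param grid optional named list overriding the default hyperparameter grid
#'   (LR has none; RF: `mtry`; SVM: `cost`; GLMEN: `alpha`, lambda chosen by
#'   inner CV).
#' @param seed integer seed for the stochastic learners.
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("LR", "RF", "SVM", "GLMEN"),
                       grid = NULL, seed = 1L) {
  family <- match.arg(family)
  default_grid <- switch(family,
    LR = list(),
    RF = list(mtry = c(2L, 3L), ntree = 300L),
    SVM = list(cost = c(0.1, 1, 10)),
    GLMEN = list(alpha = c(0.2, 0.5, 0.8)))
  if (!is.null(grid)) default_grid[names(grid)] <- grid
  structure(list(family = family, grid = default_grid, seed = as.integer(seed)),
            class = "model_spec")
}

# fit one configuration on (x, y) and score newx; y is 0/1 numeric
.fit_one <- function(family, par, x, y, newx, seed) {
  with_seed(seed, switch(family,
    LR = {
      df <- data.frame(y = y, x)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      suppressWarnings(
        stats::predict(fit, newdata = data.frame(newx), type = "response"))
    },
    RF = {
      fit <- randomForest::randomForest(
        x, factor(y, levels = c(0, 1)),
        ntree = par$ntree %||% 300L,
        mtry = min(par$mtry %||% 3L, ncol(x)))
      stats::predict(fit, newx, type = "prob")[, "1"]
    },
    SVM = {
      fit <- e1071::svm(x, factor(y, levels = c(0, 1)),
                        kernel = "radial", cost = par$cost %||% 1,
                        probability = TRUE)
      attr(stats::predict(fit, newx, probability = TRUE),
           "probabilities")[, "1"]
    },
    GLMEN = {
      fit <- glmnet::glmnet(x, y, family = "binomial",
                            alpha = par$alpha %||% 0.5,
                            lambda = par$lambda)
      as.numeric(stats::predict(fit, newx, s = par$lambda, type = "response"))
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expand the grid into a list of parameter sets
.grid_points <- function(family, grid) {
  if (family == "LR") return(list(list()))
  if (family == "RF")
    return(lapply(grid$mtry, function(m) list(mtry = m, ntree = grid$ntree)))
  if (family == "SVM")
    return(lapply(grid$cost, function(cst) list(cost = cst)))
  if (family == "GLMEN") {
    lam <- 10^seq(-0.5, -3.5, length.out = 12)
    out <- list()
    for (a in grid$alpha) for (l in lam)
      out[[length(out) + 1L]] <- list(alpha = a, lambda = l)
    return(out)
  }
}

#' Fit a model on a training fold and score a test fold
#'
#' Features are z-scored with training-fold statistics only; constant
#' training columns are dropped with a warning. Hyperparameters, where the
#' family has any, are chosen by stratified grouped inner cross-validation on
#' the training fold only (inner AUC, maximised).
#'
#' @param spec a [model_spec()].
#' @param train,test data.frames with columns label, patient_id and feature
#'   columns (everything not named sample_id/patient_id/label).
#' @param inner_folds number of inner folds (default 5).
#' @return numeric vector of probability-like scores in \[0,1\], one per test
#'   row (cancer-oriented).
#' @export
fit_predict <- function(spec, train, test, inner_folds = 5L) {
  stopifnot(inherits(spec, "model_spec"))
  meta <- c("sample_id", "patient_id", "label")
  fcols <- setdiff(names(train), meta)
  if (length(unique(train$label)) < 2L)
    stop("input error: training fold must contain both classes")
  y <- as.numeric(train$label == "cancer")
  xs <- .standardize(as.matrix(train[, fcols, drop = FALSE]),
                     as.matrix(test[, fcols, drop = FALSE]))
  pts <- .grid_points(spec$family, spec$grid)
  best <- pts[[1L]]
  if (length(pts) > 1L) {
    inner <- with_seed(derive_seed(spec$seed, "inner"),
                       .assign_groups(
                         vapply(unique(train$patient_id), function(p)
                           if (any(train$label[train$patient_id == p] == "cancer"))
                             "cancer" else "control", character(1)),
                         inner_folds))
    fold_of <- inner[match(train$patient_id, unique(train$patient_id))]
    score <- vapply(seq_along(pts), function(j) {
      aucs <- c()
      for (k in seq_len(inner_folds)) {
        tr <- fold_of != k
        if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
        s <- .fit_one(spec$family, pts[[j]], xs$train[tr, , drop = FALSE],
                      y[tr], xs$train[!tr, , drop = FALSE],
                      derive_seed(spec$seed, paste0("inner/", j, "/", k)))
        aucs <- c(aucs, auc(s, y[!tr]))
      }
      if (length(aucs)) mean(aucs) else 0.5
    }, numeric(1))
    best <- pts[[which.max(score)]]
  }
  s <- .fit_one(spec$family, best, xs$train, y, xs$test,
                derive_seed(spec$seed, "final"))
  pmin(pmax(as.numeric(s), 0), 1)
}

#' Area under the ROC curve by pair counting
#'
#' Mann-Whitney AUC: the fraction of (positive, negative) pairs ranked
#' correctly, ties credited 0.5.
#'
#' @param scores numeric scores (higher = more cancer-like).
#' @param labels "cancer"/"control" (or 1/0) per score.
#' @return AUC in \[0,1\].
#' @export
auc <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.numeric(as.character(labels) == "cancer") else as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("input error: AUC undefined with a single class")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a fixed score threshold
#'
#' @param scores numeric scores; `score >= t` predicts cancer.
#' @param labels "cancer"/"control" (or 1/0).
#' @param t threshold (default 0.5).
#' @return named vector: accuracy, sensitivity, specificity, precision,
#'   recall.
#' @export
metrics_at_threshold <- function(scores, labels, t = 0.5) {
  y <- if (is.character(labels) || is.factor(labels))
    as.numeric(as.character(labels) == "cancer") else as.numeric(labels)
  pred <- as.numeric(scores >= t)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  c(accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Run the full repeated grouped cross-validation experiment
#'
#' For each repeat, builds a grouped stratified outer partition, fits every
#' model family on each training fold (with inner tuning) and scores the
#' held-out fold; aggregates the `repeats * outer_folds` per-iteration AUCs
#' and threshold metrics. Scenario flags restrict to baseline samples and/or
#' a feature subset.
#'
#' @param fmatrix feature matrix from [feature_matrix()] (columns sample_id,
#'   patient_id, label, features; a `timepoint` column enables
#'   `scenario = "baseline"`).
#' @param specs list of [model_spec()] (default: all four families).
#' @param scheme a [cv_scheme()].
#' @param scenario "all" or "baseline" (baseline samples only).
#' @param features "all" or a character vector of feature columns to use.
#' @return named list (per family) of `cv_result`: list(auc (length 50),
#'   metrics (data.frame, 50 rows), scores (out-of-fold score table)).
#' @export
run_experiment <- function(fmatrix,
                           specs = lapply(c("LR", "RF", "SVM", "GLMEN"),
                                          model_spec),
                           scheme = cv_scheme(),
                           scenario = c("all", "baseline"),
                           features = "all") {
  scenario <- match.arg(scenario)
  if (scenario == "baseline") {
    if (is.null(fmatrix$timepoint))
      stop("input error: baseline scenario needs a timepoint column")
    fmatrix <- fmatrix[fmatrix$timepoint == "baseline", , drop = FALSE]
  }
  meta <- intersect(c("sample_id", "patient_id", "label", "timepoint"),
                    names(fmatrix))
  fcols <- setdiff(names(fmatrix), meta)
  if (!identical(features, "all")) {
    miss <- setdiff(features, fcols)
    if (length(miss))
      stop("input error: unknown feature(s) ", paste(miss, collapse = ", "))
    fcols <- features
  }
  dat <- fmatrix[, c("sample_id", "patient_id", "label", fcols)]
  splits <- make_splits(dat$label, dat$patient_id, scheme)

  names(specs) <- vapply(specs, `[[`, character(1), "family")
  out <- lapply(specs, function(spec) {
    aucs <- numeric(0); mets <- list(); scs <- list()
    for (r in seq_along(splits)) {
      f <- splits[[r]]
      for (k in seq_len(scheme$outer_folds)) {
        tr <- dat[f != k, , drop = FALSE]
        te <- dat[f == k, , drop = FALSE]
        s <- fit_predict(spec, tr, te, inner_folds = scheme$inner_folds)
        it <- length(aucs) + 1L
        aucs[it] <- if (length(unique(te$label)) == 2L) auc(s, te$label) else NA_real_
        mets[[it]] <- metrics_at_threshold(s, te$label)
        scs[[it]] <- data.frame(repeat_id = r, fold = k,
                                sample_id = te$sample_id, score = s,
                                label = te$label, stringsAsFactors = FALSE)
      }
    }
    structure(list(auc = aucs,
                   metrics = as.data.frame(do.call(rbind, mets)),
                   scores = do.call(rbind, scs),
                   family = spec$family),
              class = "cv_result")
  })
  out
}

#' Single-feature classification AUC
#'
#' AUC of one raw feature used directly as the score, oriented so the
#' reported AUC is >= 0.5; the orientation is returned alongside.
#'
#' @param fmatrix feature matrix with a `label` column.
#' @param feature feature column name.
#' @return list(auc, direction) where direction is +1 (higher = cancer) or
#'   -1 (lower = cancer).
#' @export
single_feature_auc <- function(fmatrix, feature) {
  if (!feature %in% names(fmatrix))
    stop("input error: unknown feature ", feature)
  a <- auc(fmatrix[[feature]], fmatrix$label)
  if (a >= 0.5) list(auc = a, direction = 1) else list(auc = 1 - a, direction = -1)
}

# k-means++ seeding: spread initial centers with distance-proportional draws
.kmpp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2L:k) {
    pick <- if (all(d2 == 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' k-means clustering of the feature matrix
#'
#' Lloyd's algorithm with k-means++ initialisation, 10 restarts, best
#' within-cluster sum of squares kept; features are z-scored first.
#'
#' @param fmatrix feature matrix (with label column for the composition).
#' @param k number of clusters (default 2).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (default 10).
#' @return list(assignments, composition (per-cluster size and cancer
#'   fraction), tot_withinss).
#' @export
cluster_kmeans <- function(fmatrix, k = 2L, seed = 1L, restarts = 10L) {
  meta <- intersect(c("sample_id", "patient_id", "label", "timepoint"),
                    names(fmatrix))
  x <- scale(as.matrix(fmatrix[, setdiff(names(fmatrix), meta), drop = FALSE]))
  x <- x[, !apply(x, 2, anyNA), drop = FALSE]
  if (k > nrow(x)) stop("input error: k exceeds number of samples")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(derive_seed(seed, paste0("kmeans/", r)), {
      cen <- .kmpp_centers(x, k)
      suppressWarnings(stats::kmeans(x, centers = cen, iter.max = 100L,
                                     algorithm = "Lloyd"))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  comp <- do.call(rbind, lapply(seq_len(k), function(j) {
    idx <- best$cluster == j
    data.frame(cluster = j, n = sum(idx),
               n_cancer = sum(fmatrix$label[idx] == "cancer"),
               cancer_fraction = mean(fmatrix$label[idx] == "cancer"))
  }))
  list(assignments = best$cluster, composition = comp,
       tot_withinss = best$tot.withinss)
}

#' PCA summary of the feature matrix
#'
#' Principal components of the z-scored features; reporting only.
#'
#' @param fmatrix feature matrix.
#' @return list(variance_explained, loadings, scores).
#' @export
pca_summary <- function(fmatrix) {
  meta <- intersect(c("sample_id", "patient_id", "label", "timepoint"),
                    names(fmatrix))
  x <- as.matrix(fmatrix[, setdiff(names(fmatrix), meta), drop = FALSE])
  if (nrow(x) < 3L) stop("input error: need >= 3 samples")
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) stop("input error: all features have zero variance")
  x <- x[, sds > 0, drop = FALSE]
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  list(variance_explained = p$sdev^2 / sum(p$sdev^2),
       loadings = p$rotation, scores = p$x)
}
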