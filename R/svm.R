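#' Classification protocol: bootstrap, split, RBF-SVM search and evaluation
#'
#' The protocol is: (optionally bootstrap-augment), split 70:30 stratified by
#' class, tune an RBF-kernel soft-margin SVM by random search over (cost,
#' gamma) scored by 10-fold cross-validated balanced accuracy, train the final
#' model, and evaluate it on the held-out test set with the full
#' confusion-matrix battery (Cohen's kappa, macro sensitivity/specificity,
#' balanced accuracy, exact binomial CI, and the squared-error loss on
#' integer-encoded labels).
#'
#' @name svm_protocol
NULL

# Largest-remainder allocation of `total` among groups with weights `w`.
allocate_counts <- function(w, total) {
  raw <- w / sum(w) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified bootstrap resampling
#'
#' Samples rows with replacement within each class so the output class
#' proportions match the input proportions to rounding. Used to augment the
#' small study sample (default n_out = 1000) before model tuning.
#'
#' @param x numeric feature matrix.
#' @param y class labels, length nrow(x); every class must be non-empty.
#' @param n_out number of output rows.
#' @param seed optional integer seed (deterministic output when given).
#' @return list with \code{x}, \code{y} of size \code{n_out}, and
#'   \code{origin}: for each output row, the index of the input row it copies
#'   (used downstream to keep duplicates of one specimen inside a single
#'   cross-validation fold).
#' @export
stratified_bootstrap <- function(x, y, n_out = 1000L, seed = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  classes <- sort(unique(y))
  if (any(!nzchar(classes)) || length(classes) == 0L ||
      any(table(y) == 0L)) stop("every class must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  counts <- allocate_counts(as.numeric(table(factor(y, classes))), n_out)
  idx <- unlist(lapply(seq_along(classes), function(i) {
    pool <- which(y == classes[i])
    pool[sample.int(length(pool), counts[i], replace = TRUE)]
  }))
  idx <- idx[sample.int(length(idx))]
  list(x = x[idx, , drop = FALSE], y = y[idx], origin = idx)
}

#' Stratified train/test split
#'
#' @param x numeric feature matrix.
#' @param y class labels; every class needs >= 2 members.
#' @param train_fraction fraction of rows in the training partition
#'   (|train| = round(train_fraction * n), stratified so each class's train
#'   fraction is within one sample of the target).
#' @param seed optional integer seed.
#' @return list with \code{train} and \code{test}, each a list
#'   (\code{x}, \code{y}, \code{idx}); the index sets are disjoint and their
#'   union is the input.
#' @export
train_test_split <- function(x, y, train_fraction = 0.70, seed = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  classes <- sort(unique(y))
  if (any(table(y) < 2L))
    stop("every class needs at least 2 members to be split")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  n_train <- round(train_fraction * n)
  per_class <- allocate_counts(as.numeric(table(factor(y, classes))), n_train)
  train_idx <- unlist(lapply(seq_along(classes), function(i) {
    pool <- which(y == classes[i])
    pool[sample.int(length(pool))][seq_len(min(per_class[i],
                                               length(pool) - 1L))]
  }))
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = list(x = x[train_idx, , drop = FALSE], y = y[train_idx],
                    idx = train_idx),
       test = list(x = x[test_idx, , drop = FALSE], y = y[test_idx],
                   idx = test_idx))
}

#' Gaussian radial-basis-function kernel
#'
#' \code{exp(-gamma * ||u - v||^2)}, the kernel that maps the input vectors
#' into the SVM's non-linear feature space.
#'
#' @param u,v numeric vectors of equal length.
#' @param gamma positive kernel width parameter.
#' @return scalar in (0, 1].
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((u - v)^2))
}

# Mean per-class recall over the classes present in y_true.
balanced_accuracy <- function(y_true, y_pred) {
  cls <- sort(unique(y_true))
  mean(vapply(cls, function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1)))
}

#' Random hyperparameter search for the RBF SVM
#'
#' Samples \code{n_iter} (cost, gamma) pairs log-uniformly from the given
#' ranges and scores each by mean balanced accuracy over stratified k-fold
#' cross-validation on the training set, returning the first-encountered
#' maximiser. The default ranges [1e-2, 1e3] x [1e-2, 1e3] are wide enough to
#' contain typical optima for both metric and PC-score inputs.
#'
#' When the training set was bootstrap-augmented, pass the bootstrap's
#' \code{origin} vector as \code{groups}: fold assignment is then done at the
#' level of originating specimens, so duplicated copies of one specimen never
#' straddle a fold boundary. Without this, memorising hyperparameter settings
#' (very large gamma and cost) score perfectly in cross-validation on
#' duplicated rows and the search loses its ability to rank configurations.
#'
#' @param x training feature matrix.
#' @param y training labels (all classes present; k must not exceed the
#'   smallest class count).
#' @param n_iter number of random search iterations (default 50).
#' @param k number of cross-validation folds (default 10).
#' @param cost_range,gamma_range length-2 positive ranges sampled
#'   log-uniformly.
#' @param seed optional integer seed.
#' @param groups optional vector, one entry per row of \code{x}; rows sharing
#'   a group value are assigned to the same fold.
#' @param scale_features standardise feature columns inside each fit (the
#'   libsvm convention). Appropriate for mixed-unit measurement features;
#'   set FALSE for PC-score inputs, which are already on a common scale and
#'   whose trailing near-zero-variance columns must not be amplified.
#' @return object of class \code{svm_config}: list with \code{cost},
#'   \code{gamma}, \code{cv_balanced_accuracy}, \code{n_iter}, \code{k}.
#' @export
random_search_svm <- function(x, y, n_iter = 50L, k = 10L,
                              cost_range = c(1e-2, 1e3),
                              gamma_range = c(1e-2, 1e3),
                              seed = NULL, groups = NULL,
                              scale_features = TRUE) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (n_iter < 1L) stop("n_iter must be at least 1")
  if (is.null(groups)) groups <- seq_along(y)
  if (length(groups) != length(y)) stop("groups must match rows of x")
  grp_class <- tapply(y, groups, function(v) v[1])
  min_class <- min(table(grp_class))
  if (k > min_class)
    stop("k = ", k, " exceeds the smallest per-class count of distinct ",
         "training specimens (", min_class,
         "); reduce k or enlarge the training sample")
  if (!is.null(seed)) set.seed(seed)
  costs <- exp(stats::runif(n_iter, log(cost_range[1]), log(cost_range[2])))
  gammas <- exp(stats::runif(n_iter, log(gamma_range[1]), log(gamma_range[2])))

  # stratified fold assignment at specimen (group) level
  grp_fold <- integer(length(grp_class))
  names(grp_fold) <- names(grp_class)
  for (cl in sort(unique(grp_class))) {
    pool <- which(grp_class == cl)
    grp_fold[pool[sample.int(length(pool))]] <-
      rep_len(seq_len(k), length(pool))
  }
  fold <- grp_fold[as.character(groups)]
  cv_score <- function(cost, gamma) {
    accs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]),
                        type = "C-classification", kernel = "radial",
                        cost = cost, gamma = gamma, scale = scale_features)
      pred <- as.character(stats::predict(fit, x[!tr, , drop = FALSE]))
      balanced_accuracy(y[!tr], pred)
    }, numeric(1))
    mean(accs)
  }
  best <- -Inf
  best_i <- 1L
  scores <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    scores[i] <- cv_score(costs[i], gammas[i])
    if (scores[i] > best) { best <- scores[i]; best_i <- i }
  }
  structure(list(cost = costs[best_i], gamma = gammas[best_i],
                 cv_balanced_accuracy = best, n_iter = n_iter, k = k),
            class = "svm_config")
}

#' @export
print.svm_config <- function(x, ...) {
  cat("SVM config: cost = ", format(x$cost, digits = 5), ", gamma = ",
      format(x$gamma, digits = 5), " (CV balanced accuracy ",
      round(x$cv_balanced_accuracy, 4), " over ", x$k, " folds, ",
      x$n_iter, " search iterations)\n", sep = "")
  invisible(x)
}

#' Train the final RBF-kernel SVM
#'
#' Soft-margin C-classification SVM with the radial kernel; multiclass
#' handling is the standard one-vs-one scheme.
#'
#' @param x training feature matrix (>= 2 classes).
#' @param y training labels.
#' @param config an \code{svm_config} (or any list with \code{cost} and
#'   \code{gamma}).
#' @param scale_features standardise feature columns inside the fit; match
#'   the setting used during the hyperparameter search.
#' @return a fitted model exposing \code{predict}; the config is attached as
#'   attribute \code{"config"}.
#' @export
train_svm <- function(x, y, config, scale_features = TRUE) {
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("training set contains a single class")
  if (config$cost <= 0 || config$gamma <= 0)
    stop("cost and gamma must be positive")
  fit <- e1071::svm(as.matrix(x), y, type = "C-classification",
                    kernel = "radial", cost = config$cost,
                    gamma = config$gamma, scale = scale_features)
  attr(fit, "config") <- config
  fit
}

#' Evaluate a trained classifier on a test set
#'
#' Builds the confusion matrix in fixed alphabetical label order (for the
#' study protocol: dog = 0, fox = 1, wolf = 2) and derives the evaluation
#' battery: Cohen's kappa, macro-averaged sensitivity TP/(TP+FN) and
#' specificity TN/(TN+FP), balanced accuracy (mean per-class recall), the
#' exact Clopper-Pearson 95\% CI on the proportion correct, and the global
#' mean squared error of the integer-coded local errors E = i - x (true code
#' minus predicted code). A perfectly classified test set gives kappa =
#' sensitivity = specificity = balanced accuracy = 1 and MSE = 0.
#'
#' @param model a model from \code{\link{train_svm}}.
#' @param x_test,y_test held-out features and labels; test labels must be a
#'   subset of the training labels.
#' @return object of class \code{classification_report}.
#' @export
evaluate_classifier <- function(model, x_test, y_test) {
  y_test <- as.character(y_test)
  if (length(y_test) == 0L) stop("empty test set")
  lev <- sort(model$levels)
  unseen <- setdiff(unique(y_test), lev)
  if (length(unseen))
    stop("test labels not seen in training: ", paste(unseen, collapse = ", "))
  pred <- as.character(stats::predict(model, as.matrix(x_test)))
  report <- classification_metrics(y_test, pred, levels = lev)
  report$config <- attr(model, "config")
  report
}

#' Classification metrics from true and predicted labels
#'
#' The metric battery underlying \code{\link{evaluate_classifier}}, exposed
#' directly so any classifier's predictions can be scored.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param levels label universe fixing the confusion-matrix order (default:
#'   sorted union of the observed labels; the study protocol's alphabetical
#'   order gives dog = 0, fox = 1, wolf = 2 integer codes).
#' @return a \code{classification_report} (without a hyperparameter config).
#' @export
classification_metrics <- function(y_true, y_pred,
                                   levels = sort(unique(c(y_true, y_pred)))) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  lev <- levels
  tr <- factor(y_true, levels = lev)
  pr <- factor(y_pred, levels = lev)
  confusion <- table(true = tr, predicted = pr)
  n <- length(y_true)
  y_test <- y_true
  pred <- y_pred

  diag_sum <- sum(diag(confusion))
  po <- diag_sum / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)

  sens <- spec <- numeric(length(lev))
  for (i in seq_along(lev)) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, -i])
    fp <- sum(confusion[-i, i])
    tn <- n - tp - fn - fp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  bal_acc <- mean(sens, na.rm = TRUE)
  ci <- stats::binom.test(diag_sum, n)$conf.int

  codes <- stats::setNames(seq_along(lev) - 1L, lev)
  e <- codes[y_test] - codes[pred]
  mse <- mean(e^2)

  structure(list(confusion = confusion,
                 kappa = kappa,
                 sensitivity = mean(sens, na.rm = TRUE),
                 specificity = mean(spec, na.rm = TRUE),
                 balanced_accuracy = bal_acc,
                 accuracy = po,
                 ci_low = ci[1], ci_high = ci[2],
                 mse = unname(mse),
                 n_test = n,
                 labels = lev,
                 powerful = kappa > 0.8,
                 config = NULL),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (n_test = ", x$n_test, ")\n", sep = "")
  print(x$confusion)
  cat(sprintf(paste0("kappa %.4f | sensitivity %.4f | specificity %.4f | ",
                     "balanced accuracy %.4f\n"),
              x$kappa, x$sensitivity, x$specificity, x$balanced_accuracy))
  cat(sprintf("accuracy %.4f [%.4f, %.4f] | MSE %.6g | powerful: %s\n",
              x$accuracy, x$ci_low, x$ci_high, x$mse,
              if (isTRUE(x$powerful)) "yes (kappa > 0.8)" else "no"))
  invisible(x)
}

#' Microbenchmark SVM training time
#'
#' Repeats the final-model training and reports the mean wall-clock time in
#' milliseconds. Timing is hardware-dependent and is reported, never compared
#' against published values.
#'
#' @param x,y training data.
#' @param config an \code{svm_config}.
#' @param n_rep number of repetitions (the study protocol uses 200).
#' @return mean milliseconds, with the individual timings attached as
#'   attribute \code{"times_ms"}.
#' @export
benchmark_training <- function(x, y, config, n_rep = 200L) {
  if (n_rep < 1L) stop("n_rep must be at least 1")
  times <- vapply(seq_len(n_rep), function(i) {
    t0 <- proc.time()[["elapsed"]]
    train_svm(x, y, config)
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  structure(mean(times), times_ms = times)
}
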