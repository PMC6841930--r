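#' Configuration for the full four-view analysis protocol
#'
#' The study analyses four data views: the score cross-section measurements
#' with and without the opening angle, shape-space PC scores of the
#' GPA-aligned score cross-sections, and form-space PC scores of the
#' GPA-aligned pits (shape is used for scores and form for pits). Each view is
#' run through pairwise MANOVA (dog vs wolf, dog vs fox) and the SVM
#' classification protocol.
#'
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it, so identical configurations give byte-identical results.
#' @param spec a \code{\link{simulation_spec}} (defaults to the reference
#'   study sample sizes); ignored when \code{data} is supplied.
#' @param data optional list with \code{pits} and \code{scores} landmark
#'   datasets to analyse instead of simulated ones.
#' @param views character subset of \code{c("with_oa", "without_oa",
#'   "scores_shape", "pits_form")}; at least one.
#' @param train_fraction,folds,search_iter,bootstrap_n SVM protocol
#'   parameters (defaults 0.70, 10, 50, 1000).
#' @param paper_order when TRUE, bootstrap the full sample before splitting
#'   (the literal published order); the default FALSE splits first and
#'   bootstraps only the training partition, which cannot leak duplicated
#'   rows into the test set.
#' @param form_units centroid-size unit multiplier for form space (1000 =
#'   treat millimetre input as micrometres so all log centroid sizes are
#'   positive).
#' @param benchmark when TRUE, microbenchmark the final training of each view
#'   (200 repetitions) and include mean milliseconds in the reports. Off by
#'   default so repeated runs are byte-identical.
#' @param manova_groups list of length-2 character vectors of group pairs.
#' @return object of class \code{protocol_config}.
#' @export
protocol_config <- function(seed = 1L,
                            spec = NULL,
                            data = NULL,
                            views = c("with_oa", "without_oa",
                                      "scores_shape", "pits_form"),
                            train_fraction = 0.70,
                            folds = 10L,
                            search_iter = 50L,
                            bootstrap_n = 1000L,
                            paper_order = FALSE,
                            form_units = 1000,
                            benchmark = FALSE,
                            manova_groups = list(c("dog", "wolf"),
                                                 c("dog", "fox"))) {
  if (length(views) == 0L) stop("at least one analysis view must be enabled")
  views <- match.arg(views, several.ok = TRUE)
  if (is.null(spec)) spec <- simulation_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), spec = spec, data = data,
                 views = views, train_fraction = train_fraction,
                 folds = as.integer(folds),
                 search_iter = as.integer(search_iter),
                 bootstrap_n = as.integer(bootstrap_n),
                 paper_order = isTRUE(paper_order),
                 form_units = form_units, benchmark = isTRUE(benchmark),
                 manova_groups = manova_groups),
            class = "protocol_config")
}

# Assemble the feature matrix, labels and PC scores for one analysis view.
build_view <- function(view, scores_ds, pits_ds, form_units) {
  switch(view,
    with_oa = {
      tab <- measurement_table(scores_ds, include_oa = TRUE)
      list(x = tab$values, y = tab$labels,
           pc = gm_pca(tab$values), pc_mode = "form")
    },
    without_oa = {
      tab <- measurement_table(scores_ds, include_oa = FALSE)
      list(x = tab$values, y = tab$labels,
           pc = gm_pca(tab$values), pc_mode = "form")
    },
    scores_shape = {
      g <- gpa(scores_ds)
      p <- gm_pca(g$tangent)
      m <- count_pc_scores(p, "shape")
      list(x = p$scores[, seq_len(m), drop = FALSE], y = g$labels,
           pc = p, pc_mode = "shape", gpa = g)
    },
    pits_form = {
      g <- gpa(pits_ds)
      fm <- to_form_space(g, units = form_units)
      p <- gm_pca(fm)
      list(x = p$scores, y = g$labels, pc = p, pc_mode = "form", gpa = g)
    },
    stop("unknown view: ", view))
}

#' Run the full analysis protocol
#'
#' Executes every enabled view end to end: feature construction (measurement
#' table or GPA + PCA), stratified 70:30 split, stratified bootstrap
#' augmentation of the training partition (or of the full sample first under
#' \code{paper_order}), cross-validated random hyperparameter search, final
#' SVM training and held-out evaluation, plus pairwise MANOVAs on the view's
#' PC scores.
#'
#' @param config a \code{\link{protocol_config}}.
#' @return object of class \code{report_bundle}: list with
#'   \code{reports} (one \code{classification_report} per view),
#'   \code{manova} (one \code{manova_result} per view x group pair),
#'   \code{pca} (per-view PC bookkeeping), and \code{config}.
#' @export
run_protocol <- function(config) {
  if (!inherits(config, "protocol_config"))
    stop("config must come from protocol_config()")
  if (!is.null(config$data)) {
    pits_ds <- config$data$pits
    scores_ds <- config$data$scores
  } else {
    sample_data <- simulate_reference_sample(config$seed, config$spec)
    pits_ds <- sample_data$pits
    scores_ds <- sample_data$scores
  }
  need_pits <- "pits_form" %in% config$views
  if (need_pits && is.null(pits_ds)) stop("stage pits_form: no pit data")
  if (any(config$views != "pits_form") && is.null(scores_ds))
    stop("stage measurements/scores: no score data")

  reports <- list()
  manovas <- list()
  pca_summaries <- list()
  for (i in seq_along(config$views)) {
    view <- config$views[i]
    vd <- tryCatch(build_view(view, scores_ds, pits_ds, config$form_units),
                   error = function(e)
                     stop("stage ", view, " (features): ",
                          conditionMessage(e)))
    seed_base <- config$seed + 100L * i
    if (config$paper_order) {
      boot <- stratified_bootstrap(vd$x, vd$y, config$bootstrap_n,
                                   seed = seed_base + 1L)
      split <- train_test_split(boot$x, boot$y, config$train_fraction,
                                seed = seed_base + 2L)
      train <- split$train
      train_groups <- boot$origin[split$train$idx]
    } else {
      split <- train_test_split(vd$x, vd$y, config$train_fraction,
                                seed = seed_base + 2L)
      boot <- stratified_bootstrap(split$train$x, split$train$y,
                                   config$bootstrap_n, seed = seed_base + 1L)
      train <- boot
      train_groups <- boot$origin
    }
    # measurement features mix units (mm, degrees) and are standardised
    # inside the SVM; PC scores are already commensurate and must not have
    # their trailing near-zero-variance columns amplified
    scale_features <- view %in% c("with_oa", "without_oa")
    tuned <- random_search_svm(train$x, train$y,
                               n_iter = config$search_iter,
                               k = config$folds, seed = seed_base + 3L,
                               groups = train_groups,
                               scale_features = scale_features)
    model <- train_svm(train$x, train$y, tuned,
                       scale_features = scale_features)
    report <- evaluate_classifier(model, split$test$x, split$test$y)
    if (config$benchmark)
      report$training_time_ms <-
        as.numeric(benchmark_training(train$x, train$y, tuned, 200L))
    reports[[view]] <- report

    for (pair in config$manova_groups) {
      key <- paste0(view, ".", pair[1], "_vs_", pair[2])
      manovas[[key]] <- manova_pairwise(vd$pc$scores, vd$y, pair[1], pair[2])
    }
    pca_summaries[[view]] <- list(
      n_scores = count_pc_scores(vd$pc, vd$pc_mode),
      mode = vd$pc_mode,
      explained_first_two =
        sum(vd$pc$explained[seq_len(min(2, length(vd$pc$explained)))]))
  }
  structure(list(reports = reports, manova = manovas, pca = pca_summaries,
                 config = config),
            class = "report_bundle")
}

report_rows <- c("Optimal Cost", "Optimal Gamma", "Kappa", "Accuracy",
                 "Lower CI", "Upper CI", "MSE", "Sensitivity", "Specificity")

#' Render a report bundle to JSON and text
#'
#' Writes \code{report.json} (the full bundle) and \code{summary.txt} (a
#' table of the classical evaluation rows -- Optimal Cost, Optimal Gamma,
#' Kappa, Accuracy, Lower/Upper CI, MSE, Sensitivity, Specificity, plus
#' Training Time (ms) when benchmarking was enabled -- with one column per
#' view, and the pairwise MANOVA p-values). Rendering is pure: the same
#' bundle always produces identical files.
#'
#' @param bundle a \code{report_bundle} from \code{\link{run_protocol}}.
#' @param dir output directory (created if absent).
#' @return invisibly, character vector of the paths written.
#' @export
render_report <- function(bundle, dir) {
  if (!inherits(bundle, "report_bundle"))
    stop("bundle must come from run_protocol()")
  missing_parts <- setdiff(bundle$config$views, names(bundle$reports))
  if (length(missing_parts))
    stop("incomplete bundle; missing analyses: ",
         paste(missing_parts, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  views <- names(bundle$reports)
  val <- function(r) c(r$config$cost, r$config$gamma, r$kappa,
                       r$balanced_accuracy, r$ci_low, r$ci_high, r$mse,
                       r$sensitivity, r$specificity)
  tab <- vapply(bundle$reports, val, numeric(length(report_rows)))
  rownames(tab) <- report_rows
  timed <- vapply(bundle$reports, function(r)
    !is.null(r$training_time_ms), logical(1))
  if (all(timed))
    tab <- rbind(tab, "Training Time (ms)" =
                   vapply(bundle$reports, function(r)
                     r$training_time_ms, numeric(1)))

  txt <- c("Support vector machine evaluation metrics by data view", "",
           utils::capture.output(print(round(tab, 4))), "",
           "Pairwise MANOVA (p-values)")
  for (key in names(bundle$manova)) {
    m <- bundle$manova[[key]]
    txt <- c(txt, sprintf("  %-40s %-16s p = %s", key, m$statistic_name,
                          format.pval(m$p_value, digits = 3)))
  }
  txt <- c(txt, "", "PC score bookkeeping")
  for (v in names(bundle$pca))
    txt <- c(txt, sprintf("  %-14s %s space: %d PC scores", v,
                          bundle$pca[[v]]$mode, bundle$pca[[v]]$n_scores))

  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "summary.txt")
  jsonlite::write_json(serialize_bundle(bundle), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(txt, txt_path)
  invisible(c(json_path, txt_path))
}

serialize_bundle <- function(bundle) {
  list(
    seed = bundle$config$seed,
    views = lapply(bundle$reports, function(r) {
      out <- list(optimal_cost = r$config$cost,
                  optimal_gamma = r$config$gamma,
                  kappa = r$kappa,
                  accuracy = r$balanced_accuracy,
                  lower_ci = r$ci_low, upper_ci = r$ci_high,
                  mse = r$mse,
                  sensitivity = r$sensitivity,
                  specificity = r$specificity,
                  n_test = r$n_test,
                  confusion = unclass(as.matrix(r$confusion)),
                  labels = r$labels)
      if (!is.null(r$training_time_ms))
        out$training_time_ms <- r$training_time_ms
      out
    }),
    manova = lapply(bundle$manova, function(m)
      list(statistic = m$statistic_name, value = m$statistic,
           F = m$F_approx, df = as.list(m$df), p_value = m$p_value,
           homogeneity_p = m$homogeneity_p,
           n_components = m$n_components)),
    pca = bundle$pca)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Protocol report bundle:", length(x$reports), "classification views,",
      length(x$manova), "MANOVA comparisons\n")
  for (v in names(x$reports))
    cat(sprintf("  %-14s balanced accuracy %.3f, kappa %.3f (n_test %d)\n",
                v, x$reports[[v]]$balanced_accuracy, x$reports[[v]]$kappa,
                x$reports[[v]]$n_test))
  invisible(x)
}
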