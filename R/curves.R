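#' Classification problem definitions
#'
#' Parses problem names of the form `"ABCD/E"` — groups of Bonn class
#' letters separated by slashes — into label maps.  The study's five
#' standard sub-problems are the default: `ABCD/E`, `AB/CD/E`, `A/D/E`,
#' `A/E`, `D/E` (three binary and two three-class problems, seizure class
#' `E` always present).
#'
#' @param names Character vector of problem names.
#' @return List of `problem_def` objects, each with `name`, `groups`
#'   (character vector of group names) and `map` (named vector from class
#'   tag to group name).
#' @examples
#' problem_definitions("A/E")[[1]]$map
#' @export
problem_definitions <- function(names = c("ABCD/E", "AB/CD/E", "A/D/E",
                                          "A/E", "D/E")) {
  lapply(names, function(nm) {
    groups <- strsplit(nm, "/", fixed = TRUE)[[1]]
    if (length(groups) < 2L)
      stop("problem ", nm, ": need at least two groups")
    tags <- strsplit(groups, "")
    map <- stats::setNames(rep(groups, lengths(tags)), unlist(tags))
    if (anyDuplicated(names(map)))
      stop("problem ", nm, ": class appears in more than one group")
    structure(list(name = nm, groups = groups, map = map),
              class = "problem_def")
  })
}

# map raw labels onto a problem's groups; classes outside the problem -> NA
apply_problem <- function(labels, problem) {
  m <- problem$map[as.character(labels)]
  factor(unname(m), levels = problem$groups)
}

#' Accuracy versus number of top-ranked features
#'
#' Evaluates [nested_cv_accuracy()] on the top-`n` ranked features for
#' `n = 1..n_max`, locating the optimal point: the smallest `n` attaining
#' the maximum accuracy.  Two ranking modes are available:
#'
#' * `"global"` — the supplied ranking (computed once on the full matrix)
#'   orders features for every fold.  This mirrors a single published
#'   feature ranking but lets the ranking see test folds.
#' * `"foldwise"` — features are re-ranked with ReliefF inside each outer
#'   training fold, so feature selection never sees the held-out fold
#'   (leakage-safe).  The per-fold rankings are returned for inspection.
#'
#' @param x Feature matrix/data frame (see [nested_cv_accuracy()]).
#' @param labels Class labels.
#' @param classifier A [classifier_spec()] or kind string.
#' @param ranking A [relieff_rank()] result covering all feature columns
#'   (required for `"global"`, ignored for `"foldwise"`).
#' @param seed Integer seed.
#' @param n_max Longest feature prefix evaluated (default: all features).
#' @param ranking_mode `"global"` or `"foldwise"`.
#' @param outer_folds,inner_folds Fold counts.
#' @param k_neighbors ReliefF neighbours for foldwise re-ranking.
#' @return Object of class `evaluation_curve`: `accuracy` (vector indexed
#'   by `n`), `optimal_n`, `optimal_accuracy`, `all_features_accuracy`,
#'   `classifier`, and (foldwise) `fold_rankings`.
#' @export
sequential_curve <- function(x, labels, classifier = "svm_linear",
                             ranking = NULL, seed = 0, n_max = NULL,
                             ranking_mode = c("global", "foldwise"),
                             outer_folds = 10, inner_folds = 10,
                             k_neighbors = 10) {
  ranking_mode <- match.arg(ranking_mode)
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  xm <- feature_columns(x)
  labels <- droplevels(factor(labels))
  nf <- ncol(xm)
  n_max <- min(n_max %||% nf, nf)
  fold_rankings <- NULL
  if (ranking_mode == "global") {
    if (is.null(ranking))
      stop("sequential_curve: global mode needs a feature ranking")
    if (!all(colnames(xm) %in% ranking$order))
      stop("sequential_curve: ranking does not cover all features")
    acc <- vapply(seq_len(n_max), function(n)
      as.numeric(nested_cv_accuracy(xm, labels, classifier,
                                    feature_subset = top_n(ranking, n),
                                    seed = seed, outer_folds = outer_folds,
                                    inner_folds = inner_folds)),
      numeric(1))
  } else {
    folds <- stratified_folds(labels, outer_folds, derive_seed(seed, 1))
    fold_rankings <- vector("list", length(folds))
    fold_acc <- matrix(NA_real_, length(folds), n_max)
    for (f in seq_along(folds)) {
      te <- folds[[f]]
      tr <- setdiff(seq_len(nrow(xm)), te)
      rk <- relieff_rank(xm[tr, , drop = FALSE], labels[tr],
                         k_neighbors = k_neighbors)
      fold_rankings[[f]] <- rk
      for (n in seq_len(n_max)) {
        sub <- top_n(rk, n)
        g <- select_grid_point(classifier,
                               xm[tr, sub, drop = FALSE], labels[tr],
                               inner_folds, derive_seed(seed, 2, f))
        sc <- fit_scaler(xm[tr, sub, drop = FALSE])
        model <- fit_classifier(classifier$kind,
                                classifier$grid[g, , drop = FALSE],
                                apply_scaler(xm[tr, sub, drop = FALSE], sc),
                                labels[tr], seed = derive_seed(seed, 3, f, n))
        pred <- predict_classifier(model,
                                   apply_scaler(xm[te, sub, drop = FALSE], sc))
        fold_acc[f, n] <- mean(pred == labels[te])
      }
    }
    acc <- 100 * colMeans(fold_acc)
  }
  all_feat <- if (n_max == nf) acc[nf]
              else as.numeric(nested_cv_accuracy(
                xm, labels, classifier, seed = seed,
                outer_folds = outer_folds, inner_folds = inner_folds))
  opt_n <- which.max(acc)            # first max = smallest n attaining it
  structure(list(accuracy = acc,
                 optimal_n = opt_n,
                 optimal_accuracy = acc[opt_n],
                 all_features_accuracy = all_feat,
                 classifier = classifier$kind,
                 ranking_mode = ranking_mode,
                 fold_rankings = fold_rankings),
            class = "evaluation_curve")
}

#' @export
print.evaluation_curve <- function(x, ...) {
  cat(sprintf("<evaluation_curve> %s (%s ranking)\n", x$classifier,
              x$ranking_mode))
  cat(sprintf("  optimal: %.2f%% with %d feature(s); all features: %.2f%%\n",
              x$optimal_accuracy, x$optimal_n, x$all_features_accuracy))
  invisible(x)
}

#' @export
plot.evaluation_curve <- function(x, ...) {
  graphics::plot(seq_along(x$accuracy), x$accuracy, type = "b",
                 xlab = "Number of top-ranked features",
                 ylab = "Accuracy (%)",
                 main = sprintf("%s (%s ranking)", x$classifier,
                                x$ranking_mode), ...)
  graphics::points(x$optimal_n, x$optimal_accuracy, pch = 19,
                   col = "red")
  invisible(x)
}

#' Evaluate all problems against all classifiers
#'
#' For each classification problem, restricts the feature matrix to the
#' problem's classes, ranks the 30 features with ReliefF on that subset,
#' and computes a [sequential_curve()] per classifier.  The report mirrors
#' the study's two summary tables: the five top-ranked features per
#' problem, and per problem/classifier the optimal accuracy (with its
#' feature count) next to the all-features (no-selection) accuracy.
#'
#' @param features A feature data frame from [extract_feature_matrix()]
#'   (must contain a `label` column).
#' @param problems List from [problem_definitions()].
#' @param classifiers Character vector of kinds or list of
#'   [classifier_spec()]s.
#' @param ranking_mode `"global"` or `"foldwise"` (see
#'   [sequential_curve()]).
#' @param seed Integer seed.
#' @param k_neighbors ReliefF neighbour count.
#' @param n_max,outer_folds,inner_folds Passed to [sequential_curve()].
#' @return Object of class `suite_report`: per-problem rankings, curves
#'   indexed `[[problem]][[classifier]]`, and a `summary` data frame.
#' @export
run_problem_suite <- function(features, problems = problem_definitions(),
                              classifiers = c("mlp", "svm_linear",
                                              "svm_rbf"),
                              ranking_mode = c("global", "foldwise"),
                              seed = 0, k_neighbors = 10, n_max = NULL,
                              outer_folds = 10, inner_folds = 10) {
  ranking_mode <- match.arg(ranking_mode)
  stopifnot(is.data.frame(features), "label" %in% colnames(features))
  classifiers <- lapply(classifiers, function(cl)
    if (is.character(cl)) classifier_spec(cl) else cl)
  cl_names <- vapply(classifiers, `[[`, "", "kind")
  rankings <- list(); curves <- list(); rows <- list()
  for (pr in problems) {
    y_all <- apply_problem(features$label, pr)
    keep <- !is.na(y_all)
    sub <- features[keep, , drop = FALSE]
    y <- droplevels(y_all[keep])
    rk <- relieff_rank(feature_columns(sub), y, k_neighbors = k_neighbors)
    rankings[[pr$name]] <- rk
    curves[[pr$name]] <- list()
    for (i in seq_along(classifiers)) {
      cv <- sequential_curve(sub, y, classifiers[[i]], ranking = rk,
                             seed = derive_seed(seed, i),
                             n_max = n_max, ranking_mode = ranking_mode,
                             outer_folds = outer_folds,
                             inner_folds = inner_folds,
                             k_neighbors = k_neighbors)
      curves[[pr$name]][[cl_names[i]]] <- cv
      rows[[length(rows) + 1L]] <- data.frame(
        problem = pr$name, classifier = cl_names[i],
        accuracy_with_selection = cv$optimal_accuracy,
        n_features = cv$optimal_n,
        accuracy_without_selection = cv$all_features_accuracy,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(rankings = rankings,
                 curves = curves,
                 top5 = lapply(rankings, function(r)
                   utils::head(r$order, 5L)),
                 summary = do.call(rbind, rows),
                 ranking_mode = ranking_mode,
                 seed = seed),
            class = "suite_report")
}

#' @export
print.suite_report <- function(x, ...) {
  cat("<suite_report>", length(x$rankings), "problem(s),",
      length(x$curves[[1]]), "classifier(s),", x$ranking_mode,
      "ranking\n\nTop-5 features per problem:\n")
  for (nm in names(x$top5))
    cat(sprintf("  %-8s %s\n", nm, paste(x$top5[[nm]], collapse = ", ")))
  cat("\nAccuracy with (n features) / without selection:\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %-11s %6.2f%% (%d)  /  %6.2f%%\n",
                s$problem[i], s$classifier[i],
                s$accuracy_with_selection[i], s$n_features[i],
                s$accuracy_without_selection[i]))
  invisible(x)
}
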