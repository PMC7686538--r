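## Split metadata columns from feature columns of a feature table.
feature_matrix <- function(features) {
  meta <- intersect(c("subject", "population"), names(features))
  x <- features[, setdiff(names(features), meta), drop = FALSE]
  if (ncol(x) == 0) abort("no feature columns found")
  as.data.frame(x, check.names = FALSE)
}

## Stratified fold assignment: within each class, shuffled subjects are
## dealt to folds round-robin, so fold class balance is as even as possible.
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds) {
        abort(sprintf("class '%s' has %d subjects; %d needed for %d-fold stratified CV",
                      cl, length(idx), n_folds, n_folds))
      }
      folds[idx] <- (sample(seq_along(idx)) %% n_folds) + 1L
    }
  })
  folds
}

rf_fit <- function(x, labels, n_trees, seed) {
  df <- data.frame(x, check.names = FALSE)
  df[[".label"]] <- factor(labels)
  ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, importance = "impurity",
    num.threads = 1, seed = seed
  )
}

#' Cross-validated random-forest accuracy and feature importances
#'
#' Fits a 500-tree random forest under stratified 10-fold cross-validation
#' (the classifier and protocol used throughout the pipeline) and returns
#' the mean held-out accuracy together with importances — mean impurity
#' decrease, normalized to sum to 1 — from a forest fit on all rows.
#'
#' @param features Feature table restricted to two populations (metadata
#'   columns `subject`/`population` are dropped automatically), or any data
#'   frame of numeric features.
#' @param labels Class labels, one per row; exactly two classes, each with
#'   at least `n_folds` subjects. Defaults to the table's `population`
#'   column.
#' @param n_trees,n_folds Forest size and fold count.
#' @param seed Integer seed governing both the fold split and the forests.
#' @return `list(accuracy, fold_accuracy, importance)` where `importance` is
#'   a named vector summing to 1.
#' @export
cv_accuracy <- function(features, labels = features$population,
                        n_trees = 500, n_folds = 10, seed = 1L) {
  x <- feature_matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) abort("cross-validation needs two classes")
  folds <- stratified_folds(labels, n_folds, derive_seed(seed, "folds"))
  fold_acc <- vapply(seq_len(n_folds), function(f) {
    train <- folds != f
    fit <- rf_fit(x[train, , drop = FALSE], labels[train], n_trees,
                  derive_seed(seed, paste0("fold", f)))
    # vote ties at prediction time are broken by the RNG: seed it too
    pred <- predict(fit, data.frame(x[!train, , drop = FALSE], check.names = FALSE),
                    num.threads = 1, seed = derive_seed(seed, paste0("pred", f)))$predictions
    mean(as.character(pred) == labels[!train])
  }, numeric(1))
  full <- rf_fit(x, labels, n_trees, derive_seed(seed, "full"))
  imp <- full$variable.importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  names(imp) <- colnames(x)
  list(accuracy = mean(fold_acc), fold_accuracy = fold_acc, importance = imp)
}

#' Serial feature-addition accuracy curve
#'
#' Ranks all features by full-model importance (ties broken by feature name
#' for determinism), then re-runs cross-validation on the top-k features for
#' k = 1, ..., K, growing the list one feature at a time.
#'
#' @inheritParams cv_accuracy
#' @return Tibble with columns `k`, `feature` (the feature added at step k),
#'   `cv_accuracy`; attribute `importance` holds the full-model ranking.
#' @export
serial_selection <- function(features, labels = features$population,
                             n_trees = 500, n_folds = 10, seed = 1L) {
  x <- feature_matrix(features)
  full <- cv_accuracy(features, labels, n_trees, n_folds, seed)
  ord <- order(-full$importance, names(full$importance))
  ranking <- names(full$importance)[ord]
  acc <- vapply(seq_along(ranking), function(k) {
    if (k == length(ranking)) return(full$accuracy)
    cv_accuracy(x[, ranking[seq_len(k)], drop = FALSE], labels,
                n_trees, n_folds, seed)$accuracy
  }, numeric(1))
  out <- tibble::tibble(k = seq_along(ranking), feature = ranking, cv_accuracy = acc)
  attr(out, "importance") <- full$importance[ord]
  out
}

#' Parsimony rule for the optimal feature count
#'
#' Picks the smallest k whose cross-validated accuracy is no worse than the
#' curve's maximum by more than `tolerance` (default 0.01, i.e. "no worse
#' than 1%" read as an absolute margin).
#'
#' @param curve Numeric accuracy vector over k = 1..K, or the tibble from
#'   [serial_selection()].
#' @param tolerance Allowed absolute accuracy sacrifice.
#' @return The optimal k (integer).
#' @export
select_optimal <- function(curve, tolerance = 0.01) {
  acc <- if (is.data.frame(curve)) curve$cv_accuracy else curve
  if (length(acc) == 0) abort("empty accuracy curve")
  which(acc >= max(acc) - tolerance)[1]
}

#' Run one reference-vs-target classification experiment
#'
#' Builds frequency-score features with `ref_pop` as the reference, restricts
#' to the two populations, runs the serial feature-addition protocol and
#' applies the parsimony rule. Swapping reference and target changes the
#' features themselves (scores are rarities relative to the reference), so
#' the two orientations of a population pair are distinct experiments and
#' their accuracies need not agree.
#'
#' @param blocks Named list of filtered genotype blocks.
#' @param panel Panel tibble.
#' @param ref_pop,target_pop Population codes.
#' @param mode `"mt"`, `"nuc"` or `"pair"`.
#' @param n_trees,n_folds,tolerance Protocol parameters.
#' @param seed Integer pipeline seed; all folds, forests and tie-breaks
#'   derive from it.
#' @return An `rf_experiment` object; see [tidy.rf_experiment()].
#' @export
run_experiment <- function(blocks, panel, ref_pop, target_pop,
                           mode = c("mt", "nuc", "pair"),
                           n_trees = 500, n_folds = 10, tolerance = 0.01,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (!all(c(ref_pop, target_pop) %in% panel$population)) {
    abort("reference and target populations must appear in the panel")
  }
  features <- build_feature_table(blocks, panel, ref_pop, mode)
  two <- dplyr::filter(features, .data$population %in% c(ref_pop, target_pop))
  exp_seed <- derive_seed(seed, paste(ref_pop, target_pop, mode, sep = ":"))
  curve <- serial_selection(two, two$population, n_trees, n_folds, exp_seed)
  imp <- attr(curve, "importance")
  k_opt <- select_optimal(curve, tolerance)
  structure(
    list(ref_pop = ref_pop, target_pop = target_pop, mode = mode, seed = seed,
         n_subjects = nrow(two), curve = curve,
         importance = tibble::tibble(feature = names(imp), importance = unname(imp),
                                     rank = seq_along(imp)),
         optimal_k = k_opt,
         optimal_features = curve$feature[seq_len(k_opt)],
         accuracy = curve$cv_accuracy[k_opt]),
    class = "rf_experiment"
  )
}

#' @export
print.rf_experiment <- function(x, ...) {
  cat(sprintf("<rf_experiment> %s (ref) vs %s (target), mode %s\n",
              x$ref_pop, x$target_pop, x$mode))
  cat(sprintf("  optimal accuracy %.3f with %d/%d features\n",
              x$accuracy, x$optimal_k, nrow(x$curve)))
  invisible(x)
}

#' Run the full experiment set for one mode
#'
#' One experiment per ordered population pair: for `P` populations,
#' `P * (P - 1)` experiments (6 for three populations).
#'
#' @inheritParams run_experiment
#' @param populations Populations to use (default: all in the panel).
#' @return Named list of `rf_experiment`s (`"REF_vs_TARGET"`).
#' @export
run_experiment_set <- function(blocks, panel, populations = NULL,
                               mode = c("mt", "nuc", "pair"),
                               n_trees = 500, n_folds = 10, tolerance = 0.01,
                               seed = 1L) {
  mode <- match.arg(mode)
  populations <- populations %||% unique(panel$population)
  pairs <- expand.grid(ref = populations, target = populations,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$target, ]
  out <- purrr::pmap(pairs, function(ref, target) {
    run_experiment(blocks, panel, ref, target, mode,
                   n_trees, n_folds, tolerance, seed)
  })
  names(out) <- paste0(pairs$ref, "_vs_", pairs$target)
  out
}

#' Accuracy matrix across an experiment set
#'
#' @param results Named list of `rf_experiment`s.
#' @return Tibble `ref_pop`, `target_pop`, `mode`, `accuracy`, `optimal_k` —
#'   the (reference x target) accuracy table with feature counts; the table
#'   is not symmetric in general.
#' @export
accuracy_matrix <- function(results) {
  purrr::map_dfr(results, function(r) {
    tibble::tibble(ref_pop = r$ref_pop, target_pop = r$target_pop, mode = r$mode,
                   accuracy = r$accuracy, optimal_k = r$optimal_k)
  })
}
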