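# Random-forest baseline on the hand-crafted features, and the
# cell-vs-noncell quality filter, both with grid-search hyperparameter
# selection.  The features-per-split grid is expressed as fractions of the
# actual feature count (sqrt, 25%, 50%, 75%, 100%) because the absolute
# grid of the 435-feature battery does not transfer to other widths.

#' Random-forest hyperparameter grid
#'
#' @param n_trees Candidate forest sizes.
#' @param mtry_fractions Candidate features-per-split values, as fractions
#'   of the feature count; `"sqrt"` means floor(sqrt(p)).
#' @param min_node_size Candidate minimum terminal node sizes.
#' @return An `rf_grid` object.
#' @export
rf_grid <- function(n_trees = c(50, 100, 250, 500, 1000),
                    mtry_fractions = c("sqrt", 0.25, 0.5, 0.75, 1),
                    min_node_size = c(1, 2, 5, 10, 50)) {
  stopifnot(length(n_trees) >= 1, length(mtry_fractions) >= 1,
            length(min_node_size) >= 1)
  structure(list(n_trees = n_trees, mtry_fractions = mtry_fractions,
                 min_node_size = min_node_size), class = "rf_grid")
}

#' Reduced grid for desk-scale runs
#' @rdname rf_grid
#' @export
rf_grid_small <- function() {
  rf_grid(n_trees = c(100, 250), mtry_fractions = c("sqrt", 0.25),
          min_node_size = c(1, 5))
}

resolve_mtry <- function(fraction, p) {
  if (identical(fraction, "sqrt")) return(as.integer(max(1, floor(sqrt(p)))))
  as.integer(max(1, min(p, floor(as.numeric(fraction) * p))))
}

#' Train the random-forest baseline with grid search
#'
#' Evaluates the full grid (forest size x features-per-split x minimum
#' node size) by validation accuracy, refits nothing (the forest trained
#' on the training fold is kept), and reports the chosen triple.
#'
#' @param train_table Feature matrix for training cells.
#' @param train_labels Class labels (character or factor).
#' @param val_table,val_labels Validation fold used for model selection.
#' @param grid An [rf_grid()].
#' @param seed Integer seed.
#' @return An `rf_baseline`: list with `model` (randomForest), `chosen`
#'   (n_trees, mtry, min_node_size), `grid_results` (data.frame), and
#'   `classes`.
#' @export
train_rf_baseline <- function(train_table, train_labels, val_table,
                              val_labels, grid = rf_grid_small(), seed = 1L) {
  train_labels <- factor(train_labels)
  if (nlevels(train_labels) < 2)
    stop("training data must contain at least two classes")
  val_labels <- factor(val_labels, levels = levels(train_labels))
  p <- ncol(train_table)
  combos <- expand.grid(n_trees = grid$n_trees,
                        mtry_fraction = grid$mtry_fractions,
                        min_node_size = grid$min_node_size,
                        stringsAsFactors = FALSE)
  results <- combos
  results$mtry <- vapply(combos$mtry_fraction, resolve_mtry, 1L, p = p)
  results$val_acc <- NA_real_
  best <- list(acc = -1)
  for (i in seq_len(nrow(combos))) {
    fit <- with_seed(derive_seed(seed, i), randomForest::randomForest(
      x = train_table, y = train_labels,
      ntree = combos$n_trees[i], mtry = results$mtry[i],
      nodesize = combos$min_node_size[i]))
    acc <- mean(predict(fit, val_table) == val_labels)
    results$val_acc[i] <- acc
    if (acc > best$acc) best <- list(acc = acc, model = fit, row = i)
  }
  structure(list(model = best$model,
                 chosen = list(n_trees = results$n_trees[best$row],
                               mtry = results$mtry[best$row],
                               min_node_size = results$min_node_size[best$row]),
                 val_acc = best$acc,
                 grid_results = results,
                 classes = levels(train_labels)),
            class = "rf_baseline")
}

#' Class probabilities / calls from the baseline forest
#'
#' @param baseline An `rf_baseline`.
#' @param table Feature matrix.
#' @return `predict_rf_proba`: matrix of class vote fractions;
#'   `predict_rf_class`: character labels.
#' @export
predict_rf_proba <- function(baseline, table) {
  predict(baseline$model, table, type = "prob")
}

#' @rdname predict_rf_proba
#' @export
predict_rf_class <- function(baseline, table) {
  as.character(predict(baseline$model, table))
}

#' Train the cell-quality filter
#'
#' Random forest discriminating good cells from noncells, with 10-fold
#' cross-validation over the features-per-split grid and over whether to
#' downsample the (majority) cell class in each bootstrap sample.
#'
#' @param cell_features Feature matrix of good-quality cells.
#' @param noncell_features Feature matrix of artifacts.
#' @param cv_folds Number of cross-validation folds.
#' @param mtry_fractions Features-per-split candidates (fractions or "sqrt").
#' @param n_trees Forest size (100, as in the reference procedure).
#' @param seed Integer seed.
#' @return A `quality_filter`: list with `model`, `cv_results`, `chosen`,
#'   `cv_acc`.
#' @export
train_quality_filter <- function(cell_features, noncell_features,
                                 cv_folds = 10,
                                 mtry_fractions = c("sqrt", 0.25, 0.5, 0.75, 1),
                                 n_trees = 100, seed = 1L) {
  if (nrow(cell_features) == 0 || nrow(noncell_features) == 0)
    stop("both classes must be non-empty")
  X <- rbind(cell_features, noncell_features)
  y <- factor(c(rep("cell", nrow(cell_features)),
                rep("nonCell", nrow(noncell_features))),
              levels = c("cell", "nonCell"))
  n <- nrow(X)
  if (n < cv_folds) stop("fewer rows (", n, ") than folds (", cv_folds, ")")
  p <- ncol(X)
  folds <- with_seed(derive_seed(seed, 1L), sample(rep(seq_len(cv_folds),
                                                       length.out = n)))
  combos <- expand.grid(mtry_fraction = mtry_fractions,
                        downsample = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  combos$mtry <- vapply(combos$mtry_fraction, resolve_mtry, 1L, p = p)
  combos$cv_acc <- NA_real_
  for (i in seq_len(nrow(combos))) {
    correct <- 0
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      sampsize <- if (combos$downsample[i]) {
        nmin <- min(table(y[tr]))
        c(cell = nmin, nonCell = nmin)
      }
      fit <- with_seed(derive_seed(seed, i, f), randomForest::randomForest(
        x = X[tr, , drop = FALSE], y = y[tr], ntree = n_trees,
        mtry = combos$mtry[i], strata = y[tr],
        sampsize = if (is.null(sampsize)) table(y[tr]) else sampsize))
      correct <- correct + sum(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }
    combos$cv_acc[i] <- correct / n
  }
  bi <- which.max(combos$cv_acc)
  sampsize <- if (combos$downsample[bi]) {
    nmin <- min(table(y)); c(cell = nmin, nonCell = nmin)
  } else table(y)
  model <- with_seed(derive_seed(seed, 999L), randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = combos$mtry[bi],
    strata = y, sampsize = sampsize))
  structure(list(model = model,
                 chosen = list(mtry = combos$mtry[bi],
                               downsample = combos$downsample[bi],
                               n_trees = n_trees),
                 cv_acc = combos$cv_acc[bi],
                 cv_results = combos),
            class = "quality_filter")
}

#' Apply the quality filter
#'
#' @param filter A `quality_filter`.
#' @param feature_table Feature matrix of cells to screen.
#' @return Logical vector: TRUE for rows kept (classified as cells).
#' @export
apply_quality_filter <- function(filter, feature_table) {
  stopifnot(inherits(filter, "quality_filter"))
  as.character(predict(filter$model, feature_table)) == "cell"
}
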