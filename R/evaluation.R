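# Classification evaluation: confusion matrix, accuracy, Cohen's kappa,
# per-class precision/recall, and stratified bootstrap confidence
# intervals in which resampling happens within each true class so that
# class counts are identical in every replicate.

#' Confusion matrix and summary metrics
#'
#' Rows of the confusion matrix are true classes, columns predicted.
#' Accuracy is trace/total; kappa is `(p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` computed from the row/column marginals.
#' Per-class recall is the diagonal over row sums, precision over column
#' sums; classes absent from the truth (or never predicted) yield `NA`,
#' not zero.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @param class_order Class vocabulary (default: sorted union).
#' @return An `eval_report`: list with `confusion`, `accuracy`, `kappa`,
#'   `per_class` (data.frame), `n`.
#' @export
confusion_and_metrics <- function(true_labels, pred_labels,
                                  class_order = NULL) {
  if (length(true_labels) == 0) stop("empty input")
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  if (is.null(class_order))
    class_order <- sort(unique(c(true_labels, pred_labels)))
  if (!all(c(true_labels, pred_labels) %in% class_order))
    stop("labels outside class_order")
  tt <- factor(true_labels, levels = class_order)
  pp <- factor(pred_labels, levels = class_order)
  cm <- unclass(table(true = tt, pred = pp))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  rs <- rowSums(cm); cs <- colSums(cm)
  per_class <- data.frame(
    class = class_order,
    support = as.integer(rs),
    recall = ifelse(rs > 0, diag(cm) / rs, NA_real_),
    precision = ifelse(cs > 0, diag(cm) / cs, NA_real_),
    row.names = NULL)
  structure(list(confusion = cm, accuracy = po, kappa = kappa,
                 per_class = per_class, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d, accuracy = %.4f, kappa = %.4f\n",
              x$n, x$accuracy, x$kappa))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Stratified bootstrap confidence intervals for precision and recall
#'
#' Resamples (true, predicted) pairs with replacement within each true
#' class, so every replicate has exactly the original class counts.
#' Per-class precision and recall are computed per replicate and the
#' 2.5%/97.5% percentiles form the 95% interval (percentile method).
#' Precision replicates in which a class receives zero predictions are
#' dropped for that class before taking percentiles.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @param n_boot Number of bootstrap replicates (20,000 at full scale;
#'   desk-scale tests use 2,000).
#' @param level Confidence level.
#' @param seed Integer seed (resampling is reproducible bit-for-bit).
#' @param class_order Class vocabulary (default: sorted union).
#' @return data.frame with class, precision/recall point estimates and
#'   lower/upper bounds; classes with zero support have `NA` bounds.
#' @export
stratified_bootstrap_ci <- function(true_labels, pred_labels,
                                    n_boot = 20000, level = 0.95,
                                    seed = 1L, class_order = NULL,
                                    keep_replicates = FALSE) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  base <- confusion_and_metrics(true_labels, pred_labels, class_order)
  classes <- base$per_class$class
  K <- length(classes)
  ti <- match(true_labels, classes)
  pi_ <- match(pred_labels, classes)
  idx_by_class <- split(seq_along(ti), factor(ti, levels = seq_len(K)))
  alpha <- (1 - level) / 2
  rec <- matrix(NA_real_, n_boot, K)
  prec <- matrix(NA_real_, n_boot, K)
  class_counts <- if (keep_replicates) matrix(NA_integer_, n_boot, K)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_class, function(ix)
        if (length(ix)) ix[sample.int(length(ix), length(ix),
                                      replace = TRUE)] else integer(0)),
        use.names = FALSE)
      cm <- matrix(tabulate(ti[take] + K * (pi_[take] - 1L), nbins = K * K),
                   K, K)
      rs <- rowSums(cm); cs <- colSums(cm)
      if (keep_replicates) class_counts[b, ] <- as.integer(rs)
      rec[b, ] <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
      prec[b, ] <- ifelse(cs > 0, diag(cm) / cs, NA_real_)
    }
  })
  qs <- function(m) apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(c(NA_real_, NA_real_))
    stats::quantile(col, c(alpha, 1 - alpha), names = FALSE)
  })
  rq <- qs(rec); pq <- qs(prec)
  out <- base$per_class
  out$recall_lower <- rq[1, ]; out$recall_upper <- rq[2, ]
  out$precision_lower <- pq[1, ]; out$precision_upper <- pq[2, ]
  out$recall_lower[out$support == 0] <- NA_real_
  out$recall_upper[out$support == 0] <- NA_real_
  attr(out, "n_boot") <- n_boot
  attr(out, "level") <- level
  if (keep_replicates) {
    colnames(class_counts) <- classes
    attr(out, "replicate_class_counts") <- class_counts
    attr(out, "replicate_recall") <- rec
    attr(out, "replicate_precision") <- prec
  }
  out
}

#' Full evaluation report with bootstrap intervals
#'
#' @inheritParams stratified_bootstrap_ci
#' @return An `eval_report` whose `per_class` carries CI columns and
#'   `n_boot`.
#' @export
evaluate_predictions <- function(true_labels, pred_labels, n_boot = 2000,
                                 seed = 1L, class_order = NULL) {
  rep_ <- confusion_and_metrics(true_labels, pred_labels, class_order)
  rep_$per_class <- stratified_bootstrap_ci(true_labels, pred_labels,
                                            n_boot = n_boot, seed = seed,
                                            class_order = class_order)
  rep_$n_boot <- n_boot
  rep_
}

#' Protein-level accuracy with and without a minimum-cell filter
#'
#' @param protein_calls data.frame from [aggregate_proteins()].
#' @param truth Named character vector: true compartment per protein id.
#' @param min_cells Minimum cells for the filtered accuracy.
#' @return List with `overall` and `filtered`, each carrying `correct`,
#'   `total`, `accuracy` and a `fraction` string ("correct/total").
#' @export
protein_level_report <- function(protein_calls, truth, min_cells = 10) {
  missing <- setdiff(protein_calls$protein_id, names(truth))
  if (length(missing))
    stop("proteins without truth labels: ", paste(missing, collapse = ", "))
  correct <- protein_calls$map_label ==
    truth[protein_calls$protein_id]
  mk <- function(ok) {
    list(correct = sum(ok), total = length(ok),
         accuracy = if (length(ok)) mean(ok) else NA_real_,
         fraction = sprintf("%d/%d", sum(ok), length(ok)))
  }
  keep <- protein_calls$n_cells >= min_cells
  list(overall = mk(correct), filtered = mk(correct[keep]),
       min_cells = min_cells)
}
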