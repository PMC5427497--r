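# The desk-scale benchmark study: one function that generates a dataset,
# trains both model families on identical folds, aggregates proteins,
# runs the transfer comparison and the interpretability summaries.  The
# test suite and the acceptance script both drive their ordering checks
# through this single code path.

#' Run the desk-scale ordering study for one seed
#'
#' Generates a 12-class synthetic dataset at default difficulty
#' (`proteins_per_class` x `cells_per_protein` cells per class,
#' protein-level folds 0.72/0.14/0.14), extracts the classic feature
#' table, trains the grid-searched random-forest baseline and the desk
#' CNN preset on the same folds, and measures:
#' single-cell test accuracy of both models; protein-level accuracy with
#' and without the >= `min_cells` filter; transfer-learning accuracy of
#' network features vs classic features on four unseen classes at small
#' training sizes; median neuron--class mutual information and median
#' strongest feature correlation at conv-1 and FC-1.
#'
#' @param seed Master seed for the whole study.
#' @param proteins_per_class,cells_per_protein Dataset size per class.
#' @param epochs CNN training epochs (desk preset).
#' @param transfer_sizes Training images per class for the transfer
#'   curves.
#' @param transfer_reps Repetitions per transfer size.
#' @param mixture Also run the two-compartment mixture-protein analysis
#'   (20 nucleus+cytoplasm proteins at fraction 0.5, 30 cells each).
#' @param verbose Log progress.
#' @return List of measurements; see Details.
#' @export
ordering_study <- function(seed = 1L, proteins_per_class = 8L,
                           cells_per_protein = 12L, epochs = 14L,
                           transfer_sizes = c(1, 3, 5, 10),
                           transfer_reps = 3L, mixture = FALSE,
                           verbose = FALSE) {
  log_ <- function(...) if (verbose) message("[study ", seed, "] ", ...)
  spec <- dataset_spec(classes = core_classes(),
                       proteins_per_class = proteins_per_class,
                       cells_per_protein = cells_per_protein,
                       seed = derive_seed(seed, 1L, 21L))
  log_("generating ", length(spec$classes) * proteins_per_class *
         cells_per_protein, " cells")
  ds <- generate_dataset(spec)
  man <- ds$manifest
  tr <- man$fold == "train"; va <- man$fold == "val"; te <- man$fold == "test"
  log_("classic features")
  ft <- extract_feature_table(ds)
  log_("baseline forest")
  rf <- train_rf_baseline(ft[tr, ], man$label[tr], ft[va, ], man$label[va],
                          rf_grid_small(), seed = derive_seed(seed, 2L, 21L))
  rf_acc <- mean(predict_rf_class(rf, ft[te, ]) == man$label[te])
  log_("training CNN (", epochs, " epochs)")
  net <- build_network(small_network_config(12),
                       seed = derive_seed(seed, 3L, 21L))
  cnn <- train_network(net, ds,
                       small_train_config(derive_seed(seed, 4L, 21L),
                                          epochs = epochs))
  P <- predict_proba(cnn, ds$images[man$cell_id[te]])
  cnn_acc <- mean(predict_class(P) == man$label[te])
  log_(sprintf("cell-level accuracy: cnn %.3f rf %.3f", cnn_acc, rf_acc))

  calls <- aggregate_proteins(P, man$protein_id[te])
  truth <- tapply(man$label[te], man$protein_id[te], `[`, 1)
  prot <- protein_level_report(calls, truth, min_cells = 10)

  # transfer to four unseen classes
  log_("transfer classes")
  tspec <- dataset_spec(classes = transfer_classes(), proteins_per_class = 5L,
                        cells_per_protein = 8L,
                        fold_fractions = c(0.4, 0.2, 0.4),
                        seed = derive_seed(seed, 5L, 21L))
  tds <- generate_dataset(tspec)
  tman <- tds$manifest
  deep <- extract_activations(cnn, tds, layer_index = 9L)
  classic <- extract_feature_table(tds)
  lc <- transfer_learning_curve(
    list(deep = deep, classic = classic), tman$label,
    train_idx = which(tman$fold == "train"),
    val_idx = which(tman$fold == "val"),
    test_idx = which(tman$fold == "test"),
    sizes = transfer_sizes, n_reps = transfer_reps,
    seed = derive_seed(seed, 6L, 21L))

  # interpretability summaries on the held-out cells; mutual information
  # is per neuron output (conv map neurons subsampled for tractability),
  # correlations use the pooled per-channel summaries
  ho <- which(!tr)
  imgs_ho <- ds$images[man$cell_id[ho]]
  a1 <- extract_activations(cnn, imgs_ho, 1L)
  a1n <- extract_activations(cnn, imgs_ho, 1L, pool_channels = FALSE)
  a1n <- a1n[, with_seed(derive_seed(seed, 7L, 21L),
                         sample.int(ncol(a1n), 512L)), drop = FALSE]
  afc <- extract_activations(cnn, imgs_ho, 9L)
  y_ho <- man$label[ho]
  mi1 <- neuron_class_mutual_information(a1n, y_ho)
  mifc <- neuron_class_mutual_information(afc, y_ho)
  r1 <- max_feature_correlation(a1, ft[ho, ])
  rfc <- max_feature_correlation(afc, ft[ho, ])

  out <- list(seed = seed,
              n_cells = nrow(man),
              cnn_acc = cnn_acc, rf_acc = rf_acc,
              protein_acc_all = prot$overall$accuracy,
              protein_acc_min10 = prot$filtered$accuracy,
              protein_fraction_min10 = prot$filtered$fraction,
              transfer = lc,
              mi_conv1_median = stats::median(mi1),
              mi_fc1_median = stats::median(mifc),
              maxr_conv1_median = stats::median(r1, na.rm = TRUE),
              maxr_fc1_median = stats::median(rfc, na.rm = TRUE),
              test_probs = P, test_protein_ids = man$protein_id[te],
              test_labels = man$label[te],
              cnn = cnn, baseline = rf, dataset_manifest = man)
  if (mixture) {
    log_("mixture proteins")
    hits <- vapply(seq_len(20), function(i) {
      cells <- generate_mixture_protein(c("nucleus", "cytoplasm"), 0.5, 30,
                                        seed = derive_seed(seed, 100L + i, 21L),
                                        protein_id = sprintf("mix%02d", i))
      pp <- predict_proba(cnn, cells)
      post <- dirichlet_posterior(pp, protein_id = sprintf("mix%02d", i))
      top2 <- top_k_classes(post, 2)$label
      all(c("nucleus", "cytoplasm") %in% top2)
    }, TRUE)
    out$mixture_top2_rate <- mean(hits)
    # a pure protein's mass should concentrate on its compartment
    pure <- lapply(seq_len(20), function(i)
      render_cell("vacuole", seed = derive_seed(seed, 200L + i, 21L)))
    ppp <- predict_proba(cnn, pure)
    post <- dirichlet_posterior(ppp, protein_id = "pure")
    out$pure_top1_fraction <- top_k_classes(post, 1)$mass_fraction
  }
  out
}

#' Summarize ordering studies across seeds
#'
#' @param studies List of [ordering_study()] results.
#' @return One-row data.frame of seed-averaged quantities used by the
#'   ordering checks.
#' @export
summarize_studies <- function(studies) {
  m <- function(f) mean(vapply(studies, `[[`, 0, f))
  tr_gap <- vapply(studies, function(s) {
    ag <- stats::aggregate(accuracy ~ source, s$transfer, mean)
    ag$accuracy[ag$source == "deep"] - ag$accuracy[ag$source == "classic"]
  }, 0)
  data.frame(cnn_acc = m("cnn_acc"), rf_acc = m("rf_acc"),
             protein_acc_min10 = m("protein_acc_min10"),
             mi_conv1 = m("mi_conv1_median"), mi_fc1 = m("mi_fc1_median"),
             maxr_conv1 = m("maxr_conv1_median"),
             maxr_fc1 = m("maxr_fc1_median"),
             transfer_gap = mean(tr_gap))
}
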