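# Confusion metrics, Cohen's kappa, stratified bootstrap.

test_that("kappa matches hand-worked confusion examples", {
  # 2x2 with [[40,10],[20,30]]: p_o = 0.70, p_e = 0.50, kappa = 0.40
  truth <- c(rep("a", 50), rep("b", 50))
  pred <- c(rep("a", 40), rep("b", 10), rep("a", 20), rep("b", 30))
  r <- confusion_and_metrics(truth, pred)
  expect_equal(r$accuracy, 0.70)
  expect_equal(r$kappa, 0.40)
  expect_equal(unname(r$confusion), rbind(c(40, 10), c(20, 30)))

  # symmetric 50/50 confusion: kappa = 0
  pred0 <- c(rep(c("a", "b"), 25), rep(c("a", "b"), 25))
  r0 <- confusion_and_metrics(truth, pred0)
  expect_equal(r0$kappa, 0)

  # perfect predictions
  rp <- confusion_and_metrics(truth, truth)
  expect_equal(rp$accuracy, 1)
  expect_equal(rp$kappa, 1)
})

test_that("kappa agrees with the e1071 implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(5)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    n <- 200
    truth <- sample(letters[1:K], n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.6, truth,
                   sample(letters[1:K], n, replace = TRUE))
    r <- confusion_and_metrics(truth, pred, class_order = letters[1:K])
    ca <- e1071::classAgreement(r$confusion)
    expect_equal(r$kappa, ca$kappa, tolerance = 1e-12)
    expect_equal(r$accuracy, ca$diag, tolerance = 1e-12)
  }
})

test_that("micro-averaged recall equals accuracy and absent classes give NA", {
  set.seed(9)
  truth <- sample(c("a", "b", "c"), 120, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 120, replace = TRUE)
  r <- confusion_and_metrics(truth, pred, class_order = c("a", "b", "c", "d"))
  pc <- r$per_class
  micro <- sum(pc$recall * pc$support, na.rm = TRUE) / sum(pc$support)
  expect_equal(micro, r$accuracy)
  expect_true(is.na(pc$recall[pc$class == "d"]))
  expect_error(confusion_and_metrics(character(0), character(0)), "empty")
  expect_error(confusion_and_metrics("a", c("a", "b")), "length")
})

test_that("bootstrap replicates preserve class counts exactly", {
  set.seed(2)
  truth <- sample(c("a", "b", "c"), 90, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  pred <- ifelse(stats::runif(90) < 0.7, truth,
                 sample(c("a", "b", "c"), 90, replace = TRUE))
  ci <- stratified_bootstrap_ci(truth, pred, n_boot = 200, seed = 4,
                                keep_replicates = TRUE)
  counts <- attr(ci, "replicate_class_counts")
  orig <- as.vector(table(factor(truth, levels = c("a", "b", "c"))))
  expect_true(all(apply(counts, 1, function(x) all(x == orig))))
})

test_that("bootstrap CIs behave at the degenerate and asymptotic ends", {
  truth <- rep(c("a", "b"), each = 30)
  ci <- stratified_bootstrap_ci(truth, truth, n_boot = 300, seed = 1)
  expect_true(all(ci$recall_lower == 1 & ci$recall_upper == 1))
  expect_true(all(ci$precision_lower == 1 & ci$precision_upper == 1))

  # reproducible bit-for-bit under a fixed seed
  set.seed(8)
  t2 <- sample(c("a", "b"), 80, replace = TRUE)
  p2 <- ifelse(stats::runif(80) < 0.8, t2, sample(c("a", "b"), 80, TRUE))
  c1 <- stratified_bootstrap_ci(t2, p2, n_boot = 500, seed = 99)
  c2 <- stratified_bootstrap_ci(t2, p2, n_boot = 500, seed = 99)
  expect_identical(c1, c2)

  # interval widths shrink with per-class sample size
  width_at <- function(n) {
    set.seed(123)
    tt <- rep(c("a", "b"), each = n)
    pp <- ifelse(stats::runif(2 * n) < 0.8, tt,
                 ifelse(tt == "a", "b", "a"))
    ci <- stratified_bootstrap_ci(tt, pp, n_boot = 400, seed = 5)
    stats::median(ci$recall_upper - ci$recall_lower)
  }
  expect_lt(width_at(1000), width_at(100))
})

test_that("protein-level report splits by the min-cell filter", {
  calls <- data.frame(protein_id = paste0("p", 1:6),
                      n_cells = c(3, 12, 15, 9, 20, 30),
                      map_label = c("x", "x", "y", "y", "x", "y"))
  truth <- stats::setNames(c("x", "x", "y", "x", "x", "x"), calls$protein_id)
  rep_ <- protein_level_report(calls, truth, min_cells = 10)
  expect_equal(rep_$overall$fraction, "4/6")
  expect_equal(rep_$filtered$fraction, "3/4")
  expect_equal(rep_$overall$accuracy, 4 / 6)
  # perfect agreement is 100% both ways
  perf <- protein_level_report(calls, stats::setNames(calls$map_label,
                                                      calls$protein_id), 10)
  expect_equal(perf$overall$accuracy, 1)
  expect_equal(perf$filtered$accuracy, 1)
  expect_error(protein_level_report(calls, truth[1:3], 10), "without truth")

  # 3 wrong of 282 proteins rounds to 99%, and the filtered subset
  # adjusts its own denominator
  calls282 <- data.frame(protein_id = paste0("q", 1:282),
                         n_cells = c(rep(5, 60), rep(20, 222)),
                         map_label = "nucleus")
  truth282 <- stats::setNames(rep("nucleus", 282), calls282$protein_id)
  truth282[c("q1", "q2", "q61")] <- "vacuole"  # two low-count, one high
  r282 <- protein_level_report(calls282, truth282, min_cells = 10)
  expect_equal(r282$overall$fraction, "279/282")
  expect_equal(round(100 * r282$overall$accuracy), 99)
  expect_equal(r282$filtered$fraction, "221/222")
})
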