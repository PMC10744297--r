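test_that("leave-one-patient-out builds one fold per patient, partitioning the cohort", {
  co <- generate_cohort(small_sim_config(seed = 1, n_patients = 5L))
  plan <- lopo_splits(co)
  expect_equal(length(plan$folds), 5L)
  val_ids <- unlist(lapply(plan$folds, `[[`, "validation"))
  expect_setequal(val_ids, co$meta$spectrum_id)
  expect_equal(anyDuplicated(val_ids), 0L)
  for (f in plan$folds) {
    tr_pts <- co$meta$patient_id[match(f$train, co$meta$spectrum_id)]
    va_pts <- co$meta$patient_id[match(f$validation, co$meta$spectrum_id)]
    expect_length(intersect(tr_pts, va_pts), 0L)
  }
})

test_that("fold sizes follow per-patient spectrum counts", {
  g <- seq(500, 599, by = 1)
  n <- c(2L, 3L, 4L)
  meta <- data.frame(
    spectrum_id = sprintf("S%d", 1:9),
    patient_id = rep(c("A", "B", "C"), times = n),
    label = rep_len(c(0L, 1L), 9))
  co <- raman_cohort(g, matrix(1, 9, length(g)), meta)
  plan <- lopo_splits(co)
  expect_equal(vapply(plan$folds, function(f) length(f$validation),
                      integer(1)), n)

  one <- co
  one$meta$patient_id <- "A"
  expect_error(lopo_splits(one), "2 patients")
})

test_that("grouped k-fold keeps patients intact and partitions the cohort", {
  co <- generate_cohort(small_sim_config(seed = 2, n_patients = 10L))
  plan <- grouped_kfold_splits(co, k = 4L, seed = 3)
  expect_equal(length(plan$folds), 4L)
  val_ids <- unlist(lapply(plan$folds, `[[`, "validation"))
  expect_setequal(val_ids, co$meta$spectrum_id)
  expect_equal(anyDuplicated(val_ids), 0L)
  for (f in plan$folds) {
    tr_pts <- unique(co$meta$patient_id[match(f$train, co$meta$spectrum_id)])
    va_pts <- unique(co$meta$patient_id[match(f$validation,
                                              co$meta$spectrum_id)])
    expect_length(intersect(tr_pts, va_pts), 0L)
  }
  expect_error(grouped_kfold_splits(co, k = 11L), "exceeds")
})

test_that("metrics match the printed per-class rates of the best deep model", {
  # confusion counts reconstructed from per-class recalls out of 221
  truth <- rep(c(0L, 1L), each = 221L)
  pred <- c(rep(0L, 194L), rep(1L, 27L),   # healthy: 194 correct
            rep(0L, 11L), rep(1L, 210L))   # cancerous: 210 correct
  m <- confusion_and_metrics(truth, pred)
  expect_equal(unname(m$confusion), matrix(c(194L, 11L, 27L, 210L), 2, 2))
  expect_equal(m$report$accuracy[1], 91.4)
  expect_equal(m$report$recall, c(87.8, 95.0))
  expect_equal(m$report$precision, c(94.6, 88.6))
  expect_equal(m$report$f1, c(91.1, 91.7))
})

test_that("perfect and degenerate predictions give the expected extremes", {
  truth <- rep(c(0L, 1L), each = 10L)
  m <- confusion_and_metrics(truth, truth)
  expect_equal(m$accuracy, 100)
  expect_equal(m$per_class$precision, c(100, 100))
  expect_equal(sum(m$confusion) - sum(diag(m$confusion)), 0L)
  expect_error(confusion_and_metrics(truth, truth[-1]), "equal length")
  expect_error(confusion_and_metrics(truth, truth + 1L), "0 .healthy. or 1")
})

test_that("metric formulas agree with a brute-force counting oracle", {
  set.seed(44)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    truth <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0L, 1L)
    pred <- sample(c(0L, 1L), n, replace = TRUE)
    m <- confusion_and_metrics(truth, pred)
    o <- metrics_oracle(truth, pred)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$per_class$precision, o$precision)
    expect_equal(m$per_class$recall, o$recall)
    # equal class supports: accuracy is the mean of the two recalls
    if (sum(truth == 0) == sum(truth == 1))
      expect_equal(m$accuracy, mean(m$per_class$recall))
  }
})

test_that("cross-validated experiments separate a clean synthetic cohort", {
  co <- generate_cohort(small_sim_config(seed = 6, n_patients = 12L,
                                         per_class = 8L))
  plan <- lopo_splits(co)
  cv <- run_cv_experiment(co, "paper_ml", model_spec("xgboost", seed = 1),
                          plan)
  expect_equal(sum(cv$metrics$confusion), nrow(co$intensities))
  expect_gt(cv$metrics$accuracy, 90)
  expect_equal(nrow(cv$predictions), nrow(co$intensities))
  expect_equal(nrow(cv$per_fold), length(plan$folds))
})

test_that("permuted labels drop a pipeline to chance level", {
  co <- generate_cohort(small_sim_config(seed = 7))
  set.seed(10)
  co$meta$label <- sample(co$meta$label)
  plan <- grouped_kfold_splits(co, k = 4L, seed = 2)
  cv <- run_cv_experiment(
    co, pipeline_spec("raw", list(), region = "low_plus_high"),
    model_spec("xgboost", seed = 1, n_rounds = 50L), plan)
  expect_gt(cv$metrics$accuracy, 30)
  expect_lt(cv$metrics$accuracy, 70)
})

test_that("the ablation report labels its cumulative stages and telescopes", {
  co <- generate_cohort(small_sim_config(seed = 8, n_patients = 6L,
                                         per_class = 5L))
  plan <- grouped_kfold_splits(co, k = 3L, seed = 1)
  ab <- run_ablation(co, model_spec("xgboost", seed = 1, n_rounds = 50L),
                     plan)
  expect_equal(ab$steps$step,
               c("raw", "baseline_correction", "l2_normalization",
                 "median_filter", "pca"))
  expect_equal(sum(ab$steps$delta_accuracy), ab$total_accuracy_improvement)
  expect_equal(ab$total_accuracy_improvement,
               ab$steps$accuracy[5] - ab$steps$accuracy[1])
  expect_equal(sum(ab$steps$delta_recall), ab$total_recall_improvement)
})

test_that("pipeline comparison returns one deterministic row pair per preset", {
  co <- generate_cohort(small_sim_config(seed = 9, n_patients = 6L,
                                         per_class = 5L))
  plan <- grouped_kfold_splits(co, k = 3L, seed = 1)
  spec <- model_spec("xgboost", seed = 1, n_rounds = 50L)
  cmp <- compare_pipelines(co, spec, plan,
                           pipelines = c("pipeline_c", "pipeline_c"))
  expect_equal(nrow(cmp$table), 4L)  # two per-class rows per pipeline
  expect_equal(cmp$table[1:2, -1], cmp$table[3:4, -1],
               ignore_attr = TRUE)
})
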