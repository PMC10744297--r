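#' Cross-validation, metrics, ablation and pipeline comparison
#'
#' Patient-grouped validation schemes (leave-one-patient-out and grouped
#' k-fold), pooled confusion-matrix metrics, the sequential preprocessing
#' ablation harness and a side-by-side pipeline comparison.
#'
#' @name evaluation
NULL

#' Leave-one-patient-out fold plan
#'
#' One fold per patient: all of that patient's spectra form the validation
#' set, every other spectrum the training set.
#'
#' @param cohort a \code{raman_cohort} with at least 2 patients.
#' @return a \code{fold_plan}: list of folds, each with \code{train} and
#'   \code{validation} spectrum-id character vectors.
#' @export
lopo_splits <- function(cohort) {
  stopifnot(inherits(cohort, "raman_cohort"))
  pts <- unique(cohort$meta$patient_id)
  if (length(pts) < 2L)
    stop("leave-one-patient-out needs at least 2 patients", call. = FALSE)
  folds <- lapply(pts, function(p) {
    val <- cohort$meta$patient_id == p
    list(patient = p,
         train = cohort$meta$spectrum_id[!val],
         validation = cohort$meta$spectrum_id[val])
  })
  structure(list(scheme = "lopo", k = length(pts), folds = folds),
            class = "fold_plan")
}

#' Patient-grouped k-fold plan
#'
#' Patients are shuffled (seeded) and dealt into k groups balanced by
#' spectrum count; no patient's spectra straddle a train/validation
#' boundary.
#'
#' @param cohort a \code{raman_cohort}.
#' @param k number of folds (default 10; at most the number of patients).
#' @param seed RNG seed for the patient shuffle.
#' @return a \code{fold_plan}.
#' @export
grouped_kfold_splits <- function(cohort, k = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "raman_cohort"))
  k <- as.integer(k)
  pts <- unique(cohort$meta$patient_id)
  if (k > length(pts))
    stop(sprintf("k = %d exceeds the number of patients (%d)",
                 k, length(pts)), call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  counts <- table(cohort$meta$patient_id)[pts]
  set.seed(seed)
  ord <- pts[sample.int(length(pts))]
  ord <- ord[order(-as.integer(counts[ord]))]  # big patients first
  group_sizes <- numeric(k)
  assignment <- character(0)
  group_of <- stats::setNames(integer(length(ord)), ord)
  for (p in ord) {
    g <- which.min(group_sizes)
    group_of[p] <- g
    group_sizes[g] <- group_sizes[g] + counts[[p]]
  }
  folds <- lapply(seq_len(k), function(g) {
    val_pts <- names(group_of)[group_of == g]
    val <- cohort$meta$patient_id %in% val_pts
    list(patients = val_pts,
         train = cohort$meta$spectrum_id[!val],
         validation = cohort$meta$spectrum_id[val])
  })
  structure(list(scheme = "grouped_kfold", k = k, seed = seed, folds = folds),
            class = "fold_plan")
}

#' Confusion matrix and classification metrics
#'
#' Rows of the confusion matrix are the true class (healthy, cancerous),
#' columns the predicted class. Per-class precision, recall and F1 plus
#' overall accuracy and support-weighted averages, as percentages; the
#' \code{report} element rounds to 1 decimal, raw values are retained.
#'
#' @param truth integer vector of true labels (0/1).
#' @param predictions integer vector of predicted labels (0/1).
#' @return a \code{metrics_report} list: \code{confusion} (2x2 matrix),
#'   \code{per_class} (data.frame, raw percentages), \code{accuracy} (raw),
#'   \code{weighted} (named vector), \code{report} (1-decimal data.frame).
#' @export
confusion_and_metrics <- function(truth, predictions) {
  if (length(truth) != length(predictions))
    stop("truth and predictions must have equal length", call. = FALSE)
  truth <- as.integer(truth); predictions <- as.integer(predictions)
  if (!all(truth %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L)))
    stop("labels must be 0 (healthy) or 1 (cancerous)", call. = FALSE)
  cm <- matrix(0L, 2, 2,
               dimnames = list(truth = c("healthy", "cancerous"),
                               predicted = c("healthy", "cancerous")))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, predictions[i] + 1L] <-
      cm[truth[i] + 1L, predictions[i] + 1L] + 1L
  support <- rowSums(cm)
  tp <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0) * 100
  recall <- ifelse(support > 0, tp / support, 0) * 100
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  accuracy <- sum(tp) / length(truth) * 100
  w <- support / sum(support)
  weighted <- c(precision = sum(w * precision), recall = sum(w * recall),
                f1 = sum(w * f1))
  per_class <- data.frame(class = c("healthy", "cancerous"),
                          support = as.integer(support),
                          precision = as.numeric(precision),
                          recall = as.numeric(recall),
                          f1 = as.numeric(f1))
  report <- data.frame(class = per_class$class,
                       precision = round(per_class$precision, 1),
                       recall = round(per_class$recall, 1),
                       f1 = round(per_class$f1, 1),
                       accuracy = round(accuracy, 1))
  structure(list(confusion = cm, per_class = per_class, accuracy = accuracy,
                 weighted = weighted, report = report),
            class = "metrics_report")
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\nPer-class metrics (%):\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("\nAccuracy: %.1f%% | weighted P/R/F1: %.1f / %.1f / %.1f\n",
              x$accuracy, x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}

# fit pipeline + model on the training side of one fold and predict the
# validation side; per-spectrum stages are precomputed by the caller
.fit_predict_fold <- function(region_cohort, pca_k, model_spec_obj,
                              train_ids, val_ids) {
  mat <- region_cohort$intensities
  meta <- region_cohort$meta
  tr <- match(train_ids, meta$spectrum_id)
  va <- match(val_ids, meta$spectrum_id)
  x_tr <- mat[tr, , drop = FALSE]
  x_va <- mat[va, , drop = FALSE]
  if (!is.null(pca_k)) {
    st <- fit_pca(x_tr, pca_k)
    x_tr <- transform_pca(st, x_tr)
    x_va <- transform_pca(st, x_va)
  }
  mdl <- build_model(model_spec_obj, input_length = ncol(x_tr))
  mdl <- fit_model(mdl, x_tr, meta$label[tr])
  list(ids = val_ids, truth = meta$label[va], pred = predict_label(mdl, x_va),
       prob = predict_prob(mdl, x_va))
}

#' Run a cross-validated experiment
#'
#' For each fold the pipeline state (PCA, if any) and the model are fitted
#' on the training side only; validation predictions are pooled into a
#' single confusion matrix. Per-spectrum stages are label-free and
#' spectrum-local, so they are computed once for the whole cohort.
#'
#' @param cohort a \code{raman_cohort}.
#' @param pipeline a \code{pipeline_spec} or preset name.
#' @param model a \code{model_spec}.
#' @param plan a \code{fold_plan}.
#' @return a \code{cv_result}: pooled \code{metrics} (a
#'   \code{metrics_report}), \code{per_fold} metrics data.frame, and the
#'   pooled \code{predictions} data.frame.
#' @export
run_cv_experiment <- function(cohort, pipeline, model, plan) {
  if (is.character(pipeline)) pipeline <- pipeline_preset(pipeline)
  stopifnot(inherits(model, "model_spec"), inherits(plan, "fold_plan"))
  kinds <- vapply(pipeline$stages, `[[`, character(1), "kind")
  pca_k <- if (any(kinds == "pca"))
    pipeline$stages[[which(kinds == "pca")]]$params$n_components else NULL
  region_cohort <- apply_spectral_stages(cohort, pipeline)
  fold_results <- lapply(seq_along(plan$folds), function(i) {
    f <- plan$folds[[i]]
    r <- tryCatch(
      .fit_predict_fold(region_cohort, pca_k, model, f$train, f$validation),
      error = function(e)
        stop(sprintf("fold %d: %s", i, conditionMessage(e)), call. = FALSE))
    r$fold <- i
    r
  })
  pooled <- do.call(rbind, lapply(fold_results, function(r)
    data.frame(fold = r$fold, spectrum_id = r$ids, truth = r$truth,
               predicted = r$pred, probability = r$prob)))
  metrics <- confusion_and_metrics(pooled$truth, pooled$predicted)
  per_fold <- do.call(rbind, lapply(fold_results, function(r)
    data.frame(fold = r$fold, n = length(r$truth),
               accuracy = mean(r$truth == r$pred) * 100)))
  structure(list(pipeline = pipeline$name, model = model$family,
                 scheme = plan$scheme, metrics = metrics,
                 per_fold = per_fold, predictions = pooled),
            class = "cv_result")
}

#' Sequential preprocessing ablation
#'
#' Evaluates the cumulative pipeline sequence — raw spectra, then adding
#' SNIP baseline correction, L2 normalization, median filtering and
#' PCA(30) — on the low+high region with the same folds, and reports
#' per-step accuracy/recall, per-step deltas and the total improvement
#' (final minus first; equal to the sum of the deltas by construction).
#' Recall is the support-weighted average recall (equal to accuracy at
#' exact class balance); per-class recalls are retained.
#'
#' @param cohort a \code{raman_cohort}.
#' @param model a \code{model_spec}.
#' @param plan a \code{fold_plan}.
#' @param region region name for every step (default
#'   \code{"low_plus_high"}).
#' @return an \code{ablation_report}: \code{steps} data.frame (label,
#'   accuracy, recall, delta_accuracy, delta_recall),
#'   \code{total_accuracy_improvement}, \code{total_recall_improvement},
#'   and the per-step \code{cv_results}.
#' @export
run_ablation <- function(cohort, model, plan, region = "low_plus_high") {
  s <- stage_spec
  seqs <- list(
    raw                 = list(),
    baseline_correction = list(s("snip_baseline")),
    l2_normalization    = list(s("snip_baseline"), s("l2_normalize")),
    median_filter       = list(s("snip_baseline"), s("l2_normalize"),
                               s("median_filter")),
    pca                 = list(s("snip_baseline"), s("l2_normalize"),
                               s("median_filter"),
                               s("pca", n_components = 30L)))
  results <- lapply(names(seqs), function(nm) {
    run_cv_experiment(cohort,
                      pipeline_spec(nm, seqs[[nm]], region = region),
                      model, plan)
  })
  names(results) <- names(seqs)
  acc <- vapply(results, function(r) r$metrics$accuracy, numeric(1))
  rec <- vapply(results, function(r) r$metrics$weighted[["recall"]],
                numeric(1))
  steps <- data.frame(step = names(seqs), accuracy = as.numeric(acc),
                      recall = as.numeric(rec),
                      delta_accuracy = c(0, diff(acc)),
                      delta_recall = c(0, diff(rec)))
  structure(list(steps = steps,
                 total_accuracy_improvement = acc[[length(acc)]] - acc[[1]],
                 total_recall_improvement = rec[[length(rec)]] - rec[[1]],
                 cv_results = results),
            class = "ablation_report")
}

#' @export
#' @method print ablation_report
print.ablation_report <- function(x, ...) {
  cat("Preprocessing ablation (cumulative stages):\n")
  print(transform(x$steps, accuracy = round(accuracy, 1),
                  recall = round(recall, 1),
                  delta_accuracy = round(delta_accuracy, 1),
                  delta_recall = round(delta_recall, 1)),
        row.names = FALSE)
  cat(sprintf("Total improvement: accuracy %+.1f, recall %+.1f\n",
              x$total_accuracy_improvement, x$total_recall_improvement))
  invisible(x)
}

#' Compare named preprocessing pipelines
#'
#' Runs the same model and fold plan under each named pipeline preset and
#' collects one metrics row pair (per class) per pipeline.
#'
#' @param cohort a \code{raman_cohort}.
#' @param model a \code{model_spec}.
#' @param plan a \code{fold_plan}.
#' @param pipelines preset names (default the three reference pipelines
#'   plus the suggested ML pipeline).
#' @return list with \code{table} (per-pipeline, per-class metrics
#'   data.frame) and \code{results} (named list of \code{cv_result}).
#' @export
compare_pipelines <- function(cohort, model, plan,
                              pipelines = c("pipeline_a", "pipeline_b",
                                            "pipeline_c", "paper_ml")) {
  results <- lapply(pipelines, function(nm)
    run_cv_experiment(cohort, pipeline_preset(nm), model, plan))
  names(results) <- pipelines
  table <- do.call(rbind, lapply(pipelines, function(nm) {
    r <- results[[nm]]
    cbind(pipeline = nm, r$metrics$report)
  }))
  list(table = table, results = results)
}
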