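#' Binarize diagnoses for a stacked layer
#'
#' Layer 1 screens typical vs atypical development: `TD -> 0`,
#' `{ASD, SLC} -> 1`. Layer 2 separates autism from other delays:
#' `ASD -> 1`, `{SLC, TD} -> 0`.
#'
#' @param diagnoses Vector of diagnoses in `TD`, `SLC`, `ASD` (factor or
#'   character; names are preserved).
#' @param layer 1 or 2.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_labels <- function(diagnoses, layer) {
  if (!layer %in% c(1L, 2L)) abort("`layer` must be 1 or 2.")
  dx <- as.character(diagnoses)
  bad <- setdiff(unique(dx), DIAGNOSIS_LEVELS)
  if (length(bad) > 0) abort(paste0("unknown diagnosis: ", paste(bad, collapse = ", ")))
  out <- if (layer == 1L) as.integer(dx != "TD") else as.integer(dx == "ASD")
  names(out) <- names(diagnoses)
  out
}

#' Gate predicted-atypical children into layer 2
#'
#' The stacked design forwards only the children the screening layer flags:
#' a child passes the gate when its layer-1 ensemble probability of atypical
#' development is at least `threshold`; the rest are terminally labeled
#' typical and never reach the autism-vs-other-delay layer.
#'
#' @param predictions An [ensemble_predict()] tibble (or any tibble with
#'   `child_id` and `p_ensemble`).
#' @param threshold Probability threshold in `(0, 1]`; `0` passes everyone.
#' @return Character vector of gated child ids.
#' @export
gate_atypical <- function(predictions, threshold = 0.5) {
  predictions$child_id[predictions$p_ensemble >= threshold]
}

# Mann-Whitney AUC: rank statistic with midrank tie correction
auc_rank <- function(truth, scores) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) abort("AUC undefined: only one class in `truth`.")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Single-fold binary classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, unweighted average
#' recall (the mean of the two), accuracy, and AUC via the Mann-Whitney rank
#' statistic with midrank tie correction (equal scores contribute 1/2, so a
#' constant score gives AUC 0.5). Predicted-positive means
#' `score >= threshold`.
#'
#' @param truth 0/1 vector of true labels (both classes must be present).
#' @param scores Numeric scores (e.g. ensemble probabilities).
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble: `sensitivity`, `specificity`, `uar`, `auc`,
#'   `accuracy`, `n`.
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores)) abort("`truth` and `scores` must align.")
  if (length(unique(truth)) < 2L) {
    abort("single-class truth: sensitivity/specificity/AUC undefined.")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & truth == 1L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble(
    sensitivity = sens,
    specificity = spec,
    uar = (sens + spec) / 2,
    auc = auc_rank(truth, scores),
    accuracy = (tp + tn) / length(truth),
    n = length(truth)
  )
}

#' Cross-validated evaluation of the two-layer stacked pipeline
#'
#' For each fold: both layers' rater ensembles are trained on the training
#' children — layer 1 on all of them (typical vs atypical), layer 2 only on
#' the truly atypical ones (autism vs other delay). On the test children,
#' layer 1 is scored against the typical/atypical truth; the children it
#' flags atypical (probability >= `threshold`) are gated into layer 2, where
#' any gated typically-developing child counts as a negative. Folds whose
#' gated set contains a single class get `NA` layer-2 metrics (with a
#' warning) and are excluded from the summary mean/SD.
#'
#' @param table Annotation tibble.
#' @param vocabulary A [feature_vocabulary()].
#' @param k Number of folds (default 3).
#' @param seed Integer seed (fold split, nested validation splits, forests).
#' @param threshold Layer-1 gate and decision threshold (default 0.5). The
#'   same threshold is used for layer-2 label decisions.
#' @param config A [rater_model_config()].
#' @param folds Optional precomputed [assign_folds()] tibble.
#' @return A `stack_cv` object: per-fold metrics (`$folds`), summary mean/SD
#'   per layer (`$summary`), and the per-fold test predictions (`$details`).
#'   `tidy()` returns per-fold metrics, `glance()` the summary in wide form.
#' @export
evaluate_stack_cv <- function(table, vocabulary, k = 3L, seed = 1L,
                              threshold = 0.5, config = rater_model_config(),
                              folds = NULL) {
  table <- validate_annotations(table, vocabulary)
  rec <- child_records(table, vocabulary)
  if (is.null(folds)) {
    folds <- assign_folds(rec, k = k, seed = derive_seed(seed, "folds"))
  }
  k <- attr(folds, "k") %||% max(folds$fold)
  if (k < 2L) abort("need at least 2 folds.")
  dx <- setNames(as.character(rec$diagnosis), rec$child_id)

  fold_rows <- list()
  details <- list()
  for (f in seq_len(k)) {
    test_ids <- folds$child_id[folds$fold == f]
    train_ids <- folds$child_id[folds$fold != f]
    tab_train <- table %>% filter(.data$child_id %in% train_ids)
    tab_test <- table %>% filter(.data$child_id %in% test_ids)
    fseed <- derive_seed(seed, paste0("fold", f))

    # layer 1: typical vs atypical on all training children
    y1_train <- factor(ifelse(dx[train_ids] == "TD", "typical", "atypical"),
                       levels = c("typical", "atypical"))
    names(y1_train) <- train_ids
    ens1 <- fit_rater_ensemble(tab_train, vocabulary, labels = y1_train,
                               config = config, seed = derive_seed(fseed, "L1"))
    pred1 <- predict(ens1, tab_test, target_class = "atypical")
    truth1 <- binarize_labels(dx[pred1$child_id], 1L)
    m1 <- compute_metrics(truth1, pred1$p_ensemble, threshold) %>%
      mutate(layer = 1L, fold = f, .before = 1L)

    # layer 2: autism vs other delay, trained on truly atypical children
    atyp_train <- train_ids[dx[train_ids] != "TD"]
    y2_train <- factor(ifelse(dx[atyp_train] == "ASD", "ASD", "other_delay"),
                       levels = c("other_delay", "ASD"))
    names(y2_train) <- atyp_train
    ens2 <- fit_rater_ensemble(
      tab_train %>% filter(.data$child_id %in% atyp_train),
      vocabulary, labels = y2_train,
      config = config, seed = derive_seed(fseed, "L2")
    )
    gated <- gate_atypical(pred1, threshold)
    pred2 <- NULL
    if (length(gated) > 0) {
      pred2 <- predict(ens2, tab_test, target_class = "ASD", children = gated)
      truth2 <- binarize_labels(dx[pred2$child_id], 2L)
      if (length(unique(truth2)) < 2L) {
        warn(sprintf("fold %d: gated layer-2 set is single-class; metrics undefined.", f))
        m2 <- tibble(layer = 2L, fold = f, sensitivity = NA_real_,
                     specificity = NA_real_, uar = NA_real_, auc = NA_real_,
                     accuracy = NA_real_, n = length(gated))
      } else {
        m2 <- compute_metrics(truth2, pred2$p_ensemble, threshold) %>%
          mutate(layer = 2L, fold = f, .before = 1L)
      }
    } else {
      warn(sprintf("fold %d: no child passed the layer-1 gate.", f))
      m2 <- tibble(layer = 2L, fold = f, sensitivity = NA_real_,
                   specificity = NA_real_, uar = NA_real_, auc = NA_real_,
                   accuracy = NA_real_, n = 0L)
    }
    fold_rows[[f]] <- bind_rows(m1, m2)
    details[[f]] <- list(fold = f, layer1 = pred1, layer2 = pred2,
                         gated = gated, weights1 = ens1$weights,
                         weights2 = ens2$weights)
  }
  per_fold <- bind_rows(fold_rows)
  summary <- per_fold %>%
    tidyr::pivot_longer(c("sensitivity", "specificity", "uar", "auc", "accuracy"),
                        names_to = "metric", values_to = "value") %>%
    group_by(.data$layer, .data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n_folds = sum(!is.na(.data$value)), .groups = "drop")
  structure(list(folds = per_fold, summary = summary, details = details,
                 k = k, threshold = threshold, seed = seed),
            class = "stack_cv")
}

#' @export
print.stack_cv <- function(x, ...) {
  cat("<stack_cv> ", x$k, "-fold stacked evaluation (threshold ",
      x$threshold, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.stack_cv <- function(x, ...) {
  x$folds
}

#' @export
glance.stack_cv <- function(x, ...) {
  x$summary %>%
    mutate(cell = sprintf("%.3f (%.3f)", .data$mean, .data$sd)) %>%
    select("layer", "metric", "cell") %>%
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
}

#' Plot cross-validated stacked-pipeline metrics
#'
#' @param object A `stack_cv` object.
#' @param ... Unused.
#' @return A ggplot of per-fold metric values by layer.
#' @export
autoplot.stack_cv <- function(object, ...) {
  d <- object$folds %>%
    tidyr::pivot_longer(c("sensitivity", "specificity", "uar", "auc", "accuracy"),
                        names_to = "metric", values_to = "value") %>%
    mutate(layer = factor(paste("layer", .data$layer)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value,
                                  color = .data$layer)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        size = 2, na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}
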