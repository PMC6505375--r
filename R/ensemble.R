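#' Configuration for per-rater classifiers
#'
#' @param num_trees Number of trees in each rater's random forest (default 500).
#' @param mtry Variables tried per split; `NULL` for the randomForest default.
#' @param seed Integer seed used when fitting.
#' @return A list of class `rater_model_config`.
#' @export
rater_model_config <- function(num_trees = 500L, mtry = NULL, seed = 1L) {
  structure(list(num_trees = as.integer(num_trees),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "rater_model_config")
}

#' Train one rater's classifier
#'
#' Fits a random forest mapping a single rater's encoded answers for a child
#' to the child's class label. Each rater gets their own model so the forest
#' can adapt to that rater's strengths: features the rater scores reliably
#' carry signal, features they score poorly are down-weighted by the trees
#' themselves.
#'
#' @inheritParams encode_matrix
#' @param labels Named factor of class labels keyed by `child_id`. Defaults to
#'   the three-way diagnosis from the table; pass a binarized factor (see
#'   [binarize_labels()]) for a stacked layer.
#' @param config A [rater_model_config()].
#' @return A `rater_model`: the fitted forest plus the rater id, feature
#'   names, class levels and config. Supports `predict(model, x_matrix)`.
#' @export
train_rater_model <- function(table, vocabulary, rater_id, labels = NULL,
                              config = rater_model_config()) {
  enc <- encode_matrix(table, vocabulary, rater_id)
  if (is.null(labels)) labels <- enc$y
  keep <- intersect(rownames(enc$x), names(labels))
  if (length(keep) == 0) abort(paste0("no labeled children for rater ", rater_id))
  x <- enc$x[keep, , drop = FALSE]
  y <- factor(labels[keep])
  y <- droplevels(y)
  if (nlevels(y) < 2L) {
    abort(sprintf("rater %s has single-class training data ('%s'); cannot train.",
                  rater_id, levels(y)[1]))
  }
  fit <- local_seed(config$seed, {
    randomForest::randomForest(
      x = as.data.frame(x), y = y,
      ntree = config$num_trees,
      mtry = if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(x)))) else config$mtry
    )
  })
  structure(list(rater_id = rater_id, fit = fit,
                 features = colnames(x), classes = levels(y),
                 n_train = length(keep), config = config),
            class = "rater_model")
}

#' @export
print.rater_model <- function(x, ...) {
  cat("<rater_model> rater ", x$rater_id, ": ", length(x$classes),
      " classes, ", x$n_train, " children, ", x$config$num_trees, " trees\n",
      sep = "")
  invisible(x)
}

#' Predict class probabilities from a rater model
#'
#' @param object A `rater_model`.
#' @param x Encoded feature matrix (columns = vocabulary questions), e.g. the
#'   `x` element of [encode_matrix()].
#' @param type `"prob"` for a class-probability matrix, `"label"` for the
#'   argmax class.
#' @param ... Unused.
#' @return Probability matrix (rows follow `x`, one column per class) or a
#'   named character vector of labels.
#' @export
predict.rater_model <- function(object, x, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (!all(object$features %in% colnames(x))) abort("feature mismatch with model.")
  df <- as.data.frame(x[, object$features, drop = FALSE])
  pr <- predict(object$fit, df, type = "prob")
  rownames(pr) <- rownames(x)
  if (type == "prob") return(pr)
  lab <- object$classes[max.col(pr, ties.method = "first")]
  setNames(lab, rownames(x))
}

#' Majority vote over rater labels
#'
#' Plurality label per child over the K raters' (or rater models') labels.
#' Ties are broken by global class prevalence in `prevalence_labels`, then by
#' the fixed class order of `levels`.
#'
#' @param votes Character matrix or data frame, one row per child, one column
#'   per rater; `NA` votes are ignored.
#' @param prevalence_labels Labels (e.g. the training labels) whose class
#'   frequencies break ties; `NULL` skips straight to fixed order.
#' @param levels Fixed class order for the final tie-break; default = the
#'   distinct vote values in order of appearance within `DIAGNOSIS` order when
#'   applicable.
#' @return Character vector of consensus labels, one per row of `votes`.
#' @export
majority_vote <- function(votes, prevalence_labels = NULL, levels = NULL) {
  votes <- as.matrix(votes)
  if (nrow(votes) == 0) return(character(0))
  vals <- unique(stats::na.omit(as.character(votes)))
  if (is.null(levels)) {
    levels <- if (all(vals %in% DIAGNOSIS_LEVELS)) {
      DIAGNOSIS_LEVELS[DIAGNOSIS_LEVELS %in% vals]
    } else sort(vals)
  }
  prev <- setNames(rep(0, length(levels)), levels)
  if (!is.null(prevalence_labels)) {
    tb <- table(factor(as.character(prevalence_labels), levels = levels))
    prev[names(tb)] <- as.numeric(tb)
  }
  apply(votes, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) abort("a child has no votes.")
    cnt <- table(factor(v, levels = levels))
    ord <- order(-as.numeric(cnt), -prev, seq_along(levels))
    levels[ord[1]]
  })
}

#' Accuracy delta of a rater model against the consensus baseline
#'
#' The quantity fed into the softmax weighting: the rater model's validation
#' accuracy minus the majority-vote baseline's accuracy on the same children,
#' in accuracy-fraction units (so it lies in `[-1, 1]`).
#'
#' @param truth True labels.
#' @param model_labels The rater model's predicted labels.
#' @param baseline_labels The majority-vote baseline labels.
#' @return A single number `z`.
#' @export
accuracy_delta <- function(truth, model_labels, baseline_labels) {
  if (length(truth) == 0) abort("empty validation set.")
  if (length(model_labels) != length(truth) || length(baseline_labels) != length(truth)) {
    abort("label vectors must align with `truth`.")
  }
  mean(as.character(model_labels) == as.character(truth)) -
    mean(as.character(baseline_labels) == as.character(truth))
}

#' Softmax weights over rater accuracy deltas
#'
#' `w_j = exp(z_j) / sum_k exp(z_k)`, computed with max-subtraction for
#' numerical stability. The weights are strictly positive, sum to one, and
#' preserve the ordering of the deltas, so the ensemble leans hardest on the
#' raters whose models most outperform the consensus.
#'
#' @param z Named numeric vector of accuracy deltas (names = rater ids), or an
#'   unnamed vector (raters are then numbered).
#' @return A tibble of class `weight_vector` with columns `rater_id`, `z`, `w`.
#' @export
softmax_weights <- function(z) {
  if (length(z) == 0) abort("`z` must be non-empty.")
  if (any(!is.finite(z))) abort("`z` must be finite.")
  ids <- names(z)
  if (is.null(ids)) ids <- sprintf("rater%02d", seq_along(z))
  e <- exp(z - max(z))
  out <- tibble(rater_id = ids, z = unname(as.numeric(z)), w = unname(e / sum(e)))
  class(out) <- c("weight_vector", class(out))
  out
}

# stratified index split: selects ~frac of ids into the validation part,
# at least one per class where possible
stratified_holdout <- function(ids, labels, frac, seed) {
  stopifnot(length(ids) == length(labels))
  local_seed(seed, {
    val <- unlist(lapply(split(seq_along(ids), as.character(labels)), function(ix) {
      n_val <- max(1L, round(length(ix) * frac))
      if (n_val >= length(ix)) n_val <- length(ix) - 1L
      if (n_val < 1L) return(integer(0))
      sample(ix, n_val)
    }), use.names = FALSE)
  })
  list(train = ids[-val], validation = ids[sort(val)])
}

#' Fit the full rater-adaptive ensemble
#'
#' The complete training procedure for one classification layer:
#'
#' 1. Hold out a stratified validation subset (`val_fraction`, default 25%) of
#'    the labeled children.
#' 2. Train each rater's forest on the remaining children (that rater's own
#'    annotations).
#' 3. On the validation children, collect every rater model's predicted label,
#'    form the majority-vote baseline, and compute each rater's accuracy delta
#'    `z_j` over the validation children that rater covers.
#' 4. Convert the deltas to softmax weights.
#' 5. Refit each rater's forest on all of its labeled children, with the
#'    weights frozen from step 4.
#'
#' @inheritParams train_rater_model
#' @param val_fraction Fraction of children held out for weight estimation.
#' @param seed Integer seed controlling the validation split and model fits.
#' @param baseline `"plurality"` (default) scores raters against the majority
#'   vote of the K rater models; `"majority_class"` scores them against a
#'   constant most-frequent-class predictor.
#' @return A `rater_ensemble`: named list of `models`, the `weights` tibble
#'   ([softmax_weights()]), the validation child ids, and bookkeeping.
#' @export
fit_rater_ensemble <- function(table, vocabulary, labels = NULL,
                               config = rater_model_config(),
                               val_fraction = 0.25, seed = 1L,
                               baseline = c("plurality", "majority_class")) {
  baseline <- match.arg(baseline)
  table <- validate_annotations(table, vocabulary)
  if (is.null(labels)) {
    rec <- child_records(table, vocabulary)
    labels <- setNames(rec$diagnosis, rec$child_id)
  }
  labels <- factor(labels)
  raters <- sort(unique(table$rater_id))
  ids <- intersect(sort(unique(table$child_id)), names(labels))
  if (length(ids) < 4L) abort("too few labeled children to fit an ensemble.")
  split <- stratified_holdout(ids, labels[ids], val_fraction,
                              derive_seed(seed, "holdout"))
  train_labels <- labels[split$train]
  nested_cfg <- config
  nested_cfg$seed <- derive_seed(seed, "nested")
  tab_train <- table %>% filter(.data$child_id %in% split$train)

  # per-rater predicted labels on the validation children (NA = not covered)
  vote_mat <- matrix(NA_character_, length(split$validation), length(raters),
                     dimnames = list(split$validation, raters))
  for (r in raters) {
    nested <- train_rater_model(tab_train, vocabulary, r, labels = train_labels,
                                config = nested_cfg)
    enc <- encode_matrix(table, vocabulary, r)
    cov <- intersect(split$validation, rownames(enc$x))
    if (length(cov) > 0) {
      vote_mat[cov, r] <- predict(nested, enc$x[cov, , drop = FALSE], type = "label")
    }
  }
  covered <- rowSums(!is.na(vote_mat)) > 0
  if (!all(covered)) {
    warn(sprintf("%d validation children covered by no rater were dropped from weighting.",
                 sum(!covered)))
    vote_mat <- vote_mat[covered, , drop = FALSE]
  }
  base_lab <- if (baseline == "plurality") {
    majority_vote(vote_mat, prevalence_labels = train_labels,
                  levels = levels(labels))
  } else {
    tb <- base::table(factor(train_labels, levels = levels(labels)))
    rep(names(tb)[which.max(tb)], nrow(vote_mat))
  }
  truth <- as.character(labels[rownames(vote_mat)])
  z <- vapply(raters, function(r) {
    cov <- !is.na(vote_mat[, r])
    if (!any(cov)) return(0)
    accuracy_delta(truth[cov], vote_mat[cov, r], base_lab[cov])
  }, numeric(1))
  weights <- softmax_weights(z)

  final_cfg <- config
  final_cfg$seed <- derive_seed(seed, "final")
  models <- lapply(raters, function(r) {
    train_rater_model(table, vocabulary, r, labels = labels, config = final_cfg)
  })
  names(models) <- raters
  structure(list(models = models, weights = weights,
                 validation_children = rownames(vote_mat),
                 baseline = baseline, labels = labels,
                 vocabulary = vocabulary, config = config, seed = seed),
            class = "rater_ensemble")
}

#' @export
print.rater_ensemble <- function(x, ...) {
  cat("<rater_ensemble> ", length(x$models), " raters, classes: ",
      paste(levels(x$labels), collapse = "/"), "\n", sep = "")
  print(x$weights)
  invisible(x)
}

#' Ensemble prediction: weighted combination of rater models
#'
#' For each child, every covering rater model predicts the probability of the
#' target class from its own rater's annotations; the ensemble probability is
#' the weight-weighted sum. When a child is not covered by every rater, the
#' weights are renormalized over the covering raters, so a child rated by any
#' subset of raters still gets a prediction without imputation.
#'
#' @param models Named list of `rater_model`s (names = rater ids).
#' @param weights A `weight_vector` tibble from [softmax_weights()].
#' @param table Annotation tibble holding the children to predict.
#' @param vocabulary A [feature_vocabulary()].
#' @param target_class The class whose probability is combined (e.g. `"ASD"`,
#'   or the positive level of a binarized layer).
#' @param children Optional character vector restricting which children are
#'   predicted (default: all children in `table`).
#' @return A tibble of class `ensemble_prediction`: `child_id`, `p_ensemble`,
#'   and one `p_<rater_id>` column per rater (NA where the rater did not rate
#'   the child). The weights and target class are carried as attributes.
#' @export
ensemble_predict <- function(models, weights, table, vocabulary, target_class,
                             children = NULL) {
  table <- validate_annotations(table, vocabulary)
  if (!inherits(weights, "weight_vector")) abort("`weights` must come from softmax_weights().")
  if (!setequal(names(models), weights$rater_id)) {
    abort("model names and weight rater ids must match.")
  }
  if (is.null(children)) children <- sort(unique(table$child_id))
  raters <- weights$rater_id
  pmat <- matrix(NA_real_, length(children), length(raters),
                 dimnames = list(children, raters))
  for (r in raters) {
    if (!any(table$rater_id == r)) next
    enc <- encode_matrix(table, vocabulary, r)
    cov <- intersect(children, rownames(enc$x))
    if (length(cov) == 0) next
    pr <- predict(models[[r]], enc$x[cov, , drop = FALSE], type = "prob")
    if (!(target_class %in% colnames(pr))) {
      abort(sprintf("model for rater %s has no class '%s'.", r, target_class))
    }
    pmat[cov, r] <- pr[, target_class]
  }
  cov_any <- rowSums(!is.na(pmat)) > 0
  if (!all(cov_any)) {
    abort(paste0("child with no covering rater: ", children[which(!cov_any)[1]]))
  }
  w <- setNames(weights$w, weights$rater_id)
  p_ens <- vapply(seq_along(children), function(i) {
    cov <- !is.na(pmat[i, ])
    wi <- w[cov] / sum(w[cov])
    sum(wi * pmat[i, cov])
  }, numeric(1))
  out <- tibble(child_id = children, p_ensemble = p_ens)
  for (r in raters) out[[paste0("p_", r)]] <- pmat[, r]
  attr(out, "weights") <- weights
  attr(out, "target_class") <- target_class
  class(out) <- c("ensemble_prediction", class(out))
  out
}

#' @rdname ensemble_predict
#' @param object A `rater_ensemble` from [fit_rater_ensemble()].
#' @param ... Passed on to [ensemble_predict()].
#' @export
predict.rater_ensemble <- function(object, table, target_class, children = NULL, ...) {
  ensemble_predict(object$models, object$weights, table, object$vocabulary,
                   target_class, children = children, ...)
}

#' @export
tidy.rater_ensemble <- function(x, ...) {
  x$weights
}

#' @export
glance.rater_ensemble <- function(x, ...) {
  tibble(n_raters = length(x$models),
         n_children = length(unique(names(x$labels))),
         n_validation = length(x$validation_children),
         baseline = x$baseline,
         max_weight = max(x$weights$w),
         min_weight = min(x$weights$w))
}

#' Plot rater weights
#'
#' @param object A `rater_ensemble`.
#' @param ... Unused.
#' @return A ggplot: accuracy deltas and softmax weights per rater.
#' @export
autoplot.rater_ensemble <- function(object, ...) {
  d <- object$weights %>%
    tidyr::pivot_longer(c("z", "w"), names_to = "quantity", values_to = "value") %>%
    mutate(quantity = dplyr::recode(.data$quantity,
                                    z = "accuracy delta z",
                                    w = "softmax weight w"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rater_id, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "rater", y = NULL) +
    ggplot2::theme_minimal()
}
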