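#' Balanced class weights
#'
#' Weights inversely proportional to class frequency, `n / (2 * n_c)` for
#' class `c`, so each class contributes the same total weight (`n / 2`).
#'
#' @param y Binary labels (0/1, logical, or 2-level factor).
#' @return Numeric weight per observation.
#' @export
balanced_weights <- function(y) {
  y <- as.integer(as.factor(y)) - 1L
  n <- length(y)
  n1 <- sum(y == 1L)
  n0 <- n - n1
  if (n1 == 0L || n0 == 0L) abort("both classes must be present.")
  ifelse(y == 1L, n / (2 * n1), n / (2 * n0))
}

#' Elastic-net logistic regression objective
#'
#' The penalized loss the cross-site models minimize:
#' mean weighted logistic log-loss plus
#' `alpha * (rho * sum|beta| + (1 - rho)/2 * sum(beta^2))`, with the intercept
#' unpenalized. `rho` mixes the lasso (L1) and ridge (L2) penalties; `alpha`
#' scales the overall regularization strength. Weights are rescaled to sum to
#' the sample size, so the loss is per-sample.
#'
#' @param beta Coefficient vector (length = `ncol(X)`).
#' @param intercept Scalar intercept.
#' @param X Feature matrix.
#' @param y Binary 0/1 labels.
#' @param alpha Regularization strength, `>= 0`.
#' @param rho L1/L2 mixing parameter in `[0, 1]`.
#' @param weights Observation weights; `NULL` for balanced class weights.
#' @return Scalar objective value.
#' @export
elastic_net_objective <- function(beta, intercept, X, y, alpha, rho,
                                  weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(beta) != ncol(X)) abort("`beta` length must equal ncol(X).")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (rho < 0 || rho > 1) abort("`rho` must lie in [0, 1].")
  if (any(!is.finite(beta)) || !is.finite(intercept) || any(!is.finite(X))) {
    abort("non-finite inputs.")
  }
  if (is.null(weights)) weights <- balanced_weights(y)
  weights <- weights * length(y) / sum(weights)
  eta <- intercept + drop(X %*% beta)
  # numerically stable -[y*log(p) + (1-y)*log(1-p)]
  ll <- (1 - y) * eta + log1p(exp(-eta))
  ll[eta < -30] <- ((1 - y) * eta - eta)[eta < -30]
  loss <- sum(weights * ll) / length(y)
  penalty <- alpha * (rho * sum(abs(beta)) + (1 - rho) / 2 * sum(beta^2))
  loss + penalty
}

#' Fit an elastic-net logistic regression
#'
#' Minimizes [elastic_net_objective()] by coordinate descent (via glmnet,
#' called with `standardize = FALSE` and a warm-start path ending at the
#' requested `alpha` so the returned solution matches the stated objective).
#' Balanced class weights are the default, matching the screening setting's
#' class imbalance handling.
#'
#' @inheritParams elastic_net_objective
#' @param class_weights `"balanced"` (default), `"none"`, or a numeric weight
#'   per observation.
#' @param thresh Coordinate-descent convergence threshold.
#' @return An `elastic_net_model`: `beta` (named), `intercept`, `alpha`,
#'   `rho`, `weights`, `converged`, `npasses`. `tidy()` gives a coefficient
#'   tibble; `predict()` returns probabilities.
#' @export
fit_elastic_net <- function(X, y, alpha, rho, class_weights = "balanced",
                            thresh = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) abort("single-class `y`; cannot fit.")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (rho < 0 || rho > 1) abort("`rho` must lie in [0, 1].")
  w <- if (identical(class_weights, "balanced")) {
    balanced_weights(y)
  } else if (identical(class_weights, "none")) {
    rep(1, length(y))
  } else {
    as.numeric(class_weights)
  }
  w <- w * length(y) / sum(w)
  # decreasing warm-start path ending exactly at the requested strength
  lam <- if (alpha > 0) {
    alpha * 10^seq(3, 0, length.out = 30)
  } else {
    c(10^seq(1, -5, length.out = 25), 0)
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                        alpha = rho, lambda = lam,
                        standardize = FALSE, thresh = thresh,
                        maxit = 10^6)
  i <- length(fit$lambda)
  beta <- as.numeric(fit$beta[, i])
  names(beta) <- colnames(X)
  structure(list(beta = beta, intercept = unname(fit$a0[i]),
                 alpha = alpha, rho = rho, weights = w,
                 converged = fit$jerr == 0, npasses = fit$npasses,
                 features = colnames(X)),
            class = "elastic_net_model")
}

#' @export
print.elastic_net_model <- function(x, ...) {
  cat("<elastic_net_model> alpha=", x$alpha, ", rho=", x$rho, ", ",
      sum(abs(x$beta) > 1e-8), "/", length(x$beta), " nonzero coefficients\n",
      sep = "")
  invisible(x)
}

#' @export
predict.elastic_net_model <- function(object, X, type = c("prob", "link"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (!is.null(object$features) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$features)) {
    abort("feature mismatch with fitted model.")
  }
  eta <- object$intercept + drop(X %*% object$beta)
  if (type == "link") eta else plogis(eta)
}

#' @export
tidy.elastic_net_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$beta)),
         estimate = c(x$intercept, unname(x$beta)),
         selected = c(TRUE, abs(x$beta) > 1e-8))
}

#' @export
glance.elastic_net_model <- function(x, ...) {
  tibble(alpha = x$alpha, rho = x$rho,
         n_selected = sum(abs(x$beta) > 1e-8),
         n_features = length(x$beta),
         converged = x$converged, npasses = x$npasses)
}

# stratified sample-level folds for the grid search
sample_folds <- function(y, k, seed) {
  local_seed(seed, {
    ord <- order(y, runif(length(y)))
  })
  fold <- integer(length(y))
  fold[ord] <- rep_len(seq_len(k), length(y))
  fold
}

#' Cross-validated grid search over elastic-net hyperparameters
#'
#' Evaluates every `(alpha, rho)` pair by stratified k-fold cross-validation,
#' recording mean AUC and accuracy per cell, and selects the pair with the
#' highest mean AUC (ties broken toward larger `alpha`, then larger `rho`,
#' preferring the more regularized model). Folds where training or truth is
#' single-class are skipped with a warning.
#'
#' @inheritParams fit_elastic_net
#' @param alpha_grid,rho_grid Hyperparameter grids.
#' @param k Number of folds (default 3).
#' @param seed Integer seed for the fold split.
#' @return A `grid_search_result`: `$table` (one row per cell: `alpha`,
#'   `rho`, `auc`, `accuracy`), `$best` (selected pair), `$fold_models`
#'   (fitted per-fold models per cell, for selection-frequency analysis) and
#'   `$fold` assignment.
#' @export
grid_search_cv <- function(X, y, alpha_grid = c(1, 0.1, 0.01, 0.001),
                           rho_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           k = 3L, seed = 1L, class_weights = "balanced") {
  if (length(alpha_grid) == 0 || length(rho_grid) == 0) abort("empty grid.")
  X <- as.matrix(X)
  y <- as.numeric(y)
  fold <- sample_folds(y, k, derive_seed(seed, "grid_folds"))
  cells <- tidyr::expand_grid(alpha = alpha_grid, rho = rho_grid)
  fold_models <- vector("list", nrow(cells))
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    a <- cells$alpha[ci]; r <- cells$rho[ci]
    aucs <- accs <- numeric(0)
    models <- list()
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
        warn(sprintf("grid cell (%g, %g): fold %d skipped (single class).", a, r, f))
        next
      }
      m <- fit_elastic_net(X[tr, , drop = FALSE], y[tr], alpha = a, rho = r,
                           class_weights = class_weights)
      p <- predict(m, X[!tr, , drop = FALSE])
      aucs <- c(aucs, auc_rank(y[!tr], p))
      accs <- c(accs, mean((p >= 0.5) == (y[!tr] == 1)))
      models[[length(models) + 1L]] <- m
    }
    fold_models[[ci]] <- models
    res[[ci]] <- tibble(alpha = a, rho = r,
                        auc = mean(aucs), accuracy = mean(accs),
                        n_folds = length(aucs))
  }
  tab <- bind_rows(res)
  ord <- order(-tab$auc, -tab$alpha, -tab$rho)
  best <- tab[ord[1L], c("alpha", "rho")]
  names(fold_models) <- sprintf("alpha%g_rho%g", cells$alpha, cells$rho)
  structure(list(table = tab, best = as.list(best),
                 fold_models = fold_models, fold = fold, k = k),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result> best: alpha=", x$best$alpha,
      ", rho=", x$best$rho, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Feature-selection frequency over cross-validation folds
#'
#' Counts, per feature, the number of fitted fold models in which its
#' coefficient is numerically nonzero (`|beta| > 1e-8`).
#'
#' @param models List of `elastic_net_model`s (one per fold).
#' @return A tibble `feature`, `count`, sorted by descending count.
#' @export
selection_frequency <- function(models) {
  if (length(models) == 0) abort("need at least one fitted model.")
  feats <- names(models[[1]]$beta)
  counts <- rowSums(vapply(models, function(m) abs(m$beta) > 1e-8,
                           logical(length(feats))))
  tibble(feature = feats, count = as.integer(counts)) %>%
    arrange(dplyr::desc(.data$count), match(.data$feature, feats))
}

#' Consensus per-child feature vectors
#'
#' Collapses the multi-rater annotation table to one answer vector per child
#' by plurality vote over raters per question; ties are broken toward the
#' lowest code. Missing answers do not vote; a question no rater could score
#' gets the sentinel code.
#'
#' @inheritParams validate_annotations
#' @return List with `x` (integer matrix children x questions), `y` (factor
#'   of diagnoses) and `children` (tibble).
#' @export
consensus_features <- function(table, vocabulary) {
  table <- validate_annotations(table, vocabulary)
  rec <- child_records(table, vocabulary)
  sent <- sentinel_codes(vocabulary)
  x <- matrix(NA_integer_, nrow(rec), nrow(vocabulary),
              dimnames = list(rec$child_id, vocabulary$question))
  for (q in vocabulary$question) {
    votes <- split(table[[q]], table$child_id)
    x[, q] <- vapply(rec$child_id, function(id) {
      v <- votes[[id]]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(sent[[q]])
      cnt <- base::table(v)
      win <- as.integer(names(cnt)[cnt == max(cnt)])
      min(win)
    }, integer(1))
  }
  list(x = x, y = setNames(rec$diagnosis, rec$child_id), children = rec)
}

#' Cross-site transfer evaluation
#'
#' The generalizability analysis: on the training site, split children 80/20
#' (stratified), grid-search elastic-net hyperparameters by cross-validation
#' on the 80%, fit the final model with the selected pair and balanced class
#' weights, then report AUC and accuracy on the same-site 20% held-out set
#' and on the full other site. Children are represented by consensus answer
#' vectors ([consensus_features()]); the positive class is autism.
#'
#' @param train_table,test_table Annotation tibbles for the two sites.
#' @param vocabulary A [feature_vocabulary()].
#' @param alpha_grid,rho_grid Hyperparameter grids (see [grid_search_cv()]).
#' @param k Cross-validation folds in the grid search.
#' @param holdout Held-out fraction of the training site (default 0.2).
#' @param seed Integer seed (split and folds).
#' @param positive Positive diagnosis (default `"ASD"`).
#' @return A `transfer_result`: `$metrics` (one row each for `heldout` and
#'   `cross_site`), `$model` (final fit), `$grid` (search result), and
#'   `$selection` (per-alpha selection-frequency tibbles at that alpha's best
#'   `rho`).
#' @export
transfer_evaluate <- function(train_table, test_table, vocabulary,
                              alpha_grid = c(1, 0.1, 0.01, 0.001),
                              rho_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              k = 3L, holdout = 0.2, seed = 1L,
                              positive = "ASD") {
  tr <- consensus_features(train_table, vocabulary)
  te <- consensus_features(test_table, vocabulary)
  if (!identical(colnames(tr$x), colnames(te$x))) {
    abort("feature mismatch between sites.")
  }
  y_tr <- as.integer(as.character(tr$y) == positive)
  y_te <- as.integer(as.character(te$y) == positive)
  split <- stratified_holdout(seq_along(y_tr), y_tr, holdout,
                              derive_seed(seed, "transfer_holdout"))
  fit_ids <- split$train
  hold_ids <- split$validation
  grid <- grid_search_cv(tr$x[fit_ids, , drop = FALSE], y_tr[fit_ids],
                         alpha_grid = alpha_grid, rho_grid = rho_grid,
                         k = k, seed = seed)
  model <- fit_elastic_net(tr$x[fit_ids, , drop = FALSE], y_tr[fit_ids],
                           alpha = grid$best$alpha, rho = grid$best$rho)
  eval_on <- function(x, y, which) {
    p <- predict(model, x)
    tibble(set = which, auc = auc_rank(y, p),
           accuracy = mean((p >= 0.5) == (y == 1)), n = length(y))
  }
  metrics <- bind_rows(
    eval_on(tr$x[hold_ids, , drop = FALSE], y_tr[hold_ids], "heldout"),
    eval_on(te$x, y_te, "cross_site")
  )
  # per-alpha selection frequencies at that alpha's best-AUC rho
  selection <- lapply(alpha_grid, function(a) {
    sub <- grid$table %>% filter(.data$alpha == a)
    r <- sub$rho[order(-sub$auc, -sub$rho)][1]
    selection_frequency(grid$fold_models[[sprintf("alpha%g_rho%g", a, r)]]) %>%
      mutate(alpha = a, rho = r)
  })
  names(selection) <- sprintf("alpha%g", alpha_grid)
  structure(list(metrics = metrics, model = model, grid = grid,
                 selection = selection, seed = seed, positive = positive),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer_result> positive class: ", x$positive, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.transfer_result <- function(x, ...) {
  x$metrics
}

#' @export
glance.transfer_result <- function(x, ...) {
  tibble(alpha = x$grid$best$alpha, rho = x$grid$best$rho,
         heldout_auc = x$metrics$auc[x$metrics$set == "heldout"],
         cross_site_auc = x$metrics$auc[x$metrics$set == "cross_site"],
         heldout_accuracy = x$metrics$accuracy[x$metrics$set == "heldout"],
         cross_site_accuracy = x$metrics$accuracy[x$metrics$set == "cross_site"])
}
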