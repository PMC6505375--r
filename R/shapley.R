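# interventional value function: predictions with features in `keep_cols`
# taken from each x row and the rest from reference rows, averaged over the
# reference set. `fun` maps a feature matrix to a numeric vector.

model_fun <- function(model, target_class) {
  if (is.function(model)) return(model)
  if (inherits(model, "rater_model")) {
    if (is.null(target_class)) abort("`target_class` required for a rater_model.")
    return(function(m) {
      pr <- predict(model, m, type = "prob")
      as.numeric(pr[, target_class])
    })
  }
  abort("`model` must be a rater_model or a function(matrix) -> numeric.")
}

#' Per-model Shapley attribution
#'
#' Interventional Shapley values of each feature for each video (child), with
#' the base value defined as the mean predicted target-class probability over
#' a reference set. Local accuracy holds by construction: for every video,
#' base value + sum of its Shapley values = the model's predicted probability.
#'
#' Two computation paths:
#' * `"exact"` — all-subset enumeration (feasible up to `max_exact` features);
#'   exact interventional Shapley values.
#' * `"sampling"` — paired permutation sampling: each draw pairs a random
#'   feature ordering with a random reference row, and marginal contributions
#'   telescope, so local accuracy is exact even though individual values are
#'   Monte-Carlo estimates (the base value is then the mean prediction over
#'   the sampled reference rows).
#'
#' `"auto"` picks exact when the feature count allows it.
#'
#' @param model A `rater_model`, or a function mapping a feature matrix to a
#'   numeric prediction vector.
#' @param X Encoded feature matrix of the videos to explain (rows = children).
#' @param reference Encoded reference matrix (e.g. the training fold's
#'   matrix) defining the base value.
#' @param target_class Class whose predicted probability is attributed
#'   (ignored when `model` is already a function).
#' @param method `"auto"`, `"exact"` or `"sampling"`.
#' @param n_perm Permutation draws for the sampling path (default 2048).
#' @param seed Seed for the sampling path.
#' @param max_exact Largest feature count for the exact path (default 12).
#' @return An `attribution_matrix`: list with `phi` (videos x features),
#'   `base`, `prediction` (per-video model output), `target_class`, `method`.
#' @export
model_shapley <- function(model, X, reference, target_class = NULL,
                          method = c("auto", "exact", "sampling"),
                          n_perm = 2048L, seed = 1L, max_exact = 12L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  reference <- as.matrix(reference)
  if (nrow(reference) == 0) abort("`reference` must be non-empty.")
  if (!identical(colnames(X), colnames(reference)) && !is.null(colnames(X))) {
    abort("feature mismatch between `X` and `reference`.")
  }
  if (inherits(model, "rater_model") &&
      !identical(colnames(X), model$features)) {
    abort("feature mismatch between `X` and the model.")
  }
  f <- model_fun(model, target_class)
  p <- ncol(X)
  if (method == "auto") method <- if (p <= max_exact) "exact" else "sampling"
  res <- if (method == "exact") {
    if (p > max_exact) abort(sprintf("exact path limited to %d features.", max_exact))
    shapley_exact(f, X, reference)
  } else {
    shapley_sampling(f, X, reference, n_perm = n_perm, seed = seed)
  }
  structure(list(phi = res$phi, base = res$base, prediction = f(X),
                 target_class = target_class, method = method),
            class = "attribution_matrix")
}

# exact interventional Shapley by all-subset enumeration.
# v[mask, i] = mean over reference rows of f(x_i on mask, reference elsewhere);
# phi accumulated with the factorial subset weights.
shapley_exact <- function(f, X, reference) {
  p <- ncol(X)
  n <- nrow(X)
  m <- nrow(reference)
  n_mask <- bitwShiftL(1L, p)
  # subset membership table: n_mask x p logical
  members <- matrix(FALSE, n_mask, p)
  for (k in seq_len(p)) {
    members[, k] <- bitwAnd(seq_len(n_mask) - 1L, bitwShiftL(1L, k - 1L)) > 0L
  }
  sizes <- rowSums(members)
  v <- matrix(NA_real_, n_mask, n)
  # composite block for one subset: n*m rows (x rows cycled over reference)
  xi <- rep(seq_len(n), each = m)
  zi <- rep(seq_len(m), times = n)
  for (mask in seq_len(n_mask)) {
    keep <- members[mask, ]
    comp <- reference[zi, , drop = FALSE]
    if (any(keep)) comp[, keep] <- X[xi, keep, drop = FALSE]
    pred <- f(comp)
    v[mask, ] <- colMeans(matrix(pred, nrow = m))
  }
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  phi <- matrix(0, n, p, dimnames = list(rownames(X), colnames(X)))
  for (k in seq_len(p)) {
    without <- which(!members[, k])
    with_k <- without + bitwShiftL(1L, k - 1L)
    w <- wts[sizes[without] + 1L]
    phi[, k] <- colSums(w * (v[with_k, , drop = FALSE] - v[without, , drop = FALSE]))
  }
  list(phi = phi, base = unname(v[1L, ]))
}

# paired permutation sampling: each draw couples a feature ordering with one
# reference row; marginal contributions telescope from f(z) to f(x)
shapley_sampling <- function(f, X, reference, n_perm, seed) {
  p <- ncol(X)
  n <- nrow(X)
  phi <- matrix(0, n, p, dimnames = list(rownames(X), colnames(X)))
  base_sum <- 0
  local_seed(seed, {
    perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
    zrows <- sample.int(nrow(reference), n_perm, replace = TRUE)
  })
  chunk <- max(1L, floor(20000 / ((p + 1) * n)))
  for (start in seq(1L, n_perm, by = chunk)) {
    bs <- start:min(start + chunk - 1L, n_perm)
    comps <- vector("list", length(bs))
    for (ci in seq_along(bs)) {
      b <- bs[ci]
      z <- reference[zrows[b], ]
      steps <- matrix(rep(z, each = (p + 1L) * n), (p + 1L) * n, p)
      colnames(steps) <- colnames(X)
      # step s has the first s features of the permutation taken from x
      for (s in seq_len(p)) {
        rows <- (s * n + 1L):((p + 1L) * n)  # steps s..p include feature perm[s]
        steps[rows, perms[[b]][s]] <- rep(X[, perms[[b]][s]], times = p - s + 1L)
      }
      comps[[ci]] <- steps
    }
    pred <- f(do.call(rbind, comps))
    off <- 0L
    for (ci in seq_along(bs)) {
      b <- bs[ci]
      block <- matrix(pred[(off + 1L):(off + (p + 1L) * n)], nrow = n)
      off <- off + (p + 1L) * n
      base_sum <- base_sum + block[1L, 1L]
      d <- block[, 2L:(p + 1L), drop = FALSE] - block[, 1L:p, drop = FALSE]
      phi[, perms[[b]]] <- phi[, perms[[b]]] + d
    }
  }
  list(phi = phi / n_perm, base = rep(base_sum / n_perm, n))
}

#' Brute-force Shapley oracle
#'
#' Classic Shapley values for a single input by direct evaluation of the
#' factorial-weighted subset formula, with the value of a coalition defined by
#' reference-value substitution (features outside the coalition are replaced
#' by each reference row in turn and predictions averaged). Exponential in the
#' feature count; intended as an independent correctness oracle for small
#' problems, not for production use.
#'
#' @inheritParams model_shapley
#' @param x A single feature vector (or 1-row matrix).
#' @return Named numeric vector of per-feature Shapley values.
#' @export
exact_shapley_oracle <- function(model, x, reference, target_class = NULL) {
  f <- model_fun(model, target_class)
  reference <- as.matrix(reference)
  x <- if (is.matrix(x)) x[1L, ] else x
  p <- length(x)
  if (p > 12L) abort("oracle limited to 12 features.")
  value <- function(S) {
    comp <- reference
    if (length(S) > 0) comp[, S] <- matrix(rep(x[S], each = nrow(reference)),
                                           nrow(reference))
    mean(f(comp))
  }
  phi <- numeric(p)
  others <- seq_len(p)
  for (k in seq_len(p)) {
    rest <- setdiff(others, k)
    for (s in 0:length(rest)) {
      subsets <- if (s == 0) list(integer(0)) else
        utils::combn(rest, s, simplify = FALSE)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      for (S in subsets) {
        phi[k] <- phi[k] + w * (value(c(S, k)) - value(S))
      }
    }
  }
  names(phi) <- if (!is.null(names(x))) names(x) else colnames(reference)
  phi
}

#' Ensemble-level Shapley attribution
#'
#' Because the ensemble prediction is the weight-weighted linear combination
#' of the rater models' predictions, its Shapley values are the same
#' combination of the per-model Shapley values, and its base value the same
#' combination of per-model base values — no re-explanation needed. Local
#' accuracy at the ensemble level follows by linearity.
#'
#' @param per_model Named list of `attribution_matrix` objects, one per rater,
#'   aligned on (video, feature); names must match `weights$rater_id`.
#' @param weights A `weight_vector` from [softmax_weights()].
#' @return An `ensemble_attribution`: `phi`, `base`, `prediction`, `weights`.
#' @export
ensemble_shapley <- function(per_model, weights) {
  if (!inherits(weights, "weight_vector")) abort("`weights` must come from softmax_weights().")
  if (!setequal(names(per_model), weights$rater_id)) {
    abort("attribution names and weight rater ids must match.")
  }
  ref <- per_model[[weights$rater_id[1]]]
  for (a in per_model) {
    if (!identical(dim(a$phi), dim(ref$phi)) ||
        !identical(rownames(a$phi), rownames(ref$phi)) ||
        !identical(colnames(a$phi), colnames(ref$phi))) {
      abort("attribution matrices are misaligned on (video, feature).")
    }
  }
  w <- setNames(weights$w, weights$rater_id)
  phi <- Reduce(`+`, lapply(weights$rater_id, function(r) w[[r]] * per_model[[r]]$phi))
  base <- Reduce(`+`, lapply(weights$rater_id, function(r) w[[r]] * per_model[[r]]$base))
  pred <- Reduce(`+`, lapply(weights$rater_id, function(r) w[[r]] * per_model[[r]]$prediction))
  structure(list(phi = phi, base = base, prediction = pred, weights = weights),
            class = "ensemble_attribution")
}

#' Global feature importance from attributions
#'
#' A feature's global importance is the sum over videos of the absolute value
#' of its (ensemble) Shapley values; features are ranked by that sum, ties
#' broken by feature order.
#'
#' @param attr An `attribution_matrix` or `ensemble_attribution`.
#' @return A tibble `feature`, `importance`, `rank`, sorted by rank.
#' @export
global_importance <- function(attr) {
  phi <- attr$phi
  if (nrow(phi) < 1L) abort("need at least one video.")
  imp <- colSums(abs(phi))
  ord <- order(-imp, seq_along(imp))
  tibble(feature = colnames(phi)[ord], importance = unname(imp[ord]),
         rank = seq_along(imp))
}

#' @export
tidy.attribution_matrix <- function(x, ...) {
  as_tibble(x$phi, rownames = "child_id") %>%
    tidyr::pivot_longer(-"child_id", names_to = "feature", values_to = "phi")
}

#' @export
tidy.ensemble_attribution <- tidy.attribution_matrix

#' Explain a fitted rater ensemble
#'
#' Computes per-rater Shapley attributions (each rater model explained on its
#' own annotations of the requested children, against its own annotations of
#' the reference children) and combines them with the ensemble weights.
#' Children must be covered by every rater.
#'
#' @param ensemble A [fit_rater_ensemble()] result.
#' @param table Annotation tibble containing the children to explain.
#' @param target_class Class whose probability is attributed.
#' @param children Children to explain (default: all in `table`).
#' @param reference_children Children defining the base value (default: the
#'   explained children themselves).
#' @inheritParams model_shapley
#' @return An `ensemble_attribution`.
#' @export
explain_ensemble <- function(ensemble, table, target_class, children = NULL,
                             reference_children = NULL,
                             method = c("auto", "exact", "sampling"),
                             n_perm = 2048L, seed = 1L, max_exact = 12L) {
  method <- match.arg(method)
  voc <- ensemble$vocabulary
  table <- validate_annotations(table, voc)
  if (is.null(children)) children <- sort(unique(table$child_id))
  if (is.null(reference_children)) reference_children <- children
  per_model <- lapply(ensemble$weights$rater_id, function(r) {
    enc <- encode_matrix(table, voc, r)
    missing_kids <- setdiff(c(children, reference_children), rownames(enc$x))
    if (length(missing_kids) > 0) {
      abort(sprintf("rater %s did not rate child %s.", r, missing_kids[1]))
    }
    model_shapley(ensemble$models[[r]],
                  X = enc$x[children, , drop = FALSE],
                  reference = enc$x[reference_children, , drop = FALSE],
                  target_class = target_class, method = method,
                  n_perm = n_perm, seed = derive_seed(seed, r),
                  max_exact = max_exact)
  })
  names(per_model) <- ensemble$weights$rater_id
  ensemble_shapley(per_model, ensemble$weights)
}

#' Plot global feature importance
#'
#' @param object An `ensemble_attribution` (or `attribution_matrix`).
#' @param top_n Number of features shown (default 15).
#' @param ... Unused.
#' @return A ggplot bar chart of summed absolute Shapley values.
#' @export
autoplot.ensemble_attribution <- function(object, top_n = 15L, ...) {
  d <- global_importance(object) %>% head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, .data$importance),
                                  y = .data$importance)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sum of |Shapley value| over videos") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.attribution_matrix <- autoplot.ensemble_attribution
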