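test_that("rater models learn separable data and are seed-deterministic", {
  voc <- small_vocab(3L)
  # one question fully determines the label
  children <- sprintf("c%02d", 1:30)
  dx <- setNames(rep(c("TD", "ASD", "SLC"), each = 10), children)
  tab <- blank_table(children, "r1", voc, dx)
  tab$q01 <- c(TD = 0L, ASD = 2L, SLC = 1L)[tab$diagnosis]
  m <- train_rater_model(tab, voc, "r1", config = rater_model_config(num_trees = 100))
  enc <- encode_matrix(tab, voc, "r1")
  expect_identical(unname(predict(m, enc$x, type = "label")),
                   as.character(enc$y))
  m2 <- train_rater_model(tab, voc, "r1", config = rater_model_config(num_trees = 100))
  expect_equal(predict(m, enc$x), predict(m2, enc$x))

  single <- dplyr::filter(tab, diagnosis == "TD")
  expect_error(train_rater_model(single, voc, "r1"), "single-class")
})

test_that("shuffled labels yield held-out accuracy near the majority rate", {
  fx <- small_annotations(n_per_class = 20L, seed = 30L, separation = 0.9)
  voc <- fx$vocabulary
  ids <- sort(unique(fx$table$child_id))
  accs <- numeric(30)
  withr::with_seed(99, {
    for (i in seq_along(accs)) {
      fake <- setNames(sample(rep(c("A", "B"), c(36, 24))), ids)
      train_ids <- ids[1:40]
      test_ids <- ids[41:60]
      m <- train_rater_model(
        dplyr::filter(fx$table, child_id %in% train_ids), voc, "r1",
        labels = factor(fake[train_ids]),
        config = rater_model_config(num_trees = 60, seed = i)
      )
      enc <- encode_matrix(fx$table, voc, "r1")
      pred <- predict(m, enc$x[test_ids, ], type = "label")
      accs[i] <- mean(pred == fake[test_ids])
    }
  })
  # labels carry no signal: held-out accuracy stays at chance level,
  # bounded by the 60/40 majority rate plus Monte-Carlo slack
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.70)
})

test_that("majority vote matches a brute-force plurality oracle", {
  expect_identical(majority_vote(matrix(c("ASD", "ASD", "SLC"), 1)), "ASD")
  expect_identical(majority_vote(matrix("SLC", 1, 1)), "SLC")

  # exhaustive 3-voter, 3-class enumeration against an independent oracle
  lv <- c("TD", "SLC", "ASD")
  prev_labels <- c("TD", "TD", "TD", "SLC", "SLC", "ASD")  # TD > SLC > ASD
  oracle <- function(v) {
    cnt <- sapply(lv, function(l) sum(v == l))
    top <- lv[cnt == max(cnt)]
    if (length(top) == 1L) return(top)
    prev <- sapply(top, function(l) sum(prev_labels == l))
    top <- top[prev == max(prev)]
    top[1]  # fixed class order TD, SLC, ASD
  }
  combos <- expand.grid(lv, lv, lv, stringsAsFactors = FALSE)
  got <- majority_vote(as.matrix(combos), prevalence_labels = prev_labels,
                       levels = lv)
  want <- apply(as.matrix(combos), 1, oracle)
  expect_identical(unname(got), unname(want))
})

test_that("accuracy deltas are plain accuracy differences", {
  truth <- c("A", "A", "B", "B", "A")
  model <- c("A", "A", "B", "B", "B")   # 4/5
  base <- c("A", "B", "B", "A", "B")    # 2/5... adjust to 3/5
  base <- c("A", "A", "B", "A", "B")    # 3/5
  expect_equal(accuracy_delta(truth, model, base), 0.2)
  expect_equal(accuracy_delta(truth, model, model), 0)
  expect_equal(accuracy_delta(truth, truth, c("B", "B", "A", "A", "B")), 1)
  expect_error(accuracy_delta(character(0), character(0), character(0)), "empty")
})

test_that("softmax weights match the analytic formula and its properties", {
  w <- softmax_weights(c(a = 0, b = 0, c = 0))
  expect_equal(w$w, rep(1 / 3, 3))

  w2 <- softmax_weights(c(log(2), 0, 0))
  expect_equal(w2$w, c(0.5, 0.25, 0.25))

  z <- c(0.3, -0.1, 0.0)
  expect_equal(softmax_weights(z)$w, exp(z) / sum(exp(z)), tolerance = 1e-12)

  # properties over random vectors: simplex, shift invariance, monotonicity
  withr::with_seed(4, {
    for (i in 1:20) {
      zi <- rnorm(5)
      wi <- softmax_weights(zi)
      expect_true(all(wi$w > 0))
      expect_equal(sum(wi$w), 1, tolerance = 1e-9)
      expect_equal(softmax_weights(zi + 3.7)$w, wi$w, tolerance = 1e-12)
      expect_identical(order(wi$z), order(wi$w))
      zj <- zi; zj[2] <- zj[2] + 0.5
      wj <- softmax_weights(zj)
      expect_gt(wj$w[2], wi$w[2])
      expect_true(all(wj$w[-2] < wi$w[-2]))
    }
  })

  expect_error(softmax_weights(numeric(0)), "non-empty")
  expect_error(softmax_weights(c(1, Inf)), "finite")
})

test_that("ensemble prediction is the exact weighted combination", {
  voc <- small_vocab(3L)
  children <- sprintf("c%02d", 1:10)
  dx <- setNames(rep(c("TD", "ASD"), 5), children)
  tab <- blank_table(children, c("r1", "r2", "r3"), voc, dx)

  withr::with_seed(17, {
    for (rep in 1:10) {
      probs <- lapply(1:3, function(i) setNames(runif(10), children))
      models <- lapply(1:3, function(i) {
        fake_rater_model(paste0("r", i), voc$question, probs[[i]])
      })
      names(models) <- paste0("r", 1:3)
      wt <- softmax_weights(setNames(rnorm(3), paste0("r", 1:3)))
      pred <- ensemble_predict(models, wt, tab, voc, "pos")
      pmat <- do.call(cbind, lapply(probs, function(p) p[pred$child_id]))
      manual <- unname(drop(pmat %*% wt$w))
      expect_equal(pred$p_ensemble, manual, tolerance = 1e-12)
      # bounded by per-rater extremes
      expect_true(all(pred$p_ensemble >= apply(pmat, 1, min) - 1e-12))
      expect_true(all(pred$p_ensemble <= apply(pmat, 1, max) + 1e-12))
    }
  })
})

test_that("degenerate and partial-coverage ensembles behave as specified", {
  voc <- small_vocab(3L)
  children <- sprintf("c%02d", 1:6)
  dx <- setNames(rep(c("TD", "ASD"), 3), children)
  tab <- blank_table(children, c("r1", "r2"), voc, dx)
  p1 <- setNames(seq(0.1, 0.6, by = 0.1), children)
  p2 <- setNames(rep(0.9, 6), children)
  models <- list(r1 = fake_rater_model("r1", voc$question, p1),
                 r2 = fake_rater_model("r2", voc$question, p2))

  # weight (1, 0): first model's probability exactly
  w10 <- softmax_weights(c(r1 = 0, r2 = -700))
  pred <- ensemble_predict(models, w10, tab, voc, "pos")
  expect_equal(pred$p_ensemble, unname(p1[pred$child_id]), tolerance = 1e-12)

  # equal weights: arithmetic mean
  weq <- softmax_weights(c(r1 = 0.3, r2 = 0.3))
  pred_eq <- ensemble_predict(models, weq, tab, voc, "pos")
  expect_equal(pred_eq$p_ensemble, unname((p1 + p2)[pred_eq$child_id] / 2))

  # a child unseen by r2: weights renormalize onto r1
  tab_part <- dplyr::filter(tab, !(rater_id == "r2" & child_id == "c01"))
  wt <- softmax_weights(c(r1 = 0.1, r2 = 0.4))
  pp <- ensemble_predict(models, wt, tab_part, voc, "pos")
  expect_equal(pp$p_ensemble[pp$child_id == "c01"], unname(p1["c01"]))
  expect_true(is.na(pp$p_r2[pp$child_id == "c01"]))

  # a child covered by nobody: error
  tab_none <- dplyr::filter(tab, child_id != "c02")
  expect_error(
    ensemble_predict(models, wt, tab_none, voc, "pos", children = children),
    "no covering rater"
  )
})

test_that("the full ensemble fit recovers rater quality structure", {
  fx <- small_annotations(
    n_per_class = 15L, p = 6L, seed = 77L, separation = 0.7,
    profiles = list(
      rater_profile("good", 0.95, 0, small_vocab(6L)),
      rater_profile("bad", 0.35, 0, small_vocab(6L))
    )
  )
  labels <- binarize_labels(encode_matrix(fx$table, fx$vocabulary, "good")$y, 1L)
  labels <- setNames(factor(labels), names(labels))
  ens <- fit_rater_ensemble(fx$table, fx$vocabulary, labels = labels,
                            config = rater_model_config(num_trees = 150),
                            seed = 5)
  expect_s3_class(ens$weights, "weight_vector")
  expect_equal(sum(ens$weights$w), 1, tolerance = 1e-9)
  # deterministic refit
  ens2 <- fit_rater_ensemble(fx$table, fx$vocabulary, labels = labels,
                             config = rater_model_config(num_trees = 150),
                             seed = 5)
  expect_equal(ens$weights, ens2$weights)
  expect_identical(tidy(ens), ens$weights)
  expect_equal(glance(ens)$n_raters, 2L)
})
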