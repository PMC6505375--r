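# Shared fixtures: small vocabularies, tiny simulated tables, and fake rater
# models with prescribed probabilities (for arithmetic oracles).

small_vocab <- function(p = 5L, n_codes = 3L) {
  feature_vocabulary(
    questions = sprintf("q%02d", seq_len(p)),
    names = sprintf("item %02d", seq_len(p)),
    labels = rep(list(sprintf("choice %d", seq_len(n_codes))), p)
  )
}

# small annotated cohort on a small vocabulary
small_annotations <- function(n_per_class = 8L, p = 5L, seed = 42L,
                              separation = 0.9, profiles = NULL,
                              missingness = 0) {
  voc <- small_vocab(p)
  spec <- cohort_spec(n_per_class, n_per_class, n_per_class,
                      archetypes = default_archetypes(voc, separation),
                      vocabulary = voc)
  cohort <- generate_cohort(spec, seed = seed)
  if (is.null(profiles)) {
    profiles <- list(rater_profile("r1", 0.95, missingness, voc),
                     rater_profile("r2", 0.75, missingness, voc))
  }
  list(vocabulary = voc, cohort = cohort,
       table = simulate_raters(cohort, profiles, seed = seed + 1L))
}

# a "rater model" whose probabilities are a fixed lookup by child id, for
# exact-arithmetic ensemble tests
fake_rater_model <- function(rater_id, features, prob_pos, classes = c("neg", "pos")) {
  fit <- structure(list(prob_pos = prob_pos, classes = classes), class = "fakefit")
  structure(list(rater_id = rater_id, fit = fit, features = features,
                 classes = classes, n_train = length(prob_pos),
                 config = rater_model_config()),
            class = "rater_model")
}

predict.fakefit <- function(object, newdata, type = "prob", ...) {
  p <- object$prob_pos[rownames(newdata)]
  out <- cbind(1 - p, p)
  colnames(out) <- object$classes
  rownames(out) <- rownames(newdata)
  out
}
.S3method("predict", "fakefit", predict.fakefit)

# annotation table where every rater rates every child with code 0 everywhere
blank_table <- function(children, raters, voc, diagnosis) {
  grid <- expand.grid(child_id = children, rater_id = raters,
                      stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(grid)
  tab$diagnosis <- diagnosis[tab$child_id]
  tab$site <- NA_character_
  for (q in voc$question) tab[[q]] <- 0L
  tab
}
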