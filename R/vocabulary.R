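#' Define the multiple-choice instrument vocabulary
#'
#' A feature vocabulary describes the behavioral instrument: one entry per
#' question, with a human-readable name and an ordered set of answer choices.
#' Answers are encoded as ordinal integer codes `0, 1, ..., n_codes - 1` in the
#' order the choices are listed (choices are severity-ordered, so ordinal
#' coding keeps attribution directions interpretable). A child-level answer a
#' rater could not score ("unratable"/missing) is carried as a distinct
#' sentinel code equal to `n_codes` — one past the last real choice — rather
#' than imputed, so tree models can route on missingness.
#'
#' @param questions Character vector of question identifiers (e.g. `"q01"`).
#' @param names Character vector of human-readable feature names, same length
#'   as `questions`, unique.
#' @param labels List of character vectors, one per question, giving the
#'   ordered answer choices. Lengths may differ between questions.
#' @return A tibble of class `feature_vocabulary` with columns `question`,
#'   `name`, `n_codes` and list-column `labels`. The sentinel code for each
#'   question is its `n_codes` value.
#' @seealso [default_vocabulary()] for the 31-question screening instrument.
#' @export
feature_vocabulary <- function(questions, names, labels) {
  if (length(questions) != length(names) || length(questions) != length(labels)) {
    abort("`questions`, `names` and `labels` must have the same length.")
  }
  if (anyDuplicated(questions)) abort("question identifiers must be unique.")
  if (anyDuplicated(names)) abort("feature names must be unique.")
  n_codes <- vapply(labels, length, integer(1))
  if (any(n_codes < 2L)) abort("every question needs at least 2 answer choices.")
  out <- tibble(
    question = as.character(questions),
    name = as.character(names),
    n_codes = as.integer(n_codes),
    labels = lapply(labels, as.character)
  )
  class(out) <- c("feature_vocabulary", class(out))
  out
}

#' The default 31-question screening vocabulary
#'
#' A schematic version of the 31-item behavioral video-rating instrument used
#' for developmental-delay screening. Eight clinically salient features (eye
#' contact, stereotyped interests and actions, language understanding, sensory
#' seeking, calling attention to objects, responsiveness, social
#' participation, stereotyped speech) carry their field names; the remaining
#' items are generic behavioral probes. Every question has four
#' severity-ordered choices (codes 0-3); code 4 is the missing/unratable
#' sentinel.
#'
#' @param n_questions Number of questions (default 31).
#' @return A [feature_vocabulary()].
#' @export
default_vocabulary <- function(n_questions = 31L) {
  named <- c(
    "eye contact",
    "stereotyped interests and actions",
    "understands language",
    "sensory seeking",
    "calls attention to objects",
    "responsiveness to name",
    "social participation",
    "stereotyped speech"
  )
  n_questions <- as.integer(n_questions)
  if (n_questions < 1L) abort("`n_questions` must be >= 1.")
  nm <- character(n_questions)
  k <- min(length(named), n_questions)
  nm[seq_len(k)] <- named[seq_len(k)]
  if (n_questions > k) {
    nm[(k + 1L):n_questions] <- sprintf("behavioral item %02d", (k + 1L):n_questions)
  }
  severity <- c(
    "typical for age",
    "mildly atypical",
    "clearly atypical",
    "severely atypical / observed the entire time"
  )
  feature_vocabulary(
    questions = sprintf("q%02d", seq_len(n_questions)),
    names = nm,
    labels = rep(list(severity), n_questions)
  )
}

#' @export
print.feature_vocabulary <- function(x, ...) {
  cat("<feature_vocabulary> ", nrow(x), " questions\n", sep = "")
  NextMethod()
}

# sentinel (missing/unratable) code per question
sentinel_codes <- function(vocabulary) {
  setNames(vocabulary$n_codes, vocabulary$question)
}

assert_vocabulary <- function(vocabulary) {
  if (!inherits(vocabulary, "feature_vocabulary")) {
    abort("`vocabulary` must be a feature_vocabulary object.")
  }
  invisible(vocabulary)
}

#' Read or write a vocabulary as YAML
#'
#' The on-disk form maps each question id to its `name` and ordered `choices`.
#'
#' @param path File path.
#' @return `read_vocabulary()` returns a [feature_vocabulary()];
#'   `write_vocabulary()` returns `path` invisibly.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  feature_vocabulary(
    questions = names(raw),
    names = vapply(raw, function(q) q$name, character(1)),
    labels = lapply(raw, function(q) q$choices)
  )
}

#' @rdname read_vocabulary
#' @param vocabulary A [feature_vocabulary()].
#' @export
write_vocabulary <- function(vocabulary, path) {
  assert_vocabulary(vocabulary)
  out <- lapply(seq_len(nrow(vocabulary)), function(i) {
    list(name = vocabulary$name[i], choices = as.list(vocabulary$labels[[i]]))
  })
  names(out) <- vocabulary$question
  yaml::write_yaml(out, path)
  invisible(path)
}
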