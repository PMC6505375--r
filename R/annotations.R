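#' Read, validate and write annotation tables
#'
#' An annotation table is a tibble with one row per (child, rater) pair:
#' columns `child_id`, `rater_id`, `diagnosis` (one of `TD`, `SLC`, `ASD`),
#' an optional `site` tag, and one integer column per vocabulary question.
#' Answer cells hold the ordinal code of the chosen answer; an empty cell (or
#' `NA`) means the rater could not score the item and is kept as missing (its
#' encoded form is the question's sentinel code, see [encode_matrix()]).
#'
#' `read_annotations()` rejects malformed input loudly: an answer code outside
#' the question's valid range (and not the sentinel), a duplicated
#' (child, rater) pair, a child with conflicting diagnoses, or a header that
#' does not cover the vocabulary all raise errors naming the offence.
#'
#' @param path CSV file path.
#' @param vocabulary A [feature_vocabulary()]; the CSV must contain one column
#'   per question id.
#' @return A validated tibble, one row per (child, rater).
#' @export
read_annotations <- function(path, vocabulary) {
  assert_vocabulary(vocabulary)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(c("child_id", "rater_id", "diagnosis", vocabulary$question),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  tab <- as_tibble(raw)
  for (q in vocabulary$question) {
    v <- tab[[q]]
    v[v == ""] <- NA_character_
    suppressWarnings(iv <- as.integer(v))
    bad <- which(!is.na(v) & is.na(iv))
    if (length(bad) > 0) {
      abort(sprintf("non-integer answer '%s' in row %d, question %s",
                    v[bad[1]], bad[1], q))
    }
    tab[[q]] <- iv
  }
  if (!("site" %in% names(tab))) tab$site <- NA_character_
  tab$site[tab$site == ""] <- NA_character_
  tab <- tab[, c("child_id", "rater_id", "diagnosis", "site", vocabulary$question)]
  validate_annotations(tab, vocabulary)
}

#' @rdname read_annotations
#' @param table An annotation tibble.
#' @export
validate_annotations <- function(table, vocabulary) {
  assert_vocabulary(vocabulary)
  table <- as_tibble(table)
  need <- c("child_id", "rater_id", "diagnosis", vocabulary$question)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!("site" %in% names(table))) table$site <- NA_character_
  bad_dx <- setdiff(unique(as.character(table$diagnosis)), DIAGNOSIS_LEVELS)
  if (length(bad_dx) > 0) {
    abort(paste0("unknown diagnosis value(s): ", paste(bad_dx, collapse = ", ")))
  }
  dup <- duplicated(table[, c("child_id", "rater_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate (child, rater) pair: (%s, %s)",
                  table$child_id[i], table$rater_id[i]))
  }
  n_dx <- table %>%
    distinct(.data$child_id, .data$diagnosis) %>%
    count(.data$child_id) %>%
    filter(.data$n > 1L)
  if (nrow(n_dx) > 0) {
    abort(paste0("child with conflicting diagnoses: ", n_dx$child_id[1]))
  }
  sent <- sentinel_codes(vocabulary)
  for (q in vocabulary$question) {
    v <- table[[q]]
    bad <- which(!is.na(v) & (v < 0L | v > sent[[q]]))
    if (length(bad) > 0) {
      abort(sprintf("invalid answer code %d in row %d, question %s (valid: 0..%d)",
                    v[bad[1]], bad[1], q, sent[[q]]))
    }
  }
  table$child_id <- as.character(table$child_id)
  table$rater_id <- as.character(table$rater_id)
  table$diagnosis <- factor(as.character(table$diagnosis), levels = DIAGNOSIS_LEVELS)
  table[, c("child_id", "rater_id", "diagnosis", "site", vocabulary$question)]
}

#' @rdname read_annotations
#' @export
write_annotations <- function(table, path, vocabulary) {
  table <- validate_annotations(table, vocabulary)
  out <- table
  out$diagnosis <- as.character(out$diagnosis)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Child records of an annotation table
#'
#' One row per child: `child_id`, `diagnosis`, `site`.
#'
#' @inheritParams validate_annotations
#' @return A tibble sorted by `child_id`.
#' @export
child_records <- function(table, vocabulary) {
  table <- validate_annotations(table, vocabulary)
  table %>%
    distinct(.data$child_id, .data$diagnosis, .data$site) %>%
    arrange(.data$child_id)
}

#' Encode one rater's annotations as a feature matrix
#'
#' Produces the per-child feature matrix a rater-specific classifier is
#' trained on: one row per child rated by `rater_id` (sorted by `child_id`),
#' one column per question, ordinal integer codes with missing answers mapped
#' to the question's sentinel code (`n_codes`, one past the valid range).
#'
#' @inheritParams validate_annotations
#' @param rater_id Which rater's rows to encode.
#' @return A list with `x` (integer matrix, rownames = child ids, colnames =
#'   question ids) and `y` (factor of diagnoses aligned with the rows).
#' @export
encode_matrix <- function(table, vocabulary, rater_id) {
  table <- validate_annotations(table, vocabulary)
  rows <- table %>% filter(.data$rater_id == !!rater_id) %>% arrange(.data$child_id)
  if (nrow(rows) == 0) abort(paste0("rater not present in table: ", rater_id))
  sent <- sentinel_codes(vocabulary)
  x <- as.matrix(rows[, vocabulary$question])
  storage.mode(x) <- "integer"
  for (j in seq_along(vocabulary$question)) {
    x[is.na(x[, j]), j] <- sent[[vocabulary$question[j]]]
  }
  rownames(x) <- rows$child_id
  list(x = x, y = setNames(rows$diagnosis, rows$child_id))
}

#' Assign children to cross-validation folds
#'
#' Children (not annotation rows) are partitioned into `k` folds, stratified
#' by diagnosis: within every fold each class count is within one child of its
#' proportional share, and total fold sizes differ by at most one. The
#' assignment is deterministic given `seed`.
#'
#' @param children Tibble with columns `child_id` and `diagnosis`
#'   (e.g. from [child_records()]).
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return A tibble `child_id`, `fold` (1..k) of class `fold_assignment`, with
#'   attributes `k` and `seed`.
#' @export
assign_folds <- function(children, k = 3L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.")
  children <- as_tibble(children)
  if (anyDuplicated(children$child_id)) abort("`children` must have unique child_id.")
  if (nrow(children) < k) abort("fewer children than folds.")
  # deal the class-blocked, within-class-shuffled sequence cyclically: the
  # cyclic deal is what guarantees both the per-class and the total balance
  local_seed(seed, {
    ord <- order(match(as.character(children$diagnosis), DIAGNOSIS_LEVELS),
                 runif(nrow(children)))
  })
  fold <- integer(nrow(children))
  fold[ord] <- rep_len(seq_len(k), nrow(children))
  out <- tibble(child_id = children$child_id, fold = fold)
  attr(out, "k") <- k
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("fold_assignment", class(out))
  out
}
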