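#' Specify a synthetic cohort
#'
#' A cohort spec fixes the class sizes and, for each diagnosis class, a
#' behavioral archetype: one probability vector per question over that
#' question's valid answer codes. Children of a class draw their latent
#' ("true") answers independently per question from the class archetype; rater
#' noise is layered on top by [simulate_raters()]. The default class sizes
#' (55 ASD, 50 SLC, 54 TD) mirror a screening cohort of 159 children.
#'
#' @param n_asd,n_slc,n_td Class sizes.
#' @param archetypes Named list (`TD`, `SLC`, `ASD`), each a list of numeric
#'   probability vectors, one per vocabulary question, each summing to 1.
#'   Defaults to [default_archetypes()].
#' @param vocabulary A [feature_vocabulary()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 55L, n_slc = 50L, n_td = 54L,
                        archetypes = NULL,
                        vocabulary = default_vocabulary()) {
  assert_vocabulary(vocabulary)
  counts <- c(ASD = as.integer(n_asd), SLC = as.integer(n_slc), TD = as.integer(n_td))
  if (any(counts < 0L)) abort("class counts must be >= 0.")
  if (is.null(archetypes)) archetypes <- default_archetypes(vocabulary)
  check_archetypes(archetypes, vocabulary)
  structure(list(counts = counts, archetypes = archetypes, vocabulary = vocabulary),
            class = "cohort_spec")
}

check_archetypes <- function(archetypes, vocabulary) {
  if (!setequal(names(archetypes), DIAGNOSIS_LEVELS)) {
    abort("archetypes must be a named list with entries TD, SLC, ASD.")
  }
  for (cl in DIAGNOSIS_LEVELS) {
    a <- archetypes[[cl]]
    if (length(a) != nrow(vocabulary)) {
      abort(sprintf("archetype for %s has %d questions; vocabulary has %d.",
                    cl, length(a), nrow(vocabulary)))
    }
    for (j in seq_along(a)) {
      p <- a[[j]]
      if (length(p) != vocabulary$n_codes[j]) {
        abort(sprintf("archetype %s, question %s: %d probabilities for %d codes.",
                      cl, vocabulary$question[j], length(p), vocabulary$n_codes[j]))
      }
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        abort(sprintf("archetype %s, question %s: not a probability vector.",
                      cl, vocabulary$question[j]))
      }
    }
  }
  invisible(archetypes)
}

#' Default class-conditional behavioral archetypes
#'
#' Severity-graded multinomials over each question's codes: TD children
#' concentrate on low (typical) codes, ASD children on high (atypical) codes,
#' SLC children in between. `separation` in `[0, 1]` scales how far the class
#' modes are pulled apart; 0 collapses all classes onto the same distribution
#' (a null cohort with no class signal), 1 gives strongly separated classes.
#'
#' @param vocabulary A [feature_vocabulary()].
#' @param separation Class separation in `[0, 1]` (default 0.2).
#' @return Named list of per-class archetype lists, as used by [cohort_spec()].
#' @export
default_archetypes <- function(vocabulary = default_vocabulary(), separation = 0.2) {
  assert_vocabulary(vocabulary)
  if (separation < 0 || separation > 1) abort("`separation` must be in [0, 1].")
  centers <- c(TD = 0, SLC = 0.5, ASD = 1)  # position along the severity axis
  out <- lapply(centers, function(ctr) {
    lapply(seq_len(nrow(vocabulary)), function(j) {
      m <- vocabulary$n_codes[j]
      grid <- seq(0, 1, length.out = m)
      # triangular-kernel mass around the class center, flattened toward
      # uniform as separation decreases
      w <- pmax(1e-3, 1 - 2 * abs(grid - ctr))
      p <- separation * w / sum(w) + (1 - separation) / m
      p / sum(p)
    })
  })
  names(out) <- names(centers)
  out[DIAGNOSIS_LEVELS]
}

#' Rater reliability profiles
#'
#' A rater profile gives, per question, the probability `reliability` that the
#' rater reports the child's latent answer (otherwise the report is uniform
#' over the remaining codes) and the probability `missingness` that the rater
#' marks the item unratable instead of answering.
#'
#' @param rater_id Rater identifier.
#' @param reliability Numeric scalar or per-question vector in `[0, 1]`.
#' @param missingness Numeric scalar or per-question vector in `[0, 1]`.
#' @param vocabulary A [feature_vocabulary()].
#' @return A list of class `rater_profile`.
#' @export
rater_profile <- function(rater_id, reliability, missingness = 0,
                          vocabulary = default_vocabulary()) {
  assert_vocabulary(vocabulary)
  p <- nrow(vocabulary)
  reliability <- rep_len(as.numeric(reliability), p)
  missingness <- rep_len(as.numeric(missingness), p)
  if (any(reliability < 0 | reliability > 1)) abort("reliability must lie in [0, 1].")
  if (any(missingness < 0 | missingness > 1)) abort("missingness must lie in [0, 1].")
  structure(list(rater_id = as.character(rater_id),
                 reliability = setNames(reliability, vocabulary$question),
                 missingness = setNames(missingness, vocabulary$question)),
            class = "rater_profile")
}

#' The default three-rater scenario
#'
#' The shipped simulation scenario: one expert rater (reliability 0.95 on all
#' questions), one feature-complementary rater (mean reliability 0.75,
#' arranged as 0.95 on even-indexed questions and 0.55 on odd-indexed ones, so
#' its strengths complement the others'), and one near-chance rater
#' (reliability 0.40 everywhere). This is the heterogeneous,
#' feature-specific-expertise structure the rater-adaptive weighting is
#' designed to exploit.
#'
#' @param vocabulary A [feature_vocabulary()].
#' @param missingness Shared per-question missingness probability (default 0.02).
#' @return List of three [rater_profile()]s named `expert`, `complementary`,
#'   `near_chance`.
#' @export
default_rater_profiles <- function(vocabulary = default_vocabulary(),
                                   missingness = 0.02) {
  p <- nrow(vocabulary)
  comp <- ifelse(seq_len(p) %% 2L == 0L, 0.95, 0.55)
  list(
    expert = rater_profile("expert", 0.95, missingness, vocabulary),
    complementary = rater_profile("complementary", comp, missingness, vocabulary),
    near_chance = rater_profile("near_chance", 0.40, missingness, vocabulary)
  )
}

#' Generate a synthetic cohort
#'
#' Draws each child's latent answer vector from its class archetype.
#' Deterministic given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param site Optional site tag stored on every child.
#' @param id_prefix Prefix for generated child ids.
#' @return A list of class `cohort`: `children` (tibble `child_id`,
#'   `diagnosis`, `site`), `latent` (integer matrix children x questions of
#'   true answer codes) and the `vocabulary`.
#' @export
generate_cohort <- function(spec, seed = 1L, site = NA_character_, id_prefix = "C") {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  voc <- spec$vocabulary
  dx <- factor(rep(names(spec$counts), spec$counts), levels = DIAGNOSIS_LEVELS)
  n <- length(dx)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  latent <- matrix(NA_integer_, n, nrow(voc),
                   dimnames = list(ids, voc$question))
  local_seed(seed, {
    for (cl in DIAGNOSIS_LEVELS) {
      rows <- which(dx == cl)
      if (length(rows) == 0) next
      for (j in seq_len(nrow(voc))) {
        p <- spec$archetypes[[cl]][[j]]
        latent[rows, j] <- sample.int(length(p), length(rows), replace = TRUE,
                                      prob = p) - 1L
      }
    }
  })
  structure(list(
    children = tibble(child_id = ids, diagnosis = dx, site = site),
    latent = latent,
    vocabulary = voc
  ), class = "cohort")
}

#' Simulate heterogeneous raters annotating a cohort
#'
#' For each (child, rater, question): with probability `missingness` the
#' answer is missing (unratable); otherwise, with probability `reliability`
#' the rater reports the latent answer, else one of the remaining codes
#' uniformly. Deterministic given `seed`. With reliability 1 and missingness 0
#' the annotations reproduce the latent truth exactly.
#'
#' @param cohort A [generate_cohort()] result.
#' @param profiles List of [rater_profile()]s (at least one).
#' @param seed Integer seed.
#' @return An annotation tibble (see [read_annotations()] for the layout).
#' @export
simulate_raters <- function(cohort, profiles, seed = 1L) {
  if (!inherits(cohort, "cohort")) abort("`cohort` must come from generate_cohort().")
  if (length(profiles) < 1L) abort("need at least one rater profile.")
  voc <- cohort$vocabulary
  n <- nrow(cohort$latent)
  out <- vector("list", length(profiles))
  local_seed(seed, {
    for (r in seq_along(profiles)) {
      pr <- profiles[[r]]
      if (!inherits(pr, "rater_profile")) abort("profiles must be rater_profile objects.")
      ans <- cohort$latent
      for (j in seq_len(nrow(voc))) {
        m <- voc$n_codes[j]
        rel <- pr$reliability[[voc$question[j]]]
        mis <- pr$missingness[[voc$question[j]]]
        u_mis <- runif(n)
        u_err <- runif(n)
        err <- u_err >= rel
        if (any(err)) {
          # uniform over the m - 1 codes other than the latent one
          shift <- sample.int(m - 1L, sum(err), replace = TRUE)
          ans[err, j] <- (ans[err, j] + shift) %% m
        }
        ans[u_mis < mis, j] <- NA_integer_
      }
      tab <- as_tibble(as.data.frame(ans))
      tab <- dplyr::bind_cols(
        tibble(child_id = cohort$children$child_id,
               rater_id = pr$rater_id,
               diagnosis = cohort$children$diagnosis,
               site = cohort$children$site),
        tab
      )
      out[[r]] <- tab
    }
  })
  validate_annotations(bind_rows(out), voc)
}

#' Specify a cross-site distribution shift
#'
#' Describes how site B's class archetypes differ from site A's: for every
#' question in `questions`, each class archetype is mixed toward the
#' class-pooled mean archetype with weight `magnitude`. `magnitude = 0` leaves
#' site B identical to site A; `magnitude = 1` removes all class signal from
#' the shifted questions at site B (their answers no longer depend on
#' diagnosis).
#'
#' @param questions Character vector of question ids to shift.
#' @param magnitude Mixing weight in `[0, 1]`.
#' @return A list of class `site_shift_spec`.
#' @export
site_shift_spec <- function(questions, magnitude) {
  if (magnitude < 0 || magnitude > 1) abort("`magnitude` must lie in [0, 1].")
  structure(list(questions = as.character(questions), magnitude = magnitude),
            class = "site_shift_spec")
}

apply_site_shift <- function(spec, shift) {
  voc <- spec$vocabulary
  unknown <- setdiff(shift$questions, voc$question)
  if (length(unknown) > 0) {
    abort(paste0("shift names unknown question(s): ", paste(unknown, collapse = ", ")))
  }
  arch <- spec$archetypes
  for (q in shift$questions) {
    j <- match(q, voc$question)
    pooled <- Reduce(`+`, lapply(DIAGNOSIS_LEVELS, function(cl) arch[[cl]][[j]])) /
      length(DIAGNOSIS_LEVELS)
    for (cl in DIAGNOSIS_LEVELS) {
      p <- (1 - shift$magnitude) * arch[[cl]][[j]] + shift$magnitude * pooled
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        abort("site shift produced an invalid probability vector.")
      }
      arch[[cl]][[j]] <- p
    }
  }
  cohort_spec(n_asd = spec$counts[["ASD"]], n_slc = spec$counts[["SLC"]],
              n_td = spec$counts[["TD"]], archetypes = arch, vocabulary = voc)
}

#' Generate two site-tagged cohorts under a distribution shift
#'
#' Site A is drawn from the base spec, site B from the spec with
#' [site_shift_spec()] applied; the two sites use disjoint, seed-derived
#' sampling streams, so each is reproducible on its own.
#'
#' @param spec A [cohort_spec()] (site A's archetypes).
#' @param shift A [site_shift_spec()].
#' @param seed Integer seed.
#' @return List with cohorts `site_a` and `site_b`.
#' @export
generate_two_sites <- function(spec, shift, seed = 1L) {
  if (!inherits(shift, "site_shift_spec")) abort("`shift` must be a site_shift_spec.")
  spec_b <- apply_site_shift(spec, shift)
  list(
    site_a = generate_cohort(spec, seed = derive_seed(seed, "site_a"),
                             site = "A", id_prefix = "A"),
    site_b = generate_cohort(spec_b, seed = derive_seed(seed, "site_b"),
                             site = "B", id_prefix = "B")
  )
}

#' Simulate the default annotated screening cohort
#'
#' Convenience wrapper: default archetypes and class sizes (55/50/54), the
#' default three-rater profile set, one call. This is the scenario the
#' package's simulation-based checks run on.
#'
#' @param n_asd,n_slc,n_td Class sizes.
#' @param seed Integer seed.
#' @param separation Class separation passed to [default_archetypes()].
#' @param missingness Per-question missingness for all raters.
#' @param vocabulary A [feature_vocabulary()].
#' @return An annotation tibble.
#' @export
simulate_default_scenario <- function(n_asd = 55L, n_slc = 50L, n_td = 54L,
                                      seed = 1L, separation = 0.2,
                                      missingness = 0.02,
                                      vocabulary = default_vocabulary()) {
  spec <- cohort_spec(n_asd, n_slc, n_td,
                      archetypes = default_archetypes(vocabulary, separation),
                      vocabulary = vocabulary)
  cohort <- generate_cohort(spec, seed = derive_seed(seed, "cohort"))
  simulate_raters(cohort, default_rater_profiles(vocabulary, missingness),
                  seed = derive_seed(seed, "raters"))
}

#' Fully separated point-mass archetypes
#'
#' Degenerate archetypes in which every class answers every question with a
#' single, class-specific code (TD the lowest, ASD the highest, SLC in
#' between). With perfectly reliable raters this gives a noiseless,
#' perfectly separable dataset — the limit in which every classification
#' metric must reach 1.
#'
#' @param vocabulary A [feature_vocabulary()].
#' @return Archetype list for [cohort_spec()].
#' @export
separable_archetypes <- function(vocabulary = default_vocabulary()) {
  assert_vocabulary(vocabulary)
  code_for <- c(TD = 0, SLC = 0.5, ASD = 1)
  out <- lapply(code_for, function(pos) {
    lapply(seq_len(nrow(vocabulary)), function(j) {
      m <- vocabulary$n_codes[j]
      p <- numeric(m)
      p[1L + round(pos * (m - 1L))] <- 1
      p
    })
  })
  names(out) <- names(code_for)
  out[DIAGNOSIS_LEVELS]
}

#' Read or write a simulation scenario as YAML
#'
#' A scenario file holds the cohort class counts, the archetype `separation`,
#' and one entry per rater with its `reliability` and `missingness` (scalars
#' or per-question vectors).
#'
#' @param path File path.
#' @param vocabulary A [feature_vocabulary()].
#' @return `read_scenario()`: a list with `spec` (a [cohort_spec()]) and
#'   `profiles` (list of [rater_profile()]s).
#' @export
read_scenario <- function(path, vocabulary = default_vocabulary()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  sc <- yaml::read_yaml(path)
  spec <- cohort_spec(
    n_asd = sc$n_asd %||% 55L, n_slc = sc$n_slc %||% 50L, n_td = sc$n_td %||% 54L,
    archetypes = default_archetypes(vocabulary, sc$separation %||% 0.2),
    vocabulary = vocabulary
  )
  profiles <- lapply(names(sc$raters), function(id) {
    r <- sc$raters[[id]]
    rater_profile(id, unlist(r$reliability), unlist(r$missingness %||% 0), vocabulary)
  })
  names(profiles) <- names(sc$raters)
  list(spec = spec, profiles = profiles)
}
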