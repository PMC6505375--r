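# independent high-precision recomputation of the penalized objective
naive_objective <- function(beta, intercept, X, y, alpha, rho, w) {
  w <- w * length(y) / sum(w)
  p <- 1 / (1 + exp(-(intercept + as.vector(X %*% beta))))
  loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / length(y)
  loss + alpha * (rho * sum(abs(beta)) + (1 - rho) / 2 * sum(beta^2))
}

rand_instance <- function(n = 60, p = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    beta_true <- c(1.5, -1, 0.5, rep(0, p - 3))
    y <- rbinom(n, 1, plogis(X %*% beta_true))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    list(X = X, y = y)
  })
}

test_that("the elastic-net objective matches closed forms and a naive oracle", {
  d <- rand_instance(40, 4, seed = 11)
  # null model on balanced weights: log 2 per sample, no penalty
  expect_equal(elastic_net_objective(rep(0, 4), 0, d$X, d$y, 0.5, 0.5), log(2))
  # alpha = 0: pure log-loss
  withr::with_seed(2, b <- rnorm(4) / 4)
  w <- balanced_weights(d$y)
  expect_equal(elastic_net_objective(b, 0.1, d$X, d$y, 0, 0.7, w),
               naive_objective(b, 0.1, d$X, d$y, 0, 0.7, w), tolerance = 1e-10)
  # random penalized instances against the independent recomputation
  withr::with_seed(3, {
    for (i in 1:10) {
      b <- rnorm(4) / 2
      ic <- rnorm(1)
      a <- runif(1, 0, 2)
      r <- runif(1)
      expect_equal(elastic_net_objective(b, ic, d$X, d$y, a, r, w),
                   naive_objective(b, ic, d$X, d$y, a, r, w), tolerance = 1e-10)
    }
  })
  expect_error(elastic_net_objective(c(b, 1), 0, d$X, d$y, 1, 0.5), "length")
  expect_error(elastic_net_objective(rep(NA_real_, 4), 0, d$X, d$y, 1, 0.5),
               "non-finite")
})

test_that("balanced class weights equalize per-class totals", {
  y <- c(rep(1, 7), rep(0, 23))
  w <- balanced_weights(y)
  expect_equal(sum(w[y == 1]), sum(w[y == 0]), tolerance = 1e-9)
  expect_equal(sum(w), length(y))
  expect_error(balanced_weights(rep(1, 5)), "both classes")
})

test_that("alpha = 0 reproduces the unpenalized weighted logistic fit", {
  d <- rand_instance(80, 4, seed = 21)
  w <- balanced_weights(d$y)
  fit <- fit_elastic_net(d$X, d$y, alpha = 0, rho = 0.5)
  ref <- suppressWarnings(
    glm(d$y ~ d$X, family = quasibinomial(), weights = w)
  )
  expect_equal(unname(fit$beta), unname(coef(ref)[-1]), tolerance = 1e-4)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("total shrinkage zeroes coefficients and leaves the weighted log-odds", {
  d <- rand_instance(70, 5, seed = 31)
  fit <- fit_elastic_net(d$X, d$y, alpha = 50, rho = 1, class_weights = "none")
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-6)
  # with balanced weights the weighted log-odds is exactly zero
  fitb <- fit_elastic_net(d$X, d$y, alpha = 50, rho = 1)
  expect_true(all(fitb$beta == 0))
  expect_equal(fitb$intercept, 0, tolerance = 1e-6)
})

test_that("the fitted solution minimizes the stated objective", {
  d <- rand_instance(60, 4, seed = 41)
  for (pars in list(c(0.05, 1), c(0.05, 0), c(0.1, 0.5))) {
    fit <- fit_elastic_net(d$X, d$y, alpha = pars[1], rho = pars[2])
    j0 <- elastic_net_objective(fit$beta, fit$intercept, d$X, d$y,
                                pars[1], pars[2])
    withr::with_seed(7, {
      for (i in 1:20) {
        pert <- fit$beta + rnorm(4, sd = 0.05)
        expect_gte(elastic_net_objective(pert, fit$intercept, d$X, d$y,
                                         pars[1], pars[2]), j0 - 1e-7)
      }
    })
  }
})

test_that("the lasso end of the path is at least as sparse as the ridge end", {
  nz <- function(m) sum(abs(m$beta) > 1e-8)
  sparser <- logical(20)
  for (s in 1:20) {
    d <- rand_instance(50, 8, seed = 100 + s)
    sparser[s] <- nz(fit_elastic_net(d$X, d$y, 0.1, 1)) <=
      nz(fit_elastic_net(d$X, d$y, 0.1, 0))
  }
  expect_true(all(sparser))
})

test_that("grid search selects the argmax with the documented tie-breaks", {
  d <- rand_instance(60, 5, seed = 51)
  g1 <- grid_search_cv(d$X, d$y, alpha_grid = 0.1, rho_grid = 0.5, seed = 2)
  expect_equal(g1$best, list(alpha = 0.1, rho = 0.5))
  expect_equal(nrow(g1$table), 1L)

  g <- grid_search_cv(d$X, d$y, alpha_grid = c(0.1, 0.01),
                      rho_grid = c(0.3, 0.7), seed = 2)
  # selected cell attains the maximal mean AUC
  expect_equal(max(g$table$auc),
               g$table$auc[g$table$alpha == g$best$alpha &
                           g$table$rho == g$best$rho])
  # duplicated alpha values give identical per-cell scores
  gd <- grid_search_cv(d$X, d$y, alpha_grid = c(0.1, 0.1), rho_grid = 0.5,
                       seed = 2)
  expect_equal(gd$table$auc[1], gd$table$auc[2])
  expect_equal(gd$table$accuracy[1], gd$table$accuracy[2])

  # tie-break: equal AUC resolves to larger alpha, then larger rho
  tie <- tibble::tibble(alpha = c(0.01, 0.1, 0.1), rho = c(0.9, 0.3, 0.7),
                        auc = c(0.8, 0.8, 0.8))
  ord <- order(-tie$auc, -tie$alpha, -tie$rho)
  expect_equal(tie[ord[1], ]$alpha, 0.1)
  expect_equal(tie[ord[1], ]$rho, 0.7)
})

test_that("selection frequency counts nonzero coefficients per fold", {
  d <- rand_instance(60, 4, seed = 61)
  zero <- fit_elastic_net(d$X, d$y, alpha = 50, rho = 1)
  expect_true(all(selection_frequency(list(zero, zero))$count == 0L))

  dense <- fit_elastic_net(d$X, d$y, alpha = 0.001, rho = 0.1)
  sf3 <- selection_frequency(list(dense, dense, dense))
  expect_true(all(sf3$count[sf3$feature %in% paste0("x", 1:2)] == 3L))

  mix <- selection_frequency(list(zero, dense))
  manual <- rowSums(cbind(abs(zero$beta) > 1e-8, abs(dense$beta) > 1e-8))
  expect_equal(setNames(mix$count, mix$feature)[names(manual)],
               manual, ignore_attr = FALSE, tolerance = 0)
})

test_that("consensus features take the plurality answer, lowest code on ties", {
  voc <- small_vocab(2L, n_codes = 4L)
  tab <- blank_table(c("a", "b"), c("r1", "r2", "r3"), voc,
                     c(a = "TD", b = "ASD"))
  tab$q01 <- c(2L, 2L, 1L, 0L, 3L, 3L)  # a: 2,1,... rows ordered child within rater?
  # set explicitly to avoid row-order assumptions
  tab$q01[tab$child_id == "a"] <- c(2L, 2L, 1L)
  tab$q01[tab$child_id == "b"] <- c(0L, 3L, 3L)
  tab$q02[tab$child_id == "a"] <- c(1L, 2L, NA)   # tie 1 vs 2 -> 1
  tab$q02[tab$child_id == "b"] <- c(NA, NA, NA)   # all missing -> sentinel
  cf <- consensus_features(tab, voc)
  expect_equal(unname(cf$x["a", ]), c(2L, 1L))
  expect_equal(unname(cf$x["b", ]), c(3L, 4L))
})

test_that("transfer evaluation is deterministic and structurally sound", {
  voc <- small_vocab(6L)
  spec <- cohort_spec(40, 20, 40, vocabulary = voc,
                      archetypes = default_archetypes(voc, 0.6))
  sites <- generate_two_sites(spec, site_shift_spec("q01", 0.5), seed = 4)
  profiles <- list(rater_profile("r1", 0.9, 0, voc))
  tab_a <- simulate_raters(sites$site_a, profiles, seed = 5)
  tab_b <- simulate_raters(sites$site_b, profiles, seed = 6)
  tr <- transfer_evaluate(tab_a, tab_b, voc, alpha_grid = c(0.1, 0.01),
                          rho_grid = c(0.3, 0.7), seed = 9)
  expect_setequal(tr$metrics$set, c("heldout", "cross_site"))
  expect_true(all(tr$metrics$auc >= 0 & tr$metrics$auc <= 1))
  expect_equal(tr$metrics$n[tr$metrics$set == "cross_site"], 100L)
  # same seed, same everything
  tr2 <- transfer_evaluate(tab_a, tab_b, voc, alpha_grid = c(0.1, 0.01),
                           rho_grid = c(0.3, 0.7), seed = 9)
  expect_equal(tr$metrics, tr2$metrics)
  expect_equal(glance(tr), glance(tr2))
  # selection tables bounded by fold count
  for (sel in tr$selection) expect_true(all(sel$count <= tr$grid$k))
})
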