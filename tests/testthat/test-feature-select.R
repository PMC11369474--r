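test_that("a perfectly separating feature drives the criterion far below null", {
  d <- separated_feature(n = 100, gap = 3, sd = 0.1, seed = 1)
  null_dev <- 2 * 100 * log(2)
  expect_lt(deviance_criterion(d$x, d$y, folds = 5, seed = 1), 0.1 * null_dev)
})

test_that("an uninformative feature scores near the closed-form null deviance", {
  withr::with_seed(2, {
    y <- rep(0:4, each = 20)
    x <- matrix(rnorm(100), ncol = 1)
    null_dev <- 2 * 100 * log(5) # 321.888
    crit <- deviance_criterion(x, y, folds = 5, seed = 3)
    expect_lt(abs(crit - null_dev) / null_dev, 0.10)
  })
})

test_that("duplicating an included feature leaves the criterion essentially unchanged", {
  withr::with_seed(5, {
    y <- rep(0:4, each = 20)
    x <- matrix(rnorm(100 * 3), 100, 3)
    x[, 1] <- x[, 1] + y
    d1 <- deviance_criterion(x, y, folds = 5, seed = 9)
    d2 <- deviance_criterion(cbind(x, x[, 1]), y, folds = 5, seed = 9)
    # O(lambda) shift from the penalty split across duplicated columns
    expect_lt(abs(d2 - d1) / d1, 1e-4)
  })
})

test_that("the criterion is deterministic given the seed and validates folds", {
  d <- separated_feature(seed = 4)
  expect_identical(deviance_criterion(d$x, d$y, folds = 5, seed = 7),
                   deviance_criterion(d$x, d$y, folds = 5, seed = 7))
  expect_error(deviance_criterion(d$x, d$y, folds = 1, seed = 1), "folds")
  expect_error(deviance_criterion(d$x, rep(0, 100), folds = 5, seed = 1),
               "2 classes")
})

test_that("the first greedy pick matches exhaustive single-feature search", {
  tb <- toy_feature_table(n_per_class = 18, informative = 2, noise = 8,
                          gap = 2.5, seed = 6)
  feats <- table_features(tb)
  crit1 <- vapply(feats, function(f) {
    deviance_criterion(as.matrix(tb[f]), tb$fraction, folds = 5, seed = 11)
  }, numeric(1))
  best_single <- feats[which.min(crit1)]
  sel <- sequential_forward_select(tb, max_k = 3, folds = 5, seed = 11)
  expect_identical(sel$selected[1], best_single)
})

test_that("greedy selection reproduces a step-by-step greedy oracle at max_k = 2", {
  tb <- toy_feature_table(n_per_class = 10, informative = 2, noise = 4,
                          gap = 2, seed = 8)
  feats <- table_features(tb)
  sel <- sequential_forward_select(tb, max_k = 2, folds = 5, seed = 13)
  # oracle: exhaustive greedy re-run over all candidates at each step
  crit <- function(cols) deviance_criterion(as.matrix(tb[cols]), tb$fraction,
                                            folds = 5, seed = 13)
  c1 <- vapply(feats, function(f) crit(f), numeric(1))
  f1 <- feats[which.min(c1)]
  rest <- setdiff(feats, f1)
  c2 <- vapply(rest, function(f) crit(c(f1, f)), numeric(1))
  f2 <- rest[which.min(c2)]
  expect_identical(sel$selected[seq_len(min(2, length(sel$selected)))],
                   head(c(f1, f2), length(sel$selected)))
  # and the greedy criterion values agree with the oracle's
  expect_equal(sel$criterion_trace[1], min(c1), tolerance = 1e-12)
})

test_that("max_k = 0 yields an empty selection and trace", {
  tb <- toy_feature_table(seed = 9)
  sel <- sequential_forward_select(tb, max_k = 0)
  expect_length(sel$selected, 0)
  expect_length(sel$criterion_trace, 0)
})

test_that("the criterion trace is non-increasing and selection is deterministic", {
  tb <- toy_feature_table(n_per_class = 12, informative = 3, noise = 5,
                          gap = 1.5, seed = 10)
  sel1 <- sequential_forward_select(tb, max_k = 5, folds = 5, seed = 17)
  sel2 <- sequential_forward_select(tb, max_k = 5, folds = 5, seed = 17)
  expect_identical(sel1$selected, sel2$selected)
  expect_true(all(diff(sel1$criterion_trace) <= 0))
  expect_lte(length(sel1$selected), 5)
  expect_error(sequential_forward_select(tb[0, ]), "empty")
})

test_that("selection results serialize to JSON and back", {
  tb <- toy_feature_table(seed = 12)
  sel <- sequential_forward_select(tb, max_k = 3, seed = 19)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_identical(back$selected, sel$selected)
  expect_equal(back$criterion_trace, sel$criterion_trace, tolerance = 1e-12)

  td <- tidy(sel)
  expect_identical(td$feature, sel$selected)
  expect_identical(glance(sel)$n_selected, length(sel$selected))
})

test_that("the ridge multinomial fit agrees with independent GLM routes", {
  skip_if_not_installed("glmnet")
  # overlapping classes keep the MLE finite, so at vanishing ridge strength
  # all three solvers must agree on the fitted probabilities
  d <- withr::with_seed(14, {
    x <- matrix(c(rnorm(30, 0, 1), rnorm(30, 2, 1)), ncol = 1)
    list(x = cbind(x, rnorm(60)), y = rep(0:1, each = 30))
  })
  xs <- scale(d$x)
  fit <- multinom_ridge_fit(cbind(1, xs), as.integer(d$y), K = 2L,
                            lambda = 1e-6, maxit = 200, tol = 1e-12)
  p_ours <- multinom_ridge_prob(cbind(1, xs), fit$coef)[, 2]

  gfit <- glmnet::glmnet(xs, factor(d$y), family = "binomial", alpha = 0,
                         lambda = 1e-8, standardize = FALSE, thresh = 1e-14)
  p_glmnet <- as.numeric(predict(gfit, xs, type = "response"))
  expect_lt(max(abs(p_ours - p_glmnet)), 1e-5)

  p_glm <- stats::fitted(stats::glm(d$y ~ xs, family = stats::binomial))
  expect_lt(max(abs(p_ours - unname(p_glm))), 1e-5)
})
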