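# hierarchical logistic and ordered-logit regressions: planted-truth
# recovery, null behavior, predicted levels, pairwise differences

quick_cfg <- sampler_config(4, 800, 800, 2, seed = 7)

sim_logistic <- function(n_part = 60, n_trial = 8, shift = 0, seed = 1) {
  set.seed(seed)
  g <- sample(c("x", "y"), n_part, replace = TRUE)
  u <- rnorm(n_part, 0, 0.5)
  rows <- expand.grid(part = seq_len(n_part), trial = seq_len(n_trial))
  eta <- ifelse(g[rows$part] == "x", shift / 2, -shift / 2) + u[rows$part]
  data.frame(participant_id = paste0("p", rows$part),
             grp = g[rows$part],
             outcome = rbinom(nrow(rows), 1, plogis(eta)))
}

test_that("logistic regression recovers a planted log-odds shift", {
  dat <- sim_logistic(n_part = 120, shift = 1.2, seed = 11)
  fit <- fit_hierarchical_logistic(
    dat, regression_spec("outcome", "bernoulli", "grp"), quick_cfg)
  expect_lt(max(fit$rhat), 1.02)
  # contrast coding: level-x effect is +shift/2 on the linear scale
  b <- extract_draws(fit, "grp1")[, 1]
  h <- hdi(b)
  expect_true(h[1] <= 0.6 && 0.6 <= h[2])
  pd <- pairwise_difference(fit, "grp", "x", "y")
  expect_true(pd$excludes_zero)
  expect_equal(pd$median, 1.2, tolerance = 0.35)
})

test_that("null data leave coefficient HDIs covering zero", {
  dat <- sim_logistic(n_part = 80, shift = 0, seed = 12)
  fit <- fit_hierarchical_logistic(
    dat, regression_spec("outcome", "bernoulli", "grp"), quick_cfg)
  h <- hdi(extract_draws(fit, "grp1")[, 1])
  expect_true(h[1] <= 0 && 0 <= h[2])
  # intercept-only prediction on balanced outcomes sits near 0.5
  pl <- predicted_levels(fit, "grp")
  expect_true(all(abs(pl$median - 0.5) < 0.15))
})

test_that("non-binary outcomes are rejected by the logistic fit", {
  dat <- sim_logistic(seed = 13)
  dat$outcome <- dat$outcome + 1L
  expect_error(fit_hierarchical_logistic(
    dat, regression_spec("outcome", "bernoulli", "grp"), quick_cfg),
    "binary")
  expect_error(fit_hierarchical_logistic(
    dat, regression_spec("outcome", "ordered", "grp"), quick_cfg),
    "bernoulli")
})

sim_ordered <- function(n_part = 80, shift = 1, seed = 2) {
  set.seed(seed)
  g <- rep(c("x", "y"), length.out = n_part)
  u <- rnorm(n_part, 0, 0.5)
  rows <- expand.grid(part = seq_len(n_part), trial = 1:6)
  eta <- ifelse(g[rows$part] == "x", shift / 2, -shift / 2) + u[rows$part]
  cuts <- c(-1, 0.2, 1.3)
  lat <- eta + rlogis(nrow(rows))
  y <- findInterval(lat, cuts) + 1L
  data.frame(participant_id = paste0("p", rows$part),
             grp = g[rows$part], outcome = y)
}

test_that("ordered logit recovers the sign of a planted latent shift", {
  dat <- sim_ordered(shift = 1.2, seed = 21)
  fit <- fit_ordered_logit(
    dat, regression_spec("outcome", "ordered", "grp"), quick_cfg)
  expect_lt(max(fit$rhat), 1.02)
  b <- extract_draws(fit, "grp1")[, 1]
  expect_gt(median(b), 0)
  expect_true(pairwise_difference(fit, "grp", "x", "y")$excludes_zero)
  # cutpoints are strictly increasing in every draw
  cuts <- vaxcog:::.assoc_cutpoints(fit)
  expect_true(all(cuts[, 2] > cuts[, 1]))
  expect_true(all(cuts[, 3] > cuts[, 2]))
  # predicted level-values fall inside the outcome range
  pl <- predicted_levels(fit, "grp")
  expect_true(all(pl$median >= 1 & pl$median <= 4))
  expect_gt(pl$median[pl$level == "x"], pl$median[pl$level == "y"])
})

test_that("two-level outcomes are rejected by the ordered fit", {
  dat <- sim_ordered(seed = 22)
  dat$outcome <- as.integer(dat$outcome > 2)
  expect_error(fit_ordered_logit(
    dat, regression_spec("outcome", "ordered", "grp"), quick_cfg),
    "at least 3 levels")
})

test_that("pairwise differences are antisymmetric and null on identity", {
  dat <- sim_logistic(n_part = 50, shift = 0.8, seed = 23)
  fit <- fit_hierarchical_logistic(
    dat, regression_spec("outcome", "bernoulli", "grp"), quick_cfg)
  ab <- pairwise_difference(fit, "grp", "x", "y")
  ba <- pairwise_difference(fit, "grp", "y", "x")
  expect_equal(ab$difference, -ba$difference)
  aa <- pairwise_difference(fit, "grp", "x", "x")
  expect_equal(aa$median, 0)
  expect_false(aa$excludes_zero)
  expect_error(pairwise_difference(fit, "grp", "x", "zzz"), "unknown level")
})

test_that("predicted levels agree with an explicit per-draw computation", {
  dat <- sim_logistic(n_part = 50, shift = 0.8, seed = 24)
  fit <- fit_hierarchical_logistic(
    dat, regression_spec("outcome", "bernoulli", "grp"), quick_cfg)
  pl <- predicted_levels(fit, "grp")
  draws <- extract_draws(fit, c("Intercept", "grp1"))
  # oracle: loop over draws, contr.sum row for each level
  manual_x <- plogis(draws[, "Intercept"] + draws[, "grp1"])
  manual_y <- plogis(draws[, "Intercept"] - draws[, "grp1"])
  expect_equal(pl$median[pl$level == "x"], median(manual_x))
  expect_equal(pl$median[pl$level == "y"], median(manual_y))
  # sum-to-zero identity on the linear scale
  eta <- vaxcog:::.assoc_level_linpred(fit, "grp")
  expect_equal(rowMeans(eta), draws[, "Intercept"], tolerance = 1e-12)
})

test_that("odds ratios are exp(coefficients) with the 0.2 relevance mark", {
  dat <- sim_logistic(n_part = 100, shift = 1.5, seed = 25)
  fit <- fit_hierarchical_logistic(
    dat, regression_spec("outcome", "bernoulli", "grp"), quick_cfg)
  or <- coefficient_odds_ratios(fit)
  b <- extract_draws(fit, "grp1")[, 1]
  expect_equal(or$odds_ratio[or$coefficient == "grp1"], median(exp(b)))
  expect_true(or$practically_relevant[or$coefficient == "grp1"])
})

test_that("interaction terms expand into contrast-product columns", {
  dat <- sim_logistic(n_part = 60, shift = 0.5, seed = 26)
  dat$brand <- sample(c("A", "B", "C"), nrow(dat), replace = TRUE)
  fit <- fit_hierarchical_logistic(
    dat, regression_spec("outcome", "bernoulli", c("grp", "brand"),
                         interactions = "grp:brand"),
    sampler_config(2, 600, 600, 2, seed = 9))
  cols <- colnames(fit$design$X)
  expect_true(all(c("grp1", "brand1", "brand2", "grp1:brand1",
                    "grp1:brand2") %in% cols))
  expect_lt(max(fit$rhat), 1.05)
})

test_that("type-I error of the excludes-zero flag is near nominal", {
  hits <- 0
  for (r in 1:12) {
    dat <- sim_logistic(n_part = 40, n_trial = 6, shift = 0, seed = 300 + r)
    fit <- fit_hierarchical_logistic(
      dat, regression_spec("outcome", "bernoulli", "grp"),
      sampler_config(2, 250, 250, 2, seed = 400 + r))
    if (pairwise_difference(fit, "grp", "x", "y")$excludes_zero) {
      hits <- hits + 1
    }
  }
  expect_lte(hits, 3)  # ~5% nominal; loose small-sample bound
})
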