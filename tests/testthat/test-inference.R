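# diagnostics and posterior machinery: R-hat, HDI, draw bookkeeping,
# posterior-predictive accuracy, recovery reporting

test_that("R-hat separates mixed from unmixed chains", {
  set.seed(1)
  mixed <- matrix(rnorm(4000), ncol = 4)
  expect_lt(compute_rhat(mixed), 1.01)
  unmixed <- cbind(rnorm(1000), rnorm(1000, 10), rnorm(1000), rnorm(1000, 10))
  expect_gt(compute_rhat(unmixed), 1.5)
  expect_error(compute_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("R-hat agrees with a textbook split-PSRF implementation", {
  # plain split R-hat (no rank normalization) as the independent reference;
  # on well-behaved normal draws the two variants coincide closely
  split_psrf <- function(x) {
    half <- nrow(x) %/% 2
    m <- cbind(x[1:half, ], x[(nrow(x) - half + 1):nrow(x), ])
    n <- nrow(m)
    w <- mean(apply(m, 2, var))
    b <- n * var(colMeans(m))
    sqrt(((n - 1) / n * w + b / n) / w)
  }
  set.seed(2)
  for (shift in c(0, 0.1, 0.3)) {
    x <- cbind(rnorm(500), rnorm(500), rnorm(500, shift), rnorm(500, shift))
    expect_equal(compute_rhat(x), split_psrf(x), tolerance = 0.02)
  }
})

test_that("HDI is the narrowest interval with the requested mass", {
  set.seed(3)
  u <- runif(20000)
  h <- hdi(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.02)
  expect_equal(hdi(rep(1.7, 100), 0.9), c(1.7, 1.7))
  z <- rnorm(50000)
  hz <- hdi(z, 0.95)
  expect_equal(hz, c(-1.96, 1.96), tolerance = 0.06)
  # exact check against exhaustive search on a small skewed sample
  set.seed(4)
  x <- rexp(200)
  h2 <- hdi(x, 0.8)
  xs <- sort(x)
  k <- ceiling(0.8 * 200)
  widths <- xs[(k + 1):200] - xs[1:(200 - k)]
  expect_equal(h2[2] - h2[1], min(widths))
  # nesting: the 80% HDI lies inside the 95% HDI
  h80 <- hdi(z, 0.8); h95 <- hdi(z, 0.95)
  expect_gte(h80[1], h95[1])
  expect_lte(h80[2], h95[2])
  expect_error(hdi(rnorm(10)), "at least 50")
})

test_that("prior-predictive acceptance probabilities span the unit interval", {
  set.seed(5)
  n <- 3000
  beta <- rnorm(n); beta_i <- beta + rgamma(n, 2, 1) * rnorm(n)
  phi <- pnorm(rnorm(n))
  v <- runif(n, -12, 4)  # valuations across the plausible range
  xb <- rnorm(n) * 0.5
  p <- plogis(beta_i + xb + phi * v)
  expect_gt(mean(p < 0.1), 0.05)
  expect_gt(mean(p > 0.9), 0.05)
  expect_gt(mean(p > 0.25 & p < 0.75), 0.1)
})

# one small fitted model shared by the remaining tests
small_fit_env <- local({
  cc <- cohort_config(groups = list(attitude_group("neutral", 25)))
  b <- generate_cohort(cc, seed = 101)
  s <- summarize_trials(b$events,
                        b$decisions[, c("participant_id", "trial_index",
                                        "vaccine")], evidence)
  pd <- build_pt_data(b$decisions, b$ratings, s$outcomes, evidence)
  fit <- fit_pt_model(pd, sampler_config(4, 400, 400, 2, seed = 17))
  list(bundle = b, data = pd, fit = fit)
})

test_that("draw bookkeeping matches chains x sampling / thin", {
  fit <- small_fit_env$fit
  expect_equal(fit$n_draws, 4 * 400 / 2)
  expect_equal(dim(fit$draws)[1], 200)
  expect_equal(dim(fit$draws)[2], 4)
  expect_length(fit$rhat, dim(fit$draws)[3])
  expect_true(all(is.finite(fit$rhat)))
})

test_that("posterior-predictive accuracy behaves at the extremes", {
  # perfectly separated decisions: keep only participants whose planted
  # bias is large enough to pin every decision
  gp_sep <- pt_group_parameters(beta = 0, sigma = c(8, 0.3, 0.3))
  cc <- cohort_config(groups = list(attitude_group("pro", 40,
                                                   group_params = gp_sep)))
  b <- generate_cohort(cc, seed = 103)
  keep <- b$participants$participant_id[abs(b$participants$true_beta_i) > 4]
  keep <- head(keep, 24)
  dec <- b$decisions[b$decisions$participant_id %in% keep, ]
  s <- summarize_trials(b$events,
                        dec[, c("participant_id", "trial_index", "vaccine")],
                        evidence)
  pd <- build_pt_data(dec, b$ratings, s$outcomes, evidence)
  fit <- fit_pt_model(pd, sampler_config(2, 300, 300, 2, seed = 19))
  acc <- posterior_predictive_accuracy(fit)
  expect_gt(acc$balanced_accuracy, 0.9)
  # chance-level decisions: full ignorance and no bias spread
  gp_null <- pt_group_parameters(beta = 0, sigma = c(1e-4, 0.3, 0.3))
  pol_full <- inspection_policy(p_full_ignorance = 1, p_no_ignorance = 0)
  cc0 <- cohort_config(groups = list(attitude_group("neutral", 60,
                                                    group_params = gp_null,
                                                    policy = pol_full)))
  b0 <- generate_cohort(cc0, seed = 104)
  s0 <- summarize_trials(b0$events,
                         b0$decisions[, c("participant_id", "trial_index",
                                          "vaccine")], evidence)
  pd0 <- build_pt_data(b0$decisions, b0$ratings, s0$outcomes, evidence)
  fit0 <- fit_pt_model(pd0, sampler_config(2, 300, 300, 2, seed = 23))
  acc0 <- posterior_predictive_accuracy(fit0)
  expect_lt(abs(acc0$balanced_accuracy - 0.5), 0.15)
  # loo does not exceed in-sample accuracy by more than Monte-Carlo noise
  fit_s <- small_fit_env$fit
  a_in <- posterior_predictive_accuracy(fit_s, method = "in_sample")
  a_loo <- posterior_predictive_accuracy(fit_s, method = "loo")
  expect_lte(a_loo$balanced_accuracy, a_in$balanced_accuracy + 0.05)
})

test_that("recovery report flags coverage consistently with the HDIs", {
  fit <- small_fit_env$fit
  truth <- vaxcog:::.default_group_params()$neutral
  rr <- recovery_report(truth, fit)
  expect_setequal(
    rr$parameter,
    c("beta", paste0("beta_j", 1:4), "lambda", "gamma", "alpha", "phi",
      "sigma_beta", "sigma_lambda", "sigma_gamma"))
  post <- pt_group_posterior(fit)
  for (k in seq_len(nrow(rr))) {
    h <- hdi(post[[rr$parameter[k]]], 0.95)
    expect_equal(rr$covered[k],
                 rr$truth[k] >= h[1] && rr$truth[k] <= h[2])
  }
  # truth placed at the posterior median has zero standardized bias
  tweaked <- truth
  tweaked$beta <- median(post$beta)
  rr2 <- recovery_report(tweaked, fit)
  expect_equal(rr2$std_bias[rr2$parameter == "beta"], 0, tolerance = 1e-10)
})

test_that("group-parameter HDIs sharpen with more participants", {
  widths <- sapply(c(15, 60), function(n) {
    cc <- cohort_config(groups = list(attitude_group("neutral", n)))
    b <- generate_cohort(cc, seed = 105)
    s <- summarize_trials(b$events,
                          b$decisions[, c("participant_id", "trial_index",
                                          "vaccine")], evidence)
    pd <- build_pt_data(b$decisions, b$ratings, s$outcomes, evidence)
    fit <- fit_pt_model(pd, sampler_config(2, 350, 350, 2, seed = 29))
    h <- hdi(pt_group_posterior(fit)$beta, 0.95)
    h[2] - h[1]
  })
  expect_lt(widths[2], widths[1])
})
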