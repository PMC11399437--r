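# prospect-theory primitives: value function, probability weighting,
# valuation, acceptance probability, parameter transforms, contrasts, and
# the joint log density (against a brute-force oracle and the sampler's
# C++ implementation)

test_that("value function implements the three cases", {
  expect_equal(value_function(-3, 0.7, 1, "side_effect", ignored = TRUE), 0)
  # alpha = 3 magnifies an extreme rating to 125 x the loss multiplier
  expect_equal(value_function(-5, 0.7, 3, "side_effect"), -0.7 * 125)
  expect_equal(value_function(5, 0.7, 3, "benefit"), 0.3 * 125)
  # loss neutrality at lambda = 0.5: symmetric magnitudes
  for (a in 1:5) {
    expect_equal(abs(value_function(-a, 0.5, 1, "side_effect")),
                 value_function(a, 0.5, 1, "benefit"))
  }
  expect_error(value_function(0, 0.5, 1, "benefit"), "not on the scale")
  expect_error(value_function(2, 0.5, 1, "side_effect"), "negative")
})

test_that("value-function signs and loss aversion hold across the grid", {
  for (lambda in c(0.2, 0.5, 0.8)) {
    for (alpha in c(0.5, 1, 2.5)) {
      for (a in 1:5) {
        v_se <- value_function(-a, lambda, alpha, "side_effect")
        v_b <- value_function(a, lambda, alpha, "benefit")
        expect_lte(v_se, 0)
        expect_gte(v_b, 0)
        if (lambda > 0.5) expect_gt(abs(v_se), v_b)
      }
    }
  }
})

test_that("probability weighting matches its closed forms", {
  # gamma = 0 collapses all inspected weights to exp(-1) ~ 0.37
  for (p in c(0.00002, 0.1, 0.5, 0.95)) {
    expect_equal(round(weight_probability(p, 0), 2), 0.37)
  }
  # gamma = 1 is linear weighting
  expect_equal(weight_probability(0.95, 1), 0.95)
  expect_equal(weight_probability(0.00002, 1), 0.00002, tolerance = 1e-9)
  # neglected probabilities get the fixed 0.5 weight
  expect_equal(weight_probability(0.2, 0.7, neglected = TRUE), 0.5)
  expect_equal(weight_probability(NA, 0.7), 0.5)
  # high-precision oracle for an intermediate curvature
  expect_equal(weight_probability(0.00002, 0.5),
               exp(-sqrt(-log(0.00002))), tolerance = 1e-12)
  expect_equal(round(weight_probability(0.00002, 0.5), 4), 0.0373)
  expect_error(weight_probability(1.5, 0.5), "outside")
})

test_that("weights are increasing in p with fixed point at exp(-1)", {
  p_grid <- seq(0.001, 0.999, length.out = 60)
  for (gamma in c(0.1, 0.4, 0.7, 1)) {
    w <- weight_probability(p_grid, gamma)
    expect_true(all(diff(w) > 0))
    expect_equal(weight_probability(exp(-1), gamma), exp(-1),
                 tolerance = 1e-12)
  }
})

test_that("subjective valuation sums value x weight with case handling", {
  base <- data.frame(rating = c(-2, 4), probability = c(0.3, 0.9),
                     kind = c("side_effect", "benefit"),
                     outcome_ignored = c(FALSE, FALSE),
                     probability_neglected = c(FALSE, FALSE))
  # hand evaluation: lambda = .5, gamma = 1, alpha = 1
  expect_equal(subjective_valuation(base, 0.5, 1, 1),
               -0.5 * 2 * 0.3 + 0.5 * 4 * 0.9)
  # one side effect only, linear weighting: V = -0.5 * 2 * p
  se_only <- base[1, ]
  expect_equal(subjective_valuation(se_only, 0.5, 1, 1), -0.5 * 2 * 0.3)
  # full ignorance -> 0
  ign <- base
  ign$outcome_ignored <- TRUE
  expect_equal(subjective_valuation(ign, 0.7, 0.4, 1.2), 0)
  # only benefits inspected -> positive valuation
  ben <- base
  ben$outcome_ignored <- c(TRUE, FALSE)
  expect_gt(subjective_valuation(ben, 0.9, 0.4, 1), 0)
  # a neglected probability on an ignored outcome is contradictory
  bad <- base
  bad$outcome_ignored <- c(TRUE, FALSE)
  bad$probability_neglected <- c(TRUE, FALSE)
  expect_error(subjective_valuation(bad, 0.5, 0.5, 1), "ignored")
})

test_that("acceptance probability is the logistic of the linear predictor", {
  expect_equal(acceptance_probability(0, rep(0, 4), rep(0, 4), 0.3, 0), 0.5)
  expect_equal(acceptance_probability(1, c(1, 0, 0, 0), c(-0.5, 0, 0, 0),
                                      1, 0.5),
               plogis(1), tolerance = 1e-12)
  expect_lt(acceptance_probability(-30, rep(0, 4), rep(0, 4), 0.5, 0), 1e-10)
})

test_that("individual transforms use the normal CDF", {
  gp <- pt_group_parameters(lambda_probit = 0, gamma_probit = 0)
  ind <- transform_individual_parameters(gp, c(0, 0, 0))
  expect_equal(ind$lambda_i, 0.5)
  expect_equal(loss_aversion_multiplier(ind$lambda_i), 1)
  gp2 <- pt_group_parameters(lambda_probit = 1.6449)
  ind2 <- transform_individual_parameters(gp2, c(0, 0, 0))
  expect_equal(ind2$lambda_i, 0.95, tolerance = 1e-4)
  # matrix form
  z <- matrix(rnorm(9), 3)
  ind3 <- transform_individual_parameters(gp, z)
  expect_equal(ind3$lambda_i, pnorm(z[, 2]))
})

test_that("contrast matrix is 8 x 4 with sum-to-zero columns", {
  x <- contrast_matrix(evidence)
  expect_equal(dim(x), c(8L, 4L))
  # summing one representative row per category level gives zero
  df <- unique(as.data.frame(evidence)[, c("vaccine", "country_category",
                                           "technology_category")])
  reps_country <- df$vaccine[match(c("US", "China", "other"),
                                   df$country_category)]
  reps_tech <- df$vaccine[match(c("mRNA", "vector", "other"),
                                df$technology_category)]
  expect_equal(unname(colSums(x[reps_country, 1:2])), c(0, 0))
  expect_equal(unname(colSums(x[reps_tech, 3:4])), c(0, 0))
  # vaccines sharing a category level share that part of the row
  expect_equal(x["BioNTech/Pfizer", 3:4], x["Moderna", 3:4])
})

test_that("group-parameter validation catches bad inputs", {
  expect_error(pt_group_parameters(sigma = c(1, -1, 1)), "sigma")
  bad_r <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(pt_group_parameters(correlation = bad_r), "positive-definite")
})

test_that("joint log density equals the brute-force oracle", {
  b <- tiny_cohort(seed = 11)
  s <- summarize_trials(b$events,
                        b$decisions[, c("participant_id", "trial_index",
                                        "vaccine")], evidence)
  pd <- build_pt_data(b$decisions, b$ratings, s$outcomes, evidence)
  set.seed(3)
  gp <- pt_group_parameters(beta = -0.8, beta_j = rnorm(4, 0, 0.3),
                            lambda_probit = 0.6, gamma_probit = -0.3,
                            alpha_raw = 0.1, phi_probit = -0.5,
                            sigma = c(1.2, 0.4, 0.5),
                            correlation = diag(3))
  zeta <- matrix(rnorm(pd$n_participants * 3, 0, 0.4), ncol = 3)
  expect_equal(model_log_density(pd, gp, zeta),
               brute_force_log_density(pd, gp, zeta), tolerance = 1e-10)
})

test_that("sampler density equals centered density plus exact jacobians", {
  b <- tiny_cohort(seed = 12)
  s <- summarize_trials(b$events,
                        b$decisions[, c("participant_id", "trial_index",
                                        "vaccine")], evidence)
  pd <- build_pt_data(b$decisions, b$ratings, s$outcomes, evidence)
  set.seed(4)
  R <- matrix(c(1, 0.3, -0.2, 0.3, 1, 0.1, -0.2, 0.1, 1), 3)
  gp <- pt_group_parameters(beta = 0.4, beta_j = rnorm(4, 0, 0.3),
                            lambda_probit = 0.2, gamma_probit = 0.5,
                            alpha_raw = -0.2, phi_probit = 0.3,
                            sigma = c(0.8, 0.35, 0.6), correlation = R)
  zeta <- matrix(rnorm(pd$n_participants * 3, 0, 0.4), ncol = 3)
  theta <- vaxcog:::.pt_params_to_theta(gp, zeta)
  cpp <- vaxcog:::model_logp_grad_cpp(list(type = "pt", data = pd$cpp), theta)
  # analytic jacobian of the (sigma, correlation, displacement) transforms
  L <- t(chol(R))
  n <- pd$n_participants
  s1 <- L[2, 2]; s2 <- sqrt(1 - L[3, 1]^2); s3 <- L[3, 3] / s2
  jac <- n * log(det(diag(gp$sigma) %*% L)) +
    log(gp$sigma[1]) +
    sum(log(gp$sigma[2:3] * (1 - gp$sigma[2:3]))) +
    3 * log(s1) + 3 * log(s2) + 2 * log(s3)
  expect_equal(cpp$logp, model_log_density(pd, gp, zeta) + jac,
               tolerance = 1e-8)
})

test_that("C++ gradients agree with finite differences", {
  b <- tiny_cohort(seed = 13, n_per_group = 2)
  s <- summarize_trials(b$events,
                        b$decisions[, c("participant_id", "trial_index",
                                        "vaccine")], evidence)
  pd <- build_pt_data(b$decisions, b$ratings, s$outcomes, evidence)
  spec <- list(type = "pt", data = pd$cpp)
  set.seed(5)
  d <- vaxcog:::model_dim_cpp(spec)
  for (rep in 1:2) {
    theta <- rnorm(d, 0, 0.6)
    res <- vaxcog:::model_logp_grad_cpp(spec, theta)
    fd <- vapply(seq_len(d), function(k) {
      h <- 1e-5
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (vaxcog:::model_logp_grad_cpp(spec, tp)$logp -
         vaxcog:::model_logp_grad_cpp(spec, tm)$logp) / (2 * h)
    }, numeric(1))
    expect_equal(res$grad, fd, tolerance = 1e-5)
  }
})
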