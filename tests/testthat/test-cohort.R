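# synthetic-cohort generator: hierarchy draws, rating distributions,
# planted inspection patterns, generative consistency, reproducibility

test_that("participant draws follow the stated hierarchy", {
  # degenerate covariance pins lambda at Phi(lambda_probit)
  gp0 <- pt_group_parameters(lambda_probit = 0, sigma = c(1e-8, 1e-8, 1e-8))
  g0 <- attitude_group("neutral", 5, group_params = gp0)
  p0 <- sample_participants(g0, seed = 1)
  expect_equal(p0$true_lambda_i, rep(0.5, 5), tolerance = 1e-6)
  # seed reproducibility
  g <- attitude_group("anti", 8)
  expect_identical(sample_participants(g, seed = 7),
                   sample_participants(g, seed = 7))
  # large-sample check of the probit-scale mean against the MVN
  gp <- pt_group_parameters(lambda_probit = 0.6, sigma = c(1, 1, 1))
  gl <- attitude_group("pro", 10000, group_params = gp)
  pl <- sample_participants(gl, seed = 9)
  probit_lambda <- qnorm(pl$true_lambda_i)
  se <- 1 / sqrt(10000)
  expect_lt(abs(mean(probit_lambda) - 0.6), 3 * se)
})

test_that("affect ratings respect sign constraints and severity ordering", {
  r <- sample_affect_ratings("neutral", evidence, seed = 2)
  expect_equal(nrow(r), 18L)
  expect_true(all(r$rating[r$kind == "side_effect"] %in% -5:-1))
  expect_true(all(r$rating[r$kind == "benefit"] %in% 1:5))
  # degenerate config: point mass at -5 for extreme side effects
  cfg <- default_rating_config()
  cfg$anti["extreme"] <- 1
  ra <- sample_affect_ratings("anti", evidence, cfg, seed = 3)
  expect_true(all(ra$rating[ra$severity == "extreme"] == -5L))
  # expected ordering holds in a large sample of participants
  set.seed(4)
  many <- do.call(rbind, lapply(1:300, function(i) {
    sample_affect_ratings("pro", evidence)
  }))
  m <- tapply(many$rating[many$kind == "side_effect"],
              many$severity[many$kind == "side_effect"], mean)
  expect_lt(m["extreme"], m["severe"])
  expect_lt(m["severe"], m["mild"])
  # reproducibility
  expect_identical(sample_affect_ratings("anti", evidence, seed = 5),
                   sample_affect_ratings("anti", evidence, seed = 5))
  bad <- default_rating_config()
  bad$anti["mild"] <- 2
  expect_error(sample_affect_ratings("anti", evidence, bad), "q in")
})

test_that("forced policies produce the planted ignorance patterns", {
  g <- attitude_group("neutral", 1)
  profile <- sample_participants(g, seed = 6)[1, ]
  ratings <- sample_affect_ratings("neutral", evidence, seed = 6)
  # full ignorance: no real evidence events, decision driven by bias only
  pol_full <- inspection_policy(p_full_ignorance = 1, p_no_ignorance = 0)
  set.seed(7)
  tr <- sample_trial(profile, ratings, "AstraZeneca", 1, pol_full,
                     g$group_params, evidence)
  real <- tr$events[tr$events$duration_ms >= 200, ]
  expect_equal(nrow(real), 0L)
  expect_equal(tr$decision$v_iv, 0)
  expect_equal(tr$decision$p_accept,
               acceptance_probability(profile$true_beta_i,
                                      contrast_matrix(evidence)["AstraZeneca", ],
                                      g$group_params$beta_j,
                                      pnorm(g$group_params$phi_probit), 0))
  # no ignorance + zero neglect: filtered log classifies as none, no flags
  pol_none <- inspection_policy(p_full_ignorance = 0, p_no_ignorance = 1,
                                neglect_rates = c(mild = 0, severe = 0,
                                                  extreme = 0, benefit = 0))
  set.seed(8)
  tr2 <- sample_trial(profile, ratings, "Novavax", 2, pol_none,
                      g$group_params, evidence)
  dec <- data.frame(participant_id = profile$participant_id,
                    trial_index = 2L, vaccine = "Novavax")
  s2 <- summarize_trials(tr2$events, dec, evidence)
  expect_equal(s2$trials$ignorance_level, "none")
  expect_false(any(unlist(s2$trials[, grep("neglect", names(s2$trials))])))
})

test_that("an extreme decision bias saturates acceptance", {
  gp <- pt_group_parameters(beta = 10, sigma = c(1e-6, 0.3, 0.3))
  g <- attitude_group("pro", 1, group_params = gp)
  profile <- sample_participants(g, seed = 10)[1, ]
  ratings <- sample_affect_ratings("pro", evidence, seed = 10)
  pol <- inspection_policy()
  set.seed(11)
  dec <- replicate(50, sample_trial(profile, ratings, "Moderna", 1, pol,
                                    gp, evidence)$decision$decision)
  expect_gte(mean(dec == "accept"), 0.98)
})

test_that("generative probabilities are reproducible from stored truth", {
  b <- tiny_cohort(seed = 31, n_per_group = 3)
  s <- summarize_trials(b$events,
                        b$decisions[, c("participant_id", "trial_index",
                                        "vaccine")], evidence)
  pd <- build_pt_data(b$decisions, b$ratings, s$outcomes, evidence)
  xmat <- contrast_matrix(evidence)
  for (t in seq_len(nrow(pd$trials))) {
    row <- pd$trials[t, ]
    prof <- b$participants[b$participants$participant_id ==
                             row$participant_id, ]
    gp <- do.call(pt_group_parameters,
                  c(b$truth$groups[[prof$attitude]][
                    c("beta", "beta_j", "lambda_probit", "gamma_probit",
                      "alpha_raw", "phi_probit", "sigma")],
                    list(correlation = b$truth$groups[[prof$attitude]]$correlation)))
    v <- subjective_valuation(pd$outcomes[[t]], prof$true_lambda_i,
                              prof$true_gamma_i, exp(gp$alpha_raw))
    p <- acceptance_probability(prof$true_beta_i, xmat[row$vaccine, ],
                                gp$beta_j, pnorm(gp$phi_probit), v)
    stored <- b$decisions$p_accept[b$decisions$participant_id ==
                                     row$participant_id &
                                     b$decisions$trial_index == row$trial_index]
    expect_equal(p, stored, tolerance = 1e-12)
  }
})

test_that("cohort generation is deterministic and complete", {
  cc <- cohort_config(groups = list(attitude_group("anti", 2),
                                    attitude_group("neutral", 2),
                                    attitude_group("pro", 2)))
  b1 <- generate_cohort(cc, seed = 55)
  expect_equal(nrow(b1$decisions), 48L)  # 6 participants x 8 vaccines
  expect_equal(nrow(b1$participants), 6L)
  # every participant decides on every vaccine exactly once
  tab <- table(b1$decisions$participant_id, b1$decisions$vaccine)
  expect_true(all(tab == 1L))
  # same seed -> byte-identical files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(b1, d1)
  write_cohort(generate_cohort(cc, seed = 55), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("planted inspection rates are recovered from a generated cohort", {
  pol <- inspection_policy(p_full_ignorance = 0.18, p_no_ignorance = 0.40,
                           neglect_rates = c(mild = 0.05, severe = 0.05,
                                             extreme = 0.10, benefit = 0.05))
  cc <- cohort_config(groups = list(attitude_group("anti", 120,
                                                   policy = pol)))
  b <- generate_cohort(cc, seed = 77)
  s <- summarize_trials(b$events,
                        b$decisions[, c("participant_id", "trial_index",
                                        "vaccine")], evidence)
  n <- nrow(s$trials)
  p_full <- mean(s$trials$ignorance_level == "full")
  p_none <- mean(s$trials$ignorance_level == "none")
  expect_lt(abs(p_full - 0.18), 3 * sqrt(0.18 * 0.82 / n))
  expect_lt(abs(p_none - 0.40), 3 * sqrt(0.40 * 0.60 / n))
  # planted conditional neglect rate among eligible partial trials
  partial <- s$trials$ignorance_level == "partial"
  has_extreme <- s$trials$vaccine %in%
    unique(evidence$vaccine[evidence$severity == "extreme"])
  eligible <- partial & has_extreme
  rate <- mean(s$trials$neglect_extreme[eligible])
  expect_lt(abs(rate - 0.10), 3 * sqrt(0.10 * 0.90 / sum(eligible)))
})
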