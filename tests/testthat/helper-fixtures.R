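# shared fixtures built in code

evidence <- load_evidence_table()

# a tiny deterministic cohort reused across tests
tiny_cohort <- function(seed = 42, n_per_group = 3,
                        groups = c("anti", "pro")) {
  cc <- cohort_config(groups = lapply(groups, function(g) {
    attitude_group(g, n_per_group)
  }))
  generate_cohort(cc, seed = seed)
}

# hand-built hover events for one participant/trial
make_events <- function(box_ids, durations, participant = "p1", trial = 1L,
                        vaccine = "AstraZeneca") {
  n <- length(box_ids)
  data.frame(participant_id = rep_len(participant, n),
             trial_index = rep_len(trial, n),
             vaccine = rep_len(vaccine, n), box_id = box_ids,
             onset_ms = seq(0, by = 1000, length.out = n),
             duration_ms = durations, stringsAsFactors = FALSE)
}

# named zero counts for a vaccine layout
zero_counts <- function(layout) {
  stats::setNames(rep(0L, nrow(layout)), layout$box_id)
}

# brute-force independent evaluation of the centered log density on a
# pt_data object: per-trial hand computation of Eq-style terms plus priors
brute_force_log_density <- function(data, group, zeta) {
  phi <- pnorm(group$phi_probit)
  alpha <- exp(group$alpha_raw)
  ind_beta <- group$beta + zeta[, 1]
  ind_lambda <- pnorm(group$lambda_probit + zeta[, 2])
  ind_gamma <- pnorm(group$gamma_probit + zeta[, 3])
  ll <- 0
  for (t in seq_len(nrow(data$trials))) {
    i <- data$trials$participant_index[t]
    tr <- data$outcomes[[t]]
    v <- 0
    for (o in seq_len(nrow(tr))) {
      if (tr$outcome_ignored[o]) next
      a <- tr$rating[o]
      val <- if (tr$kind[o] == "side_effect") {
        -ind_lambda[i] * abs(a)^alpha
      } else {
        (1 - ind_lambda[i]) * a^alpha
      }
      w <- if (tr$probability_neglected[o] || is.na(tr$probability[o])) {
        0.5
      } else {
        p <- min(max(tr$probability[o], 1e-8), 1 - 1e-8)
        exp(-(-log(p))^ind_gamma[i])
      }
      v <- v + val * w
    }
    eta <- ind_beta[i] + sum(data$contrasts[t, ] * group$beta_j) + phi * v
    p_acc <- 1 / (1 + exp(-eta))
    y <- data$trials$accept[t]
    ll <- ll + log(ifelse(y == 1, p_acc, 1 - p_acc))
  }
  # priors, term by term
  sdl <- 0.13
  trunc_const <- log(pnorm(1, 0.5, sdl) - pnorm(0, 0.5, sdl))
  lp <- sum(dnorm(c(group$beta, group$beta_j, group$lambda_probit,
                    group$gamma_probit, group$phi_probit), 0, 1, log = TRUE))
  lp <- lp + dnorm(group$alpha_raw, 0, 0.5, log = TRUE)
  lp <- lp + dgamma(group$sigma[1], 2, 1, log = TRUE)
  lp <- lp + sum(dnorm(group$sigma[2:3], 0.5, sdl, log = TRUE) - trunc_const)
  lp <- lp + 4 * log(det(group$correlation))   # LKJ(5), unnormalized
  Sigma <- diag(group$sigma) %*% group$correlation %*% diag(group$sigma)
  Sinv <- solve(Sigma)
  for (i in seq_len(nrow(zeta))) {
    q <- drop(zeta[i, ] %*% Sinv %*% zeta[i, ])
    lp <- lp - 0.5 * (3 * log(2 * pi) + log(det(Sigma)) + q)
  }
  ll + lp
}
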