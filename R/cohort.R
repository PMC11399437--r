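# Synthetic study cohorts generated from the hierarchical prospect-theory
# model with known ground truth: participants with individual parameters
# drawn from the group hierarchy, affect ratings by attitude and severity,
# Mouselab hover-event logs produced by an explicit inspection policy, and
# Bernoulli accept/refuse decisions from the generative model.
#
# The inspection policy is a descriptive construct (the underlying study
# does not model inspection behavior generatively): it plants
# deliberate-ignorance levels and probability-neglect patterns at
# configurable rates so that preprocessing can be tested against known
# truth. Defaults are calibrated to the observed group descriptives
# (full ignorance 18/9/7%, side-effect neglect about 15/13/9% of decisions
# for anti/neutral/pro groups).

#' Inspection policy for synthetic trials
#'
#' @param p_full_ignorance Probability that a trial inspects nothing.
#' @param p_no_ignorance Probability that a trial inspects every box.
#' @param neglect_rates Named numeric vector with entries `mild`, `severe`,
#'   `extreme`, `benefit`: probability that a partial-ignorance trial plants
#'   a probability-neglect pattern for that category (given the vaccine
#'   displays at least one such outcome with a probability).
#' @param q_inspect Probability that a non-forced outcome (and its
#'   probability) is inspected in a partial trial.
#' @param incidental_event_rate Per-box probability of an incidental
#'   (< 200 ms) hover event.
#' @param duration_meanlog,duration_sdlog Log-normal inspection-duration
#'   parameters in ms (default median 800 ms).
#' @return An `inspection_policy` object.
#' @export
inspection_policy <- function(p_full_ignorance = 0.1,
                              p_no_ignorance = 0.5,
                              neglect_rates = c(mild = 0.1, severe = 0.1,
                                                extreme = 0.1, benefit = 0.1),
                              q_inspect = 0.85,
                              incidental_event_rate = 0.05,
                              duration_meanlog = log(800),
                              duration_sdlog = 0.5) {
  stopifnot(p_full_ignorance >= 0, p_no_ignorance >= 0,
            p_full_ignorance + p_no_ignorance <= 1,
            all(c("mild", "severe", "extreme", "benefit") %in%
                  names(neglect_rates)),
            all(neglect_rates >= 0 & neglect_rates <= 1),
            q_inspect >= 0, q_inspect <= 1,
            incidental_event_rate >= 0, incidental_event_rate <= 1)
  structure(list(p_full_ignorance = p_full_ignorance,
                 p_no_ignorance = p_no_ignorance,
                 neglect_rates = neglect_rates,
                 q_inspect = q_inspect,
                 incidental_event_rate = incidental_event_rate,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog),
            class = "inspection_policy")
}

# Defaults calibrated to the observed trial-level descriptives: full
# ignorance 18/9/7% and overall side-effect neglect 15/13/9% of decisions
# (benefits 8/6/4%) for the anti/neutral/pro groups. With partial-trial
# shares of 0.40/0.41/0.38, the conditional per-category rates below solve
# overall = p_partial * mean over vaccines of (1 - prod(1 - r_cat)),
# keeping a fixed 1.5 : 1.2 : 1.0 extreme : severe : mild emphasis.
.default_policies <- function() {
  list(
    anti = inspection_policy(0.18, 0.42,
                             c(mild = 0.214, severe = 0.257, extreme = 0.321,
                               benefit = 0.200)),
    neutral = inspection_policy(0.09, 0.50,
                                c(mild = 0.178, severe = 0.213, extreme = 0.266,
                                  benefit = 0.146)),
    pro = inspection_policy(0.07, 0.55,
                            c(mild = 0.130, severe = 0.156, extreme = 0.195,
                              benefit = 0.105))
  )
}

# default group-level parameters per attitude; decision biases, loss
# aversion (Lambda ~ 2.3 anti, ~ 4 neutral/pro) and probability sensitivity
# orderings follow the fitted-group patterns; alpha = 1 and phi = 0.3
.default_group_params <- function() {
  list(
    anti = pt_group_parameters(beta = -2.5, beta_j = c(0.3, -0.2, 0.1, -0.1),
                               lambda_probit = stats::qnorm(0.7),
                               gamma_probit = stats::qnorm(0.3),
                               alpha_raw = 0, phi_probit = stats::qnorm(0.3),
                               sigma = c(1.5, 0.45, 0.45)),
    neutral = pt_group_parameters(beta = -0.5, beta_j = c(0.3, -0.2, 0.1, -0.1),
                                  lambda_probit = stats::qnorm(0.8),
                                  gamma_probit = 0,
                                  alpha_raw = 0, phi_probit = stats::qnorm(0.3),
                                  sigma = c(1.5, 0.45, 0.45)),
    pro = pt_group_parameters(beta = 1.5, beta_j = c(0.3, -0.2, 0.1, -0.1),
                              lambda_probit = stats::qnorm(0.8),
                              gamma_probit = stats::qnorm(0.4),
                              alpha_raw = 0, phi_probit = stats::qnorm(0.3),
                              sigma = c(1.5, 0.45, 0.45))
  )
}

#' Default affect-rating configuration
#'
#' Shifted-binomial ordinal rating distributions with one success
#' probability `q` per attitude x category; higher `q` means more extreme
#' ratings (more negative for side effects, more positive for benefits).
#' Defaults order severity classes (extreme > severe > mild in magnitude)
#' and attitudes (anti most negative about side effects, pro most positive
#' about benefits).
#'
#' @return Named list (`anti`, `neutral`, `pro`) of `q` vectors with
#'   entries `mild`, `severe`, `extreme`, `benefit`.
#' @export
default_rating_config <- function() {
  list(anti = c(mild = 0.35, severe = 0.65, extreme = 0.90, benefit = 0.45),
       neutral = c(mild = 0.30, severe = 0.60, extreme = 0.85, benefit = 0.60),
       pro = c(mild = 0.25, severe = 0.55, extreme = 0.80, benefit = 0.80))
}

#' Attitude-group configuration
#'
#' @param name `"anti"`, `"neutral"`, or `"pro"`.
#' @param n_participants Number of participants in the group.
#' @param group_params A [pt_group_parameters()] object (defaults to the
#'   packaged attitude-specific values).
#' @param policy An [inspection_policy()] (defaults to the packaged
#'   attitude-specific calibration).
#' @return An `attitude_group` object.
#' @export
attitude_group <- function(name, n_participants,
                           group_params = NULL, policy = NULL) {
  name <- match.arg(name, c("anti", "neutral", "pro"))
  stopifnot(n_participants >= 1)
  if (is.null(group_params)) group_params <- .default_group_params()[[name]]
  if (is.null(policy)) policy <- .default_policies()[[name]]
  stopifnot(inherits(group_params, "pt_group_parameters"),
            inherits(policy, "inspection_policy"))
  structure(list(name = name, n_participants = as.integer(n_participants),
                 group_params = group_params, policy = policy),
            class = "attitude_group")
}

#' Draw participant profiles from the group hierarchy
#'
#' Displacements `zeta_i ~ MVN(0, Sigma)` with
#' `Sigma = diag(sigma) R diag(sigma)`, then `beta_i = beta + zeta_1`,
#' `lambda_i = Phi(lambda_probit + zeta_2)`,
#' `gamma_i = Phi(gamma_probit + zeta_3)`.
#'
#' @param group An [attitude_group()].
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for participant ids.
#' @return Data frame with columns `participant_id`, `attitude`,
#'   `zeta_beta`, `zeta_lambda`, `zeta_gamma`, `true_beta_i`,
#'   `true_lambda_i`, `true_gamma_i`.
#' @export
sample_participants <- function(group, seed = NULL, id_prefix = NULL) {
  stopifnot(inherits(group, "attitude_group"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id_prefix)) id_prefix <- group$name
  gp <- group$group_params
  n <- group$n_participants
  L <- t(chol(gp$correlation))
  z <- matrix(stats::rnorm(3 * n), ncol = 3)
  zeta <- t(diag(gp$sigma) %*% L %*% t(z))
  ind <- transform_individual_parameters(gp, zeta)
  data.frame(
    participant_id = sprintf("%s_%04d", id_prefix, seq_len(n)),
    attitude = group$name,
    zeta_beta = zeta[, 1], zeta_lambda = zeta[, 2], zeta_gamma = zeta[, 3],
    true_beta_i = ind$beta_i, true_lambda_i = ind$lambda_i,
    true_gamma_i = ind$gamma_i,
    stringsAsFactors = FALSE
  )
}

#' Draw affect ratings for one participant
#'
#' Ratings are drawn independently per outcome from shifted-binomial
#' ordinal distributions: side effects `-(1 + Binomial(4, q))` on -5..-1,
#' benefits `1 + Binomial(4, q)` on 1..5, with `q` configured per
#' attitude x severity category. Defaults order categories so that extreme
#' side effects are rated more negatively than severe, and severe than
#' mild.
#'
#' @param attitude `"anti"`, `"neutral"`, or `"pro"`.
#' @param evidence An `evidence_table` (supplies the outcome labels).
#' @param rating_config Named list per attitude of `q` values per category
#'   (`mild`, `severe`, `extreme`, `benefit`), all in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Data frame with columns `outcome_label`, `kind`, `severity`,
#'   `rating`.
#' @export
sample_affect_ratings <- function(attitude, evidence,
                                  rating_config = default_rating_config(),
                                  seed = NULL) {
  attitude <- match.arg(attitude, c("anti", "neutral", "pro"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- rating_config[[attitude]]
  if (is.null(cfg) ||
      !all(c("mild", "severe", "extreme", "benefit") %in% names(cfg)) ||
      any(cfg < 0 | cfg > 1)) {
    stop("rating_config must supply q in [0,1] for mild/severe/extreme/benefit")
  }
  df <- unique(as.data.frame(evidence)[, c("outcome_label", "outcome_kind",
                                           "severity")])
  cat_ <- ifelse(df$outcome_kind == "benefit", "benefit", df$severity)
  q <- cfg[cat_]
  lvl <- stats::rbinom(nrow(df), 4, q)
  rating <- ifelse(df$outcome_kind == "benefit", 1 + lvl, -(1 + lvl))
  data.frame(outcome_label = df$outcome_label, kind = df$outcome_kind,
             severity = df$severity, rating = as.integer(rating),
             stringsAsFactors = FALSE)
}

# plant the per-outcome inspection pattern for one partial-ignorance trial;
# returns list(outcome_inspected, probability_inspected, forced categories)
.plant_partial_pattern <- function(spec, policy) {
  n_out <- nrow(spec)
  has_prob <- !is.na(spec$probability)
  cat_ <- ifelse(spec$outcome_kind == "benefit", "benefit", spec$severity)
  inspected <- stats::runif(n_out) < policy$q_inspect
  p_inspected <- inspected & has_prob
  forced <- character(0)
  for (cc in unique(cat_)) {
    eligible <- which(cat_ == cc & has_prob)
    if (length(eligible) == 0) next
    if (stats::runif(1) < policy$neglect_rates[[cc]]) {
      pick <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      inspected[pick] <- TRUE
      p_inspected[pick] <- FALSE
      forced <- c(forced, cc)
    }
  }
  # enforce a nonempty strict subset of the boxes
  n_boxes_total <- n_out + sum(has_prob)
  n_boxes_insp <- sum(inspected) + sum(p_inspected)
  if (n_boxes_insp == 0) {
    pick <- sample.int(n_out, 1)
    inspected[pick] <- TRUE
    p_inspected[pick] <- has_prob[pick]
  } else if (n_boxes_insp == n_boxes_total) {
    # only reachable without planted neglect; drop one outcome + probability
    pick <- sample.int(n_out, 1)
    inspected[pick] <- FALSE
    p_inspected[pick] <- FALSE
  }
  list(outcome_inspected = inspected, probability_inspected = p_inspected,
       forced = forced)
}

#' Simulate one Mouselab trial
#'
#' Draws an ignorance pattern from the policy (full / none / partial with
#' planted probability neglect), emits hover events whose real inspections
#' last at least 200 ms plus incidental sub-200 ms events, computes the
#' subjective valuation from the post-filter inspection pattern, and draws
#' the accept/refuse decision from the generative model.
#'
#' @param profile One row of [sample_participants()] output.
#' @param ratings The participant's [sample_affect_ratings()] output.
#' @param vaccine Vaccine brand name.
#' @param trial_index Trial position (1-8).
#' @param policy An [inspection_policy()].
#' @param group_params The group's [pt_group_parameters()].
#' @param evidence An `evidence_table`.
#' @return List with `events` (hover-event data frame), `decision` (one-row
#'   data frame incl. the true acceptance probability `p_accept`), and the
#'   planted `pattern`.
#' @export
sample_trial <- function(profile, ratings, vaccine, trial_index, policy,
                         group_params, evidence) {
  spec <- vaccine_spec(evidence, vaccine)
  layout <- evidence_layout(evidence, vaccine)
  n_out <- nrow(spec)
  has_prob <- !is.na(spec$probability)

  u <- stats::runif(1)
  if (u < policy$p_full_ignorance) {
    pat <- list(outcome_inspected = rep(FALSE, n_out),
                probability_inspected = rep(FALSE, n_out))
  } else if (u < policy$p_full_ignorance + policy$p_no_ignorance) {
    pat <- list(outcome_inspected = rep(TRUE, n_out),
                probability_inspected = has_prob)
  } else {
    pat <- .plant_partial_pattern(spec, policy)
  }

  # hover events: real inspections >= 200 ms, plus incidental (< 200 ms)
  kind_tag <- ifelse(spec$outcome_kind == "side_effect", "se", "b")
  knum <- ifelse(spec$outcome_kind == "side_effect", seq_len(n_out),
                 seq_len(n_out) - 3L)
  out_id <- paste0(kind_tag, knum, "_outcome")
  prob_id <- paste0(kind_tag, knum, "_prob")
  boxes <- c(out_id[pat$outcome_inspected], prob_id[pat$probability_inspected])
  n_rep <- if (length(boxes) > 0) 1L + stats::rpois(length(boxes), 0.4) else integer(0)
  real_boxes <- rep(boxes, n_rep)
  real_dur <- pmax(200, round(stats::rlnorm(length(real_boxes),
                                            policy$duration_meanlog,
                                            policy$duration_sdlog)))
  inc_sel <- stats::runif(nrow(layout)) < policy$incidental_event_rate
  inc_boxes <- layout$box_id[inc_sel]
  inc_dur <- round(stats::runif(length(inc_boxes), 50, 199))
  all_boxes <- c(real_boxes, inc_boxes)
  all_dur <- c(real_dur, inc_dur)
  events <- if (length(all_boxes) > 0) {
    ord <- sample.int(length(all_boxes))
    onset <- cumsum(c(0, all_dur[ord][-length(ord)] +
                        round(stats::runif(length(ord) - 1, 50, 400))))
    data.frame(participant_id = profile$participant_id,
               trial_index = trial_index,
               vaccine = vaccine,
               box_id = all_boxes[ord],
               onset_ms = as.integer(onset),
               duration_ms = as.integer(all_dur[ord]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(participant_id = character(0), trial_index = integer(0),
               vaccine = character(0), box_id = character(0),
               onset_ms = integer(0), duration_ms = integer(0),
               stringsAsFactors = FALSE)
  }

  # decision from the generative model, using the post-filter pattern
  rmap <- stats::setNames(ratings$rating, normalize_label(ratings$outcome_label))
  rating <- rmap[normalize_label(spec$outcome_label)]
  trial_input <- data.frame(
    rating = as.numeric(rating),
    probability = spec$probability,
    kind = spec$outcome_kind,
    outcome_ignored = !pat$outcome_inspected,
    probability_neglected = pat$outcome_inspected & has_prob &
      !pat$probability_inspected,
    stringsAsFactors = FALSE
  )
  alpha <- exp(group_params$alpha_raw)
  phi <- stats::pnorm(group_params$phi_probit)
  v_iv <- subjective_valuation(trial_input, profile$true_lambda_i,
                               profile$true_gamma_i, alpha)
  xmat <- contrast_matrix(evidence)
  p_accept <- acceptance_probability(profile$true_beta_i, xmat[vaccine, ],
                                     group_params$beta_j, phi, v_iv)
  decision <- data.frame(
    participant_id = profile$participant_id,
    trial_index = trial_index,
    vaccine = vaccine,
    decision = ifelse(stats::runif(1) < p_accept, "accept", "refuse"),
    p_accept = p_accept,
    v_iv = v_iv,
    stringsAsFactors = FALSE
  )
  list(events = events, decision = decision, pattern = pat)
}

#' Cohort configuration
#'
#' @param groups List of [attitude_group()] objects.
#' @param rating_config See [sample_affect_ratings()].
#' @param evidence An `evidence_table` (defaults to the packaged table).
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(groups = list(attitude_group("anti", 365),
                                        attitude_group("neutral", 373),
                                        attitude_group("pro", 462)),
                          rating_config = default_rating_config(),
                          evidence = load_evidence_table()) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, "attitude_group")))
  structure(list(groups = groups, rating_config = rating_config,
                 evidence = evidence),
            class = "cohort_config")
}

#' Generate a complete synthetic cohort
#'
#' Draws participants, affect ratings, hover-event logs, and decisions for
#' every group in the configuration; every participant decides on all eight
#' vaccines. Deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes
#'   `participants.csv`, `ratings.csv`, `events.csv`, `decisions.csv`, and
#'   `truth.json`.
#' @return A `cohort` bundle: list with `participants`, `ratings`,
#'   `events`, `decisions` (including the true per-trial acceptance
#'   probability) and `truth` (group-level parameters per attitude).
#' @export
generate_cohort <- function(config, seed, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  ev <- config$evidence
  vaccines <- attr(ev, "vaccines")
  parts <- list(); rats <- list(); evs <- list(); decs <- list()
  truth_groups <- list()
  for (g in config$groups) {
    profiles <- sample_participants(g)
    parts[[g$name]] <- profiles
    truth_groups[[g$name]] <- unclass(g$group_params)
    for (i in seq_len(nrow(profiles))) {
      profile <- profiles[i, ]
      pr <- sample_affect_ratings(g$name, ev, config$rating_config)
      pr$participant_id <- profile$participant_id
      rats[[profile$participant_id]] <- pr
      for (t in seq_along(vaccines)) {
        tr <- sample_trial(profile, pr, vaccines[t], t, g$policy,
                           g$group_params, ev)
        evs[[paste(profile$participant_id, t)]] <- tr$events
        decs[[paste(profile$participant_id, t)]] <- tr$decision
      }
    }
  }
  participants <- do.call(rbind, parts)
  rownames(participants) <- NULL
  ratings <- do.call(rbind, rats)
  rownames(ratings) <- NULL
  events <- do.call(rbind, evs)
  rownames(events) <- NULL
  decisions <- do.call(rbind, decs)
  rownames(decisions) <- NULL
  bundle <- structure(list(participants = participants,
                           ratings = ratings[, c("participant_id",
                                                 "outcome_label", "rating")],
                           events = events,
                           decisions = decisions,
                           truth = list(seed = seed, groups = truth_groups),
                           evidence = ev),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

#' Write a cohort bundle to CSV files plus a ground-truth JSON
#'
#' @param bundle A `cohort` from [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = TRUE)
  }
  w(bundle$participants[, c("participant_id", "attitude")], "participants.csv")
  w(bundle$ratings, "ratings.csv")
  w(bundle$events, "events.csv")
  w(bundle$decisions[, c("participant_id", "trial_index", "vaccine",
                         "decision")], "decisions.csv")
  truth <- bundle$truth
  truth$individual <- bundle$participants
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
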