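# Assembly of prospect-theory model inputs from decisions, affect ratings,
# per-outcome inspection flags, and the evidence table.

#' Assemble model inputs for one attitude group
#'
#' Joins decisions, affect ratings, and the per-outcome inspection flags
#' produced by [summarize_trials()] with the evidence table into the
#' trial-level structure the likelihood needs: for every non-ignored outcome
#' its rating magnitude, kind, and either an inspected probability (Prelec
#' weighting) or the fixed 0.5 weight (probability neglected, or no
#' probability displayed).
#'
#' @param decisions Data frame with columns `participant_id`, `trial_index`,
#'   `vaccine`, `decision` (`"accept"`/`"refuse"`).
#' @param ratings Data frame with columns `participant_id`, `outcome_label`,
#'   `rating` (signed: -5..-1 side effects, 1..5 benefits).
#' @param outcome_flags Data frame with columns `participant_id`,
#'   `trial_index`, `vaccine`, `outcome_index`, `outcome_inspected`,
#'   `probability_inspected` (see [summarize_trials()]).
#' @param evidence An `evidence_table`.
#' @return A `pt_data` object: list with `participants` (data frame, row
#'   order defines the participant index), `n_participants`, `trials`
#'   (participant_index, vaccine, accept), `contrasts` (trials x 4),
#'   `outcomes` (list of per-trial outcome data frames), and `cpp` (the
#'   flattened representation used by the sampler).
#' @export
build_pt_data <- function(decisions, ratings, outcome_flags, evidence) {
  stopifnot(inherits(evidence, "evidence_table"))
  req <- c("participant_id", "trial_index", "vaccine", "decision")
  stopifnot(all(req %in% names(decisions)))
  stopifnot(all(c("participant_id", "outcome_label", "rating") %in% names(ratings)))
  stopifnot(all(c("participant_id", "trial_index", "vaccine", "outcome_index",
                  "outcome_inspected", "probability_inspected") %in%
                  names(outcome_flags)))
  if (!all(decisions$decision %in% c("accept", "refuse"))) {
    stop("decision must be 'accept' or 'refuse'")
  }

  pid <- sort(unique(decisions$participant_id))
  participants <- data.frame(participant_id = pid, stringsAsFactors = FALSE)
  n <- length(pid)

  decisions <- decisions[order(match(decisions$participant_id, pid),
                               decisions$trial_index), ]
  xmat <- contrast_matrix(evidence)
  if (!all(decisions$vaccine %in% rownames(xmat))) {
    stop("decisions reference unknown vaccine(s)")
  }

  # fast rating lookup: participant x normalized label
  rkey <- paste(ratings$participant_id, normalize_label(ratings$outcome_label))
  rmap <- ratings$rating
  names(rmap) <- rkey

  # per-trial outcome flags lookup
  fkey <- paste(outcome_flags$participant_id, outcome_flags$trial_index,
                outcome_flags$outcome_index)
  insp <- outcome_flags$outcome_inspected
  pinsp <- outcome_flags$probability_inspected
  names(insp) <- fkey
  names(pinsp) <- fkey

  layouts <- lapply(attr(evidence, "vaccines"), function(v) vaccine_spec(evidence, v))
  names(layouts) <- attr(evidence, "vaccines")

  T_ <- nrow(decisions)
  outcomes <- vector("list", T_)
  part_idx <- match(decisions$participant_id, pid)
  accept <- as.integer(decisions$decision == "accept")
  contrasts <- xmat[decisions$vaccine, , drop = FALSE]

  # flattened arrays for the sampler
  out_m <- numeric(0); out_se <- integer(0); out_hasp <- integer(0)
  out_tneg <- numeric(0)
  off <- integer(T_ + 1L)

  for (t in seq_len(T_)) {
    spec <- layouts[[decisions$vaccine[t]]]
    key0 <- paste(decisions$participant_id[t], decisions$trial_index[t],
                  seq_len(6L))
    inspected <- insp[key0]
    p_inspected <- pinsp[key0]
    if (any(is.na(inspected))) {
      stop("missing outcome flags for participant ", decisions$participant_id[t],
           ", trial ", decisions$trial_index[t])
    }
    rating <- rmap[paste(decisions$participant_id[t],
                         normalize_label(spec$outcome_label))]
    if (any(is.na(rating))) {
      stop("missing affect rating(s) for participant ",
           decisions$participant_id[t])
    }
    is_se <- spec$outcome_kind == "side_effect"
    if (any(is_se & rating > 0) || any(!is_se & rating < 0) || any(rating == 0)) {
      stop("affect rating sign inconsistent with outcome kind for participant ",
           decisions$participant_id[t])
    }
    has_prob_box <- !is.na(spec$probability)
    neglected <- inspected & has_prob_box & !p_inspected
    tr <- data.frame(
      rating = as.numeric(rating),
      probability = spec$probability,
      kind = spec$outcome_kind,
      outcome_ignored = !inspected,
      probability_neglected = neglected,
      stringsAsFactors = FALSE
    )
    outcomes[[t]] <- tr
    keep <- inspected
    # Prelec only when the probability was displayed and inspected
    hasp <- has_prob_box[keep] & p_inspected[keep]
    pc <- pmin(pmax(spec$probability[keep], 1e-8), 1 - 1e-8)
    tneg <- ifelse(hasp, -log(pc), 0)
    off[t + 1L] <- off[t] + sum(keep)
    out_m <- c(out_m, abs(rating[keep]))
    out_se <- c(out_se, as.integer(is_se[keep]))
    out_hasp <- c(out_hasp, as.integer(hasp))
    out_tneg <- c(out_tneg, tneg)
  }

  cpp <- list(N = n,
              part = part_idx - 1L,
              y = accept,
              X = unname(contrasts),
              off = off,
              m = out_m,
              is_se = out_se,
              has_p = out_hasp,
              tneg = out_tneg,
              lkj_eta = 5)

  structure(list(participants = participants,
                 n_participants = n,
                 trials = data.frame(participant_index = part_idx,
                                     participant_id = decisions$participant_id,
                                     trial_index = decisions$trial_index,
                                     vaccine = decisions$vaccine,
                                     accept = accept,
                                     stringsAsFactors = FALSE),
                 contrasts = contrasts,
                 outcomes = outcomes,
                 cpp = cpp),
            class = "pt_data")
}

# unconstrained sampler coordinates <-> centered parameters -----------------

# named index helpers for the unconstrained vector
.pt_theta_names <- function(n) {
  c("beta", paste0("beta_j[", 1:4, "]"), "lambda_probit", "gamma_probit",
    "alpha_raw", "phi_probit", "log_sigma_beta", "logit_sigma_lambda",
    "logit_sigma_gamma", paste0("corr_raw[", 1:3, "]"),
    paste0("z[", rep(seq_len(n), each = 3), ",", rep(1:3, n), "]"))
}

# Cholesky factor of the displacement correlation from the tanh parameters
.pt_chol_from_raw <- function(yr) {
  c1 <- tanh(yr[1]); c2 <- tanh(yr[2]); c3 <- tanh(yr[3])
  s1 <- sqrt(1 - c1^2); s2 <- sqrt(1 - c2^2); s3 <- sqrt(1 - c3^2)
  matrix(c(1, 0, 0,
           c1, s1, 0,
           c2, c3 * s2, s2 * s3), nrow = 3, byrow = TRUE)
}

# centered parameters implied by one unconstrained draw
.pt_theta_to_params <- function(theta, n) {
  L <- .pt_chol_from_raw(theta[13:15])
  sigma <- c(exp(theta[10]), stats::plogis(theta[11]), stats::plogis(theta[12]))
  group <- pt_group_parameters(
    beta = theta[1], beta_j = theta[2:5],
    lambda_probit = theta[6], gamma_probit = theta[7],
    alpha_raw = theta[8], phi_probit = theta[9],
    sigma = sigma, correlation = L %*% t(L))
  z <- matrix(theta[-(1:15)], ncol = 3L, byrow = TRUE)
  zeta <- t(diag(sigma) %*% L %*% t(z))
  list(group = group, zeta = zeta)
}

# unconstrained vector from centered parameters (inverse of the above);
# used for planting ground truth and for tests
.pt_params_to_theta <- function(group, zeta) {
  L <- t(chol(group$correlation))
  c1 <- L[2, 1]
  s1 <- L[2, 2]
  c2 <- L[3, 1]
  s2 <- sqrt(1 - c2^2)
  c3 <- L[3, 2] / s2
  z <- t(solve(diag(group$sigma) %*% L, t(zeta)))
  c(group$beta, group$beta_j, group$lambda_probit, group$gamma_probit,
    group$alpha_raw, group$phi_probit,
    log(group$sigma[1]), stats::qlogis(group$sigma[2]),
    stats::qlogis(group$sigma[3]),
    atanh(c1), atanh(c2), atanh(c3),
    as.vector(t(z)))
}
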