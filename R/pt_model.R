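# Hierarchical prospect-theory model of accept/refuse vaccination decisions.
#
# A participant i's probability of accepting vaccine v is
#   P(accept) = logistic(beta_i + X_v %*% beta_j + phi * V_iv),
# where beta_i is an individual decision bias, X_v a sum-to-zero contrast row
# coding the vaccine's country of origin and technology, and V_iv the
# prospect-theory valuation of the inspected evidence:
#   V_iv = sum_se v(a_se) w(p_se) + sum_b v(a_b) w(p_b)
# with a three-case value function (side effect / benefit / ignored) and a
# two-case probability weight (one-parameter Prelec for inspected
# probabilities, fixed 0.5 for neglected ones).

.P_EPS <- 1e-8  # probabilities clamped to [.P_EPS, 1 - .P_EPS] before Prelec

#' Prospect-theory value of an affect rating
#'
#' Three cases: an ignored outcome contributes 0; a side effect rated `a`
#' contributes `-lambda_i * |a|^alpha`; a benefit contributes
#' `(1 - lambda_i) * a^alpha`. With `lambda_i = 0.5` side effects and
#' benefits are weighted equally (loss neutrality); `lambda_i > 0.5`
#' overweights side effects (loss aversion, `Lambda = lambda/(1-lambda) > 1`).
#'
#' @param rating Signed integer affect rating: -5..-1 for side effects,
#'   1..5 for benefits. Zero is not on the scale and is rejected.
#' @param lambda_i Loss-aversion parameter in (0, 1).
#' @param alpha Rating-scale curvature, > 0.
#' @param kind `"side_effect"` or `"benefit"`.
#' @param ignored Logical; if `TRUE` the value is 0.
#' @return Numeric value (<= 0 for side effects, >= 0 for benefits).
#' @export
value_function <- function(rating, lambda_i, alpha, kind, ignored = FALSE) {
  kind <- match.arg(kind, c("side_effect", "benefit"))
  if (any(rating == 0)) stop("affect rating 0 is not on the scale (-5..-1, 1..5)")
  stopifnot(lambda_i > 0, lambda_i < 1, alpha > 0)
  if (kind == "side_effect" && any(rating > 0)) {
    stop("side-effect ratings must be negative")
  }
  if (kind == "benefit" && any(rating < 0)) {
    stop("benefit ratings must be positive")
  }
  v <- if (kind == "side_effect") {
    -lambda_i * abs(rating)^alpha
  } else {
    (1 - lambda_i) * rating^alpha
  }
  ifelse(rep_len(ignored, length(rating)), 0, v)
}

#' Decision weight of a probability
#'
#' Inspected probabilities are transformed with the one-parameter Prelec
#' weighting function `w(p) = exp(-(-log p)^gamma_i)`; `gamma_i = 1` is
#' linear weighting (`w(p) = p`), `gamma_i = 0` collapses all weights to
#' `exp(-1) ~= 0.37`. Neglected probabilities (outcome inspected, probability
#' not) receive the fixed weight 0.5. Probabilities are clamped to
#' `[1e-8, 1 - 1e-8]` before the transform.
#'
#' @param p Probability in \[0, 1\], or `NA` when no probability was
#'   displayed (treated as neglected when the outcome was inspected).
#' @param gamma_i Probability-sensitivity parameter in \[0, 1\].
#' @param neglected Logical; `TRUE` if the probability was not inspected
#'   although the outcome was.
#' @return Decision weight in (0, 1).
#' @export
weight_probability <- function(p, gamma_i, neglected = FALSE) {
  stopifnot(gamma_i >= 0, gamma_i <= 1)
  neglected <- rep_len(neglected, length(p)) | is.na(p)
  if (any(!neglected & (p < 0 | p > 1))) stop("probability outside [0, 1]")
  pc <- pmin(pmax(p, .P_EPS), 1 - .P_EPS)
  w <- exp(-(-log(pc))^gamma_i)
  ifelse(neglected, 0.5, w)
}

#' Subjective valuation of a vaccine
#'
#' Sums value x weight over the vaccine's side effects and benefits given
#' the trial's inspection pattern. A full-ignorance trial (all outcomes
#' ignored) has valuation 0.
#'
#' @param trial Data frame with one row per outcome and columns `rating`
#'   (signed), `probability` (fraction or NA), `kind`
#'   (`"side_effect"`/`"benefit"`), `outcome_ignored`,
#'   `probability_neglected` (logicals).
#' @param lambda_i,gamma_i Individual parameters in (0, 1).
#' @param alpha Rating-scale curvature, > 0.
#' @return The scalar valuation `V_iv`.
#' @export
subjective_valuation <- function(trial, lambda_i, gamma_i, alpha) {
  stopifnot(is.data.frame(trial),
            all(c("rating", "probability", "kind", "outcome_ignored",
                  "probability_neglected") %in% names(trial)))
  if (any(trial$probability_neglected & trial$outcome_ignored)) {
    stop("an ignored outcome cannot have a neglected probability")
  }
  total <- 0
  for (i in seq_len(nrow(trial))) {
    if (trial$outcome_ignored[i]) next
    v <- value_function(trial$rating[i], lambda_i, alpha, trial$kind[i])
    w <- weight_probability(trial$probability[i], gamma_i,
                            neglected = trial$probability_neglected[i])
    total <- total + v * w
  }
  total
}

#' Acceptance probability
#'
#' Logistic of `beta_i + X_v %*% beta_j + phi * V`.
#'
#' @param beta_i Individual decision bias.
#' @param x_v Numeric contrast row for the vaccine (length 4).
#' @param beta_j Contrast coefficients (length 4).
#' @param phi Valuation scale in \[0, 1\].
#' @param v_iv Subjective valuation `V_iv`.
#' @return Probability of acceptance.
#' @export
acceptance_probability <- function(beta_i, x_v, beta_j, phi, v_iv) {
  stopifnot(length(x_v) == length(beta_j), phi >= 0, phi <= 1)
  stats::plogis(beta_i + sum(x_v * beta_j) + phi * v_iv)
}

#' Group-level parameter bundle
#'
#' Collects the group-level parameters of the hierarchical model. The
#' hierarchy places individual displacements `zeta_i ~ MVN(0, Sigma)` with
#' `Sigma = diag(sigma) R diag(sigma)` around the group parameters:
#' `beta_i = beta + zeta_b`, `lambda_i = Phi(lambda_probit + zeta_l)`,
#' `gamma_i = Phi(gamma_probit + zeta_g)` (`Phi` = standard normal CDF).
#'
#' @param beta Group decision bias.
#' @param beta_j Length-4 vector of sum-to-zero contrast coefficients
#'   (2 country + 2 technology).
#' @param lambda_probit,gamma_probit Group loss aversion / probability
#'   sensitivity on the probit scale.
#' @param alpha_raw Log of the rating-scale curvature (`alpha = exp(alpha_raw)`).
#' @param phi_probit Valuation scale on the probit scale (`phi = Phi(phi_probit)`).
#' @param sigma Length-3 positive SDs of the displacements (beta, lambda,
#'   gamma components).
#' @param correlation 3x3 correlation matrix of the displacements.
#' @return An object of class `pt_group_parameters` (a named list).
#' @export
pt_group_parameters <- function(beta = 0, beta_j = rep(0, 4),
                                lambda_probit = 0, gamma_probit = 0,
                                alpha_raw = 0, phi_probit = 0,
                                sigma = c(1, 0.5, 0.5),
                                correlation = diag(3)) {
  stopifnot(length(beta_j) == 4L, length(sigma) == 3L, all(sigma > 0),
            is.matrix(correlation), all(dim(correlation) == c(3L, 3L)))
  if (max(abs(correlation - t(correlation))) > 1e-10 ||
      max(abs(diag(correlation) - 1)) > 1e-10) {
    stop("correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation matrix is not positive-definite")
  structure(list(beta = beta, beta_j = beta_j,
                 lambda_probit = lambda_probit, gamma_probit = gamma_probit,
                 alpha_raw = alpha_raw, phi_probit = phi_probit,
                 sigma = sigma, correlation = correlation),
            class = "pt_group_parameters")
}

#' Individual parameters from group parameters and displacements
#'
#' `beta_i = beta + zeta[1]`; `lambda_i = Phi(lambda_probit + zeta[2])`;
#' `gamma_i = Phi(gamma_probit + zeta[3])`.
#'
#' @param group A [pt_group_parameters()] object.
#' @param zeta Numeric displacement vector of length 3, or an n x 3 matrix.
#' @return Data frame with columns `beta_i`, `lambda_i`, `gamma_i`.
#' @export
transform_individual_parameters <- function(group, zeta) {
  stopifnot(inherits(group, "pt_group_parameters"))
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1L)
  stopifnot(ncol(zeta) == 3L, all(is.finite(zeta)))
  data.frame(
    beta_i = group$beta + zeta[, 1L],
    lambda_i = stats::pnorm(group$lambda_probit + zeta[, 2L]),
    gamma_i = stats::pnorm(group$gamma_probit + zeta[, 3L])
  )
}

#' Loss-aversion multiplier
#'
#' `Lambda = lambda / (1 - lambda)`; `Lambda = 1` is loss neutrality,
#' `Lambda > 1` loss aversion.
#'
#' @param lambda Loss-aversion parameter(s) in (0, 1).
#' @return Numeric vector of multipliers.
#' @export
loss_aversion_multiplier <- function(lambda) {
  stopifnot(all(lambda > 0 & lambda < 1))
  lambda / (1 - lambda)
}

#' Sum-to-zero contrast matrix for the eight vaccines
#'
#' Columns 1-2 code the country of origin (US, China, other) and columns
#' 3-4 the vaccine technology (mRNA, vector, other) with sum-to-zero
#' contrasts: each column sums to zero over the three category levels.
#'
#' @param ev An `evidence_table`.
#' @return An 8 x 4 matrix with vaccine brand row names.
#' @export
contrast_matrix <- function(ev) {
  stopifnot(inherits(ev, "evidence_table"))
  df <- unique(as.data.frame(ev)[, c("vaccine", "country_category",
                                     "technology_category")])
  country_levels <- c("US", "China", "other")
  tech_levels <- c("mRNA", "vector", "other")
  if (!all(df$country_category %in% country_levels) ||
      !all(df$technology_category %in% tech_levels)) {
    stop("unknown country/technology category")
  }
  for (lv in country_levels) {
    if (!lv %in% df$country_category) stop("country level with no vaccines: ", lv)
  }
  for (lv in tech_levels) {
    if (!lv %in% df$technology_category) stop("technology level with no vaccines: ", lv)
  }
  cs <- stats::contr.sum(3)
  country <- cs[match(df$country_category, country_levels), , drop = FALSE]
  tech <- cs[match(df$technology_category, tech_levels), , drop = FALSE]
  x <- cbind(country, tech)
  dimnames(x) <- list(df$vaccine,
                      c("country1", "country2", "tech1", "tech2"))
  x
}

# ---- centered joint log density --------------------------------------------

# log MVN(zeta | 0, Sigma) density with Sigma = diag(sigma) R diag(sigma)
.log_mvn <- function(zeta, sigma, correlation) {
  L <- t(chol(correlation))
  n <- nrow(zeta)
  logdet <- 2 * sum(log(sigma)) + 2 * sum(log(diag(L)))
  q <- 0
  for (i in seq_len(n)) {
    u <- forwardsolve(L, zeta[i, ] / sigma)
    q <- q + sum(u^2)
  }
  -0.5 * (n * (3 * log(2 * pi) + logdet) + q)
}

# log prior of the group-level parameters (centered scale); LKJ term is
# unnormalized ((eta - 1) * log det R); truncated-normal terms include the
# truncation constant
.log_group_prior <- function(group, lkj_eta = 5) {
  sdl <- 0.13
  trunc_const <- log(stats::pnorm(1, 0.5, sdl) - stats::pnorm(0, 0.5, sdl))
  sum(stats::dnorm(c(group$beta, group$beta_j, group$lambda_probit,
                     group$gamma_probit, group$phi_probit), 0, 1, log = TRUE)) +
    stats::dnorm(group$alpha_raw, 0, 0.5, log = TRUE) +
    stats::dgamma(group$sigma[1L], shape = 2, rate = 1, log = TRUE) +
    sum(stats::dnorm(group$sigma[2:3], 0.5, sdl, log = TRUE) - trunc_const) +
    (lkj_eta - 1) * determinant(group$correlation, logarithm = TRUE)$modulus[1L]
}

#' Joint log density of the hierarchical prospect-theory model
#'
#' Bernoulli log likelihood of the decisions plus log priors, evaluated at
#' centered parameter values: standard normal priors on the group decision
#' bias, contrast coefficients, and probit-scale group parameters; N(0, 0.5)
#' on `alpha_raw`; gamma(2, 1) on `sigma[1]`; N(0.5, 0.13) truncated to
#' (0, 1) on `sigma[2:3]`; LKJ(eta = 5) on the correlation matrix
#' (unnormalized); MVN(0, Sigma) on the displacement rows.
#'
#' @param data A `pt_data` object from [build_pt_data()].
#' @param group A [pt_group_parameters()] object.
#' @param zeta n x 3 matrix of individual displacements (participants in
#'   the order of `data$participants`).
#' @param lkj_eta LKJ shape for the correlation prior.
#' @return The scalar log density; an error if any term is non-finite.
#' @export
model_log_density <- function(data, group, zeta, lkj_eta = 5) {
  stopifnot(inherits(data, "pt_data"), inherits(group, "pt_group_parameters"))
  if (is.null(dim(zeta))) zeta <- matrix(zeta, ncol = 3L)
  if (nrow(zeta) != data$n_participants) {
    stop("zeta must have one row per participant (", data$n_participants, ")")
  }
  ind <- transform_individual_parameters(group, zeta)
  alpha <- exp(group$alpha_raw)
  phi <- stats::pnorm(group$phi_probit)
  ll <- 0
  for (t in seq_len(nrow(data$trials))) {
    i <- data$trials$participant_index[t]
    tr <- data$outcomes[[t]]
    v_iv <- subjective_valuation(tr, ind$lambda_i[i], ind$gamma_i[i], alpha)
    p <- acceptance_probability(ind$beta_i[i], data$contrasts[t, ],
                                group$beta_j, phi, v_iv)
    ll <- ll + stats::dbinom(data$trials$accept[t], 1, p, log = TRUE)
  }
  lp <- .log_group_prior(group, lkj_eta) + .log_mvn(zeta, group$sigma,
                                                    group$correlation)
  out <- ll + lp
  if (!is.finite(out)) {
    stop("non-finite log density (likelihood = ", ll, ", prior = ", lp, ")")
  }
  out
}
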