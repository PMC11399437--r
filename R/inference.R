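# Posterior sampling for the prospect-theory model, convergence
# diagnostics (split rank-normalized R-hat), highest density intervals,
# posterior-predictive balanced accuracy, and parameter-recovery reports.

#' Sampler configuration
#'
#' Defaults follow the choice-model setup: 4 chains, 2000 warm-up
#' iterations, 3000 sampling iterations with every second draw recorded
#' (6000 recorded draws in total). The supporting regressions use
#' [assoc_sampler_config()]: 4 chains of 4000 iterations, first half
#' warm-up, every second draw recorded (4000 recorded draws).
#'
#' @param n_chains,n_warmup,n_sampling,thin Positive integers.
#' @param seed Integer seed controlling all sampler randomness.
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(n_chains = 4, n_warmup = 2000, n_sampling = 3000,
                           thin = 2, seed = 1) {
  stopifnot(n_chains >= 1, n_warmup >= 1, n_sampling >= 1, thin >= 1,
            n_sampling %% thin == 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_sampling = as.integer(n_sampling),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "sampler_config")
}

#' @rdname sampler_config
#' @export
assoc_sampler_config <- function(n_chains = 4, n_warmup = 2000,
                                 n_sampling = 2000, thin = 2, seed = 1) {
  sampler_config(n_chains, n_warmup, n_sampling, thin, seed)
}

# shared driver: run NUTS on a C++ model spec and wrap the result
.run_nuts <- function(model_spec, config, par_names, init_radius = 1,
                      max_treedepth = 10, delta = 0.8) {
  d <- model_dim_cpp(model_spec)
  stopifnot(length(par_names) == d)
  set.seed(config$seed)
  inits <- matrix(stats::runif(config$n_chains * d, -init_radius, init_radius),
                  nrow = config$n_chains)
  res <- nuts_sample_cpp(model_spec, inits, config$n_warmup,
                         config$n_sampling, config$thin,
                         max_treedepth, delta)
  n_keep <- config$n_sampling %/% config$thin
  draws <- array(NA_real_, c(n_keep, config$n_chains, d),
                 dimnames = list(NULL, NULL, par_names))
  for (c in seq_len(config$n_chains)) draws[, c, ] <- res$chains[[c]]
  rhat <- apply(draws, 3, compute_rhat)
  structure(list(draws = draws,
                 rhat = rhat,
                 n_draws = n_keep * config$n_chains,
                 config = config,
                 diagnostics = list(divergences = res$divergences,
                                    stepsize = res$stepsize,
                                    accept_stat = res$accept_stat,
                                    max_depth_hits = res$max_depth_hits)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", x$n_draws, "recorded draws (",
      dim(x$draws)[2], "chains x", dim(x$draws)[1], "kept iterations),",
      dim(x$draws)[3], "parameters\n")
  cat("  max split R-hat:", round(max(x$rhat), 4),
      "| divergences:", sum(x$diagnostics$divergences), "\n")
  invisible(x)
}

#' Fit the hierarchical prospect-theory model
#'
#' Samples the posterior of the choice model for one attitude group with
#' the built-in No-U-Turn sampler (non-centered parameterization; the
#' target density equals the centered specification of
#' [model_log_density()] plus the exact transform jacobians).
#'
#' @param data A `pt_data` object from [build_pt_data()].
#' @param config A [sampler_config()].
#' @return A `posterior_samples` object (class also `pt_fit`). Parameters
#'   are on the unconstrained sampling scale; use [pt_group_posterior()]
#'   for interpretable group-level quantities.
#' @export
fit_pt_model <- function(data, config = sampler_config()) {
  stopifnot(inherits(data, "pt_data"), inherits(config, "sampler_config"))
  spec <- list(type = "pt", data = data$cpp)
  fit <- .run_nuts(spec, config, .pt_theta_names(data$n_participants))
  fit$model <- "pt"
  fit$data <- data
  class(fit) <- c("pt_fit", class(fit))
  fit
}

#' Split rank-normalized R-hat
#'
#' Potential-scale-reduction statistic on split chains after rank
#' normalization, taking the maximum of the bulk and the folded
#' (median-absolute-deviation) variants. Values below 1.01 indicate
#' well-mixed chains.
#'
#' @param x Draws matrix (iterations x chains).
#' @return Scalar R-hat.
#' @export
compute_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat needs at least 2 chains")
  if (nrow(x) < 4) stop("R-hat needs at least 4 draws per chain")
  split_chains <- function(m) {
    n <- nrow(m)
    half <- n %/% 2
    cbind(m[seq_len(half), , drop = FALSE],
          m[(n - half + 1):n, , drop = FALSE])
  }
  basic_rhat <- function(m) {
    n <- nrow(m)
    mu <- colMeans(m)
    s2 <- apply(m, 2, stats::var)
    w <- mean(s2)
    b <- n * stats::var(mu)
    if (w < 1e-300) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  }
  rank_normalize <- function(m) {
    r <- rank(m, ties.method = "average")
    matrix(stats::qnorm((r - 3 / 8) / (length(m) + 1 / 4)), nrow = nrow(m))
  }
  xs <- split_chains(x)
  bulk <- basic_rhat(rank_normalize(xs))
  folded <- basic_rhat(rank_normalize(abs(xs - stats::median(xs))))
  max(bulk, folded)
}

#' Highest density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass
#' (minimal-width window over the sorted draws).
#'
#' @param draws Numeric vector of posterior draws (>= 50).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 50) stop("HDI needs at least 50 draws")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(draws[1], draws[n]))
  widths <- draws[(k + 1):n] - draws[1:(n - k)]
  i <- which.min(widths)
  c(draws[i], draws[i + k])
}

#' Flatten posterior draws to a matrix
#'
#' @param fit A `posterior_samples` object.
#' @param pars Optional character vector of parameter names.
#' @return Matrix (total draws x parameters), chains stacked.
#' @export
extract_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "posterior_samples"))
  d <- fit$draws
  m <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
  colnames(m) <- dimnames(d)[[3]]
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

#' Interpretable group-level posterior of a prospect-theory fit
#'
#' Transforms each unconstrained draw to the constrained scale: `beta`,
#' `lambda = Phi(lambda_probit)`, the loss-aversion multiplier
#' `Lambda = lambda / (1 - lambda)` (computed per draw, then summarized),
#' `gamma`, `alpha = exp(alpha_raw)`, `phi = Phi(phi_probit)`,
#' displacement SDs, and displacement correlations.
#'
#' @param fit A `pt_fit`.
#' @return Data frame with one row per recorded draw.
#' @export
pt_group_posterior <- function(fit) {
  stopifnot(inherits(fit, "pt_fit"))
  m <- extract_draws(fit)
  lam <- stats::pnorm(m[, "lambda_probit"])
  r <- lapply(seq_len(nrow(m)), function(s) {
    L <- .pt_chol_from_raw(m[s, c("corr_raw[1]", "corr_raw[2]", "corr_raw[3]")])
    R <- L %*% t(L)
    c(R[2, 1], R[3, 1], R[3, 2])
  })
  r <- do.call(rbind, r)
  data.frame(
    beta = m[, "beta"],
    beta_j1 = m[, "beta_j[1]"], beta_j2 = m[, "beta_j[2]"],
    beta_j3 = m[, "beta_j[3]"], beta_j4 = m[, "beta_j[4]"],
    lambda = lam,
    Lambda = lam / (1 - lam),
    gamma = stats::pnorm(m[, "gamma_probit"]),
    alpha = exp(m[, "alpha_raw"]),
    phi = stats::pnorm(m[, "phi_probit"]),
    sigma_beta = exp(m[, "log_sigma_beta"]),
    sigma_lambda = stats::plogis(m[, "logit_sigma_lambda"]),
    sigma_gamma = stats::plogis(m[, "logit_sigma_gamma"]),
    r_beta_lambda = r[, 1], r_beta_gamma = r[, 2], r_lambda_gamma = r[, 3]
  )
}

#' Posterior-predictive balanced accuracy
#'
#' Computes the per-trial posterior-predictive acceptance probability,
#' classifies at 0.5, and reports the mean of the accept-class and
#' refuse-class accuracies. `method = "loo"` approximates leave-one-out
#' predictive probabilities by importance reweighting of the posterior
#' draws (truncated importance sampling: per-trial weights
#' `1 / p(y_t | theta_s)` truncated at `sqrt(S)` times their mean).
#'
#' @param fit A `pt_fit`.
#' @param data The `pt_data` the model was fitted to (defaults to the data
#'   stored in the fit).
#' @param method `"in_sample"` or `"loo"`.
#' @return List with `balanced_accuracy`, `accuracy_accept`,
#'   `accuracy_refuse`, and the per-trial predictive probabilities `p`.
#' @export
posterior_predictive_accuracy <- function(fit, data = fit$data,
                                          method = c("in_sample", "loo")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "pt_fit"), inherits(data, "pt_data"))
  if (data$n_participants != fit$data$n_participants) {
    stop("dataset does not match the fitted model")
  }
  P <- pt_acceptance_probs_cpp(data$cpp, extract_draws(fit))
  y <- data$trials$accept
  if (method == "in_sample") {
    p_hat <- rowMeans(P)
  } else {
    S <- ncol(P)
    lik <- ifelse(matrix(y, nrow(P), S) == 1, P, 1 - P)
    w <- 1 / pmax(lik, 1e-12)
    cap <- sqrt(S) * rowMeans(w)
    w <- pmin(w, cap)
    p_hat <- rowSums(w * P) / rowSums(w)
  }
  cls <- as.integer(p_hat > 0.5)
  acc1 <- if (any(y == 1)) mean(cls[y == 1] == 1) else NA_real_
  acc0 <- if (any(y == 0)) mean(cls[y == 0] == 0) else NA_real_
  list(balanced_accuracy = mean(c(acc1, acc0), na.rm = TRUE),
       accuracy_accept = acc1, accuracy_refuse = acc0, p = p_hat)
}

#' Parameter-recovery report
#'
#' Compares the group-level posterior of a fit to the ground-truth
#' parameters used to generate a synthetic cohort.
#'
#' @param truth A [pt_group_parameters()] object (or the `truth$groups`
#'   entry of a cohort bundle coerced with `do.call(pt_group_parameters,)`).
#' @param fit A `pt_fit` on data generated under `truth`.
#' @param mass HDI mass (default 0.95).
#' @return Data frame with one row per group-level parameter: posterior
#'   median, HDI bounds, `covered` flag, and standardized bias
#'   (median minus truth, in posterior-SD units).
#' @export
recovery_report <- function(truth, fit, mass = 0.95) {
  stopifnot(inherits(truth, "pt_group_parameters"), inherits(fit, "pt_fit"))
  post <- pt_group_posterior(fit)
  truth_vals <- c(
    beta = truth$beta,
    beta_j1 = truth$beta_j[1], beta_j2 = truth$beta_j[2],
    beta_j3 = truth$beta_j[3], beta_j4 = truth$beta_j[4],
    lambda = stats::pnorm(truth$lambda_probit),
    gamma = stats::pnorm(truth$gamma_probit),
    alpha = exp(truth$alpha_raw),
    phi = stats::pnorm(truth$phi_probit),
    sigma_beta = truth$sigma[1],
    sigma_lambda = truth$sigma[2],
    sigma_gamma = truth$sigma[3]
  )
  rows <- lapply(names(truth_vals), function(par) {
    dr <- post[[par]]
    h <- hdi(dr, mass)
    md <- stats::median(dr)
    sdv <- stats::sd(dr)
    data.frame(parameter = par, truth = unname(truth_vals[par]),
               median = md, hdi_lower = h[1], hdi_upper = h[2],
               covered = truth_vals[par] >= h[1] & truth_vals[par] <= h[2],
               std_bias = if (sdv > 0) (md - truth_vals[par]) / sdv else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
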