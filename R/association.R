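# Supporting Bayesian hierarchical regressions: logistic for binary
# outcomes and cumulative ordered-logit for ordinal outcomes, both with a
# participant random intercept, sum-to-zero contrasts for all (categorical)
# predictors, and weakly informative Student-t(3, 0, 2.5) priors on the
# coefficients (half-t on the random-intercept SD). Predicted per-level
# outcome values are obtained by setting all other predictors to zero and
# pushing intercept + level effect through the inverse link; pairwise
# level comparisons subtract linear-scale predicted values per draw and
# flag evidence when the 95% HDI of the difference excludes zero.

#' Regression specification
#'
#' @param outcome Name of the outcome column.
#' @param family `"bernoulli"` (binary) or `"ordered"` (ordinal, >= 3
#'   levels).
#' @param predictors Character vector of categorical predictor columns
#'   (coded with sum-to-zero contrasts).
#' @param interactions Optional character vector of `"a:b"` pairs.
#' @param random_intercept Grouping column for the random intercept.
#' @param prior_scale Scale of the Student-t(3, 0, scale) coefficient
#'   prior.
#' @return A `regression_spec` object.
#' @export
regression_spec <- function(outcome, family = c("bernoulli", "ordered"),
                            predictors, interactions = NULL,
                            random_intercept = "participant_id",
                            prior_scale = 2.5) {
  family <- match.arg(family)
  stopifnot(length(predictors) >= 1, prior_scale > 0)
  structure(list(outcome = outcome, family = family, predictors = predictors,
                 interactions = interactions,
                 random_intercept = random_intercept,
                 prior_scale = prior_scale),
            class = "regression_spec")
}

# sum-to-zero design matrix; returns list(X, factors = name -> levels,
# columns = name -> column indices)
.build_design <- function(data, spec, intercept) {
  factors <- list(); blocks <- list(); columns <- list()
  for (f in spec$predictors) {
    xf <- factor(data[[f]])
    if (nlevels(xf) < 2) stop("predictor '", f, "' has fewer than 2 levels")
    C <- stats::contr.sum(nlevels(xf))
    B <- C[as.integer(xf), , drop = FALSE]
    colnames(B) <- paste0(f, seq_len(ncol(B)))
    factors[[f]] <- levels(xf)
    blocks[[f]] <- B
  }
  for (ia in spec$interactions %||% character(0)) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% names(blocks))) {
      stop("interaction '", ia, "' must name two declared predictors")
    }
    A <- blocks[[parts[1]]]; B <- blocks[[parts[2]]]
    AB <- do.call(cbind, lapply(seq_len(ncol(A)), function(i) {
      out <- A[, i] * B
      colnames(out) <- paste0(colnames(A)[i], ":", colnames(B))
      out
    }))
    blocks[[ia]] <- AB
  }
  X <- do.call(cbind, blocks)
  if (intercept) X <- cbind(Intercept = 1, X)
  start <- if (intercept) 1L else 0L
  pos <- start
  for (nm in names(blocks)) {
    k <- ncol(blocks[[nm]])
    columns[[nm]] <- (pos + 1L):(pos + k)
    pos <- pos + k
  }
  list(X = X, factors = factors, columns = columns, intercept = intercept)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a hierarchical logistic regression
#'
#' Bernoulli outcome, logit link, participant random intercept
#' (non-centered), sum-to-zero contrasts, Student-t(3, 0, 2.5) coefficient
#' priors and half-t(3, 0, 2.5) on the random-intercept SD.
#'
#' @param data Data frame with the outcome (0/1 or logical), predictor,
#'   and grouping columns.
#' @param spec A [regression_spec()] with `family = "bernoulli"`.
#' @param config A [sampler_config()]; default [assoc_sampler_config()].
#' @return An `assoc_fit` (also `posterior_samples`).
#' @export
fit_hierarchical_logistic <- function(data, spec,
                                      config = assoc_sampler_config()) {
  stopifnot(inherits(spec, "regression_spec"))
  if (spec$family != "bernoulli") stop("spec family must be 'bernoulli'")
  y <- data[[spec$outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary (0/1)")
  des <- .build_design(data, spec, intercept = TRUE)
  grp <- factor(data[[spec$random_intercept]])
  P <- nlevels(grp)
  cpp <- list(y = as.integer(y), X = unname(des$X),
              part = as.integer(grp) - 1L, P = P,
              prior_scale = spec$prior_scale)
  par_names <- c(colnames(des$X), "log_sigma_u",
                 paste0("u[", seq_len(P), "]"))
  # hierarchical-scale geometry benefits from a higher acceptance target
  fit <- .run_nuts(list(type = "logistic", data = cpp), config, par_names,
                   delta = 0.9)
  fit$model <- "logistic"
  fit$spec <- spec
  fit$design <- des
  fit$group_levels <- levels(grp)
  class(fit) <- c("assoc_fit", class(fit))
  fit
}

#' Fit a hierarchical cumulative ordered-logit regression
#'
#' Ordinal outcome with at least 3 levels; ordered cutpoints absorb the
#' intercept, predictors and priors as in
#' [fit_hierarchical_logistic()].
#'
#' @param data Data frame; the outcome must be an ordered factor or
#'   integer-like with >= 3 distinct levels.
#' @inheritParams fit_hierarchical_logistic
#' @return An `assoc_fit`.
#' @export
fit_ordered_logit <- function(data, spec, config = assoc_sampler_config()) {
  stopifnot(inherits(spec, "regression_spec"))
  if (spec$family != "ordered") stop("spec family must be 'ordered'")
  y_raw <- data[[spec$outcome]]
  yf <- if (is.ordered(y_raw)) y_raw else factor(y_raw, ordered = TRUE)
  K <- nlevels(yf)
  if (K < 3) stop("ordered outcome needs at least 3 levels; use the logistic model")
  y <- as.integer(yf)
  des <- .build_design(data, spec, intercept = FALSE)
  grp <- factor(data[[spec$random_intercept]])
  P <- nlevels(grp)
  cpp <- list(y = y, X = unname(des$X), part = as.integer(grp) - 1L,
              P = P, K = K, prior_scale = spec$prior_scale)
  par_names <- c(colnames(des$X), paste0("cut_raw[", seq_len(K - 1), "]"),
                 "log_sigma_u", paste0("u[", seq_len(P), "]"))
  fit <- .run_nuts(list(type = "ordered", data = cpp), config, par_names,
                   delta = 0.9)
  fit$model <- "ordered"
  fit$spec <- spec
  fit$design <- des
  fit$outcome_levels <- levels(yf)
  fit$group_levels <- levels(grp)
  class(fit) <- c("assoc_fit", class(fit))
  fit
}

# per-draw ordered cutpoints from the raw parameterization
.assoc_cutpoints <- function(fit) {
  K <- length(fit$outcome_levels)
  raw <- extract_draws(fit, paste0("cut_raw[", seq_len(K - 1), "]"))
  cuts <- raw
  if (K > 2) {
    for (k in 2:(K - 1)) cuts[, k] <- cuts[, k - 1] + exp(raw[, k])
  }
  cuts
}

# per-draw linear-scale predicted value for each level of a factor
# (all other predictors at zero, random intercept at its mean 0)
.assoc_level_linpred <- function(fit, factor_name) {
  des <- fit$design
  if (!factor_name %in% names(des$factors)) {
    stop("unknown factor '", factor_name, "'; available: ",
         paste(names(des$factors), collapse = ", "))
  }
  levels_ <- des$factors[[factor_name]]
  C <- stats::contr.sum(length(levels_))
  cols <- colnames(des$X)[des$columns[[factor_name]]]
  B <- extract_draws(fit, cols)
  eta <- B %*% t(C)
  if (des$intercept) eta <- eta + extract_draws(fit, "Intercept")[, 1]
  colnames(eta) <- levels_
  eta
}

#' Posterior predicted outcome values per factor level
#'
#' For each level of the factor, computes the posterior of the linear
#' predictor at that level with all other predictors at zero, and pushes
#' it through the inverse link: predicted probability for the logistic
#' family, expected outcome level (probability-weighted mean of the
#' ordinal scale values) for the ordered family.
#'
#' @param fit An `assoc_fit`.
#' @param factor_name One of the fitted predictors.
#' @param mass HDI mass.
#' @return Data frame with one row per level: posterior median and HDI of
#'   the predicted value, plus the linear-scale median.
#' @export
predicted_levels <- function(fit, factor_name, mass = 0.95) {
  stopifnot(inherits(fit, "assoc_fit"))
  eta <- .assoc_level_linpred(fit, factor_name)
  if (fit$model == "logistic") {
    val <- stats::plogis(eta)
  } else {
    cuts <- .assoc_cutpoints(fit)
    K <- length(fit$outcome_levels)
    scale_vals <- suppressWarnings(as.numeric(fit$outcome_levels))
    if (any(is.na(scale_vals))) scale_vals <- seq_len(K)
    val <- matrix(NA_real_, nrow(eta), ncol(eta),
                  dimnames = dimnames(eta))
    for (l in seq_len(ncol(eta))) {
      cum <- stats::plogis(cuts - eta[, l])  # draws x (K-1)
      pk <- cbind(cum[, 1], if (K > 2) cum[, -1, drop = FALSE] -
                    cum[, -(K - 1), drop = FALSE], 1 - cum[, K - 1])
      val[, l] <- pk %*% scale_vals
    }
  }
  rows <- lapply(colnames(eta), function(l) {
    h <- hdi(val[, l], mass)
    data.frame(level = l, median = stats::median(val[, l]),
               hdi_lower = h[1], hdi_upper = h[2],
               linear_median = stats::median(eta[, l]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise posterior difference between two factor levels
#'
#' Posterior of the linear-scale predicted-value difference
#' (`level_a - level_b`); evidence for a difference is flagged when the
#' HDI excludes zero.
#'
#' @inheritParams predicted_levels
#' @param level_a,level_b Factor levels to compare.
#' @return List with `median`, `hdi`, `excludes_zero`, and the per-draw
#'   `difference` vector.
#' @export
pairwise_difference <- function(fit, factor_name, level_a, level_b,
                                mass = 0.95) {
  eta <- .assoc_level_linpred(fit, factor_name)
  if (!all(c(level_a, level_b) %in% colnames(eta))) {
    stop("unknown level(s); available: ",
         paste(colnames(eta), collapse = ", "))
  }
  diff <- eta[, level_a] - eta[, level_b]
  if (identical(level_a, level_b)) {
    return(list(median = 0, hdi = c(0, 0), excludes_zero = FALSE,
                difference = diff * 0))
  }
  h <- hdi(diff, mass)
  list(median = stats::median(diff), hdi = h,
       excludes_zero = h[1] > 0 || h[2] < 0, difference = diff)
}

#' Coefficient odds ratios
#'
#' `exp(coefficient)` per contrast column with HDI; |log(OR)| >= 0.2 is
#' marked as the conventional practical-relevance boundary.
#'
#' @param fit An `assoc_fit` with logit link.
#' @param mass HDI mass.
#' @return Data frame with one row per coefficient.
#' @export
coefficient_odds_ratios <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "assoc_fit"))
  cols <- unlist(lapply(fit$design$columns, function(ix) colnames(fit$design$X)[ix]))
  B <- extract_draws(fit, cols)
  rows <- lapply(cols, function(cn) {
    h <- hdi(exp(B[, cn]), mass)
    md <- stats::median(exp(B[, cn]))
    data.frame(coefficient = cn, odds_ratio = md,
               hdi_lower = h[1], hdi_upper = h[2],
               practically_relevant = abs(log(md)) >= 0.2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
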