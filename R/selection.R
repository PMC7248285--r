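#' Fixed-effects group Bayes factor
#'
#' Treats every subject as sharing one mechanism: the group log Bayes
#' factor is the sum over subjects of the difference in log model evidence,
#' converted to base 10.  With evidence = maximised log-likelihood and
#' models of equal parameter count this is a raw evidence-ratio comparison
#' with no complexity penalty.
#'
#' @param evidence numeric matrix, subjects x models, of log evidences in
#'   nats; column names are model ids (see [evidence_matrix()]).
#' @param model_a,model_b model ids to compare (A vs B).
#' @return An object of class `ffx_result` with `log10_group_bayes_factor`
#'   (positive favours `model_a`), `model_a`, `model_b`, `winning_model`.
#' @export
ffx_bayes_factor <- function(evidence, model_a, model_b) {
  check_evidence(evidence)
  for (m in c(model_a, model_b)) {
    if (!m %in% colnames(evidence)) {
      stop("unknown model id: ", m, call. = FALSE)
    }
  }
  log10_bf <- sum(evidence[, model_a] - evidence[, model_b]) / log(10)
  structure(list(
    log10_group_bayes_factor = log10_bf,
    model_a = model_a, model_b = model_b,
    winning_model = if (log10_bf > 0) model_a else if (log10_bf < 0) model_b
                    else NA_character_
  ), class = "ffx_result")
}

#' @export
print.ffx_result <- function(x, ...) {
  cat("Fixed-effects comparison ", x$model_a, " vs ", x$model_b, ":\n",
      "  log10 group BF = ", format(x$log10_group_bayes_factor, digits = 4),
      "  (winner: ", ifelse(is.na(x$winning_model), "tie", x$winning_model),
      ")\n", sep = "")
  invisible(x)
}

#' Random-effects Bayesian model selection
#'
#' Treats the governing model as a random effect across subjects and
#' estimates a Dirichlet posterior over model frequencies by the standard
#' variational scheme: iterate subject-wise posterior model assignments
#' `u_nk` proportional to `exp(logE_nk + digamma(alpha_k) -
#' digamma(sum(alpha)))` (normalised per subject) and `alpha_k = alpha0 +
#' sum_n u_nk`, until the largest change in alpha falls below `tol`.
#' Exceedance probabilities — the posterior probability that each model is
#' the most frequent in the population — are computed from the converged
#' Dirichlet via [exceedance_probabilities()].
#'
#' @param evidence numeric matrix, subjects x models, of log evidences.
#' @param alpha0 Dirichlet prior count per model (default 1, flat).
#' @param tol convergence tolerance on alpha (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @param exceedance_draws Monte-Carlo draws used when more than two models
#'   are compared (two-model exceedance is closed-form).
#' @param exceedance_seed seed for the Monte-Carlo draw.
#' @return An object of class `bms_result` with `alpha` (posterior Dirichlet
#'   parameters), `expected_frequencies`, `exceedance_probabilities`,
#'   `model_ids`, `n_iterations`, `converged`.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, tol = 1e-6, max_iter = 10000,
                    exceedance_draws = 1e6, exceedance_seed = 1) {
  check_evidence(evidence)
  if (alpha0 <= 0) stop("`alpha0` must be positive", call. = FALSE)
  K <- ncol(evidence)
  alpha <- rep(alpha0, K)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    log_u <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    log_u <- log_u - apply(log_u, 1, max)
    u <- exp(log_u)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  alpha <- setNames(alpha, colnames(evidence))
  structure(list(
    alpha = alpha,
    expected_frequencies = alpha / sum(alpha),
    exceedance_probabilities = exceedance_probabilities(
      alpha, n_draws = exceedance_draws, seed = exceedance_seed),
    model_ids = colnames(evidence),
    n_iterations = iter,
    converged = converged
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$alpha), "models,",
      x$n_iterations, "iterations",
      if (!x$converged) "[NOT CONVERGED]", "\n")
  m <- rbind(alpha = x$alpha,
             `E[freq]` = x$expected_frequencies,
             `p_exc` = x$exceedance_probabilities)
  print(round(m, 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' For each model, the posterior probability that its population frequency
#' exceeds that of every other model.  With two models this is closed-form
#' through the regularised incomplete beta function:
#' `P(r1 > 0.5) = 1 - pbeta(0.5, alpha1, alpha2)`.  With three or more
#' models it is estimated by Monte-Carlo Dirichlet sampling under a fixed
#' seed.
#'
#' @param alpha positive Dirichlet parameters (named by model if available).
#' @param n_draws Monte-Carlo draws for the K >= 3 case (default 1e6).
#' @param seed seed for the Monte-Carlo draw.
#' @return Numeric simplex (sums to 1) of exceedance probabilities.
#' @examples
#' exceedance_probabilities(c(1, 1))  # 0.5, 0.5
#' exceedance_probabilities(c(3, 1))  # 0.875, 0.125
#' @export
exceedance_probabilities <- function(alpha, n_draws = 1e6, seed = 1) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  K <- length(alpha)
  if (K < 2) stop("need at least two models", call. = FALSE)
  if (K == 2) {
    p1 <- 1 - pbeta(0.5, alpha[1], alpha[2])
    out <- c(p1, 1 - p1)
  } else {
    out <- with_seed(seed, {
      g <- matrix(rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                  nrow = n_draws, ncol = K)
      tabulate(max.col(g, ties.method = "first"), K) / n_draws
    })
  }
  setNames(out, names(alpha))
}

check_evidence <- function(evidence) {
  if (!is.matrix(evidence) || nrow(evidence) < 1 || ncol(evidence) < 2) {
    stop("`evidence` must be a subjects x models matrix with >= 2 models",
         call. = FALSE)
  }
  if (any(!is.finite(evidence))) {
    stop("`evidence` must be finite", call. = FALSE)
  }
  invisible(evidence)
}
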