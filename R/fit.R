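#' Maximum-likelihood fit of a choice model to one subject
#'
#' Minimises the negative log-likelihood by bounded quasi-Newton (L-BFGS-B)
#' with analytic gradients, restarted from a deterministic grid of starting
#' values (every combination of slopes in \{0.1, 1, 3\} and criteria in
#' \{-1, 0, 1\}); the best optimum wins, ties broken by grid order.  Slopes
#' are bounded to \[0, `w_max`\], criteria to \[-`b_max`, `b_max`\].
#' Identical inputs and settings give identical output.  Degenerate data
#' (all responses the same) return a fit pinned at a parameter bound with
#' `at_bound = TRUE` rather than an error.
#'
#' @param trials data frame with columns `emotion`, `morph_level`, `gaze`,
#'   `response`; a `subject` column, if present, labels the result.
#' @param model "M1", "M2" or "M3".
#' @param n_levels number of morph levels (default 7).
#' @param w_max,b_max box constraints for slopes and criteria.
#' @return An object of class `model_fit`: `subject_id`, `model`,
#'   `parameters` ([observer_params()]), `log_likelihood` (nats, <= 0),
#'   `n_trials`, `converged`, `n_restarts_used`, `at_bound`.
#' @export
fit_ml <- function(trials, model = c("M1", "M2", "M3"), n_levels = 7,
                   w_max = 20, b_max = 5) {
  model <- match.arg(model)
  check_trials(trials)
  X <- model_design_matrix(model, trials, n_levels)
  y <- as.numeric(trials$response == "anger")
  par_names <- colnames(X)
  is_slope <- grepl("^w", par_names)
  lower <- ifelse(is_slope, 0, -b_max)
  upper <- ifelse(is_slope, w_max, b_max)

  nll <- function(theta) {
    p <- pmin(pmax(pnorm(drop(X %*% theta)), P_FLOOR), 1 - P_FLOOR)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  gr <- function(theta) {
    eta <- drop(X %*% theta)
    p <- pmin(pmax(pnorm(eta), P_FLOOR), 1 - P_FLOOR)
    drop(crossprod(X, (p - y) * dnorm(eta) / (p * (1 - p))))
  }

  grid_axes <- lapply(is_slope, function(s) if (s) c(0.1, 1, 3) else c(-1, 0, 1))
  starts <- as.matrix(expand.grid(grid_axes, KEEP.OUT.ATTRS = FALSE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], nll, gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  if (is.null(best)) {
    stop("all optimisation starts failed", call. = FALSE)
  }
  theta <- setNames(best$par, par_names)
  at_bound <- any(abs(theta - lower) < 1e-6 & !(is_slope & abs(theta) < 1e-6)) ||
    any(abs(theta - upper) < 1e-6)
  structure(list(
    subject_id = if ("subject" %in% names(trials)) trials$subject[1] else NA,
    model = model,
    parameters = do.call(observer_params, c(list(model), as.list(theta))),
    log_likelihood = -best$value,
    n_trials = nrow(trials),
    converged = best$convergence == 0,
    n_restarts_used = nrow(starts),
    at_bound = at_bound
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("ML fit, model ", x$model,
      if (!is.na(x$subject_id)) paste0(", subject ", x$subject_id), "\n",
      "  logL = ", format(x$log_likelihood, digits = 6),
      " over ", x$n_trials, " trials",
      if (!x$converged) "  [NOT CONVERGED]",
      if (x$at_bound) "  [at parameter bound]", "\n  ", sep = "")
  cat(paste(sprintf("%s = %.4g", names(x$parameters$theta),
                    x$parameters$theta), collapse = ", "), "\n")
  invisible(x)
}

#' Fit one or more models to every subject in a trial table
#'
#' Splits trials by `subject` and runs [fit_ml()] per subject and model.
#'
#' @param trials data frame including a `subject` column.
#' @param models character vector of model ids.
#' @param n_levels number of morph levels (default 7).
#' @return A data frame with one row per subject x model: `subject`,
#'   `model`, `logL`, `n_trials`, `converged`, `at_bound`, and one column
#'   per parameter (NA where a parameter does not belong to the model).
#' @export
fit_cohort <- function(trials, models = c("M1", "M2"), n_levels = 7) {
  if (!"subject" %in% names(trials)) {
    stop("`trials` needs a `subject` column", call. = FALSE)
  }
  all_pars <- unique(unlist(lapply(models, model_param_names)))
  rows <- list()
  for (sub in unique(trials$subject)) {
    sub_trials <- trials[trials$subject == sub, , drop = FALSE]
    for (m in models) {
      fit <- fit_ml(sub_trials, m, n_levels = n_levels)
      row <- data.frame(subject = sub, model = m,
                        logL = fit$log_likelihood, n_trials = fit$n_trials,
                        converged = fit$converged, at_bound = fit$at_bound,
                        stringsAsFactors = FALSE)
      for (p in all_pars) {
        row[[p]] <- if (p %in% names(fit$parameters$theta)) {
          fit$parameters$theta[[p]]
        } else {
          NA_real_
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-evidence matrix from a cohort fit table
#'
#' With `penalty = "none"` the evidence is the raw maximised log-likelihood,
#' appropriate when the compared models have the same number of parameters
#' (M1 vs M2, both 3).  When the 4-parameter combined model M3 enters a
#' comparison, `penalty = "bic"` subtracts the Schwarz complexity term
#' `k/2 * log(n_trials)` per subject so model evidences stay comparable.
#'
#' @param fits data frame from [fit_cohort()].
#' @param penalty "none" (raw log-likelihood) or "bic".
#' @return Numeric matrix, subjects x models, of log evidences in nats;
#'   row names are subject ids, column names model ids.
#' @export
evidence_matrix <- function(fits, penalty = c("none", "bic")) {
  penalty <- match.arg(penalty)
  subjects <- unique(fits$subject)
  models <- unique(fits$model)
  out <- matrix(NA_real_, length(subjects), length(models),
                dimnames = list(subjects, models))
  for (i in seq_len(nrow(fits))) {
    ev <- fits$logL[i]
    if (penalty == "bic") {
      k <- length(model_param_names(fits$model[i]))
      ev <- ev - 0.5 * k * log(fits$n_trials[i])
    }
    out[as.character(fits$subject[i]), fits$model[i]] <- ev
  }
  if (any(is.na(out))) {
    stop("missing subject x model combinations in `fits`", call. = FALSE)
  }
  out
}
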