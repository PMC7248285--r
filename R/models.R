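#' Signed emotion evidence for a stimulus
#'
#' Maps a morphed face onto a single signed evidence axis: anger morphs are
#' positive, fear morphs negative, neutral faces zero, with magnitude
#' `morph_level / n_levels` (linear in morph intensity).  A full-strength
#' anger morph is +1, a full-strength fear morph is -1.
#'
#' @param emotion character vector: "anger", "fear" or "neutral".
#' @param morph_level integer vector: 0 for neutral, 1..`n_levels` otherwise.
#' @param n_levels number of morph levels (default 7).
#' @return Numeric vector in \[-1, 1\].
#' @examples
#' signed_evidence("anger", 7, 7)  # +1
#' signed_evidence("fear", 4, 7)   # -4/7
#' @export
signed_evidence <- function(emotion, morph_level, n_levels = 7) {
  n_levels <- stopifnot_count(n_levels, "n_levels", min = 1)
  if (length(emotion) != length(morph_level)) {
    stop("`emotion` and `morph_level` must have equal length", call. = FALSE)
  }
  ok <- emotion %in% c("anger", "fear", "neutral")
  if (!all(ok)) {
    stop("unknown emotion: ", emotion[!ok][1], call. = FALSE)
  }
  neutral <- emotion == "neutral"
  if (any(neutral & morph_level != 0)) {
    stop("invalid stimulus: neutral faces must have morph_level 0",
         call. = FALSE)
  }
  if (any(!neutral & (morph_level < 1 | morph_level > n_levels))) {
    stop("invalid stimulus: emotional faces need morph_level in 1..",
         n_levels, call. = FALSE)
  }
  sign <- ifelse(emotion == "anger", 1, ifelse(emotion == "fear", -1, 0))
  sign * morph_level / n_levels
}

#' Threat congruence of a gaze-emotion combination
#'
#' Threat+ faces are the self-relevant combinations: anger with direct gaze
#' (the anger is aimed at the observer) or fear with averted gaze (the feared
#' danger is nearby).  The alternate combinations are Threat-.  Neutral faces
#' carry no emotion and are returned as `NA`.
#'
#' @param gaze character vector: "direct" or "averted".
#' @param emotion character vector: "anger", "fear" or "neutral".
#' @return Character vector: "threat_plus", "threat_minus" or `NA`.
#' @export
threat_congruence <- function(gaze, emotion) {
  if (!all(gaze %in% c("direct", "averted"))) {
    stop("`gaze` must be \"direct\" or \"averted\"", call. = FALSE)
  }
  if (!all(emotion %in% c("anger", "fear", "neutral"))) {
    stop("`emotion` must be \"anger\", \"fear\" or \"neutral\"",
         call. = FALSE)
  }
  out <- ifelse((gaze == "direct") == (emotion == "anger"),
                "threat_plus", "threat_minus")
  out[emotion == "neutral"] <- NA_character_
  out
}

model_param_names <- function(model) {
  switch(model,
         M1 = c("w_plus", "w_minus", "b"),
         M2 = c("w", "b_direct", "b_averted"),
         M3 = c("w_plus", "w_minus", "b_direct", "b_averted"),
         stop("unknown model id: ", model, call. = FALSE))
}

#' Construct an observer parameter set
#'
#' Three probit observers are supported.  M1 (perceptual sensitivity) has
#' separate evidence slopes for Threat+ and Threat- faces and a single
#' criterion: `w_plus`, `w_minus`, `b`.  M2 (decision bias) has one slope and
#' a gaze-conditioned criterion: `w`, `b_direct`, `b_averted`.  M3 combines
#' both mechanisms: `w_plus`, `w_minus`, `b_direct`, `b_averted`.  Slopes
#' must be non-negative; positive criteria push responses towards "anger".
#'
#' @param model "M1", "M2" or "M3".
#' @param ... named numeric parameters for that model (see above).
#' @return An object of class `observer_params`.
#' @examples
#' observer_params("M1", w_plus = 1.2, w_minus = 0.9, b = 0)
#' @export
observer_params <- function(model = c("M1", "M2", "M3"), ...) {
  model <- match.arg(model)
  wanted <- model_param_names(model)
  given <- list(...)
  if (!setequal(names(given), wanted)) {
    stop("model ", model, " needs exactly parameters: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  theta <- vapply(given[wanted], as.numeric, numeric(1))
  if (any(!is.finite(theta))) {
    stop("parameters must be finite", call. = FALSE)
  }
  slopes <- grep("^w", wanted)
  if (any(theta[slopes] < 0)) {
    stop("slopes must be non-negative", call. = FALSE)
  }
  structure(list(model = model, theta = theta), class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Observer (", x$model, "): ",
      paste(sprintf("%s = %.4g", names(x$theta), x$theta), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Model design matrix: every observer is a probit GLM in its parameter
# vector.  M1: eta = w_plus*(u on Threat+) + w_minus*(u on Threat-) + b
# (neutral faces have u = 0, so the neutral slope never enters).  M2:
# eta = w*u + b_direct or b_averted by gaze.  M3 combines both columns.
model_design_matrix <- function(model, stimuli, n_levels = 7) {
  u <- signed_evidence(stimuli$emotion, stimuli$morph_level, n_levels)
  tc <- threat_congruence(stimuli$gaze, stimuli$emotion)
  u_plus <- ifelse(!is.na(tc) & tc == "threat_plus", u, 0)
  u_minus <- ifelse(!is.na(tc) & tc == "threat_minus", u, 0)
  gd <- as.numeric(stimuli$gaze == "direct")
  switch(model,
         M1 = cbind(w_plus = u_plus, w_minus = u_minus, b = 1),
         M2 = cbind(w = u, b_direct = gd, b_averted = 1 - gd),
         M3 = cbind(w_plus = u_plus, w_minus = u_minus,
                    b_direct = gd, b_averted = 1 - gd),
         stop("unknown model id: ", model, call. = FALSE))
}

#' Probability of an "anger" response
#'
#' The choice rule is a probit on the signed evidence axis:
#' `P(anger) = pnorm(w_eff * u + b_eff)`, where the effective slope and
#' criterion depend on the model.  M1 uses `w_plus` on Threat+ faces,
#' `w_minus` on Threat- faces (their mean on neutral, where it is moot since
#' u = 0) and a fixed criterion `b`.  M2 uses one slope `w` and criterion
#' `b_direct` or `b_averted` by gaze, so bias acts even on neutral faces.
#' M3 applies both rules.  Probabilities are clamped to
#' \[1e-6, 1 - 1e-6\] so likelihoods stay finite.
#'
#' @param params an [observer_params()] object.
#' @param stimuli data frame with columns `emotion`, `morph_level`, `gaze`.
#' @param n_levels number of morph levels (default 7).
#' @return Numeric vector of anger-response probabilities.
#' @export
p_choose_anger <- function(params, stimuli, n_levels = 7) {
  stopifnot(inherits(params, "observer_params"))
  X <- model_design_matrix(params$model, stimuli, n_levels)
  eta <- drop(X %*% params$theta)
  pmin(pmax(pnorm(eta), P_FLOOR), 1 - P_FLOOR)
}

#' Negative log-likelihood of a trial set
#'
#' Sums `-log P(response_t)` over trials under the probit choice model,
#' neutral trials included.  Responses must be "anger" or "fear".
#'
#' @param params an [observer_params()] object.
#' @param trials data frame with columns `emotion`, `morph_level`, `gaze`,
#'   `response`.
#' @param n_levels number of morph levels (default 7).
#' @return A single non-negative number (nats).
#' @export
negative_log_likelihood <- function(params, trials, n_levels = 7) {
  check_trials(trials)
  p <- p_choose_anger(params, trials, n_levels)
  y <- trials$response == "anger"
  -sum(log(ifelse(y, p, 1 - p)))
}

check_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("`trials` must be a non-empty data frame", call. = FALSE)
  }
  need <- c("emotion", "morph_level", "gaze", "response")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("`trials` lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(trials$response %in% c("anger", "fear"))) {
    stop("responses must be \"anger\" or \"fear\"", call. = FALSE)
  }
  invisible(trials)
}
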