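#' Score trial correctness
#'
#' A response is correct when it names the emotion of the morphed stimulus.
#' Neutral faces have no correct answer; they score `NA`.
#'
#' @param trials data frame with columns `emotion` and `response`.
#' @return Logical vector (`NA` for neutral trials).
#' @export
score_correct <- function(trials) {
  out <- trials$response == trials$emotion
  out[trials$emotion == "neutral"] <- NA
  out
}

#' Exclude low-accuracy subjects
#'
#' Computes each subject's accuracy over emotional (non-neutral) trials and
#' retains subjects at or above the threshold — "at least 60%" is inclusive,
#' so exactly 60.0% is retained.
#'
#' @param trials data frame with columns `subject`, `emotion`, `response`.
#' @param threshold minimum proportion correct (default 0.60).
#' @return A list: `retained` (trial subset for retained subjects) and
#'   `report` (data frame: subject, n_emotion_trials, accuracy, excluded).
#' @export
exclusion_filter <- function(trials, threshold = 0.60) {
  if (!"subject" %in% names(trials)) {
    stop("`trials` needs a `subject` column", call. = FALSE)
  }
  correct <- score_correct(trials)
  subjects <- unique(trials$subject)
  acc <- vapply(subjects, function(s) {
    ok <- trials$subject == s & !is.na(correct)
    if (!any(ok)) {
      stop("subject ", s, " has no emotional trials", call. = FALSE)
    }
    mean(correct[ok])
  }, numeric(1))
  n_emo <- vapply(subjects, function(s) {
    sum(trials$subject == s & trials$emotion != "neutral")
  }, numeric(1))
  report <- data.frame(subject = subjects, n_emotion_trials = n_emo,
                       accuracy = acc, excluded = acc < threshold,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(retained = trials[trials$subject %in% subjects[acc >= threshold], ,
                         drop = FALSE],
       report = report)
}

#' Per-cell accuracy table
#'
#' Proportion correct and trial count per subject x emotion x gaze x morph
#' level, over emotional trials only (neutral faces have no correct answer).
#'
#' @param trials data frame with columns `subject`, `emotion`,
#'   `morph_level`, `gaze`, `response`.
#' @return Data frame: `subject`, `emotion`, `gaze`, `morph_level`,
#'   `accuracy`, `n_trials`.
#' @export
accuracy_table <- function(trials) {
  if (!"subject" %in% names(trials)) trials$subject <- "s1"
  correct <- score_correct(trials)
  keep <- !is.na(correct)
  d <- data.frame(subject = trials$subject[keep],
                  emotion = trials$emotion[keep],
                  gaze = trials$gaze[keep],
                  morph_level = trials$morph_level[keep],
                  correct = as.numeric(correct[keep]),
                  stringsAsFactors = FALSE)
  agg <- aggregate(correct ~ subject + emotion + gaze + morph_level, d, mean)
  n <- aggregate(correct ~ subject + emotion + gaze + morph_level, d, length)
  agg$n_trials <- n$correct
  names(agg)[names(agg) == "correct"] <- "accuracy"
  agg <- agg[order(agg$subject, agg$emotion, agg$gaze, agg$morph_level), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Per-subject mean accuracy for each gaze x emotion combination, each morph
# level weighted equally.
cell_means_2x2 <- function(table) {
  need <- expand.grid(emotion = c("anger", "fear"),
                      gaze = c("direct", "averted"),
                      stringsAsFactors = FALSE)
  out <- list()
  for (s in unique(table$subject)) {
    sub <- table[table$subject == s, , drop = FALSE]
    row <- data.frame(subject = s, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(need))) {
      cell <- sub[sub$emotion == need$emotion[i] & sub$gaze == need$gaze[i], ]
      if (nrow(cell) == 0) {
        stop("subject ", s, " is missing cell ", need$emotion[i], " x ",
             need$gaze[i], call. = FALSE)
      }
      row[[paste(need$emotion[i], need$gaze[i], sep = "_")]] <-
        mean(cell$accuracy)
    }
    out[[length(out) + 1]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Threat+ minus Threat- accuracy contrast
#'
#' Per subject: mean accuracy over the threat-congruent cells (anger-direct,
#' fear-averted) minus the incongruent cells (anger-averted, fear-direct),
#' morph levels weighted equally.
#'
#' @param table accuracy table from [accuracy_table()].
#' @return Data frame: `subject`, `threat_plus`, `threat_minus`, `contrast`.
#' @export
threat_contrast <- function(table) {
  cm <- cell_means_2x2(table)
  data.frame(
    subject = cm$subject,
    threat_plus = (cm$anger_direct + cm$fear_averted) / 2,
    threat_minus = (cm$anger_averted + cm$fear_direct) / 2,
    contrast = (cm$anger_direct + cm$fear_averted) / 2 -
      (cm$anger_averted + cm$fear_direct) / 2,
    stringsAsFactors = FALSE)
}

#' Paired t-test with Cohen's d
#'
#' Classic paired t on within-subject differences `x - y`.  Cohen's d uses
#' the within-subject convention: mean difference divided by the standard
#' deviation of the differences.  `tail = "one"` tests the directional
#' hypothesis that `x > y`.
#'
#' @param x,y paired per-subject values (equal length >= 2).
#' @param tail "two" (default) or "one".
#' @return A list of class `gz_test`: `statistic`, `df`, `p_value`, `tail`,
#'   `cohen_d`, `mean_diff`.
#' @export
paired_t <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (length(x) != length(y) || length(x) < 2) {
    stop("`x` and `y` must be paired vectors of length >= 2", call. = FALSE)
  }
  d <- x - y
  if (sd(d) == 0) {
    stop("differences have zero variance: t statistic undefined",
         call. = FALSE)
  }
  tt <- t.test(x, y, paired = TRUE,
               alternative = if (tail == "one") "greater" else "two.sided")
  structure(list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    tail = tail,
    cohen_d = mean(d) / sd(d),
    mean_diff = mean(d)
  ), class = "gz_test")
}

#' @export
print.gz_test <- function(x, ...) {
  lab <- if (!is.null(x$F_statistic)) {
    sprintf("F(1, %d) = %.3f", x$df, x$F_statistic)
  } else {
    sprintf("t(%d) = %.3f", x$df, x$statistic)
  }
  cat(lab, ", p = ", format(x$p_value, digits = 3),
      " (", x$tail, "-tailed), d = ", format(x$cohen_d, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Gaze x emotion interaction test (within-subject 2 x 2)
#'
#' For a within-subject 2 x 2 layout the interaction has one degree of
#' freedom and is exactly a one-sample t-test on each subject's difference
#' of differences, `(anger_direct - anger_averted) - (fear_direct -
#' fear_averted)`; the repeated-measures F is its square with df (1, n-1).
#' A positive value is the Threat+ advantage pattern.  Cell means pool
#' morph levels with equal weight.  If every subject's difference of
#' differences is exactly zero the statistic is 0 (no interaction).
#'
#' @param table accuracy table from [accuracy_table()].
#' @return A list of class `gz_test` with `statistic` (t), `F_statistic`
#'   (= t^2), `df` (n - 1; the F reference distribution is F(1, df)),
#'   `p_value` (two-tailed), `cohen_d`, `mean_diff`.
#' @export
interaction_2x2 <- function(table) {
  cm <- cell_means_2x2(table)
  dd <- (cm$anger_direct - cm$anger_averted) -
    (cm$fear_direct - cm$fear_averted)
  n <- length(dd)
  if (n < 2) stop("need >= 2 subjects", call. = FALSE)
  if (sd(dd) == 0) {
    if (all(dd == 0)) {
      return(structure(list(statistic = 0, F_statistic = 0, df = n - 1,
                            p_value = 1, tail = "two", cohen_d = 0,
                            mean_diff = 0), class = "gz_test"))
    }
    stop("differences have zero variance: t statistic undefined",
         call. = FALSE)
  }
  tt <- t.test(dd)
  structure(list(
    statistic = unname(tt$statistic),
    F_statistic = unname(tt$statistic)^2,
    df = n - 1,
    p_value = tt$p.value,
    tail = "two",
    cohen_d = mean(dd) / sd(dd),
    mean_diff = mean(dd)
  ), class = "gz_test")
}

#' Neutral-face response split by gaze
#'
#' The behavioural fingerprint separating the bias and sensitivity accounts:
#' under a gaze-conditioned decision bias, neutral faces — which carry no
#' emotion evidence — draw more "anger" responses under direct than averted
#' gaze; under a pure sensitivity change they do not.
#'
#' @param trials data frame with columns `emotion`, `gaze`, `response`.
#' @return Data frame with one row per gaze direction: `gaze`, `n_trials`,
#'   `n_anger`, `p_anger`.
#' @export
neutral_gaze_split <- function(trials) {
  neu <- trials[trials$emotion == "neutral", , drop = FALSE]
  if (nrow(neu) == 0) stop("no neutral trials", call. = FALSE)
  out <- lapply(c("direct", "averted"), function(g) {
    sub <- neu[neu$gaze == g, , drop = FALSE]
    data.frame(gaze = g, n_trials = nrow(sub),
               n_anger = sum(sub$response == "anger"),
               p_anger = mean(sub$response == "anger"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
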