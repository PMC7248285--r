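make_trials <- function(emotion, response, subject = "s1", gaze = "direct",
                        morph_level = NULL) {
  n <- max(length(emotion), length(response))
  emotion <- rep_len(emotion, n)
  if (is.null(morph_level)) {
    morph_level <- ifelse(emotion == "neutral", 0L, 1L)
  }
  data.frame(subject = subject, emotion = emotion,
             morph_level = rep_len(morph_level, n),
             gaze = rep_len(gaze, n), response = rep_len(response, n),
             stringsAsFactors = FALSE)
}

test_that("correctness scoring matches the stimulus emotion, NA for neutral", {
  tr <- make_trials(c("anger", "fear", "neutral"), c("anger", "anger", "fear"))
  expect_equal(score_correct(tr), c(TRUE, FALSE, NA))
})

test_that("the 60% exclusion criterion is inclusive at the boundary", {
  # 335/560 = 59.8% -> excluded; 336/560 = exactly 60% -> retained
  low <- make_trials("anger", c(rep("anger", 335), rep("fear", 225)),
                     subject = "low")
  edge <- make_trials("anger", c(rep("anger", 336), rep("fear", 224)),
                      subject = "edge")
  perfect <- make_trials("anger", "anger", subject = "perfect")[rep(1, 20), ]
  res <- exclusion_filter(rbind(low, edge, perfect))
  rep_ <- res$report
  expect_true(rep_$excluded[rep_$subject == "low"])
  expect_false(rep_$excluded[rep_$subject == "edge"])
  expect_false(rep_$excluded[rep_$subject == "perfect"])
  expect_equal(rep_$accuracy[rep_$subject == "low"], 335 / 560)
  expect_setequal(unique(res$retained$subject), c("edge", "perfect"))
  # neutral trials do not count towards the criterion
  only_neutral <- make_trials("neutral", "anger", subject = "n")
  expect_error(exclusion_filter(only_neutral), "no emotional trials")
})

test_that("accuracy table counts match the balanced design", {
  coh <- default_cohort_analysis()$cohort
  one <- coh$trials[coh$trials$subject == "control_01", ]
  tab <- accuracy_table(one)
  # every emotion x gaze x morph combination occurs once per identity,
  # so 20 trials per cell over the 560 emotional trials (28 cells)
  expect_equal(nrow(tab), 2 * 2 * 7)
  expect_true(all(tab$n_trials == 20))
  expect_equal(sum(tab$n_trials), 560)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})

test_that("threat contrast equals its cell-mean arithmetic", {
  cells <- expand.grid(subject = "s1", emotion = c("anger", "fear"),
                       gaze = c("direct", "averted"), morph_level = 1:3,
                       stringsAsFactors = FALSE)
  flat <- cells
  flat$accuracy <- 0.7
  flat$n_trials <- 5
  expect_equal(threat_contrast(flat)$contrast, 0)
  extreme <- cells
  extreme$accuracy <- ifelse((extreme$gaze == "direct") ==
                               (extreme$emotion == "anger"), 1, 0)
  extreme$n_trials <- 5
  expect_equal(threat_contrast(extreme)$contrast, 1)
  set.seed(12)
  rand <- cells
  rand$accuracy <- runif(nrow(rand))
  rand$n_trials <- 5
  got <- threat_contrast(rand)$contrast
  # independent recomputation: average the four cell means directly
  cm <- tapply(rand$accuracy, list(rand$emotion, rand$gaze), mean)
  want <- (cm["anger", "direct"] + cm["fear", "averted"]) / 2 -
    (cm["anger", "averted"] + cm["fear", "direct"]) / 2
  expect_equal(got, unname(want), tolerance = 1e-12)
  # a missing cell is named in the error
  expect_error(threat_contrast(rand[rand$emotion != "fear" |
                                      rand$gaze != "direct", ]),
               "fear x direct")
})

test_that("paired t matches hand arithmetic and the tail relation", {
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)  # diffs 1, 2, 3
  res <- paired_t(x, y)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$cohen_d, 2)
  one <- paired_t(x, y, tail = "one")
  expect_equal(one$p_value, res$p_value / 2, tolerance = 1e-12)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, y[1:2]), "paired")
})

test_that("2x2 interaction is the difference-of-differences t, F = t^2", {
  # per-subject cell means via single-morph accuracy rows
  cohort_cells <- function(mat) {
    rows <- list()
    for (i in seq_len(nrow(mat))) {
      rows[[i]] <- data.frame(
        subject = paste0("s", i),
        emotion = c("anger", "anger", "fear", "fear"),
        gaze = c("direct", "averted", "direct", "averted"),
        morph_level = 1L, accuracy = unlist(mat[i, ]), n_trials = 5,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  set.seed(30)
  mat <- data.frame(ad = runif(8, 0.6, 1), aa = runif(8, 0.5, 0.9),
                    fd = runif(8, 0.4, 0.9), fa = runif(8, 0.5, 0.95))
  tab <- cohort_cells(mat)
  res <- interaction_2x2(tab)
  dd <- (mat$ad - mat$aa) - (mat$fd - mat$fa)
  tt <- t.test(dd)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$F_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # cross-check against the repeated-measures ANOVA interaction F
  long <- tab
  long$subject <- factor(long$subject)
  long$emotion <- factor(long$emotion)
  long$gaze <- factor(long$gaze)
  fit <- stats::aov(accuracy ~ emotion * gaze +
                      Error(subject / (emotion * gaze)), data = long)
  aov_tab <- summary(fit)[["Error: subject:emotion:gaze"]][[1]]
  expect_equal(res$F_statistic, aov_tab["emotion:gaze", "F value"],
               tolerance = 1e-8)
  # additive cells in every subject: no interaction, statistic exactly 0
  add <- mat
  add$fa <- add$fd - add$ad + add$aa  # forces dd = 0 rowwise
  res0 <- interaction_2x2(cohort_cells(add))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$F_statistic, 0)
})

test_that("simulated accuracy hits the saturation and chance limits", {
  grid <- enumerate_stimuli(20, 7)
  sharp <- observer_params("M1", w_plus = 100, w_minus = 100, b = 0)
  set.seed(3)
  tr <- simulate_trials(sharp, grid)
  acc <- accuracy_table(tr)
  # weakest morph is u = 1/7, eta = 100/7 >> 0: essentially perfect
  expect_true(all(acc$accuracy > 0.99))
  guess <- observer_params("M1", w_plus = 0, w_minus = 0, b = 0)
  tr2 <- simulate_trials(guess, grid[rep(seq_len(nrow(grid)), 5), ])
  overall <- mean(score_correct(tr2), na.rm = TRUE)
  expect_lt(abs(overall - 0.5), 3 * sqrt(0.25 / 2800))
})

test_that("neutral gaze split exposes bias but not sensitivity observers", {
  grid <- enumerate_stimuli(20, 7)
  big <- grid[rep(seq_len(nrow(grid)), 25), ]  # 1000 neutral trials
  set.seed(18)
  biased <- observer_params("M2", w = 1, b_direct = 0.5, b_averted = -0.5)
  split_b <- neutral_gaze_split(simulate_trials(biased, big))
  expect_gt(split_b$p_anger[split_b$gaze == "direct"],
            split_b$p_anger[split_b$gaze == "averted"] + 0.2)
  sensitive <- observer_params("M1", w_plus = 1.5, w_minus = 0.8, b = 0)
  split_s <- neutral_gaze_split(simulate_trials(sensitive, big))
  diff_s <- split_s$p_anger[split_s$gaze == "direct"] -
    split_s$p_anger[split_s$gaze == "averted"]
  expect_lt(abs(diff_s), 3 * sqrt(0.5 / 500))
})
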