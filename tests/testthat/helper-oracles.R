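# Independent per-trial likelihood oracle: scalar loop, its own effective
# slope/criterion logic, no shared code with the package's vectorised path.
oracle_nll <- function(params, trials, n_levels = 7, p_floor = 1e-6) {
  th <- params$theta
  total <- 0
  for (i in seq_len(nrow(trials))) {
    em <- trials$emotion[i]
    ml <- trials$morph_level[i]
    gz <- trials$gaze[i]
    u <- if (em == "anger") ml / n_levels
         else if (em == "fear") -ml / n_levels else 0
    congruent <- (gz == "direct" && em == "anger") ||
                 (gz == "averted" && em == "fear")
    if (params$model == "M1") {
      w <- if (em == "neutral") (th[["w_plus"]] + th[["w_minus"]]) / 2
           else if (congruent) th[["w_plus"]] else th[["w_minus"]]
      b <- th[["b"]]
    } else if (params$model == "M2") {
      w <- th[["w"]]
      b <- if (gz == "direct") th[["b_direct"]] else th[["b_averted"]]
    } else {
      w <- if (em == "neutral") (th[["w_plus"]] + th[["w_minus"]]) / 2
           else if (congruent) th[["w_plus"]] else th[["w_minus"]]
      b <- if (gz == "direct") th[["b_direct"]] else th[["b_averted"]]
    }
    p <- min(max(pnorm(w * u + b), p_floor), 1 - p_floor)
    pr <- if (trials$response[i] == "anger") p else 1 - p
    total <- total - log(pr)
  }
  total
}

# Vectorised independent NLL for one M1 parameter triple, used by the grid
# oracle (a scalar loop over ~100k grid points would be impractical).
m1_nll_direct <- function(w_plus, w_minus, b, trials, n_levels = 7) {
  u <- ifelse(trials$emotion == "anger", trials$morph_level / n_levels,
              ifelse(trials$emotion == "fear",
                     -trials$morph_level / n_levels, 0))
  congruent <- (trials$gaze == "direct") == (trials$emotion == "anger")
  w <- ifelse(trials$emotion == "neutral", (w_plus + w_minus) / 2,
              ifelse(congruent, w_plus, w_minus))
  p <- pmin(pmax(pnorm(w * u + b), 1e-6), 1 - 1e-6)
  y <- trials$response == "anger"
  -sum(log(ifelse(y, p, 1 - p)))
}

# Dense grid-search oracle for the M1 maximum likelihood: coarse sweep at
# step 0.1 over the plausible box, then a step-0.01 grid around the coarse
# minimum.  Returns the smallest NLL found.
m1_grid_search_nll <- function(trials, n_levels = 7) {
  sweep_grid <- function(wp, wm, bb) {
    best <- Inf
    arg <- c(NA, NA, NA)
    for (a in wp) for (m in wm) for (b in bb) {
      v <- m1_nll_direct(a, m, b, trials, n_levels)
      if (v < best) {
        best <- v
        arg <- c(a, m, b)
      }
    }
    list(nll = best, par = arg)
  }
  coarse <- sweep_grid(seq(0, 4, by = 0.1), seq(0, 4, by = 0.1),
                       seq(-2, 2, by = 0.1))
  p <- coarse$par
  fine <- sweep_grid(pmax(0, p[1] + seq(-0.15, 0.15, by = 0.01)),
                     pmax(0, p[2] + seq(-0.15, 0.15, by = 0.01)),
                     p[3] + seq(-0.15, 0.15, by = 0.01))
  min(coarse$nll, fine$nll)
}

# Small random trial table (not from the balanced design) for likelihood
# order/oracle checks.
random_trials <- function(n, seed) {
  set.seed(seed)
  emotion <- sample(c("anger", "fear", "neutral"), n, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
  data.frame(
    emotion = emotion,
    morph_level = ifelse(emotion == "neutral", 0L,
                         sample.int(7, n, replace = TRUE)),
    gaze = sample(c("direct", "averted"), n, replace = TRUE),
    response = sample(c("anger", "fear"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
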