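#' Enumerate the full face-stimulus grid
#'
#' Builds the symbolic stimulus set for the emotion categorisation task: per
#' identity, every combination of emotion (anger, fear) x morph level
#' (1..`n_levels`, weakest to strongest) x gaze (direct, averted), plus two
#' neutral faces (morph level 0, one per gaze direction).  With 7 morph
#' levels this gives 30 stimuli per identity and 600 for 20 identities.
#'
#' Identity genders alternate female/male so the set splits half/half; for
#' an odd identity count the extra identity is female.
#'
#' @param n_identities number of face identities (default 20).
#' @param n_levels number of morph levels per emotion (default 7).
#' @return A data frame with one row per stimulus and columns `identity_id`,
#'   `gender` ("female"/"male"), `emotion` ("anger"/"fear"/"neutral"),
#'   `morph_level` (0 for neutral, 1..`n_levels` otherwise) and `gaze`
#'   ("direct"/"averted").
#' @examples
#' nrow(enumerate_stimuli(1, 7))   # 30
#' nrow(enumerate_stimuli(20, 7))  # 600
#' @export
enumerate_stimuli <- function(n_identities = 20, n_levels = 7) {
  n_identities <- stopifnot_count(n_identities, "n_identities", min = 0)
  n_levels <- stopifnot_count(n_levels, "n_levels", min = 1)
  if (n_identities == 0) {
    return(data.frame(identity_id = integer(), gender = character(),
                      emotion = character(), morph_level = integer(),
                      gaze = character(), stringsAsFactors = FALSE))
  }
  gender <- ifelse(seq_len(n_identities) %% 2 == 1, "female", "male")
  emotional <- expand.grid(morph_level = seq_len(n_levels),
                           emotion = c("anger", "fear"),
                           gaze = c("direct", "averted"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  neutral <- data.frame(morph_level = 0L,
                        emotion = "neutral",
                        gaze = c("direct", "averted"),
                        stringsAsFactors = FALSE)
  per_identity <- rbind(emotional, neutral)
  out <- per_identity[rep(seq_len(nrow(per_identity)), times = n_identities), ]
  out$identity_id <- rep(seq_len(n_identities), each = nrow(per_identity))
  out$gender <- gender[out$identity_id]
  out <- out[, c("identity_id", "gender", "emotion", "morph_level", "gaze")]
  out$morph_level <- as.integer(out$morph_level)
  rownames(out) <- NULL
  out
}

#' Build a balanced, seeded trial schedule
#'
#' Partitions a stimulus grid into `n_blocks` equally sized blocks so that
#' every stimulus appears exactly once and every block carries exactly the
#' same number of trials per level of emotion, gaze, gender and morph level.
#' Balance is enforced exactly by stratified assignment: stimuli are grouped
#' by the full gender x emotion x morph x gaze cell, each cell is dealt
#' evenly across blocks, and trial order within each block is then shuffled
#' under `seed`.
#'
#' @param stimuli data frame from [enumerate_stimuli()] (or the same columns).
#' @param n_blocks number of blocks (default 5).
#' @param seed integer seed controlling the shuffle; identical inputs and
#'   seed give an identical schedule.
#' @return A data frame of class `trial_schedule`: the stimulus columns plus
#'   `block` (1..`n_blocks`) and `trial` (position within block), ordered by
#'   block then trial.  The seed is stored in attribute `"seed"`.
#' @export
build_schedule <- function(stimuli, n_blocks = 5, seed = 1) {
  n_blocks <- stopifnot_count(n_blocks, "n_blocks", min = 1)
  n <- nrow(stimuli)
  if (n == 0 || n %% n_blocks != 0) {
    stop("balance infeasible: ", n, " stimuli cannot fill ", n_blocks,
         " equal blocks", call. = FALSE)
  }
  strata <- interaction(stimuli$gender, stimuli$emotion, stimuli$morph_level,
                        stimuli$gaze, drop = TRUE)
  counts <- table(strata)
  if (any(counts %% n_blocks != 0)) {
    bad <- names(counts)[counts %% n_blocks != 0][1]
    stop("balance infeasible: stratum ", bad, " has ", counts[[bad]],
         " stimuli, not divisible by ", n_blocks, " blocks", call. = FALSE)
  }
  out <- with_seed(seed, {
    block <- integer(n)
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      block[idx] <- rep(seq_len(n_blocks), times = length(idx) / n_blocks)
    }
    ord <- order(block, sample.int(n))
    sched <- stimuli[ord, , drop = FALSE]
    sched$block <- block[ord]
    sched$trial <- as.integer(unlist(lapply(tabulate(sched$block, n_blocks),
                                            seq_len), use.names = FALSE))
    sched
  })
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Anger/fear response-key mapping for a subject
#'
#' The hand assignment is constant within a subject and counterbalanced
#' across subjects by parity: even subject indices map anger to the left
#' hand, odd indices to the right.  The mapping is schedule metadata only
#' and never enters the choice models.
#'
#' @param subject_index non-negative integer.
#' @return Named character vector `c(anger = ..., fear = ...)`.
#' @examples
#' response_mapping(0)  # anger: left
#' response_mapping(1)  # anger: right
#' @export
response_mapping <- function(subject_index) {
  stopifnot_count(subject_index, "subject_index", min = 0)
  if (subject_index %% 2 == 0) {
    c(anger = "left", fear = "right")
  } else {
    c(anger = "right", fear = "left")
  }
}
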