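#' Read and write trial tables
#'
#' Trial tables travel as UTF-8 CSV with a header row and columns `subject`,
#' `group`, `identity_id`, `gender`, `emotion`, `morph_level`, `gaze`,
#' `response`, `correct`; `correct` is empty for neutral trials (no ground
#' truth).  Extra columns (e.g. `block`, `trial`) round-trip unchanged.
#'
#' @param trials data frame of trial records.
#' @param file path to a CSV file.
#' @return `read_trials()` returns the trial data frame; `write_trials()`
#'   returns `file` invisibly.
#' @export
write_trials <- function(trials, file) {
  write.csv(trials, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE, na.strings = "")
  need <- c("subject", "emotion", "morph_level", "gaze", "response")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("trial file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("correct" %in% names(out)) out$correct <- as.logical(out$correct)
  out
}

#' Read and write trial schedules
#'
#' Schedules are CSV with columns `block`, `trial`, `identity_id`,
#' `gender`, `emotion`, `morph_level`, `gaze`.
#'
#' @param schedule a [build_schedule()] result.
#' @param file path to a CSV file.
#' @return `read_schedule()` returns the schedule data frame;
#'   `write_schedule()` returns `file` invisibly.
#' @export
write_schedule <- function(schedule, file) {
  write.csv(as.data.frame(schedule), file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE, na.strings = "")
  need <- c("block", "identity_id", "emotion", "morph_level", "gaze")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("schedule file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out
}
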