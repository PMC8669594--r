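# Movement onset/end detection from the button channel, pseudo-onsets for
# no-movement trials, the four trial-discard rules, and behavioural phase
# segmentation from the force channel.

#' Detect rising and falling edges of an auxiliary channel
#'
#' Thresholds the signal at half its dynamic range (by default) and returns
#' the times at which it crosses upward and downward. Pulses shorter than
#' the debounce interval are ignored.
#'
#' @param x 1-D numeric signal (finite)
#' @param rate sampling rate in Hz
#' @param threshold crossing level; default `min(x) + diff(range(x))/2`
#' @param debounce_s minimum pulse/gap duration in seconds (default 10 ms)
#' @return list with numeric vectors `rising` and `falling` (seconds from
#'   signal start; the time of the first sample at or above / below the
#'   threshold)
#' @export
detect_edges <- function(x, rate, threshold = NULL, debounce_s = 0.01) {
  stopifnot(is.numeric(x), all(is.finite(x)), rate > 0)
  if (is.null(threshold)) {
    rg <- range(x)
    if (diff(rg) == 0) return(list(rising = numeric(0), falling = numeric(0)))
    threshold <- rg[1] + diff(rg) / 2
  }
  hi <- x >= threshold
  if (!any(hi) || all(hi)) return(list(rising = numeric(0), falling = numeric(0)))
  d <- diff(c(FALSE, hi, FALSE))
  starts <- which(d == 1)          # first index at/above threshold
  ends <- which(d == -1)           # first index back below threshold
  keep <- (ends - starts) >= max(1L, round(debounce_s * rate))
  starts <- starts[keep]; ends <- ends[keep]
  ends <- pmin(ends, length(x) + 1L)
  list(rising = (starts - 1L) / rate,
       falling = (ends - 1L) / rate)
}

#' Build the per-trial event table of a recording
#'
#' For every trial of the recording's cue protocol, pairs the first button
#' rising edge after the task cue with the first subsequent falling edge
#' (movement onset and end), and the force rising/falling edges within the
#' movement (grasp start and end). Reaction time is `onset_t - go_t`.
#' No-movement trials legitimately have no button activity and keep `NA`
#' onsets until [assign_pseudo_onsets()] fills them in.
#'
#' @param recording a `grasp_recording` with a `protocol` data frame
#'   (columns `trial`, `task`, `cue_t`, `go_t`)
#' @return data frame (one row per trial) with columns `trial`, `task`,
#'   `cue_t`, `go_t`, `onset_t`, `end_t`, `grasp_start_t`, `grasp_end_t`,
#'   `reaction_time`, `pseudo_onset`, `flag`
#' @export
build_event_table <- function(recording) {
  stopifnot(inherits(recording, "grasp_recording"),
            !is.null(recording$protocol))
  p <- recording$protocol
  be <- detect_edges(recording$button, recording$rate, threshold = 0.5)
  fe <- detect_edges(recording$force, recording$rate, threshold = 0.5)
  n <- nrow(p)
  win_end <- c(p$cue_t[-1], recording$duration)
  tab <- data.frame(trial = p$trial, task = p$task,
                    cue_t = p$cue_t, go_t = p$go_t,
                    onset_t = NA_real_, end_t = NA_real_,
                    grasp_start_t = NA_real_, grasp_end_t = NA_real_,
                    reaction_time = NA_real_, pseudo_onset = FALSE,
                    flag = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- be$rising[be$rising >= p$cue_t[i] & be$rising < win_end[i]]
    if (length(r) > 0) {
      on <- r[1]
      f <- be$falling[be$falling > on & be$falling < win_end[i]]
      tab$onset_t[i] <- on
      tab$end_t[i] <- if (length(f) > 0) f[1] else NA_real_
      tab$reaction_time[i] <- on - p$go_t[i]
      fr <- fe$rising[fe$rising >= p$cue_t[i] & fe$rising < win_end[i]]
      ff <- fe$falling[fe$falling >= p$cue_t[i] & fe$falling < win_end[i]]
      if (length(fr) > 0) tab$grasp_start_t[i] <- fr[1]
      if (length(ff) > 0) tab$grasp_end_t[i] <- ff[1]
    }
  }
  tab
}

#' Apply the four trial-discard rules
#'
#' Flags each trial with exactly one code, checked in order:
#' \describe{
#'   \item{R1}{button released before the "go" cue (`onset_t < go_t`);}
#'   \item{R2}{no return to the button within 5 s of "go" (movement trial
#'     with missing onset/end, or `end_t > go_t + 5`);}
#'   \item{R3}{reaction time above 1.5 s;}
#'   \item{R4}{wrong movement executed — decidable only from simulation
#'     ground truth (`truth` argument); a no-op on real data;}
#'   \item{OK}{none of the above.}
#' }
#' Re-running on an already flagged table reproduces the same flags
#' (idempotent).
#'
#' @param table event table from [build_event_table()]
#' @param truth optional planted-event data frame with columns `trial` and
#'   `task`/`task_executed` (from a `grasp_experiment`'s `truth$events`,
#'   one session)
#' @return the table with the `flag` column filled
#' @export
apply_discard_rules <- function(table, truth = NULL) {
  flag <- rep("OK", nrow(table))
  mov <- table$task != "no-movement"
  r1 <- mov & !is.na(table$onset_t) & table$onset_t < table$go_t
  r2 <- mov & (is.na(table$onset_t) | is.na(table$end_t) |
                 table$end_t > table$go_t + 5)
  r3 <- mov & !is.na(table$reaction_time) & table$reaction_time > 1.5
  r4 <- rep(FALSE, nrow(table))
  if (!is.null(truth)) {
    m <- match(table$trial, truth$trial)
    r4 <- mov & !is.na(m) & truth$task_executed[m] != truth$task[m]
  }
  flag[r4] <- "R4"; flag[r3 & flag == "OK"] <- "R3"
  flag[r2 & flag %in% c("OK", "R3")] <- "R2"
  flag[r1] <- "R1"
  table$flag <- flag
  table
}

#' Assign pseudo-onsets to no-movement trials
#'
#' The subject-level mean reaction time of valid (`flag == "OK"`) movement
#' trials is added to each no-movement trial's "go" cue time.
#'
#' @param table flagged event table (possibly several sessions row-bound;
#'   the mean is taken over all valid movement trials present)
#' @return table with `onset_t` and `pseudo_onset` filled for no-movement
#'   trials
#' @export
assign_pseudo_onsets <- function(table) {
  ok_mov <- table$flag == "OK" & table$task != "no-movement" &
    !is.na(table$reaction_time)
  if (!any(ok_mov))
    stop("no valid movement trials: cannot compute mean reaction time")
  mrt <- mean(table$reaction_time[ok_mov])
  nm <- table$task == "no-movement"
  table$onset_t[nm] <- table$go_t[nm] + mrt
  table$pseudo_onset[nm] <- TRUE
  table
}

#' Segment the four behavioural phases of a trial
#'
#' For valid movement trials: reacting `[go, onset]`, reaching
#' `[onset, grasp_start]`, grasping `[grasp_start, grasp_end]`, returning
#' `[grasp_end, end]`. Trials whose force edges are missing or fall outside
#' `[onset, end]` are flagged `"FORCE"` and get `NA` phases.
#'
#' @param table flagged event table
#' @return table with columns `react_start/end`, `reach_start/end`,
#'   `grasp_start/end`, `return_start/end` appended
#' @export
segment_phases <- function(table) {
  for (col in c("react_start", "react_end", "reach_start", "reach_end",
                "grasp_start", "grasp_end", "return_start", "return_end"))
    table[[col]] <- NA_real_
  mov <- table$task != "no-movement" & table$flag == "OK"
  for (i in which(mov)) {
    gs <- table$grasp_start_t[i]; ge <- table$grasp_end_t[i]
    on <- table$onset_t[i]; en <- table$end_t[i]
    if (is.na(gs) || is.na(ge) || gs < on || ge > en || gs > ge) {
      table$flag[i] <- "FORCE"
      next
    }
    table$react_start[i] <- table$go_t[i]; table$react_end[i] <- on
    table$reach_start[i] <- on;            table$reach_end[i] <- gs
    table$grasp_start[i] <- gs;            table$grasp_end[i] <- ge
    table$return_start[i] <- ge;           table$return_end[i] <- en
  }
  table
}

#' Write / read an event table as TSV
#'
#' @param table event table data frame
#' @param path file path
#' @return `read_event_table` returns the data frame
#' @export
write_event_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
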