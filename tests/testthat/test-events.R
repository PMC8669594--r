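# Edge detection, pseudo-onsets, discard rules, phase segmentation.

test_that("edges are detected at threshold crossings", {
  rate <- 1000
  x <- numeric(10000)
  x[5001:7000] <- 1                      # step to 1 at t = 5.0 s
  e <- detect_edges(x, rate)
  expect_equal(e$rising, 5.0)
  expect_equal(e$falling, 7.0)

  expect_equal(detect_edges(numeric(1000), rate),
               list(rising = numeric(0), falling = numeric(0)))

  pulse <- numeric(10000)
  pulse[5801:8300] <- 1                  # square pulse 5.8 - 8.3 s
  e <- detect_edges(pulse, rate)
  expect_equal(e$rising, 5.8)
  expect_equal(e$falling, 8.3)

  # sub-debounce glitches are ignored
  glitch <- numeric(2000)
  glitch[1001:1004] <- 1
  expect_length(detect_edges(glitch, rate)$rising, 0)
})

make_table <- function(...) {
  dfl <- lapply(list(...), function(r) {
    d <- list(task = NA_character_, cue_t = 3, go_t = 5,
              onset_t = NA_real_, end_t = NA_real_,
              grasp_start_t = NA_real_, grasp_end_t = NA_real_,
              reaction_time = NA_real_, pseudo_onset = FALSE,
              flag = NA_character_)
    d[names(r)] <- r
    as.data.frame(d, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfl)
  df$trial <- seq_len(nrow(df))
  df
}

test_that("pseudo-onsets use the mean reaction time of valid movement trials", {
  tab <- make_table(
    list(task = "palmar", onset_t = 5.4, end_t = 8, reaction_time = 0.4),
    list(task = "pinch", onset_t = 5.6, end_t = 8, reaction_time = 0.6),
    list(task = "no-movement"))
  tab <- apply_discard_rules(tab)
  out <- assign_pseudo_onsets(tab)
  expect_equal(out$onset_t[3], 5.5)
  expect_true(out$pseudo_onset[3])

  one <- make_table(
    list(task = "twist", onset_t = 5.3, end_t = 8, reaction_time = 0.3),
    list(task = "no-movement"))
  one <- apply_discard_rules(one)
  expect_equal(assign_pseudo_onsets(one)$onset_t[2], 5.3)

  none <- apply_discard_rules(make_table(list(task = "no-movement")))
  expect_error(assign_pseudo_onsets(none), "valid movement")
})

test_that("discard rules flag R1-R4 exclusively and idempotently", {
  tab <- make_table(
    list(task = "palmar", onset_t = 4.8, end_t = 8, reaction_time = -0.2),  # R1
    list(task = "pinch", onset_t = 5.4, end_t = 10.5, reaction_time = 0.4), # R2
    list(task = "push", onset_t = 6.6, end_t = 9.5, reaction_time = 1.6),   # R3
    list(task = "twist", onset_t = 5.4, end_t = 8.4, reaction_time = 0.4),  # R4 via truth
    list(task = "plug", onset_t = 5.5, end_t = 8.5, reaction_time = 0.5),   # OK
    list(task = "no-movement"))
  truth <- data.frame(trial = 1:6,
                      task = c("palmar", "pinch", "push", "twist", "plug",
                               "no-movement"),
                      task_executed = c("palmar", "pinch", "push", "plug",
                                        "plug", "no-movement"))
  out <- apply_discard_rules(tab, truth)
  expect_equal(out$flag, c("R1", "R2", "R3", "R4", "OK", "OK"))
  # exactly one flag each, and re-application changes nothing
  expect_identical(apply_discard_rules(out, truth), out)
  # without truth, R4 is a no-op
  expect_equal(apply_discard_rules(tab)$flag[4], "OK")
})

test_that("planted violations in a simulated session are all flagged", {
  cfg <- sim_config(n_sessions = 1, trials_per_task_per_session = 4,
                    n_sources = 24,
                    contamination = c(R1 = 0.1, R2 = 0.1, R3 = 0.1, R4 = 0.1),
                    seed = 21)
  ex <- simulate_experiment(cfg)
  tab <- build_event_table(ex$sessions[[1]])
  out <- apply_discard_rules(tab, truth = ex$truth$events)
  planted <- ex$truth$events$planted_rule
  expect_equal(sum(out$flag != "OK"), sum(planted != "OK"))
  expect_equal(out$flag[planted != "OK"], planted[planted != "OK"])
})

test_that("behavioural phases are ordered and recovered near the planted boundaries", {
  tab <- make_table(
    list(task = "palmar", onset_t = 5.5, end_t = 8.5,
         grasp_start_t = 6.5, grasp_end_t = 7.5, reaction_time = 0.5))
  out <- segment_phases(apply_discard_rules(tab))
  expect_equal(unlist(out[1, c("react_start", "react_end", "reach_start",
                               "reach_end", "grasp_start", "grasp_end",
                               "return_start", "return_end")],
                      use.names = FALSE),
               c(5, 5.5, 5.5, 6.5, 6.5, 7.5, 7.5, 8.5))

  noforce <- make_table(
    list(task = "palmar", onset_t = 5.5, end_t = 8.5, reaction_time = 0.5))
  out2 <- segment_phases(apply_discard_rules(noforce))
  expect_equal(out2$flag[1], "FORCE")
  expect_true(is.na(out2$grasp_start[1]))

  # simulated trials: detected boundaries match planted truth within 1 sample
  ex <- small_experiment()
  tab <- build_event_table(ex$sessions[[1]])
  tab <- apply_discard_rules(tab, truth = ex$truth$events)
  out <- segment_phases(tab)
  tr <- ex$truth$events[ex$truth$events$session == 1, ]
  mov <- out$flag == "OK" & out$task != "no-movement"
  tol <- 1 / ex$sessions[[1]]$rate + 1e-9
  expect_true(all(abs(out$reach_end[mov] - tr$grasp_start_t[mov]) <= tol))
  expect_true(all(abs(out$grasp_end[mov] - tr$grasp_end_t[mov]) <= tol))
  expect_true(all(abs(out$return_end[mov] - tr$end_t[mov]) <= tol))
})

test_that("event tables round-trip through TSV", {
  tab <- apply_discard_rules(make_table(
    list(task = "palmar", onset_t = 5.5, end_t = 8.5, reaction_time = 0.5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_table(tab, path)
  back <- read_event_table(path)
  expect_equal(back$onset_t, tab$onset_t)
  expect_equal(back$flag, tab$flag)
})
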