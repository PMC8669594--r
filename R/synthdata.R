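# Synthetic reach-and-grasp EEG experiments with known ground truth.
#
# The generator emulates the recording protocol of a cue-based six-condition
# paradigm: per trial, a beep at 0 s, a task cue at 3 s, a "go" cue at 5 s,
# then a reach-grasp-return movement executed within 5 s. Sessions contain a
# balanced, randomised task order; a 10-s rest recording precedes the
# experiment. Condition-specific low-frequency source waveforms (MRCP) are
# planted in motor and visual regions with left-hemisphere lateralisation,
# projected through a leadfield, and buried in spatially mixed 1/f-like
# sensor noise scaled in microvolts.

EPOCH_WINDOW <- c(-3, 3.5)   # padded epoch around movement onset, seconds
TROI <- c(-2, 3.5)           # temporal region of interest, seconds

#' Simulation configuration
#'
#' Collects and validates the parameters of a synthetic experiment. Defaults
#' reproduce the study design: 40 EEG channels at 1000 Hz, 8 sessions with
#' 10 trials of each of 6 tasks (480 trials in total).
#'
#' @param n_channels number of EEG channels
#' @param n_sources number of cortical sources (>= 24; every ROI of
#'   [grasp_rois()] receives at least one source)
#' @param sample_rate sampling rate in Hz
#' @param n_sessions number of recording sessions
#' @param trials_per_task_per_session trials per task within one session
#' @param tasks task labels; last-listed `"no-movement"` is the control
#' @param reaction_time_mean,reaction_time_sd seconds; per-trial reaction
#'   times are drawn from this normal, truncated to `[0.15, 1.4]` s so that
#'   clean trials respect the 1.5-s validity rule
#' @param snr amplitude ratio of the noiseless projected source signal
#'   (epoch-wide sensor RMS) to the sensor-noise standard deviation;
#'   `Inf` disables noise
#' @param amp_var log-normal standard deviation of the per-trial MRCP
#'   amplitude scale (inter-trial variability; 0 = identical trials)
#' @param trial_len_s length of one trial slot in seconds
#' @param contamination named fractions (`R1`, `R2`, `R3`, `R4`) of movement
#'   trials planted to violate each discard rule
#' @param seed master RNG seed; a fixed seed reproduces the experiment
#'   bit-identically
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_channels = 40, n_sources = 48, sample_rate = 1000,
                       n_sessions = 8, trials_per_task_per_session = 10,
                       tasks = grasp_tasks(),
                       reaction_time_mean = 0.5, reaction_time_sd = 0.1,
                       snr = 3, amp_var = 0.2, trial_len_s = 12,
                       contamination = c(R1 = 0, R2 = 0, R3 = 0, R4 = 0),
                       seed = 1) {
  stopifnot(n_channels >= 2, n_sources >= 24, sample_rate > 0,
            n_sessions >= 1, trials_per_task_per_session >= 1,
            length(tasks) >= 2, "no-movement" %in% tasks,
            reaction_time_mean > 0, reaction_time_sd >= 0,
            snr > 0, amp_var >= 0, trial_len_s >= 10)
  cont <- c(R1 = 0, R2 = 0, R3 = 0, R4 = 0)
  cont[names(contamination)] <- contamination
  stopifnot(all(cont >= 0), sum(cont) <= 1)
  structure(list(
    n_channels = as.integer(n_channels), n_sources = as.integer(n_sources),
    sample_rate = sample_rate, n_sessions = as.integer(n_sessions),
    trials_per_task_per_session = as.integer(trials_per_task_per_session),
    tasks = tasks, n_tasks = length(tasks),
    reaction_time_mean = reaction_time_mean,
    reaction_time_sd = reaction_time_sd,
    snr = snr, amp_var = amp_var, trial_len_s = trial_len_s,
    contamination = cont, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Random unit-column leadfield with ROI atlas
#'
#' Forward gain matrix mapping source amplitudes to sensor potentials.
#' Columns are independent Gaussian vectors normalised to unit norm; each
#' source is tagged with exactly one of the 24 atlas ROIs (round-robin, so
#' every ROI is covered whenever `n_sources >= 24`).
#'
#' @param n_channels,n_sources dimensions of the gain matrix
#' @param seed RNG seed (deterministic per seed)
#' @param identity if `TRUE` (requires `n_channels == n_sources`) return the
#'   identity gain, useful for analytic checks
#' @return object of class `grasp_leadfield` with elements `gain`
#'   (channels x sources) and `roi` (source ROI labels)
#' @export
generate_leadfield <- function(n_channels, n_sources, seed = 1,
                               identity = FALSE) {
  if (n_sources < 24)
    stop("n_sources must be >= 24: every ROI needs at least one source")
  stopifnot(n_channels >= 2)
  rois <- grasp_rois()[rep(seq_len(24), length.out = n_sources)]
  if (identity) {
    stopifnot(n_channels == n_sources)
    gain <- diag(n_channels)
  } else {
    gain <- run_seeded(seed, function()
      matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources))
    gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
  }
  structure(list(gain = gain, roi = rois), class = "grasp_leadfield")
}

# 24 x n_sources averaging matrix (rows sum sources within each ROI / count)
roi_average_matrix <- function(roi_labels) {
  rois <- grasp_rois()
  A <- matrix(0, length(rois), length(roi_labels),
              dimnames = list(rois, NULL))
  for (r in rois) {
    idx <- which(roi_labels == r)
    if (length(idx) == 0) stop("ROI without sources: ", r)
    A[r, idx] <- 1 / length(idx)
  }
  A
}

#' Ground-truth source activity for the synthetic paradigm
#'
#' Builds per-condition 24 x T source waveform templates on the padded epoch
#' grid `[-3, 3.5)` s (time zero = movement onset). Motor/premotor templates
#' are smooth negative deflections that stay near baseline until about
#' 0.7 s, then deflect sharply and peak near 1.5 s (inside the grasping
#' phase), with condition-specific peak amplitude and latency and a
#' left-hemisphere dominance (right = 0.4 x left). Visual ROIs carry a
#' non-lateralised reaching-phase response with an opposite-polarity
#' returning-phase rebound. The no-movement condition has identically zero
#' motor/sensorimotor templates and only a small cue response in visual
#' areas.
#'
#' @param config a [sim_config()]
#' @return object of class `grasp_truth`: `roi_templates` (24 x T x
#'   conditions array), `template_time`, `coupled_roi_pairs` (data frame of
#'   symmetric ROI pairs with planted phase coupling), oscillation
#'   parameters, and the epoch window
#' @export
default_ground_truth <- function(config) {
  rate <- config$sample_rate
  t <- time_axis_ho(EPOCH_WINDOW[1], EPOCH_WINDOW[2], rate)
  tasks <- config$tasks
  rois <- grasp_rois()
  tpl <- array(0, dim = c(24, length(t), length(tasks)),
               dimnames = list(rois, NULL, tasks))

  # condition-specific motor peak amplitude (arbitrary source units chosen
  # so the projected sensor MRCP peaks around 10 uV) and latency (s); the
  # slow readiness negativity is common to all movement conditions, and
  # visual responses distinguish movement from no-movement only, so the
  # grasp types are told apart by peak amplitude and latency alone
  peak_amp <- c(palmar = 10, pinch = 7, push = 9, twist = 6, plug = 8,
                "no-movement" = 0)
  peak_lat <- c(palmar = 1.3, pinch = 1.5, push = 1.7, twist = 1.4,
                plug = 1.6, "no-movement" = 1.5)
  vis_amp <- c(palmar = 4, pinch = 4, push = 4, twist = 4, plug = 4,
               "no-movement" = 1.5)
  readiness_amp <- 3

  motor_gain <- c(BA4a = 1, BA6 = 1, BA4p = 0.7,
                  BA1 = 0.5, BA2 = 0.5, BA3a = 0.5, BA3b = 0.5,
                  BA44 = 0.2, BA45 = 0.2)
  vis_gain <- c(V1 = 1, V2 = 0.9, MT = 0.8)

  for (task in tasks) {
    a <- if (task %in% names(peak_amp)) peak_amp[[task]] else 5
    lat <- if (task %in% names(peak_lat)) peak_lat[[task]] else 1.5
    b <- if (task %in% names(vis_amp)) vis_amp[[task]] else 2
    if (a > 0) {
      # slow readiness negativity + sharp peri-grasp peak
      w <- -readiness_amp * exp(-((t - 0.4) / 0.9)^2) -
        a * exp(-((t - lat) / 0.35)^2)
      for (r in names(motor_gain)) {
        tpl[paste0(r, "_L"), , task] <- motor_gain[[r]] * w
        tpl[paste0(r, "_R"), , task] <- 0.4 * motor_gain[[r]] * w
      }
    }
    if (task == "no-movement") {
      v <- b * exp(-((t - 0.3) / 0.3)^2)             # cue response only
    } else {
      v <- b * exp(-((t - 0.5) / 0.4)^2) -
        0.7 * b * exp(-((t - 2.5) / 0.4)^2)          # reach + return rebound
    }
    for (r in names(vis_gain)) {
      tpl[paste0(r, "_L"), , task] <- tpl[paste0(r, "_L"), , task] +
        vis_gain[[r]] * v
      tpl[paste0(r, "_R"), , task] <- tpl[paste0(r, "_R"), , task] +
        vis_gain[[r]] * v
    }
  }

  structure(list(
    roi_templates = tpl, template_time = t, rate = rate,
    epoch_window = EPOCH_WINDOW,
    coupled_roi_pairs = data.frame(
      roi_a = c("BA4a_L", "V1_L"), roi_b = c("BA6_L", "V2_L"),
      coupling = c(0.9, 0.8), stringsAsFactors = FALSE),
    osc_freq = 1.5, osc_amp = 1.5, phase_diffusion = 3
  ), class = "grasp_truth")
}

# Temporally coloured (AR(1), ~1/f^2 above f_c) Gaussian noise, spatially
# correlated through a random mixing matrix; rows rescaled to unit SD.
colored_noise <- function(n_series, n_samples, rate, f_c = 2) {
  rho <- exp(-2 * pi * f_c / rate)
  w <- matrix(stats::rnorm(n_series * n_samples), n_series, n_samples)
  x <- t(apply(w, 1, function(e)
    as.numeric(stats::filter(e, rho, method = "recursive"))))
  mix <- diag(n_series) +
    0.5 * matrix(stats::rnorm(n_series^2), n_series) / sqrt(n_series)
  x <- mix %*% x
  sds <- apply(x, 1, stats::sd)
  sds[sds == 0] <- 1
  x / sds
}

# Per-trial ROI oscillation phases: random-walk (diffusing) phase per ROI,
# with planted coupling tying pair members' phase trajectories together.
osc_phases <- function(truth, n_samples, rate) {
  rois <- grasp_rois()
  step_sd <- truth$phase_diffusion / sqrt(rate)
  W <- t(apply(matrix(stats::rnorm(24 * n_samples, 0, step_sd),
                      24, n_samples), 1, cumsum))
  phi0 <- stats::runif(24, 0, 2 * pi)
  rownames(W) <- rois
  names(phi0) <- rois
  cp <- truth$coupled_roi_pairs
  for (k in seq_len(nrow(cp))) {
    a <- cp$roi_a[k]; b <- cp$roi_b[k]; c <- cp$coupling[k]
    W[b, ] <- c * W[a, ] + (1 - c) * W[b, ]
    phi0[b] <- c * phi0[a] + (1 - c) * phi0[b]
  }
  t_ax <- (seq_len(n_samples) - 1) / rate
  sweep(W, 2, 2 * pi * truth$osc_freq * t_ax, "+") + phi0
}

# RMS of the noiseless sensor projection of the templates over all
# conditions; defines the signal scale against which snr is interpreted.
template_sensor_rms <- function(truth, leadfield) {
  A_src <- truth$roi_templates[leadfield$roi, , , drop = FALSE]
  tot <- 0; n <- 0
  for (k in seq_len(dim(A_src)[3])) {
    s <- leadfield$gain %*% A_src[, , k]
    tot <- tot + sum(s^2); n <- n + length(s)
  }
  sqrt(tot / n)
}

#' Simulate a full synthetic experiment
#'
#' Generates one recording per session plus a 10-s rest recording (sensor
#' noise only), following the trial protocol: beep at slot start, task cue
#' at +3 s, "go" cue at +5 s, movement onset after a random reaction time,
#' reach/grasp/return phases of roughly 1 s each. The button channel is high
#' between movement onset and return; the force channel is high during the
#' grasp. A configurable fraction of movement trials is planted to violate
#' each of the four discard rules (R1 release before go, R2 no return
#' within 5 s of go, R3 reaction time > 1.5 s, R4 wrong movement).
#'
#' @param config a [sim_config()]
#' @param truth a `grasp_truth` (default [default_ground_truth()])
#' @param leadfield a `grasp_leadfield` (default random unit-column gain
#'   seeded from the config)
#' @return object of class `grasp_experiment`: `sessions` (list of
#'   `grasp_recording`), `rest` (`grasp_recording`), `truth` (with the
#'   planted per-trial event table in `$events`), `leadfield`, `config`
#' @export
simulate_experiment <- function(config, truth = NULL, leadfield = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- default_ground_truth(config)
  if (is.null(leadfield))
    leadfield <- generate_leadfield(config$n_channels, config$n_sources,
                                    seed = config$seed)
  if (!identical(dim(truth$roi_templates)[c(1, 3)],
                 c(24L, length(config$tasks))) ||
      dim(truth$roi_templates)[2] !=
        n_samples_ho(EPOCH_WINDOW[1], EPOCH_WINDOW[2], config$sample_rate))
    stop("roi_templates shape does not match the ROI atlas / epoch window")
  if (ncol(leadfield$gain) != config$n_sources)
    stop("leadfield does not match config$n_sources")

  rate <- config$sample_rate
  seeds <- child_seeds(config$seed, config$n_sessions + 1L)
  sig_rms <- template_sensor_rms(truth, leadfield)
  noise_sd <- if (is.infinite(config$snr)) 0 else {
    if (sig_rms == 0) 1 else sig_rms / config$snr
  }

  sessions <- vector("list", config$n_sessions)
  ev_all <- list()
  for (s in seq_len(config$n_sessions)) {
    sim <- run_seeded(seeds[s], function()
      simulate_session(s, config, truth, leadfield, noise_sd))
    sessions[[s]] <- sim$recording
    ev_all[[s]] <- sim$events
  }
  rest <- run_seeded(seeds[config$n_sessions + 1L], function() {
    n <- n_samples_ho(0, 10, rate)
    eeg <- if (noise_sd > 0)
      noise_sd * colored_noise(config$n_channels, n, rate)
    else matrix(0, config$n_channels, n)
    new_recording(eeg, numeric(n), numeric(n), rate, protocol = NULL)
  })
  truth$events <- do.call(rbind, ev_all)
  truth$noise_sd <- noise_sd
  structure(list(sessions = sessions, rest = rest, truth = truth,
                 leadfield = leadfield, config = config),
            class = "grasp_experiment")
}

new_recording <- function(eeg, button, force, rate, protocol) {
  n <- ncol(eeg)
  structure(list(eeg = eeg, button = button, force = force, rate = rate,
                 channels = channel_names(nrow(eeg)), protocol = protocol,
                 duration = n / rate),
            class = "grasp_recording")
}

channel_names <- function(n) {
  std40 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1",
             "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1",
             "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8", "PO7", "PO3",
             "POz", "PO4", "PO8", "O1", "Oz", "O2", "AF3", "AF4", "F5",
             "F1", "F2", "F6", "FC3")
  if (n <= length(std40)) std40[seq_len(n)] else paste0("EEG", seq_len(n))
}

# One session: balanced random task order, planted rule violations,
# button/force construction, source projection, additive sensor noise.
simulate_session <- function(session, config, truth, leadfield, noise_sd) {
  rate <- config$sample_rate
  tpt <- config$trials_per_task_per_session
  tasks <- sample(rep(config$tasks, each = tpt))
  n_trials <- length(tasks)
  n_total <- n_samples_ho(0, n_trials * config$trial_len_s + 2, rate)

  mov_idx <- which(tasks != "no-movement")
  planted <- rep("OK", n_trials)
  pool <- mov_idx
  for (rule in c("R1", "R2", "R3", "R4")) {
    k <- round(config$contamination[[rule]] * length(mov_idx))
    if (k > 0) {
      pick <- if (length(pool) == 1) pool else sample(pool, min(k, length(pool)))
      planted[pick] <- rule
      pool <- setdiff(pool, pick)
    }
  }

  eeg <- if (noise_sd > 0)
    noise_sd * colored_noise(config$n_channels, n_total, rate)
  else matrix(0, config$n_channels, n_total)
  button <- numeric(n_total)
  force <- numeric(n_total)
  n_ep <- dim(truth$roi_templates)[2]
  src_roi <- leadfield$roi
  mov_tasks <- setdiff(config$tasks, "no-movement")

  ev <- data.frame(session = session, trial = seq_len(n_trials),
                   task = tasks, task_executed = tasks,
                   cue_t = NA_real_, go_t = NA_real_, onset_t = NA_real_,
                   end_t = NA_real_, grasp_start_t = NA_real_,
                   grasp_end_t = NA_real_, reaction_time = NA_real_,
                   planted_rule = planted, stringsAsFactors = FALSE)

  for (i in seq_len(n_trials)) {
    start <- (i - 1) * config$trial_len_s
    cue_t <- start + 3
    go_t <- start + 5
    rule <- planted[i]
    task <- tasks[i]
    is_mov <- task != "no-movement"

    # clean reaction times clipped to 1.2 s so that onset + the three
    # movement phases always ends within 5 s of "go" (rule R2 margin)
    rt <- min(max(stats::rnorm(1, config$reaction_time_mean,
                               config$reaction_time_sd), 0.15), 1.2)
    if (rule == "R1") rt <- -stats::runif(1, 0.2, 0.5)
    if (rule == "R3") rt <- stats::runif(1, 1.6, 1.9)
    exec <- task
    if (rule == "R4") exec <- sample(setdiff(mov_tasks, task), 1)

    onset <- go_t + if (is_mov) rt else config$reaction_time_mean
    reach_d <- stats::runif(1, 0.8, 1.1)
    grasp_d <- stats::runif(1, 0.8, 1.1)
    return_d <- stats::runif(1, 0.8, 1.1)
    gs <- onset + reach_d
    ge <- gs + grasp_d
    end <- ge + return_d
    if (rule == "R2") end <- go_t + stats::runif(1, 5.3, 6.3)
    if (rule == "R3") end <- min(end, go_t + 4.9)

    if (is_mov) {
      button[grid_index(onset, 0, rate):(grid_index(end, 0, rate) - 1L)] <- 1
      force[grid_index(gs, 0, rate):(grid_index(ge, 0, rate) - 1L)] <- 1
      ev$onset_t[i] <- onset; ev$end_t[i] <- end
      ev$grasp_start_t[i] <- gs; ev$grasp_end_t[i] <- ge
      ev$reaction_time[i] <- rt
    } else {
      ev$onset_t[i] <- onset   # truth alignment of the planted cue response
    }
    ev$cue_t[i] <- cue_t; ev$go_t[i] <- go_t
    ev$task_executed[i] <- exec

    # source activity on the padded epoch support, projected to sensors
    scale <- if (config$amp_var > 0)
      exp(stats::rnorm(1, 0, config$amp_var)) else 1
    roi_sig <- scale * truth$roi_templates[, , exec]
    if (truth$osc_amp > 0)
      roi_sig <- roi_sig + truth$osc_amp *
        cos(osc_phases(truth, n_ep, rate))
    i0 <- grid_index(onset + EPOCH_WINDOW[1], 0, rate)
    idx <- i0:(i0 + n_ep - 1L)
    keep <- idx >= 1L & idx <= n_total
    eeg[, idx[keep]] <- eeg[, idx[keep]] +
      leadfield$gain %*% roi_sig[src_roi, keep, drop = FALSE]
  }

  protocol <- ev[, c("trial", "task", "cue_t", "go_t")]
  list(recording = new_recording(eeg, button, force, rate, protocol),
       events = ev)
}

#' Simulate source-space epochs directly
#'
#' Bypasses the sensor chain and produces ROI source epochs (sMRCP-like
#' trials) from the ground-truth templates plus white source noise, on the
#' padded epoch grid at any rate. Used to exercise the decoder and the
#' connectivity stage under exactly known conditions.
#'
#' @param truth a `grasp_truth`
#' @param n_per_class trials per condition
#' @param snr ratio of template RMS (over movement conditions) to the noise
#'   standard deviation; `Inf` for noiseless trials
#' @param rate output sampling rate in Hz
#' @param seed RNG seed
#' @param amp_var log-normal SD of the per-trial amplitude scale
#' @param tasks conditions to simulate (default all template conditions)
#' @return object of class `grasp_sources` (see [apply_inverse()]) with a
#'   `labels` field
#' @export
simulate_source_epochs <- function(truth, n_per_class = 10, snr = 10,
                                   rate = 16, seed = 1, amp_var = 0,
                                   tasks = NULL) {
  if (is.null(tasks)) tasks <- dimnames(truth$roi_templates)[[3]]
  t_out <- time_axis_ho(truth$epoch_window[1], truth$epoch_window[2], rate)
  n_t <- length(t_out)
  tpl16 <- array(0, c(24, n_t, length(tasks)),
                 dimnames = list(grasp_rois(), NULL, tasks))
  for (k in seq_along(tasks)) {
    tpl16[, , k] <- t(apply(truth$roi_templates[, , tasks[k]], 1, function(x)
      stats::approx(truth$template_time, x, xout = t_out, rule = 2)$y))
  }
  mov <- setdiff(tasks, "no-movement")
  sig_rms <- sqrt(mean(tpl16[, , mov, drop = FALSE]^2))
  noise_sd <- if (is.infinite(snr)) 0 else sig_rms / snr
  n_trials <- n_per_class * length(tasks)
  labels <- rep(tasks, each = n_per_class)
  data <- array(0, c(n_trials, 24, n_t))
  run_seeded(seed, function() {
    ord <- sample(n_trials)
    labels <<- labels[ord]
    for (i in seq_len(n_trials)) {
      scale <- if (amp_var > 0) exp(stats::rnorm(1, 0, amp_var)) else 1
      data[i, , ] <<- scale * tpl16[, , labels[i]] +
        noise_sd * matrix(stats::rnorm(24 * n_t), 24, n_t)
    }
  })
  structure(list(data = data, roi = grasp_rois(), rate = rate,
                 time = t_out, labels = labels),
            class = "grasp_sources")
}

#' @export
print.grasp_recording <- function(x, ...) {
  cat(sprintf("<grasp_recording> %d EEG channels, %.1f s at %g Hz, %s\n",
              nrow(x$eeg), x$duration, x$rate,
              if (is.null(x$protocol)) "rest (no trials)"
              else sprintf("%d trials", nrow(x$protocol))))
  invisible(x)
}

#' @export
print.grasp_experiment <- function(x, ...) {
  cat(sprintf("<grasp_experiment> %d sessions x %d trials (%d total), %d channels at %g Hz\n",
              x$config$n_sessions,
              x$config$trials_per_task_per_session * x$config$n_tasks,
              x$config$n_sessions * x$config$trials_per_task_per_session *
                x$config$n_tasks,
              x$config$n_channels, x$config$sample_rate))
  invisible(x)
}
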