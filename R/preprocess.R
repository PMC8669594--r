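# Filtering, resampling, epoching, trial rejection and referencing: the
# chain that turns raw recordings into MRCP epochs.
#
# Pipeline order: 0.1-40 Hz band-pass -> downsample to 100 Hz -> epoch at
# [-3, 3.5) s around movement onset -> amplitude / joint-probability /
# kurtosis rejection -> common average reference -> 0.1-3 Hz MRCP band.

#' Zero-phase Butterworth filter
#'
#' Order-4 Butterworth design applied forward and backward
#' (`signal::filtfilt`), i.e. zero net phase and an effective order-8
#' magnitude response. `low = 0` gives a low-pass. Band-passes are applied
#' as a cascade of an order-`order` high-pass at `low` and an
#' order-`order` low-pass at `high`: with the widely separated edges used
#' here (0.1 vs 40 Hz, 0.1 vs 3 Hz) the passband response is equivalent to
#' the direct band-pass design, whose transfer-function form is
#' numerically unstable at narrow normalised edges.
#'
#' @param x numeric vector, or matrix filtered along rows (channels x time)
#' @param rate sampling rate in Hz
#' @param low,high band edges in Hz; `0 <= low < high < rate/2`
#' @param order filter order of each one-way design
#' @return filtered signal, same shape as `x`
#' @export
butter_zero_phase <- function(x, rate, low, high, order = 4) {
  stopifnot(rate > 0, low >= 0, high > low)
  if (high >= rate / 2) stop("band edge at or above Nyquist frequency")
  lp <- signal::butter(order, high / (rate / 2), type = "low")
  hp <- if (low > 0)
    signal::butter(order, low / (rate / 2), type = "high") else NULL
  ff <- function(v) {
    # a band-pass rejects DC, so demean first: this suppresses the slow
    # edge transients the filters' long impulse responses leave otherwise
    if (!is.null(hp)) v <- v - mean(v)
    v <- signal::filtfilt(lp, v)
    if (!is.null(hp)) v <- signal::filtfilt(hp, v)
    v
  }
  if (is.matrix(x)) t(apply(x, 1, ff)) else ff(x)
}

#' Downsample with anti-alias filtering
#'
#' Applies a zero-phase low-pass at `0.45 * target_rate` and interpolates
#' onto the half-open target grid, preserving duration to within one
#' sample: the output has `round(n * target_rate / rate)` samples.
#'
#' @param x numeric vector or channels-x-time matrix
#' @param rate input rate in Hz
#' @param target_rate output rate in Hz, strictly below `rate`
#' @return resampled signal
#' @export
resample_signal <- function(x, rate, target_rate) {
  if (target_rate >= rate) stop("only downsampling is supported")
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, 1) else x
  # filter about the channel mean: DC passes exactly and edge transients of
  # the anti-alias low-pass do not leak the offset
  mu <- rowMeans(xm)
  xm <- butter_zero_phase(xm - mu, rate, 0, 0.45 * target_rate) + mu
  n_in <- ncol(xm)
  n_out <- as.integer(round(n_in * target_rate / rate))
  t_in <- (seq_len(n_in) - 1) / rate
  t_out <- (seq_len(n_out) - 1) / target_rate
  out <- t(apply(xm, 1, function(r)
    stats::approx(t_in, r, xout = t_out, rule = 2)$y))
  if (v) as.numeric(out) else out
}

#' Extract epochs around movement onsets
#'
#' Cuts `[window[1], window[2])` s around each onset (default `[-3, 3.5)`:
#' the `[-2, 3.5)` s temporal region of interest padded by 1 s so a causal
#' 1-s feature window exists at every tROI time point). Onsets without full
#' window support are dropped with a warning.
#'
#' @param eeg channels x time matrix
#' @param rate sampling rate of `eeg` in Hz
#' @param onsets onset times in seconds from recording start
#' @param labels task label per onset
#' @param window epoch window in seconds relative to onset (half-open)
#' @return object of class `grasp_epochs`: `data` (trials x channels x
#'   samples array), `labels`, `time` (seconds, 0 = onset), `rate`,
#'   `reject` (per-trial flag, `"OK"` initially)
#' @export
epoch_recording <- function(eeg, rate, onsets, labels,
                            window = EPOCH_WINDOW) {
  stopifnot(is.matrix(eeg), length(onsets) == length(labels))
  n_s <- n_samples_ho(window[1], window[2], rate)
  t_ax <- time_axis_ho(window[1], window[2], rate)
  keep <- logical(length(onsets))
  idx0 <- integer(length(onsets))
  for (i in seq_along(onsets)) {
    i0 <- grid_index(onsets[i] + window[1], 0, rate)
    keep[i] <- i0 >= 1L && (i0 + n_s - 1L) <= ncol(eeg)
    idx0[i] <- i0
  }
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: epoch window outside recording")
  data <- array(NA_real_, c(sum(keep), nrow(eeg), n_s))
  for (j in seq_along(which(keep))) {
    i <- which(keep)[j]
    data[j, , ] <- eeg[, idx0[i]:(idx0[i] + n_s - 1L)]
  }
  structure(list(data = data, labels = labels[keep], time = t_ax,
                 rate = rate, reject = rep("OK", sum(keep))),
            class = "grasp_epochs")
}

# per-trial joint (negative log-)probability statistic under per-channel
# empirical Gaussians pooled across trials
jp_statistic <- function(data) {
  n_ch <- dim(data)[2]
  stat <- numeric(dim(data)[1])
  for (c in seq_len(n_ch)) {
    x <- data[, c, , drop = FALSE]
    mu <- mean(x); s <- stats::sd(x)
    if (s == 0) next
    stat <- stat + apply(x, 1, function(v) -sum(stats::dnorm(v, mu, s, log = TRUE)))
  }
  stat
}

# per-trial kurtosis statistic: mean over channels of the excess-free
# sample kurtosis of the trial's samples
kurt_statistic <- function(data) {
  apply(data, 1, function(tr) {
    ks <- apply(tr, 1, function(v) {
      s2 <- mean((v - mean(v))^2)
      if (s2 == 0) return(0)
      mean((v - mean(v))^4) / s2^2
    })
    mean(ks)
  })
}

#' Flag trials for rejection
#'
#' Three screens: `AMP` if any sample exceeds `amp_thresh` in magnitude
#' (pre-CAR, in microvolts); `JP` if the trial's joint log-probability
#' statistic deviates from the trial-population mean by more than `n_sd`
#' standard deviations; `KURT` likewise for the trial-mean kurtosis. When a
#' statistic has zero spread across trials, no trial is flagged by it. Data
#' are retained; only the mask is set. Flag precedence: AMP > JP > KURT.
#'
#' @param epochs a `grasp_epochs`
#' @param amp_thresh amplitude threshold in microvolts (default 100)
#' @param n_sd deviation threshold in standard deviations (default 5)
#' @return `grasp_epochs` with the `reject` mask filled
#' @export
reject_trials <- function(epochs, amp_thresh = 100, n_sd = 5) {
  n <- dim(epochs$data)[1]
  if (n < 8) stop("need at least 8 trials for rejection statistics")
  flag <- rep("OK", n)
  amp <- apply(epochs$data, 1, function(tr) max(abs(tr)))
  flag[amp > amp_thresh] <- "AMP"
  for (nm in c("JP", "KURT")) {
    st <- if (nm == "JP") jp_statistic(epochs$data) else
      kurt_statistic(epochs$data)
    s <- stats::sd(st)
    if (is.na(s) || s == 0) next
    out <- abs(st - mean(st)) > n_sd * s
    flag[out & flag == "OK"] <- nm
  }
  if (all(flag != "OK")) stop("all trials rejected")
  epochs$reject <- flag
  epochs
}

#' Drop rejected trials
#'
#' @param epochs a `grasp_epochs` with a filled `reject` mask
#' @return `grasp_epochs` containing only `reject == "OK"` trials
#' @export
drop_rejected <- function(epochs) {
  keep <- epochs$reject == "OK"
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$labels <- epochs$labels[keep]
  epochs$reject <- epochs$reject[keep]
  epochs
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels; the
#' channel mean of the output is exactly zero. Idempotent.
#'
#' @param epochs a `grasp_epochs` (>= 2 channels)
#' @return re-referenced `grasp_epochs`
#' @export
common_average_reference <- function(epochs) {
  if (dim(epochs$data)[2] < 2) stop("CAR needs at least 2 channels")
  for (i in seq_len(dim(epochs$data)[1])) {
    tr <- epochs$data[i, , ]
    epochs$data[i, , ] <- sweep(tr, 2, colMeans(tr))
  }
  epochs
}

#' Band-pass epochs to the MRCP band (0.1-3 Hz)
#'
#' @param epochs a `grasp_epochs`
#' @param low,high band edges in Hz
#' @return filtered `grasp_epochs`
#' @export
mrcp_band <- function(epochs, low = 0.1, high = 3) {
  for (i in seq_len(dim(epochs$data)[1]))
    epochs$data[i, , ] <- butter_zero_phase(epochs$data[i, , ],
                                            epochs$rate, low, high)
  epochs
}

#' Run the preprocessing chain on an experiment's sessions
#'
#' Per session: band-pass 0.1-40 Hz, downsample to `work_rate`, epoch at
#' `[-3, 3.5)` s around the (pseudo-)onsets of non-discarded trials; then,
#' pooled over sessions: amplitude/JP/kurtosis rejection, drop flagged
#' trials, common average reference, MRCP band-pass 0.1-3 Hz. The rest
#' recording goes through the identical filter/resample/CAR chain.
#'
#' @param experiment a `grasp_experiment`
#' @param event_tables list of flagged event tables (one per session) with
#'   onsets assigned; by default they are derived with the events module
#'   using the planted truth for rule R4
#' @param work_rate working rate after downsampling (Hz)
#' @param amp_thresh,n_sd rejection parameters, see [reject_trials()]
#' @return list with `epochs` (a cleaned `grasp_epochs`), `rest` (channels
#'   x time matrix preprocessed like the movement data), `events` (the
#'   row-bound event table used)
#' @export
preprocess_experiment <- function(experiment, event_tables = NULL,
                                  work_rate = 100, amp_thresh = 100,
                                  n_sd = 5) {
  stopifnot(inherits(experiment, "grasp_experiment"))
  if (is.null(event_tables)) {
    event_tables <- lapply(seq_along(experiment$sessions), function(s) {
      tab <- build_event_table(experiment$sessions[[s]])
      tr <- experiment$truth$events
      apply_discard_rules(tab, truth = tr[tr$session == s, ])
    })
    pooled <- do.call(rbind, lapply(seq_along(event_tables), function(s)
      cbind(session = s, event_tables[[s]])))
    pooled <- assign_pseudo_onsets(pooled)
    event_tables <- split(pooled, pooled$session)
  }
  ep_list <- list()
  for (s in seq_along(experiment$sessions)) {
    rec <- experiment$sessions[[s]]
    tab <- event_tables[[s]]
    use <- tab$flag == "OK" & !is.na(tab$onset_t)
    eeg <- butter_zero_phase(rec$eeg, rec$rate, 0.1, 40)
    eeg <- resample_signal(eeg, rec$rate, work_rate)
    ep_list[[s]] <- epoch_recording(eeg, work_rate, tab$onset_t[use],
                                    tab$task[use])
  }
  epochs <- ep_list[[1]]
  if (length(ep_list) > 1) {
    epochs$data <- do.call(abind3, lapply(ep_list, `[[`, "data"))
    epochs$labels <- unlist(lapply(ep_list, `[[`, "labels"))
    epochs$reject <- rep("OK", length(epochs$labels))
  }
  epochs <- reject_trials(epochs, amp_thresh = amp_thresh, n_sd = n_sd)
  epochs <- drop_rejected(epochs)
  epochs <- common_average_reference(epochs)
  epochs <- mrcp_band(epochs)

  rest <- butter_zero_phase(experiment$rest$eeg, experiment$rest$rate,
                            0.1, 40)
  rest <- resample_signal(rest, experiment$rest$rate, work_rate)
  rest <- sweep(rest, 2, colMeans(rest))        # CAR
  rest <- butter_zero_phase(rest, work_rate, 0.1, 3)

  list(epochs = epochs, rest = rest,
       events = do.call(rbind, event_tables))
}

# bind trial arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 1L))
  out <- array(NA_real_, c(n, d[2], d[3]))
  at <- 1L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[at:(at + k - 1L), , ] <- p
    at <- at + k
  }
  out
}

#' @export
print.grasp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<grasp_epochs> %d trials x %d channels x %d samples at %g Hz, [%g, %g) s\n",
              d[1], d[2], d[3], x$rate, x$time[1],
              x$time[length(x$time)] + 1 / x$rate))
  invisible(x)
}
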