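# Sliding-window amplitude features on sMRCP, multiclass shrinkage-LDA,
# repeated stratified cross-validation, accuracy/precision time courses,
# confusion matrices, the exact-binomial chance level, and the window-size
# experiment.

#' Resample source epochs
#'
#' @param sources a `grasp_sources`
#' @param target_rate output rate in Hz (default 16, the decoding grid)
#' @return resampled `grasp_sources`
#' @export
resample_sources <- function(sources, target_rate = 16) {
  n_tr <- dim(sources$data)[1]
  t0 <- sources$time[1]
  one <- resample_signal(sources$data[1, , ], sources$rate, target_rate)
  out <- array(NA_real_, c(n_tr, dim(one)))
  out[1, , ] <- one
  if (n_tr > 1)
    for (i in 2:n_tr)
      out[i, , ] <- resample_signal(sources$data[i, , ], sources$rate,
                                    target_rate)
  sources$data <- out
  sources$rate <- target_rate
  sources$time <- t0 + (seq_len(dim(one)[2]) - 1) / target_rate
  sources
}

#' Number of sliding-window models over the tROI
#'
#' One sLDA model per sample of the half-open temporal region of interest:
#' `round((troi[2] - troi[1]) * rate)`. Defaults give 88.
#'
#' @param troi temporal region of interest in seconds (half-open)
#' @param rate decoding grid rate in Hz
#' @return integer model count
#' @export
count_models <- function(troi = TROI, rate = 16) {
  n_samples_ho(troi[1], troi[2], rate)
}

#' Extract amplitude features for one causal window
#'
#' Takes amplitude values every `step_s` inside the causal half-open window
#' `[t_end - window_s, t_end)` and concatenates them over signals (ROIs or
#' channels): `n_signals * round(window_s / step_s)` features, i.e.
#' 24 x 8 = 192 at the defaults.
#'
#' @param data trials x signals x samples array on the decoding grid
#' @param time time axis of `data` in seconds
#' @param rate grid rate in Hz
#' @param t_end window end time (seconds; a tROI grid point)
#' @param window_s window length in seconds
#' @param step_s amplitude sampling step inside the window (seconds)
#' @return trials x features matrix
#' @export
extract_features <- function(data, time, rate, t_end, window_s = 1,
                             step_s = 0.125) {
  n_amp <- max(1L, as.integer(round(window_s / step_s)))
  samp_t <- t_end - window_s + (seq_len(n_amp) - 1) * step_s
  if (samp_t[1] < time[1] - 1e-9)
    stop("feature window extends before the padded epoch start")
  idx <- grid_index(samp_t, time[1], rate)
  if (any(idx < 1L) || any(idx > length(time)))
    stop("feature window outside the epoch")
  n_tr <- dim(data)[1]
  n_sig <- dim(data)[2]
  X <- matrix(NA_real_, n_tr, n_sig * n_amp)
  for (i in seq_len(n_tr)) {
    sl <- matrix(data[i, , idx, drop = FALSE], n_sig, n_amp)
    X[i, ] <- as.numeric(t(sl))   # per signal, amplitudes contiguous
  }
  X
}

#' Fit a multiclass shrinkage-LDA classifier
#'
#' Single multiclass linear discriminant with class means and one pooled
#' within-class covariance shrunk toward a scaled identity, with the
#' analytic (Ledoit-Wolf) shrinkage intensity estimated from the data. The
#' shrunk covariance is positive definite even when features outnumber
#' samples.
#'
#' @param X samples x features matrix
#' @param y class labels (>= 2 classes, >= 2 samples per class)
#' @return object of class `slda` with elements `means`, `sigma_inv_mu`,
#'   `const`, `classes`, `shrinkage`
#' @export
fit_slda <- function(X, y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 2)) stop("every class needs at least 2 samples")
  p <- ncol(X)
  n <- nrow(X)
  mu <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(p)))
  Xc <- X - mu[match(y, classes), , drop = FALSE]
  S <- crossprod(Xc) / n
  # Ledoit-Wolf intensity toward (tr(S)/p) I
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2)
  q <- rowSums(Xc^2)
  b2bar <- (sum(q^2) - n * sum(S^2)) / n^2
  b2 <- min(max(b2bar, 0), d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  Sigma <- (1 - rho) * S + diag(rho * m, p)
  ch <- chol(Sigma)
  simu <- backsolve(ch, forwardsolve(t(ch), t(mu)))   # Sigma^{-1} mu_k
  const <- -0.5 * colSums(t(mu) * simu) + log(as.numeric(cnt[classes]) / n)
  structure(list(means = mu, sigma_inv_mu = simu, const = const,
                 classes = classes, shrinkage = rho), class = "slda")
}

#' Predict with a shrinkage-LDA model
#'
#' @param object an `slda` model
#' @param newdata samples x features matrix
#' @param ... unused
#' @return character vector of predicted class labels
#' @export
predict.slda <- function(object, newdata, ...) {
  scores <- newdata %*% object$sigma_inv_mu
  scores <- sweep(scores, 2, object$const, "+")
  object$classes[max.col(scores, ties.method = "first")]
}

#' Exact-binomial adjusted chance level
#'
#' Smallest accuracy `k/n` whose upper-tail probability under random
#' guessing (`Binomial(n, 1/n_classes)`) is at most `alpha`.
#'
#' @param n_trials number of test trials
#' @param n_classes number of classes (default 6)
#' @param alpha significance level (default 0.05)
#' @return fraction in (0, 1]
#' @export
chance_level <- function(n_trials, n_classes = 6, alpha = 0.05) {
  stopifnot(n_trials >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- 1 / n_classes
  if (p >= 1) return(1)
  k <- stats::qbinom(1 - alpha, n_trials, p) + 1
  min(k, n_trials) / n_trials
}

# stratified fold assignment (one permutation per call)
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (k in unique(y)) {
    idx <- which(y == k)
    if (length(idx) < folds)
      stop("class '", k, "' has fewer trials than folds")
    f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  f
}

#' Repeated cross-validated sliding-window decoding
#'
#' For every causal window ending on a tROI grid point, fits shrinkage-LDA
#' under stratified k-fold cross-validation repeated `repeats` times (fold
#' reshuffling per repeat, all randomness from `seed`), and reports the
#' mean accuracy and per-class precision time courses, per-window confusion
#' matrices (fold-summed counts averaged over repeats), the peak, and the
#' exact-binomial chance level.
#'
#' @param sources a `grasp_sources` on the decoding grid (or any
#'   trials x signals x samples container with `time`, `rate`, `labels`)
#' @param labels class labels (default `sources$labels`)
#' @param folds,repeats cross-validation design (defaults 5 x 10)
#' @param seed master RNG seed
#' @param window_s,step_s feature window parameters (defaults 1 s, 125 ms)
#' @param troi temporal region of interest (half-open, seconds)
#' @return object of class `decoding_result`: `window_end_s`,
#'   `accuracy_curve`, `precision_curves` (classes x windows), `confusion`
#'   (classes x classes x windows), `peak_accuracy`, `peak_time`,
#'   `chance_level`, `n_trials`
#' @export
cross_validated_curves <- function(sources, labels = NULL, folds = 5,
                                   repeats = 10, seed = 1, window_s = 1,
                                   step_s = 0.125, troi = TROI) {
  data <- sources$data
  time <- sources$time
  rate <- sources$rate
  if (is.null(labels)) labels <- sources$labels
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  n_tr <- dim(data)[1]
  stopifnot(length(labels) == n_tr)

  ends <- time_axis_ho(troi[1], troi[2], rate)
  feasible <- ends - window_s >= time[1] - 1e-9
  ends <- ends[feasible]
  n_win <- length(ends)
  if (n_win == 0) stop("window size exceeds the epoch padding everywhere")

  Xs <- lapply(ends, function(te)
    extract_features(data, time, rate, te, window_s, step_s))

  n_cl <- length(classes)
  conf <- array(0, c(n_cl, n_cl, n_win),
                dimnames = list(classes, classes, NULL))
  seeds <- child_seeds(seed, repeats)
  for (r in seq_len(repeats)) {
    fold <- run_seeded(seeds[r], function() stratified_folds(labels, folds))
    for (f in seq_len(folds)) {
      te <- fold == f
      for (w in seq_len(n_win)) {
        mdl <- fit_slda(Xs[[w]][!te, , drop = FALSE], labels[!te])
        pred <- predict(mdl, Xs[[w]][te, , drop = FALSE])
        conf[, , w] <- conf[, , w] +
          table(factor(labels[te], classes), factor(pred, classes))
      }
    }
  }
  conf <- conf / repeats
  acc <- apply(conf, 3, function(cm) sum(diag(cm)) / sum(cm))
  prec <- apply(conf, 3, function(cm) {
    cs <- colSums(cm)
    ifelse(cs > 0, diag(cm) / cs, NA_real_)
  })
  peak_w <- which.max(acc)[1]          # ties -> earliest window
  structure(list(window_end_s = ends, accuracy_curve = as.numeric(acc),
                 precision_curves = matrix(prec, nrow = n_cl,
                                           dimnames = list(classes, NULL)),
                 confusion = conf,
                 peak_accuracy = acc[peak_w], peak_time = ends[peak_w],
                 chance_level = chance_level(n_tr, n_cl),
                 n_trials = n_tr, classes = classes,
                 folds = folds, repeats = repeats, window_s = window_s),
            class = "decoding_result")
}

#' Confusion matrix at a query time
#'
#' @param result a `decoding_result`
#' @param t_query window end time in seconds (nearest window used)
#' @return classes x classes matrix of (repeat-averaged) counts
#' @export
confusion_at <- function(result, t_query) {
  w <- which.min(abs(result$window_end_s - t_query))
  result$confusion[, , w]
}

#' Window-size experiment
#'
#' Runs the cross-validated sliding-window decoder for several feature
#' window sizes and tabulates the peak accuracy and peak time per size.
#' `window_s` equal to one grid sample (`1/rate`) reproduces the
#' "one sample" condition.
#'
#' @param sources a `grasp_sources` on the decoding grid
#' @param labels class labels
#' @param sizes window sizes in seconds (default one sample, 0.5, 1, 1.5)
#' @param ... passed to [cross_validated_curves()]
#' @return data frame with columns `window_s`, `peak_accuracy`, `peak_time`
#' @export
window_size_experiment <- function(sources, labels = NULL,
                                   sizes = c(1 / 16, 0.5, 1, 1.5), ...) {
  rows <- lapply(sizes, function(ws) {
    res <- cross_validated_curves(sources, labels, window_s = ws, ...)
    data.frame(window_s = ws, peak_accuracy = res$peak_accuracy,
               peak_time = res$peak_time)
  })
  do.call(rbind, rows)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d windows (%g-s features), %d trials, %dx%d CV\n",
              length(x$window_end_s), x$window_s, x$n_trials, x$folds,
              x$repeats))
  cat(sprintf("  peak accuracy %.1f%% at %.4f s (chance level %.2f%%)\n",
              100 * x$peak_accuracy, x$peak_time, 100 * x$chance_level))
  invisible(x)
}
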