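# Filtering, resampling, epoching, rejection, referencing.

test_that("zero-phase band-pass removes DC, passes the band, adds no lag", {
  rate <- 100
  dc <- rep(2, 2000)
  out <- butter_zero_phase(dc, rate, 0.1, 3)
  expect_lt(max(abs(out[201:1800])), 1e-3 * 2)

  t <- seq(0, 40, by = 1 / rate)[-4001]
  y <- sin(2 * pi * t)
  f <- butter_zero_phase(y, rate, 0.1, 3)
  mid <- 1001:3000
  gain <- sqrt((2 * mean(f[mid] * sin(2 * pi * t[mid])))^2 +
                 (2 * mean(f[mid] * cos(2 * pi * t[mid])))^2)
  expect_gte(gain, 0.95)
  expect_lte(gain, 1.0)

  # zero net phase: filtering the reversed signal equals reversing the
  # filtered signal away from the edge transients
  set.seed(1)
  x <- rnorm(2000)
  a <- butter_zero_phase(rev(x), rate, 0, 3)
  b <- rev(butter_zero_phase(x, rate, 0, 3))
  expect_lt(max(abs(a - b)[201:1800]), 1e-6)

  expect_error(butter_zero_phase(x, rate, 0.1, 60), "Nyquist")
})

test_that("resampling preserves duration on the half-open grid", {
  y <- rep(3, 550)                               # 5.5 s at 100 Hz
  r <- resample_signal(y, 100, 16)
  expect_length(r, 88)
  expect_equal(r, rep(3, 88), tolerance = 1e-9)

  t <- seq(0, 10, by = 1e-3)[-10001]
  s <- sin(2 * pi * 2 * t)
  r2 <- resample_signal(s, 1000, 100)
  expect_length(r2, 1000)
  tr <- seq(0, 10, by = 0.01)[-1001]
  expect_lt(max(abs(r2 - sin(2 * pi * 2 * tr))[51:950]), 1e-3)

  expect_error(resample_signal(s, 100, 200), "downsampling")
})

test_that("epoching uses the padded [-3, 3.5) window with a 550-sample tROI", {
  rate <- 100
  eeg <- matrix(rnorm(2 * 3000), 2)               # 30 s, 2 channels
  ep <- epoch_recording(eeg, rate, onsets = c(10, 20),
                        labels = c("a", "b"))
  expect_equal(dim(ep$data), c(2, 2, 650))
  expect_equal(sum(ep$time >= -2 & ep$time < 3.5), 550)
  expect_equal(ep$time[1], -3)

  expect_warning(
    ep2 <- epoch_recording(eeg, rate, onsets = c(1, 10), labels = c("a", "b")),
    "dropped")
  expect_equal(dim(ep2$data)[1], 1)

  const <- matrix(5, 1, 3000)
  ep3 <- epoch_recording(const, rate, 15, "a")
  expect_true(all(ep3$data == 5))
})

make_epochs <- function(data, rate = 100) {
  structure(list(data = data, labels = rep("a", dim(data)[1]),
                 time = -3 + (seq_len(dim(data)[3]) - 1) / rate,
                 rate = rate, reject = rep("OK", dim(data)[1])),
            class = "grasp_epochs")
}

test_that("rejection flags amplitude, joint-probability and kurtosis outliers", {
  set.seed(4)
  data <- array(rnorm(20 * 3 * 200, sd = 10), c(20, 3, 200))
  spiked <- data
  spiked[3, 2, 50] <- 150
  ep <- reject_trials(make_epochs(spiked))
  expect_equal(which(ep$reject == "AMP"), 3L)

  # identical trials: zero spread in every statistic, nothing flagged
  same <- array(rep(rnorm(3 * 200, sd = 5), each = 12), c(12, 3, 200))
  expect_true(all(reject_trials(make_epochs(same))$reject == "OK"))

  # planted heavy-tailed trial (variance matched to the population so the
  # joint-probability screen stays quiet) is caught by the kurtosis screen
  set.seed(5)
  data <- array(rnorm(40 * 2 * 300, sd = 10), c(40, 2, 300))
  heavy <- rt(2 * 300, df = 4)
  heavy <- heavy / sd(heavy) * 10
  data[17, , ] <- pmin(pmax(heavy, -95), 95)
  ep <- reject_trials(make_epochs(data))
  expect_equal(ep$reject[17], "KURT")
  expect_true(all(ep$reject[-17] == "OK"))

  # planted high-variance trial is caught by the joint-probability screen
  data2 <- data
  data2[17, , ] <- rnorm(2 * 300, sd = 10)
  data2[9, , ] <- pmin(pmax(rnorm(2 * 300, sd = 35), -95), 95)
  ep2 <- reject_trials(make_epochs(data2))
  expect_equal(ep2$reject[9], "JP")

  # raising the amplitude threshold never rejects more trials
  n_amp <- function(th) sum(reject_trials(make_epochs(spiked),
                                          amp_thresh = th)$reject == "AMP")
  expect_true(n_amp(100) >= n_amp(200))
  expect_error(reject_trials(make_epochs(data[1:5, , , drop = FALSE])),
               "at least 8")
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  two <- make_epochs(array(rep(c(1, -1), each = 1, times = 100),
                           c(1, 2, 100)))
  expect_equal(common_average_reference(two)$data, two$data)

  same <- make_epochs(array(rep(rnorm(100), each = 4), c(1, 4, 100)))
  expect_true(all(abs(common_average_reference(same)$data) < 1e-12))

  set.seed(6)
  ep <- make_epochs(array(rnorm(5 * 6 * 100), c(5, 6, 100)))
  car <- common_average_reference(ep)
  sums <- apply(car$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-10)
  expect_equal(common_average_reference(car)$data, car$data,
               tolerance = 1e-12)
  expect_error(common_average_reference(make_epochs(array(1, c(2, 1, 10)))),
               "2 channels")
})

test_that("the preprocessing chain yields clean MRCP epochs from a simulation", {
  pp <- small_preprocessed()
  ep <- pp$epochs
  expect_s3_class(ep, "grasp_epochs")
  expect_equal(dim(ep$data)[3], 650)
  expect_equal(ep$rate, 100)
  expect_true(all(abs(ep$data) <= 100))
  expect_true(all(ep$reject == "OK"))
  # CAR held after the final band-pass to numerical precision
  sums <- apply(ep$data[1, , ], 2, sum)
  expect_lt(max(abs(sums)) / max(abs(ep$data)), 1e-6)
  expect_equal(nrow(pp$rest), dim(ep$data)[2])
})
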