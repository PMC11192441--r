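test_that("downsampling decimates samples and rescales markers", {
  rec <- cbfv_recording(seq_len(4000), seq_len(4000) + 1, fs = 100,
                        markers = c(401, 2001))
  ds <- downsample(rec, 25)
  expect_length(ds$left, 1000)
  expect_equal(ds$fs, 25)
  expect_equal(ds$markers, c(101, 501))  # sample 400 (0-based) -> 100
  # constant signal unchanged in value
  recc <- cbfv_recording(rep(7, 400), rep(7, 400), 100, 101)
  expect_true(all(downsample(recc, 25)$left == 7))
  expect_error(downsample(rec, 30), "non-integer")
})

test_that("quantile artefact flagging catches spikes, spares clean signal", {
  set.seed(51)
  n <- 100000
  x <- rnorm(n)
  x[12345] <- 50  # single huge spike
  rec <- cbfv_recording(x, rnorm(n), fs = 100, markers = 50000)
  fl <- reject_extreme_samples(rec)
  expect_true(fl$flagged[12345])
  # clean Gaussian: about 0.02% flagged per channel (empirical quantiles
  # leave roughly n*1e-4 samples outside each tail)
  frac <- mean(fl$flagged)
  expect_lt(frac, 0.001)
  expect_gt(frac, 0)
  # constant channel: degenerate band, no flags
  recc <- cbfv_recording(rep(3, 1000), rep(3, 1000), 100, 500)
  expect_false(any(reject_extreme_samples(recc)$flagged))
  # interpolate policy removes the spike and clears flags
  rec2 <- cbfv_recording(x, rnorm(n), fs = 100, markers = 50000)
  ip <- reject_extreme_samples(rec2, policy = "interpolate")
  expect_false(any(ip$flagged))
  expect_lt(abs(ip$left[12345]), 5)
})

test_that("normalisation sets each channel mean to 100%", {
  set.seed(52)
  left <- rnorm(500, 60, 2)
  right <- rnorm(500, 50, 2)
  rec <- cbfv_recording(left, right, 25, 100)
  rec <- reject_extreme_samples(rec)
  nm <- normalise(rec)
  expect_equal(mean(nm$left[!nm$flagged]), 100)
  expect_equal(mean(nm$right[!nm$flagged]), 100)
  # scale invariance: scaling a channel pre-normalisation changes nothing
  rec2 <- reject_extreme_samples(cbfv_recording(left * 3, right, 25, 100))
  expect_equal(normalise(rec2)$left, nm$left)
  # arithmetic oracle on a 10-sample toy channel
  toy <- reject_extreme_samples(cbfv_recording(1:10, rep(2, 10), 25, 5))
  expect_equal(normalise(toy)$left, (1:10) / mean(1:10) * 100)
  bad <- reject_extreme_samples(cbfv_recording(rep(-1, 10), rep(1, 10), 25, 5))
  expect_error(normalise(bad), "non-positive")
})

test_that("heart-cycle integration replaces cycles by their means", {
  # synthetic 70 bpm pulse with known per-cycle means 100 (L) and 98 (R)
  fs <- 25
  t <- (0:(fs * 60 - 1)) / fs
  pulse <- 10 * (0.5 * (1 - cos(2 * pi * 70 / 60 * t)))^2
  rec <- cbfv_recording(100 + pulse - mean(pulse), 98 + pulse - mean(pulse),
                        fs, markers = 10)
  rec <- normalise(reject_extreme_samples(rec))
  hi <- heart_cycle_integrate(rec)
  # output is piecewise constant on cycles and near the channel mean
  cyc <- hi$cycle
  expect_true(all(tapply(hi$left, cyc, function(v) max(v) - min(v)) < 1e-9))
  inner <- cyc %in% setdiff(unique(cyc), range(cyc))  # full cycles only
  expect_lt(max(abs(hi$left[inner] - 100)), 1)
  expect_lt(max(abs(hi$right[inner] - 100)), 1)
  # oracle: per-cycle means computed directly
  expect_equal(hi$left, as.numeric(stats::ave(rec$left, cyc)))

  # doubling pulse amplitude leaves cycle boundaries unchanged
  rec2 <- cbfv_recording(100 + 2 * (pulse - mean(pulse)),
                         98 + 2 * (pulse - mean(pulse)), fs, markers = 10)
  rec2 <- normalise(reject_extreme_samples(rec2))
  expect_equal(heart_cycle_integrate(rec2)$cycle, cyc)

  # constant input is returned unchanged
  recc <- normalise(reject_extreme_samples(
    cbfv_recording(rep(5, 200), rep(5, 200), fs, 10)))
  expect_equal(heart_cycle_integrate(recc)$left, recc$left)
  # non-constant but pulseless signal errors with a rate-band hint
  drift <- normalise(reject_extreme_samples(
    cbfv_recording(seq(50, 60, length.out = 500),
                   seq(50, 60, length.out = 500), fs, 10)))
  expect_error(heart_cycle_integrate(drift), "rate_band")
})

test_that("epoching slices the recording and flags truncated trials", {
  fs <- 25
  n <- fs * 1300
  set.seed(53)
  rec <- cbfv_recording(rnorm(n, 100), rnorm(n, 100), fs,
                        markers = round(seq(15, 1115, by = 50) * fs) + 1)
  rec <- normalise(reject_extreme_samples(rec))
  ep <- epochize(rec)
  expect_equal(dim(ep$epochs), c(42 * fs, 2, 23))  # 23 trials of 42 s
  expect_equal(ep$time_axis[1], -12)
  expect_equal(ep$time_axis[length(ep$time_axis)], 30 - 1 / fs)
  # epoch content equals a direct slice
  m <- rec$markers[3]
  expect_equal(ep$epochs[, "left", 3],
               rec$left[(m - 12 * fs):(m + 30 * fs - 1)])
  # marker 5 s from start -> truncated
  rec2 <- cbfv_recording(rnorm(n, 100), rnorm(n, 100), fs,
                         markers = c(5 * fs, 20 * fs))
  ep2 <- epochize(normalise(reject_extreme_samples(rec2)))
  expect_false(ep2$kept[1])
  expect_equal(ep2$reasons[1], "truncated")
  expect_error(epochize(cbfv_recording(1:10, 1:10, 25, integer())),
               "no trial markers")
})

test_that("baseline correction zeroes the pre-stimulus window per side", {
  ep <- make_flat_epochs(n_trials = 5, noise_sd = 2, seed = 54)
  ep$baseline_corrected <- FALSE
  bc <- baseline_correct(ep)
  sel <- bc$time_axis >= -10 & bc$time_axis < 0
  for (i in 1:5) for (ch in 1:2)
    expect_lt(abs(mean(bc$epochs[sel, ch, i])), 1e-10)
  # flat epoch at 100%: all zeros after correction
  flat <- make_flat_epochs(n_trials = 2, noise_sd = 0)
  flat$epochs[] <- 100
  expect_true(all(baseline_correct(flat)$epochs == 0))
  # arithmetic: baseline 102, POI 105 -> POI reads 3
  a <- make_flat_epochs(n_trials = 1, noise_sd = 0)
  a$epochs[] <- 102
  poi_sel <- a$time_axis >= 7 & a$time_axis < 17
  a$epochs[poi_sel, "left", 1] <- 105
  ac <- baseline_correct(a)
  expect_equal(unique(ac$epochs[poi_sel, "left", 1]), 3)
  expect_error(baseline_correct(ep, baseline = c(-20, -15)), "baseline")
})

test_that("trial rejection flags out-of-band trials with reasons", {
  ep <- make_flat_epochs(n_trials = 15, noise_sd = 0)
  ep$raw[] <- 100
  # craft exactly 4 violating trials
  ep$raw[5, "left", 2] <- 55    # dip -> low-signal
  ep$raw[9, "right", 6] <- 30
  ep$raw[100, "left", 9] <- 150  # spike -> high-signal
  ep$raw[3, "right", 14] <- 141
  rj <- reject_trials(ep)
  expect_equal(sum(rj$kept), 11)
  expect_equal(rj$reasons[2], "low-signal")
  expect_equal(rj$reasons[9], "high-signal")
  # all trials within [80, 120]: none rejected at default bounds
  ep2 <- make_flat_epochs(n_trials = 6, noise_sd = 0)
  ep2$raw[] <- 100
  ep2$raw[1, , ] <- 81; ep2$raw[2, , ] <- 119
  expect_true(all(reject_trials(ep2)$kept))
  # the literal upper bound of 100 is selectable and rejects those trials
  expect_false(any(reject_trials(ep2, high_pct = 100)$kept))
})

test_that("participant exclusion uses the strict >20% rule", {
  expect_false(participant_exclusion(c(3, 15))$excluded)
  expect_true(participant_exclusion(c(4, 15))$excluded)
  expect_equal(participant_exclusion(c(0, 15))$threshold, 3)
  expect_false(participant_exclusion(c(0, 1))$excluded)
  ep <- make_flat_epochs(n_trials = 10)
  ep$kept[1:3] <- FALSE
  out <- participant_exclusion(ep)
  expect_true(out$excluded)       # 3 of 10 > floor(2)
  expect_equal(out$threshold, 2)
})

test_that("epoch averaging matches hand arithmetic", {
  ep <- make_flat_epochs(n_trials = 3, noise_sd = 1, seed = 55)
  av <- average_epochs(ep)
  expect_equal(av$left, rowMeans(ep$epochs[, "left", ]))
  expect_equal(av$diff, av$left - av$right)
  # two identical trials average to either
  ep2 <- make_flat_epochs(n_trials = 2, noise_sd = 0)
  ep2$epochs[, , 1] <- ep2$epochs[, , 2] <- matrix(rnorm(2 * 1050), ncol = 2)
  expect_equal(average_epochs(ep2)$left, ep2$epochs[, "left", 1])
  # symmetric left/right -> zero difference trace
  ep3 <- make_flat_epochs(n_trials = 2, noise_sd = 0)
  ep3$epochs[, "right", ] <- ep3$epochs[, "left", ]
  expect_true(all(average_epochs(ep3)$diff == 0))
  ep$kept[] <- FALSE
  expect_error(average_epochs(ep), "zero kept trials")
})

test_that("interaction model recovers injected lateralisation", {
  ep <- make_flat_epochs(n_trials = 8, delta = 6, noise_sd = 1, seed = 56)
  fit <- li_ftcd(ep)
  expect_gt(fit$estimate, 0)
  expect_true(fit$ci_low <= 6 && fit$ci_high >= 6)
  expect_equal(fit$ci_low, fit$estimate - 1.96 * fit$se)
  expect_equal(fit$n_trials_used, 8)
  # swapping channels negates the LI exactly, |se| unchanged
  sw <- ep
  sw$epochs <- ep$epochs[, c(2, 1), , drop = FALSE]
  dimnames(sw$epochs)[[2]] <- c("left", "right")
  fsw <- li_ftcd(sw)
  expect_equal(fsw$estimate, -fit$estimate)
  expect_equal(fsw$se, fit$se)
  # POI covering the whole epoch is rank-deficient
  expect_error(li_ftcd(ep, poi = c(-12, 30)), "rank-deficient")
})

test_that("interaction model agrees with an independent penalised fit", {
  # dual-route check: mgcv with the same fixed terms and a penalised smooth
  ep <- make_flat_epochs(n_trials = 6, delta = 4, noise_sd = 1, seed = 57)
  fit <- li_ftcd(ep)
  ta <- ep$time_axis
  k <- seq_len(6)
  nt <- length(ta)
  dat <- data.frame(
    y = c(ep$epochs[, "left", ], ep$epochs[, "right", ]),
    time = rep(ta, times = 12),
    poi = rep(ta >= 7 & ta < 17, times = 12),
    side = factor(rep(c("left", "right"), each = nt * 6),
                  levels = c("right", "left")),
    epoch = factor(rep(rep(k, each = nt), times = 2)))
  g <- mgcv::gam(y ~ s(time) + side + poi + epoch + side:poi, data = dat)
  expect_equal(unname(fit$estimate),
               unname(coef(g)[["sideleft:poiTRUE"]]), tolerance = 0.02)
})

test_that("model reduces to the subtraction LI in the flat limit", {
  # epochs constant inside and outside the POI: the interaction equals
  # mean(L - R in POI) - mean(L - R outside POI)
  ep <- make_flat_epochs(n_trials = 4, noise_sd = 0)
  ep$epochs[] <- 0
  poi_sel <- ep$time_axis >= 7 & ep$time_axis < 17
  ep$epochs[poi_sel, "left", ] <- 5
  ep$epochs[!poi_sel, "left", ] <- 1
  ep$epochs[poi_sel, "right", ] <- 2
  ep$epochs[!poi_sel, "right", ] <- 0.5
  fit <- li_ftcd(ep)
  oracle <- (5 - 2) - (1 - 0.5)
  expect_equal(fit$estimate, oracle, tolerance = 1e-6)
  expect_equal(latmirror:::subtraction_li(ep, c(7, 17)), oracle)
})

test_that("baseline correction leaves the interaction estimate unchanged", {
  ep <- make_flat_epochs(n_trials = 6, delta = 3, noise_sd = 1, seed = 58)
  ep$baseline_corrected <- TRUE
  f1 <- li_ftcd(ep)
  ep2 <- baseline_correct(ep)
  f2 <- li_ftcd(ep2)
  # per-(trial, side) constants cancel in the POI-vs-rest contrast
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-8)
})

test_that("display scaling by 6 maps an LI of 6 to 1 and keeps categories", {
  ep <- make_flat_epochs(n_trials = 6, delta = 6, noise_sd = 0.5, seed = 59)
  fit <- li_ftcd(ep)
  sc <- scale_li(fit, 6)
  expect_equal(sc$estimate, fit$estimate / 6)
  expect_equal(sc$se, fit$se / 6)
  expect_identical(scale_li(fit, 1)$estimate, fit$estimate)
  set.seed(60)
  for (i in 1:50) {
    lo <- rnorm(1); hi <- lo + abs(rnorm(1))
    expect_equal(categorise(lo / 6, hi / 6), categorise(lo, hi))
  }
})

test_that("the preprocessing orchestrator enforces the stage order", {
  syn <- synth_cbfv(n_trials = 3, fs = 100, seed = 61)
  rec <- syn$recording
  expect_error(normalise(heart_cycle_integrate(downsample(rec))),
               "order violation")
  nm <- normalise(reject_extreme_samples(downsample(rec)))
  expect_error(downsample(nm), "order violation")
  expect_error(reject_extreme_samples(nm), "order violation")
  # the canonical order runs clean end to end
  ep <- ftcd_preprocess(syn$recording)
  expect_s3_class(ep, "cbfv_epochs")
  expect_true(ep$baseline_corrected)
})
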