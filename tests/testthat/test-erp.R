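# small epoch_set builders ---------------------------------------------------

blank_epochs <- function(n_ch = 4, srate = 256, tmin = -0.1, tmax = 0.5,
                         n_tr = 3, fill = 0) {
  times <- epoch_times(srate, tmin, tmax)
  epoch_set(array(fill, c(n_ch, length(times), n_tr)), times,
            sprintf("E%02d", seq_len(n_ch)), srate)
}

noise_epochs <- function(n_ch = 4, n_tr = 3, seed = 1, srate = 256) {
  ep <- blank_epochs(n_ch, srate = srate, n_tr = n_tr)
  set.seed(seed)
  ep$data <- array(rnorm(length(ep$data), sd = 5), dim(ep$data))
  ep
}

test_that("band-pass preserves the passband and rejects stopband and DC", {
  srate <- 1024
  times <- epoch_times(srate, -0.1, 0.5)
  probe <- function(f_hz) {
    x <- sin(2 * pi * f_hz * times / 1000)
    ep <- epoch_set(array(x, c(1, length(x), 1)), times, "E01", srate)
    y <- bandpass_epochs(ep, 0.1, 30)$data[1, , 1]
    mid <- which(times > 50 & times < 350)
    sd(y[mid]) / sd(x[mid])
  }
  # independent frequency-domain oracle: H(f) from the coefficients directly;
  # zero-phase application squares the magnitude response
  bf <- signal::butter(4, c(0.1, 30) / (srate / 2), type = "pass")
  H2 <- function(f_hz) {
    w <- 2 * pi * f_hz / srate
    k <- seq_along(bf$b) - 1
    Mod(sum(bf$b * exp(-1i * w * k)) / sum(bf$a * exp(-1i * w * k)))^2
  }
  for (f in c(5, 10, 20)) {
    expect_equal(probe(f), H2(f), tolerance = 0.05,
                 label = sprintf("passband %g Hz", f))
  }
  expect_gt(probe(10), 0.9)                    # passband within 10%
  expect_lt(probe(50), 10^(-20 / 20))          # >= 20 dB at 50 Hz
  expect_equal(probe(50), H2(50), tolerance = 0.02)
  # constant (DC) input is fully removed
  ep <- blank_epochs(fill = 7)
  expect_lt(max(abs(bandpass_epochs(ep)$data)), 1e-9)
  expect_error(bandpass_epochs(blank_epochs(srate = 50), 0.1, 30), "Nyquist")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- blank_epochs(fill = 5)
  out <- baseline_correct(ep)
  expect_lt(max(abs(out$data)), 1e-12)

  ep2 <- noise_epochs(seed = 2)
  out2 <- baseline_correct(ep2)
  idx <- which(out2$times_ms >= -100 & out2$times_ms <= 0)
  bl <- apply(out2$data[, idx, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # already-corrected data are unchanged
  out3 <- baseline_correct(out2)
  expect_equal(out3$data, out2$data, tolerance = 1e-12)
  expect_error(baseline_correct(ep2, c(-500, 0)), "outside")
})

test_that("common-average referencing zeroes the instantaneous channel mean", {
  ep <- noise_epochs(n_ch = 6, seed = 3)
  out <- rereference_car(ep)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  expect_equal(rereference_car(out)$data, out$data, tolerance = 1e-12)
  # identical channels cancel entirely
  ep2 <- blank_epochs(n_ch = 3)
  ep2$data[] <- rep(rnorm(dim(ep2$data)[2] * dim(ep2$data)[3]), each = 3)
  expect_lt(max(abs(rereference_car(ep2)$data)), 1e-12)
  ep1 <- blank_epochs(n_ch = 1)
  expect_error(rereference_car(ep1), "2 channels")
})

test_that("baseline correction and re-referencing commute", {
  ep <- noise_epochs(n_ch = 5, n_tr = 4, seed = 4)
  a <- rereference_car(baseline_correct(ep))
  b <- baseline_correct(rereference_car(ep))
  expect_equal(a$data, b$data, tolerance = 1e-10)
})

test_that("voltage rejection applies the strict +/-100 uV rule in 0-500 ms", {
  ep <- blank_epochs(n_tr = 4)
  t200 <- which.min(abs(ep$times_ms - 200))
  ep$data[2, t200, 1] <- 150    # blink-like deflection -> rejected
  ep$data[3, t200, 2] <- 99     # under the limit -> retained
  ep$data[1, t200, 3] <- 100    # exactly at the limit -> retained (strict >)
  ep$data[1, 2, 4] <- 500       # outside the scan window (pre-stimulus)
  out <- reject_epochs(ep)
  expect_equal(dim(out$data)[3], 3L)
  expect_equal(attr(out, "n_rejected"), 1L)
  log <- attr(out, "rejection_log")
  expect_equal(log$trial, 1L)
  expect_equal(log$channel, "E02")
  # all trials bad is an error
  ep_bad <- blank_epochs(n_tr = 2)
  ep_bad$data[1, t200, ] <- 200
  expect_error(reject_epochs(ep_bad), "unusable")
})

test_that("planted artifacts are rejected at their generating rate", {
  mdl <- simple_erp_model(noise_sd_uv = 3, n_extra = 0)
  mdl$artifact_rate <- 0.1
  ep <- generate_erp_epochs("P01", "EA", 100, mdl, n_trials = 400, seed = 12,
                            srate = 256, tmin = -0.1, tmax = 0.5)
  out <- reject_epochs(ep)
  frac <- attr(out, "n_rejected") / 400
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 400) + 0.01)
})

test_that("spherical-spline interpolation recovers a smooth scalp field", {
  mont <- synthetic_montage(n_extra = 16)
  ep <- blank_epochs(n_ch = nrow(mont), n_tr = 2)
  ep$channels <- mont$channel
  dimnames(ep$data) <- NULL
  # smooth field: first-order harmonic of position, constant in time
  field <- 1.5 + 2 * mont$x + mont$y - 0.5 * mont$z
  ep$data[] <- field
  out <- interpolate_bad_channels(ep, bad = "LOT3", montage = mont)
  i <- match("LOT3", mont$channel)
  err <- abs(out$data[i, 1, 1] - field[i])
  expect_lt(err, 0.1 * sd(field))
  # good channels untouched
  expect_equal(out$data[-i, , ], ep$data[-i, , ], tolerance = 1e-12)
  # empty bad list is the identity
  expect_identical(interpolate_bad_channels(ep, character(0), mont), ep)
  # re-interpolating the same channel is stable
  out2 <- interpolate_bad_channels(out, bad = "LOT3", montage = mont)
  expect_equal(out2$data, out$data, tolerance = 1e-9)
  expect_error(interpolate_bad_channels(ep, mont$channel[1:9], mont), "25%")
})

test_that("condition averaging is the trial mean with the expected convergence", {
  ep <- blank_epochs(n_tr = 1)
  ep$data[1, 10, 1] <- 3
  avg <- condition_average(ep)
  expect_equal(unname(avg$data[1, 10]), 3)
  expect_equal(avg$n_trials, 1L)
  # opposite-sign trials cancel
  ep2 <- blank_epochs(n_tr = 2)
  ep2$data[, , 1] <- 2
  ep2$data[, , 2] <- -2
  expect_lt(max(abs(condition_average(ep2)$data)), 1e-12)
  # error of the mean shrinks like n^{-1/2}
  est_err <- function(n_tr, seed) {
    set.seed(seed)
    ep <- blank_epochs(n_ch = 1, n_tr = n_tr)
    ep$data[] <- 2 + rnorm(length(ep$data))
    condition_average(ep)$data[1, 20] - 2
  }
  e16 <- sd(vapply(1:40, function(s) est_err(16, s), numeric(1)))
  e256 <- sd(vapply(1:40, function(s) est_err(256, 100 + s), numeric(1)))
  expect_gt(e16 / e256, 2)    # expect ~4
  expect_lt(e16 / e256, 8)
})

test_that("self-contrasts are degenerate at every sample", {
  mdl <- simple_erp_model(noise_sd_uv = 1, n_extra = 0)
  coh <- generate_erp_cohort(3, mdl, seed = 5, levels = 20, n_trials = 4,
                             srate = 256, tmin = -0.1, tmax = 0.5)
  erps <- lapply(coh, condition_average)
  # duplicate the EA condition under the WE label: identical data
  erps_dup <- lapply(erps[vapply(erps, function(e) e$race == "EA", TRUE)],
                     function(e) { e$race <- "WE"; e })
  bfts <- cluster_bf_scan(c(erps[vapply(erps, function(e) e$race == "EA", TRUE)],
                            erps_dup),
                          attr(mdl$montage, "clusters")$LH,
                          list(a = "EA", b = "WE", coherence = 20))
  expect_true(all(is.na(bfts$bf10)))
  expect_true(all(bfts$time_ms >= 0 & bfts$time_ms <= 420))
})

test_that("an injected race effect is localized in time by the cluster scan", {
  mont <- synthetic_montage(n_extra = 8)
  mdl <- erp_model(montage = mont, noise_sd_uv = 1.5, lat_sd_ms = 0,
                   race_effects = list(
                     race_effect(c(150, 190), -0.5, 0.5, 20, hemis = "RH")))
  coh <- generate_erp_cohort(36, mdl, seed = 41, levels = 20, n_trials = 16,
                             srate = 256, tmin = -0.1, tmax = 0.5)
  erps <- preprocess_cohort(coh)
  bfts <- cluster_bf_scan(erps, attr(mont, "clusters")$RH,
                          list(a = "EA", b = "WE", coherence = 20))
  t_max <- bfts$time_ms[which.max(bfts$bf10)]
  expect_gte(t_max, 140)
  expect_lte(t_max, 200)
  # the EA condition is more negative inside the window
  mid <- bfts$time_ms >= 160 & bfts$time_ms <= 180
  expect_lt(mean(bfts$mean_diff_uv[mid]), 0)
})

test_that("face-structure contrast peaks at the occipito-temporal clusters", {
  mdl <- simple_erp_model(noise_sd_uv = 0, n_extra = 8)
  pe <- list(amp_scale = 1, lat_shift = 0, effect_delta = numeric(0))
  avg_at <- function(coh) {
    condition_average(generate_erp_epochs("P01", "EA", coh, mdl, n_trials = 1,
                                          seed = 1, part_effects = pe,
                                          srate = 256, tmin = -0.1,
                                          tmax = 0.5))
  }
  d <- avg_at(100)$data - avg_at(10)$data
  idx <- which(avg_at(100)$times_ms >= 130 & avg_at(100)$times_ms <= 210)
  peak_ch <- mdl$montage$channel[which.max(abs(rowMeans(d[, idx])))]
  expect_true(peak_ch %in% c(sprintf("LOT%d", 1:8), sprintf("ROT%d", 1:8)))
})

test_that("evidence windows report exact run statistics on a hand-built series", {
  bfts <- tibble::tibble(
    time_ms = seq(0, 90, by = 10),
    bf10 = c(1, 12, 15, 1, 1, 20, 25, 30, 0.2, 1),
    mean_diff_uv = c(0, -1, -1, 0, 0, 1, 1, 1, 0.5, 0))
  w <- extract_windows(bfts)
  alt <- w[w$kind == "alternative", ]
  expect_equal(nrow(alt), 2L)
  expect_equal(alt$onset_ms, c(10, 50))
  expect_equal(alt$offset_ms, c(20, 70))
  expect_equal(alt$mean_bf, c(13.5, 25))
  expect_equal(alt$max_bf, c(15, 30))
  expect_equal(alt$t_max_ms, c(20, 70))
  expect_equal(alt$direction, c(-1, 1))
  nul <- w[w$kind == "null", ]
  expect_equal(nrow(nul), 1L)
  expect_equal(nul$onset_ms, 80)
  expect_equal(nul$offset_ms, 80)   # single-sample window: onset = offset
  # a flat series yields no windows at all
  flat <- tibble::tibble(time_ms = 0:10, bf10 = rep(1, 11))
  expect_equal(nrow(extract_windows(flat)), 0L)
  # single sample above threshold
  one <- tibble::tibble(time_ms = c(0, 10, 20), bf10 = c(1, 11, 1))
  w1 <- extract_windows(one)
  expect_equal(w1$onset_ms, w1$offset_ms)
})

test_that("topographies localize effects and flag identical conditions", {
  set.seed(31)
  times <- epoch_times(256, -0.1, 0.4)
  chans <- sprintf("E%02d", 1:6)
  win <- times >= 150 & times <= 190
  mk_erp <- function(p, race, bump) {
    base <- matrix(rnorm(6 * length(times), sd = 0.2), 6, length(times))
    if (bump) base[c(2, 5), win] <- base[c(2, 5), win] + 1
    structure(list(data = `dimnames<-`(base, list(chans, NULL)),
                   times_ms = times, channels = chans, srate = 256,
                   n_trials = 10L, participant = p, race = race,
                   coherence = 20), class = "erp_average")
  }
  erps <- c(lapply(1:10, function(p) mk_erp(p, "EA", TRUE)),
            lapply(1:10, function(p) mk_erp(p, "WE", FALSE)))
  topo <- bf_topomap(erps, list(a = "EA", b = "WE", coherence = 20),
                     c(150, 190))
  top2 <- topo$channel[order(-topo$bf10)][1:2]
  expect_setequal(top2, c("E02", "E05"))
  expect_gt(min(topo$mean_diff_uv[topo$channel %in% top2]), 0.5)
  # identical conditions: zero differences, degenerate BFs
  same <- lapply(1:4, function(p) mk_erp(p, "EA", FALSE))
  dup <- lapply(same, function(e) { e$race <- "WE"; e })
  topo0 <- bf_topomap(c(same, dup), list(a = "EA", b = "WE", coherence = 20),
                      c(150, 190))
  expect_true(all(topo0$mean_diff_uv == 0))
  expect_true(all(is.na(topo0$bf10)))
})

test_that("epoch sets survive RDS and CSV round trips", {
  ep <- noise_epochs(n_ch = 3, n_tr = 2, seed = 9)
  ep$participant <- "P01"; ep$race <- "EA"; ep$coherence <- 20
  p1 <- withr::local_tempfile(fileext = ".rds")
  write_epoch_set(ep, p1)
  expect_equal(read_epoch_set(p1), ep)
  d1 <- withr::local_tempdir()
  write_epoch_set(ep, d1, format = "csv")
  back <- read_epoch_set(d1, format = "csv")
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_identical(back$channels, ep$channels)
  expect_equal(back$coherence, 20)
})
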