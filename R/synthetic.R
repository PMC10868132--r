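#' Behavioral generative model for race-in-noise sessions
#'
#' Describes how a simulated participant categorizes face race as a function
#' of phase coherence. On each trial the participant lapses with probability
#' \code{lapse}; otherwise they perceive the race with probability
#' \eqn{\pi_r(c) = \mathrm{logistic}(k_r (c - c50_r))} and respond correctly;
#' on lapse or non-perception they guess, responding "WE" with probability
#' \code{guess_bias_we}. The EA threshold \code{c50_ea} sits below
#' \code{c50_we}, producing an other-race categorization advantage that
#' emerges at the 20\% coherence level. Reaction times are shifted lognormal,
#' decreasing in coherence, with an ORCA speed-up \code{orca_shift_ms}
#' applied to EA trials from \code{orca_onset} upward. Default parameter
#' values are tuned so the closed-form condition means emulate the published
#' group means of the paradigm (e.g. EA/WE accuracy 0.83/0.70 near 20\%
#' coherence, chance with a WE guessing bias at 10\%).
#'
#' @param levels coherence levels in percent.
#' @param k_ea,c50_ea,k_we,c50_we logistic slope/threshold per race
#'   (coherence in percent).
#' @param guess_bias_we probability of a "WE" response when guessing.
#' @param lapse attention-lapse probability (lapses always guess).
#' @param rt_floor_ms lognormal shift (non-decision floor).
#' @param rt_base_10_ms mean RT at 10\% coherence for WE faces.
#' @param rt_slope_ms decrease in mean RT per coherence point.
#' @param rt_sdlog lognormal sigma of trial RT.
#' @param orca_onset coherence level (percent) from which the EA speed
#'   advantage applies; below it the shift is exactly 0.
#' @param orca_shift_ms named vector of EA RT advantages (ms) by level.
#' @param sd_part_rt_ms between-participant SD of the RT intercept.
#' @param sd_part_orca_ms between-participant SD of the ORCA shift.
#' @param sd_part_c50 between-participant SD of both race thresholds.
#' @param outlier_rate probability a trial's RT is replaced by an
#'   out-of-range value (planted violations of the 100--2000 ms band).
#' @return a \code{behavior_model} object (a parameter list).
#' @export
behavior_model <- function(levels = c(10, 20, 30, 40, 50, 60, 100),
                           k_ea = 0.45, c50_ea = 18.1,
                           k_we = 0.143, c50_we = 26,
                           guess_bias_we = 0.58, lapse = 0.03,
                           rt_floor_ms = 250,
                           rt_base_10_ms = 850, rt_slope_ms = 1.9,
                           rt_sdlog = 0.35,
                           orca_onset = 20,
                           orca_shift_ms = c("20" = 55, "30" = 90, "40" = 60,
                                             "50" = 75, "60" = 45, "100" = 0),
                           sd_part_rt_ms = 60, sd_part_orca_ms = 35,
                           sd_part_c50 = 2, outlier_rate = 0) {
  stopifnot(all(levels > 0 & levels <= 100), !is.unsorted(levels))
  structure(as.list(environment()), class = "behavior_model")
}

orca_shift_at <- function(model, coherence) {
  if (coherence < model$orca_onset) return(0)
  s <- model$orca_shift_ms[as.character(coherence)]
  if (is.na(s)) 0 else unname(s)
}

#' Closed-form cell probabilities of a behavior model
#'
#' @param model a [behavior_model()].
#' @param race "EA" or "WE".
#' @param coherence level in percent.
#' @param c50_shift participant threshold deviation (0 for the population
#'   curve).
#' @return expected accuracy of the cell.
#' @export
model_accuracy <- function(model, race, coherence, c50_shift = 0) {
  c50 <- if (race == "EA") model$c50_ea else model$c50_we
  k <- if (race == "EA") model$k_ea else model$k_we
  p_perc <- (1 - model$lapse) * stats::plogis(k * (coherence - (c50 + c50_shift)))
  g <- if (race == "WE") model$guess_bias_we else 1 - model$guess_bias_we
  p_perc + (1 - p_perc) * g
}

#' @rdname model_accuracy
#' @return \code{model_mean_rt}: expected mean RT (ms) of the cell.
#' @export
model_mean_rt <- function(model, race, coherence) {
  m <- model$rt_base_10_ms - model$rt_slope_ms * (coherence - 10)
  if (race == "EA") m <- m - orca_shift_at(model, coherence)
  m
}

#' Simulate one behavioral session
#'
#' Generates exactly 60 trials per race x coherence cell (840 in total under
#' the default 2 x 7 design), in shuffled order, with responses and RTs drawn
#' from the behavior model plus participant-level random effects derived
#' deterministically from the seed. The generating parameters (including the
#' participant's realized random effects) are attached as the
#' \code{ground_truth} attribute.
#'
#' @param participant participant id.
#' @param seed integer seed.
#' @param model a [behavior_model()].
#' @param n_per_cell trials per race x coherence cell.
#' @return tibble of trials in the schema of [validate_trials()].
#' @export
generate_session <- function(participant, seed, model = behavior_model(),
                             n_per_cell = 60) {
  with_private_seed(seed, function() {
    part_rt <- stats::rnorm(1, 0, model$sd_part_rt_ms)
    part_orca <- stats::rnorm(1, 0, model$sd_part_orca_ms)
    part_c50 <- stats::rnorm(1, 0, model$sd_part_c50)
    cells <- expand.grid(race = c("EA", "WE"), coherence = model$levels,
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      race <- cells$race[i]; lev <- cells$coherence[i]
      acc_p <- model_accuracy(model, race, lev, part_c50)
      correct <- stats::runif(n_per_cell) < acc_p
      response <- ifelse(correct, race, setdiff(c("EA", "WE"), race))
      m <- model$rt_base_10_ms + part_rt -
        model$rt_slope_ms * (lev - 10)
      if (race == "EA") {
        sh <- orca_shift_at(model, lev)
        if (sh != 0) m <- m - (sh + part_orca)
      }
      m <- max(m, model$rt_floor_ms + 50)
      mu <- log(m - model$rt_floor_ms) - model$rt_sdlog^2 / 2
      rt <- model$rt_floor_ms + stats::rlnorm(n_per_cell, mu, model$rt_sdlog)
      if (model$outlier_rate > 0) {
        out <- stats::runif(n_per_cell) < model$outlier_rate
        n_out <- sum(out)
        if (n_out) {
          rt[out] <- ifelse(stats::runif(n_out) < 0.5,
                            stats::runif(n_out, 20, 99),
                            stats::runif(n_out, 2001, 3500))
        }
      }
      tibble::tibble(participant = participant, race = race, coherence = lev,
                     response = response, correct = correct, rt_ms = rt)
    })
    trials <- dplyr::bind_rows(rows)
    trials <- trials[sample.int(nrow(trials)), ]
    attr(trials, "ground_truth") <- list(
      model = unclass(model), seed = seed,
      participant_effects = c(rt_intercept = part_rt, orca_dev = part_orca,
                              c50_shift = part_c50))
    trials
  })
}

#' Simulate a behavioral cohort
#'
#' @param n_participants cohort size (the study analyzed 36).
#' @param seed integer base seed; participant seeds are derived from it.
#' @param model a [behavior_model()].
#' @param n_per_cell trials per cell.
#' @return tibble of all trials, participants labelled \code{P01, P02, ...}.
#' @export
generate_behavior_cohort <- function(n_participants = 36, seed = 1L,
                                     model = behavior_model(),
                                     n_per_cell = 60) {
  dplyr::bind_rows(lapply(seq_len(n_participants), function(i) {
    generate_session(sprintf("P%02d", i), (seed + 7919 * i) %% 2147483647,
                     model = model, n_per_cell = n_per_cell)
  }))
}

#' Synthetic EEG montage
#'
#' A labelled montage on the unit sphere with designated left and right
#' occipito-temporal clusters of eight sensors each (the face-sensitive
#' regions the cluster scans average over) plus a configurable number of
#' additional sensors spread over the upper head.
#'
#' @param n_extra number of non-cluster channels (>= 0).
#' @return tibble with \code{channel, x, y, z, cluster} (+x right, +y front,
#'   +z up); attribute \code{clusters} holds the two [electrode_cluster()]s.
#' @export
synthetic_montage <- function(n_extra = 16) {
  ring <- function(center, labels, radius = 0.28) {
    center <- center / sqrt(sum(center^2))
    # orthonormal tangent basis at the center
    u <- c(-center[2], center[1], 0); u <- u / sqrt(sum(u^2))
    v <- c(center[2] * u[3] - center[3] * u[2],
           center[3] * u[1] - center[1] * u[3],
           center[1] * u[2] - center[2] * u[1])
    ang <- seq(0, 2 * pi, length.out = length(labels) + 1L)[-1L]
    p <- t(vapply(ang, function(a) {
      q <- center + radius * (cos(a) * u + sin(a) * v)
      q / sqrt(sum(q^2))
    }, numeric(3)))
    tibble::tibble(channel = labels, x = p[, 1], y = p[, 2], z = p[, 3])
  }
  lot <- ring(c(-0.66, -0.66, 0.35), sprintf("LOT%d", 1:8))
  rot <- ring(c(0.66, -0.66, 0.35), sprintf("ROT%d", 1:8))
  extra <- if (n_extra > 0) {
    # Fibonacci spread over the upper head, kept clear of the two
    # occipito-temporal foci so the clusters stay the face-sensitive maxima
    i <- seq_len(4L * n_extra + 16L)
    zs <- 0.15 + 0.8 * (i - 0.5) / max(i)
    az <- pi * (1 + sqrt(5)) * i
    pts <- cbind(sqrt(1 - zs^2) * cos(az), sqrt(1 - zs^2) * sin(az), zs)
    foci <- rbind(c(-0.66, -0.66, 0.35), c(0.66, -0.66, 0.35))
    foci <- foci / sqrt(rowSums(foci^2))
    ang_min <- apply(acos(pmin(pmax(pts %*% t(foci), -1), 1)), 1, min)
    pts <- pts[ang_min > 0.55, , drop = FALSE][seq_len(n_extra), , drop = FALSE]
    tibble::tibble(channel = sprintf("CH%02d", seq_len(n_extra)),
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  } else NULL
  m <- dplyr::bind_rows(
    dplyr::mutate(lot, cluster = "LH"),
    dplyr::mutate(rot, cluster = "RH"),
    if (!is.null(extra)) dplyr::mutate(extra, cluster = NA_character_))
  attr(m, "clusters") <- list(
    LH = electrode_cluster("LH", lot$channel),
    RH = electrode_cluster("RH", rot$channel))
  m
}

#' ERP component description
#'
#' @param name component label.
#' @param polarity +1 or -1.
#' @param latency_ms peak latency.
#' @param width_ms Gaussian temporal SD.
#' @param amplitude_uv peak amplitude at full structure (100\% coherence).
#' @param center direction (length-3) of the scalp focus; channel weights
#'   fall off with angular distance (\code{spread}).
#' @param spread angular falloff SD in radians.
#' @param bilateral if TRUE the mirrored focus (x -> -x) is added.
#' @export
erp_component <- function(name, polarity, latency_ms, width_ms, amplitude_uv,
                          center, spread = 0.6, bilateral = TRUE) {
  stopifnot(width_ms > 0, polarity %in% c(-1, 1))
  structure(list(name = name, polarity = polarity, latency_ms = latency_ms,
                 width_ms = width_ms, amplitude_uv = amplitude_uv,
                 center = center / sqrt(sum(center^2)), spread = spread,
                 bilateral = bilateral),
            class = "erp_component")
}

#' Race-effect injection description
#'
#' An additive voltage difference applied to one race's epochs on the
#' channels of one or both clusters, within a time window, at the listed
#' coherence levels. The temporal profile is a flat-topped window with
#' raised-cosine ramps. Per participant the injected amplitude is
#' \code{delta_uv + N(0, sd_uv)}, so \code{delta_uv / sd_uv} is the planted
#' between-participant standardized effect size (attenuated slightly by
#' trial noise in the measured contrast).
#'
#' @param window c(onset, offset) in ms.
#' @param delta_uv mean injected amplitude (negative = more negative voltage
#'   for the target race).
#' @param sd_uv between-participant SD of the amplitude.
#' @param levels coherence levels (percent) at which the effect is present.
#' @param race which race condition receives the injection.
#' @param hemis clusters carrying it ("LH", "RH" or both).
#' @param ramp_frac fraction of the window used by each cosine ramp.
#' @export
race_effect <- function(window, delta_uv, sd_uv, levels, race = "EA",
                        hemis = c("LH", "RH"), ramp_frac = 0.2) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  structure(list(window = window, delta_uv = delta_uv, sd_uv = sd_uv,
                 levels = levels, race = race, hemis = hemis,
                 ramp_frac = ramp_frac),
            class = "race_effect")
}

default_erp_components <- function() {
  occ <- c(0, -0.95, 0.3)
  ot_l <- c(-0.66, -0.66, 0.35)
  list(
    erp_component("P1", +1, 94, 18, 4.0, occ, spread = 0.7, bilateral = FALSE),
    erp_component("N170", -1, 165, 15, 6.0, ot_l, spread = 0.5),
    erp_component("N250", -1, 290, 30, 3.0, ot_l, spread = 0.55))
}

default_race_effects <- function() {
  list(
    race_effect(c(158, 186), -0.8, 1.0, 20),                      # late N170, EA
    race_effect(c(260, 330), -1.0, 1.0, c(30, 40)),               # N250, EA
    race_effect(c(265, 295), -0.7, 0.9, c(50, 60), hemis = "RH"), # N250, EA, RH
    race_effect(c(88, 98), +0.6, 0.8, 60, hemis = "RH"),          # P1, EA
    race_effect(c(80, 97), +0.8, 0.9, 100, hemis = "LH"),         # P1, EA
    race_effect(c(145, 150), -0.5, 0.7, 100, race = "WE", hemis = "RH"),
    race_effect(c(330, 348), -0.6, 0.8, 100, race = "WE", hemis = "LH"))
}

#' ERP generative model
#'
#' Defines the synthetic EEG cohort: a montage with designated LH/RH
#' clusters, P1/N170/N250 components whose amplitudes scale linearly with
#' structure (gain 0 at 10\% coherence, 1 at 100\%, so face-evoked structure
#' vanishes at the lowest level), a schedule of race-effect injections
#' emulating the published result pattern (late-N170 EA effect at 20\%,
#' N250 EA effects at 30--60\%, P1 EA effects at 60/100\%, WE N170/N250
#' effects at 100\% — synthetic, not the study's data), and 1/f^alpha plus
#' white sensor noise with participant-level amplitude and latency
#' variability.
#'
#' @param montage a [synthetic_montage()].
#' @param components list of [erp_component()]s.
#' @param race_effects list of [race_effect()]s.
#' @param noise_sd_uv per-sample SD of the single-trial sensor noise.
#' @param alpha 1/f exponent of the colored noise component.
#' @param white_frac fraction of noise variance that is white.
#' @param amp_sdlog lognormal SD of participant component-amplitude scaling.
#' @param lat_sd_ms Gaussian SD of participant component-latency shifts
#'   (applied to base components, not to race-effect injections).
#' @param artifact_rate probability that a trial carries a planted
#'   high-voltage (~150 uV) deflection near 200 ms.
#' @export
erp_model <- function(montage = synthetic_montage(),
                      components = default_erp_components(),
                      race_effects = default_race_effects(),
                      noise_sd_uv = 10, alpha = 1, white_frac = 0.3,
                      amp_sdlog = 0.2, lat_sd_ms = 10,
                      artifact_rate = 0) {
  stopifnot(noise_sd_uv >= 0, white_frac >= 0, white_frac <= 1,
            artifact_rate >= 0, artifact_rate <= 1)
  structure(as.list(environment()), class = "erp_model")
}

structure_gain <- function(coherence) pmin(pmax((coherence - 10) / 90, 0), 1)

# channel weights of a component on a montage
component_weights <- function(comp, montage) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  ang <- acos(pmin(pmax(pos %*% comp$center, -1), 1))
  w <- exp(-ang^2 / (2 * comp$spread^2))
  if (comp$bilateral) {
    c2 <- comp$center * c(-1, 1, 1)
    ang2 <- acos(pmin(pmax(pos %*% c2, -1), 1))
    w <- pmax(w, exp(-ang2^2 / (2 * comp$spread^2)))
  }
  as.numeric(w)
}

# flat-topped window with raised-cosine ramps, peak value 1
effect_profile <- function(times_ms, window, ramp_frac) {
  len <- window[2] - window[1]
  ramp <- ramp_frac * len
  p <- numeric(length(times_ms))
  inside <- times_ms >= window[1] & times_ms <= window[2]
  tt <- times_ms[inside]
  v <- rep(1, length(tt))
  lo <- tt < window[1] + ramp
  hi <- tt > window[2] - ramp
  v[lo] <- 0.5 * (1 - cos(pi * (tt[lo] - window[1]) / ramp))
  v[hi] <- 0.5 * (1 - cos(pi * (window[2] - tt[hi]) / ramp))
  p[inside] <- v
  p
}

# n_series columns of 1/f^alpha + white noise, each scaled to sd target
onef_noise <- function(n, n_series, srate, alpha, white_frac, sd_target) {
  if (sd_target == 0) return(matrix(0, n, n_series))
  f <- (seq_len(n) - 1) / n * srate
  f[f > srate / 2] <- srate - f[f > srate / 2]  # mirrored axis
  ampl <- ifelse(f > 0, f^(-alpha / 2), 0)
  spec <- matrix(stats::rnorm(n * n_series), n, n_series) +
    1i * matrix(stats::rnorm(n * n_series), n, n_series)
  spec <- spec * ampl
  colored <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  colored <- sweep(colored, 2, apply(colored, 2, stats::sd), `/`)
  white <- matrix(stats::rnorm(n * n_series), n, n_series)
  mix <- sqrt(1 - white_frac) * colored + sqrt(white_frac) * white
  mix * sd_target
}

# participant-level random draws for an erp_model (one draw per cohort seed)
draw_participant_effects <- function(model, part_seed) {
  with_private_seed(part_seed, function() {
    list(
      amp_scale = stats::rlnorm(length(model$components), 0, model$amp_sdlog),
      lat_shift = stats::rnorm(length(model$components), 0, model$lat_sd_ms),
      effect_delta = vapply(model$race_effects, function(e) {
        e$delta_uv + stats::rnorm(1, 0, e$sd_uv)
      }, numeric(1)))
  })
}

#' Simulate epochs for one participant and condition
#'
#' @param participant id.
#' @param race,coherence condition.
#' @param model an [erp_model()].
#' @param n_trials epochs to generate.
#' @param seed condition seed (noise and artifacts).
#' @param part_effects participant draws from the cohort generator; when
#'   NULL, population values are used (no participant variability).
#' @param srate,tmin,tmax epoch geometry (defaults: the study's 1024 Hz,
#'   -100 to 1000 ms).
#' @return an [epoch_set()].
#' @export
generate_erp_epochs <- function(participant, race, coherence,
                                model = erp_model(), n_trials = 60,
                                seed = 1L, part_effects = NULL,
                                srate = 1024, tmin = -0.1, tmax = 1.0) {
  times <- epoch_times(srate, tmin, tmax)
  n_s <- length(times)
  montage <- model$montage
  n_ch <- nrow(montage)
  for (comp in model$components) {
    if (comp$latency_ms > max(times)) {
      stop(sprintf("epoch ends before component %s (%g ms)",
                   comp$name, comp$latency_ms))
    }
  }
  if (is.null(part_effects)) {
    part_effects <- list(
      amp_scale = rep(1, length(model$components)),
      lat_shift = rep(0, length(model$components)),
      effect_delta = vapply(model$race_effects, `[[`, numeric(1), "delta_uv"))
  }
  gain <- structure_gain(coherence)
  signal <- matrix(0, n_ch, n_s)
  for (i in seq_along(model$components)) {
    comp <- model$components[[i]]
    wave <- comp$polarity * comp$amplitude_uv * part_effects$amp_scale[i] *
      gain * exp(-(times - comp$latency_ms - part_effects$lat_shift[i])^2 /
                   (2 * comp$width_ms^2))
    signal <- signal + component_weights(comp, montage) %o% wave
  }
  cl <- attr(montage, "clusters")
  for (j in seq_along(model$race_effects)) {
    eff <- model$race_effects[[j]]
    if (!identical(eff$race, race)) next
    if (!any(vapply(eff$levels, function(l)
      isTRUE(all.equal(l, coherence)), TRUE))) next
    prof <- part_effects$effect_delta[j] *
      effect_profile(times, eff$window, eff$ramp_frac)
    chans <- unlist(lapply(eff$hemis, function(h) cl[[h]]$channels))
    idx <- match(chans, montage$channel)
    signal[idx, ] <- signal[idx, ] + matrix(prof, length(idx), n_s,
                                            byrow = TRUE)
  }
  data <- with_private_seed(seed, function() {
    noise <- onef_noise(n_s, n_ch * n_trials, srate, model$alpha,
                        model$white_frac, model$noise_sd_uv)
    arr <- array(0, c(n_ch, n_s, n_trials))
    k <- 0L
    for (tr in seq_len(n_trials)) {
      arr[, , tr] <- signal + t(noise[, k + seq_len(n_ch), drop = FALSE])
      k <- k + n_ch
    }
    if (model$artifact_rate > 0) {
      hit <- stats::runif(n_trials) < model$artifact_rate
      for (tr in which(hit)) {
        ch <- sample.int(n_ch, 1)
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 130, 180)
        arr[ch, , tr] <- arr[ch, , tr] +
          amp * exp(-(times - 200)^2 / (2 * 30^2))
      }
      attr(arr, "n_artifact_trials") <- sum(hit)
    }
    arr
  })
  ep <- epoch_set(data, times, montage$channel, srate,
                  participant = participant, race = race,
                  coherence = coherence)
  attr(ep, "n_artifact_trials") <- attr(ep$data, "n_artifact_trials")
  ep
}

#' Simulate an ERP cohort
#'
#' Generates epochs for every participant x race x coherence condition, with
#' participant random effects drawn once per participant (so race-effect
#' injections are consistent across that participant's conditions) and
#' independent noise per condition. Defaults mirror the study's design
#' (36 participants, 60 trials per condition, 1024 Hz, -100 to 1000 ms);
#' reduced geometries for simulation studies are set explicitly.
#'
#' @param n_participants cohort size.
#' @param model an [erp_model()].
#' @param seed integer base seed.
#' @param levels coherence levels to generate.
#' @param races race conditions.
#' @param n_trials trials per condition.
#' @param srate,tmin,tmax epoch geometry.
#' @return list of [epoch_set()]s with a \code{ground_truth} attribute (see
#'   [ground_truth_report()]).
#' @export
generate_erp_cohort <- function(n_participants = 36, model = erp_model(),
                                seed = 1L,
                                levels = c(10, 20, 30, 40, 50, 60, 100),
                                races = c("EA", "WE"), n_trials = 60,
                                srate = 1024, tmin = -0.1, tmax = 1.0) {
  out <- list()
  for (i in seq_len(n_participants)) {
    part_seed <- (seed + 7919 * i) %% 2147483647
    pe <- draw_participant_effects(model, part_seed)
    for (race in races) {
      for (lev in levels) {
        cond_seed <- (part_seed + 104729 * match(race, c("EA", "WE")) +
                        1299709 * match(lev, levels)) %% 2147483647
        out[[length(out) + 1L]] <- generate_erp_epochs(
          sprintf("P%02d", i), race, lev, model = model,
          n_trials = n_trials, seed = cond_seed, part_effects = pe,
          srate = srate, tmin = tmin, tmax = tmax)
      }
    }
  }
  attr(out, "ground_truth") <- ground_truth_report(model, seed = seed)
  out
}

#' Machine-readable generating truth of a synthetic cohort
#'
#' Emits every generating parameter — component schedule, race-effect
#' injections (window, amplitude, SD, levels, clusters), noise parameters,
#' artifact rate and the seed — for parameter-recovery scoring. Regenerating
#' with the same model and seed reproduces the identical table.
#'
#' @param model an [erp_model()] (or a cohort carrying a
#'   \code{ground_truth} attribute).
#' @param seed cohort seed to record.
#' @return a list; \code{effects} is a tibble of injections.
#' @export
ground_truth_report <- function(model, seed = NA_integer_) {
  if (!inherits(model, "erp_model") && !is.null(attr(model, "ground_truth"))) {
    return(attr(model, "ground_truth"))
  }
  stopifnot(inherits(model, "erp_model"))
  effects <- dplyr::bind_rows(lapply(model$race_effects, function(e) {
    tibble::tibble(onset_ms = e$window[1], offset_ms = e$window[2],
                   delta_uv = e$delta_uv, sd_uv = e$sd_uv,
                   race = e$race, hemis = paste(e$hemis, collapse = "+"),
                   levels = paste(e$levels, collapse = ","))
  }))
  components <- dplyr::bind_rows(lapply(model$components, function(comp) {
    tibble::tibble(name = comp$name, polarity = comp$polarity,
                   latency_ms = comp$latency_ms, width_ms = comp$width_ms,
                   amplitude_uv = comp$amplitude_uv)
  }))
  list(seed = seed, components = components, effects = effects,
       noise = list(noise_sd_uv = model$noise_sd_uv, alpha = model$alpha,
                    white_frac = model$white_frac,
                    amp_sdlog = model$amp_sdlog, lat_sd_ms = model$lat_sd_ms,
                    artifact_rate = model$artifact_rate))
}
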