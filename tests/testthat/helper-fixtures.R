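# Independent reference values for the JZS one-sample Bayes factor,
# computed with pingouin.bayesfactor_ttest (an unrelated implementation of
# the same integral; its prior scale is the rounded r = 0.707).
jzs_reference_grid <- function() {
  tibble::tibble(
    t = rep(c(0, 0.5, 1, 2, 3, 5, 10), each = 2),
    n = rep(c(10L, 36L), times = 7),
    bf10 = c(0.30882983, 0.17902579,
             0.34353370, 0.20119731,
             0.46491779, 0.28423607,
             1.28237150, 1.05946820,
             4.49780200, 7.74210160,
             52.60648700, 1326.92680000,
             5055.83480000, 1063652400))
}

# brute-force quadrature oracle on the raw g axis (pracma::quadgk in two
# pieces, no log transform) -- deliberately a different route from the
# package's log-space adaptive quadrature
jzs_bruteforce_oracle <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  f <- function(g) {
    (1 + n * g)^(-0.5) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (r^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
  }
  num <- pracma::quadgk(f, 1e-12, 1, tol = 1e-12) +
    pracma::quadgk(f, 1, 1e6, tol = 1e-12)
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# deterministic smooth test image (even dimensions, values in [0, 1])
smooth_test_image <- function(n = 32, phase = 0) {
  g <- outer(seq_len(n), seq_len(n), function(i, j) {
    0.5 + 0.2 * sin(2 * pi * i / n + phase) * cos(2 * pi * 2 * j / n) +
      0.15 * cos(2 * pi * 3 * (i + j) / n)
  })
  gray_image(g)
}

random_test_image <- function(n = 32, seed = 1, lo = 0.25, hi = 0.75) {
  set.seed(seed)
  gray_image(matrix(runif(n * n, lo, hi), n, n))
}

# minimal hand-built trial table
make_trials <- function(rt_ms, participant = "P01", race = "EA",
                        coherence = 100, correct = TRUE) {
  n <- length(rt_ms)
  race <- rep_len(race, n)
  correct <- rep_len(correct, n)
  tibble::tibble(
    participant = rep_len(participant, n), race = race,
    coherence = rep_len(coherence, n),
    response = ifelse(correct, race, ifelse(race == "EA", "WE", "EA")),
    correct = correct, rt_ms = rt_ms)
}

# trials for one participant with exact hit / false-alarm counts
# (signal race WE): n_sig WE faces with k_hit "WE" responses, n_noise EA
# faces with k_fa "WE" responses
make_sdt_trials <- function(k_hit, n_sig, k_fa, n_noise,
                            participant = "P01", coherence = 10) {
  we <- tibble::tibble(
    participant = participant, race = "WE", coherence = coherence,
    response = rep(c("WE", "EA"), c(k_hit, n_sig - k_hit)))
  ea <- tibble::tibble(
    participant = participant, race = "EA", coherence = coherence,
    response = rep(c("WE", "EA"), c(k_fa, n_noise - k_fa)))
  out <- dplyr::bind_rows(we, ea)
  out$correct <- out$response == out$race
  out$rt_ms <- 500
  out
}

# single-component noise-free ERP model on a small montage
simple_erp_model <- function(noise_sd_uv = 0, race_effects = list(),
                             n_extra = 0, amplitude_uv = 5,
                             latency_ms = 170) {
  mont <- synthetic_montage(n_extra = n_extra)
  erp_model(
    montage = mont,
    components = list(erp_component("N170", -1, latency_ms, 15, amplitude_uv,
                                    c(-0.66, -0.66, 0.35))),
    race_effects = race_effects,
    noise_sd_uv = noise_sd_uv, amp_sdlog = 0, lat_sd_ms = 0)
}
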