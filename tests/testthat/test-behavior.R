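test_that("RT filter keeps the stated bounds inclusively", {
  tr <- make_trials(c(99, 100, 500, 2000, 2001))
  kept <- suppressMessages(filter_trials(tr))
  expect_setequal(kept$rt_ms, c(100, 500, 2000))
  excl <- attr(kept, "exclusions")
  expect_equal(excl$n_excluded, 2L)
  # all in range: identity
  tr2 <- make_trials(c(150, 800, 1999))
  expect_equal(nrow(filter_trials(tr2)), 3L)
})

test_that("planted out-of-range RTs are excluded at their generating rate", {
  mdl <- behavior_model(outlier_rate = 0.05)
  trials <- generate_behavior_cohort(4, seed = 21, model = mdl)
  kept <- suppressMessages(filter_trials(trials))
  frac <- 1 - nrow(kept) / nrow(trials)
  # 4 x 840 trials: binomial 3-sigma band around 5%
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(trials)) + 0.005)
})

test_that("participant screening applies the 75% full-structure criterion at the boundary", {
  mk <- function(p, acc100) {
    tibble::tibble(participant = p, race = c("EA", "WE"),
                   coherence = 100, accuracy = acc100,
                   mean_rt_correct = 700, n_trials_accepted = 60L)
  }
  s <- dplyr::bind_rows(mk("low", 0.74), mk("edge", 0.75), mk("high", 1.0),
                        mk("chance", 0.5))
  inc <- screen_participants(s)
  expect_setequal(inc, c("edge", "high"))
  expect_setequal(attr(inc, "excluded"), c("low", "chance"))
  # missing the 100% condition is an error
  s2 <- tibble::tibble(participant = "p9", race = "EA", coherence = 60,
                       accuracy = 1, mean_rt_correct = 700,
                       n_trials_accepted = 60L)
  expect_error(screen_participants(dplyr::bind_rows(s, s2)), "p9")
})

test_that("condition summaries use accepted trials for both accuracy and RT", {
  tr <- dplyr::bind_rows(
    make_trials(c(300, 400, 500), correct = c(TRUE, TRUE, FALSE),
                race = "EA", coherence = 20),
    make_trials(c(600, 700), correct = TRUE, race = "WE", coherence = 20))
  s <- condition_summaries(tr)
  ea <- s[s$race == "EA", ]
  expect_equal(ea$accuracy, 2 / 3)
  expect_equal(ea$mean_rt_correct, 350)  # correct trials only
  expect_equal(ea$n_trials_accepted, 3L)
})

test_that("degenerate all-equal cells abort the contrast naming the cell", {
  s <- tidyr::expand_grid(participant = sprintf("P%02d", 1:6),
                          race = c("EA", "WE"), coherence = c(20, 100))
  s$accuracy <- 0.9
  s$mean_rt_correct <- 700   # EA and WE identical everywhere
  s$n_trials_accepted <- 60L
  expect_error(orca_contrasts(s), "coherence 20")
})

test_that("a null behavioral model rarely produces evidence for a race effect", {
  mdl <- behavior_model(c50_ea = 22, k_ea = 0.2, c50_we = 22, k_we = 0.2,
                        guess_bias_we = 0.5,
                        orca_shift_ms = c("20" = 0, "30" = 0, "40" = 0,
                                          "50" = 0, "60" = 0, "100" = 0))
  n_rep <- 20
  hits <- 0L; total <- 0L
  for (r in seq_len(n_rep)) {
    trials <- generate_behavior_cohort(12, seed = 1000 + r, model = mdl,
                                       n_per_cell = 20)
    s <- condition_summaries(suppressMessages(filter_trials(trials)))
    oc <- orca_contrasts(s)
    hits <- hits + sum(oc$rt_bf10 > 3) + sum(oc$acc_bf10 > 3)
    total <- total + 2L * nrow(oc)
  }
  # 280 null Bayes factors: the false-evidence rate stays small
  expect_lt(hits / total, 0.08)
})

test_that("the RT advantage is first detected at its generating onset level", {
  n_rep <- 8
  first_level <- integer(0)
  for (r in seq_len(n_rep)) {
    trials <- generate_behavior_cohort(16, seed = 3000 + r, n_per_cell = 40)
    s <- condition_summaries(suppressMessages(filter_trials(trials)))
    oc <- orca_contrasts(s)
    alt <- oc$coherence[oc$rt_evidence == "alternative"]
    first_level <- c(first_level, if (length(alt)) min(alt) else NA_integer_)
  }
  # the generator's ORCA onset is 20% coherence
  expect_gt(mean(first_level == 20, na.rm = TRUE), 0.5)
})

test_that("SDT identities and arithmetic follow the normal-quantile definitions", {
  # hit = fa = 0.5 gives d' = 0 and C = 0 exactly
  tr <- make_sdt_trials(k_hit = 10, n_sig = 20, k_fa = 10, n_noise = 20)
  r <- sdt_analysis(tr, coherence = 10)
  expect_identical(r$dprime, 0)
  expect_identical(r$criterion, 0)

  # group-level 10%-condition rates: z-transform oracle
  tr2 <- make_sdt_trials(k_hit = 289, n_sig = 500, k_fa = 279, n_noise = 500)
  r2 <- sdt_analysis(tr2, coherence = 10)
  expect_equal(r2$hit_rate, 0.578)
  expect_equal(r2$fa_rate, 0.558)
  expect_equal(r2$dprime, qnorm(0.578) - qnorm(0.558))
  expect_equal(r2$criterion, (qnorm(0.578) + qnorm(0.558)) / 2)
  expect_equal(r2$dprime, 0.051, tolerance = 0.02)  # small discriminability
  expect_gt(r2$criterion, 0)                          # bias toward WE

  # extreme rates are clamped to 1/(2N)
  tr3 <- make_sdt_trials(k_hit = 20, n_sig = 20, k_fa = 0, n_noise = 20)
  r3 <- sdt_analysis(tr3, coherence = 10)
  expect_equal(r3$hit_rate, 1 - 1 / 40)
  expect_equal(r3$fa_rate, 1 / 40)
})

test_that("swapping the signal race preserves d-prime and negates the criterion", {
  # z(1 - f) - z(1 - h) = z(h) - z(f): discriminability does not depend on
  # which race is labelled the signal; the bias direction flips sign
  tr <- make_sdt_trials(k_hit = 15, n_sig = 20, k_fa = 8, n_noise = 20)
  a <- sdt_analysis(tr, coherence = 10, signal_race = "WE")
  b <- sdt_analysis(tr, coherence = 10, signal_race = "EA")
  expect_equal(a$dprime, b$dprime)
  expect_equal(a$criterion, -b$criterion)
})

test_that("bootstrap intervals are deterministic, degenerate on constants, and calibrated", {
  s <- tidyr::expand_grid(participant = sprintf("P%02d", 1:10),
                          race = "EA", coherence = 20)
  s$accuracy <- 0.8
  s$mean_rt_correct <- 700
  s$n_trials_accepted <- 60L
  ci <- bootstrap_ci(s, "accuracy", B = 200, seed = 4)
  expect_equal(ci$lower, ci$upper)   # constant statistic: zero width
  expect_equal(ci$estimate, 0.8)

  set.seed(8)
  s$accuracy <- runif(10, 0.6, 1)
  ci1 <- bootstrap_ci(s, "accuracy", B = 300, seed = 5)
  ci2 <- bootstrap_ci(s, "accuracy", B = 300, seed = 5)
  expect_identical(ci1, ci2)
  expect_error(bootstrap_ci(s, "accuracy", B = 50), "at least 100")

  # coverage of the known mean across replicate cohorts
  covered <- vapply(seq_len(200), function(r) {
    set.seed(6000 + r)
    sr <- s
    sr$accuracy <- rnorm(10, 0.8, 0.05)
    ci <- bootstrap_ci(sr, "accuracy", B = 300, seed = r)
    ci$lower <= 0.8 && 0.8 <= ci$upper
  }, logical(1))
  expect_gt(mean(covered), 0.85)
  expect_lte(mean(covered), 1.0)
})

test_that("trial tables round-trip through CSV", {
  tr <- generate_session("P07", 99)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  expect_equal(nrow(back), 840L)
  expect_equal(back$rt_ms, tr$rt_ms, tolerance = 1e-8)
  expect_identical(back$response, tr$response)
})
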