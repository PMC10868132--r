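#' Validate a behavioral trial table
#'
#' The trial schema is one row per keypress: \code{participant},
#' \code{race} ("EA"/"WE"), \code{coherence} (percent, one of 10..60, 100),
#' \code{response} ("EA"/"WE"), \code{correct} (logical; must equal
#' \code{response == race}) and \code{rt_ms} (positive reaction time).
#'
#' @param trials data frame of trials.
#' @return the validated tibble, invisibly coerced.
#' @export
validate_trials <- function(trials) {
  need <- c("participant", "race", "coherence", "response", "correct", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "))
  trials <- tibble::as_tibble(trials)
  if (!all(trials$race %in% c("EA", "WE"))) stop("race must be 'EA' or 'WE'")
  if (!all(trials$response %in% c("EA", "WE"))) stop("response must be 'EA' or 'WE'")
  if (any(trials$rt_ms <= 0)) stop("rt_ms must be positive")
  if (!identical(as.logical(trials$correct),
                 trials$response == trials$race)) {
    stop("`correct` is inconsistent with response == race")
  }
  trials
}

#' Filter trials on reaction time
#'
#' Excludes trials with reaction times shorter than 100 ms or longer than
#' 2000 ms; the stated exclusions are strict, so the bounds themselves are
#' retained. Per-participant exclusion counts are attached as the
#' \code{exclusions} attribute and reported via message.
#'
#' @param trials trial table (see [validate_trials()]).
#' @param min_rt,max_rt inclusive retention bounds in ms.
#' @export
filter_trials <- function(trials, min_rt = 100, max_rt = 2000) {
  trials <- validate_trials(trials)
  keep <- trials$rt_ms >= min_rt & trials$rt_ms <= max_rt
  excl <- trials[!keep, ] |>
    dplyr::count(.data$participant, name = "n_excluded")
  out <- trials[keep, ]
  if (!nrow(out)) warning("all trials excluded by the RT filter")
  if (nrow(excl)) {
    message(sprintf("RT filter: excluded %d of %d trials (%d participant(s))",
                    sum(!keep), nrow(trials), nrow(excl)))
  }
  attr(out, "exclusions") <- excl
  out
}

#' Per-participant condition summaries
#'
#' Condition means per participant, race and coherence: accuracy is correct
#' responses divided by accepted trials; mean RT is taken over correct trials
#' only, untransformed. Both derive from the same accepted-trial set.
#'
#' @param trials filtered trial table.
#' @return tibble with \code{participant, race, coherence, accuracy,
#'   mean_rt_correct, n_trials_accepted}.
#' @export
condition_summaries <- function(trials) {
  trials <- validate_trials(trials)
  trials |>
    dplyr::group_by(.data$participant, .data$race, .data$coherence) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      mean_rt_correct = ifelse(any(.data$correct),
                               mean(.data$rt_ms[.data$correct]), NA_real_),
      n_trials_accepted = dplyr::n(),
      .groups = "drop")
}

#' Screen participants on full-structure accuracy
#'
#' Excludes participants whose pooled (EA + WE, trial-weighted) accuracy in
#' the 100\% coherence condition falls below the threshold — the criterion
#' that removes disengaged, single-key or chance-level responders.
#'
#' @param summaries output of [condition_summaries()].
#' @param threshold minimum pooled accuracy at 100\% coherence (inclusive).
#' @return character vector of included participant ids; excluded ids are in
#'   the \code{excluded} attribute.
#' @export
screen_participants <- function(summaries, threshold = 0.75) {
  full <- summaries |> dplyr::filter(.data$coherence == 100)
  all_p <- unique(as.character(summaries$participant))
  have <- unique(as.character(full$participant))
  miss <- setdiff(all_p, have)
  if (length(miss)) {
    stop("participant(s) missing the 100% coherence condition: ",
         paste(miss, collapse = ", "))
  }
  pooled <- full |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      acc = sum(.data$accuracy * .data$n_trials_accepted) /
        sum(.data$n_trials_accepted), .groups = "drop")
  included <- as.character(pooled$participant[pooled$acc >= threshold])
  structure(included,
            excluded = as.character(pooled$participant[pooled$acc < threshold]))
}

#' Per-coherence Bayes factor contrasts for the ORCA
#'
#' For each coherence level, computes paired JZS Bayes factors across
#' participants for the EA vs WE contrast on mean correct RT and on accuracy
#' (per-participant condition proportions treated as continuous paired
#' observations), with condition means and evidence labels at the behavioral
#' boundaries (alternative > 3, null <= 0.33).
#'
#' @param summaries output of [condition_summaries()], already screened.
#' @param rscale JZS prior scale.
#' @return tibble with one row per coherence level: group means per race,
#'   mean differences (EA - WE), \code{rt_bf10}, \code{acc_bf10} and their
#'   evidence labels.
#' @export
orca_contrasts <- function(summaries, rscale = sqrt(2) / 2) {
  wide <- summaries |>
    dplyr::select("participant", "race", "coherence",
                  "accuracy", "mean_rt_correct") |>
    tidyr::pivot_wider(names_from = "race",
                       values_from = c("accuracy", "mean_rt_correct"))
  rows <- lapply(sort(unique(wide$coherence)), function(lev) {
    w <- wide |> dplyr::filter(.data$coherence == lev) |> stats::na.omit()
    if (nrow(w) < 2L) stop(sprintf("coherence %g: fewer than 2 complete participants", lev))
    bf_or_stop <- function(a, b, what) {
      tryCatch(jzs_paired_bf(a, b, rscale = rscale),
               error = function(e) stop(sprintf(
                 "coherence %g, %s: %s", lev, what, conditionMessage(e)),
                 call. = FALSE))
    }
    rt <- bf_or_stop(w$mean_rt_correct_EA, w$mean_rt_correct_WE, "RT")
    ac <- bf_or_stop(w$accuracy_EA, w$accuracy_WE, "accuracy")
    tibble::tibble(
      coherence = lev, n = nrow(w),
      mean_rt_ea = mean(w$mean_rt_correct_EA),
      mean_rt_we = mean(w$mean_rt_correct_WE),
      rt_diff = rt$mean_diff, rt_bf10 = rt$bf10,
      rt_evidence = as.character(classify_evidence(rt$bf10, "behavioral")),
      mean_acc_ea = mean(w$accuracy_EA),
      mean_acc_we = mean(w$accuracy_WE),
      acc_diff = ac$mean_diff, acc_bf10 = ac$bf10,
      acc_evidence = as.character(classify_evidence(ac$bf10, "behavioral")))
  })
  dplyr::bind_rows(rows)
}

#' Signal detection analysis at one coherence level
#'
#' Treats responses naming the signal race (default WE) as "signal" responses:
#' a hit is a WE response to a WE face, a false alarm a WE response to an EA
#' face (incorrect EA-face responses thus enter as WE false alarms). Rates of
#' exactly 0 or 1 are corrected per participant to 1/(2N) and 1 - 1/(2N)
#' before the z transform. d' = z(H) - z(FA). The criterion is reported as
#' C = +(z(H) + z(FA))/2, so that C > 0 means a bias toward responding the
#' signal race; the sign convention is recorded in the output attributes.
#'
#' @param trials filtered trial table.
#' @param coherence the single coherence level to analyze.
#' @param signal_race which race plays "signal" (default "WE").
#' @return tibble with one row per participant (\code{hit_rate, fa_rate,
#'   dprime, criterion}); group means in the \code{group_means} attribute,
#'   sign convention in \code{criterion_convention}.
#' @export
sdt_analysis <- function(trials, coherence, signal_race = "WE") {
  trials <- validate_trials(trials)
  stopifnot(signal_race %in% c("EA", "WE"))
  noise_race <- setdiff(c("EA", "WE"), signal_race)
  tr <- trials |> dplyr::filter(.data$coherence == !!coherence)
  if (!nrow(tr)) stop("no trials at coherence ", coherence)
  rows <- lapply(split(tr, as.character(tr$participant)), function(p) {
    sig <- p[p$race == signal_race, ]
    noi <- p[p$race == noise_race, ]
    if (!nrow(sig) || !nrow(noi)) return(NULL)
    clamp <- function(k, n) {
      r <- k / n
      if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
    }
    h <- clamp(sum(sig$response == signal_race), nrow(sig))
    f <- clamp(sum(noi$response == signal_race), nrow(noi))
    tibble::tibble(participant = p$participant[1], hit_rate = h, fa_rate = f,
                   dprime = stats::qnorm(h) - stats::qnorm(f),
                   criterion = (stats::qnorm(h) + stats::qnorm(f)) / 2)
  })
  dropped <- names(rows)[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    warning("participant(s) without trials of both races excluded: ",
            paste(dropped, collapse = ", "))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "group_means") <- c(dprime = mean(out$dprime),
                                criterion = mean(out$criterion))
  attr(out, "criterion_convention") <-
    sprintf("C = +(zH + zFA)/2; C > 0 is a bias toward '%s' responses",
            signal_race)
  attr(out, "signal_race") <- signal_race
  out
}

#' Bootstrap confidence intervals for condition statistics
#'
#' Percentile bootstrap intervals for a per-condition statistic, resampling
#' participants (the unit of analysis) with replacement — the intervals shown
#' as shaded ribbons on the behavioral curves.
#'
#' @param summaries output of [condition_summaries()].
#' @param statistic name of the summary column to bootstrap
#'   (\code{"accuracy"} or \code{"mean_rt_correct"}).
#' @param level confidence level.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed; identical seeds give identical intervals.
#' @return tibble with \code{race, coherence, estimate, lower, upper}.
#' @export
bootstrap_ci <- function(summaries, statistic = "mean_rt_correct",
                         level = 0.95, B = 2000, seed = 1L) {
  stopifnot(statistic %in% names(summaries))
  if (B < 100) stop("B must be at least 100")
  parts <- unique(as.character(summaries$participant))
  if (length(parts) < 2L) stop("need at least 2 participants")
  wide <- summaries |>
    dplyr::select("participant", "race", "coherence",
                  value = dplyr::all_of(statistic))
  cells <- wide |> dplyr::distinct(.data$race, .data$coherence)
  # participants x cells matrix of the statistic
  key <- paste(wide$race, wide$coherence)
  M <- matrix(NA_real_, length(parts), nrow(cells),
              dimnames = list(parts, paste(cells$race, cells$coherence)))
  M[cbind(as.character(wide$participant), key)] <- wide$value
  alpha <- (1 - level) / 2
  boot <- with_private_seed(seed, function() {
    idx <- matrix(sample.int(length(parts), length(parts) * B, replace = TRUE),
                  nrow = B)
    res <- matrix(NA_real_, B, ncol(M))
    for (b in seq_len(B)) {
      res[b, ] <- colMeans(M[idx[b, ], , drop = FALSE], na.rm = TRUE)
    }
    res
  })
  qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  tibble::tibble(
    race = cells$race, coherence = cells$coherence,
    estimate = unname(colMeans(M, na.rm = TRUE)),
    lower = unname(qs[1, ]), upper = unname(qs[2, ]))
}
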