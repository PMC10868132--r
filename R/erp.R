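#' Epoched EEG container
#'
#' A set of stimulus-locked EEG epochs for one participant and condition:
#' a channels x samples x trials voltage array (microvolts) with its time
#' axis. The study's epochs span -100 to 1000 ms at 1024 Hz, but the
#' container accepts any sampling rate and span.
#'
#' @param data numeric array, channels x samples x trials.
#' @param times_ms numeric vector of sample times in ms relative to stimulus
#'   onset; length must equal \code{dim(data)[2]}.
#' @param channels character vector of unique channel labels, length
#'   \code{dim(data)[1]}.
#' @param srate sampling rate in Hz.
#' @param participant,race,coherence condition metadata.
#' @return An \code{epoch_set} object.
#' @export
epoch_set <- function(data, times_ms, channels, srate,
                      participant = NA, race = NA_character_,
                      coherence = NA_real_) {
  if (length(dim(data)) != 3L) stop("`data` must be channels x samples x trials")
  if (length(times_ms) != dim(data)[2]) {
    stop("`times_ms` length must match the sample dimension")
  }
  if (length(channels) != dim(data)[1]) {
    stop("`channels` length must match the channel dimension")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.numeric(srate) || srate <= 0) stop("`srate` must be positive")
  if (is.unsorted(times_ms, strictly = TRUE)) {
    stop("`times_ms` must be strictly increasing")
  }
  structure(
    list(data = data, times_ms = as.numeric(times_ms),
         channels = as.character(channels), srate = srate,
         participant = participant, race = race, coherence = coherence),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epoch_set: %d channels x %d samples x %d trials @ %g Hz, %g..%g ms\n",
    d[1], d[2], d[3], x$srate, min(x$times_ms), max(x$times_ms)))
  cat(sprintf("  participant %s, race %s, coherence %s\n",
              as.character(x$participant), as.character(x$race),
              as.character(x$coherence)))
  invisible(x)
}

#' Default epoch time axis
#'
#' @param srate sampling rate (Hz).
#' @param tmin,tmax epoch bounds in seconds relative to onset.
#' @return times in ms; sample k maps to t = (k - t0_index)/srate * 1000 with
#'   the 0 ms sample included.
#' @export
epoch_times <- function(srate = 1024, tmin = -0.1, tmax = 1.0) {
  idx <- seq(floor(tmin * srate), ceiling(tmax * srate))
  idx / srate * 1000
}

#' Zero-phase band-pass filter epochs
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, so component latencies are preserved) to every channel and
#' trial. Each trace is demeaned first: the high-pass period (10 s at 0.1 Hz)
#' far exceeds the epoch length, and removing the epoch mean up front
#' suppresses the filter transient that would otherwise dominate, making the
#' DC rejection actual rather than asymptotic.
#'
#' @param epochs an [epoch_set()].
#' @param low,high band edges in Hz.
#' @return filtered \code{epoch_set}.
#' @export
bandpass_epochs <- function(epochs, low = 0.1, high = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$srate / 2
  if (high >= nyq) stop("`high` must be below the Nyquist frequency")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  d <- epochs$data
  dm <- dim(d)
  # samples x (channels*trials): one vectorized zero-phase pass over all traces
  X <- matrix(aperm(d, c(2, 1, 3)), dm[2], dm[1] * dm[3])
  X <- sweep(X, 2, colMeans(X), `-`)
  Y <- filtfilt_mat(bf$b, bf$a, X)
  epochs$data <- aperm(array(Y, c(dm[2], dm[1], dm[3])), c(2, 1, 3))
  epochs
}

# forward IIR (direct form II transposed) over the columns (time axis) of a
# series x samples matrix; contiguous column access keeps it cache-friendly
iir_filter_rows <- function(b, a, Xt) {
  b <- b / a[1]; a <- a / a[1]
  k <- max(length(a), length(b))
  b <- c(b, rep(0, k - length(b)))
  a <- c(a, rep(0, k - length(a)))
  n <- ncol(Xt); m <- nrow(Xt)
  Y <- matrix(0, m, n)
  Z <- matrix(0, m, k - 1)
  for (t in seq_len(n)) {
    x <- Xt[, t]
    y <- b[1] * x + Z[, 1]
    if (k > 2) for (j in seq_len(k - 2)) {
      Z[, j] <- b[j + 1] * x + Z[, j + 1] - a[j + 1] * y
    }
    Z[, k - 1] <- b[k] * x - a[k] * y
    Y[, t] <- y
  }
  Y
}

# zero-phase filtering of every column of a samples x series matrix:
# odd-reflection padding, forward and reverse passes (scipy-style filtfilt)
filtfilt_mat <- function(b, a, X) {
  n <- nrow(X)
  pad <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  top <- 2 * matrix(X[1, ], pad, ncol(X), byrow = TRUE) -
    X[pad + 1 - seq_len(pad) + 1, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[n - seq_len(pad), , drop = FALSE]
  Xt <- t(rbind(top, X, bot))
  Y <- iir_filter_rows(b, a, Xt)
  Y <- iir_filter_rows(b, a, Y[, rev(seq_len(ncol(Y))), drop = FALSE])
  Y <- Y[, rev(seq_len(ncol(Y))), drop = FALSE]
  t(Y[, pad + seq_len(n), drop = FALSE])
}

#' Preprocess a cohort of epoch sets
#'
#' Runs the standard chain — band-pass, baseline correction, common-average
#' reference, voltage rejection, condition averaging — over a list of
#' [epoch_set()]s with identical geometry, batching the zero-phase filter
#' across the whole cohort (one vectorized pass instead of one per trace),
#' which is what makes large simulation studies practical.
#'
#' @param cohort list of [epoch_set()]s (e.g. from [generate_erp_cohort()]).
#' @param bp_low,bp_high band edges in Hz.
#' @param baseline_window baseline window in ms.
#' @param reject_uv voltage rejection limit (microvolts).
#' @param reject_window rejection scan window in ms.
#' @return list of [condition_average()] results, one per input epoch set.
#' @export
preprocess_cohort <- function(cohort, bp_low = 0.1, bp_high = 30,
                              baseline_window = c(-100, 0), reject_uv = 100,
                              reject_window = c(0, 500)) {
  stopifnot(length(cohort) > 0, all(vapply(cohort, inherits, TRUE, "epoch_set")))
  e1 <- cohort[[1L]]
  nyq <- e1$srate / 2
  if (bp_high >= nyq) stop("`bp_high` must be below the Nyquist frequency")
  dims <- vapply(cohort, function(e) dim(e$data), integer(3))
  same_geom <- all(dims[2, ] == dims[2, 1])
  if (!same_geom) stop("cohort epoch sets must share the sample dimension")
  bf <- signal::butter(4, c(bp_low, bp_high) / nyq, type = "pass")
  n_s <- dims[2, 1]
  X <- do.call(cbind, lapply(cohort, function(e) {
    dm <- dim(e$data)
    matrix(aperm(e$data, c(2, 1, 3)), n_s, dm[1] * dm[3])
  }))
  X <- sweep(X, 2, colMeans(X), `-`)
  Y <- filtfilt_mat(bf$b, bf$a, X)
  out <- vector("list", length(cohort))
  col0 <- 0L
  for (i in seq_along(cohort)) {
    e <- cohort[[i]]
    dm <- dim(e$data)
    k <- dm[1] * dm[3]
    e$data <- aperm(array(Y[, col0 + seq_len(k), drop = FALSE],
                          c(n_s, dm[1], dm[3])), c(2, 1, 3))
    col0 <- col0 + k
    e <- baseline_correct(e, baseline_window)
    e <- rereference_car(e)
    e <- reject_epochs(e, reject_uv, reject_window)
    out[[i]] <- condition_average(e)
  }
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and trial, the average voltage in the baseline
#' window (default -100 to 0 ms) so the baseline mean is exactly zero.
#'
#' @param epochs an [epoch_set()].
#' @param window baseline window in ms, inclusive.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$times_ms >= window[1] & epochs$times_ms <= window[2])
  if (!length(idx) || window[1] < min(epochs$times_ms) ||
      window[2] > max(epochs$times_ms)) {
    stop("baseline window falls outside the epoch")
  }
  d <- epochs$data
  bl <- rowMeans(aperm(d[, idx, , drop = FALSE], c(1, 3, 2)),
                 dims = 2)  # channels x trials
  d <- sweep(d, c(1, 3), bl, `-`)
  epochs$data <- d
  epochs
}

#' Common-average re-reference
#'
#' Re-expresses every channel relative to the instantaneous mean over all
#' channels, so at every sample the channel mean is zero.
#'
#' @param epochs an [epoch_set()].
#' @export
rereference_car <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] < 2L) stop("common-average reference needs >= 2 channels")
  d <- epochs$data
  avg <- colMeans(d)  # samples x trials
  epochs$data <- sweep(d, c(2, 3), avg, `-`)
  epochs
}

#' Reject epochs on a voltage criterion
#'
#' Drops trials whose absolute voltage exceeds \code{limit} microvolts on any
#' channel within the scan window (default the first 500 ms after stimulus
#' onset). The criterion is strict: a trial peaking at exactly the limit is
#' retained. The rejection log (trial indices and offending channels) is
#' attached as the \code{rejection_log} attribute.
#'
#' @param epochs an [epoch_set()].
#' @param limit voltage limit in microvolts.
#' @param window scan window in ms.
#' @export
reject_epochs <- function(epochs, limit = 100, window = c(0, 500)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$times_ms >= window[1] & epochs$times_ms <= window[2])
  if (!length(idx)) stop("rejection window falls outside the epoch")
  d <- epochs$data
  n_tr <- dim(d)[3]
  # channels x trials peak within the scan window
  pk <- apply(abs(d[, idx, , drop = FALSE]), c(1, 3), max)
  bad <- colSums(pk > limit) > 0
  off <- which(pk > limit, arr.ind = TRUE)
  log <- if (nrow(off)) {
    tibble::tibble(trial = as.integer(off[, 2]),
                   channel = epochs$channels[off[, 1]],
                   peak_uv = unname(pk[off]))
  } else NULL
  if (all(bad)) {
    stop(sprintf(
      "all %d trials exceed %g uV in %g-%g ms; data unusable as given",
      n_tr, limit, window[1], window[2]))
  }
  epochs$data <- d[, , !bad, drop = FALSE]
  attr(epochs, "rejection_log") <-
    if (!is.null(log)) dplyr::arrange(log, .data$trial) else
      tibble::tibble(trial = integer(), channel = character(),
                     peak_uv = numeric())
  attr(epochs, "n_rejected") <- sum(bad)
  epochs
}

# Legendre polynomial values P_1..P_nmax at x (vector), by recursion
legendre_upto <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  p0 <- rep(1, length(x)); p1 <- x
  out[, 1] <- p1
  for (n in 2:nmax) {
    p2 <- ((2 * n - 1) * x * p1 - (n - 1) * p0) / n
    out[, n] <- p2
    p0 <- p1; p1 <- p2
  }
  out
}

# Perrin-style spherical-spline kernel g(cos angle), m = 4
spline_g <- function(cosang, m = 4, nmax = 50) {
  P <- legendre_upto(pmin(pmax(cosang, -1), 1), nmax)
  n <- seq_len(nmax)
  w <- (2 * n + 1) / (n^m * (n + 1)^m)
  as.numeric(P %*% w) / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed channels, per sample and trial, with spherical-spline
#' estimates computed from the remaining channels using their positions on
#' the unit sphere (Perrin-style spline, order m = 4). Good channels are
#' untouched. Refuses montages with more than 25\% bad channels.
#'
#' @param epochs an [epoch_set()].
#' @param bad character vector of bad channel labels.
#' @param montage data frame with columns \code{channel, x, y, z} (unit-sphere
#'   positions) covering every channel in the epochs.
#' @export
interpolate_bad_channels <- function(epochs, bad, montage) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!length(bad)) return(epochs)
  if (!all(bad %in% epochs$channels)) stop("unknown bad channel label(s)")
  if (length(bad) > 0.25 * length(epochs$channels)) {
    stop("more than 25% of channels marked bad; montage unreliable")
  }
  if (!all(epochs$channels %in% montage$channel)) {
    stop("montage must provide positions for every channel")
  }
  pos <- as.matrix(montage[match(epochs$channels, montage$channel),
                           c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  good <- which(!(epochs$channels %in% bad))
  badi <- which(epochs$channels %in% bad)
  G <- matrix(spline_g(tcrossprod(pos[good, , drop = FALSE])),
              length(good), length(good))
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  Gb <- matrix(spline_g(pos[badi, , drop = FALSE] %*% t(pos[good, , drop = FALSE])),
               length(badi), length(good))
  d <- epochs$data
  for (tr in seq_len(dim(d)[3])) {
    z <- matrix(d[good, , tr], length(good), dim(d)[2])  # good x samples
    sol <- solve(A, rbind(z, 0))                     # (good+1) x samples
    d[badi, , tr] <- Gb %*% sol[seq_along(good), , drop = FALSE] +
      matrix(sol[length(good) + 1L, ], length(badi), dim(d)[2], byrow = TRUE)
  }
  epochs$data <- d
  epochs
}

#' Average epochs into a condition ERP
#'
#' @param epochs an [epoch_set()] with at least one trial.
#' @return An \code{erp_average}: list with \code{data} (channels x samples
#'   matrix), \code{times_ms}, \code{channels}, \code{srate}, \code{n_trials}
#'   and the condition metadata.
#' @export
condition_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[3]
  if (n_tr < 1L) stop("no trials to average")
  m <- rowMeans(epochs$data, dims = 2)
  dimnames(m) <- list(epochs$channels, NULL)
  structure(
    list(data = m, times_ms = epochs$times_ms, channels = epochs$channels,
         srate = epochs$srate, n_trials = n_tr,
         participant = epochs$participant, race = epochs$race,
         coherence = epochs$coherence),
    class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("erp_average: %d channels x %d samples (n = %d trials), %s/%s/%s\n",
              nrow(x$data), ncol(x$data), x$n_trials,
              as.character(x$participant), as.character(x$race),
              as.character(x$coherence)))
  invisible(x)
}

#' Electrode cluster
#'
#' A named set of exactly eight sensors, mirroring the left/right
#' occipito-temporal clusters used for the cluster-mean Bayes factor scans.
#'
#' @param name cluster name, e.g. \code{"LH"} or \code{"RH"}.
#' @param channels character vector of exactly 8 channel labels.
#' @export
electrode_cluster <- function(name, channels) {
  if (length(channels) != 8L) stop("an electrode cluster has exactly 8 channels")
  if (anyDuplicated(channels)) stop("cluster channels must be unique")
  structure(list(name = name, channels = as.character(channels)),
            class = "electrode_cluster")
}

# participants x samples matrix of cluster-mean voltages for one condition
cluster_condition_matrix <- function(erps, cluster, race, coherence) {
  sel <- Filter(function(e) identical(as.character(e$race), race) &&
                  isTRUE(all.equal(as.numeric(e$coherence), coherence)),
                erps)
  if (!length(sel)) return(NULL)
  rows <- lapply(sel, function(e) {
    if (!all(cluster$channels %in% e$channels)) {
      stop("cluster channels missing from ERP montage")
    }
    colMeans(e$data[cluster$channels, , drop = FALSE])
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(sel, function(e) as.character(e$participant), "")
  m
}

#' Sample-wise cluster Bayes factor scan
#'
#' For one contrast (race A vs race B at one coherence level), averages the
#' voltage over the cluster's eight channels per participant and condition,
#' then computes a paired JZS Bayes factor across participants at every time
#' sample from 0 to 420 ms (bounds inclusive; the range stops before
#' motor-preparation activity). Participants missing either condition are
#' dropped and logged. Samples whose paired differences are all zero are
#' degenerate and recorded as missing, never interpolated.
#'
#' @param erps list of [condition_average()] results covering both conditions.
#' @param cluster an [electrode_cluster()].
#' @param contrast list with \code{a}, \code{b} (race labels; the difference
#'   is a - b) and \code{coherence}.
#' @param t_range scan window in ms.
#' @param rscale JZS prior scale.
#' @return A \code{bf_timeseries}: tibble with columns \code{time_ms, bf10,
#'   mean_diff_uv, t_stat}, attributes \code{cluster}, \code{contrast},
#'   \code{n} and \code{dropped}.
#' @export
cluster_bf_scan <- function(erps, cluster, contrast,
                            t_range = c(0, 420), rscale = sqrt(2) / 2) {
  stopifnot(inherits(cluster, "electrode_cluster"))
  stopifnot(all(c("a", "b", "coherence") %in% names(contrast)))
  ma <- cluster_condition_matrix(erps, cluster, contrast$a, contrast$coherence)
  mb <- cluster_condition_matrix(erps, cluster, contrast$b, contrast$coherence)
  if (is.null(ma) || is.null(mb)) stop("contrast condition(s) absent from `erps`")
  common <- intersect(rownames(ma), rownames(mb))
  dropped <- setdiff(union(rownames(ma), rownames(mb)), common)
  if (length(common) < 2L) stop("need >= 2 participants with both conditions")
  ma <- ma[common, , drop = FALSE]
  mb <- mb[common, , drop = FALSE]
  e1 <- erps[[1L]]
  idx <- which(e1$times_ms >= t_range[1] & e1$times_ms <= t_range[2])
  times <- e1$times_ms[idx]
  bf10 <- t_stat <- mean_diff <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    d <- ma[, idx[k]] - mb[, idx[k]]
    mean_diff[k] <- mean(d)
    if (all(d == 0) || stats::sd(d) == 0) next  # degenerate: left missing
    r <- jzs_paired_bf(ma[, idx[k]], mb[, idx[k]], rscale = rscale)
    bf10[k] <- r$bf10
    t_stat[k] <- r$t_stat
  }
  out <- tibble::tibble(time_ms = times, bf10 = bf10,
                        mean_diff_uv = mean_diff, t_stat = t_stat)
  attr(out, "cluster") <- cluster
  attr(out, "contrast") <- contrast
  attr(out, "n") <- length(common)
  attr(out, "dropped") <- dropped
  class(out) <- c("bf_timeseries", class(out))
  out
}

#' Extract evidence windows from a Bayes factor time series
#'
#' Finds maximal contiguous runs of samples whose \eqn{BF_{10}} exceeds the
#' evidence boundary (default 10, the raised boundary used for the sample-wise
#' EEG scans) and, separately, runs at or below the null boundary (default
#' 0.33). Each window reports onset/offset in ms, mean and max BF, the time
#' of the max, and the sign of the mean voltage difference within the window.
#' Single-sample windows (onset = offset) are legitimate and reported.
#'
#' @param bfts a \code{bf_timeseries} from [cluster_bf_scan()] (any tibble
#'   with \code{time_ms}, \code{bf10} and optionally \code{mean_diff_uv}).
#' @param threshold evidence boundary for the alternative (strict >).
#' @param null_threshold boundary for null evidence (inclusive <=).
#' @return tibble with columns \code{kind} ("alternative"/"null"),
#'   \code{onset_ms, offset_ms, n_samples, mean_bf, max_bf, t_max_ms,
#'   direction}.
#' @export
extract_windows <- function(bfts, threshold = 10, null_threshold = 0.33) {
  stopifnot(all(c("time_ms", "bf10") %in% names(bfts)))
  if (!nrow(bfts)) stop("`bfts` is empty")
  runs_of <- function(flag) {
    flag[is.na(flag)] <- FALSE
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    cbind(starts[keep], ends[keep])
  }
  window_row <- function(i0, i1, kind) {
    seg <- bfts[i0:i1, ]
    kmax <- which.max(seg$bf10)
    tibble::tibble(
      kind = kind,
      onset_ms = seg$time_ms[1], offset_ms = seg$time_ms[nrow(seg)],
      n_samples = nrow(seg),
      mean_bf = mean(seg$bf10), max_bf = max(seg$bf10),
      t_max_ms = seg$time_ms[kmax],
      direction = if ("mean_diff_uv" %in% names(seg)) {
        sign(mean(seg$mean_diff_uv))
      } else NA_real_)
  }
  alt <- runs_of(bfts$bf10 > threshold)
  nul <- runs_of(bfts$bf10 <= null_threshold)
  rows <- c(
    lapply(seq_len(nrow(alt)), function(k) window_row(alt[k, 1], alt[k, 2], "alternative")),
    lapply(seq_len(nrow(nul)), function(k) window_row(nul[k, 1], nul[k, 2], "null")))
  if (!length(rows)) {
    return(tibble::tibble(kind = character(), onset_ms = numeric(),
                          offset_ms = numeric(), n_samples = integer(),
                          mean_bf = numeric(), max_bf = numeric(),
                          t_max_ms = numeric(), direction = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$kind, .data$onset_ms)
}

#' Per-electrode Bayes factor topography
#'
#' For a contrast and time window, computes each electrode's window-mean
#' voltage per participant and condition, then the paired JZS Bayes factor
#' and signed mean difference across participants — the scalp-map complement
#' of the cluster scans.
#'
#' @param erps list of [condition_average()] results.
#' @param contrast list with \code{a}, \code{b}, \code{coherence}.
#' @param window time window in ms (inclusive).
#' @param rscale JZS prior scale.
#' @return tibble with columns \code{channel, mean_diff_uv, bf10, t_stat, n}.
#' @export
bf_topomap <- function(erps, contrast, window, rscale = sqrt(2) / 2) {
  e1 <- erps[[1L]]
  idx <- which(e1$times_ms >= window[1] & e1$times_ms <= window[2])
  if (!length(idx) || window[1] < min(e1$times_ms) ||
      window[2] > max(e1$times_ms)) {
    stop("time window falls outside the epoch")
  }
  get_cond <- function(race) {
    sel <- Filter(function(e) identical(as.character(e$race), race) &&
                    isTRUE(all.equal(as.numeric(e$coherence),
                                     contrast$coherence)), erps)
    m <- do.call(rbind, lapply(sel, function(e) {
      rowMeans(e$data[, idx, drop = FALSE])
    }))
    rownames(m) <- vapply(sel, function(e) as.character(e$participant), "")
    m
  }
  ma <- get_cond(contrast$a); mb <- get_cond(contrast$b)
  common <- intersect(rownames(ma), rownames(mb))
  if (length(common) < 2L) stop("need >= 2 participants with both conditions")
  ma <- ma[common, , drop = FALSE]; mb <- mb[common, , drop = FALSE]
  rows <- lapply(seq_along(e1$channels), function(ch) {
    d <- ma[, ch] - mb[, ch]
    if (all(d == 0) || stats::sd(d) == 0) {
      return(tibble::tibble(channel = e1$channels[ch], mean_diff_uv = mean(d),
                            bf10 = NA_real_, t_stat = NA_real_,
                            n = length(common)))
    }
    r <- jzs_paired_bf(ma[, ch], mb[, ch], rscale = rscale)
    tibble::tibble(channel = e1$channels[ch], mean_diff_uv = r$mean_diff,
                   bf10 = r$bf10, t_stat = r$t_stat, n = r$n)
  })
  dplyr::bind_rows(rows)
}
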