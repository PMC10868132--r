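#' Read / write behavioral trial tables
#'
#' CSV schema: header \code{participant,race,coherence,response,correct,rt_ms};
#' \code{correct} is written as TRUE/FALSE.
#'
#' @param path CSV file path.
#' @return [read_trials_csv()] returns a validated trial tibble.
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$correct <- as.logical(d$correct)
  validate_trials(d)
}

#' @param trials trial table.
#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(validate_trials(trials), path, row.names = FALSE)
  invisible(path)
}

#' Read / write an epoch set
#'
#' Two containers are supported. \code{format = "rds"} (default) stores the
#' full object losslessly. \code{format = "csv"} writes a plain-text
#' directory: \code{meta.csv} (participant, race, coherence, srate),
#' \code{times_ms.csv}, \code{channels.csv} and one \code{trial_NNN.csv}
#' (channels x samples) per trial — readable anywhere, intended for small
#' sets.
#'
#' @param epochs an [epoch_set()].
#' @param path file (rds) or directory (csv).
#' @param format "rds" or "csv".
#' @export
write_epoch_set <- function(epochs, path, format = c("rds", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(epochs, "epoch_set"))
  if (format == "rds") {
    saveRDS(epochs, path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(participant = epochs$participant,
                                race = epochs$race,
                                coherence = epochs$coherence,
                                srate = epochs$srate),
                     file.path(path, "meta.csv"), row.names = FALSE)
    utils::write.csv(data.frame(times_ms = epochs$times_ms),
                     file.path(path, "times_ms.csv"), row.names = FALSE)
    utils::write.csv(data.frame(channel = epochs$channels),
                     file.path(path, "channels.csv"), row.names = FALSE)
    for (tr in seq_len(dim(epochs$data)[3])) {
      utils::write.csv(as.data.frame(epochs$data[, , tr]),
                       file.path(path, sprintf("trial_%03d.csv", tr)),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path, format = c("rds", "csv")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  meta <- utils::read.csv(file.path(path, "meta.csv"))
  times <- utils::read.csv(file.path(path, "times_ms.csv"))$times_ms
  channels <- utils::read.csv(file.path(path, "channels.csv"))$channel
  files <- sort(list.files(path, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no trial_*.csv files under ", path)
  mats <- lapply(files, function(f) as.matrix(utils::read.csv(f)))
  data <- array(unlist(mats), c(length(channels), length(times),
                                length(files)))
  epoch_set(data, times, channels, meta$srate,
            participant = meta$participant, race = meta$race,
            coherence = meta$coherence)
}
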