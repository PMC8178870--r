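#' Construct an epoch-level step-count stream for one participant-day
#'
#' An epoch stream is the raw unit of non-wear detection: the ordered
#' step counts recorded by the device over one full day, at a fixed epoch
#' length (typically 5 or 10 seconds).
#'
#' @param participant_id scalar identifier.
#' @param year measurement occasion, 0 = baseline, 1, 2.
#' @param day_of_week integer 1 (Monday) to 7 (Sunday).
#' @param steps integer vector of non-negative per-epoch step counts. Must
#'   cover exactly 24 hours: `length(steps) * epoch_len == 86400`.
#' @param week week index; 1 is the measurement week, 2 the following week.
#' @param epoch_len epoch length in seconds (default 5).
#' @return an object of class `epoch_stream`.
#' @export
epoch_stream <- function(participant_id, year, day_of_week, steps,
                         week = 1L, epoch_len = 5L) {
  stopifnot(length(participant_id) == 1L, length(year) == 1L,
            length(day_of_week) == 1L)
  year <- as.integer(year)
  day_of_week <- as.integer(day_of_week)
  epoch_len <- as.integer(epoch_len)
  if (epoch_len <= 0L) stop("epoch_len must be a positive integer")
  if (!year %in% 0:2) stop("year must be 0, 1 or 2")
  if (!day_of_week %in% 1:7) stop("day_of_week must be in 1..7 (1 = Monday)")
  if (anyNA(steps) || any(steps < 0))
    stop("steps must be non-negative and complete")
  if (length(steps) * epoch_len != DAY_SECONDS)
    stop(sprintf("stream must cover 24 h: length %d x epoch_len %d != 86400 s",
                 length(steps), epoch_len))
  structure(list(participant_id = participant_id, year = year,
                 day_of_week = day_of_week, week = as.integer(week),
                 epoch_len = epoch_len, steps = as.numeric(steps)),
            class = "epoch_stream")
}

#' Flag non-wear epochs in a stream
#'
#' Every maximal run of consecutive zero-step epochs lasting at least
#' `run_minutes` is flagged as non-wear; all other epochs count as worn.
#' This is the conventional zero-run rule used by accelerometer software
#' (common thresholds are 20, 40 or 60 minutes).
#'
#' @param stream an [epoch_stream()].
#' @param run_minutes minimum zero-run duration, in minutes, to treat as
#'   device removal. Must be a positive multiple of the epoch length.
#' @return logical vector, `TRUE` for worn epochs, same length as the stream.
#' @export
detect_nonwear <- function(stream, run_minutes = 60) {
  stopifnot(inherits(stream, "epoch_stream"))
  if (run_minutes <= 0) stop("run_minutes must be positive")
  epochs_per_run <- run_minutes * 60 / stream$epoch_len
  if (abs(epochs_per_run - round(epochs_per_run)) > 1e-8)
    stop("run_minutes must be a multiple of the epoch length")
  epochs_per_run <- round(epochs_per_run)
  z <- stream$steps == 0
  r <- rle(z)
  nonwear_run <- r$values & r$lengths >= epochs_per_run
  worn <- !inverse.rle(structure(list(lengths = r$lengths,
                                      values = nonwear_run),
                                 class = "rle"))
  worn
}

#' Aggregate a masked stream to a day-level record
#'
#' @param stream an [epoch_stream()].
#' @param mask worn mask from [detect_nonwear()] on the same stream.
#' @return a one-row data frame (`participant_id`, `year`, `week`,
#'   `day_of_week`, `step_count`, `wear_minutes`, `status`,
#'   `substituted_from`), with `status` not yet set.
#' @export
summarize_day <- function(stream, mask) {
  stopifnot(inherits(stream, "epoch_stream"))
  if (length(mask) != length(stream$steps))
    stop("mask length does not match stream length")
  wear_minutes <- sum(mask) * stream$epoch_len / 60
  step_count <- sum(stream$steps[mask])
  data.frame(participant_id = stream$participant_id, year = stream$year,
             week = stream$week, day_of_week = stream$day_of_week,
             step_count = step_count, wear_minutes = wear_minutes,
             status = NA_character_, substituted_from = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Classify day records by wear time
#'
#' A day is `missing` when wear time is zero (the device was not worn at
#' all), `partial` when wear time is positive but below the cut-off (the
#' recorded count is then a right-censored version of the true daily count),
#' and `observed` when wear time reaches the cut-off. Wear time exactly at
#' the cut-off counts as observed, reading "at least `cutoff` minutes" as
#' compliant.
#'
#' @param days data frame of day records with a `wear_minutes` column (as
#'   produced by [summarize_day()] or [read_trial()]).
#' @param cutoff_minutes wear-time cut-off in minutes (default 540 = 9 h).
#' @return `days` with `status` filled in.
#' @export
classify_days <- function(days, cutoff_minutes = 540) {
  if (cutoff_minutes <= 0) stop("cutoff_minutes must be positive")
  if (!"wear_minutes" %in% names(days)) stop("days must have wear_minutes")
  w <- days$wear_minutes
  if (anyNA(w) || any(w < 0)) stop("wear_minutes must be non-negative")
  if (any(w > 1440)) stop("wear_minutes cannot exceed 1440")
  days$status <- ifelse(w == 0, "missing",
                        ifelse(w < cutoff_minutes, "partial", "observed"))
  days
}

#' @rdname classify_days
#' @param record a one-row day record.
#' @export
classify_day <- function(record, cutoff_minutes = 540) {
  classify_days(record, cutoff_minutes = cutoff_minutes)
}

#' Convert epoch streams to classified day records
#'
#' Runs [detect_nonwear()], [summarize_day()] and [classify_days()] over a
#' list of epoch streams.
#'
#' @param streams list of [epoch_stream()] objects.
#' @inheritParams detect_nonwear
#' @inheritParams classify_days
#' @return data frame of classified day records.
#' @export
epochs_to_days <- function(streams, run_minutes = 60, cutoff_minutes = 540) {
  recs <- lapply(streams, function(s) {
    summarize_day(s, detect_nonwear(s, run_minutes = run_minutes))
  })
  classify_days(do.call(rbind, recs), cutoff_minutes = cutoff_minutes)
}

#' Read epoch-level step counts from a long CSV
#'
#' Expected header: `participant_id,year,week,day_of_week,epoch_index,steps`.
#' Epochs must be complete for each participant-day.
#'
#' @param path CSV file path.
#' @param epoch_len epoch length in seconds.
#' @return list of [epoch_stream()] objects.
#' @export
read_epochs <- function(path, epoch_len = 5L) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "year", "week", "day_of_week",
            "epoch_index", "steps")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("epoch file missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(x$participant_id, x$year, x$week, x$day_of_week,
                     drop = TRUE)
  lapply(split(x, key), function(d) {
    d <- d[order(d$epoch_index), ]
    epoch_stream(d$participant_id[1], d$year[1], d$day_of_week[1],
                 d$steps, week = d$week[1], epoch_len = epoch_len)
  })
}
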