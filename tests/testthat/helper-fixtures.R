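# shared fixtures, built in code

# epoch stream from run-length (minutes, steps-per-epoch) pairs
stream_from_runs <- function(runs, epoch_len = 5, pid = "p1", year = 0,
                             dow = 1, week = 1) {
  per_min <- 60 / epoch_len
  steps <- unlist(lapply(runs, function(r)
    rep(r[2], r[1] * per_min)), use.names = FALSE)
  total_min <- sum(vapply(runs, `[`, numeric(1), 1))
  stopifnot(total_min == 1440)
  epoch_stream(pid, year, dow, steps, week = week, epoch_len = epoch_len)
}

# brute-force non-wear oracle: scan all maximal zero runs
nonwear_oracle <- function(steps, epoch_len, run_minutes) {
  n <- length(steps)
  worn <- rep(TRUE, n)
  i <- 1
  while (i <= n) {
    if (steps[i] == 0) {
      j <- i
      while (j < n && steps[j + 1] == 0) j <- j + 1
      if ((j - i + 1) * epoch_len >= run_minutes * 60) worn[i:j] <- FALSE
      i <- j + 1
    } else i <- i + 1
  }
  worn
}

# hand-built small trial: n participants, all cells observed unless edited
tiny_trial <- function(n = 6, counts = 7000, extra_week = FALSE,
                       aux = TRUE, seed = 42) {
  set.seed(seed)
  grid <- expand.grid(day_of_week = 1:7, year = 0:2, i = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE)
  weeks <- if (extra_week) c(1L, 2L) else 1L
  days <- do.call(rbind, lapply(weeks, function(w) {
    d <- grid
    d$week <- w
    d
  }))
  days$participant_id <- sprintf("p%02d", days$i)
  days$i <- NULL
  days$step_count <- rep_len(counts, nrow(days))
  days$wear_minutes <- 800
  days$status <- "observed"
  days$substituted_from <- NA_integer_
  participants <- data.frame(
    participant_id = sprintf("p%02d", seq_len(n)),
    arm = rep_len(c(1, 2, 3), n), female = rep_len(c(0, 1), n),
    age = seq(60, 80, length.out = n),
    region = rep_len(c("ra", "rb"), n), bmi = seq(24, 36, length.out = n),
    stringsAsFactors = FALSE)
  aux_df <- NULL
  if (aux) {
    aux_df <- do.call(rbind, lapply(weeks, function(w) {
      a <- grid
      a$week <- w
      a
    }))
    aux_df$participant_id <- sprintf("p%02d", aux_df$i)
    aux_df$i <- NULL
    aux_df$date <- as.Date("2014-06-02") + aux_df$day_of_week - 1
    aux_df$temperature <- round(rnorm(nrow(aux_df), 14, 4), 1)
    aux_df$sqrt_rainfall <- round(abs(rnorm(nrow(aux_df), 1, 0.5)), 2)
    aux_df$sunshine <- round(runif(nrow(aux_df), 0, 10), 1)
    aux_df$daylength <- round(runif(nrow(aux_df), 8, 16), 2)
  }
  trial_dataset(days, participants, aux_df)
}

# fetch one week-1 day record
inwindow_cell <- function(dataset, pid, yr, dow) {
  d <- dataset$days
  d[d$participant_id == pid & d$year == yr & d$day_of_week == dow &
      d$week == 1, ]
}

# set one week-1 cell of a tiny trial to a given status
set_cell <- function(dataset, pid, yr, dow, status, count = 0, wear = 0,
                     wk = 1) {
  d <- dataset$days
  i <- which(d$participant_id == pid & d$year == yr &
               d$day_of_week == dow & d$week == wk)
  stopifnot(length(i) == 1)
  dataset$days$status[i] <- status
  dataset$days$step_count[i] <- count
  dataset$days$wear_minutes[i] <- wear
  dataset
}
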