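#' Configuration for the synthetic trial generator
#'
#' Defaults emulate a three-arm motivational-therapy trial in older adults
#' at high cardiovascular risk, measured by accelerometer for 7 days at
#' baseline, year 1 and year 2: allocation 3:4:3 (individual therapy,
#' group therapy, usual care), a London-like climate driving weather
#' auxiliaries, a weekend decrement in activity, wear time for worn days
#' drawn from a scaled Beta with median near 750 min, and configurable
#' MCAR/MAR/MNAR wear mechanisms.
#'
#' @param n_participants number randomized.
#' @param alloc allocation weights for arms 1:3.
#' @param baseline_log_mean,sd_participant mean and between-participant SD
#'   of latent log daily steps.
#' @param year_effects log-scale secular shift per occasion (length 3).
#' @param arm_effects 3 x 2 matrix of additive arm effects (steps/day) at
#'   years 1 and 2; row 3 (usual care) is the reference, so the true
#'   week-average contrasts versus usual care are
#'   `arm_effects[1:2, ] - arm_effects[3, ]` exactly.
#' @param weekday_effects log-scale day-of-week effects, Monday..Sunday.
#' @param weather_coefs named log-scale coefficients for `temperature`,
#'   `sqrt_rainfall`, `sunshine`, `daylength`.
#' @param sd_year occasion-level residual SD per arm (length 3 or scalar).
#' @param sd_day day-level residual SD.
#' @param latitude degrees north, for daylength.
#' @param wear_beta shape parameters of the Beta wear-fraction draw for
#'   worn days (default median ~ 750/1440).
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"` non-wear mechanism.
#' @param miss_rate target marginal probability that a day is fully
#'   non-worn (missing).
#' @param mar_coefs logit-scale coefficients of missingness on
#'   `sqrt_rainfall` (centred), `weekend` and standardized BMI (MAR and
#'   MNAR mechanisms).
#' @param mnar_coef additional logit-scale coefficient on the day's
#'   standardized latent log activity (negative = under-wearing on
#'   low-activity days; MNAR only).
#' @param extra_week_prob probability that a participant-occasion provides
#'   a following (substitution) week of day records.
#' @param force_full_wear set every worn day to 1440 min (a zero-partial,
#'   and with `miss_rate = 0` a zero-missingness, world).
#' @param cutoff_minutes,run_minutes classification settings the generator
#'   respects when labelling days and building epoch streams.
#' @param female_prob,age_mean,age_sd,bmi_mean,bmi_sd,n_regions covariate
#'   distributions.
#' @param epoch_len epoch length (seconds) for generated streams.
#' @param seed integer seed; same config + seed is bit-reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 300L, alloc = c(3, 4, 3),
                       baseline_log_mean = log(6500), sd_participant = 0.45,
                       year_effects = c(0, -0.03, -0.05),
                       arm_effects = rbind(c(600, 400), c(350, 250), c(0, 0)),
                       weekday_effects = c(0, 0, 0, 0, 0, -0.05, -0.15),
                       weather_coefs = c(temperature = 0.004,
                                         sqrt_rainfall = -0.03,
                                         sunshine = 0.008,
                                         daylength = 0.005),
                       sd_year = 0.25, sd_day = 0.35, latitude = 51.4,
                       wear_beta = c(5, 4.6),
                       mechanism = c("MCAR", "MAR", "MNAR"),
                       miss_rate = 0.1,
                       mar_coefs = c(sqrt_rainfall = 0.5, weekend = 0.6,
                                     bmi = 0.3),
                       mnar_coef = -1,
                       extra_week_prob = 0.25, force_full_wear = FALSE,
                       cutoff_minutes = 540, run_minutes = 60,
                       female_prob = 0.5, age_mean = 69.75, age_sd = 6.7,
                       bmi_mean = 32, bmi_sd = 5, n_regions = 3L,
                       epoch_len = 5L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate must be in [0, 1)")
  arm_effects <- matrix(arm_effects, 3, 2)
  sd_year <- rep_len(sd_year, 3)
  if (any(c(sd_participant, sd_year, sd_day) < 0))
    stop("standard deviations must be non-negative")
  if (length(weekday_effects) != 7) stop("weekday_effects must have length 7")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a trial with known truth
#'
#' Generates participants, per-day weather auxiliaries, latent daily step
#' counts, a wear process with the configured missingness mechanism, and
#' (optionally) epoch-level streams whose reconstruction by
#' [detect_nonwear()]/[classify_days()] reproduces the simulated wear and
#' status labels.
#'
#' Daily counts are `round(exp(latent) + arm effect)` with the latent scale
#' carrying participant, occasion and day residuals plus weekday and
#' weather effects; arm effects are additive on the count scale so the
#' true week-average contrasts versus usual care equal
#' `arm_effects[1:2, ] - arm_effects[3, ]` by construction. Partial days
#' record activity proportional to worn time, so the recorded count is a
#' genuinely right-censored version of the full-day count — the structural
#' assumption Tobit imputation relies on.
#'
#' @param config a [sim_config()].
#' @param epochs also generate epoch streams for week-1 days? (Memory
#'   scales as `n * 21 * 86400 / epoch_len`; intended for small n.)
#' @return list with `dataset` (a classified [trial_dataset()], including
#'   any extra-week records and auxiliaries), `truth` (true contrasts,
#'   full-day counts, per-cell labels, the config) and `streams` (list of
#'   [epoch_stream()] or `NULL`).
#' @export
simulate_trial <- function(config = sim_config(), epochs = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  n <- as.integer(cf$n_participants)

  # participants: allocation by ratio, then shuffled
  counts <- floor(n * cf$alloc / sum(cf$alloc))
  rem <- n - sum(counts)
  if (rem > 0) counts[order(-(n * cf$alloc / sum(cf$alloc) - counts))[
    seq_len(rem)]] <- counts[order(-(n * cf$alloc / sum(cf$alloc) -
                                       counts))[seq_len(rem)]] + 1L
  arm <- sample(rep.int(1:3, counts))
  participants <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)), arm = arm,
    female = rbinom(n, 1, cf$female_prob),
    age = round(rnorm(n, cf$age_mean, cf$age_sd), 1),
    region = paste0("r", sample.int(cf$n_regions, n, replace = TRUE)),
    bmi = round(rnorm(n, cf$bmi_mean, cf$bmi_sd), 1),
    stringsAsFactors = FALSE)

  # day grid: week 1 always; week 2 per participant-occasion with prob
  monday0 <- as.Date("2014-01-06")      # a Monday
  start_week <- matrix(sample.int(52L, n * 3L, replace = TRUE) - 1L, n, 3L)
  has_w2 <- matrix(runif(n * 3L) < cf$extra_week_prob, n, 3L)
  grid1 <- expand.grid(k = 1:7, j = 0:2, i = seq_len(n),
                       KEEP.OUT.ATTRS = FALSE)
  grid1$week <- 1L
  g2 <- expand.grid(k = 1:7, j = 0:2, i = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  g2$week <- 2L
  g2 <- g2[has_w2[cbind(g2$i, g2$j + 1L)], ]
  grid <- rbind(grid1, g2)
  # dates: per-occasion random start Monday; 364 days keeps the weekday
  grid$date <- monday0 + 7L * start_week[cbind(grid$i, grid$j + 1L)] +
    364L * grid$j + 7L * (grid$week - 1L) + (grid$k - 1L)
  N <- nrow(grid)

  # weather: seasonal sinusoids with naturally correlated components
  doy <- as.integer(strftime(grid$date, "%j"))
  daylength <- compute_daylength(cf$latitude, grid$date)
  temperature <- 11 + 8 * cos(2 * pi * (doy - 200) / 365.25) + rnorm(N, 0, 3)
  sunshine <- pmax(0, 0.45 * daylength - 1.5 + rnorm(N, 0, 1.8))
  sqrt_rainfall <- pmax(0, rnorm(N, 1.1 - 0.05 * sunshine, 0.6))

  # latent daily activity
  mu_i <- cf$baseline_log_mean + rnorm(n, 0, cf$sd_participant)
  u_ij <- matrix(rnorm(n * 3L, 0, rep(cf$sd_year[arm], 3L)), n, 3L)
  wc <- cf$weather_coefs
  latent <- mu_i[grid$i] + cf$year_effects[grid$j + 1L] +
    cf$weekday_effects[grid$k] +
    wc[["temperature"]] * temperature + wc[["sqrt_rainfall"]] * sqrt_rainfall +
    wc[["sunshine"]] * sunshine + wc[["daylength"]] * daylength +
    u_ij[cbind(grid$i, grid$j + 1L)] + rnorm(N, 0, cf$sd_day)
  arm_add <- numeric(N)
  post <- grid$j > 0L
  arm_add[post] <- cf$arm_effects[cbind(arm[grid$i[post]], grid$j[post])]
  y_full <- pmax(round(exp(latent) + arm_add), 0)

  # missingness mechanism: calibrate the intercept to the target rate
  if (cf$miss_rate == 0) {
    p_mis <- rep(0, N)
  } else {
    lp <- rep(0, N)
    if (cf$mechanism %in% c("MAR", "MNAR")) {
      bmi_z <- (participants$bmi - mean(participants$bmi)) /
        sd(participants$bmi)
      lp <- cf$mar_coefs[["sqrt_rainfall"]] *
        (sqrt_rainfall - mean(sqrt_rainfall)) +
        cf$mar_coefs[["weekend"]] * (grid$k >= 6) +
        cf$mar_coefs[["bmi"]] * bmi_z[grid$i]
    }
    if (cf$mechanism == "MNAR")
      lp <- lp + cf$mnar_coef * (latent - mean(latent)) / sd(latent)
    a0 <- uniroot(function(a) mean(plogis(a + lp)) - cf$miss_rate,
                  c(-30, 30))$root
    p_mis <- plogis(a0 + lp)
  }
  missing_day <- runif(N) < p_mis

  # wear time for worn days: scaled Beta, snapped to whole minutes and to
  # a reconstructible gap (non-wear is 0 or >= run_minutes)
  wear <- ifelse(missing_day, 0, round(rbeta(N, cf$wear_beta[1],
                                             cf$wear_beta[2]) * 1440))
  if (cf$force_full_wear) wear[!missing_day] <- 1440
  wear[!missing_day & wear < 1] <- 1
  snap <- !missing_day & (1440 - wear) > 0 & (1440 - wear) < cf$run_minutes
  wear[snap] <- 1440
  status <- ifelse(missing_day, "missing",
                   ifelse(wear < cf$cutoff_minutes, "partial", "observed"))
  recorded <- ifelse(status == "observed", y_full,
                     ifelse(status == "partial",
                            round(y_full * wear / 1440), 0))
  # keep worn days reconstructible from epochs (no spurious 60-min gaps)
  floor_steps <- ceiling(2 * wear / cf$run_minutes)
  recorded <- ifelse(status == "partial",
                     pmax(recorded, floor_steps), recorded)

  days <- data.frame(participant_id = participants$participant_id[grid$i],
                     year = grid$j, week = grid$week, day_of_week = grid$k,
                     step_count = recorded, wear_minutes = wear,
                     status = status, substituted_from = NA_integer_,
                     stringsAsFactors = FALSE)
  aux <- data.frame(participant_id = participants$participant_id[grid$i],
                    year = grid$j, week = grid$week, day_of_week = grid$k,
                    date = grid$date, temperature = temperature,
                    sqrt_rainfall = sqrt_rainfall, sunshine = sunshine,
                    daylength = daylength, stringsAsFactors = FALSE)
  dataset <- trial_dataset(days, participants, aux)

  truth <- list(
    contrasts = cf$arm_effects[1:2, , drop = FALSE] -
      rep(cf$arm_effects[3, ], each = 2),
    full_day_counts = data.frame(participant_id = days$participant_id,
                                 year = days$year, week = days$week,
                                 day_of_week = days$day_of_week,
                                 y_full = y_full, p_missing = p_mis,
                                 stringsAsFactors = FALSE),
    mechanism = cf$mechanism, config = cf)

  streams <- NULL
  if (epochs) {
    w1 <- which(grid$week == 1L)
    streams <- lapply(w1, function(r) {
      build_epoch_stream(participants$participant_id[grid$i[r]], grid$j[r],
                         grid$k[r], recorded[r], wear[r], cf$epoch_len)
    })
  }
  list(dataset = dataset, truth = truth, streams = streams)
}

# one simulated day's epochs: a single non-wear zero block (>= run_minutes
# by construction) at the start of the day, steps spread evenly over worn
# epochs so no worn zero-run can approach the detection threshold
build_epoch_stream <- function(pid, year, dow, count, wear_min, epoch_len) {
  n_epochs <- DAY_SECONDS / epoch_len
  per_min <- 60 / epoch_len
  worn <- wear_min * per_min
  steps <- numeric(n_epochs)
  if (worn > 0 && count > 0) {
    pos <- n_epochs - worn + seq_len(worn)   # worn block at end of day
    base <- count %/% worn
    extra <- count - base * worn
    alloc <- rep.int(base, worn)
    if (extra > 0)
      alloc[unique(round(seq(1, worn, length.out = extra)))] <-
        alloc[unique(round(seq(1, worn, length.out = extra)))] + 1
    # rounding of the spread positions can drop a few: top up deterministically
    short <- count - sum(alloc)
    if (short > 0) alloc[seq_len(short)] <- alloc[seq_len(short)] + 1
    steps[pos] <- alloc
  }
  epoch_stream(pid, year, dow, steps, week = 1L, epoch_len = epoch_len)
}
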