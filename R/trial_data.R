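#' Assemble a trial dataset
#'
#' The working data model: classified day records joined to participant
#' covariates and (optionally) day-level weather auxiliaries.
#'
#' @param days data frame with columns `participant_id`, `year` (0,1,2),
#'   `week`, `day_of_week` (1..7), `step_count`, `wear_minutes`, `status`,
#'   and optionally `substituted_from`.
#' @param participants data frame with columns `participant_id`, `arm`
#'   (1 = individual therapy, 2 = group therapy, 3 = usual care), `female`
#'   (0/1), `age` (years), `region` (categorical), `bmi` (kg/m^2).
#' @param aux optional data frame with columns `participant_id`, `year`,
#'   `week`, `day_of_week`, `date`, `temperature` (deg C, daytime maximum),
#'   `sqrt_rainfall` (square root of mm/24 h), `sunshine` (hours),
#'   `daylength` (hours).
#' @param age_center value to centre age at; defaults to the sample mean.
#'   Stored on the object so model matrices are reproducible.
#' @return an object of class `trial_dataset`.
#' @export
trial_dataset <- function(days, participants, aux = NULL, age_center = NULL) {
  need_d <- c("participant_id", "year", "week", "day_of_week",
              "step_count", "wear_minutes", "status")
  miss <- setdiff(need_d, names(days))
  if (length(miss))
    stop("days is missing column(s): ", paste(miss, collapse = ", "))
  if (!"substituted_from" %in% names(days))
    days$substituted_from <- NA_integer_
  days$substituted_from <- as.integer(days$substituted_from)
  need_p <- c("participant_id", "arm", "female", "age", "region", "bmi")
  miss <- setdiff(need_p, names(participants))
  if (length(miss))
    stop("participants is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(participants$participant_id))
    stop("duplicate participant_id in participants")
  if (!all(participants$arm %in% 1:3))
    stop("arm codes must be 1 (individual), 2 (group) or 3 (usual care)")
  if (!all(days$day_of_week %in% 1:7))
    stop("day_of_week must be in 1..7")
  if (!all(days$year %in% 0:2)) stop("year must be 0, 1 or 2")
  if (!all(days$status %in% STATUS_LEVELS))
    stop("status must be one of: ", paste(STATUS_LEVELS, collapse = ", "))
  if (!all(days$participant_id %in% participants$participant_id))
    stop("days contains participants absent from the covariate table")
  key <- interaction(days$participant_id, days$year, days$week,
                     days$day_of_week, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (participant, year, week, day_of_week) day records")
  bad <- days$status == "missing" &
    (days$wear_minutes != 0 | days$step_count != 0)
  if (any(bad))
    stop("missing days must have zero wear time and zero step count")
  if (!is.null(aux)) {
    if (!"week" %in% names(aux)) aux$week <- 1L
    need_a <- c("participant_id", "year", "week", "day_of_week",
                "temperature", "sqrt_rainfall", "sunshine", "daylength")
    miss <- setdiff(need_a, names(aux))
    if (length(miss))
      stop("aux is missing column(s): ", paste(miss, collapse = ", "))
    if (any(aux$sqrt_rainfall < 0)) stop("sqrt_rainfall must be >= 0")
    if (any(aux$daylength <= 0 | aux$daylength >= 24))
      stop("daylength must lie in (0, 24) hours")
  }
  participants$region <- as.factor(participants$region)
  if (is.null(age_center)) age_center <- mean(participants$age)
  structure(list(days = days, participants = participants, aux = aux,
                 age_center = age_center),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- nrow(x$participants)
  cat(sprintf("trial_dataset: %d participants, %d day records\n",
              n, nrow(x$days)))
  cat("  arms:", paste(sprintf("%d=%d", 1:3, tabulate(x$participants$arm, 3)),
                       collapse = " "), "\n")
  tab <- table(factor(x$days$status, STATUS_LEVELS))
  cat("  day status:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  auxiliaries:", if (is.null(x$aux)) "none" else "present", "\n")
  invisible(x)
}

#' Photoperiod (daylength) from latitude and date
#'
#' Daylength in hours from solar orbital geometry (the CBM model of
#' Forsythe et al. 1995: solar declination from day of year, then the
#' sunrise hour angle). Valid away from the polar circles.
#'
#' @param latitude degrees north (negative = south); must satisfy
#'   `abs(latitude) < 66.5`.
#' @param date a `Date` (or string coercible to one), or an integer day of
#'   year in 1..366.
#' @return daylength in hours.
#' @export
compute_daylength <- function(latitude, date) {
  if (any(abs(latitude) >= 66.5))
    stop("polar latitudes (|lat| >= 66.5) are not supported")
  if (inherits(date, "Date") || is.character(date)) {
    date <- as.Date(date)
    doy <- as.integer(strftime(date, "%j"))
  } else {
    doy <- as.numeric(date)
    if (any(doy < 1 | doy > 366)) stop("day of year must be in 1..366")
  }
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  phi <- asin(0.39795 * cos(theta))         # solar declination, radians
  p <- 0.8333 * pi / 180                    # sun centre + refraction
  latr <- latitude * pi / 180
  a <- (sin(p) + sin(latr) * sin(phi)) / (cos(latr) * cos(phi))
  a <- pmin(pmax(a, -1), 1)
  24 - (24 / pi) * acos(a)
}

#' Read and write a trial dataset as plain CSV files
#'
#' `write_trial()` writes `days.csv`, `participants.csv` and (if present)
#' `aux.csv` under `dir`; `read_trial()` reads them back, validating the
#' schema. Round-tripping a valid dataset is an identity.
#'
#' @param dataset a [trial_dataset()].
#' @param dir directory for the CSV files.
#' @return `read_trial()` returns a [trial_dataset()].
#' @export
write_trial <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(dataset$days, file.path(dir, "days.csv"), row.names = FALSE)
  write.csv(dataset$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  if (!is.null(dataset$aux))
    write.csv(dataset$aux, file.path(dir, "aux.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial
#' @param age_center passed to [trial_dataset()].
#' @export
read_trial <- function(dir, age_center = NULL) {
  days <- read.csv(file.path(dir, "days.csv"), stringsAsFactors = FALSE)
  participants <- read.csv(file.path(dir, "participants.csv"),
                           stringsAsFactors = FALSE)
  aux_path <- file.path(dir, "aux.csv")
  aux <- if (file.exists(aux_path))
    read.csv(aux_path, stringsAsFactors = FALSE) else NULL
  trial_dataset(days, participants, aux, age_center = age_center)
}

# in-window (week 1) day records ordered participant x year x day
inwindow_days <- function(dataset) {
  d <- dataset$days[dataset$days$week == 1L, ]
  d[order(match(d$participant_id, dataset$participants$participant_id),
          d$year, d$day_of_week), ]
}

# check the in-window grid is complete: one record per (participant, year, day)
assert_complete_grid <- function(dataset) {
  d <- inwindow_days(dataset)
  n <- nrow(dataset$participants)
  if (nrow(d) != n * 21L)
    stop("expected one week-1 record per (participant, year, day): have ",
         nrow(d), ", want ", n * 21L)
  invisible(d)
}

# n x 21 matrices of counts / wear / status for week-1 records
day_matrices <- function(dataset) {
  d <- assert_complete_grid(dataset)
  n <- nrow(dataset$participants)
  ids <- dataset$participants$participant_id
  idx <- cbind(match(d$participant_id, ids), yd_col(d$year, d$day_of_week))
  mk <- function(v, init) {
    m <- matrix(init, n, 21L, dimnames = list(ids, yd_labels()))
    m[idx] <- v
    m
  }
  list(count = mk(d$step_count, NA_real_),
       status = mk(d$status, NA_character_))
}

# n x 21 x 4 array of auxiliaries (temperature, sqrt_rainfall, sunshine,
# daylength) for week-1 records; NULL when aux is absent
aux_array <- function(dataset) {
  if (is.null(dataset$aux)) return(NULL)
  a <- dataset$aux[dataset$aux$week == 1L, ]
  ids <- dataset$participants$participant_id
  n <- length(ids)
  vars <- c("temperature", "sqrt_rainfall", "sunshine", "daylength")
  arr <- array(NA_real_, c(n, 21L, 4L), dimnames = list(ids, yd_labels(), vars))
  idx <- cbind(match(a$participant_id, ids), yd_col(a$year, a$day_of_week))
  for (v in seq_along(vars)) arr[cbind(idx, v)] <- a[[vars[v]]]
  if (anyNA(arr))
    stop("auxiliaries must cover every (participant, year, day) cell")
  arr
}

# fixed-effect covariate matrix: female, centred age, region dummies
# (reference = first level alphabetically); optionally BMI
participant_design <- function(dataset, include_bmi = FALSE) {
  p <- dataset$participants
  reg <- model.matrix(~ region, data = p)[, -1, drop = FALSE]
  Z <- cbind(female = p$female, age = p$age - dataset$age_center, reg)
  if (include_bmi) Z <- cbind(Z, bmi = p$bmi)
  rownames(Z) <- p$participant_id
  Z
}
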