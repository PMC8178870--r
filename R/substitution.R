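#' Day-substitution from the following week
#'
#' Replaces missing or partially observed in-window (week 1) days with
#' records from the following week (week 2), assuming step counts are
#' exchangeable across adjacent weeks given the day of the week:
#'
#' * a `missing` week-1 day is replaced by the week-2 record for the same
#'   day of the week — an `observed` one if available, otherwise a
#'   `partial` one (which keeps its partial status, and hence its censoring
#'   bound, downstream);
#' * a `partial` week-1 day is replaced only by an `observed` week-2 record;
#' * `observed` week-1 days are never altered.
#'
#' With `strategy = "sunshine"` the replacement is instead drawn from the
#' week-2 day (any weekday) with sunshine hours closest to the target day's,
#' restricted to the same allowed statuses; ties prefer the same day of the
#' week, then the earliest day. This requires auxiliaries covering week 2.
#'
#' @param dataset a [trial_dataset()] whose week-1 grid is complete.
#' @param strategy `"same-weekday"` (default) or `"sunshine"`.
#' @return the dataset with week-1 records substituted where possible
#'   (`substituted_from` records the source week) and week-2 records
#'   dropped; exactly one record per (participant, year, day) remains.
#' @export
day_substitute <- function(dataset, strategy = c("same-weekday", "sunshine")) {
  stopifnot(inherits(dataset, "trial_dataset"))
  strategy <- match.arg(strategy)
  d <- dataset$days
  w1 <- d[d$week == 1L, ]
  w2 <- d[d$week == 2L, ]
  assert_complete_grid(dataset)
  if (strategy == "sunshine") {
    if (is.null(dataset$aux) || !any(dataset$aux$week == 2L))
      stop("sunshine-matched substitution requires week-2 auxiliaries")
    akey <- function(p, y, w, k) paste(p, y, w, k, sep = "\r")
    aux_sun <- setNames(dataset$aux$sunshine,
                        akey(dataset$aux$participant_id, dataset$aux$year,
                             dataset$aux$week, dataset$aux$day_of_week))
  }
  if (nrow(w2)) {
    key2 <- paste(w2$participant_id, w2$year, sep = "\r")
    w2_by <- split(seq_len(nrow(w2)), key2)
  }
  out <- w1
  needs <- which(w1$status %in% c("missing", "partial"))
  for (i in needs) {
    row <- w1[i, ]
    if (!nrow(w2)) break
    cand_idx <- w2_by[[paste(row$participant_id, row$year, sep = "\r")]]
    if (is.null(cand_idx)) next
    cand <- w2[cand_idx, ]
    # a partial in-window day may only be upgraded to observed
    allowed <- if (row$status == "missing") c("observed", "partial")
               else "observed"
    cand <- cand[cand$status %in% allowed, , drop = FALSE]
    if (!nrow(cand)) next
    if (strategy == "same-weekday") {
      cand <- cand[cand$day_of_week == row$day_of_week, , drop = FALSE]
      if (!nrow(cand)) next
      # observed beats partial when both are available
      cand <- cand[order(match(cand$status, STATUS_LEVELS)), , drop = FALSE]
      pick <- cand[1, ]
    } else {
      target_sun <- aux_sun[[akey(row$participant_id, row$year, 1L,
                                  row$day_of_week)]]
      cand_sun <- aux_sun[akey(cand$participant_id, cand$year, 2L,
                               cand$day_of_week)]
      if (is.null(target_sun) || anyNA(cand_sun))
        stop("auxiliaries do not cover the days needed for sunshine matching")
      o <- order(match(cand$status, STATUS_LEVELS),
                 abs(cand_sun - target_sun),
                 cand$day_of_week != row$day_of_week,
                 cand$day_of_week)
      pick <- cand[o[1], ]
    }
    out$step_count[i] <- pick$step_count
    out$wear_minutes[i] <- pick$wear_minutes
    out$status[i] <- pick$status
    out$substituted_from[i] <- 2L
  }
  trial_dataset(out, dataset$participants, dataset$aux,
                age_center = dataset$age_center)
}

#' Tabulate status transitions caused by day-substitution
#'
#' @param before,after the [trial_dataset()] before and after
#'   [day_substitute()]; week-1 cells must match.
#' @return data frame with columns `year`, `arm`, `day_of_week`,
#'   `status_before`, `status_after`, `n` (zero-count combinations omitted),
#'   with the overall 3x3 before-by-after contingency table attached as
#'   attribute `"overall"`.
#' @export
substitution_report <- function(before, after) {
  b <- inwindow_days(before)
  a <- inwindow_days(after)
  kb <- paste(b$participant_id, b$year, b$day_of_week, sep = "\r")
  ka <- paste(a$participant_id, a$year, a$day_of_week, sep = "\r")
  if (nrow(b) != nrow(a) || !all(kb == ka))
    stop("before/after datasets do not cover the same week-1 cells")
  arm <- before$participants$arm[match(b$participant_id,
                                       before$participants$participant_id)]
  f <- function(s) factor(s, STATUS_LEVELS)
  tab <- as.data.frame(table(year = b$year, arm = arm,
                             day_of_week = b$day_of_week,
                             status_before = f(b$status),
                             status_after = f(a$status)))
  names(tab)[names(tab) == "Freq"] <- "n"
  tab <- tab[tab$n > 0, ]
  for (v in c("year", "arm", "day_of_week"))
    tab[[v]] <- as.integer(as.character(tab[[v]]))
  rownames(tab) <- NULL
  ok <- tab$status_before == tab$status_after |
    (tab$status_before == "missing" &
       tab$status_after %in% c("observed", "partial")) |
    (tab$status_before == "partial" & tab$status_after == "observed")
  if (!all(ok))
    stop("status transitions in a disallowed direction; inputs are not a ",
         "before/after pair from day_substitute()")
  structure(tab, overall = table(before = f(b$status), after = f(a$status)))
}
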