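#' Imputation settings
#'
#' @param M number of imputations (default 20).
#' @param cycles number of chained-equation burn-in cycles (default 10).
#' @param seed integer seed; all randomness in [chained_impute()] derives
#'   from it via per-(group, imputation) substreams, so results are
#'   reproducible and imputations could be computed independently.
#' @param log_offset pseudo-count added before taking logs so observed
#'   zero-step days stay representable; counts are recovered as
#'   `max(exp(v) - log_offset, 0)`.
#' @param upper_mult the common upper bound for incomplete cells is
#'   `log(upper_mult * max recorded daily count + log_offset)` — at least
#'   as high as the log of the highest count seen in the study.
#' @param pool_arms fit shared imputation coefficients with arm indicator
#'   covariates instead of imputing separately per arm; useful when an arm
#'   subsample is too small for the day-predictor design.
#' @param maxiter Newton iteration cap for each interval regression.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(M = 20L, cycles = 10L, seed = 1L,
                            log_offset = 1, upper_mult = 1.5,
                            pool_arms = FALSE, maxiter = 300L) {
  if (M < 2) stop("M must be at least 2")
  if (cycles < 1) stop("cycles must be at least 1")
  if (log_offset <= 0) stop("log_offset must be positive")
  structure(list(M = as.integer(M), cycles = as.integer(cycles),
                 seed = as.integer(seed), log_offset = log_offset,
                 upper_mult = upper_mult, pool_arms = isTRUE(pool_arms),
                 maxiter = as.integer(maxiter)),
            class = "imputation_spec")
}

#' Interval-censoring bounds for every (participant, year, day) cell
#'
#' On the `log(count + offset)` scale: observed cells get a degenerate
#' interval at their recorded value; partial cells (when imputed as
#' censored) are bounded below by their recorded value and above by the
#' common limit `U`; missing cells are unbounded below (`-Inf`) and bounded
#' above by `U`. With `impute_partial_as_censored = FALSE` (the dismissive
#' treatment) partial cells are handled as missing. A partial cell whose
#' recorded count is zero carries no censoring information and is demoted
#' to missing with a warning.
#'
#' @param dataset a classified (and optionally substituted) [trial_dataset()]
#'   with a complete week-1 grid.
#' @param spec an [imputation_spec()].
#' @param impute_partial_as_censored keep partial cells as right-censored?
#' @return list with `lower`, `upper` (n x 21 matrices), `status`
#'   (effective status actually imputed under), `orig_status`, and `U`.
#' @export
build_bounds <- function(dataset, spec = imputation_spec(),
                         impute_partial_as_censored = TRUE) {
  m <- day_matrices(dataset)
  off <- spec$log_offset
  status <- m$status
  if (any(status == "partial" & m$count == 0)) {
    warning("partial day(s) with zero recorded steps treated as missing")
    status[status == "partial" & m$count == 0] <- "missing"
  }
  orig <- status
  if (!impute_partial_as_censored) status[status == "partial"] <- "missing"
  U <- log(spec$upper_mult * max(m$count) + off)
  lv <- log(m$count + off)
  lower <- ifelse(status == "observed", lv,
                  ifelse(status == "partial", lv, -Inf))
  upper <- ifelse(status == "observed", lv, U)
  if (any(lower[is.finite(lower)] > upper[is.finite(lower)]))
    stop("a censoring lower bound exceeds the common upper limit U")
  dimnames(lower) <- dimnames(upper) <- dimnames(status) <- dimnames(m$count)
  list(lower = lower, upper = upper, status = status, orig_status = orig,
       U = U)
}

#' Multiple imputation of daily log step counts by chained equations
#'
#' Implements the per-arm chained-equations scheme with interval-censored
#' Gaussian regressions. Within each arm (or pooled, with arm indicators)
#' and each imputation:
#'
#' 1. incomplete cells are initialised by draws from the empirical
#'    distribution of observed log counts for the same (group, year,
#'    day of week), restricted to the cell's bounds;
#' 2. for each burn-in cycle, each baseline day is regressed on the other
#'    six baseline days, all seven year-1 and year-2 days, sex, centred
#'    age, region dummies and — when auxiliaries are used — BMI and that
#'    day's temperature, square-root rainfall, sunshine and daylength;
#'    incomplete cells are redrawn from the truncated posterior predictive.
#'    The within-week mean of baseline logs is then refreshed and used in
#'    place of the seven daily baseline predictors when each year-1 day,
#'    and then each year-2 day, is imputed analogously;
#' 3. parameters are redrawn from the asymptotic-normal approximate
#'    posterior at every regression, so each imputation propagates
#'    parameter uncertainty.
#'
#' Days are visited Monday to Sunday within each year, years in order
#' baseline, 1, 2; the order is fixed for reproducibility.
#'
#' @param dataset a classified [trial_dataset()] with a complete week-1 grid.
#' @param spec an [imputation_spec()].
#' @param use_auxiliaries include BMI and day-level weather in the
#'   imputation designs (requires the dataset to carry auxiliaries).
#' @param impute_partial_as_censored passed to [build_bounds()].
#' @return an object of class `imputed_set`: `log_steps` is an
#'   `n x 21 x M` array of completed log counts (columns `y0_d1` ...
#'   `y2_d7`), plus the bounds used, the effective and original statuses,
#'   participant covariates and per-regression coefficient diagnostics
#'   from the final cycle.
#' @export
chained_impute <- function(dataset, spec = imputation_spec(),
                           use_auxiliaries = !is.null(dataset$aux),
                           impute_partial_as_censored = TRUE) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(spec, "imputation_spec"))
  if (use_auxiliaries && is.null(dataset$aux))
    stop("use_auxiliaries = TRUE but the dataset has no auxiliaries")
  b <- build_bounds(dataset, spec, impute_partial_as_censored)
  m <- day_matrices(dataset)
  n <- nrow(dataset$participants)
  off <- spec$log_offset
  Y0 <- log(m$count + off)         # observed values; incomplete get redrawn
  incomplete <- b$status != "observed"
  Z <- participant_design(dataset, include_bmi = use_auxiliaries)
  AUX <- if (use_auxiliaries) aux_array(dataset) else NULL
  arm <- dataset$participants$arm
  groups <- if (spec$pool_arms) list(all = seq_len(n)) else
    split(seq_len(n), arm)
  if (spec$pool_arms)
    Z <- cbind(Z, arm1 = as.numeric(arm == 1), arm2 = as.numeric(arm == 2))

  out <- array(NA_real_, c(n, 21L, spec$M),
               dimnames = list(rownames(Y0), yd_labels(), NULL))
  diagnostics <- vector("list", spec$M)

  if (!any(incomplete)) {          # nothing to impute: M identical copies
    for (mm in seq_len(spec$M)) out[, , mm] <- Y0
    return(new_imputed_set(out, b, Y0, dataset, spec, use_auxiliaries,
                           diagnostics))
  }

  set.seed(spec$seed)
  substream <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(groups) * spec$M),
                      nrow = length(groups))

  # predictor block for response column cc within group rows
  make_design <- function(Y, b0mean, cc, rows) {
    j <- (cc - 1L) %/% 7L
    if (j == 0L) {
      P <- Y[rows, setdiff(1:21, cc), drop = FALSE]
    } else {
      P <- cbind(b0mean = b0mean[rows],
                 Y[rows, setdiff(8:21, cc), drop = FALSE])
    }
    P <- cbind(P, Z[rows, , drop = FALSE])
    if (!is.null(AUX)) P <- cbind(P, AUX[rows, cc, , drop = TRUE])
    P
  }

  # reduced design for regressions the full day-predictor design cannot
  # identify (e.g. a column with too few exact rows): year-mean log
  # predictors (own column excluded from its year) plus the covariates
  make_reduced_design <- function(Y, cc, rows) {
    yr_mean <- function(cols) {
      if (cc %in% cols) cols <- setdiff(cols, cc)
      rowMeans(Y[rows, cols, drop = FALSE])
    }
    P <- cbind(m0 = yr_mean(1:7), m1 = yr_mean(8:14), m2 = yr_mean(15:21),
               Z[rows, , drop = FALSE])
    if (!is.null(AUX)) P <- cbind(P, AUX[rows, cc, , drop = TRUE])
    P
  }

  for (mm in seq_len(spec$M)) {
    Y <- Y0
    diag_m <- list()
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      if (!any(incomplete[rows, ])) next
      set.seed(substream[g, mm])
      # empirical initialisation within bounds
      for (cc in 1:21) {
        inc <- rows[incomplete[rows, cc]]
        if (!length(inc)) next
        cand <- Y0[rows, cc][!incomplete[rows, cc]]
        mu0 <- if (length(cand) > 1) mean(cand) else mean(Y0[!incomplete])
        sd0 <- if (length(cand) > 1) max(sd(cand), 0.1) else
          max(sd(Y0[!incomplete]), 0.1)
        for (i in inc) {
          ok <- cand[cand >= b$lower[i, cc] & cand <= b$upper[i, cc]]
          Y[i, cc] <- if (length(ok)) sample(ok, 1L) else
            rtruncnorm(1L, mu0, sd0, b$lower[i, cc], b$upper[i, cc])
        }
      }
      warm <- vector("list", 21L)
      ncov <- ncol(Z) + if (is.null(AUX)) 0L else 4L
      if (length(rows) < 20L + ncov + 3L)
        stop("group of ", length(rows), " participants is too small for the ",
             "imputation design; consider imputation_spec(pool_arms = TRUE)")
      b0mean <- rowMeans(Y[, 1:7, drop = FALSE])
      for (cyc in seq_len(spec$cycles)) {
        last <- cyc == spec$cycles
        for (cc in 1:21) {
          if (cc == 8L) b0mean <- rowMeans(Y[, 1:7, drop = FALSE])
          inc <- incomplete[rows, cc]
          if (!any(inc)) next
          P <- make_design(Y, b0mean, cc, rows)
          fit <- tryCatch(
            fit_interval_regression(P, b$lower[rows, cc], b$upper[rows, cc],
                                    maxiter = spec$maxiter,
                                    init = warm[[cc]]),
            error = function(e) {
              tryCatch(
                if (!is.null(warm[[cc]]))  # retry cold if warm start failed
                  fit_interval_regression(P, b$lower[rows, cc],
                                          b$upper[rows, cc],
                                          maxiter = spec$maxiter)
                else stop(e),
                error = function(e2) e2)   # marker: full design failed
            })
          if (inherits(fit, "error")) {
            # the full day-predictor design is not identified for this
            # column (common under heavy censoring in small groups):
            # fall back to year-mean predictors
            warning("column ", yd_labels()[cc], ", group ", g,
                    ": falling back to the reduced year-mean design (",
                    conditionMessage(fit), ")", call. = FALSE)
            P <- make_reduced_design(Y, cc, rows)
            fit <- fit_interval_regression(P, b$lower[rows, cc],
                                           b$upper[rows, cc],
                                           maxiter = spec$maxiter)
            warm[[cc]] <- NULL
          } else {
            warm[[cc]] <- if (!length(fit$dropped))
              c(fit$coefficients, log(fit$sigma)) else NULL
          }
          Y[rows[inc], cc] <- draw_imputations(
            fit, P[inc, , drop = FALSE],
            b$lower[rows, cc][inc], b$upper[rows, cc][inc])
          if (last)
            diag_m[[paste0("g", g, "_", yd_labels()[cc])]] <-
              list(coefficients = fit$coefficients, sigma = fit$sigma)
        }
        b0mean <- rowMeans(Y[, 1:7, drop = FALSE])
      }
    }
    out[, , mm] <- Y
    diagnostics[[mm]] <- diag_m
  }
  new_imputed_set(out, b, Y0, dataset, spec, use_auxiliaries, diagnostics)
}

new_imputed_set <- function(log_steps, bounds, Y0, dataset, spec,
                            aux_used, diagnostics) {
  structure(list(log_steps = log_steps, lower = bounds$lower,
                 upper = bounds$upper, status = bounds$status,
                 orig_status = bounds$orig_status, U = bounds$U,
                 observed_log = Y0, offset = spec$log_offset,
                 M = dim(log_steps)[3], participants = dataset$participants,
                 age_center = dataset$age_center, aux_used = aux_used,
                 spec = spec, diagnostics = diagnostics),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("imputed_set: %d participants x 21 day cells x M = %d\n",
              dim(x$log_steps)[1], x$M))
  tab <- table(factor(x$status, STATUS_LEVELS))
  cat("  cell status:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  upper limit U = %.3f (log scale), offset = %g\n",
              x$U, x$offset))
  invisible(x)
}

#' Export an imputed set as a long data frame
#'
#' @param x an `imputed_set`.
#' @param ... unused.
#' @return data frame with columns `imp`, `participant_id`, `year`,
#'   `day_of_week`, `log_steps`, `steps` (back-transformed, floored at 0),
#'   `status`.
#' @export
as.data.frame.imputed_set <- function(x, ...) {
  n <- dim(x$log_steps)[1]
  grid <- expand.grid(participant_id = rownames(x$log_steps),
                      col = 1:21, imp = seq_len(x$M),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  v <- as.vector(x$log_steps)
  data.frame(imp = grid$imp, participant_id = grid$participant_id,
             year = (grid$col - 1L) %/% 7L,
             day_of_week = (grid$col - 1L) %% 7L + 1L,
             log_steps = v, steps = pmax(exp(v) - x$offset, 0),
             status = rep(as.vector(x$status), times = x$M),
             stringsAsFactors = FALSE)
}
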