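#' Week-average step counts
#'
#' Back-transforms completed daily log counts (`exp` minus the offset,
#' floored at 0) and averages the seven days of each (participant, year):
#' the week-average outcome of the primary analysis.
#'
#' For an `imputed_set` the result carries one block of rows per
#' imputation (`imp` column). A `trial_dataset` may be averaged directly
#' only when every in-window day is observed (the complete-data fit used
#' as a reference in simulations).
#'
#' @param x an `imputed_set` or fully observed [trial_dataset()].
#' @param ... unused.
#' @return data frame with columns `imp` (for imputed input),
#'   `participant_id`, `ybar0`, `ybar1`, `ybar2` (steps/day), `arm`,
#'   `female`, `age` (centred), `region`.
#' @export
week_average <- function(x, ...) UseMethod("week_average")

#' @export
week_average.imputed_set <- function(x, ...) {
  do.call(rbind, lapply(seq_len(x$M), function(mm) {
    steps <- pmax(exp(x$log_steps[, , mm]) - x$offset, 0)
    cbind(imp = mm, weekavg_frame(steps, x$participants, x$age_center))
  }))
}

#' @export
week_average.trial_dataset <- function(x, ...) {
  m <- day_matrices(x)
  if (any(m$status != "observed"))
    stop("week_average on a trial_dataset requires every in-window day ",
         "to be observed; impute first")
  weekavg_frame(m$count, x$participants, x$age_center)
}

weekavg_frame <- function(steps, participants, age_center) {
  stopifnot(ncol(steps) == 21L)
  data.frame(participant_id = participants$participant_id,
             ybar0 = rowMeans(steps[, 1:7, drop = FALSE]),
             ybar1 = rowMeans(steps[, 8:14, drop = FALSE]),
             ybar2 = rowMeans(steps[, 15:21, drop = FALSE]),
             arm = participants$arm, female = participants$female,
             age = participants$age - age_center,
             region = droplevels(as.factor(participants$region)),
             stringsAsFactors = FALSE)
}

#' Primary analysis: bivariate GLS with arm-specific residual covariance
#'
#' Fits, by maximum likelihood, the pre-specified week-average model: for
#' years j = 1, 2,
#' \deqn{\bar y_{ij} = \beta_0 + \beta_1 \mathrm{yr2} + \beta_2 I(\mathrm{arm}=1)
#'   + \beta_3 I(\mathrm{arm}=2) + \beta_4 \mathrm{yr2}\,I(\mathrm{arm}=1)
#'   + \beta_5 \mathrm{yr2}\,I(\mathrm{arm}=2) + \beta_6 \bar y_{i0}
#'   + \beta_7 \mathrm{yr2}\,\bar y_{i0} + \beta_8 \mathrm{female}
#'   + \beta_9 \mathrm{age} + \mathrm{region\ dummies} + e_{ij},}
#' with \eqn{(e_{i1}, e_{i2})' \sim N(0, \Sigma_{\mathrm{arm}_i})} and an
#' unstructured 2x2 covariance per arm (the intervention can change both
#' level and variability). Estimation iterates generalised least squares
#' for the coefficients with closed-form covariance updates from arm-wise
#' residual cross-products until the log-likelihood is stable.
#'
#' @param weeks one imputation's week-average table (see [week_average()];
#'   if an `imp` column is present it must be constant).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param sigma_df_adjust subtract this from each arm's n in the covariance
#'   divisor (0 = maximum likelihood, the default).
#' @return object of class `primary_fit`: `coefficients`, `vcov`, `Sigma`
#'   (list of per-arm 2x2 matrices), `loglik`, `n` (analysis rows),
#'   `iterations`, `converged`.
#' @export
fit_primary <- function(weeks, tol = 1e-8, max_iter = 500,
                        sigma_df_adjust = 0) {
  if ("imp" %in% names(weeks)) {
    if (length(unique(weeks$imp)) > 1)
      stop("fit_primary expects a single imputation; see pool_rubin()")
    weeks$imp <- NULL
  }
  need <- c("ybar0", "ybar1", "ybar2", "arm", "female", "age", "region")
  miss <- setdiff(need, names(weeks))
  if (length(miss))
    stop("weeks is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(weeks)
  if (any(tabulate(weeks$arm, 3) < 2))
    stop("need at least 2 participants per arm")
  weeks$region <- droplevels(as.factor(weeks$region))
  reg <- if (nlevels(weeks$region) > 1)
    model.matrix(~ region, data = weeks)[, -1, drop = FALSE]
  else matrix(0, n, 0)
  base <- cbind(arm1 = as.numeric(weeks$arm == 1),
                arm2 = as.numeric(weeks$arm == 2),
                baseline = weeks$ybar0, female = weeks$female,
                age = weeks$age, reg)
  # year-specific design rows; year-2 rows switch on yr2 and interactions
  X1 <- cbind("(Intercept)" = 1, yr2 = 0, base[, c("arm1", "arm2")],
              "yr2:arm1" = 0, "yr2:arm2" = 0, baseline = base[, "baseline"],
              "yr2:baseline" = 0, base[, -(1:3), drop = FALSE])
  X2 <- X1
  X2[, "yr2"] <- 1
  X2[, "yr2:arm1"] <- base[, "arm1"]
  X2[, "yr2:arm2"] <- base[, "arm2"]
  X2[, "yr2:baseline"] <- base[, "baseline"]
  y1 <- weeks$ybar1
  y2 <- weeks$ybar2
  arm_idx <- split(seq_len(n), weeks$arm)
  p <- ncol(X1)

  Sigma <- rep(list(diag(c(var(y1), var(y2)))), 3)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    for (a in 1:3) {
      idx <- arm_idx[[as.character(a)]]
      W <- solve(Sigma[[a]])
      x1 <- X1[idx, , drop = FALSE]; x2 <- X2[idx, , drop = FALSE]
      A <- A + W[1, 1] * crossprod(x1) + W[2, 2] * crossprod(x2) +
        W[1, 2] * (crossprod(x1, x2) + crossprod(x2, x1))
      bvec <- bvec + W[1, 1] * crossprod(x1, y1[idx]) +
        W[2, 2] * crossprod(x2, y2[idx]) +
        W[1, 2] * (crossprod(x1, y2[idx]) + crossprod(x2, y1[idx]))
    }
    beta <- drop(solve(A, bvec))
    r1 <- y1 - drop(X1 %*% beta)
    r2 <- y2 - drop(X2 %*% beta)
    ll <- -n * log(2 * pi)
    for (a in 1:3) {
      idx <- arm_idx[[as.character(a)]]
      na <- length(idx)
      S <- matrix(c(sum(r1[idx]^2), sum(r1[idx] * r2[idx]),
                    sum(r1[idx] * r2[idx]), sum(r2[idx]^2)), 2)
      Sigma[[a]] <- S / max(na - sigma_df_adjust, 2)
      if (det(Sigma[[a]]) <= 0 || any(diag(Sigma[[a]]) <= 0))
        stop("covariance update for arm ", a, " is not positive definite ",
             "(n = ", na, ")")
      W <- solve(Sigma[[a]])
      quad <- W[1, 1] * sum(r1[idx]^2) + W[2, 2] * sum(r2[idx]^2) +
        2 * W[1, 2] * sum(r1[idx] * r2[idx])
      ll <- ll - 0.5 * (na * log(det(Sigma[[a]])) + quad)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged)
    stop("primary analysis did not converge in ", max_iter, " iterations ",
         "(last log-likelihood ", signif(ll_old, 8), ")")
  # information-based covariance at the final Sigma
  A <- matrix(0, p, p)
  for (a in 1:3) {
    idx <- arm_idx[[as.character(a)]]
    W <- solve(Sigma[[a]])
    x1 <- X1[idx, , drop = FALSE]; x2 <- X2[idx, , drop = FALSE]
    A <- A + W[1, 1] * crossprod(x1) + W[2, 2] * crossprod(x2) +
      W[1, 2] * (crossprod(x1, x2) + crossprod(x2, x1))
  }
  V <- solve(A)
  names(beta) <- colnames(X1)
  dimnames(V) <- list(names(beta), names(beta))
  names(Sigma) <- paste0("arm", 1:3)
  structure(list(coefficients = beta, vcov = V, Sigma = Sigma,
                 loglik = ll_old, n = 2L * n, n_participants = n,
                 iterations = it, converged = converged),
            class = "primary_fit")
}

#' @export
print.primary_fit <- function(x, ...) {
  cat(sprintf("primary_fit: %d analysis rows, loglik %.3f (%d iterations)\n",
              x$n, x$loglik, x$iterations))
  est <- cbind(estimate = x$coefficients, se = sqrt(diag(x$vcov)))
  print(round(est, 4))
  for (a in 1:3) {
    s <- x$Sigma[[a]]
    cat(sprintf("  arm %d residual SDs (%.1f, %.1f), correlation %.3f\n", a,
                sqrt(s[1, 1]), sqrt(s[2, 2]), s[1, 2] / sqrt(s[1, 1] * s[2, 2])))
  }
  invisible(x)
}

#' Pool analysis fits across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the M estimates; total variance is
#' the within-imputation variance plus `(1 + 1/M)` times the
#' between-imputation variance. Degrees of freedom use the Barnard-Rubin
#' small-sample correction with complete-data df `n - p`.
#'
#' @param fits list of M `primary_fit` objects on identically structured
#'   designs.
#' @param conf_level confidence level for the intervals.
#' @return object of class `pooled_result` with a per-coefficient table
#'   (`estimate`, `W`, `B`, `T`, `df`, `t`, `lo`, `hi`), the pooled
#'   covariance matrices (`Wmat`, `Bmat`, `Tmat`), the averaged per-arm
#'   residual covariances, and `M`.
#' @export
pool_rubin <- function(fits, conf_level = 0.95) {
  M <- length(fits)
  if (M < 2) stop("need at least 2 fits to pool")
  if (!all(vapply(fits, inherits, TRUE, "primary_fit")))
    stop("fits must be primary_fit objects")
  cn <- names(fits[[1]]$coefficients)
  if (!all(vapply(fits, function(f)
    identical(names(f$coefficients), cn), TRUE)))
    stop("fits have mismatched coefficient sets")
  est <- t(vapply(fits, coef, numeric(length(cn))))
  qbar <- colMeans(est)
  Wmat <- Reduce(`+`, lapply(fits, function(f) f$vcov)) / M
  Bmat <- if (M > 1) cov(est) else matrix(0, length(cn), length(cn))
  Tmat <- Wmat + (1 + 1 / M) * Bmat
  W <- diag(Wmat); B <- diag(Bmat); Tv <- diag(Tmat)
  nu_com <- fits[[1]]$n - length(cn)
  df <- barnard_rubin_df(W, B, Tv, M, nu_com)
  tstat <- qbar / sqrt(Tv)
  q <- qt(1 - (1 - conf_level) / 2, df)
  table <- data.frame(term = cn, estimate = qbar, W = W, B = B, T = Tv,
                      df = df, t = tstat,
                      lo = qbar - q * sqrt(Tv), hi = qbar + q * sqrt(Tv),
                      row.names = NULL, stringsAsFactors = FALSE)
  Sigma <- setNames(lapply(1:3, function(a)
    Reduce(`+`, lapply(fits, function(f) f$Sigma[[a]])) / M),
    paste0("arm", 1:3))
  structure(list(table = table, qbar = qbar, Wmat = Wmat, Bmat = Bmat,
                 Tmat = Tmat, Sigma = Sigma, M = M, nu_com = nu_com,
                 conf_level = conf_level),
            class = "pooled_result")
}

barnard_rubin_df <- function(W, B, Tv, M, nu_com) {
  lambda <- pmin(pmax((1 + 1 / M) * B / Tv, 0), 1)
  df <- ifelse(lambda < .Machine$double.eps^0.5, nu_com, {
    nu_old <- (M - 1) / pmax(lambda^2, .Machine$double.eps)
    nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
    nu_old * nu_obs / (nu_old + nu_obs)
  })
  pmin(df, nu_com)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("pooled_result: M = %d imputations, %g%% intervals\n",
              x$M, 100 * x$conf_level))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Treatment contrasts versus usual care
#'
#' Differences in expected week-average step count for each intervention
#' arm (1 = individual therapy, 2 = group therapy) against usual care
#' (arm 3), at year 1 (the arm main effect) and year 2 (arm effect plus
#' its year-2 interaction). Variances come from the pooled covariance by
#' the delta method; degrees of freedom are Barnard-Rubin per contrast.
#'
#' @param pooled a `pooled_result` (or a single `primary_fit`, in which
#'   case plain normal-theory intervals are returned).
#' @param conf_level confidence level.
#' @return data frame with columns `arm`, `year`, `estimate`, `se`, `df`,
#'   `lo`, `hi`.
#' @export
arm_contrasts <- function(pooled, conf_level = 0.95) {
  single <- inherits(pooled, "primary_fit")
  if (!single) stopifnot(inherits(pooled, "pooled_result"))
  cn <- if (single) names(pooled$coefficients) else names(pooled$qbar)
  rows <- expand.grid(arm = 1:2, year = 1:2)
  out <- lapply(seq_len(nrow(rows)), function(r) {
    a <- rows$arm[r]; yr <- rows$year[r]
    cvec <- setNames(numeric(length(cn)), cn)
    cvec[paste0("arm", a)] <- 1
    if (yr == 2) cvec[paste0("yr2:arm", a)] <- 1
    if (single) {
      estv <- sum(cvec * pooled$coefficients)
      Tv <- drop(cvec %*% pooled$vcov %*% cvec)
      df <- pooled$n - length(cn)
    } else {
      estv <- sum(cvec * pooled$qbar)
      Wc <- drop(cvec %*% pooled$Wmat %*% cvec)
      Bc <- drop(cvec %*% pooled$Bmat %*% cvec)
      Tv <- drop(cvec %*% pooled$Tmat %*% cvec)
      df <- barnard_rubin_df(Wc, Bc, Tv, pooled$M, pooled$nu_com)
    }
    q <- qt(1 - (1 - conf_level) / 2, df)
    data.frame(arm = a, year = yr, estimate = estv, se = sqrt(Tv), df = df,
               lo = estv - q * sqrt(Tv), hi = estv + q * sqrt(Tv))
  })
  do.call(rbind, out)
}

#' Fit the primary analysis to every imputation and pool
#'
#' @param imputed an `imputed_set`.
#' @param ... passed to [fit_primary()].
#' @return a `pooled_result`.
#' @export
analyze_imputed <- function(imputed, ...) {
  weeks <- week_average(imputed)
  fits <- lapply(split(weeks, weeks$imp), fit_primary, ...)
  pool_rubin(fits)
}
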