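#' Gaussian interval (Tobit) regression
#'
#' Maximum-likelihood fit of a Gaussian linear model where each response is
#' known only up to an interval: exact rows (`lower == upper`) contribute
#' normal densities, interval rows contribute differences of normal CDFs.
#' A lower bound of `-Inf` encodes a completely missing count (bounded only
#' above), a finite lower bound with finite upper bound encodes a partially
#' observed (right-censored) count. The numerical work is delegated to
#' [survival::survreg()], the standard R Tobit route; results are returned
#' with the joint covariance of `(coefficients, log sigma)` needed for
#' posterior draws.
#'
#' Columns with zero variance, or involved in pairwise correlation above
#' 0.999, are dropped with a warning before fitting (chained-equations
#' designs with 20+ day predictors can degenerate in small arms).
#'
#' @param X numeric design matrix (no intercept column; one is added).
#' @param lower,upper interval bounds per row; `lower == upper` marks an
#'   exactly observed response.
#' @param maxiter maximum Newton iterations (default 300; near-saturated
#'   chained-equations designs can need many).
#' @param init optional initial values `c(coefficients, log sigma)` on the
#'   post-pruning design (used to warm-start repeated fits).
#' @return object of class `interval_fit`: `coefficients`, `sigma`, `vcov`
#'   (over `(coefficients, log sigma)`), `loglik`, `n`, `dropped` (names of
#'   pruned columns), `kept` (retained column names).
#' @export
fit_interval_regression <- function(X, lower, upper, maxiter = 300,
                                    init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(lower) != n || length(upper) != n)
    stop("bounds must have one entry per design row")
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- prune_columns(X)
  dropped <- setdiff(colnames(X), keep)
  if (length(dropped))
    warning("dropping degenerate column(s): ", paste(dropped, collapse = ", "))
  Xk <- X[, keep, drop = FALSE]
  if (n < ncol(Xk) + 3L)
    stop("too few rows (", n, ") for ", ncol(Xk), " predictors")
  t1 <- ifelse(is.finite(lower), lower, NA_real_)
  t2 <- ifelse(is.finite(upper), upper, NA_real_)
  sv <- survival::Surv(t1, t2, type = "interval2")
  attempt <- function(iters, tol, ini) {
    ran_out <- FALSE
    fit <- withCallingHandlers(
      survival::survreg(
        sv ~ Xk, dist = "gaussian",
        control = survival::survreg.control(maxiter = iters,
                                            rel.tolerance = tol),
        init = ini),
      warning = function(w) {
        if (grepl("Ran out of iterations", conditionMessage(w))) {
          ran_out <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    list(fit = fit, ran_out = ran_out)
  }
  a <- attempt(maxiter, 1e-8, init)
  if (a$ran_out) {  # heavily censored columns can oscillate: retry, warmer
    ini <- c(coef(a$fit), log(a$fit$scale))
    a <- attempt(3L * maxiter, 1e-6, if (anyNA(ini)) NULL else ini)
  }
  fit <- a$fit
  if (a$ran_out)
    stop("interval regression did not converge in ", 4L * maxiter,
         " iterations (last log-likelihood ", signif(fit$loglik[2], 8), ")")
  beta <- coef(fit)
  if (anyNA(beta))
    stop("rank-deficient design; could not estimate: ",
         paste(sub("^Xk", "", names(beta)[is.na(beta)]), collapse = ", "))
  names(beta) <- c("(Intercept)", colnames(Xk))
  V <- fit$var  # covariance of (coefficients, log sigma)
  dimnames(V) <- rep(list(c(names(beta), "log(sigma)")), 2)
  structure(list(coefficients = beta, sigma = fit$scale, vcov = V,
                 loglik = fit$loglik[2], n = n, dropped = dropped,
                 kept = keep, iter = fit$iter),
            class = "interval_fit")
}

#' @export
print.interval_fit <- function(x, ...) {
  cat(sprintf("interval_fit: n = %d, p = %d, sigma = %.4g, loglik = %.4f\n",
              x$n, length(x$coefficients), x$sigma, x$loglik))
  print(x$coefficients)
  invisible(x)
}

# drop zero-variance columns and one of each pair with |cor| > 0.999
prune_columns <- function(X) {
  if (!ncol(X)) return(character())
  sds <- apply(X, 2, sd)
  keep <- colnames(X)[sds > 0]
  if (length(keep) > 1) {
    C <- abs(suppressWarnings(cor(X[, keep, drop = FALSE])))
    C[!is.finite(C)] <- 0
    drop <- logical(length(keep))
    for (j in seq_along(keep)[-1]) {
      if (any(C[j, seq_len(j - 1)][!drop[seq_len(j - 1)]] > 0.999))
        drop[j] <- TRUE
    }
    keep <- keep[!drop]
  }
  keep
}

# log-likelihood of an interval-regression model at given parameters;
# independent of survreg's internals, used as a cross-check and in tests
interval_loglik <- function(beta, sigma, X, lower, upper, intercept = TRUE) {
  X <- as.matrix(X)
  mu <- drop(if (intercept) beta[1] + X %*% beta[-1] else X %*% beta)
  exact <- is.finite(lower) & lower == upper
  ll <- numeric(length(mu))
  ll[exact] <- dnorm(lower[exact], mu[exact], sigma, log = TRUE)
  iv <- !exact
  if (any(iv)) {
    a <- pnorm((upper[iv] - mu[iv]) / sigma)
    b <- pnorm((lower[iv] - mu[iv]) / sigma)
    ll[iv] <- log(pmax(a - b, .Machine$double.xmin))
  }
  sum(ll)
}

#' Truncated-normal sampling, stable in the tails
#'
#' Inverse-CDF sampling of `N(mean, sd^2)` truncated to `[lower, upper]`.
#' When the interval lies so deep in a tail that `pnorm()` underflows, the
#' computation moves to the log scale of the nearer tail instead of
#' silently clamping.
#'
#' @param n number of draws (recycled against the other arguments).
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds (`-Inf`/`Inf` allowed).
#' @return numeric vector of draws, all within their bounds.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  pa <- pnorm(a)
  pb <- pnorm(b)
  u <- runif(n)
  out <- qnorm(pa + u * (pb - pa)) * sd + mean
  bad <- !is.finite(out) | out < lower | out > upper | (pb - pa) < 1e-12
  if (any(bad)) {
    for (i in which(bad)) {
      if (a[i] >= 0) {        # interval in the upper tail: work on log survival
        la <- pnorm(a[i], lower.tail = FALSE, log.p = TRUE)
        lb <- pnorm(b[i], lower.tail = FALSE, log.p = TRUE)
        # log survival of the draw, uniform between lb and la on prob scale
        lp <- la + log1p(u[i] * expm1(lb - la))
        z <- qnorm(lp, lower.tail = FALSE, log.p = TRUE)
      } else {                # lower tail: mirror
        la <- pnorm(-a[i], lower.tail = FALSE, log.p = TRUE)
        lb <- pnorm(-b[i], lower.tail = FALSE, log.p = TRUE)
        lp <- lb + log1p((1 - u[i]) * expm1(la - lb))
        z <- -qnorm(lp, lower.tail = FALSE, log.p = TRUE)
      }
      out[i] <- min(max(z * sd[i] + mean[i], lower[i]), upper[i])
    }
  }
  out
}

#' Posterior-predictive draws from an interval-regression fit
#'
#' Draws one parameter vector `(beta, log sigma)` from the asymptotic-normal
#' approximate posterior centred at the MLE, then draws each incomplete cell
#' from `N(x'beta, sigma^2)` truncated to its interval. Call once per
#' imputation so each of the M imputations carries its own parameter draw.
#'
#' @param fit an [fit_interval_regression()] result.
#' @param X design rows (same columns as the fitting design) for the cells
#'   to impute.
#' @param lower,upper truncation bounds per row.
#' @return numeric vector of imputed values, one per row of `X`.
#' @export
draw_imputations <- function(fit, X, lower, upper) {
  stopifnot(inherits(fit, "interval_fit"))
  X <- as.matrix(X)
  Xk <- X[, fit$kept, drop = FALSE]
  theta <- c(fit$coefficients, log(fit$sigma))
  R <- chol(nearest_pd(fit$vcov))
  theta_star <- drop(theta + crossprod(R, rnorm(length(theta))))
  p <- length(fit$coefficients)
  beta <- theta_star[seq_len(p)]
  sigma <- exp(theta_star[p + 1L])
  mu <- drop(beta[1] + Xk %*% beta[-1])
  rtruncnorm(nrow(Xk), mean = mu, sd = sigma, lower = lower, upper = upper)
}

# minimal eigenvalue repair so chol() succeeds on near-singular covariances
nearest_pd <- function(V) {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) > 0) return(V)
  lam <- pmax(ev$values, max(ev$values) * 1e-10)
  ev$vectors %*% (lam * t(ev$vectors))
}
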