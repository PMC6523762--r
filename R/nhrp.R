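#' NHRP logistic discovery-curve parameters
#'
#' The non-homogeneous renewal-process (NHRP) discovery model assumes that
#' the expected cumulative number of described species follows a logistic
#' curve in time,
#' \deqn{\Lambda(t) = N / (1 + e^{-v_1 (t - v_2)}),}
#' where `N` is the asymptotic number of species to be discovered, `v1`
#' (1/yr) controls the steepness of the curve and `v2` is the inflection
#' year, at which exactly `N / 2` species have been described. Annual
#' description counts are modelled as counts with mean
#' \eqn{\mu(t) = \Lambda(t + 1) - \Lambda(t)} (the bin `[t, t+1)` holds
#' species described in calendar year `t`), Poisson when the dispersion
#' `phi = 1` and negative binomial with variance `phi * mu` when
#' `phi > 1`.
#'
#' @param N Asymptotic species total, `> 0`.
#' @param v1 Steepness, `> 0`, in 1/yr.
#' @param v2 Inflection year.
#' @return An `nhrp_params` object (named list).
#' @export
#' @examples
#' p <- nhrp_params(N = 4000, v1 = 0.04, v2 = 2020)
#' logistic_cumulative(p, 2020) # N / 2
nhrp_params <- function(N, v1, v2) {
  stopifnot(is.finite(N), N > 0, is.finite(v1), v1 > 0, is.finite(v2))
  structure(list(N = N, v1 = v1, v2 = v2), class = "nhrp_params")
}

as_nhrp_params <- function(p) {
  if (inherits(p, "nhrp_params")) {
    return(p)
  }
  nhrp_params(p[["N"]], p[["v1"]], p[["v2"]])
}

#' @rdname nhrp_params
#' @param params An [nhrp_params()] object (or named list with `N`, `v1`,
#'   `v2`).
#' @param t Calendar year(s); may be fractional.
#' @return `logistic_cumulative()` returns the expected cumulative number
#'   of described species at time `t`; numerically stable for extreme
#'   `v1 * (t - v2)`.
#' @export
logistic_cumulative <- function(params, t) {
  p <- as_nhrp_params(params)
  p$N * plogis(p$v1 * (t - p$v2))
}

#' @rdname nhrp_params
#' @return `logistic_intensity()` returns the instantaneous description
#'   rate \eqn{d\Lambda/dt} (species/yr), which peaks at `N * v1 / 4` at
#'   the inflection year.
#' @export
logistic_intensity <- function(params, t) {
  p <- as_nhrp_params(params)
  p$N * p$v1 * dlogis(p$v1 * (t - p$v2))
}

#' Expected annual description counts under the NHRP model
#'
#' @param params An [nhrp_params()].
#' @param yrs Integer calendar years.
#' @return Numeric vector of means `Lambda(yr + 1) - Lambda(yr)`.
#' @export
nhrp_annual_means <- function(params, yrs) {
  p <- as_nhrp_params(params)
  logistic_cumulative(p, yrs + 1) - logistic_cumulative(p, yrs)
}

#' NHRP log-likelihood of an annual count series
#'
#' Sum over years of the count log-probability with mean
#' \eqn{\mu(t) = \Lambda(t+1) - \Lambda(t)}: Poisson when `phi = 1`,
#' negative binomial with mean \eqn{\mu} and variance \eqn{\phi \mu}
#' (size \eqn{\mu / (\phi - 1)}) when `phi > 1`.
#'
#' @param params An [nhrp_params()].
#' @param data An [annual_counts()] series.
#' @param phi Dispersion, `>= 1`; `phi = 1` is Poisson.
#' @return Log-likelihood (may be `-Inf` for impossible data).
#' @export
nhrp_loglik <- function(params, data, phi = 1) {
  stopifnot(inherits(data, "annual_counts"), phi >= 1)
  mu <- pmax(nhrp_annual_means(params, years(data)), 1e-12)
  k <- data$counts
  if (phi <= 1 + 1e-12) {
    sum(dpois(k, mu, log = TRUE))
  } else {
    sum(dnbinom(k, size = mu / (phi - 1), mu = mu, log = TRUE))
  }
}

#' Default NHRP parameter bounds for a count series
#'
#' `N` in `[observed total, 100 x observed total]`, `v1` in `(0, 1]`,
#' `v2` in `[first year - 200, last year + 300]`. These boxes keep the fit
#' identifiable when the observed curve is right-censored (the inflection
#' lies near or beyond the edge of the data).
#'
#' @param data An [annual_counts()] series.
#' @return List with `lower` and `upper` named vectors over
#'   `(N, v1, v2, phi)`.
#' @export
nhrp_default_bounds <- function(data) {
  total <- max(sum(data$counts), 1)
  list(
    lower = c(N = total, v1 = 1e-4, v2 = data$start_year - 200, phi = 1),
    upper = c(N = 100 * total, v1 = 1, v2 = data$end_year + 300, phi = 50)
  )
}

#' Fit the logistic NHRP model to annual description counts
#'
#' Maximizes [nhrp_loglik()] over `(N, v1, v2)` (and `phi` when
#' `estimate_dispersion = TRUE`) with bounded quasi-Newton optimization
#' (`optim`, L-BFGS-B, on log scale for `N`, `v1` and `phi - 1`) from a
#' deterministic multi-start grid: `N` at 1, 2, 4 and 8 times the observed
#' total, `v2` at the first, middle and last observed year, `v1` at 0.01,
#' 0.05 and 0.1 /yr. The reported fit is the best converged start; if no
#' start converges, or the series is flat (all counts equal, which leaves
#' the curve's shape unidentified), the fit is flagged `converged = FALSE`
#' with a diagnostic rather than failing silently.
#'
#' @param data An [annual_counts()] series spanning at least 10 years with
#'   at least one nonzero count.
#' @param init Optional [nhrp_params()] used as an additional start.
#' @param bounds Optional bounds list as from [nhrp_default_bounds()].
#' @param estimate_dispersion If `TRUE`, estimate `phi` (negative
#'   binomial); otherwise `phi` is fixed at 1 (Poisson).
#' @return An `nhrp_fit` object: `params`, `phi`, `loglik`, `n_obs_years`,
#'   `converged`, `diagnostic`, `vcov` (curvature-based covariance of
#'   `(N, v1, v2[, phi])`, or `NULL`), `fit_window`, `bounds` and the
#'   fitted `data`.
#' @export
fit_nhrp <- function(data, init = NULL, bounds = NULL,
                     estimate_dispersion = FALSE) {
  stopifnot(inherits(data, "annual_counts"))
  n_years <- length(data$counts)
  if (n_years < 10) {
    stop("need at least 10 years of counts to fit the NHRP", call. = FALSE)
  }
  if (all(data$counts == 0)) {
    stop("need at least one nonzero annual count", call. = FALSE)
  }
  bounds <- bounds %||% nhrp_default_bounds(data)
  base <- list(
    params = NULL, phi = if (estimate_dispersion) NA_real_ else 1,
    loglik = NA_real_, n_obs_years = n_years, converged = FALSE,
    diagnostic = "", vcov = NULL,
    fit_window = c(data$start_year, data$end_year),
    bounds = bounds, estimate_dispersion = estimate_dispersion,
    data = data
  )
  if (length(unique(data$counts)) == 1L) {
    base$diagnostic <-
      "flat series: all annual counts equal; curve shape unidentified"
    return(structure(base, class = "nhrp_fit"))
  }

  total <- sum(data$counts)
  yrs <- years(data)
  starts <- expand.grid(
    N = pmin(total * c(1, 2, 4, 8), bounds$upper["N"]),
    v1 = c(0.01, 0.05, 0.1),
    v2 = c(yrs[1], yrs[ceiling(n_years / 2)], yrs[n_years])
  )
  if (!is.null(init)) {
    init <- as_nhrp_params(init)
    starts <- rbind(starts, data.frame(N = init$N, v1 = init$v1, v2 = init$v2))
  }

  to_theta <- function(N, v1, v2, phi = NULL) {
    th <- c(log(N), log(v1), v2)
    if (estimate_dispersion) th <- c(th, log(max(phi, 1 + 1e-8) - 1 + 1e-8))
    th
  }
  from_theta <- function(th) {
    p <- list(N = exp(th[1]), v1 = exp(th[2]), v2 = th[3])
    phi <- if (estimate_dispersion) 1 + exp(th[4]) - 1e-8 else 1
    list(params = p, phi = max(phi, 1))
  }
  negll <- function(th) {
    x <- from_theta(th)
    ll <- tryCatch(
      nhrp_loglik(
        nhrp_params(x$params$N, x$params$v1, x$params$v2),
        data,
        phi = x$phi
      ),
      error = function(e) -Inf
    )
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- to_theta(bounds$lower["N"], bounds$lower["v1"], bounds$lower["v2"],
    phi = bounds$lower["phi"]
  )
  upper <- to_theta(bounds$upper["N"], bounds$upper["v1"], bounds$upper["v2"],
    phi = bounds$upper["phi"]
  )

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- to_theta(starts$N[i], starts$v1[i], starts$v2[i], phi = 1.5)
    th0 <- pmin(pmax(th0, lower), upper)
    res <- tryCatch(
      optim(th0, negll,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(res) || res$convergence != 0 || !is.finite(res$value) ||
      res$value >= 1e10) {
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    base$diagnostic <- "no multi-start converged"
    return(structure(base, class = "nhrp_fit"))
  }
  sol <- from_theta(best$par)
  base$params <- nhrp_params(sol$params$N, sol$params$v1, sol$params$v2)
  base$phi <- sol$phi
  base$loglik <- -best$value
  base$converged <- TRUE
  base$diagnostic <- "ok"
  base$vcov <- nhrp_vcov(base, data)
  base$vcov_theta <- nhrp_vcov_theta(base, data)
  structure(base, class = "nhrp_fit")
}

# curvature-based covariance on the natural (N, v1, v2[, phi]) scale
nhrp_vcov <- function(fit, data) {
  p <- fit$params
  par <- c(N = p$N, v1 = p$v1, v2 = p$v2)
  if (fit$estimate_dispersion) par <- c(par, phi = fit$phi)
  f <- function(v) {
    phi <- if (fit$estimate_dispersion) max(v[4], 1) else 1
    ll <- tryCatch(
      nhrp_loglik(nhrp_params(v[1], v[2], v[3]), data, phi = phi),
      error = function(e) NA_real_
    )
    if (is.finite(ll)) -ll else NA_real_
  }
  tryCatch(
    {
      h <- optimHess(par, f)
      v <- solve(h)
      dimnames(v) <- list(names(par), names(par))
      if (any(!is.finite(v)) || any(diag(v) <= 0)) NULL else v
    },
    error = function(e) NULL
  )
}

# covariance on the (log N, log v1, v2) scale, used for parameter
# re-draws: N and v1 are right-skewed on right-censored curves, so a
# Gaussian on the log scale approximates their sampling distribution far
# better than one on the natural scale
nhrp_vcov_theta <- function(fit, data) {
  p <- fit$params
  th <- c(logN = log(p$N), logv1 = log(p$v1), v2 = p$v2)
  f <- function(t) {
    ll <- tryCatch(
      nhrp_loglik(
        nhrp_params(exp(t[1]), exp(t[2]), t[3]), data,
        phi = fit$phi
      ),
      error = function(e) NA_real_
    )
    if (is.finite(ll)) -ll else NA_real_
  }
  tryCatch(
    {
      h <- optimHess(th, f)
      v <- solve(h)
      dimnames(v) <- list(names(th), names(th))
      if (any(!is.finite(v)) || any(diag(v) <= 0)) NULL else v
    },
    error = function(e) NULL
  )
}

#' @export
print.nhrp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<nhrp_fit: NOT converged -", x$diagnostic, ">\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0(
      "<nhrp_fit: N = %.1f, v1 = %.4f /yr, v2 = %.1f, phi = %.2f, ",
      "logLik = %.2f over %d years>\n"
    ),
    x$params$N, x$params$v1, x$params$v2, x$phi, x$loglik, x$n_obs_years
  ))
  invisible(x)
}

#' Serialize an NHRP fit as JSON
#'
#' @param fit An `nhrp_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nhrp_fit <- function(fit, path) {
  payload <- list(
    params = if (fit$converged) unclass(fit$params) else NULL,
    phi = fit$phi,
    loglik = fit$loglik,
    n_obs_years = fit$n_obs_years,
    converged = fit$converged,
    diagnostic = fit$diagnostic,
    fit_window = fit$fit_window,
    bounds = lapply(fit$bounds, as.list),
    vcov = if (!is.null(fit$vcov)) {
      list(
        parameters = colnames(fit$vcov),
        matrix = unname(apply(fit$vcov, 1, as.list, simplify = FALSE))
      )
    } else {
      NULL
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
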