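# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic substream seed for replicate r; stays below 2^31 - 1
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 3021377) %%
    2147483629) + 1L
}

#' Simulate an annual description-count series from the NHRP model
#'
#' Description years are sampled as a counting process following the
#' logistic trend with random variability: the count for year `t` is drawn
#' with mean \eqn{\mu(t) = \Lambda(t+1) - \Lambda(t)} from a Poisson
#' distribution when `phi = 1`, or a negative binomial with variance
#' `phi * mu(t)` when `phi > 1`. Output is reproducible under a fixed
#' seed, and the caller's RNG state is left untouched.
#'
#' @param params An [nhrp_params()].
#' @param phi Dispersion (`>= 1`; 1 = Poisson).
#' @param start,end First and last simulated year (inclusive).
#' @param seed Integer seed.
#' @return An [annual_counts()] series.
#' @export
simulate_descriptions <- function(params, phi = 1, start, end, seed) {
  stopifnot(start <= end, phi >= 1)
  p <- as_nhrp_params(params)
  yrs <- seq(start, end)
  mu <- pmax(nhrp_annual_means(p, yrs), 0)
  counts <- with_seed(seed, {
    if (phi <= 1 + 1e-12) {
      rpois(length(mu), mu)
    } else {
      k <- rnbinom(length(mu), size = pmax(mu, 1e-12) / (phi - 1), mu = mu)
      k[mu == 0] <- 0L
      k
    }
  })
  new_annual_counts(counts, start)
}

#' Predict the number of species described over future horizons
#'
#' Forward-simulates the fitted NHRP from the year after the last
#' observation out to the farthest horizon, `n_reps` times, and summarizes
#' the total number of newly described species at each horizon by its
#' median, mean and central 95% interval (2.5th-97.5th percentiles).
#' Every replicate uses an independently derived seed substream, and all
#' horizons are read off the same simulated path per replicate, so
#' predictions to a later horizon dominate those to an earlier one
#' replicate by replicate.
#'
#' By default only process (sampling) noise enters the interval. With
#' `propagate_param_uncertainty = TRUE`, each replicate first re-draws
#' the parameters from the fit's curvature-based Gaussian approximation
#' on the `(log N, log v1, v2)` scale (clamped to the fit bounds),
#' widening the interval by parameter uncertainty.
#'
#' @param fit A converged `nhrp_fit`.
#' @param last_observed_year Final year of the observed series; simulation
#'   starts the following year.
#' @param horizons Years to predict to (each `>= last_observed_year`).
#' @param n_reps Number of replicates (1000 or more recommended).
#' @param seed Integer seed.
#' @param propagate_param_uncertainty Re-draw parameters each replicate.
#' @param keep_reps If `TRUE`, attach the replicate x horizon totals as
#'   attribute `"reps"`.
#' @return A tibble with one row per horizon: `horizon_year`, `n_reps`,
#'   `median_new`, `mean_new`, `lower95`, `upper95`.
#' @export
predict_new_species <- function(fit, last_observed_year, horizons,
                                n_reps = 1000, seed = 1,
                                propagate_param_uncertainty = FALSE,
                                keep_reps = FALSE) {
  stopifnot(inherits(fit, "nhrp_fit"), n_reps >= 1)
  if (!fit$converged) {
    stop(
      "cannot predict from a non-converged fit: ", fit$diagnostic,
      call. = FALSE
    )
  }
  horizons <- sort(unique(as.integer(horizons)))
  if (any(horizons < last_observed_year)) {
    stop("horizons must not precede last_observed_year", call. = FALSE)
  }
  hmax <- max(horizons)
  sim_years <- if (hmax > last_observed_year) {
    seq(last_observed_year + 1L, hmax)
  } else {
    integer()
  }
  chol_v <- NULL
  if (propagate_param_uncertainty) {
    if (is.null(fit$vcov_theta)) {
      stop(
        "no parameter covariance available to propagate; refit or use ",
        "propagate_param_uncertainty = FALSE",
        call. = FALSE
      )
    }
    v <- fit$vcov_theta
    chol_v <- tryCatch(chol(v), error = function(e) {
      chol(v + diag(1e-8 * pmax(diag(v), 1), 3))
    })
  }
  totals <- matrix(
    0, nrow = n_reps, ncol = length(horizons),
    dimnames = list(NULL, horizons)
  )
  for (r in seq_len(n_reps)) {
    p <- fit$params
    if (!is.null(chol_v)) {
      z <- with_seed(derive_seed(seed, 2L * r), rnorm(3))
      th <- c(log(p$N), log(p$v1), p$v2) + drop(crossprod(chol_v, z))
      draw <- c(exp(th[1]), exp(th[2]), th[3])
      draw <- pmin(
        pmax(draw, fit$bounds$lower[c("N", "v1", "v2")]),
        fit$bounds$upper[c("N", "v1", "v2")]
      )
      p <- nhrp_params(draw[1], draw[2], draw[3])
    }
    if (length(sim_years) > 0) {
      sim <- simulate_descriptions(
        p, fit$phi, sim_years[1], hmax,
        seed = derive_seed(seed, 2L * r + 1L)
      )
      cum <- cumsum(sim$counts)
      idx <- horizons - last_observed_year
      totals[r, ] <- ifelse(idx == 0, 0, cum[pmax(idx, 1)])
    }
  }
  out <- tibble::tibble(
    horizon_year = horizons,
    n_reps = as.integer(n_reps),
    median_new = unname(apply(totals, 2, median)),
    mean_new = unname(colMeans(totals)),
    lower95 = unname(apply(totals, 2, quantile, probs = 0.025, names = FALSE)),
    upper95 = unname(apply(totals, 2, quantile, probs = 0.975, names = FALSE))
  )
  if (keep_reps) attr(out, "reps") <- totals
  out
}

#' Goodness of fit of an NHRP model
#'
#' Computes per-year Pearson residuals
#' \eqn{(k_t - \mu_t) / \sqrt{\phi \mu_t}}, a chi-square-style dispersion
#' statistic (mean squared Pearson residual, adjusted for the number of
#' fitted parameters; near 1 when the model fits), the length of the
#' longest same-sign residual run (a long run flags a systematic trend
#' break such as a step change in description effort), and the observed
#' and fitted cumulative curves for plotting.
#'
#' @param fit A converged `nhrp_fit`.
#' @param data The [annual_counts()] the fit should be judged against
#'   (defaults to the fitted data).
#' @return An `nhrp_gof` list: `residuals` (tibble `year`, `observed`,
#'   `expected`, `pearson`), `dispersion`, `df`, `max_sign_run`, `curves`
#'   (tibble `year`, `observed_cum`, `fitted_cum`).
#' @export
goodness_of_fit <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "nhrp_fit"), inherits(data, "annual_counts"))
  if (!fit$converged) {
    stop("goodness_of_fit() requires a converged fit", call. = FALSE)
  }
  yrs <- years(data)
  mu <- pmax(nhrp_annual_means(fit$params, yrs), 1e-12)
  pearson <- (data$counts - mu) / sqrt(fit$phi * mu)
  n_par <- 3L + as.integer(fit$estimate_dispersion)
  df <- max(length(yrs) - n_par, 1L)
  runs <- rle(sign(pearson))
  curves <- tibble::tibble(
    year = yrs,
    observed_cum = cumsum(data$counts),
    fitted_cum = logistic_cumulative(fit$params, yrs + 1) -
      logistic_cumulative(fit$params, yrs[1])
  )
  structure(
    list(
      residuals = tibble::tibble(
        year = yrs, observed = data$counts, expected = mu, pearson = pearson
      ),
      dispersion = sum(pearson^2) / df,
      df = df,
      max_sign_run = max(runs$lengths[runs$values != 0], 0),
      curves = curves
    ),
    class = "nhrp_gof"
  )
}

#' @export
print.nhrp_gof <- function(x, ...) {
  cat(sprintf(
    "<nhrp_gof: dispersion = %.3f on %d df, longest residual run = %d>\n",
    x$dispersion, x$df, x$max_sign_run
  ))
  invisible(x)
}
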