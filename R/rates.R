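#' Count species described within a year window
#'
#' Both endpoint years are inclusive: the window 1980-2018 contains every
#' species whose name was published in 1980 through 2018. Records without
#' a description year never enter (they are excluded upstream from
#' time-based analyses).
#'
#' @param x A normalized checklist.
#' @param start,end First and last year of the window (inclusive).
#' @return Integer count.
#' @export
count_described <- function(x, start, end) {
  stopifnot(inherits(x, "checklist"), start < end)
  y <- x$description_year
  sum(!is.na(y) & y >= start & y <= end)
}

#' Species-description rate over a window
#'
#' The divisor is the window span `end - start` (so 1980-2018 is a 38-year
#' window), matching the convention used for published stonefly
#' description rates. Rounding to one decimal is applied only at
#' presentation; the raw value is returned.
#'
#' @param n Number of species described in the window.
#' @param start,end Window years; `end` must exceed `start`.
#' @return Rate in species per year (unrounded).
#' @export
description_rate <- function(n, start, end) {
  if (end <= start) stop("window end must exceed start", call. = FALSE)
  n / (end - start)
}

#' Round half-up to a number of decimals
#'
#' Presentation rounding for rate tables: 0.05 rounds up to 0.1 (base R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Description-rate table across areas
#'
#' One row per named area (each checklist already restricted to species
#' described within that area via [filter_described_in()]; a "Global"
#' entry is typically the unfiltered normalized checklist). Rows are
#' ordered by rate descending, ties broken by area name, matching the
#' presentation convention for published rate tables.
#'
#' @param checklists Named list of checklists, one per area.
#' @param start,end Window years (inclusive endpoints, `end - start`
#'   divisor).
#' @return A tibble with columns `area`, `window_start`, `window_end`,
#'   `n_described`, `rate` (raw) and `rate_display` (half-up, 1 decimal).
#' @export
rate_table <- function(checklists, start, end) {
  stopifnot(
    is.list(checklists), length(checklists) > 0,
    !is.null(names(checklists)), all(nzchar(names(checklists)))
  )
  rows <- purrr::imap(checklists, function(cl, area) {
    n <- count_described(cl, start, end)
    tibble::tibble(
      area = area,
      window_start = as.integer(start),
      window_end = as.integer(end),
      n_described = n,
      rate = description_rate(n, start, end)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$rate), .data$area) |>
    dplyr::mutate(rate_display = round_half_up(.data$rate, 1))
}

#' Annual description counts
#'
#' Tallies first descriptions per calendar year over a window: element `i`
#' of `counts` is the number of species described in year `start + i - 1`.
#' This is the observed series the NHRP model is fitted to.
#'
#' @param x A normalized checklist.
#' @param start,end First and last year (inclusive).
#' @return An `annual_counts` object: a list with `start_year`,
#'   `end_year` and integer `counts` of length `end - start + 1`.
#' @export
annual_counts <- function(x, start, end) {
  stopifnot(inherits(x, "checklist"), start <= end)
  y <- x$description_year
  y <- y[!is.na(y) & y >= start & y <= end]
  counts <- tabulate(y - start + 1L, nbins = end - start + 1L)
  new_annual_counts(counts, start)
}

#' @rdname annual_counts
#' @param counts_vec Non-negative integer vector, one count per year.
#' @param start_year Calendar year of the first count.
#' @return `new_annual_counts()` builds the series directly from a count
#'   vector.
#' @export
new_annual_counts <- function(counts_vec, start_year) {
  counts <- counts_vec
  stopifnot(all(counts >= 0))
  structure(
    list(
      start_year = as.integer(start_year),
      end_year = as.integer(start_year + length(counts) - 1L),
      counts = as.integer(counts)
    ),
    class = "annual_counts"
  )
}

#' @export
print.annual_counts <- function(x, ...) {
  cat(sprintf(
    "<annual_counts %d-%d: %d species over %d years>\n",
    x$start_year, x$end_year, sum(x$counts), length(x$counts)
  ))
  invisible(x)
}

#' @rdname annual_counts
#' @param counts An `annual_counts` object.
#' @return `years()` returns the calendar years of the series;
#'   `as_tibble_counts()` a `year`/`count` tibble.
#' @export
years <- function(counts) seq(counts$start_year, counts$end_year)

#' @rdname annual_counts
#' @export
as_tibble_counts <- function(counts) {
  tibble::tibble(year = years(counts), count = counts$counts)
}
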