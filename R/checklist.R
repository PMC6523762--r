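#' Construct a taxonomic checklist
#'
#' A checklist is a tibble with one row per taxon name and a small amount of
#' metadata. Rows carry the fields the downstream stages need: the name, its
#' rank and nomenclatural status, a fossil flag, family (and optional
#' suborder), the year the name was published, the set of TDWG region codes
#' where the taxon occurs, the Level-1 region containing the type locality
#' (`described_from`), and optional country tags supporting country-level
#' subsets such as China.
#'
#' @param scientific_name Character vector of names ("Genus species" or
#'   "Genus species subspecies").
#' @param rank `"species"` or `"subspecies"`.
#' @param status Nomenclatural status: `"valid"`, `"synonym"` or `"homonym"`.
#' @param fossil Logical; fossil taxa are excluded at normalization.
#' @param family,suborder Family and (optional) suborder placement.
#' @param description_year Integer year the name was published (`NA` allowed;
#'   such records are excluded from time-based stages).
#' @param occurrence_regions List of character vectors of TDWG region codes
#'   (any level), or a single pipe-delimited character vector.
#' @param described_from Level-1 TDWG code of the type locality, or `NA`.
#' @param country_tags List of character vectors of country identifiers, or a
#'   pipe-delimited character vector.
#' @param source Free-text provenance label.
#' @param normalized Logical flag; set by [normalize_checklist()].
#' @return A `checklist` object (a tibble subclass).
#' @export
#' @examples
#' checklist(
#'   scientific_name = c("Perla alpha", "Perla beta"),
#'   family = "Perlidae",
#'   description_year = c(1901, 1995),
#'   occurrence_regions = list("EUR", c("EUR", "TEA"))
#' )
checklist <- function(scientific_name = character(),
                      rank = "species",
                      status = "valid",
                      fossil = FALSE,
                      family = NA_character_,
                      suborder = NA_character_,
                      description_year = NA_integer_,
                      occurrence_regions = list(),
                      described_from = NA_character_,
                      country_tags = list(),
                      source = "in-memory",
                      normalized = FALSE) {
  n <- length(scientific_name)
  if (n == 0L) {
    occurrence_regions <- list()
    country_tags <- list()
  } else {
    occurrence_regions <- as_region_list(occurrence_regions, n)
    country_tags <- as_region_list(country_tags, n, upper = FALSE)
  }
  records <- tibble::tibble(
    scientific_name = as.character(scientific_name),
    rank = rep_len(tolower(as.character(rank)), n),
    status = rep_len(tolower(as.character(status)), n),
    fossil = rep_len(as.logical(fossil), n),
    family = rep_len(as.character(family), n),
    suborder = rep_len(as.character(suborder), n),
    description_year = rep_len(as.integer(description_year), n),
    occurrence_regions = occurrence_regions,
    described_from = rep_len(toupper_na(as.character(described_from)), n),
    country_tags = country_tags
  )
  new_checklist(records, source = source, normalized = normalized)
}

#' @rdname checklist
#' @param records A data frame with the checklist columns (as produced by
#'   [checklist()] or by subsetting one).
#' @return `as_checklist()` returns `records` re-stamped as a checklist.
#' @export
as_checklist <- function(records, source = "in-memory", normalized = FALSE) {
  stopifnot(all(c(
    "scientific_name", "rank", "status", "fossil", "family",
    "description_year", "occurrence_regions"
  ) %in% names(records)))
  new_checklist(records, source = source, normalized = normalized)
}

new_checklist <- function(records, source = "in-memory", normalized = FALSE,
                          log = NULL) {
  stopifnot(is.data.frame(records))
  out <- tibble::as_tibble(records)
  class(out) <- c("checklist", class(tibble::tibble()))
  attr(out, "source") <- source
  attr(out, "normalized") <- isTRUE(normalized)
  attr(out, "drop_log") <- log
  out
}

as_region_list <- function(x, n, upper = TRUE) {
  if (length(x) == 0) {
    return(replicate(n, character(0), simplify = FALSE))
  }
  if (is.character(x)) {
    x <- strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE)
  }
  x <- rep_len(x, n)
  lapply(x, function(v) {
    v <- as.character(v)
    v <- v[!is.na(v) & nzchar(v)]
    if (upper) toupper(v) else v
  })
}

toupper_na <- function(x) {
  out <- toupper(x)
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' @export
print.checklist <- function(x, ...) {
  norm <- if (is_normalized(x)) "normalized" else "raw"
  cat(sprintf(
    "<checklist: %d records, %s, source: %s>\n",
    nrow(x), norm, attr(x, "source") %||% "?"
  ))
  NextMethod()
}

#' @rdname checklist
#' @param x A checklist.
#' @return `is_normalized()` returns the normalization flag.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @rdname checklist
#' @return `drop_log()` returns the per-reason record counts dropped or merged
#'   by the last [normalize_checklist()] call (or `NULL`).
#' @export
drop_log <- function(x) attr(x, "drop_log")

required_cols <- c(
  "scientific_name", "rank", "status", "fossil", "family",
  "description_year", "regions"
)

dwc_default_map <- c(
  scientific_name = "scientificName",
  rank = "taxonRank",
  status = "taxonomicStatus",
  fossil = "isFossil",
  family = "family",
  suborder = "suborder",
  description_year = "namePublishedInYear",
  regions = "occurrenceRegions",
  described_from = "describedFrom",
  countries = "countryTags"
)

#' Read a taxonomic checklist from disk
#'
#' Supports a plain delimited dialect (`csv`/`tsv`) with columns
#' `scientific_name, rank, status, fossil, family, suborder,
#' description_year, regions, described_from, countries` (the last three
#' optional; `regions`/`countries` are pipe-delimited lists), and a
#' Darwin-Core-style taxon dialect (`dwc`) using `scientificName`,
#' `taxonRank`, `taxonomicStatus`, `family` and `namePublishedInYear`, with
#' the remaining columns located through `col_map`.
#'
#' Rows with an unparseable year are kept (year set to `NA`) and surfaced
#' through the returned checklist's `"problems"` attribute together with
#' their row numbers; unknown region codes trigger a warning but the rows
#' are retained with the offending codes flagged in the same attribute.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"tsv"` or `"dwc"` (Darwin-Core-style, comma- or
#'   tab-delimited, sniffed from the header line).
#' @param col_map Named character vector overriding the Darwin-Core column
#'   mapping, names being the canonical column names.
#' @return A raw (un-normalized) [checklist()].
#' @export
read_checklist <- function(path, format = c("csv", "tsv", "dwc"),
                           col_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("checklist file not found: ", path, call. = FALSE)
  }
  delim <- if (format == "tsv") "\t" else ","
  if (format == "dwc") {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    progress = FALSE, comment = "#"
  )
  map <- stats::setNames(names(raw), names(raw))
  if (format == "dwc") {
    map <- dwc_default_map
    if (!is.null(col_map)) map[names(col_map)] <- col_map
    names(raw)[match(map, names(raw), nomatch = 0L)] <-
      names(map)[map %in% names(raw)]
  }
  missing <- setdiff(required_cols, names(raw))
  if (length(missing) > 0) {
    stop(
      "checklist is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  year_raw <- stringr::str_trim(raw$description_year)
  year <- suppressWarnings(as.integer(year_raw))
  bad_year <- which(!is.na(year_raw) & nzchar(year_raw) & is.na(year))
  problems <- tibble::tibble(
    row = integer(), column = character(), value = character(),
    issue = character()
  )
  if (length(bad_year) > 0) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      row = bad_year, column = "description_year",
      value = year_raw[bad_year], issue = "unparseable year"
    ))
    warning(
      length(bad_year), " row(s) with unparseable description_year; ",
      "kept with year = NA (see attr(x, 'problems'))",
      call. = FALSE
    )
  }
  cl <- checklist(
    scientific_name = raw$scientific_name,
    rank = raw$rank,
    status = raw$status,
    fossil = parse_flag(raw$fossil),
    family = raw$family,
    suborder = if ("suborder" %in% names(raw)) raw$suborder else NA,
    description_year = year,
    occurrence_regions = raw$regions,
    described_from = if ("described_from" %in% names(raw)) {
      raw$described_from
    } else {
      NA
    },
    country_tags = if ("countries" %in% names(raw)) raw$countries else list(),
    source = path,
    normalized = FALSE
  )
  unknown <- lapply(cl$occurrence_regions, function(v) v[!tdwg_known(v)])
  has_unknown <- which(lengths(unknown) > 0)
  if (length(has_unknown) > 0) {
    problems <- dplyr::bind_rows(problems, tibble::tibble(
      row = has_unknown, column = "regions",
      value = vapply(unknown[has_unknown], paste, "", collapse = "|"),
      issue = "unknown region code"
    ))
    warning(
      "unknown TDWG region code(s) in ", length(has_unknown),
      " row(s): ",
      paste(unique(unlist(unknown)), collapse = ", "),
      " (rows retained and flagged)",
      call. = FALSE
    )
  }
  attr(cl, "problems") <- problems
  cl
}

parse_flag <- function(x) {
  tolower(stringr::str_trim(x)) %in% c("true", "t", "1", "yes")
}

#' Write a checklist to disk
#'
#' The inverse of [read_checklist()]: emits either the plain delimited
#' dialect or the Darwin-Core-style dialect so that reading the file back
#' reproduces the records exactly.
#'
#' @inheritParams read_checklist
#' @param x A checklist.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(x, path, format = c("csv", "tsv", "dwc"),
                            col_map = NULL) {
  format <- match.arg(format)
  flat <- tibble::tibble(
    scientific_name = x$scientific_name,
    rank = x$rank,
    status = x$status,
    fossil = x$fossil,
    family = x$family,
    suborder = x$suborder,
    description_year = x$description_year,
    regions = vapply(x$occurrence_regions, paste, "", collapse = "|"),
    described_from = x$described_from,
    countries = vapply(x$country_tags, paste, "", collapse = "|")
  )
  if (format == "dwc") {
    map <- dwc_default_map
    if (!is.null(col_map)) map[names(col_map)] <- col_map
    names(flat) <- unname(map[names(flat)])
  }
  delim <- if (format == "tsv") "\t" else ","
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}

#' Normalize a checklist to distinct valid extant species
#'
#' Applies the filters and merges that turn a raw nomenclatural checklist
#' into an analysis-ready species list:
#'
#' * synonyms and homonyms are dropped (only valid names are counted);
#' * fossil taxa are dropped (the analysis concerns the extant fauna);
#' * each subspecies is collapsed into its parent species so a species is
#'   counted once — the parent keeps the earliest description year among
#'   itself and its subspecies, and the union of their occurrence regions
#'   and country tags. A subspecies whose parent binomial is absent from
#'   the checklist is promoted to a species-level record under the parent
#'   binomial, with a warning;
#' * records sharing a scientific name are merged by the same
#'   earliest-year/union rule;
#' * records are sorted canonically by family, then scientific name.
#'
#' The number of records removed or merged at each step is recorded in the
#' result's drop log ([drop_log()]). The operation is idempotent and does
#' not depend on input row order.
#'
#' @param x A checklist.
#' @return A normalized [checklist()] of species-level records.
#' @export
normalize_checklist <- function(x) {
  stopifnot(inherits(x, "checklist"))
  if (is_normalized(x)) {
    return(x)
  }
  log <- c(
    input = nrow(x), invalid_status = 0L, fossil = 0L,
    subspecies_collapsed = 0L, orphan_subspecies_promoted = 0L,
    duplicates_merged = 0L
  )
  rec <- x
  keep <- rec$status == "valid"
  log["invalid_status"] <- sum(!keep)
  rec <- rec[keep, ]
  keep <- !rec$fossil
  log["fossil"] <- sum(!keep)
  rec <- rec[keep, ]

  is_ssp <- rec$rank == "subspecies"
  rec$.was_ssp <- is_ssp
  if (any(is_ssp)) {
    parent <- binomial_of(rec$scientific_name)
    species_names <- rec$scientific_name[!is_ssp]
    orphan <- is_ssp & !(parent %in% species_names)
    if (any(orphan)) {
      warning(
        sum(orphan), " subspecies without a parent species record; ",
        "promoted to species level",
        call. = FALSE
      )
      log["orphan_subspecies_promoted"] <- sum(orphan)
    }
    log["subspecies_collapsed"] <- sum(is_ssp & !orphan)
    # collapse under the parent binomial; orphans become that species
    rec$scientific_name[is_ssp] <- parent[is_ssp]
    rec$rank[is_ssp] <- "species"
  }

  # deterministic within-species order so merges are independent of the
  # input row order: the parent species record wins ties over subspecies
  merged <- rec |>
    dplyr::arrange(
      .data$scientific_name, .data$.was_ssp, .data$description_year,
      .data$described_from
    ) |>
    dplyr::group_by(.data$scientific_name) |>
    dplyr::summarise(
      rank = "species",
      status = "valid",
      fossil = FALSE,
      family = first_non_na(.data$family),
      suborder = first_non_na(.data$suborder),
      description_year = min_or_na(.data$description_year),
      occurrence_regions = list(sort(unique(unlist(.data$occurrence_regions)))),
      described_from = first_non_na(.data$described_from),
      country_tags = list(sort(unique(unlist(.data$country_tags)))),
      .groups = "drop"
    )
  # rows absorbed beyond the subspecies collapse
  log["duplicates_merged"] <- max(
    0L, nrow(rec) - nrow(merged) - unname(log["subspecies_collapsed"])
  )
  merged <- merged |>
    dplyr::arrange(.data$family, .data$scientific_name) |>
    dplyr::select(dplyr::all_of(names(x)))
  new_checklist(
    merged,
    source = attr(x, "source"), normalized = TRUE, log = log
  )
}

binomial_of <- function(name) {
  vapply(strsplit(name, "\\s+"), function(w) {
    paste(head(w, 2L), collapse = " ")
  }, "")
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_character_ else x[[1]]
}

min_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_integer_ else as.integer(min(x))
}

#' Restrict a checklist to species described from one region
#'
#' Regional description-rate checklists must credit each species to the area
#' of its type locality, not to every area where it occurs — otherwise a
#' widespread species would inflate several regional rates. This filter
#' keeps records whose `described_from` equals the given Level-1 TDWG
#' region, or, for country-level subsets (e.g. China), records whose
#' country tags contain the country. Records lacking a `described_from`
#' value are excluded and counted in the drop log.
#'
#' @param x A normalized checklist.
#' @param region A Level-1 TDWG code, or a country tag.
#' @param type `"auto"` (a known Level-1 code is treated as a region,
#'   anything else as a country tag), `"region"` or `"country"`.
#' @return A checklist containing the matching subset.
#' @export
filter_described_in <- function(x, region,
                                type = c("auto", "region", "country")) {
  stopifnot(inherits(x, "checklist"), length(region) == 1L)
  type <- match.arg(type)
  lvl <- tdwg_level(region)
  if (type == "auto") {
    type <- if (!is.na(lvl) && lvl == 1L) "region" else "country"
  }
  if (type == "region") {
    if (is.na(lvl) || lvl != 1L) {
      stop("unknown Level-1 region code: ", region, call. = FALSE)
    }
    hit <- !is.na(x$described_from) & x$described_from == toupper(region)
    n_missing <- sum(is.na(x$described_from))
  } else {
    known <- unique(unlist(x$country_tags))
    if (!(region %in% known)) {
      stop("unknown country tag: ", region, call. = FALSE)
    }
    hit <- vapply(x$country_tags, function(v) region %in% v, TRUE)
    n_missing <- sum(lengths(x$country_tags) == 0)
  }
  out <- x[hit, ]
  attr(out, "drop_log") <- c(
    input = nrow(x), kept = sum(hit), no_described_from = n_missing
  )
  attr(out, "normalized") <- attr(x, "normalized")
  attr(out, "source") <- paste0(attr(x, "source"), " [", region, "]")
  out
}
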