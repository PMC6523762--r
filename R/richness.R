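#' Species-by-region presence/absence matrix
#'
#' Builds the binary species x region matrix underlying richness
#' tabulation. Each species' occurrence codes (recorded at any TDWG level)
#' are resolved to the requested level by walking up the region hierarchy;
#' a cell is 1 iff at least one occurrence resolves to that column's
#' region. Species with no resolvable occurrence region are excluded with
#' a warning.
#'
#' @param x A normalized checklist.
#' @param level TDWG level for the columns (1, 2 or 3); level 1 gives the
#'   continental analysis regions.
#' @param regions Optional character vector fixing the column set and
#'   order; defaults to [analysis_regions()] at level 1, otherwise to the
#'   codes observed.
#' @return A `presence_matrix`: a binary matrix with species rownames and
#'   region-code colnames.
#' @export
presence_matrix <- function(x, level = 1L, regions = NULL) {
  stopifnot(inherits(x, "checklist"), level %in% 1:3)
  if (!is_normalized(x)) {
    stop("presence_matrix() expects a normalized checklist", call. = FALSE)
  }
  resolved <- lapply(x$occurrence_regions, function(v) {
    unique(stats::na.omit(tdwg_ancestor(v, level)))
  })
  empty <- lengths(resolved) == 0
  if (any(empty)) {
    warning(
      sum(empty), " species with no resolvable occurrence region ",
      "excluded from the presence matrix",
      call. = FALSE
    )
  }
  species <- x$scientific_name[!empty]
  resolved <- resolved[!empty]
  if (is.null(regions)) {
    regions <- if (level == 1L) {
      intersect(
        c(analysis_regions(), "PAC", "ANT"),
        unique(unlist(resolved))
      )
    } else {
      sort(unique(unlist(resolved)))
    }
  }
  m <- matrix(
    0L, nrow = length(species), ncol = length(regions),
    dimnames = list(species, regions)
  )
  for (i in seq_along(species)) {
    hit <- intersect(resolved[[i]], regions)
    m[i, hit] <- 1L
  }
  structure(m, class = c("presence_matrix", "matrix", "array"), level = level)
}

#' Family-by-region richness table
#'
#' Counts valid extant species per family, globally and within each region
#' of a presence matrix, mirroring the family-by-continental-region
#' richness summaries used for checklist-scale faunas. The global count of
#' a family is its number of species; because a species may occupy several
#' regions, a family's global count can be smaller than the sum of its
#' per-region counts. Totals are always recomputed from the cells.
#'
#' @param m A [presence_matrix()].
#' @param x The normalized checklist the matrix was built from (supplies
#'   the family of each species).
#' @return A `richness_table`: a tibble with one row per family, a
#'   `global` column, one column per region, and a totals row accessible
#'   via `attr(, "totals")` as well as appended with family `"Total"`.
#' @export
richness_by_family <- function(m, x) {
  stopifnot(inherits(m, "presence_matrix"), inherits(x, "checklist"))
  fam <- x$family[match(rownames(m), x$scientific_name)]
  missing_fam <- is.na(fam) | !nzchar(fam)
  if (any(missing_fam)) {
    warning(
      sum(missing_fam), " species without family grouped as 'Unassigned'",
      call. = FALSE
    )
    fam[missing_fam] <- "Unassigned"
  }
  fams <- sort(unique(fam))
  per_region <- t(vapply(
    fams,
    function(f) colSums(m[fam == f, , drop = FALSE]),
    numeric(ncol(m))
  ))
  tab <- tibble::tibble(
    family = fams,
    global = as.integer(table(fam)[fams])
  )
  for (j in seq_len(ncol(m))) {
    tab[[colnames(m)[j]]] <- as.integer(per_region[, j])
  }
  totals <- c(
    global = sum(tab$global),
    vapply(colnames(m), function(r) sum(tab[[r]]), numeric(1))
  )
  out <- dplyr::bind_rows(
    tab,
    tibble::tibble(family = "Total", !!!as.list(as.integer(totals)) |>
      stats::setNames(names(totals)))
  )
  structure(
    out,
    class = c("richness_table", class(tibble::tibble())),
    totals = totals
  )
}

#' @rdname richness_by_family
#' @param tab A richness table.
#' @return `richness_totals()` returns the named vector of column totals
#'   (global first).
#' @export
richness_totals <- function(tab) attr(tab, "totals")

#' Write a richness table as CSV or JSON
#'
#' @param tab A [richness_by_family()] table.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else CSV).
#' @param meta Optional named list written as `# key: value` header
#'   comments (CSV) or a `meta` element (JSON).
#' @return `path`, invisibly.
#' @export
write_richness_table <- function(tab, path, meta = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      rows = tab[tab$family != "Total", ],
      totals = as.list(richness_totals(tab))
    )
    if (!is.null(meta)) payload$meta <- meta
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    write_with_header(tab, path, meta)
  }
  invisible(path)
}

write_with_header <- function(df, path, meta = NULL) {
  lines <- character()
  if (!is.null(meta)) {
    lines <- sprintf("# %s: %s", names(meta), unlist(meta))
  }
  body <- sub("\n$", "", readr::format_csv(df))
  writeLines(c(lines, body), path)
  invisible(path)
}
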