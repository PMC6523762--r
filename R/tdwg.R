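#' TDWG world geographical scheme regions
#'
#' Returns the packaged table of TDWG (Biodiversity Information Standards)
#' regions used to encode species occurrence. The scheme is hierarchical:
#' Level 1 holds continental regions (Europe, Africa, Asia-Temperate,
#' Asia-Tropical, Australasia, Pacific, North America, South America,
#' Antarctic), Level 2 subdivides them, and Levels 3-4 grade into
#' political/administrative units. A record known only from a fine-level
#' unit (say Ontario, Level 3) resolves to its continental region
#' (North America) by walking up the `parent_code` chain.
#'
#' @return A tibble with columns `level` (integer), `code`, `name` and
#'   `parent_code` (`NA` for Level-1 regions).
#' @export
#' @examples
#' tdwg_regions()
tdwg_regions <- function() {
  if (is.null(the_cache$tdwg)) {
    path <- system.file("extdata", "tdwg_regions.csv", package = "discurve")
    the_cache$tdwg <- readr::read_csv(
      path,
      col_types = readr::cols(
        level = readr::col_integer(),
        code = readr::col_character(),
        name = readr::col_character(),
        parent_code = readr::col_character()
      ),
      progress = FALSE
    )
  }
  the_cache$tdwg
}

#' The seven Level-1 regions used in continental-scale analyses
#'
#' Europe, Africa (including Madagascar), Asia-Temperate (including China),
#' Asia-Tropical, Australasia, North America (including Mexico) and South
#' America. The Pacific and Antarctic Level-1 regions are part of the TDWG
#' scheme but hold no stonefly species and are excluded from tabulations
#' by default.
#'
#' @return Character vector of seven Level-1 region codes.
#' @export
analysis_regions <- function() {
  c("EUR", "AFR", "TEA", "TRA", "AUS", "NAM", "SAM")
}

#' @rdname tdwg_regions
#' @param code Character vector of region codes.
#' @return `tdwg_level()` returns the integer level of each code
#'   (`NA` for unknown codes).
#' @export
tdwg_level <- function(code) {
  tab <- tdwg_regions()
  tab$level[match(toupper(code), tab$code)]
}

#' Resolve region codes to their ancestor at a given level
#'
#' Walks up the TDWG parent chain until the requested level is reached.
#' Codes already at the requested level are returned unchanged; codes at a
#' coarser level than requested, and codes absent from the region table,
#' resolve to `NA`.
#'
#' @param code Character vector of region codes (any level).
#' @param level Target level, an integer in 1..4.
#' @return Character vector of codes at `level`, `NA` where unresolvable.
#' @export
#' @examples
#' tdwg_ancestor("ONT", 1) # Ontario -> North America
tdwg_ancestor <- function(code, level = 1L) {
  stopifnot(length(level) == 1L, level >= 1L)
  tab <- tdwg_regions()
  code <- toupper(code)
  out <- rep(NA_character_, length(code))
  for (i in seq_along(code)) {
    cur <- code[i]
    repeat {
      j <- match(cur, tab$code)
      if (is.na(j)) break
      if (tab$level[j] == level) {
        out[i] <- cur
        break
      }
      if (tab$level[j] < level) break
      cur <- tab$parent_code[j]
      if (is.na(cur)) break
    }
  }
  out
}

#' Validate region codes against the TDWG table
#'
#' @param codes Character vector.
#' @return Logical vector, `TRUE` where the code is known.
#' @keywords internal
tdwg_known <- function(codes) {
  toupper(codes) %in% tdwg_regions()$code
}
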