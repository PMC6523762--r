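# small in-code fixtures shared across test files

# a raw checklist with one of everything normalize() must handle
messy_checklist <- function() {
  checklist(
    scientific_name = c(
      "Alpha beta", # valid species
      "Alpha beta gamma", # its subspecies, older, other region
      "Alpha obsoleta", # synonym
      "Alpha antiqua", # fossil
      "Delta epsilon" # valid species, second family
    ),
    rank = c("species", "subspecies", "species", "species", "species"),
    status = c("valid", "valid", "synonym", "valid", "valid"),
    fossil = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    family = c("Perlidae", "Perlidae", "Perlidae", "Perlidae", "Nemouridae"),
    description_year = c(1990L, 1985L, 1900L, 1880L, 2001L),
    occurrence_regions = list("EUR", "NAM", "EUR", "EUR", c("TEA", "TRA")),
    described_from = c("EUR", "NAM", "EUR", "EUR", "TEA")
  )
}

# five species x three Level-1 regions with hand-enumerated memberships
hand_matrix_checklist <- function() {
  checklist(
    scientific_name = paste("Perla", c("una", "duo", "tres", "quat", "quin")),
    family = "Perlidae",
    description_year = 2000L,
    occurrence_regions = list(
      "EUR", c("EUR", "NAM"), "NAM", c("EUR", "NAM", "SAM"), "SAM"
    ),
    normalized = TRUE
  )
}

strip_meta <- function(x) {
  x <- tibble::as_tibble(x)
  for (a in c("drop_log", "problems", "source", "normalized")) {
    attr(x, a) <- NULL
  }
  class(x) <- class(tibble::tibble())
  x
}

expect_records_equal <- function(a, b) {
  expect_equal(strip_meta(a), strip_meta(b))
}
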