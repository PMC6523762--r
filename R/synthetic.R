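#' Allocate an integer total proportionally (largest remainder)
#'
#' Splits `total` across categories proportionally to `weights`, rounding
#' so the parts sum exactly to `total`: each part gets the floor of its
#' proportional share and leftover units go to the largest fractional
#' remainders (ties broken by position). Deterministic.
#'
#' @param total Non-negative integer.
#' @param weights Non-negative weights, not all zero (unless `total` is 0).
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (total == 0) {
    return(integer(length(weights)))
  }
  stopifnot(sum(weights) > 0)
  share <- total * weights / sum(weights)
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- share - base
    idx <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Specification of a synthetic discovery world
#'
#' Defines everything needed to generate reproducible per-region
#' checklists whose description years follow logistic NHRP discovery
#' curves: per-region species budgets, per-region (or shared) NHRP
#' parameters, family composition, a probability of occupying an extra
#' region, count dispersion, the simulated year range and a seed.
#'
#' @param budgets Named integer vector: target in-window species count per
#'   Level-1 region code.
#' @param params A single [nhrp_params()] shared by all regions, or a
#'   named list of per-region parameter sets.
#' @param families Optional family composition: a named numeric vector of
#'   proportions shared by all regions, or a tibble with a `family` column
#'   plus one proportion column per region code (columns summing to 1).
#'   Defaults to a single synthetic family.
#' @param multi_region_prob Probability that a species also occupies one
#'   additional (uniformly chosen) region.
#' @param phi Count dispersion (`>= 1`; 1 = Poisson).
#' @param years Length-2 vector: first and last simulated year.
#' @param year_mode `"stochastic"` draws annual counts via
#'   [simulate_descriptions()] with the region's curve rescaled so its
#'   expected in-window total equals the budget (the realized total is
#'   random); `"deterministic"` places exactly `budget` description years
#'   by largest-remainder allocation against the logistic increments, for
#'   exact-count fixtures.
#' @param seed Integer seed.
#' @return A `world_spec` object.
#' @export
world_spec <- function(budgets, params, families = NULL,
                       multi_region_prob = 0, phi = 1,
                       years = c(1850, 2018),
                       year_mode = c("stochastic", "deterministic"),
                       seed = 1) {
  year_mode <- match.arg(year_mode)
  stopifnot(
    length(budgets) > 0, !is.null(names(budgets)), all(budgets >= 0),
    multi_region_prob >= 0, multi_region_prob <= 1,
    phi >= 1, length(years) == 2, years[1] <= years[2]
  )
  if (inherits(params, "nhrp_params")) {
    params <- stats::setNames(
      rep(list(params), length(budgets)), names(budgets)
    )
  }
  stopifnot(all(names(budgets) %in% names(params)))
  if (is.null(families)) families <- c(Familia = 1)
  structure(
    list(
      budgets = budgets, params = params, families = families,
      multi_region_prob = multi_region_prob, phi = phi,
      years = as.integer(years), year_mode = year_mode,
      seed = as.integer(seed)
    ),
    class = "world_spec"
  )
}

#' Read a world specification from a YAML config file
#'
#' @param path YAML file with keys `budgets` (map region -> count),
#'   `params` (either `N`/`v1`/`v2` or a map region -> those),
#'   and optionally `families`, `multi_region_prob`, `phi`, `years`,
#'   `year_mode`, `seed`.
#' @return A [world_spec()].
#' @export
read_world_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads an unquoted key `N` as boolean FALSE; restore it
  fix_n <- function(p) {
    names(p)[names(p) %in% c("FALSE", "false")] <- "N"
    p
  }
  cfg$params <- if (all(c("v1", "v2") %in% names(cfg$params))) {
    fix_n(cfg$params)
  } else {
    lapply(cfg$params, fix_n)
  }
  params <- if (all(c("N", "v1", "v2") %in% names(cfg$params))) {
    nhrp_params(cfg$params$N, cfg$params$v1, cfg$params$v2)
  } else {
    lapply(cfg$params, function(p) nhrp_params(p$N, p$v1, p$v2))
  }
  world_spec(
    budgets = unlist(cfg$budgets),
    params = params,
    families = if (!is.null(cfg$families)) unlist(cfg$families) else NULL,
    multi_region_prob = cfg$multi_region_prob %||% 0,
    phi = cfg$phi %||% 1,
    years = unlist(cfg$years %||% c(1850, 2018)),
    year_mode = cfg$year_mode %||% "stochastic",
    seed = cfg$seed %||% 1
  )
}

family_props_for <- function(families, code) {
  if (is.data.frame(families)) {
    stopifnot("family" %in% names(families), code %in% names(families))
    stats::setNames(families[[code]], families$family)
  } else {
    families
  }
}

#' Generate synthetic per-region checklists
#'
#' For each region of the [world_spec()], draws (or deterministically
#' places) description years along the region's logistic discovery curve,
#' assigns families by the stated proportions (largest-remainder, so
#' composition is exact), sets `described_from` to the generating region,
#' and with probability `multi_region_prob` adds one extra occurrence
#' region per species. Fully reproducible: the same spec and seed yield
#' byte-identical checklists.
#'
#' @param spec A [world_spec()].
#' @return Named list of normalized [checklist()] objects, one per region.
#' @seealso [bind_checklists()] to pool regions into a global checklist.
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  codes <- names(spec$budgets)
  yrs <- seq(spec$years[1], spec$years[2])
  out <- vector("list", length(codes))
  names(out) <- codes
  for (i in seq_along(codes)) {
    code <- codes[i]
    budget <- spec$budgets[[code]]
    p <- as_nhrp_params(spec$params[[code]])
    mu <- nhrp_annual_means(p, yrs)
    if (budget == 0) {
      counts <- integer(length(yrs))
    } else if (spec$year_mode == "deterministic") {
      counts <- largest_remainder(budget, mu)
    } else {
      scale <- budget / sum(mu)
      p2 <- nhrp_params(p$N * scale, p$v1, p$v2)
      counts <- simulate_descriptions(
        p2, spec$phi, spec$years[1], spec$years[2],
        seed = derive_seed(spec$seed, i)
      )$counts
    }
    n <- sum(counts)
    year_vec <- rep(yrs, counts)
    props <- family_props_for(spec$families, code)
    fam_counts <- largest_remainder(n, props)
    fam_vec <- rep(names(props), fam_counts)
    name_vec <- if (n > 0) {
      sprintf(
        "Genus%s%d species%d",
        tolower(code), match(fam_vec, names(props)), seq_len(n)
      )
    } else {
      character()
    }
    regions_list <- as.list(rep(code, n))
    if (n > 0 && spec$multi_region_prob > 0 && length(codes) > 1) {
      extra <- with_seed(derive_seed(spec$seed, 1000L + i), {
        gets <- runif(n) < spec$multi_region_prob
        pick <- sample(length(codes) - 1L, n, replace = TRUE)
        list(gets = gets, pick = pick)
      })
      others <- setdiff(codes, code)
      for (j in which(extra$gets)) {
        regions_list[[j]] <- c(code, others[extra$pick[j]])
      }
    }
    out[[i]] <- checklist(
      scientific_name = name_vec,
      family = fam_vec,
      description_year = year_vec,
      occurrence_regions = regions_list,
      described_from = code,
      source = sprintf("synthetic world (seed %d)", spec$seed),
      normalized = TRUE
    )
  }
  out
}

#' Pool several checklists into one
#'
#' @param checklists List of checklists (e.g. a [generate_world()]
#'   result).
#' @param source Provenance label for the pooled checklist.
#' @return A single checklist containing all records, canonically sorted.
#' @export
bind_checklists <- function(checklists, source = "pooled") {
  rec <- dplyr::bind_rows(lapply(checklists, tibble::as_tibble)) |>
    dplyr::arrange(.data$family, .data$scientific_name)
  new_checklist(
    rec,
    source = source,
    normalized = all(vapply(checklists, is_normalized, TRUE))
  )
}

#' Reference-shaped fixture checklists for the global stonefly fauna
#'
#' Deterministic synthetic checklists whose marginal counts reproduce the
#' published reference tabulations for stoneflies (Plecoptera) through
#' 2018, shipped with the package as plain CSVs of counts:
#'
#' * `"richness"` — a single global checklist whose family-by-region
#'   presence counts equal the reference family-by-continental-region
#'   richness table (3718 valid extant species across 16 families and
#'   seven TDWG Level-1 regions). Species occupying several regions are
#'   constructed so that both the per-region counts and the global count
#'   of every family are matched exactly.
#' * `"rates"` — per-area checklists (Global, the seven Level-1 regions,
#'   and China as a country subset of Asia-Temperate) whose 1980-2018
#'   in-window counts equal the reference description-rate counts (1657
#'   species globally). Each area is its own deterministic checklist,
#'   mirroring the per-region reference checklists the published counts
#'   were derived from.
#'
#' Species names are synthetic; only the count structure is real.
#'
#' @param which `"richness"` or `"rates"`.
#' @return For `"richness"`, a normalized [checklist()]; for `"rates"`, a
#'   named list of normalized checklists, one per area (first element
#'   `"Global"`).
#' @export
fixture_checklists <- function(which = c("richness", "rates")) {
  which <- match.arg(which)
  if (which == "richness") {
    fixture_richness_checklist()
  } else {
    fixture_rates_checklists()
  }
}

fixture_richness_checklist <- function() {
  path <- system.file(
    "extdata", "stonefly_richness_by_region.csv",
    package = "discurve"
  )
  ref <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  region_cols <- intersect(analysis_regions(), names(ref))
  rows <- vector("list", nrow(ref))
  for (i in seq_len(nrow(ref))) {
    fam <- ref$family[i]
    g <- ref$global[i]
    r <- stats::setNames(
      as.integer(ref[i, region_cols]), region_cols
    )
    r <- r[r > 0]
    extras <- sum(r) - g
    stopifnot(extras >= 0, extras <= max(r))
    # primary region per species: shave `extras` presences off the
    # smallest regions; those become secondary occurrences of species
    # whose primary is the largest region
    ord <- names(sort(r))
    largest <- names(which.max(r))
    e <- stats::setNames(integer(length(r)), names(r))
    left <- extras
    for (cd in setdiff(ord, largest)) {
      take <- min(left, r[[cd]])
      e[cd] <- take
      left <- left - take
      if (left == 0) break
    }
    stopifnot(left == 0)
    primary <- rep(names(r), r - e)
    regions_list <- as.list(primary)
    host <- which(primary == largest)
    k <- 0L
    for (cd in names(e)[e > 0]) {
      sel <- host[seq_len(e[[cd]]) + k]
      k <- k + e[[cd]]
      for (j in sel) regions_list[[j]] <- c(regions_list[[j]], cd)
    }
    stopifnot(length(regions_list) == g)
    rows[[i]] <- checklist(
      scientific_name = sprintf("%s sp%d", sub("dae$", "a", fam), seq_len(g)),
      family = fam,
      suborder = ref$suborder[i],
      description_year = 1850L + (seq_len(g) - 1L) %% 169L,
      occurrence_regions = regions_list,
      described_from = NA,
      normalized = TRUE
    )
  }
  bind_checklists(rows, source = "reference richness fixture")
}

fixture_rates_checklists <- function() {
  path <- system.file(
    "extdata", "stonefly_descriptions_1980_2018.csv",
    package = "discurve"
  )
  ref <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  # each area gets its own deterministic checklist, mirroring the
  # per-region reference checklists these counts were derived from (the
  # published regional counts are not an exact partition of the global
  # count, so they cannot all be filters of one pooled list)
  out <- vector("list", nrow(ref))
  names(out) <- ref$area
  for (i in seq_len(nrow(ref))) {
    n <- ref$n_described[i]
    code <- ref$code[i]
    region <- switch(ref$type[i],
      global = NA_character_,
      country = "TEA",
      code
    )
    out[[i]] <- checklist(
      scientific_name = sprintf("Perla %s%d", tolower(ref$area[i]), seq_len(n)),
      family = "Perlidae",
      description_year = 1980L + (seq_len(n) - 1L) %% 39L,
      occurrence_regions = as.list(
        rep(if (is.na(region)) "TEA" else region, n)
      ),
      described_from = region,
      country_tags = if (ref$type[i] == "country") {
        as.list(rep(code, n))
      } else {
        list()
      },
      source = sprintf("reference description-rate fixture [%s]", ref$area[i]),
      normalized = TRUE
    )
  }
  out
}

#' Inject nomenclatural contaminants into a clean checklist
#'
#' Adds synonym, fossil and subspecies rows (and clears the normalized
#' flag) so that [normalize_checklist()] can be exercised against a known
#' clean target. Subspecies are attached to seeded-randomly chosen
#' existing species, with a description year a few years after the
#' parent's (or before, to exercise the earliest-year rule).
#'
#' @param x A normalized checklist.
#' @param n_synonyms,n_fossils,n_subspecies Number of rows of each kind.
#' @param seed Integer seed.
#' @return A raw checklist containing the original records plus
#'   contaminants, in shuffled order.
#' @export
inject_contaminants <- function(x, n_synonyms = 0, n_fossils = 0,
                                n_subspecies = 0, seed = 1) {
  stopifnot(inherits(x, "checklist"), nrow(x) > 0)
  extra <- with_seed(seed, {
    parts <- list()
    if (n_synonyms > 0) {
      parts$syn <- checklist(
        scientific_name = sprintf("Synonymus syn%d", seq_len(n_synonyms)),
        status = "synonym",
        family = sample(x$family, n_synonyms, replace = TRUE),
        description_year = 1900L + seq_len(n_synonyms),
        occurrence_regions = as.list(rep("EUR", n_synonyms))
      )
    }
    if (n_fossils > 0) {
      parts$fos <- checklist(
        scientific_name = sprintf("Fossilis extincta%d", seq_len(n_fossils)),
        fossil = TRUE,
        family = sample(x$family, n_fossils, replace = TRUE),
        description_year = 1880L + seq_len(n_fossils),
        occurrence_regions = as.list(rep("EUR", n_fossils))
      )
    }
    if (n_subspecies > 0) {
      host <- sample(nrow(x), n_subspecies, replace = TRUE)
      offset <- sample(c(-3L, 2L, 5L), n_subspecies, replace = TRUE)
      parts$ssp <- checklist(
        scientific_name = sprintf(
          "%s ssp%d", x$scientific_name[host], seq_len(n_subspecies)
        ),
        rank = "subspecies",
        family = x$family[host],
        description_year = x$description_year[host] + offset,
        occurrence_regions = x$occurrence_regions[host],
        described_from = x$described_from[host]
      )
    }
    all_rec <- dplyr::bind_rows(
      c(list(tibble::as_tibble(x)), lapply(parts, tibble::as_tibble))
    )
    all_rec[sample(nrow(all_rec)), ]
  })
  new_checklist(
    extra,
    source = paste0(attr(x, "source"), " + contaminants"),
    normalized = FALSE
  )
}
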