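demo_spec <- function(...) {
  world_spec(
    budgets = c(EUR = 120, NAM = 80, SAM = 50),
    params = nhrp_params(N = 300, v1 = 0.06, v2 = 2000),
    years = c(1950, 2018),
    seed = 42,
    ...
  )
}

test_that("largest-remainder allocation is exact and deterministic", {
  expect_equal(largest_remainder(10, c(1, 1)), c(5L, 5L))
  # shares 3.5 / 1.75 / 1.75: the two .75 remainders take the leftovers
  expect_equal(largest_remainder(7, c(2, 1, 1)), c(3L, 2L, 2L))
  expect_equal(sum(largest_remainder(307, runif(20))), 307L)
  expect_equal(largest_remainder(0, c(1, 2)), c(0L, 0L))
  # ties break by position
  expect_equal(largest_remainder(1, c(1, 1)), c(1L, 0L))
})

test_that("identical spec and seed give byte-identical checklists", {
  w1 <- generate_world(demo_spec())
  w2 <- generate_world(demo_spec())
  expect_identical(
    lapply(w1, tibble::as_tibble),
    lapply(w2, tibble::as_tibble)
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_checklist(w1$EUR, p1)
  write_checklist(w2$EUR, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the stochastic draws
  w3 <- generate_world(world_spec(
    budgets = c(EUR = 120, NAM = 80, SAM = 50),
    params = nhrp_params(300, 0.06, 2000),
    years = c(1950, 2018), seed = 43
  ))
  expect_false(identical(
    tibble::as_tibble(w1$EUR), tibble::as_tibble(w3$EUR)
  ))
})

test_that("zero budgets give empty checklists", {
  w <- generate_world(world_spec(
    budgets = c(EUR = 0, NAM = 0),
    params = nhrp_params(300, 0.06, 2000),
    seed = 1
  ))
  expect_equal(vapply(w, nrow, integer(1)), c(EUR = 0L, NAM = 0L))
})

test_that("deterministic year placement hits the budget exactly through the pipeline", {
  w <- generate_world(demo_spec(year_mode = "deterministic"))
  expect_equal(nrow(w$EUR), 120L)
  expect_equal(nrow(w$SAM), 50L)
  # conservation through the rate stage: rate = count / window span
  tab <- rate_table(w, 1950, 2018)
  expect_equal(tab$rate, tab$n_described / 68)
  expect_equal(sum(tab$n_described), 250L)
  # a forced count of 307 flows through to the richness total
  w307 <- generate_world(world_spec(
    budgets = c(AUS = 307),
    params = nhrp_params(400, 0.05, 2000),
    year_mode = "deterministic", seed = 9
  ))
  m <- presence_matrix(w307$AUS, 1)
  expect_equal(unname(richness_totals(richness_by_family(m, w307$AUS))["AUS"]), 307)
})

test_that("stochastic budgets are hit in expectation and partition the pool", {
  w <- generate_world(demo_spec())
  # realized counts are random but near the budgets
  expect_gt(nrow(w$EUR), 80)
  expect_lt(nrow(w$EUR), 160)
  # described_from strictly partitions: per-region counts sum to the pool
  pool <- bind_checklists(w)
  expect_equal(
    nrow(filter_described_in(pool, "EUR")) +
      nrow(filter_described_in(pool, "NAM")) +
      nrow(filter_described_in(pool, "SAM")),
    nrow(pool)
  )
  expect_equal(
    count_described(pool, 1950, 2018),
    sum(vapply(w, count_described, integer(1), 1950, 2018))
  )
})

test_that("family proportions and extra-region occupancy are honoured", {
  spec <- world_spec(
    budgets = c(EUR = 200, NAM = 200),
    params = nhrp_params(500, 0.06, 2000),
    families = c(Perlidae = 0.5, Nemouridae = 0.3, Capniidae = 0.2),
    multi_region_prob = 0.3,
    year_mode = "deterministic",
    seed = 7
  )
  w <- generate_world(spec)
  expect_equal(
    unname(table(w$EUR$family)[c("Perlidae", "Nemouridae", "Capniidae")]),
    c(100L, 60L, 40L),
    ignore_attr = TRUE
  )
  n_multi <- sum(lengths(w$EUR$occurrence_regions) > 1)
  expect_gt(n_multi, 200 * 0.3 - 4 * sqrt(200 * 0.3 * 0.7))
  expect_lt(n_multi, 200 * 0.3 + 4 * sqrt(200 * 0.3 * 0.7))
  # every species still occurs in its own region
  expect_true(all(vapply(
    w$EUR$occurrence_regions, function(v) "EUR" %in% v, TRUE
  )))
})

test_that("per-year generated means track the logistic increments", {
  p <- nhrp_params(150, 0.1, 2000)
  spec_for <- function(s) {
    world_spec(
      budgets = c(EUR = 100), params = p,
      years = c(1990, 2010), seed = s
    )
  }
  reps <- vapply(
    1:200,
    function(s) annual_counts(generate_world(spec_for(s))$EUR, 1990, 2010)$counts,
    numeric(21)
  )
  mu <- nhrp_annual_means(p, 1990:2010)
  expected <- mu * 100 / sum(mu) # budget-rescaled increments
  mc_se <- sqrt(expected / 200)
  expect_true(all(abs(rowMeans(reps) - expected) < 4 * mc_se + 0.05))
})

test_that("the reference richness fixture matches its packaged counts cell by cell", {
  cl <- fixture_checklists("richness")
  ref <- readr::read_csv(
    system.file("extdata", "stonefly_richness_by_region.csv",
      package = "discurve"
    ),
    show_col_types = FALSE
  )
  tab <- richness_by_family(presence_matrix(cl, 1), cl)
  for (i in seq_len(nrow(ref))) {
    row <- tab[tab$family == ref$family[i], ]
    expect_equal(row$global, ref$global[i])
    for (r in analysis_regions()) expect_equal(row[[r]], ref[[r]][i])
  }
})

test_that("the reference rates fixture matches its packaged counts", {
  rts <- fixture_checklists("rates")
  ref <- readr::read_csv(
    system.file("extdata", "stonefly_descriptions_1980_2018.csv",
      package = "discurve"
    ),
    show_col_types = FALSE
  )
  got <- vapply(rts, count_described, integer(1), 1980, 2018)
  expect_equal(unname(got[ref$area]), ref$n_described)
})

test_that("contaminated checklists normalize back to the clean species set", {
  clean <- generate_world(demo_spec(year_mode = "deterministic"))$EUR
  dirty <- inject_contaminants(clean, n_synonyms = 5, n_fossils = 3, seed = 2)
  expect_false(is_normalized(dirty))
  renorm <- normalize_checklist(dirty)
  expect_setequal(renorm$scientific_name, clean$scientific_name)
  expect_equal(unname(drop_log(renorm)[c("invalid_status", "fossil")]), c(5L, 3L))

  # subspecies collapse back into their parents, possibly moving years earlier
  dirty2 <- inject_contaminants(clean, n_subspecies = 10, seed = 3)
  renorm2 <- normalize_checklist(dirty2)
  expect_setequal(renorm2$scientific_name, clean$scientific_name)
  old <- clean$description_year[match(
    renorm2$scientific_name, clean$scientific_name
  )]
  expect_true(all(renorm2$description_year <= old))
})

test_that("world specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(
    c(
      "budgets: {EUR: 50, NAM: 30}",
      "params: {N: 200, v1: 0.05, v2: 2000}",
      "multi_region_prob: 0.1",
      "phi: 1",
      "years: [1960, 2018]",
      "year_mode: deterministic",
      "seed: 5"
    ),
    path
  )
  spec <- read_world_spec(path)
  w <- generate_world(spec)
  expect_equal(nrow(w$EUR), 50L)
  expect_equal(nrow(w$NAM), 30L)
})
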