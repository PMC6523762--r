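#' Run configuration for the analysis pipeline
#'
#' A run configuration collects everything a pipeline stage needs:
#' the input checklist (a file path, or one of the built-in inputs
#' `"fixture:richness"` / `"fixture:rates"`, or `"world:<spec.yml>"` for a
#' synthetic world), its format, the analysis window, the area set for
#' rate tables, NHRP options and the output directory.
#'
#' @param path Optional YAML file to read the configuration from.
#' @param ... Named fields overriding (or, without `path`, supplying) the
#'   configuration: `input`, `format` (`"csv"`, `"tsv"`, `"dwc"`),
#'   `window` (length-2 vector), `areas` (list of lists with `name`,
#'   `code`, `type`), `horizons`, `n_reps`, `seed`, `dispersion`
#'   (`"poisson"` or `"nb"`), `propagate_param_uncertainty`, `plot`,
#'   `out_dir`.
#' @return A `run_config` object (named list).
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(
    input = NULL, format = "csv", window = c(1980L, 2018L),
    areas = NULL, horizons = c(2050L, 2100L), n_reps = 1000L,
    seed = 1L, dispersion = "poisson",
    propagate_param_uncertainty = FALSE, plot = FALSE, out_dir = "."
  )
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  cfg$window <- as.integer(unlist(cfg$window))
  cfg$horizons <- sort(as.integer(unlist(cfg$horizons)))
  stopifnot(
    length(cfg$window) == 2, cfg$window[1] < cfg$window[2],
    cfg$dispersion %in% c("poisson", "nb")
  )
  structure(cfg, class = "run_config")
}

run_meta <- function(config) {
  hashed <- unclass(config)
  hashed$out_dir <- NULL # output location is not part of the analysis
  list(
    generator = paste0(
      "discurve ",
      as.character(utils::packageVersion("discurve"))
    ),
    seed = config$seed,
    config_hash = rlang::hash(hashed)
  )
}

load_checklist_input <- function(config) {
  input <- config$input
  if (is.null(input)) stop("config$input is required", call. = FALSE)
  if (inherits(input, "checklist")) {
    cl <- input
  } else if (identical(input, "fixture:richness")) {
    cl <- fixture_checklists("richness")
  } else if (identical(input, "fixture:rates")) {
    return(fixture_checklists("rates"))
  } else if (is.character(input) && startsWith(input, "world:")) {
    world <- generate_world(read_world_spec(sub("^world:", "", input)))
    cl <- bind_checklists(world, source = input)
  } else {
    cl <- read_checklist(input, format = config$format)
  }
  if (!is_normalized(cl)) cl <- normalize_checklist(cl)
  cl
}

#' Pipeline stage: family-by-region richness summary
#'
#' Reads and normalizes the configured checklist, builds the Level-1
#' presence matrix and the family richness table, and writes it as
#' `richness.csv` and `richness.json` under the output directory (with a
#' run-metadata header).
#'
#' @param config A [run_config()].
#' @return The richness table, invisibly.
#' @export
run_summarize <- function(config) {
  cl <- load_checklist_input(config)
  if (is.list(cl) && !inherits(cl, "checklist")) cl <- cl$Global
  m <- presence_matrix(cl, level = 1L)
  tab <- richness_by_family(m, cl)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- run_meta(config)
  write_richness_table(tab, file.path(config$out_dir, "richness.csv"), meta)
  write_richness_table(tab, file.path(config$out_dir, "richness.json"), meta)
  invisible(tab)
}

#' Pipeline stage: description-rate table
#'
#' Builds the per-area rate table over the configured window. With the
#' `"fixture:rates"` input the per-area checklists are used directly; for
#' a checklist file, per-area checklists are produced by
#' [filter_described_in()] according to `config$areas` (each entry a list
#' with `name`, `code` and `type` `"region"`/`"country"`), with the full
#' checklist as the `Global` row. Writes `rates.csv`.
#'
#' @param config A [run_config()].
#' @return The rate table, invisibly.
#' @export
run_rates <- function(config) {
  cl <- load_checklist_input(config)
  if (is.list(cl) && !inherits(cl, "checklist")) {
    lists <- cl
  } else {
    lists <- list(Global = cl)
    for (a in config$areas %||% list()) {
      lists[[a$name]] <- filter_described_in(
        cl, a$code,
        type = a$type %||% "auto"
      )
    }
  }
  tab <- rate_table(lists, config$window[1], config$window[2])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_with_header(
    tab, file.path(config$out_dir, "rates.csv"), run_meta(config)
  )
  invisible(tab)
}

#' Pipeline stage: fit the NHRP and predict future descriptions
#'
#' Builds the annual description-count series (over the full span of the
#' data by default; set `config$fit_window` to restrict it), fits the
#' logistic NHRP, forward-simulates to the configured horizons, and runs
#' the goodness-of-fit diagnostics. Writes `nhrp_fit.json`,
#' `predictions.csv` and (if `config$plot`) `discovery_curve.png`. A
#' non-converged fit raises an error after writing the diagnostics file.
#'
#' @param config A [run_config()].
#' @return List with `fit`, `predictions` and `gof`, invisibly.
#' @export
run_fit_predict <- function(config) {
  cl <- load_checklist_input(config)
  if (is.list(cl) && !inherits(cl, "checklist")) cl <- cl$Global
  yrs <- cl$description_year[!is.na(cl$description_year)]
  fw <- as.integer(unlist(config$fit_window %||% range(yrs)))
  counts <- annual_counts(cl, fw[1], fw[2])
  fit <- fit_nhrp(counts, estimate_dispersion = config$dispersion == "nb")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_nhrp_fit(fit, file.path(config$out_dir, "nhrp_fit.json"))
  if (!fit$converged) {
    stop("NHRP fit did not converge: ", fit$diagnostic, call. = FALSE)
  }
  pred <- predict_new_species(
    fit,
    last_observed_year = fw[2], horizons = config$horizons,
    n_reps = config$n_reps, seed = config$seed,
    propagate_param_uncertainty = isTRUE(config$propagate_param_uncertainty)
  )
  pred$seed <- config$seed
  write_with_header(
    pred, file.path(config$out_dir, "predictions.csv"), run_meta(config)
  )
  gof <- goodness_of_fit(fit, counts)
  if (isTRUE(config$plot)) {
    gg <- plot_discovery_curve(fit, counts, pred)
    ggplot2::ggsave(
      file.path(config$out_dir, "discovery_curve.png"), gg,
      width = 7, height = 5, dpi = 150
    )
  }
  invisible(list(fit = fit, predictions = pred, gof = gof))
}

#' Pipeline stage: generate synthetic checklists
#'
#' Generates a synthetic world from `config$world` (a [world_spec()], a
#' YAML path, or an inline list with the [read_world_spec()] keys) and
#' writes one checklist CSV per region under the output directory.
#'
#' @param config A [run_config()].
#' @return The named list of checklists, invisibly.
#' @export
run_simulate <- function(config) {
  w <- config$world
  spec <- if (inherits(w, "world_spec")) {
    w
  } else if (is.character(w)) {
    read_world_spec(w)
  } else if (is.list(w)) {
    tmp <- tempfile(fileext = ".yml")
    on.exit(unlink(tmp))
    yaml::write_yaml(w, tmp)
    read_world_spec(tmp)
  } else {
    stop("config$world must be a world_spec, a YAML path or a list",
      call. = FALSE
    )
  }
  world <- generate_world(spec)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (code in names(world)) {
    write_checklist(
      world[[code]],
      file.path(config$out_dir, paste0("checklist_", code, ".csv"))
    )
  }
  invisible(world)
}

#' Discovery-curve plot
#'
#' Observed cumulative descriptions in red, the fitted logistic curve in
#' black, and (if predictions are supplied) dashed 95% interval whiskers
#' at each prediction horizon.
#'
#' @param fit A converged `nhrp_fit`.
#' @param data The observed [annual_counts()].
#' @param predictions Optional [predict_new_species()] table.
#' @return A ggplot object.
#' @export
plot_discovery_curve <- function(fit, data, predictions = NULL) {
  curves <- goodness_of_fit(fit, data)$curves
  gg <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$observed_cum), colour = "red"
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$fitted_cum), colour = "black"
    ) +
    ggplot2::labs(
      x = "Year", y = "Cumulative species described",
      title = "Species discovery curve"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(predictions)) {
    obs_total <- sum(data$counts)
    pr <- dplyr::mutate(
      predictions,
      year = .data$horizon_year,
      mid = obs_total + .data$median_new,
      lo = obs_total + .data$lower95,
      hi = obs_total + .data$upper95
    )
    gg <- gg +
      ggplot2::geom_point(data = pr, ggplot2::aes(y = .data$mid)) +
      ggplot2::geom_errorbar(
        data = pr,
        ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
        linetype = "dashed", width = 2
      )
  }
  gg
}
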