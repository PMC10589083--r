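# Pipeline orchestration: validate -> classify -> trim -> price ->
# productivity -> regress -> summarize, with config snapshotting, logging
# and tidy CSV outputs (including figure-analogue tables).

#' Pipeline run configuration
#'
#' @param farms,harvests Paths to the survey CSVs.
#' @param composition Path to a composition CSV, or `NULL` for the packaged
#'   reference ([default_composition()]).
#' @param rda An [rda_set()] (or RDA overrides as a named list).
#' @param trim Small-cell exclusion threshold (default 12).
#' @param se Standard-error flavour for the regressions (`"ols"`/`"HC1"`).
#' @param share_sold_method `"farm_mean"` or `"pooled"`.
#' @param missing_composition `"error"` or `"skip"`.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(farms, harvests, composition = NULL,
                       rda = rda_set(), trim = 12, se = "ols",
                       share_sold_method = "farm_mean",
                       missing_composition = "error",
                       out_dir = "nutriprod_out") {
  if (is.list(rda) && !inherits(rda, "rda_set")) rda <- do.call(rda_set, rda)
  cfg <- list(farms = farms, harvests = harvests, composition = composition,
              rda = rda, trim = trim, se = se,
              share_sold_method = share_sold_method,
              missing_composition = missing_composition, out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; an `rda:` block overrides
#' individual daily allowances.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    farms = y$farms, harvests = y$harvests,
    composition = y$composition,
    rda = if (is.null(y$rda)) rda_set() else do.call(rda_set, y$rda),
    trim = y$trim %||% 12, se = y$se %||% "ols",
    share_sold_method = y$share_sold_method %||% "farm_mean",
    missing_composition = y$missing_composition %||% "error",
    out_dir = y$out_dir %||% "nutriprod_out"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full productivity pipeline
#'
#' Pre-flight checks every input, then runs classification, trimming, price
#' imputation, productivity, the eight regressions and the system summaries,
#' writing every table, a config snapshot and a run log into
#' `config$out_dir`. Identical inputs and config give byte-identical
#' outputs; any stage failure aborts before partial tables are written.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisibly, a list with every computed object and `paths` of the
#'   written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$farms, config$harvests, config$composition)) {
    if (!file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  comp <- if (is.null(config$composition)) default_composition()
          else load_composition_table(config$composition)
  svy <- load_survey(config$farms, config$harvests, quiet = TRUE)
  say("validate: %d farms, %d harvest lines, %d foods", nrow(svy$farms),
      nrow(svy$harvests), length(unique(svy$harvests$food_code)))

  classified <- classify_farms(svy, comp)
  tab <- contingency_table(classified)
  trimmed <- trim_small_systems(classified, config$trim)
  say("classify: %d farms; trim (cells <= %d): %d retained, %d cells dropped",
      nrow(classified), config$trim, trimmed$n_retained,
      nrow(trimmed$excluded_cells))

  price_book <- build_price_book(svy)
  say("prices: %d lines (%d observed, %d imputed)", nrow(price_book),
      sum(price_book$provenance == "observed_farm"),
      sum(price_book$provenance != "observed_farm"))

  prod <- farm_productivity(svy, comp, config$rda, price_book,
                            config$missing_composition)
  summaries <- system_summaries(svy, trimmed$retained, comp, config$rda,
                                productivity = prod,
                                share_sold_method = config$share_sold_method)
  reg <- run_table2(svy, comp, config$rda, classified = trimmed$retained,
                    se = config$se)
  say("regress: 8 outcomes, n = %d", reg$n)

  figs <- figure_tables(summaries)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  tab_df <- tibble::as_tibble(as.data.frame(unclass(tab)),
                              rownames = "terrestrial")
  tab_df$Total <- rowSums(unclass(tab))
  tab_df <- dplyr::bind_rows(
    tab_df,
    tibble::tibble(terrestrial = "Total",
                   !!!as.list(colSums(unclass(tab))),
                   Total = sum(unclass(tab)))
  )
  readr::write_csv(tab_df, out("contingency_table.csv"))
  readr::write_csv(prod, out("farm_productivity.csv"))
  readr::write_csv(summaries$systems, out("system_summaries.csv"))
  readr::write_csv(reg$long, out("table2_long.csv"))
  readr::write_csv(reg$wide, out("table2_wide.csv"))
  for (nm in names(figs)) {
    readr::write_csv(figs[[nm]], out(paste0(nm, ".csv")))
  }
  snap <- config
  snap$rda <- c(as.list(unclass(config$rda)),
                b12_unit = attr(config$rda, "b12_unit"))
  snap$composition <- snap$composition %||% "<packaged default>"
  yaml::write_yaml(unclass(snap), out("config_snapshot.yaml"))
  writeLines(log_lines, out("run.log"))
  say("wrote %d tables to %s", 5 + length(figs), config$out_dir)

  invisible(list(
    survey = svy, composition = comp, classified = classified,
    contingency = tab, trimmed = trimmed, price_book = price_book,
    productivity = prod, summaries = summaries, regression = reg,
    figures = figs,
    paths = c(out("contingency_table.csv"), out("farm_productivity.csv"),
              out("system_summaries.csv"), out("table2_long.csv"),
              out("table2_wide.csv"),
              file.path(config$out_dir, paste0(names(figs), ".csv")))
  ))
}

#' Figure-analogue tables
#'
#' Tidy long-format tables mirroring the headline figures: per-system
#' quantities produced and shares sold by food group (`fig1`), gross value
#' per hectare by food group (`fig2`), economic productivity overlaid with
#' the seven AE series (`fig3`), and per-nutrient shares contributed by each
#' food group (`nutrient_shares`, percentages summing to 100 within system
#' and nutrient wherever the nutrient is produced at all).
#'
#' @param summaries Output of [system_summaries()].
#' @return Named list of tibbles: `fig1_quantities_shares`,
#'   `fig2_value_by_group`, `fig3_econ_and_nutrients`,
#'   `nutrient_shares_by_group`.
#' @export
figure_tables <- function(summaries) {
  groups <- summaries$groups
  fig1 <- tibble::tibble(
    system = groups$system, group = groups$group,
    kg_per_ha = groups$mean_kg_per_ha,
    share_sold_pct = 100 * groups$share_sold
  )
  fig2 <- tibble::tibble(
    system = groups$system, group = groups$group,
    usd_per_ha = groups$mean_usd_per_ha
  )
  sys <- summaries$systems
  fig3 <- tidyr::pivot_longer(
    sys[c("system", "economic_usd_per_ha", paste0("ae_", nutrient_names()))],
    -"system", names_to = "series", values_to = "value"
  )
  shares <- tidyr::pivot_longer(
    sys[c("system", grep("^ae_.*__", names(sys), value = TRUE))],
    -"system", names_to = "key", values_to = "ae"
  )
  parts <- strsplit(sub("^ae_", "", shares$key), "__", fixed = TRUE)
  shares$nutrient <- vapply(parts, `[`, "", 1L)
  shares$group <- vapply(parts, `[`, "", 2L)
  shares <- dplyr::mutate(
    dplyr::group_by(shares, .data$system, .data$nutrient),
    share_pct = if (sum(.data$ae) > 0) {
      100 * (.data$ae / sum(.data$ae))
    } else {
      rep(0, dplyr::n())
    }
  )
  shares <- dplyr::ungroup(shares)
  list(
    fig1_quantities_shares = fig1,
    fig2_value_by_group = fig2,
    fig3_econ_and_nutrients = fig3,
    nutrient_shares_by_group =
      shares[c("system", "nutrient", "group", "ae", "share_pct")]
  )
}
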