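# Survey microdata model: one farm table and one harvest table, validated
# against the schema every downstream stage assumes.

farm_csv_cols <- function() {
  c("farm_id", "upazila_id", "land_ha", "pond_ha", "head_age",
    "head_education", "head_female", "n_members", "dependency_ratio",
    "off_farm_income", "travel_time_city", "production_costs_usd")
}

harvest_csv_cols <- function() {
  c("farm_id", "food_code", "quantity_kg", "quantity_sold_kg",
    "sales_value_usd")
}

validate_farms <- function(farms) {
  miss <- setdiff(farm_csv_cols(), names(farms))
  if (length(miss)) {
    stop("farm table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(farms$farm_id)) {
    stop("duplicate farm_id: ",
         paste(unique(farms$farm_id[duplicated(farms$farm_id)]),
               collapse = ", "), call. = FALSE)
  }
  num <- setdiff(farm_csv_cols(), c("farm_id", "upazila_id"))
  for (cl in num) {
    if (anyNA(farms[[cl]])) {
      stop("missing values in farm column ", cl, call. = FALSE)
    }
  }
  # every sampled farm practices aquaculture, so pond area is positive;
  # the per-ha denominator is the full sample parcel (land + pond)
  if (any(farms$pond_ha <= 0)) {
    stop("pond_ha must be > 0 for every farm (all sampled farms farm fish)",
         call. = FALSE)
  }
  if (any(farms$land_ha < 0)) stop("land_ha must be >= 0", call. = FALSE)
  if (any(farms$production_costs_usd < 0)) {
    stop("production_costs_usd must be >= 0", call. = FALSE)
  }
  if (any(farms$dependency_ratio < 0)) {
    stop("dependency_ratio must be >= 0", call. = FALSE)
  }
  if (!all(farms$head_female %in% c(0, 1)) ||
      !all(farms$off_farm_income %in% c(0, 1))) {
    stop("head_female and off_farm_income must be 0/1", call. = FALSE)
  }
  invisible(farms)
}

validate_harvests <- function(harvests, farms) {
  miss <- setdiff(harvest_csv_cols(), names(harvests))
  if (length(miss)) {
    stop("harvest table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(unique(harvests$farm_id), farms$farm_id)
  if (length(orphan)) {
    stop("harvest lines for unknown farm_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  num <- c("quantity_kg", "quantity_sold_kg", "sales_value_usd")
  for (cl in num) {
    if (anyNA(harvests[[cl]]) || any(harvests[[cl]] < 0)) {
      stop("harvest column ", cl, " must be non-missing and >= 0",
           call. = FALSE)
    }
  }
  over <- harvests$quantity_sold_kg > harvests$quantity_kg
  if (any(over)) {
    stop("quantity_sold_kg exceeds quantity_kg on row(s): ",
         paste(utils::head(which(over), 10), collapse = ", "),
         call. = FALSE)
  }
  bad_val <- harvests$quantity_sold_kg == 0 & harvests$sales_value_usd > 0
  if (any(bad_val)) {
    stop("positive sales_value_usd with zero quantity sold on row(s): ",
         paste(utils::head(which(bad_val), 10), collapse = ", "),
         call. = FALSE)
  }
  invisible(harvests)
}

#' Construct a validated survey dataset
#'
#' Bundles a farm table and a harvest table into an `iaa_survey` object after
#' full schema validation. Farm columns: `farm_id`, `upazila_id` (subdistrict
#' of the fixed-effect design), `land_ha`, `pond_ha` (the operated sample
#' parcel; total area is their sum), household-head and household covariates,
#' and `production_costs_usd` (variable costs over the cropping cycle).
#' Harvest columns: `farm_id`, `food_code`, whole-product `quantity_kg`
#' produced over the most recent cropping cycle, `quantity_sold_kg` and
#' `sales_value_usd`. Monetary fields are assumed already converted to US$.
#'
#' Self-consumed quantity is derived, never stored:
#' `quantity_kg - quantity_sold_kg`.
#'
#' @param farms Data frame of farms.
#' @param harvests Data frame of farm-by-food harvest lines.
#' @return An `iaa_survey`: list with tibbles `farms` (plus derived
#'   `area_ha`) and `harvests`.
#' @export
iaa_survey <- function(farms, harvests) {
  farms <- tibble::as_tibble(farms)
  harvests <- tibble::as_tibble(harvests)
  farms$farm_id <- as.character(farms$farm_id)
  farms$upazila_id <- as.character(farms$upazila_id)
  harvests$farm_id <- as.character(harvests$farm_id)
  harvests$food_code <- as.character(harvests$food_code)
  validate_farms(farms)
  validate_harvests(harvests, farms)
  farms$area_ha <- farms$land_ha + farms$pond_ha
  structure(list(farms = farms, harvests = harvests), class = "iaa_survey")
}

#' @export
print.iaa_survey <- function(x, ...) {
  cat(sprintf(
    "<iaa_survey> %d farms, %d harvest lines, %d distinct foods, %d upazilas\n",
    nrow(x$farms), nrow(x$harvests), length(unique(x$harvests$food_code)),
    length(unique(x$farms$upazila_id))
  ))
  invisible(x)
}

#' Load a survey from farm and harvest CSV files
#'
#' Reads the two tables, validates the full schema (see [iaa_survey()]) and
#' reports counts. Orphan harvest lines (farm_id absent from the farm table)
#' and harvest lines selling more than was produced are hard errors.
#'
#' @param farm_csv Path to `farms.csv`.
#' @param harvest_csv Path to `harvests.csv`.
#' @param quiet Suppress the count message.
#' @return An `iaa_survey`.
#' @export
load_survey <- function(farm_csv, harvest_csv, quiet = FALSE) {
  farms <- readr::read_csv(farm_csv, show_col_types = FALSE,
                           col_types = readr::cols(
                             farm_id = "c", upazila_id = "c", .default = "d"
                           ))
  harvests <- readr::read_csv(harvest_csv, show_col_types = FALSE,
                              col_types = readr::cols(
                                farm_id = "c", food_code = "c",
                                .default = "d"
                              ))
  svy <- iaa_survey(farms, harvests)
  if (!quiet) {
    message(sprintf("loaded %d farms, %d harvest lines, %d distinct foods",
                    nrow(svy$farms), nrow(svy$harvests),
                    length(unique(svy$harvests$food_code))))
  }
  svy
}

#' Write a survey to farm and harvest CSV files
#'
#' Lossless inverse of [load_survey()] at full double precision (values are
#' serialized with all significant digits, so `load(write(x))` reproduces
#' `x`).
#'
#' @param survey An `iaa_survey`.
#' @param farm_csv,harvest_csv Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_survey <- function(survey, farm_csv, harvest_csv) {
  stopifnot(inherits(survey, "iaa_survey"))
  farms <- survey$farms[farm_csv_cols()]
  readr::write_csv(farms, farm_csv)
  readr::write_csv(survey$harvests[harvest_csv_cols()], harvest_csv)
  invisible(c(farms = farm_csv, harvests = harvest_csv))
}
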