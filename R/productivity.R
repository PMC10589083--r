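# Economic productivity (US$ per hectare) and nutrient productivity (annual
# adult equivalents per hectare), per farm and aggregated by farming system.

#' Build the unit-price book
#'
#' For every farm-by-food line with sales, the observed unit price is
#' `sales_value_usd / quantity_sold_kg`. Foods a farm produced but did not
#' sell are valued by an imputation ladder: the median observed unit price
#' among sellers of that food in the same upazila, falling back to the
#' sample-wide median among all sellers. A food produced somewhere but sold
#' nowhere in the sample has no price source and is a hard error.
#'
#' @param survey An [iaa_survey()].
#' @return Tibble with one row per produced farm-by-food line: `farm_id`,
#'   `food_code`, `unit_price_usd_kg`, and `provenance` in
#'   `observed_farm` / `imputed_group_median` / `imputed_sample_median`.
#' @export
build_price_book <- function(survey) {
  h <- survey$harvests[survey$harvests$quantity_kg > 0, ]
  h <- dplyr::left_join(h,
                        survey$farms[c("farm_id", "upazila_id")],
                        by = "farm_id")
  sellers <- h[h$quantity_sold_kg > 0, ]
  sellers$price <- sellers$sales_value_usd / sellers$quantity_sold_kg
  if (any(sellers$price <= 0)) {
    stop("non-positive observed unit price for food(s): ",
         paste(unique(sellers$food_code[sellers$price <= 0]),
               collapse = ", "), call. = FALSE)
  }
  med_upz <- dplyr::summarise(
    dplyr::group_by(sellers, .data$food_code, .data$upazila_id),
    p_upz = stats::median(.data$price), .groups = "drop"
  )
  med_all <- dplyr::summarise(
    dplyr::group_by(sellers, .data$food_code),
    p_all = stats::median(.data$price), .groups = "drop"
  )
  book <- tibble::tibble(
    farm_id = h$farm_id, food_code = h$food_code, upazila_id = h$upazila_id,
    obs = ifelse(h$quantity_sold_kg > 0,
                 h$sales_value_usd / h$quantity_sold_kg, NA_real_)
  )
  book <- dplyr::left_join(book, med_upz,
                           by = c("food_code", "upazila_id"))
  book <- dplyr::left_join(book, med_all, by = "food_code")
  book$unit_price_usd_kg <- dplyr::coalesce(book$obs, book$p_upz, book$p_all)
  book$provenance <- dplyr::case_when(
    !is.na(book$obs) ~ "observed_farm",
    !is.na(book$p_upz) ~ "imputed_group_median",
    !is.na(book$p_all) ~ "imputed_sample_median",
    TRUE ~ NA_character_
  )
  if (anyNA(book$unit_price_usd_kg)) {
    stop("no price source (no seller anywhere in sample) for food(s): ",
         paste(unique(book$food_code[is.na(book$unit_price_usd_kg)]),
               collapse = ", "), call. = FALSE)
  }
  book[c("farm_id", "food_code", "unit_price_usd_kg", "provenance")]
}

#' Economic productivity of one farm
#'
#' Gross margin per hectare over the cropping cycle: the value of everything
#' produced (self-consumed output valued at the same unit price as sales)
#' minus reported variable production costs, divided by the farm's total
#' sample-parcel area. Negative values (costs exceeding output value) pass
#' through untruncated.
#'
#' @param farm One row of the farm table (must carry `farm_id`, `area_ha`,
#'   `production_costs_usd`).
#' @param harvests Harvest lines of that farm.
#' @param price_book Output of [build_price_book()].
#' @return US$ per hectare (scalar).
#' @export
economic_productivity <- function(farm, harvests, price_book) {
  stopifnot(nrow(farm) == 1L)
  h <- harvests[harvests$farm_id == farm$farm_id &
                  harvests$quantity_kg > 0, ]
  if (nrow(h) == 0L && farm$production_costs_usd == 0) return(0)
  value <- 0
  if (nrow(h) > 0L) {
    pb <- price_book[price_book$farm_id == farm$farm_id, ]
    idx <- match(h$food_code, pb$food_code)
    if (anyNA(idx)) {
      stop("price book has no entry for farm ", farm$farm_id, " food(s): ",
           paste(h$food_code[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    value <- sum(h$quantity_kg * pb$unit_price_usd_kg[idx])
  }
  (value - farm$production_costs_usd) / farm$area_ha
}

#' Annual adult equivalents from per-hectare nutrient amounts
#'
#' Converts an amount of each nutrient produced per hectare over a year into
#' the number of adults whose full-year requirement it covers:
#' `AE = amount / (RDA_daily * 365)`. AEs are linear in amounts and inversely
#' proportional to the RDA.
#'
#' @param nutrient_amount_per_ha Nutrient vector of per-ha annual amounts.
#' @param rda An [rda_set()].
#' @return Nutrient-named vector of AEs per hectare.
#' @export
#' @examples
#' annual_adult_equivalents(nutrient_vector(energy = 9200 * 365), rda_set())
annual_adult_equivalents <- function(nutrient_amount_per_ha, rda = rda_set()) {
  if (any(rda <= 0)) stop("RDA entries must be > 0", call. = FALSE)
  x <- nutrient_amount_per_ha[nutrient_names()]
  if (anyNA(x)) {
    stop("nutrient_amount_per_ha must cover all nutrients", call. = FALSE)
  }
  x / (unclass(rda)[nutrient_names()] * 365)
}

#' Nutrient productivity of one farm
#'
#' Sums [nutrient_yield()] over the farm's harvest lines, divides by total
#' area, and converts to annual adult equivalents per hectare, with
#' decompositions by the three coarse food groups and by the twelve
#' sub-categories. Each decomposition sums exactly to the total.
#'
#' @param farm One row of the farm table.
#' @param harvests Harvest lines of that farm.
#' @param composition A `food_composition`.
#' @param rda An [rda_set()].
#' @param missing_composition `"error"` (default) or `"skip"` (drop lines
#'   with no composition entry, with a warning).
#' @return List with `total` (AE vector), `by_group` (3 x 7 matrix) and
#'   `by_subcategory` (12 x 7 matrix).
#' @export
nutrient_productivity <- function(farm, harvests, composition,
                                  rda = rda_set(),
                                  missing_composition = c("error", "skip")) {
  missing_composition <- match.arg(missing_composition)
  stopifnot(nrow(farm) == 1L)
  h <- harvests[harvests$farm_id == farm$farm_id &
                  harvests$quantity_kg > 0, ]
  sub_levels <- subcategories()
  grp_levels <- c("aquatic", "rice", "vf")
  by_sub <- matrix(0, length(sub_levels), length(nutrient_names()),
                   dimnames = list(sub_levels, nutrient_names()))
  if (nrow(h) > 0L) {
    dens <- nutrient_density_matrix(composition, h$food_code,
                                    on_missing = missing_composition)
    amt <- dens * h$quantity_kg / farm$area_ha
    known <- h$food_code %in% composition$food_code
    sub <- rep(NA_character_, nrow(h))
    sub[known] <- assign_subcategory(h$food_code[known], composition)
    for (i in which(known)) {
      by_sub[sub[i], ] <- by_sub[sub[i], ] + amt[i, ]
    }
  }
  denom <- unclass(rda)[nutrient_names()] * 365
  by_sub <- sweep(by_sub, 2, denom, "/")
  grp <- food_group(sub_levels)
  by_group <- rowsum(by_sub, grp)[grp_levels, , drop = FALSE]
  list(total = colSums(by_sub), by_group = by_group, by_subcategory = by_sub)
}

#' Per-farm productivity table
#'
#' Runs [economic_productivity()] and [nutrient_productivity()] over every
#' farm and returns a tidy per-farm table, the workhorse input of
#' [system_summaries()] and [build_design_matrix()].
#'
#' @param survey An [iaa_survey()].
#' @param composition A `food_composition`.
#' @param rda An [rda_set()].
#' @param price_book Optional precomputed [build_price_book()] output.
#' @param missing_composition Passed to [nutrient_productivity()].
#' @return Tibble with one row per farm: `farm_id`, `area_ha`,
#'   `economic_usd_per_ha`, `ae_<nutrient>` columns, and
#'   `ae_<nutrient>__<group>` columns for the three coarse groups.
#' @export
farm_productivity <- function(survey, composition, rda = rda_set(),
                              price_book = NULL,
                              missing_composition = "error") {
  if (is.null(price_book)) price_book <- build_price_book(survey)
  farms <- survey$farms
  h <- survey$harvests[survey$harvests$quantity_kg > 0, ]

  # economic: farm-level value from the price book, minus costs, per ha
  value <- stats::setNames(numeric(nrow(farms)), farms$farm_id)
  if (nrow(h) > 0L) {
    key_h <- paste(h$farm_id, h$food_code, sep = "\r")
    key_p <- paste(price_book$farm_id, price_book$food_code, sep = "\r")
    idx <- match(key_h, key_p)
    if (anyNA(idx)) {
      stop("price book has no entry for farm x food line(s): ",
           paste(utils::head(key_h[is.na(idx)], 5), collapse = "; "),
           call. = FALSE)
    }
    v <- rowsum(h$quantity_kg * price_book$unit_price_usd_kg[idx],
                h$farm_id)
    value[rownames(v)] <- v[, 1]
  }
  econ <- (value - farms$production_costs_usd) / farms$area_ha

  # nutrients: per-line AE contributions, grouped farm x coarse group
  ae_tot <- matrix(0, nrow(farms), 7,
                   dimnames = list(farms$farm_id, nutrient_names()))
  grp_levels <- c("aquatic", "rice", "vf")
  ae_grp <- matrix(0, nrow(farms), 21,
                   dimnames = list(farms$farm_id, NULL))
  colnames(ae_grp) <- paste0("ae_", rep(nutrient_names(), 3), "__",
                             rep(grp_levels, each = 7))
  if (nrow(h) > 0L) {
    dens <- nutrient_density_matrix(composition, h$food_code,
                                    on_missing = missing_composition)
    denom <- unclass(rda)[nutrient_names()] * 365
    area <- farms$area_ha[match(h$farm_id, farms$farm_id)]
    contrib <- sweep(dens * (h$quantity_kg / area), 2, denom, "/")
    known <- h$food_code %in% composition$food_code
    grp <- rep(NA_character_, nrow(h))
    grp[known] <- food_group(assign_subcategory(h$food_code[known],
                                                composition))
    tot <- rowsum(contrib, h$farm_id)
    ae_tot[rownames(tot), ] <- tot
    for (g in grp_levels) {
      sel <- which(grp == g)
      if (!length(sel)) next
      gm <- rowsum(contrib[sel, , drop = FALSE], h$farm_id[sel])
      cols <- paste0("ae_", nutrient_names(), "__", g)
      ae_grp[rownames(gm), cols] <- gm
    }
  }
  out <- tibble::tibble(
    farm_id = farms$farm_id, area_ha = farms$area_ha,
    economic_usd_per_ha = as.vector(econ)
  )
  colnames(ae_tot) <- paste0("ae_", nutrient_names())
  dplyr::bind_cols(out, tibble::as_tibble(ae_tot),
                   tibble::as_tibble(ae_grp))
}

# farm-level quantities, sales and value per coarse food group
farm_group_shares <- function(survey, composition, price_book = NULL) {
  h <- survey$harvests[survey$harvests$quantity_kg > 0, ]
  if (nrow(h) == 0L) {
    return(tibble::tibble(farm_id = character(), group = character(),
                          produced_kg = numeric(), sold_kg = numeric(),
                          value_usd = numeric(), share_sold = numeric()))
  }
  h$group <- food_group(assign_subcategory(h$food_code, composition))
  if (is.null(price_book)) price_book <- build_price_book(survey)
  idx <- match(paste(h$farm_id, h$food_code),
               paste(price_book$farm_id, price_book$food_code))
  h$value_usd <- h$quantity_kg * price_book$unit_price_usd_kg[idx]
  dplyr::summarise(
    dplyr::group_by(h, .data$farm_id, .data$group),
    produced_kg = sum(.data$quantity_kg),
    sold_kg = sum(.data$quantity_sold_kg),
    value_usd = sum(.data$value_usd),
    share_sold = .data$sold_kg / .data$produced_kg,
    .groups = "drop"
  )
}

#' Farming-system summaries
#'
#' Unweighted means over farms within each retained farming system of:
#' quantities produced per hectare and shares sold by coarse food group,
#' economic productivity, AEs per hectare per nutrient, and food-group
#' decompositions. Shares sold are computed per farm, then averaged across
#' farms (pooled totals are available via `share_sold_method = "pooled"`).
#'
#' @param survey An [iaa_survey()].
#' @param classified Output of [classify_farms()] (typically after
#'   [trim_small_systems()]).
#' @param composition A `food_composition`.
#' @param rda An [rda_set()].
#' @param productivity Optional precomputed [farm_productivity()] table.
#' @param share_sold_method `"farm_mean"` (default) or `"pooled"`.
#' @return List of tidy tibbles: `systems` (per-system means of economic and
#'   AE outcomes), `groups` (per-system by food-group quantities, shares
#'   sold, value and AE decompositions).
#' @export
system_summaries <- function(survey, classified, composition,
                             rda = rda_set(), productivity = NULL,
                             share_sold_method = c("farm_mean", "pooled")) {
  share_sold_method <- match.arg(share_sold_method)
  keep <- survey$farms$farm_id %in% classified$farm_id
  svy <- iaa_survey(
    survey$farms[keep, farm_csv_cols()],
    survey$harvests[survey$harvests$farm_id %in% classified$farm_id, ]
  )
  price_book <- build_price_book(survey)
  if (is.null(productivity)) {
    productivity <- farm_productivity(svy, composition, rda,
                                      price_book = price_book)
  } else {
    productivity <- productivity[productivity$farm_id %in%
                                   classified$farm_id, ]
  }
  prod <- dplyr::left_join(productivity,
                           classified[c("farm_id", "system")],
                           by = "farm_id")
  empty <- setdiff(unique(classified$system), prod$system)
  if (length(empty)) {
    warning("excluding empty farming system(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  systems <- dplyr::summarise(
    dplyr::group_by(prod, .data$system),
    n_farms = dplyr::n(),
    dplyr::across(dplyr::starts_with(c("economic_", "ae_")), mean),
    .groups = "drop"
  )

  # per-group physical quantities, gross value and shares sold
  shares <- farm_group_shares(svy, composition, price_book)
  shares <- dplyr::left_join(shares, classified[c("farm_id", "system")],
                             by = "farm_id")
  areas <- svy$farms[c("farm_id", "area_ha")]
  shares <- dplyr::left_join(shares, areas, by = "farm_id")
  shares$kg_per_ha <- shares$produced_kg / shares$area_ha
  shares$usd_per_ha <- shares$value_usd / shares$area_ha
  groups <- dplyr::summarise(
    dplyr::group_by(shares, .data$system, .data$group),
    n_farms_producing = dplyr::n(),
    mean_kg_per_ha = mean(.data$kg_per_ha),
    mean_usd_per_ha = mean(.data$usd_per_ha),
    share_sold = if (share_sold_method == "farm_mean") {
      mean(.data$share_sold)
    } else {
      sum(.data$sold_kg) / sum(.data$produced_kg)
    },
    .groups = "drop"
  )
  list(systems = systems, groups = groups)
}
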