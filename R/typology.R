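# Farming-system typology: the 4 x 4 grid of aquatic species combination
# (F, FP, FPS, FS) by terrestrial integration (none, rice, vf, rice_vf),
# the sample contingency table, and the small-cell trimming rule.

#' Levels of the farming-system axes
#'
#' Aquatic: `F` (fish only), `FP` (fish and prawn), `FPS` (fish, prawn and
#' shrimp), `FS` (fish and shrimp). Terrestrial: `none`, `rice`, `vf`
#' (vegetables and fruits), `rice_vf`.
#'
#' @param axis `"aquatic"` or `"terrestrial"`.
#' @return Character vector of levels in display order.
#' @export
system_levels <- function(axis = c("aquatic", "terrestrial")) {
  axis <- match.arg(axis)
  if (axis == "aquatic") c("F", "FP", "FPS", "FS")
  else c("none", "rice", "vf", "rice_vf")
}

# half-up integer rounding used for every reported percentage (R's round()
# is round-half-even, which would turn e.g. 16.5 into 16)
round_half_up <- function(x) floor(x + 0.5)

#' Classify farms into the farming-system grid
#'
#' The aquatic axis depends only on the presence of prawn and shrimp species
#' (crustacean entries flagged in the composition table) among foods with
#' positive quantity; finfish are present on every in-sample farm by the
#' sample frame. The terrestrial axis depends only on the presence of rice
#' and of vegetables/fruits. Classification is invariant to harvest-line
#' order and to splitting or merging lines of the same food.
#'
#' @param survey An [iaa_survey()].
#' @param composition A `food_composition`.
#' @return Tibble with one row per farm: `farm_id`, `aquatic`, `terrestrial`
#'   (factors over [system_levels()]), and `system` (their interaction,
#'   e.g. `"FP:rice_vf"`).
#' @export
classify_farms <- function(survey, composition) {
  h <- survey$harvests[survey$harvests$quantity_kg > 0, ]
  idx <- match(h$food_code, composition$food_code)
  if (anyNA(idx)) {
    stop("harvested food(s) absent from composition table: ",
         paste(unique(h$food_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  grp <- food_group(composition$subcategory[idx])
  cru <- composition$crustacean_type[idx]
  is_fin <- grp == "aquatic" & cru == ""

  agg <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(farm_id = h$farm_id, grp = grp, cru = cru,
                     fin = is_fin),
      .data$farm_id
    ),
    has_aquatic = any(.data$grp == "aquatic"),
    has_fin = any(.data$fin),
    has_prawn = any(.data$cru == "prawn"),
    has_shrimp = any(.data$cru == "shrimp"),
    has_rice = any(.data$grp == "rice"),
    has_vf = any(.data$grp == "vf"),
    .groups = "drop"
  )
  agg <- dplyr::left_join(tibble::tibble(farm_id = survey$farms$farm_id),
                          agg, by = "farm_id")
  agg[is.na(agg$has_aquatic), -1] <- FALSE
  if (any(!agg$has_aquatic)) {
    stop("farm(s) with no aquatic production are outside the sample frame: ",
         paste(utils::head(agg$farm_id[!agg$has_aquatic], 10),
               collapse = ", "), call. = FALSE)
  }
  no_fin <- !agg$has_fin
  if (any(no_fin)) {
    message("farm(s) with crustaceans but no finfish, classified by ",
            "crustacean presence alone: ",
            paste(utils::head(agg$farm_id[no_fin], 5), collapse = ", "))
  }
  aquatic <- dplyr::case_when(
    agg$has_prawn & agg$has_shrimp ~ "FPS",
    agg$has_prawn ~ "FP",
    agg$has_shrimp ~ "FS",
    TRUE ~ "F"
  )
  terrestrial <- dplyr::case_when(
    agg$has_rice & agg$has_vf ~ "rice_vf",
    agg$has_rice ~ "rice",
    agg$has_vf ~ "vf",
    TRUE ~ "none"
  )
  tibble::tibble(
    farm_id = agg$farm_id,
    aquatic = factor(aquatic, levels = system_levels("aquatic")),
    terrestrial = factor(terrestrial, levels = system_levels("terrestrial")),
    system = paste(aquatic, terrestrial, sep = ":")
  )
}

#' Tabulate classified farms into the 4 x 4 contingency table
#'
#' @param classified Output of [classify_farms()].
#' @return An integer matrix, rows = terrestrial integration, columns =
#'   aquatic combination, with class `system_table`.
#' @export
contingency_table <- function(classified) {
  tab <- table(terrestrial = classified$terrestrial,
               aquatic = classified$aquatic)
  tab <- unclass(tab)[system_levels("terrestrial"), system_levels("aquatic")]
  structure(tab, class = c("system_table", "matrix"))
}

#' @export
print.system_table <- function(x, ...) {
  m <- unclass(x)
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  cat("Sample distribution by farming system (terrestrial x aquatic):\n")
  print(m)
  invisible(x)
}

#' Exclude farms in small farming-system cells
#'
#' Drops every farm belonging to a cell of the contingency table with
#' `max_excluded_cell_size` or fewer observations, the rule used to restrict
#' the main analysis sample.
#'
#' @param classified Output of [classify_farms()].
#' @param max_excluded_cell_size Cells with counts at or below this are
#'   excluded (default 12).
#' @return List with `retained` (classified subset), `excluded_cells`
#'   (tibble of dropped cells with counts) and `n_retained`.
#' @export
trim_small_systems <- function(classified, max_excluded_cell_size = 12) {
  tab <- contingency_table(classified)
  small <- which(unclass(tab) <= max_excluded_cell_size, arr.ind = TRUE,
                 useNames = FALSE)
  excluded <- tibble::tibble(
    terrestrial = rownames(tab)[small[, 1]],
    aquatic = colnames(tab)[small[, 2]],
    n = unclass(tab)[small]
  )
  drop_sys <- paste(excluded$aquatic, excluded$terrestrial, sep = ":")
  retained <- classified[!classified$system %in% drop_sys, ]
  list(retained = retained, excluded_cells = excluded,
       n_retained = nrow(retained))
}

#' Share of the sample in a set of cells
#'
#' Percentage of all farms falling in the cells selected by `predicate`,
#' rounded half-up to an integer (the convention used for reported sample
#' shares).
#'
#' @param tab A `system_table`.
#' @param predicate Function of `(aquatic, terrestrial)` level names
#'   returning `TRUE` for cells to include; vectorised over both.
#' @return Integer percentage.
#' @export
#' @examples
#' # share of farms growing only fish:
#' # share_of_sample(tab, function(aq, te) aq == "F")
share_of_sample <- function(tab, predicate) {
  m <- unclass(tab)
  total <- sum(m)
  if (total == 0) stop("empty contingency table", call. = FALSE)
  aq <- matrix(colnames(m), nrow(m), ncol(m), byrow = TRUE)
  te <- matrix(rownames(m), nrow(m), ncol(m))
  keep <- matrix(predicate(as.vector(aq), as.vector(te)), nrow(m), ncol(m))
  round_half_up(100 * sum(m[keep]) / total)
}

#' Integration rate of one aquatic combination
#'
#' Percentage of farms in one aquatic column whose terrestrial axis is not
#' `none`, rounded half-up.
#'
#' @param tab A `system_table`.
#' @param aquatic One of `system_levels("aquatic")`.
#' @return Integer percentage.
#' @export
integration_rate <- function(tab, aquatic) {
  aquatic <- match.arg(aquatic, system_levels("aquatic"))
  m <- unclass(tab)
  col_total <- sum(m[, aquatic])
  if (col_total == 0) stop("no farms in aquatic column ", aquatic,
                           call. = FALSE)
  round_half_up(100 * (col_total - m["none", aquatic]) / col_total)
}

#' Analytic sub-category of a food
#'
#' @param food_code Character vector of food codes.
#' @param composition A `food_composition`.
#' @return Character vector of sub-category labels.
#' @export
assign_subcategory <- function(food_code, composition) {
  idx <- match(food_code, composition$food_code)
  if (anyNA(idx)) {
    stop("unknown food(s): ",
         paste(unique(food_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  composition$subcategory[idx]
}
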