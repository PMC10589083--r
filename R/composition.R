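# Food-composition reference: edible portion, nutrient concentrations per
# 100 g edible portion, and the analytic sub-category of every food.

#' The twelve analytic food sub-categories
#'
#' Four aquatic groups (carp, other stocked fish, unstocked fish, crustaceans)
#' and eight terrestrial groups (rice, leafy vegetables, vitamin A-rich
#' vegetables, other vegetables, root crops, vitamin A-rich fruits, other
#' fruits, nuts/oilseeds). These are the regressor groups of the productivity
#' regressions and the resolution of all food-group decompositions.
#'
#' @param realm Optionally restrict to `"aquatic"` or `"terrestrial"`.
#' @return Character vector of sub-category labels.
#' @export
subcategories <- function(realm = c("all", "aquatic", "terrestrial")) {
  realm <- match.arg(realm)
  aq <- c("carp", "other_stocked_fish", "unstocked_fish", "crustaceans")
  te <- c("rice", "leafy_vegetables", "vitaminA_rich_vegetables",
          "other_vegetables", "root_crops", "vitaminA_rich_fruits",
          "other_fruits", "nuts_oilseeds")
  switch(realm, all = c(aq, te), aquatic = aq, terrestrial = te)
}

#' Coarse food groups used for figures and decompositions
#'
#' Maps each sub-category to one of three groups: `aquatic`, `rice`, or `vf`
#' (vegetables and fruits, i.e. all terrestrial foods other than rice).
#'
#' @param subcategory Character vector of sub-category labels.
#' @return Character vector of group labels.
#' @export
food_group <- function(subcategory) {
  out <- ifelse(subcategory %in% subcategories("aquatic"), "aquatic",
                ifelse(subcategory == "rice", "rice", "vf"))
  bad <- !subcategory %in% subcategories()
  if (any(bad)) {
    stop("unknown subcategory: ", paste(unique(subcategory[bad]),
                                        collapse = ", "), call. = FALSE)
  }
  out
}

comp_nutrient_cols <- function() paste0(nutrient_names(), "_100g")

comp_csv_cols <- function() {
  c("food_code", "food_name", "realm", "subcategory", "edible_portion",
    "energy_kj_100g", "protein_g_100g", "calcium_mg_100g", "iron_mg_100g",
    "zinc_mg_100g", "vita_ug_rae_100g", "vitb12_100g")
}

# csv header -> internal per-100g column names
comp_csv_to_internal <- function() {
  stats::setNames(
    comp_nutrient_cols(),
    c("energy_kj_100g", "protein_g_100g", "calcium_mg_100g", "iron_mg_100g",
      "zinc_mg_100g", "vita_ug_rae_100g", "vitb12_100g")
  )
}

validate_composition <- function(comp) {
  stopifnot(is.data.frame(comp))
  if (anyDuplicated(comp$food_code)) {
    dups <- unique(comp$food_code[duplicated(comp$food_code)])
    stop("duplicate food_code: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  if (any(comp$edible_portion < 0 | comp$edible_portion > 1)) {
    bad <- comp$food_code[comp$edible_portion < 0 | comp$edible_portion > 1]
    stop("edible_portion outside [0,1] for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(comp$realm %in% c("aquatic", "terrestrial"))) {
    stop("realm must be 'aquatic' or 'terrestrial'", call. = FALSE)
  }
  bad_sub <- setdiff(unique(comp$subcategory), subcategories())
  if (length(bad_sub)) {
    stop("unknown subcategory label(s): ", paste(bad_sub, collapse = ", "),
         "\nvalid labels: ", paste(subcategories(), collapse = ", "),
         call. = FALSE)
  }
  mism <- food_group(comp$subcategory) == "aquatic" &
    comp$realm != "aquatic" |
    food_group(comp$subcategory) != "aquatic" & comp$realm != "terrestrial"
  if (any(mism)) {
    stop("realm/subcategory mismatch for: ",
         paste(comp$food_code[mism], collapse = ", "), call. = FALSE)
  }
  nut <- as.matrix(comp[comp_nutrient_cols()])
  if (anyNA(nut) || any(nut < 0)) {
    stop("nutrient concentrations must be non-missing and >= 0",
         call. = FALSE)
  }
  # crustacean prawn/shrimp membership is a data attribute, not a name list
  cru <- comp$subcategory == "crustaceans"
  if (any(cru & !comp$crustacean_type %in% c("prawn", "shrimp"))) {
    stop("crustacean entries need crustacean_type 'prawn' or 'shrimp': ",
         paste(comp$food_code[cru & !comp$crustacean_type %in%
                                c("prawn", "shrimp")], collapse = ", "),
         call. = FALSE)
  }
  if (any(!cru & comp$crustacean_type != "")) {
    stop("crustacean_type only applies to crustacean entries", call. = FALSE)
  }
  # B12 comes from animal-source foods only; a plant food with positive B12
  # is suspect but not fatal
  b12_plant <- comp$realm == "terrestrial" & comp$vitamin_b12_100g > 0
  if (any(b12_plant)) {
    warning("terrestrial food(s) with non-zero vitamin B12: ",
            paste(comp$food_code[b12_plant], collapse = ", "),
            call. = FALSE)
  }
  invisible(comp)
}

new_composition <- function(df) {
  comp <- tibble::as_tibble(df)
  if (!"crustacean_type" %in% names(comp)) comp$crustacean_type <- ""
  comp$crustacean_type[is.na(comp$crustacean_type)] <- ""
  validate_composition(comp)
  class(comp) <- c("food_composition", class(comp))
  comp
}

#' Load a food-composition table from CSV
#'
#' The CSV schema is
#' `food_code,food_name,realm,subcategory,edible_portion,energy_kj_100g,`
#' `protein_g_100g,calcium_mg_100g,iron_mg_100g,zinc_mg_100g,`
#' `vita_ug_rae_100g,vitb12_100g` (UTF-8, dot decimal), with an optional
#' `crustacean_type` column (`prawn`/`shrimp`, required on crustacean
#' entries) that drives the aquatic farming-system classification.
#' Concentrations are per 100 g of edible portion, the food-composition-table
#' convention.
#'
#' Validation is strict: duplicate food codes, edible portions outside
#' \[0,1\], unknown sub-category labels and realm/sub-category mismatches are
#' hard errors. A terrestrial food with non-zero vitamin B12 loads with a
#' warning (B12 occurs only in animal-source foods).
#'
#' @param source Path to a composition CSV.
#' @return A `food_composition` tibble keyed by `food_code`.
#' @seealso [default_composition()] for the packaged reference,
#'   [nutrient_yield()] for the yield arithmetic.
#' @export
load_composition_table <- function(source) {
  raw <- readr::read_csv(source, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(comp_csv_cols(), names(raw))
  if (length(missing_cols)) {
    stop("composition CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(comp_csv_cols(),
                      c("food_code", "food_name", "realm", "subcategory"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    if (anyNA(v) & !anyNA(raw[[cl]])) {
      stop("non-numeric value in column ", cl, call. = FALSE)
    }
    raw[[cl]] <- v
  }
  ren <- comp_csv_to_internal()
  names(raw)[match(names(ren), names(raw))] <- unname(ren)
  new_composition(raw)
}

#' Write a composition table to CSV
#'
#' Inverse of [load_composition_table()]; `load(write(x))` reproduces `x`.
#'
#' @param comp A `food_composition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(comp, path) {
  out <- tibble::as_tibble(comp)
  ren <- comp_csv_to_internal()
  names(out)[match(unname(ren), names(out))] <- names(ren)
  out <- out[c(comp_csv_cols(), "crustacean_type")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Packaged synthetic composition reference
#'
#' A 36-food composition table covering all twelve sub-categories, with
#' edible portions and nutrient densities chosen as plausible for southern
#' Bangladesh pond polyculture and homestead horticulture. The values are
#' synthetic illustrations patterned on public food-composition references,
#' not reproductions of any published table; vitamin B12 is zero for every
#' terrestrial food.
#'
#' @return A `food_composition` tibble.
#' @export
#' @examples
#' comp <- default_composition()
#' table(comp$subcategory)
default_composition <- function() {
  load_composition_table(
    system.file("extdata", "composition_synthetic.csv", package = "nutriprod",
                mustWork = TRUE)
  )
}

#' Nutrients obtained from a harvested quantity of one food
#'
#' Multiplies the as-produced (whole, wet) weight by the food's edible
#' portion and nutrient concentrations. Concentrations are stored per 100 g
#' edible, so per kg of edible portion the factor is 10:
#' `yield = quantity_kg * edible_portion * 10 * concentration_100g`.
#' The result is homogeneous of degree 1 in `quantity_kg`.
#'
#' @param entry One row of a `food_composition` (or a one-row subset).
#' @param quantity_kg Whole-product quantity in kg, `>= 0`.
#' @return A nutrient vector (see [nutrient_vector()]).
#' @export
#' @examples
#' comp <- default_composition()
#' nutrient_yield(comp[comp$food_code == "mola", ], 25)
nutrient_yield <- function(entry, quantity_kg) {
  entry <- tibble::as_tibble(entry)
  if (nrow(entry) != 1L) stop("entry must be a single food", call. = FALSE)
  if (!is.numeric(quantity_kg) || is.na(quantity_kg) || quantity_kg < 0) {
    stop("quantity_kg must be a non-negative number", call. = FALSE)
  }
  conc <- unlist(entry[comp_nutrient_cols()])
  names(conc) <- nutrient_names()
  conc * 10 * entry$edible_portion * quantity_kg
}

# Vectorised internal form: per-kg-of-product nutrient content for a set of
# food codes, as a codes x nutrients matrix. Missing codes follow `on_missing`.
nutrient_density_matrix <- function(comp, codes,
                                    on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  idx <- match(codes, comp$food_code)
  if (anyNA(idx)) {
    missing <- unique(codes[is.na(idx)])
    if (on_missing == "error") {
      stop("no composition entry for food(s): ",
           paste(missing, collapse = ", "),
           " (set missing_composition = 'skip' to drop them with a warning)",
           call. = FALSE)
    }
    warning("skipping food(s) with no composition entry: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(comp[idx, comp_nutrient_cols()]) * 10 *
    comp$edible_portion[idx]
  m[is.na(idx), ] <- 0
  colnames(m) <- nutrient_names()
  rownames(m) <- codes
  m
}
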