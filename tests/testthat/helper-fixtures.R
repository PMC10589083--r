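# In-code fixtures shared across test files.

# 20-food toy composition covering all 12 sub-categories
toy_composition <- function() {
  df <- tibble::tribble(
    ~food_code, ~realm, ~subcategory, ~edible_portion,
    ~energy_100g, ~protein_100g, ~calcium_100g, ~iron_100g, ~zinc_100g,
    ~vitamin_a_100g, ~vitamin_b12_100g, ~crustacean_type,
    "carp1", "aquatic", "carp", 0.6, 450, 17, 300, 1.0, 1.3, 25, 3.0, "",
    "carp2", "aquatic", "carp", 0.62, 420, 16, 280, 0.9, 1.2, 22, 2.5, "",
    "fish1", "aquatic", "other_stocked_fish", 0.55, 400, 18, 50, 0.7, 0.9,
    12, 1.5, "",
    "fish2", "aquatic", "other_stocked_fish", 0.6, 500, 16, 30, 0.6, 0.8,
    10, 1.0, "",
    "small1", "aquatic", "unstocked_fish", 0.85, 430, 17, 850, 5.7, 3.2,
    1960, 8.5, "",
    "small2", "aquatic", "unstocked_fish", 0.8, 450, 18, 450, 4.9, 2.9,
    95, 7.0, "",
    "prawn1", "aquatic", "crustaceans", 0.45, 370, 19, 210, 1.8, 1.6,
    15, 1.2, "prawn",
    "shrimp1", "aquatic", "crustaceans", 0.5, 360, 19.5, 145, 1.5, 1.4,
    12, 1.1, "shrimp",
    "rice", "terrestrial", "rice", 0.95, 1460, 7.5, 12, 1.1, 1.6, 0, 0, "",
    "leafy1", "terrestrial", "leafy_vegetables", 0.78, 180, 3.5, 230, 5.0,
    0.9, 720, 0, "",
    "leafy2", "terrestrial", "leafy_vegetables", 0.72, 120, 2.8, 110, 3.2,
    0.7, 480, 0, "",
    "pumpkin", "terrestrial", "vitaminA_rich_vegetables", 0.74, 140, 1.1,
    22, 0.6, 0.3, 410, 0, "",
    "okra", "terrestrial", "other_vegetables", 0.86, 140, 1.9, 82, 0.7,
    0.6, 19, 0, "",
    "gourd", "terrestrial", "other_vegetables", 0.77, 60, 0.6, 24, 0.3,
    0.2, 8, 0, "",
    "potato", "terrestrial", "root_crops", 0.82, 320, 2.0, 10, 0.8, 0.4,
    1, 0, "",
    "taro", "terrestrial", "root_crops", 0.8, 470, 1.5, 43, 0.7, 0.3,
    4, 0, "",
    "mango", "terrestrial", "vitaminA_rich_fruits", 0.69, 270, 0.8, 11,
    0.2, 0.1, 54, 0, "",
    "banana", "terrestrial", "other_fruits", 0.64, 370, 1.1, 5, 0.3, 0.2,
    3, 0, "",
    "guava", "terrestrial", "other_fruits", 0.95, 285, 2.6, 18, 0.3, 0.2,
    31, 0, "",
    "sesame", "terrestrial", "nuts_oilseeds", 0.96, 2390, 18, 975, 14.6,
    7.8, 3, 0, ""
  )
  df$food_name <- df$food_code
  nutriprod:::new_composition(df)
}

# write a composition to CSV and return the path
toy_composition_csv <- function(comp = toy_composition(),
                                path = withr::local_tempfile(
                                  fileext = ".csv",
                                  .local_envir = parent.frame())) {
  write_composition_table(comp, path)
  path
}

# minimal farm row
toy_farm <- function(farm_id = "f1", upazila_id = "u01", land_ha = 0.4,
                     pond_ha = 0.4, production_costs_usd = 0) {
  tibble::tibble(
    farm_id = farm_id, upazila_id = upazila_id, land_ha = land_ha,
    pond_ha = pond_ha, head_age = 45, head_education = 5, head_female = 0,
    n_members = 4, dependency_ratio = 0.8, off_farm_income = 0,
    travel_time_city = 60, production_costs_usd = production_costs_usd
  )
}

# harvest line(s)
toy_harvest <- function(farm_id, food_code, quantity_kg,
                        quantity_sold_kg = 0, sales_value_usd = 0) {
  tibble::tibble(
    farm_id = farm_id, food_code = food_code, quantity_kg = quantity_kg,
    quantity_sold_kg = quantity_sold_kg, sales_value_usd = sales_value_usd
  )
}

demo_survey <- function() {
  load_survey(
    system.file("extdata", "farms_demo.csv", package = "nutriprod"),
    system.file("extdata", "harvests_demo.csv", package = "nutriprod"),
    quiet = TRUE
  )
}
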