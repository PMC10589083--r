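test_that("economic productivity matches hand arithmetic", {
  # 1 ha farm, 500 kg prawn at 4 $/kg, costs $600 -> 1,400 $/ha
  farm <- toy_farm("f1", land_ha = 0.5, pond_ha = 0.5,
                   production_costs_usd = 600)
  h <- toy_harvest("f1", "prawn1", 500, 250, 250 * 4)
  svy <- iaa_survey(farm, h)
  pb <- build_price_book(svy)
  farm$area_ha <- 1
  expect_equal(economic_productivity(farm, h, pb), 1400)

  # no production and no costs -> 0
  empty_farm <- toy_farm("f1")
  empty_farm$area_ha <- 0.8
  expect_equal(
    economic_productivity(empty_farm, toy_harvest(character(), character(),
                                                  numeric()),
                          pb[0, ]),
    0
  )

  # doubling area with quantities and costs fixed halves the result
  farm2 <- farm
  farm2$area_ha <- 2
  expect_equal(economic_productivity(farm2, h, pb), 700)

  # negative gross margins pass through untruncated
  dear <- farm
  dear$production_costs_usd <- 5000
  expect_lt(economic_productivity(dear, h, pb), 0)
})

test_that("annual adult equivalents follow the RDA-year definition", {
  rda <- rda_set()
  # an amount equal to RDA x 365 supports exactly one adult for a year
  full_year <- nutrient_vector(
    energy = 9200 * 365, protein = 55 * 365, calcium = 1000 * 365,
    iron = 13 * 365, zinc = 10 * 365, vitamin_a = 900 * 365,
    vitamin_b12 = 2.5 * 365
  )
  expect_equal(unname(annual_adult_equivalents(full_year, rda)), rep(1, 7))
  expect_equal(unname(annual_adult_equivalents(nutrient_vector(), rda)),
               rep(0, 7))
  # 7.39e7 kJ/ha over a year at 9,200 kJ/day feeds ~22 adults
  expect_equal(
    annual_adult_equivalents(nutrient_vector(energy = 7.39e7),
                             rda)[["energy"]],
    7.39e7 / (9200 * 365)
  )
  expect_equal(round(7.39e7 / (9200 * 365)), 22)
  expect_error(annual_adult_equivalents(full_year, unclass(rda) * 0))
})

test_that("AEs are linear in quantities and inverse in the RDA", {
  comp <- toy_composition()
  set.seed(21)
  for (k in 1:100) {
    farm <- toy_farm()
    farm$area_ha <- runif(1, 0.2, 3)
    foods <- sample(comp$food_code, sample(3:8, 1))
    h <- toy_harvest("f1", foods, runif(length(foods), 1, 2000))
    s <- runif(1, 0.1, 10)
    rda <- rda_set()
    base <- nutrient_productivity(farm, h, comp, rda)
    # linearity in quantities
    h2 <- h
    h2$quantity_kg <- s * h$quantity_kg
    scaled <- nutrient_productivity(farm, h2, comp, rda)
    expect_equal(scaled$total, s * base$total, tolerance = 1e-12)
    # halving one RDA exactly doubles that nutrient's AEs
    nut <- sample(nutrient_names(), 1)
    args <- as.list(unclass(rda)[nutrient_names()])
    args[[nut]] <- args[[nut]] / 2
    halved <- nutrient_productivity(farm, h, comp, do.call(rda_set, args))
    expect_equal(halved$total[[nut]], 2 * base$total[[nut]],
                 tolerance = 1e-12)
  }
})

test_that("group decompositions sum to farm totals", {
  comp <- toy_composition()
  set.seed(22)
  for (k in 1:100) {
    farm <- toy_farm()
    farm$area_ha <- runif(1, 0.2, 3)
    foods <- sample(comp$food_code, sample(5:15, 1))
    h <- toy_harvest("f1", foods, runif(length(foods), 1, 3000))
    np <- nutrient_productivity(farm, h, comp)
    expect_equal(colSums(np$by_group), np$total, tolerance = 1e-9)
    expect_equal(colSums(np$by_subcategory), np$total, tolerance = 1e-9)
  }
})

test_that("plant-only farms produce zero vitamin B12", {
  comp <- toy_composition()
  farm <- toy_farm()
  farm$area_ha <- 0.8
  set.seed(23)
  terrestrial <- comp$food_code[comp$realm == "terrestrial"]
  for (k in 1:100) {
    foods <- sample(terrestrial, sample(1:6, 1))
    h <- toy_harvest("f1", foods, runif(length(foods), 1, 2000))
    np <- nutrient_productivity(farm, h, comp)
    expect_equal(np$total[["vitamin_b12"]], 0)
    expect_gt(np$total[["energy"]], 0)
  }
})

test_that("per-ha metrics are invariant to common scaling of the farm", {
  comp <- toy_composition()
  set.seed(24)
  for (k in 1:100) {
    c_ <- runif(1, 0.3, 5)
    farm <- toy_farm(production_costs_usd = runif(1, 0, 500))
    farm$area_ha <- runif(1, 0.3, 2)
    foods <- sample(comp$food_code, 4)
    q <- runif(4, 10, 1000)
    h <- toy_harvest("f1", foods, q, 0.5 * q, 0.5 * q * runif(4, 0.2, 3))
    svy <- iaa_survey(toy_farm(production_costs_usd =
                                 farm$production_costs_usd), h)
    pb <- build_price_book(svy)
    base_econ <- economic_productivity(farm, h, pb)
    base_np <- nutrient_productivity(farm, h, comp)

    farm2 <- farm
    farm2$area_ha <- c_ * farm$area_ha
    farm2$production_costs_usd <- c_ * farm$production_costs_usd
    h2 <- h
    h2$quantity_kg <- c_ * h$quantity_kg
    h2$quantity_sold_kg <- c_ * h$quantity_sold_kg
    h2$sales_value_usd <- c_ * h$sales_value_usd
    expect_equal(economic_productivity(farm2, h2, pb), base_econ,
                 tolerance = 1e-12)
    expect_equal(nutrient_productivity(farm2, h2, comp)$total, base_np$total,
                 tolerance = 1e-12)
  }
})

test_that("identical farms yield identical results", {
  comp <- toy_composition()
  farm_a <- toy_farm("a")
  farm_b <- toy_farm("b")
  farm_a$area_ha <- farm_b$area_ha <- 0.8
  h <- dplyr::bind_rows(toy_harvest("a", c("carp1", "rice"), c(100, 500)),
                        toy_harvest("b", c("carp1", "rice"), c(100, 500)))
  np_a <- nutrient_productivity(farm_a, h, comp)
  np_b <- nutrient_productivity(farm_b, h, comp)
  expect_identical(np_a$total, np_b$total)
})

test_that("merging farms gives the area-weighted mean of per-ha AEs", {
  comp <- toy_composition()
  set.seed(25)
  for (k in 1:25) {
    a1 <- runif(1, 0.3, 2)
    a2 <- runif(1, 0.3, 2)
    f1 <- toy_farm("m1"); f1$area_ha <- a1
    f2 <- toy_farm("m2"); f2$area_ha <- a2
    h1 <- toy_harvest("m1", sample(comp$food_code, 3), runif(3, 10, 500))
    h2 <- toy_harvest("m2", sample(comp$food_code, 3), runif(3, 10, 500))
    np1 <- nutrient_productivity(f1, h1, comp)$total
    np2 <- nutrient_productivity(f2, h2, comp)$total

    merged_farm <- toy_farm("mm")
    merged_farm$area_ha <- a1 + a2
    hm <- dplyr::bind_rows(h1, h2)
    hm$farm_id <- "mm"
    npm <- nutrient_productivity(merged_farm, hm, comp)$total
    expect_equal(npm, (a1 * np1 + a2 * np2) / (a1 + a2), tolerance = 1e-12)
  }
})

test_that("vectorised economics equal a line-by-line oracle on 100 farms", {
  gen <- generate_survey(generator_config(n_farms = 100), seed = 28)
  svy <- gen$survey
  pb <- build_price_book(svy)
  prod <- farm_productivity(svy, default_composition(), price_book = pb)
  price_of <- function(fid, code) {
    pb$unit_price_usd_kg[pb$farm_id == fid & pb$food_code == code]
  }
  for (i in seq_len(nrow(svy$farms))) {
    farm <- svy$farms[i, ]
    h <- svy$harvests[svy$harvests$farm_id == farm$farm_id, ]
    value <- 0
    for (j in seq_len(nrow(h))) {       # explicit brute-force loop
      value <- value + h$quantity_kg[j] * price_of(farm$farm_id,
                                                   h$food_code[j])
    }
    oracle <- (value - farm$production_costs_usd) / farm$area_ha
    expect_equal(prod$economic_usd_per_ha[i], oracle, tolerance = 1e-9)
  }
})

test_that("system summaries average farm-level outcomes within system", {
  comp <- default_composition()
  gen <- generate_survey(generator_config(n_farms = 200), seed = 8)
  svy <- gen$survey
  cl <- classify_farms(svy, comp)
  summ <- system_summaries(svy, cl, comp)
  expect_true(all(summ$systems$n_farms >= 1))
  expect_equal(sum(summ$systems$n_farms), 200)

  # a single-farm system's summary equals that farm's values
  prod <- farm_productivity(svy, comp)
  singles <- summ$systems[summ$systems$n_farms == 1, ]
  if (nrow(singles) > 0) {
    s <- singles$system[1]
    fid <- cl$farm_id[cl$system == s]
    expect_equal(singles$economic_usd_per_ha[1],
                 prod$economic_usd_per_ha[prod$farm_id == fid])
  }

  # all-sold farms report a 100% share sold
  farm <- toy_farm()
  h <- toy_harvest("f1", c("catla", "rice"), c(100, 200), c(100, 200),
                   c(150, 60))
  svy1 <- iaa_survey(farm, h)
  cl1 <- classify_farms(svy1, comp)
  summ1 <- system_summaries(svy1, cl1, comp)
  expect_equal(summ1$groups$share_sold, c(1, 1))
})
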