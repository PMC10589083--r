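# Structural synthetic-survey generator. Farms are assigned to the 4 x 4
# farming-system grid at the reference sample frequencies, then harvests,
# prices, covariates and costs are drawn so that economic productivity
# follows a known linear model in the sub-category yields (the generator's
# ground truth), while nutrient outcomes arise structurally from the
# composition table. Everything downstream of the master seed is
# reproducible; each farm draws from its own substream.

#' Reference sample distribution by farming system
#'
#' The 721-farm contingency table (terrestrial integration by aquatic
#' combination) that the generator's default cell probabilities reproduce.
#'
#' @return 4 x 4 integer matrix with dimnames over [system_levels()].
#' @export
table1_counts <- function() {
  m <- matrix(
    c(184, 32, 135, 52,
      16, 33, 29, 8,
      68, 31, 12, 1,
      16, 69, 35, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(terrestrial = system_levels("terrestrial"),
                    aquatic = system_levels("aquatic"))
  )
  storage.mode(m) <- "integer"
  m
}

#' Generator configuration
#'
#' Study-condition defaults: 721 farms distributed over the farming-system
#' grid at the reference frequencies; mean total farm (sample-parcel) size
#' 0.78 ha; roughly nine aquatic products per farm and 3.5 vegetable/fruit
#' types per producing farm; mean shares sold 0.71 (aquatic), 0.57
#' (vegetables and fruits) and 0.33 (rice). Economic ground truth: the true
#' coefficient of each sub-category yield (t/ha) on economic productivity is
#' 1000 x the sub-category base price (US$/kg); household controls and
#' upazila fixed effects enter through the per-ha cost equation with
#' Gaussian noise `cost_sigma`.
#'
#' @param n_farms Number of farms.
#' @param cell_probs 4 x 4 matrix of farming-system probabilities (rows =
#'   terrestrial, cols = aquatic); default `table1_counts() / 721`.
#' @param sample_cells If `FALSE` (default) cell counts are allocated
#'   deterministically by largest remainder of `n_farms * cell_probs` (at
#'   `n_farms = 721` this reproduces the reference table exactly); if `TRUE`
#'   they are drawn multinomially.
#' @param n_upazilas Number of subdistricts (fixed-effect levels).
#' @param mean_farm_ha,farm_size_sdlog Log-normal farm-size distribution
#'   (mean on the natural scale, log-scale sd).
#' @param yield_median_t_ha Named per-sub-category median per-food yield in
#'   t/ha (log-normal).
#' @param yield_sdlog Log-scale sd of per-food yields.
#' @param base_price_usd_kg Named per-sub-category unit price, US$/kg.
#' @param price_food_sdlog Log-scale sd of fixed per-food price multipliers
#'   (mean-one log-normal); 0 makes every food in a group share the group
#'   price, so the economic ground truth is exact.
#' @param price_obs_sdlog Log-scale sd of farm-level multiplicative noise on
#'   observed sale prices.
#' @param sell_prob Named per-group probability that a produced food is sold
#'   at all.
#' @param share_sold_mean Named per-group target mean share sold (including
#'   non-sellers); the Beta mean among sellers is `share_sold_mean /
#'   sell_prob`.
#' @param share_sold_conc Beta concentration of seller shares.
#' @param cost_intercept US$/ha baseline of the cost equation.
#' @param cost_gamma Named control-variable coefficients of the per-ha cost
#'   equation (their negatives are the true control coefficients on
#'   economic productivity).
#' @param cost_fe_sd SD of the upazila cost offsets (US$/ha).
#' @param cost_sigma SD of the idiosyncratic per-ha cost noise (US$/ha),
#'   the regression error of the economic ground-truth model.
#' @param composition The `food_composition` the foods are drawn from.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_farms = 721,
    cell_probs = table1_counts() / 721,
    sample_cells = FALSE,
    n_upazilas = 12,
    mean_farm_ha = 0.78,
    farm_size_sdlog = 0.6,
    yield_median_t_ha = c(
      carp = 0.35, other_stocked_fish = 0.3, unstocked_fish = 0.05,
      crustaceans = 0.18, rice = 4.0, leafy_vegetables = 0.2,
      vitaminA_rich_vegetables = 0.3, other_vegetables = 0.35,
      root_crops = 0.35, vitaminA_rich_fruits = 0.3, other_fruits = 0.3,
      nuts_oilseeds = 0.15
    ),
    yield_sdlog = 0.5,
    base_price_usd_kg = c(
      carp = 1.4, other_stocked_fish = 1.0, unstocked_fish = 1.5,
      crustaceans = 4.0, rice = 0.3, leafy_vegetables = 0.4,
      vitaminA_rich_vegetables = 0.35, other_vegetables = 0.45,
      root_crops = 0.3, vitaminA_rich_fruits = 0.6, other_fruits = 0.5,
      nuts_oilseeds = 1.2
    ),
    price_food_sdlog = 0.15,
    price_obs_sdlog = 0.05,
    sell_prob = c(aquatic = 0.9, vf = 0.75, rice = 0.65),
    share_sold_mean = c(aquatic = 0.71, vf = 0.57, rice = 0.33),
    share_sold_conc = 8,
    cost_intercept = 1500,
    cost_gamma = c(
      head_age = 2, head_education = 8, head_female = 30, n_members = 15,
      dependency_ratio = 40, off_farm_income = -60, travel_time_city = 0.5,
      land_ha = 50, pond_ha = 80
    ),
    cost_fe_sd = 150,
    cost_sigma = 300,
    composition = default_composition()) {
  cfg <- list(
    n_farms = n_farms, cell_probs = cell_probs, sample_cells = sample_cells,
    n_upazilas = n_upazilas, mean_farm_ha = mean_farm_ha,
    farm_size_sdlog = farm_size_sdlog,
    yield_median_t_ha = yield_median_t_ha, yield_sdlog = yield_sdlog,
    base_price_usd_kg = base_price_usd_kg,
    price_food_sdlog = price_food_sdlog,
    price_obs_sdlog = price_obs_sdlog,
    sell_prob = sell_prob, share_sold_mean = share_sold_mean,
    share_sold_conc = share_sold_conc, cost_intercept = cost_intercept,
    cost_gamma = cost_gamma, cost_fe_sd = cost_fe_sd,
    cost_sigma = cost_sigma, composition = composition
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_farms < 1) stop("n_farms must be >= 1", call. = FALSE)
  if (!isTRUE(all.equal(sum(cfg$cell_probs), 1)) ||
      any(cfg$cell_probs < 0)) {
    stop("cell_probs must be non-negative and sum to 1", call. = FALSE)
  }
  if (!identical(dim(cfg$cell_probs), c(4L, 4L))) {
    stop("cell_probs must be 4 x 4 (terrestrial x aquatic)", call. = FALSE)
  }
  pos <- c("mean_farm_ha", "farm_size_sdlog", "yield_sdlog",
           "share_sold_conc", "cost_sigma")
  for (p in pos) {
    if (cfg[[p]] <= 0) stop(p, " must be > 0", call. = FALSE)
  }
  if (any(cfg$yield_median_t_ha <= 0) || any(cfg$base_price_usd_kg <= 0)) {
    stop("yield medians and base prices must be > 0", call. = FALSE)
  }
  miss <- setdiff(subcategories(),
                  intersect(names(cfg$yield_median_t_ha),
                            names(cfg$base_price_usd_kg)))
  if (length(miss)) {
    stop("missing yield/price parameters for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$share_sold_mean >= cfg$sell_prob[names(cfg$share_sold_mean)])) {
    stop("share_sold_mean must be < sell_prob per group", call. = FALSE)
  }
  if (cfg$n_upazilas < 1) stop("n_upazilas must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Configuration for parameter-recovery studies
#'
#' [generator_config()] with all price jitter switched off, so economic
#' productivity follows the ground-truth linear model exactly, with i.i.d.
#' Gaussian per-ha noise from the cost equation.
#'
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
recovery_config <- function(...) {
  generator_config(price_food_sdlog = 0, price_obs_sdlog = 0, ...)
}

# substream seed for farm i under master seed (kept below 2^31)
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 65537) %% 2147483647
}

# deterministic largest-remainder apportionment of n over probabilities
allocate_cells <- function(n, probs) {
  p <- as.vector(probs)
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    extra <- order(-frac, seq_along(p))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  matrix(base, nrow(probs), ncol(probs), dimnames = dimnames(probs))
}

# one farm's harvest food set, honouring the assigned farming system
draw_food_set <- function(aquatic, terrestrial, foods) {
  pick <- function(codes, k) {
    k <- min(k, length(codes))
    if (k <= 0) return(character())
    codes[sample.int(length(codes), k)]
  }
  set <- character()
  if (stats::runif(1) < 0.96) {
    set <- c(set, pick(foods$carp, 1 + stats::rbinom(1, 3, 0.6)))
  }
  if (stats::runif(1) < 0.82) {
    set <- c(set, pick(foods$other_stocked, 1 + stats::rbinom(1, 4, 0.55)))
  }
  if (stats::runif(1) < 0.83) {
    set <- c(set, pick(foods$unstocked, 1 + stats::rbinom(1, 3, 0.6)))
  }
  if (!length(set)) set <- pick(foods$carp, 1)  # fish always present
  if (aquatic %in% c("FP", "FPS")) set <- c(set, pick(foods$prawn, 1))
  if (aquatic %in% c("FS", "FPS")) {
    set <- c(set, pick(foods$shrimp, 1 + stats::rbinom(1, 1, 0.3)))
  }
  if (terrestrial %in% c("rice", "rice_vf")) set <- c(set, foods$rice)
  if (terrestrial %in% c("vf", "rice_vf")) {
    n_vf <- min(1 + stats::rpois(1, 2.5), length(foods$vf))
    set <- c(set, pick(foods$vf, n_vf))
  }
  unique(set)
}

#' Generate a synthetic survey
#'
#' Deterministic given `seed`; farm `i` draws from its own substream so the
#' realized farms do not depend on draws for other farms. Farming-system
#' constraints hold by construction (every farm has finfish; prawn/shrimp
#' and terrestrial foods appear exactly as the assigned cell requires).
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed.
#' @return List of class `synthetic_survey`: `survey` (an [iaa_survey()]),
#'   `assignment` (per-farm latent system), and `ground_truth` (true
#'   economic coefficients per yield regressor and control, upazila cost
#'   offsets, and the generating parameters).
#' @export
generate_survey <- function(config = generator_config(), seed = 1) {
  validate_generator_config(config)
  comp <- config$composition
  foods <- list(
    carp = comp$food_code[comp$subcategory == "carp"],
    other_stocked = comp$food_code[comp$subcategory == "other_stocked_fish"],
    unstocked = comp$food_code[comp$subcategory == "unstocked_fish"],
    prawn = comp$food_code[comp$crustacean_type == "prawn"],
    shrimp = comp$food_code[comp$crustacean_type == "shrimp"],
    rice = comp$food_code[comp$subcategory == "rice"],
    vf = comp$food_code[comp$realm == "terrestrial" &
                          comp$subcategory != "rice"]
  )
  if (!length(foods$prawn) || !length(foods$shrimp)) {
    stop("composition must contain prawn- and shrimp-flagged crustaceans",
         call. = FALSE)
  }
  sub_of <- stats::setNames(comp$subcategory, comp$food_code)
  grp_of <- stats::setNames(food_group(comp$subcategory), comp$food_code)

  # survey-level draws: fixed effects and per-food price levels
  set.seed(substream_seed(seed, 0))
  fe_offsets <- stats::rnorm(config$n_upazilas, 0, config$cost_fe_sd)
  names(fe_offsets) <- sprintf("u%02d", seq_len(config$n_upazilas))
  mult <- exp(stats::rnorm(nrow(comp), -config$price_food_sdlog^2 / 2,
                           config$price_food_sdlog))
  food_price <- config$base_price_usd_kg[comp$subcategory] * mult
  names(food_price) <- comp$food_code

  # cell layout: deterministic largest-remainder apportionment by default;
  # under sample_cells each farm draws its own cell (in its substream, so
  # earlier farms never depend on how many farms follow them)
  cells <- expand.grid(terrestrial = system_levels("terrestrial"),
                       aquatic = system_levels("aquatic"),
                       stringsAsFactors = FALSE)
  if (config$sample_cells) {
    cell_idx <- vapply(seq_len(config$n_farms), function(i) {
      set.seed((substream_seed(seed, i) + 1000003) %% 2147483647)
      sample.int(16L, 1L, prob = as.vector(config$cell_probs))
    }, 0L)
  } else {
    counts <- allocate_cells(config$n_farms, config$cell_probs)
    cell_idx <- rep(seq_len(16L), as.vector(counts))
  }
  assign_te <- cells$terrestrial[cell_idx]
  assign_aq <- cells$aquatic[cell_idx]

  meanlog_area <- log(config$mean_farm_ha) - config$farm_size_sdlog^2 / 2
  seller_mean <- config$share_sold_mean / config$sell_prob
  n <- config$n_farms
  fv <- list(upz = character(n), land = numeric(n), pond = numeric(n),
             age = numeric(n), edu = numeric(n), female = numeric(n),
             members = numeric(n), dep = numeric(n), off = numeric(n),
             travel = numeric(n), costs = numeric(n))
  h_codes <- vector("list", n)
  h_qty <- vector("list", n)
  h_sold <- vector("list", n)
  h_val <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    aq <- assign_aq[i]
    te <- assign_te[i]
    upz <- sprintf("u%02d", sample.int(config$n_upazilas, 1))
    area <- stats::rlnorm(1, meanlog_area, config$farm_size_sdlog)
    if (te == "none") {
      pond <- area
      land <- 0
    } else {
      pond_share <- stats::rbeta(1, 6, 4)
      pond <- area * pond_share
      land <- area - pond
    }
    codes <- draw_food_set(aq, te, foods)
    med <- config$yield_median_t_ha[sub_of[codes]]
    qty <- stats::rlnorm(length(codes), log(med * 1000 * area),
                         config$yield_sdlog)
    grp <- grp_of[codes]
    sells <- stats::runif(length(codes)) < config$sell_prob[grp]
    mu <- seller_mean[grp]
    share <- ifelse(
      sells,
      stats::rbeta(length(codes), mu * config$share_sold_conc,
                   (1 - mu) * config$share_sold_conc),
      0
    )
    sold <- qty * share
    price_farm <- food_price[codes] *
      exp(stats::rnorm(length(codes), -config$price_obs_sdlog^2 / 2,
                       config$price_obs_sdlog))
    x <- c(
      head_age = min(max(round(stats::rnorm(1, 46, 10)), 20), 90),
      head_education = min(stats::rpois(1, 4), 16),
      head_female = stats::rbinom(1, 1, 0.08),
      n_members = 1 + stats::rpois(1, 3.2),
      dependency_ratio = round(2 * stats::rbeta(1, 2, 3), 3),
      off_farm_income = stats::rbinom(1, 1, 0.45),
      travel_time_city = round(stats::rlnorm(1, log(60), 0.5), 1),
      land_ha = land, pond_ha = pond
    )
    cost_ha <- config$cost_intercept +
      sum(config$cost_gamma[names(config$cost_gamma)] *
            x[names(config$cost_gamma)]) +
      fe_offsets[upz] + stats::rnorm(1, 0, config$cost_sigma)
    fv$upz[i] <- upz
    fv$land[i] <- land
    fv$pond[i] <- pond
    fv$age[i] <- x[["head_age"]]
    fv$edu[i] <- x[["head_education"]]
    fv$female[i] <- x[["head_female"]]
    fv$members[i] <- x[["n_members"]]
    fv$dep[i] <- x[["dependency_ratio"]]
    fv$off[i] <- x[["off_farm_income"]]
    fv$travel[i] <- x[["travel_time_city"]]
    fv$costs[i] <- max(0, cost_ha) * area
    h_codes[[i]] <- codes
    h_qty[[i]] <- qty
    h_sold[[i]] <- sold
    h_val[[i]] <- sold * price_farm
  }
  fids <- sprintf("f%05d", seq_len(n))
  farms <- tibble::tibble(
    farm_id = fids, upazila_id = fv$upz, land_ha = fv$land,
    pond_ha = fv$pond, head_age = fv$age, head_education = fv$edu,
    head_female = fv$female, n_members = fv$members,
    dependency_ratio = fv$dep, off_farm_income = fv$off,
    travel_time_city = fv$travel, production_costs_usd = fv$costs
  )
  n_lines <- lengths(h_codes)
  harvests <- tibble::tibble(
    farm_id = rep(fids, n_lines),
    food_code = unlist(h_codes, use.names = FALSE),
    quantity_kg = unlist(h_qty, use.names = FALSE),
    quantity_sold_kg = unlist(h_sold, use.names = FALSE),
    sales_value_usd = unlist(h_val, use.names = FALSE)
  )
  svy <- iaa_survey(farms, harvests)

  beta_yield <- 1000 * config$base_price_usd_kg[subcategories()]
  names(beta_yield) <- paste0("yield_", subcategories())
  ground_truth <- list(
    seed = seed,
    beta_economic_yield = as.list(beta_yield),
    beta_economic_controls = as.list(-config$cost_gamma),
    economic_noise_sd = config$cost_sigma,
    upazila_cost_offsets = as.list(fe_offsets),
    exact_linear_model = config$price_food_sdlog == 0 &&
      config$price_obs_sdlog == 0,
    cell_counts = as.vector(tabulate(cell_idx, nbins = 16L)),
    food_prices_usd_kg = as.list(round(food_price, 6))
  )
  structure(
    list(survey = svy,
         assignment = tibble::tibble(farm_id = farms$farm_id,
                                     aquatic = assign_aq,
                                     terrestrial = assign_te),
         ground_truth = ground_truth),
    class = "synthetic_survey"
  )
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("<synthetic_survey>\n")
  print(x$survey)
  invisible(x)
}

#' Write a synthetic survey to disk
#'
#' Emits `farms.csv`, `harvests.csv` and `ground_truth.yaml` into `dir`.
#'
#' @param gen A `synthetic_survey` from [generate_survey()].
#' @param dir Output directory (created if needed).
#' @return Named vector of the three paths, invisibly.
#' @export
write_synthetic_survey <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    farms = file.path(dir, "farms.csv"),
    harvests = file.path(dir, "harvests.csv"),
    ground_truth = file.path(dir, "ground_truth.yaml")
  )
  write_survey(gen$survey, paths[["farms"]], paths[["harvests"]])
  yaml::write_yaml(gen$ground_truth, paths[["ground_truth"]])
  invisible(paths)
}

#' Deterministic fixture reproducing the reference contingency table
#'
#' Builds a minimal 721-farm survey whose classification tabulates
#' cell-for-cell to [table1_counts()]: every farm grows catla; prawn,
#' shrimp, rice and okra lines are added exactly as each cell requires.
#'
#' @return An [iaa_survey()].
#' @export
#' @examples
#' tab <- contingency_table(
#'   classify_farms(generate_table1_fixture(), default_composition())
#' )
generate_table1_fixture <- function() {
  counts <- table1_counts()
  cells <- expand.grid(terrestrial = system_levels("terrestrial"),
                       aquatic = system_levels("aquatic"),
                       stringsAsFactors = FALSE)
  te <- rep(cells$terrestrial, as.vector(counts))
  aq <- rep(cells$aquatic, as.vector(counts))
  n <- length(te)
  ids <- sprintf("t%04d", seq_len(n))
  farms <- tibble::tibble(
    farm_id = ids, upazila_id = "u01", land_ha = 0.4, pond_ha = 0.4,
    head_age = 45, head_education = 5, head_female = 0, n_members = 4,
    dependency_ratio = 0.8, off_farm_income = 0, travel_time_city = 60,
    production_costs_usd = 100
  )
  one <- function(fid, code) {
    tibble::tibble(farm_id = fid, food_code = code, quantity_kg = 100,
                   quantity_sold_kg = 50, sales_value_usd = 75)
  }
  hl <- list(one(ids, "catla"))
  hl <- c(hl, list(one(ids[aq %in% c("FP", "FPS")], "golda")))
  hl <- c(hl, list(one(ids[aq %in% c("FS", "FPS")], "bagda")))
  hl <- c(hl, list(one(ids[te %in% c("rice", "rice_vf")], "rice")))
  hl <- c(hl, list(one(ids[te %in% c("vf", "rice_vf")], "okra")))
  iaa_survey(farms, dplyr::bind_rows(hl))
}
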