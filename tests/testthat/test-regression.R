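# explicit normal-equations oracle used against the fitted models
ols_oracle <- function(X, y) {
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- unname(sqrt(diag(sigma2 * XtX_inv)))
  p <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
  list(beta = as.vector(beta), se = as.vector(se), p = as.vector(p))
}

test_that("a 5-point bivariate fit matches the normal-equations oracle", {
  d <- tibble::tibble(x = c(0, 1, 2, 3, 4), y = c(1.1, 1.9, 3.2, 3.8, 5.4))
  f <- ols_fit(d, "y", regressors = "x", fixed_effects = FALSE)
  X <- cbind(1, d$x)
  o <- ols_oracle(X, d$y)
  co <- f$coefficients
  expect_equal(co$estimate, o$beta, tolerance = 1e-10)
  expect_equal(co$std_error, o$se, tolerance = 1e-10)
  expect_equal(co$p_value, o$p, tolerance = 1e-10)
})

test_that("fits equal the oracle on random small instances", {
  set.seed(41)
  for (k in 1:50) {
    n <- sample(12:50, 1)
    p <- sample(1:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    y <- rnorm(n, X %*% runif(p, -2, 2), 1)
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- y
    f <- ols_fit(d, "y", regressors = colnames(X), fixed_effects = FALSE)
    o <- ols_oracle(cbind(1, X), y)
    expect_equal(f$coefficients$estimate, o$beta, tolerance = 1e-8)
    expect_equal(f$coefficients$std_error, o$se, tolerance = 1e-8)
  }
})

test_that("an exactly linear outcome gives R^2 = 1 and zero residuals", {
  d <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- 2 + 3 * d$x1 - d$x2
  # summary.lm flags the (intended) perfect fit
  f <- suppressWarnings(
    ols_fit(d, "y", regressors = c("x1", "x2"), fixed_effects = FALSE)
  )
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(stats::residuals(f$fit)), rep(0, 30),
               tolerance = 1e-10)
  expect_equal(f$coefficients$estimate, c(2, 3, -1), tolerance = 1e-10)
})

make_design <- function(n_farms = 400, seed = 6) {
  gen <- generate_survey(generator_config(n_farms = n_farms), seed = seed)
  comp <- default_composition()
  cl <- trim_small_systems(classify_farms(gen$survey, comp))$retained
  list(design = build_design_matrix(gen$survey, cl, comp), gen = gen)
}

test_that("design matrix has yields in t/ha and honours trimming", {
  comp <- default_composition()
  # unit check: 500 kg on 1 ha -> 0.5 t/ha
  farm <- toy_farm(land_ha = 0.5, pond_ha = 0.5)
  h <- toy_harvest("f1", "catla", 500, 250, 375)
  svy <- iaa_survey(farm, h)
  cl <- classify_farms(svy, comp)
  des <- build_design_matrix(svy, cl, comp)
  expect_equal(des$yield_carp, 0.5)
  # no terrestrial production -> zeros in all eight terrestrial columns
  terr <- paste0("yield_", subcategories("terrestrial"))
  expect_equal(unname(unlist(des[terr])), rep(0, 8))

  # full synthetic run at reference frequencies keeps 700 farms
  md <- make_design(721, seed = 1)
  expect_equal(nrow(md$design), 700)
})

test_that("row order does not change the estimates", {
  md <- make_design(300, seed = 9)
  f1 <- ols_fit(md$design, "economic_usd_per_ha")
  f2 <- ols_fit(md$design[sample.int(nrow(md$design)), ],
                "economic_usd_per_ha")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-9)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  md <- make_design(300, seed = 10)
  bad <- md$design
  bad$head_age <- bad$n_members
  expect_error(ols_fit(bad, "economic_usd_per_ha"), "collinear")
})

test_that("upazila fixed effects absorb within-upazila level shifts", {
  md <- make_design(400, seed = 12)
  design <- md$design
  f0 <- ols_fit(design, "economic_usd_per_ha")
  upz <- sort(unique(design$upazila_id))[3]  # a non-reference level
  shifted <- design
  shifted$economic_usd_per_ha <- shifted$economic_usd_per_ha +
    1000 * (shifted$upazila_id == upz)
  f1 <- ols_fit(shifted, "economic_usd_per_ha")
  keep <- !startsWith(f0$coefficients$term, "factor(upazila_id)")
  expect_equal(f1$coefficients$estimate[keep],
               f0$coefficients$estimate[keep], tolerance = 1e-8)
  dummy <- paste0("factor(upazila_id)", upz)
  i <- match(dummy, f0$coefficients$term)
  expect_equal(f1$coefficients$estimate[i],
               f0$coefficients$estimate[i] + 1000, tolerance = 1e-6)
})

fake_fit <- function(estimate, p_value, block) {
  structure(
    list(outcome = "y",
         coefficients = tibble::tibble(
           term = paste0("t", seq_along(estimate)),
           estimate = estimate, std_error = 1, p_value = p_value,
           mark = "", block = block),
         r_squared = 0.5, n = 100),
    class = "productivity_fit"
  )
}

test_that("significance marks follow the a/b/c thresholds", {
  f <- fake_fit(c(1, 1, 1, 1), c(0.005, 0.03, 0.09, 0.5), rep("yield", 4))
  out <- mark_significance_and_top3(f)
  expect_equal(out$coefficients$mark, c("c", "b", "a", ""))
})

test_that("top-3 flags the largest significant food/market coefficients", {
  # nothing significant -> nothing flagged
  f <- fake_fit(c(5, 4, 3), c(0.2, 0.5, 0.9), rep("yield", 3))
  expect_equal(sum(mark_significance_and_top3(f)$coefficients$top3), 0)

  # only two significant -> only two flagged
  f <- fake_fit(c(5, 4, 3), c(0.01, 0.01, 0.9), rep("yield", 3))
  expect_equal(mark_significance_and_top3(f)$coefficients$top3,
               c(TRUE, TRUE, FALSE))

  # magnitude ordering among significant terms, controls never eligible
  f <- fake_fit(c(-10, 8, 2, 1, 50), c(0.001, 0.001, 0.001, 0.001, 0.001),
                c("yield", "yield", "market", "yield", "control"))
  expect_equal(mark_significance_and_top3(f)$coefficients$top3,
               c(TRUE, TRUE, TRUE, FALSE, FALSE))

  # ties break by smaller p-value, then column order
  f <- fake_fit(c(3, 3, 3, 3), c(0.05, 0.01, 0.05, 0.05),
                rep("yield", 4))
  expect_equal(mark_significance_and_top3(f)$coefficients$top3,
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("the eight-outcome run shares one design and reports n", {
  gen <- generate_survey(generator_config(n_farms = 300), seed = 13)
  comp <- default_composition()
  reg <- run_table2(gen$survey, comp)
  expect_named(reg$fits, regression_outcomes())
  expect_true(all(vapply(reg$fits, function(f) f$n, 0) == reg$n))
  r2 <- vapply(reg$fits, function(f) f$r_squared, 0)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_equal(nrow(reg$wide), 18)  # 15 regressors + constant + R2 + n
})

test_that("terrestrial yields have no true effect on vitamin B12", {
  # plants carry no B12, so across replicate surveys the eight
  # terrestrial-yield coefficients of the B12 model are centred on zero
  comp <- default_composition()
  terr <- paste0("yield_", subcategories("terrestrial"))
  z <- c()
  for (s in 1:8) {
    gen <- generate_survey(generator_config(n_farms = 400), seed = 100 + s)
    cl <- trim_small_systems(classify_farms(gen$survey, comp))$retained
    des <- build_design_matrix(gen$survey, cl, comp)
    f <- ols_fit(des, "ae_vitamin_b12")
    co <- f$coefficients[match(terr, f$coefficients$term), ]
    z <- c(z, co$estimate / co$std_error)
  }
  expect_lt(abs(mean(z)), 0.5)
})
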