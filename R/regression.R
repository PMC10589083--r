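# Fixed-effects OLS: economic productivity and the seven nutrient AE
# outcomes regressed on the twelve food-group yields (t/ha), market
# orientation indicators, household controls and upazila fixed effects.

#' Regressor blocks of the productivity regressions
#'
#' @return Named list: `yields` (12 sub-category yield columns, t/ha),
#'   `market` (share of aquatic production sold as a fraction, and 0/1
#'   indicators for any vegetable/fruit and any rice sales), `controls`
#'   (household covariates and operated areas).
#' @export
regressor_blocks <- function() {
  list(
    yields = paste0("yield_", subcategories()),
    market = c("aquatic_share_sold", "sold_vf", "sold_rice"),
    controls = c("head_age", "head_education", "head_female", "n_members",
                 "dependency_ratio", "off_farm_income", "travel_time_city",
                 "land_ha", "pond_ha")
  )
}

#' Outcomes of the productivity regressions
#'
#' Economic productivity plus one AE outcome per nutrient, in table order.
#'
#' @return Character vector of column names in the design data.
#' @export
regression_outcomes <- function() {
  c("economic_usd_per_ha", paste0("ae_", nutrient_names()))
}

#' Assemble the regression design data
#'
#' One row per retained farm: the eight outcome columns, the twelve
#' sub-category yields in tonnes per hectare, market-orientation variables
#' (`aquatic_share_sold` as a fraction in \[0,1\]; `sold_vf` and `sold_rice`
#' as 0/1), the household controls, and `upazila_id` for the fixed effects.
#' Full column rank (after dropping one fixed-effect reference level) is
#' verified; collinear columns are a hard error.
#'
#' @param survey An [iaa_survey()].
#' @param classified Retained classification (e.g.
#'   `trim_small_systems(...)$retained`).
#' @param composition A `food_composition`.
#' @param productivity Optional precomputed [farm_productivity()] table for
#'   the full survey.
#' @param rda An [rda_set()].
#' @return Tibble of design data, one row per retained farm.
#' @export
build_design_matrix <- function(survey, classified, composition,
                                productivity = NULL, rda = rda_set()) {
  ids <- classified$farm_id
  farms <- survey$farms[match(ids, survey$farms$farm_id), ]
  if (anyNA(farms$farm_id)) {
    stop("classified farms missing from the survey", call. = FALSE)
  }
  if (is.null(productivity)) {
    productivity <- farm_productivity(survey, composition, rda)
  }
  prod <- productivity[match(ids, productivity$farm_id), ]

  h <- survey$harvests[survey$harvests$farm_id %in% ids &
                         survey$harvests$quantity_kg > 0, ]
  h$subcategory <- assign_subcategory(h$food_code, composition)
  h$group <- food_group(h$subcategory)

  # sub-category yields, kg -> t, per total ha
  yld <- matrix(0, length(ids), 12,
                dimnames = list(ids, paste0("yield_", subcategories())))
  if (nrow(h) > 0L) {
    ys <- rowsum(h$quantity_kg / 1000,
                 paste(h$farm_id, h$subcategory, sep = "\r"))
    parts <- strsplit(rownames(ys), "\r", fixed = TRUE)
    fid <- vapply(parts, `[`, "", 1L)
    sub <- vapply(parts, `[`, "", 2L)
    yld[cbind(fid, paste0("yield_", sub))] <- ys[, 1]
  }
  yld <- yld / farms$area_ha

  # market orientation
  aq <- h[h$group == "aquatic", ]
  aq_share <- rep(0, length(ids))
  if (nrow(aq) > 0L) {
    s <- rowsum(cbind(aq$quantity_sold_kg, aq$quantity_kg), aq$farm_id)
    aq_share[match(rownames(s), ids)] <- s[, 1] / s[, 2]
  }
  sold_any <- function(group) {
    sel <- h$group == group & h$quantity_sold_kg > 0
    as.numeric(ids %in% h$farm_id[sel])
  }

  design <- dplyr::bind_cols(
    tibble::tibble(farm_id = ids),
    prod[regression_outcomes()],
    tibble::as_tibble(yld),
    tibble::tibble(aquatic_share_sold = aq_share,
                   sold_vf = sold_any("vf"), sold_rice = sold_any("rice")),
    farms[regressor_blocks()$controls],
    tibble::tibble(upazila_id = farms$upazila_id)
  )
  check_design_rank(design)
  design
}

design_model_matrix <- function(design) {
  blocks <- regressor_blocks()
  rhs <- c(blocks$yields, blocks$market, blocks$controls)
  if (length(unique(design$upazila_id)) > 1L) {
    rhs <- c(rhs, "factor(upazila_id)")
  }
  stats::model.matrix(
    stats::reformulate(rhs), data = design
  )
}

check_design_rank <- function(design) {
  X <- design_model_matrix(design)
  # with fewer farms than columns the deficiency is inherent, not a data
  # defect; ols_fit reports the insufficient n instead
  if (nrow(X) < ncol(X)) return(invisible(FALSE))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit one productivity regression by OLS
#'
#' Ordinary least squares of `outcome` on the full regressor set (yields,
#' market variables, controls, upazila fixed effects) with an intercept.
#' Inference uses conventional homoskedastic standard errors by default;
#' `se = "HC1"` switches to heteroskedasticity-robust (HC1) standard errors.
#' Two-sided t-test p-values; significance marks `a`/`b`/`c` for p < 0.10 /
#' 0.05 / 0.01 (most stringent applicable).
#'
#' @param design Output of [build_design_matrix()] (or any data frame when
#'   `regressors` is supplied).
#' @param outcome One of [regression_outcomes()] (or any column of `design`).
#' @param se `"ols"` (default) or `"HC1"`.
#' @param regressors Optional custom regressor columns; defaults to the
#'   standard blocks of [regressor_blocks()].
#' @param fixed_effects Include upazila fixed effects (default `TRUE`; they
#'   are dropped automatically when only one upazila is present).
#' @return A `productivity_fit`: list with `outcome`, tibble `coefficients`
#'   (`term`, `estimate`, `std_error`, `p_value`, `mark`, `top3`, `block`),
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
ols_fit <- function(design, outcome, se = c("ols", "HC1"),
                    regressors = NULL, fixed_effects = TRUE) {
  se <- match.arg(se)
  stopifnot(outcome %in% names(design))
  blocks <- regressor_blocks()
  rhs <- regressors %||% c(blocks$yields, blocks$market, blocks$controls)
  n_upz <- if (fixed_effects && "upazila_id" %in% names(design)) {
    length(unique(design$upazila_id))
  } else 1L
  if (n_upz > 1L) rhs <- c(rhs, "factor(upazila_id)")
  n_cols <- 1L + length(setdiff(rhs, "factor(upazila_id)")) +
    max(0L, n_upz - 1L)
  if (nrow(design) <= n_cols) {
    stop("not enough observations (n = ", nrow(design),
         ") for the design", call. = FALSE)
  }
  fml <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(fml, data = design)
  if (anyNA(stats::coef(fit))) {
    stop("singular fit; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  ct <- if (se == "HC1") {
    lmtest::coeftest(fit, vcov = sandwich::vcovHC(fit, type = "HC1"))
  } else {
    stats::coef(summary(fit))
  }
  term <- rownames(ct)
  block <- dplyr::case_when(
    term %in% blocks$yields ~ "yield",
    term %in% blocks$market ~ "market",
    term %in% blocks$controls ~ "control",
    term == "(Intercept)" ~ "constant",
    startsWith(term, "factor(upazila_id)") ~ "fixed_effect",
    TRUE ~ "custom"
  )
  coefs <- tibble::tibble(
    term = term,
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    p_value = unname(ct[, 4]),
    mark = significance_mark(unname(ct[, 4])),
    block = block
  )
  res <- structure(
    list(outcome = outcome, coefficients = coefs,
         r_squared = summary(fit)$r.squared, n = nrow(design), fit = fit),
    class = "productivity_fit"
  )
  mark_significance_and_top3(res)
}

significance_mark <- function(p) {
  dplyr::case_when(p < 0.01 ~ "c", p < 0.05 ~ "b", p < 0.10 ~ "a",
                   TRUE ~ "")
}

#' Annotate a fit with significance marks and the top-3 rule
#'
#' Recomputes marks from p-values and flags, among the food-yield and
#' market-orientation regressors only (never the constant, controls or fixed
#' effects), the three statistically significant (p < 0.10) coefficients of
#' largest absolute magnitude. Ties break by smaller p-value, then by column
#' order.
#'
#' @param result A `productivity_fit`.
#' @return The annotated `productivity_fit` (`top3` logical column set).
#' @export
mark_significance_and_top3 <- function(result) {
  co <- result$coefficients
  co$mark <- significance_mark(co$p_value)
  eligible <- co$block %in% c("yield", "market") & co$p_value < 0.10
  ord <- order(-abs(co$estimate), co$p_value, seq_len(nrow(co)))
  ranked <- ord[eligible[ord]]
  co$top3 <- seq_len(nrow(co)) %in% ranked[seq_len(min(3L, length(ranked)))]
  result$coefficients <- co
  result
}

#' @export
print.productivity_fit <- function(x, ...) {
  cat(sprintf("<productivity_fit> %s: n = %d, R^2 = %.3f\n",
              x$outcome, x$n, x$r_squared))
  show <- x$coefficients[x$coefficients$block %in% c("yield", "market"), ]
  print(show[c("term", "estimate", "std_error", "mark", "top3")], n = 15)
  invisible(x)
}

#' Run the full set of productivity regressions
#'
#' Fits the eight outcomes ([regression_outcomes()]) on one identical design
#' matrix and formats the results both long (one row per outcome x term) and
#' wide (terms x outcomes, coefficient with significance mark over standard
#' error, bold-marking the top-3 coefficients with `*`).
#'
#' @param survey An [iaa_survey()].
#' @param composition A `food_composition`.
#' @param rda An [rda_set()].
#' @param classified Optional retained classification; computed (classify +
#'   trim at 12) when omitted.
#' @param se Standard-error flavour, see [ols_fit()].
#' @param trim Small-cell threshold used when `classified` is omitted.
#' @return List with `fits` (named list of `productivity_fit`), `long`
#'   (tidy tibble), `wide` (formatted character table), `n`.
#' @export
run_table2 <- function(survey, composition, rda = rda_set(),
                       classified = NULL, se = "ols", trim = 12) {
  if (is.null(classified)) {
    classified <- trim_small_systems(classify_farms(survey, composition),
                                     trim)$retained
  }
  design <- build_design_matrix(survey, classified, composition, rda = rda)
  fits <- lapply(regression_outcomes(), function(y) ols_fit(design, y, se))
  names(fits) <- regression_outcomes()
  long <- dplyr::bind_rows(lapply(fits, function(f) {
    dplyr::mutate(f$coefficients, outcome = f$outcome,
                  r_squared = f$r_squared, n = f$n, .before = 1)
  }))

  blocks <- regressor_blocks()
  show_terms <- c(blocks$yields, blocks$market, "(Intercept)")
  cell <- function(f, term) {
    co <- f$coefficients[f$coefficients$term == term, ]
    sprintf("%s%.1f%s (%.1f)", ifelse(co$top3, "*", ""), co$estimate,
            co$mark, co$std_error)
  }
  wide <- tibble::tibble(term = show_terms)
  for (y in regression_outcomes()) {
    wide[[y]] <- vapply(show_terms, cell, "", f = fits[[y]])
  }
  wide <- dplyr::bind_rows(
    wide,
    tibble::tibble(term = "R squared",
                   !!!stats::setNames(as.list(sprintf(
                     "%.2f", vapply(fits, function(f) f$r_squared, 0))),
                     regression_outcomes())),
    tibble::tibble(term = "Observations",
                   !!!stats::setNames(as.list(sprintf(
                     "%d", vapply(fits, function(f) f$n, 0L))),
                     regression_outcomes()))
  )
  list(fits = fits, long = long, wide = wide, n = nrow(design))
}
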