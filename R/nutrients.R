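# Nutrient vectors and recommended dietary allowances (RDAs).
#
# Seven nutrients are tracked throughout the package. Units are fixed per
# component and never mixed:
#   energy      kJ
#   protein     g
#   calcium     mg
#   iron        mg
#   zinc        mg
#   vitamin_a   ug retinol activity equivalents (RAE)
#   vitamin_b12 the configured B12 unit (default ug; see `rda_set()`)

#' Names of the tracked nutrients
#'
#' Canonical order used by every nutrient vector in the package.
#'
#' @return Character vector of length 7.
#' @export
nutrient_names <- function() {
  c("energy", "protein", "calcium", "iron", "zinc", "vitamin_a", "vitamin_b12")
}

#' Construct a nutrient vector
#'
#' A nutrient vector is a named numeric vector over [nutrient_names()], one
#' amount per nutrient, all components non-negative unless `allow_negative`
#' (differences of nutrient vectors arise in tests, never in the pipeline).
#'
#' @param energy Energy in kJ.
#' @param protein Protein in g.
#' @param calcium Calcium in mg.
#' @param iron Iron in mg.
#' @param zinc Zinc in mg.
#' @param vitamin_a Vitamin A in ug RAE.
#' @param vitamin_b12 Vitamin B12 in the configured unit (default ug).
#' @param allow_negative Permit negative components (default `FALSE`).
#'
#' @return Named numeric vector of length 7.
#' @export
#' @examples
#' nutrient_vector(energy = 1460, protein = 7.5)
nutrient_vector <- function(energy = 0, protein = 0, calcium = 0, iron = 0,
                            zinc = 0, vitamin_a = 0, vitamin_b12 = 0,
                            allow_negative = FALSE) {
  x <- c(
    energy = energy, protein = protein, calcium = calcium, iron = iron,
    zinc = zinc, vitamin_a = vitamin_a, vitamin_b12 = vitamin_b12
  )
  if (anyNA(x) || !is.numeric(x)) {
    stop("nutrient amounts must be non-missing numerics", call. = FALSE)
  }
  if (!allow_negative && any(x < 0)) {
    stop("nutrient amounts must be >= 0", call. = FALSE)
  }
  x
}

#' Adult recommended dietary allowances
#'
#' Daily adult requirements used to normalize nutrient production into adult
#' equivalents (AEs). Defaults are the constants used throughout: 9,200 kJ
#' energy, 55 g protein, 1,000 mg calcium, 13 mg iron, 10 mg zinc, 900 ug RAE
#' vitamin A and 2.5 (in `b12_unit`) vitamin B12. The B12 requirement is
#' carried with an explicit unit that must match the composition table's B12
#' concentration unit; the packaged composition data use ug.
#'
#' @param energy,protein,calcium,iron,zinc,vitamin_a,vitamin_b12 Daily
#'   requirement per nutrient, same units as [nutrient_vector()].
#' @param b12_unit Unit label for the vitamin B12 requirement and for B12
#'   concentrations in any composition table used with this RDA set.
#'
#' @return An object of class `rda_set`: a named numeric vector with a
#'   `b12_unit` attribute.
#' @export
#' @examples
#' rda_set()                      # package defaults
#' rda_set(iron = 18)             # override one requirement
rda_set <- function(energy = 9200, protein = 55, calcium = 1000, iron = 13,
                    zinc = 10, vitamin_a = 900, vitamin_b12 = 2.5,
                    b12_unit = "ug") {
  x <- nutrient_vector(energy, protein, calcium, iron, zinc, vitamin_a,
                       vitamin_b12)
  if (any(x <= 0)) stop("all RDA entries must be > 0", call. = FALSE)
  structure(x, b12_unit = b12_unit, class = c("rda_set", class(x)))
}

#' @export
print.rda_set <- function(x, ...) {
  cat("Adult daily RDAs (vitamin B12 in ", attr(x, "b12_unit"), "):\n",
      sep = "")
  print(unclass(x))
  invisible(x)
}

#' Read RDA overrides from a YAML configuration
#'
#' Reads the `rda:` block of a YAML file (keys as in [nutrient_names()], plus
#' optional `b12_unit`) and returns an [rda_set()] with unspecified entries at
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `rda_set`.
#' @export
rda_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  blk <- cfg$rda
  if (is.null(blk)) return(rda_set())
  known <- c(nutrient_names(), "b12_unit")
  bad <- setdiff(names(blk), known)
  if (length(bad)) {
    stop("unknown rda keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(rda_set, blk)
}
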