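#' Jenkins total aboveground biomass
#'
#' National-scale allometry predicting total aboveground dry biomass of a
#' tree from its diameter at breast height:
#' `bm = exp(B1 + B2 * ln(DIA * 2.54))` with `DIA` in inches (the 2.54 factor
#' converts to centimetres) and `bm` in kilograms dry weight. `B1`/`B2` are
#' the species-group coefficients (`JENKINS_TOTAL_B1`, `JENKINS_TOTAL_B2`).
#'
#' @param dia_in Diameter at breast height in inches; strictly positive
#'   (the log is undefined at 0). Vectorized.
#' @param b1,b2 Jenkins intercept and slope coefficients (recycled).
#' @return Biomass in kg dry weight, same length as `dia_in`.
#' @examples
#' jenkins_biomass(10, b1 = -2.5356, b2 = 2.4349)
#' @export
jenkins_biomass <- function(dia_in, b1, b2) {
  if (!all(is.finite(b1)) || !all(is.finite(b2))) {
    ricb_stop("ricb_argument_error", "Jenkins coefficients must be finite")
  }
  if (any(!is.finite(dia_in)) || any(dia_in <= 0)) {
    ricb_stop("ricb_domain_error",
              "dia_in must be strictly positive (log undefined at 0)")
  }
  exp(b1 + b2 * log(dia_in * 2.54))
}

#' Carmean coefficient set
#'
#' Coefficients of the asymptotic site-index height curve
#' `H = b1 * S^b2 * (1 - exp(b3 * A))^(b4 * S^b5)`, where `S` is site index,
#' `A` age in years and `H` height in feet. `b1 > 0` and `b3 < 0` give the
#' decay-form curve that rises monotonically to the asymptote `b1 * S^b2`.
#'
#' @param b1,b2,b3,b4,b5 Curve coefficients.
#' @return A named numeric vector of class `carmean_coefficients`.
#' @export
carmean_coefficients <- function(b1, b2, b3, b4, b5) {
  v <- c(b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5)
  if (!all(is.finite(v))) {
    ricb_stop("ricb_argument_error", "Carmean coefficients must be finite")
  }
  if (b1 <= 0) ricb_stop("ricb_argument_error", "Carmean b1 must be positive")
  if (b3 >= 0) {
    ricb_stop("ricb_argument_error",
              "Carmean b3 must be negative (decay-form curve)")
  }
  structure(v, class = "carmean_coefficients")
}

#' Carmean site-index height curve (forward)
#'
#' Expected tree height at a given age on a site of given index:
#' `H = b1 * SI^b2 * (1 - exp(b3 * age))^(b4 * SI^b5)`. Strictly increasing
#' in age (for `b3 < 0`) towards the asymptote `b1 * SI^b2`. This forward
#' curve is the generator used for synthetic heights and the oracle for the
#' age inversion.
#'
#' @param age_yr Tree age in years, strictly positive. Vectorized.
#' @param site_index Site index (base-age height, feet), strictly positive.
#' @param coeffs A [carmean_coefficients()] (or named vector with b1..b5).
#' @return Height in feet.
#' @export
carmean_height <- function(age_yr, site_index, coeffs) {
  if (any(!is.finite(age_yr)) || any(age_yr <= 0)) {
    ricb_stop("ricb_domain_error", "age_yr must be strictly positive")
  }
  if (any(!is.finite(site_index)) || any(site_index <= 0)) {
    ricb_stop("ricb_domain_error", "site_index must be strictly positive")
  }
  b <- as.numeric(coeffs[c("b1", "b2", "b3", "b4", "b5")])
  b[1] * site_index^b[2] * (1 - exp(b[3] * age_yr))^(b[4] * site_index^b[5])
}

#' Tree age from height via the inverted Carmean curve
#'
#' Algebraic inverse of [carmean_height()]:
#' `age = (1/b3) * ln(1 - (HT / (b1*SI^b2))^(1 / (b4*SI^b5)))`,
#' with `HT` the tree height in feet. Heights at or above the curve's
#' asymptote `b1*SI^b2` have no finite inverse; those trees are assigned
#' `max_age_yr` and a warning (class `ricb_clamped_age`) reports the count.
#' All results are clamped to `[0, max_age_yr]`.
#'
#' @param ht_ft Tree height in feet, non-negative. Vectorized.
#' @param site_index Site index, strictly positive.
#' @param coeffs A [carmean_coefficients()] (or named vector with b1..b5).
#' @param max_age_yr Clamp ceiling in years (default 300).
#' @return Age in years, in `[0, max_age_yr]`.
#' @export
carmean_age <- function(ht_ft, site_index, coeffs, max_age_yr = 300) {
  if (any(!is.finite(ht_ft)) || any(ht_ft < 0)) {
    ricb_stop("ricb_domain_error", "ht_ft must be non-negative")
  }
  if (any(!is.finite(site_index)) || any(site_index <= 0)) {
    ricb_stop("ricb_domain_error", "site_index must be strictly positive")
  }
  if (!is.numeric(max_age_yr) || length(max_age_yr) != 1L || max_age_yr <= 0) {
    ricb_stop("ricb_argument_error", "max_age_yr must be a positive scalar")
  }
  b <- as.numeric(coeffs[c("b1", "b2", "b3", "b4", "b5")])
  asym <- b[1] * site_index^b[2]
  over <- ht_ft >= asym
  age <- rep(NA_real_, length(ht_ft))
  if (any(!over)) {
    ratio <- (ht_ft[!over] / (if (length(asym) > 1L) asym[!over] else asym))
    si <- if (length(site_index) > 1L) site_index[!over] else site_index
    age[!over] <- (1 / b[3]) * log(1 - ratio^(1 / (b[4] * si^b[5])))
  }
  if (any(over)) {
    age[over] <- max_age_yr
    ricb_warn("ricb_clamped_age",
              "%d height(s) at or above the site-curve asymptote; age clamped to %g",
              sum(over), max_age_yr)
  }
  pmin(pmax(age, 0), max_age_yr)
}

#' Representative species per species group
#'
#' For each eastern species group code (E_SPGRPCD) present in a tree table,
#' returns the species symbol with the largest number of individual trees in
#' that group. Ties are broken by the lexicographically smallest symbol, so
#' the result is deterministic and order-independent.
#'
#' @param trees Data frame with columns `species_symbol` and `e_spgrpcd`
#'   (one row per tree).
#' @return Named character vector: names are group codes, values the
#'   representative species symbols.
#' @export
representative_species <- function(trees) {
  if (!is.data.frame(trees) || nrow(trees) == 0L) {
    ricb_stop("ricb_argument_error", "trees must be a non-empty data frame")
  }
  counts <- as.data.frame(table(
    e_spgrpcd = trees$e_spgrpcd,
    species_symbol = trees$species_symbol), stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, ]
  # symbol sort first, then stable order by descending count: the first row
  # per group is the max-count, lexicographically-smallest symbol
  counts <- counts[order(counts$species_symbol), ]
  counts <- counts[order(-counts$Freq), ]
  first <- counts[!duplicated(counts$e_spgrpcd), ]
  first <- first[order(as.integer(first$e_spgrpcd)), ]
  stats::setNames(first$species_symbol, first$e_spgrpcd)
}
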