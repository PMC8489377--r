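#' Schwartz estimated glomerular filtration rate
#'
#' Modified (bedside) Schwartz formula for infants and children,
#' \eqn{eGFR = 88.4 \, k \, HT / SCR} with height in cm and serum creatinine in
#' \eqn{\mu}mol/L. The age-class coefficient `k` is 0.33 for preterm infants
#' under 1 year, 0.45 for full-term infants under 1 year, and 0.55 for
#' children of 2--12 years.
#'
#' @param ht height (cm), `> 0`.
#' @param scr serum creatinine (\eqn{\mu}mol/L), `> 0`.
#' @param age_class one of `"preterm<1y"`, `"term<1y"`, `"2-12y"` (recycled).
#' @return eGFR in ml/min/1.73 m^2.
#' @examples
#' egfr_schwartz(ht = 50, scr = 18.95, age_class = "term<1y")
#' @export
egfr_schwartz <- function(ht, scr, age_class = c("term<1y", "preterm<1y", "2-12y")) {
  if (any(!is.finite(ht)) || any(ht <= 0)) stop("HT must be finite and > 0")
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("SCR must be finite and > 0")
  kmap <- c("preterm<1y" = 0.33, "term<1y" = 0.45, "2-12y" = 0.55)
  age_class <- match.arg(age_class, names(kmap), several.ok = TRUE)
  k <- kmap[age_class]
  unname(88.4 * k * ht / scr)
}

# Age-class coefficient used by the cohort generator: under 12 months the
# preterm flag decides 0.33 vs 0.45; from 12 months on the child coefficient
# 0.55 applies.
schwartz_class <- function(age_months, preterm) {
  ifelse(age_months < 12, ifelse(preterm, "preterm<1y", "term<1y"), "2-12y")
}

#' Classify renal function from eGFR
#'
#' Partitions eGFR into the study groups: below 30 ml/min/1.73 m^2 is excluded
#' (inclusion criterion), 30--86 is the normal-renal-function band for infants,
#' and 86 and above is augmented renal clearance (ARC). The boundary value 86
#' belongs to the ARC group.
#'
#' @param egfr numeric vector, ml/min/1.73 m^2.
#' @return factor with levels `"excluded"`, `"normal"`, `"augmented"`.
#' @examples
#' classify_renal_function(c(29.9, 30, 85.56, 86, 128))
#' @export
classify_renal_function <- function(egfr) {
  if (any(!is.finite(egfr))) stop("eGFR must be finite")
  factor(ifelse(egfr < 30, "excluded", ifelse(egfr < 86, "normal", "augmented")),
         levels = c("excluded", "normal", "augmented"))
}
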