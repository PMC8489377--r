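## Event-table conventions: one row per dose (EVID = 1, with AMT mg and DUR h)
## or observation (EVID = 0, with DV mg/L, MDV = 0); TIME in hours since each
## subject's first dose; covariates repeated on every row of a subject.

pkdata_required <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV")

# Exhaustive validation: collects every violation before failing, so a
# malformed file is diagnosed in one pass. Returns the data sorted by subject
# (order of first appearance) and time.
validate_pkdata <- function(data) {
  if (!is.data.frame(data)) stop("dataset must be a data.frame")
  probs <- character(0)
  missing_cols <- setdiff(pkdata_required, names(data))
  if (length(missing_cols) > 0L)
    probs <- c(probs, paste("missing mandatory column(s):",
                            paste(missing_cols, collapse = ", ")))
  if (length(probs) == 0L) {
    rows <- seq_len(nrow(data))
    bad <- which(!is.finite(data$TIME) | data$TIME < 0)
    if (length(bad)) probs <- c(probs, paste("negative or missing TIME in row(s):",
                                             paste(bad, collapse = ", ")))
    bad <- which(!data$EVID %in% c(0, 1))
    if (length(bad)) probs <- c(probs, paste("EVID must be 0 or 1 in row(s):",
                                             paste(bad, collapse = ", ")))
    obs <- data$EVID == 0
    bad <- rows[obs][!is.finite(data$DV[obs])]
    if (length(bad)) probs <- c(probs, paste("observation row(s) missing DV:",
                                             paste(bad, collapse = ", ")))
    dose <- data$EVID == 1
    bad <- rows[dose][!is.finite(data$AMT[dose]) | data$AMT[dose] <= 0]
    if (length(bad)) probs <- c(probs, paste("dose row(s) with missing or non-positive AMT:",
                                             paste(bad, collapse = ", ")))
    bad <- rows[dose][!is.finite(data$DUR[dose]) | data$DUR[dose] <= 0]
    if (length(bad)) probs <- c(probs, paste("dose row(s) with missing or non-positive DUR:",
                                             paste(bad, collapse = ", ")))
    ids <- unique(data$ID)
    n_dose <- tapply(dose, factor(data$ID, levels = ids), sum)
    n_obs <- tapply(obs, factor(data$ID, levels = ids), sum)
    if (any(n_dose == 0))
      probs <- c(probs, paste("subject(s) without any dose row:",
                              paste(ids[n_dose == 0], collapse = ", ")))
    if (any(n_obs == 0))
      probs <- c(probs, paste("subject(s) without any observation row:",
                              paste(ids[n_obs == 0], collapse = ", ")))
  }
  if (length(probs) > 0L)
    stop("invalid dataset:\n  ", paste(probs, collapse = "\n  "))
  data[order(match(data$ID, unique(data$ID)), data$TIME, -data$EVID), ,
       drop = FALSE]
}

#' Read and validate an event-table dataset
#'
#' Reads a CSV event table in longitudinal dosing/observation format (columns
#' `ID`, `TIME` (h), `EVID` 1 = dose / 0 = observation, `AMT` (mg), `DUR` (h),
#' `DV` (mg/L), `MDV`, optional `KIND` (`trough`/`peak`) and covariate columns
#' `WT`, `HT`, `SCR`, `AGE`, `PRETERM`, `SEX`, ...). All validation violations
#' are collected and reported together with row numbers.
#'
#' @param path CSV file path.
#' @return validated data.frame, sorted by subject and time.
#' @export
read_pkdata <- function(path) {
  validate_pkdata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an event-table dataset
#'
#' Deterministic column order and formatting; writing the same dataset twice
#' yields byte-identical files.
#'
#' @param data dataset as returned by [simulate_cohort()] or [read_pkdata()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pkdata <- function(data, path) {
  data <- validate_pkdata(data)
  lead <- intersect(c(pkdata_required, "KIND", "GROUP", cov_columns), names(data))
  data <- data[, c(lead, setdiff(names(data), lead)), drop = FALSE]
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
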