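# Shared fixtures and independent oracles for the test suite.

# Published stepwise-search OFV table (shipped fixture), as lookup oracles.
stepwise_fixture <- function() {
  path <- system.file("extdata", "stepwise_ofv.csv", package = "vancopk")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$key[is.na(tab$key)] <- ""
  list(
    maturation = function(form) {
      row <- tab[tab$stage == "maturation" & tab$key == form, ]
      if (nrow(row) != 1L) stop("no OFV recorded for form ", form)
      row$ofv
    },
    covariates = function(covs) {
      key <- paste(sort(covs), collapse = "+")
      row <- tab[tab$stage %in% c("covariates", "base") & tab$key == key, ]
      if (nrow(row) != 1L) stop("no OFV recorded for {", key, "}")
      row$ofv
    })
}

# Hand-rolled event-table builder for tiny deterministic datasets.
toy_dataset <- function(subjects) {
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    nd <- length(s$dose_times)
    no <- length(s$obs_times)
    df <- data.frame(
      ID = i,
      TIME = c(s$dose_times, s$obs_times),
      EVID = c(rep(1L, nd), rep(0L, no)),
      AMT = c(s$amounts, rep(NA_real_, no)),
      DUR = c(s$durations, rep(NA_real_, no)),
      DV = c(rep(NA_real_, nd), s$dv),
      MDV = c(rep(1L, nd), rep(0L, no)))
    for (nm in names(s$cov)) df[[nm]] <- s$cov[[nm]]
    df
  })
  do.call(rbind, rows)
}

# Covariate-free structural model: CL and V are the two intercepts.
plain_model <- function(tvcl, tvv, omega = c(CL = 0.3),
                        error = residual_error("proportional", 0.3)) {
  pk_model("plain", theta = c(TVCL = tvcl, TVV = tvv),
           omega = omega, error = error)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns.
signed_rank_p_enum <- function(d) {
  stopifnot(length(d) <= 12, all(d != 0))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean_v <- n * (n + 1) / 4
  # both tails are already counted by the symmetric exceedance
  min(1, mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-12))
}

quiet_fit <- function(...) suppressWarnings(suppressMessages(pkfit(...)))
quiet_cohort <- function(...) suppressMessages(simulate_cohort(...))
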