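#' Mean arctangent absolute percentage error, in degrees
#'
#' `MAAPE = (180/pi) * mean(atan(|(actual - forecast) / actual|))`. Unlike
#' MAPE it stays bounded (at 90 degrees) and stable when the reference values
#' approach zero, which is exactly the situation for percent-change series
#' around baseline. Convention at `actual = 0`: the term is 90 degrees if the
#' forecast differs from 0, else 0 (the continuous limit of the arctangent
#' ratio).
#'
#' @param actual,forecast equal-length numeric series.
#' @return MAAPE in degrees, in `[0, 90]`.
#' @export
maape_deg <- function(actual, forecast) {
  if (length(actual) == 0L) stop("empty series")
  if (length(actual) != length(forecast)) stop("series lengths differ")
  ratio <- ifelse(actual == 0,
                  ifelse(forecast == 0, 0, Inf),
                  abs((actual - forecast) / actual))
  mean(atan(ratio)) * 180 / pi
}

#' Windowed coefficient of determination
#'
#' Standard R-squared of forecast vs actual over the timepoints falling in a
#' named month window: `all` (0-48), `dmab` (treatment, 0-24), `dis`
#' (immediately after discontinuation, 24-36), `end` (stabilization, 36-48),
#' or an explicit `c(lo, hi)` range. Can be negative when the forecast does
#' worse than the mean of the actuals.
#'
#' @param actual,forecast percent-change series.
#' @param months timepoints in months.
#' @param window window name or numeric `c(lo, hi)`.
#' @return R-squared over the windowed points.
#' @export
r_squared <- function(actual, forecast, months, window = "all") {
  win <- if (is.character(window)) {
    switch(window, all = c(0, 48), dmab = c(0, 24), dis = c(24, 36),
           end = c(36, 48), stop("unknown window: ", window))
  } else window
  sel <- months >= win[1] & months <= win[2]
  if (sum(sel) < 2L) stop("need at least 2 points in the window")
  a <- actual[sel]; f <- forecast[sel]
  1 - sum((a - f)^2) / sum((a - mean(a))^2)
}

#' Comparison of a simulated series against a clinical series
#'
#' @param months aligned timepoints in months.
#' @param actual clinical percent changes (user-supplied CSV).
#' @param forecast simulated percent changes.
#' @return A list with `maape_deg` and the four windowed R-squared values.
#' @export
compare_series <- function(months, actual, forecast) {
  list(maape_deg = maape_deg(actual, forecast),
       r2_all = r_squared(actual, forecast, months, "all"),
       r2_dmab = r_squared(actual, forecast, months, "dmab"),
       r2_dis = r_squared(actual, forecast, months, "dis"),
       r2_end = r_squared(actual, forecast, months, "end"))
}

#' Factorial mixed-effects model of the simulated BMC
#'
#' Fits, by REML, `BMC ~ P_A * P_B * P_C * P_D + BL + (1 | phantom)`: the
#' full factorial of the four mechanism indicators (all interactions up to
#' 4-way), the patient-specific baseline BMC as covariate, and a random
#' intercept per phantom. p-values are Wald z tests on the fixed effects.
#'
#' @param table a run table with columns `BMC`, `P_A`..`P_D`, `phantom`,
#'   `BL` (e.g. from [run_factorial()], optionally filtered to timepoints).
#' @return A list: `fit` (the `lmerMod`), `coefficients` (a `data.frame`
#'   with estimate, SE, z, p), `main_effects` (the four main-effect rows).
#' @export
fit_factorial_mixed_model <- function(table) {
  table <- as.data.frame(table)
  need <- c("BMC", "P_A", "P_B", "P_C", "P_D", "phantom", "BL")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(table$phantom)) < 2L)
    stop("need at least 2 phantoms for a random intercept")
  cells <- unique(table[, c("P_A", "P_B", "P_C", "P_D")])
  full <- expand.grid(P_A = 0:1, P_B = 0:1, P_C = 0:1, P_D = 0:1)
  present <- interaction(cells$P_A, cells$P_B, cells$P_C, cells$P_D)
  wanted <- interaction(full$P_A, full$P_B, full$P_C, full$P_D)
  absent <- full[!(wanted %in% present), ]
  if (nrow(absent) > 0L)
    stop("singular factorial design; absent cells: ",
         paste(apply(absent, 1, paste, collapse = ""), collapse = ", "))
  fit <- lme4::lmer(BMC ~ P_A * P_B * P_C * P_D + BL + (1 | phantom),
                    data = table, REML = TRUE)
  sm <- summary(fit)$coefficients
  z <- sm[, "Estimate"] / sm[, "Std. Error"]
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], z = z,
                   p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  mains <- co[co$term %in% c("P_A", "P_B", "P_C", "P_D"), ]
  list(fit = fit, coefficients = co, main_effects = mains,
       method = "REML fit (lme4), Wald z tests on fixed effects")
}

#' Read a clinical comparison CSV
#'
#' Expected columns: `month`, `mean_pct_change`, optionally `se`. The
#' clinical series (e.g. total-hip BMD percent change under treatment and
#' discontinuation) is user-supplied; no clinical data ships with the
#' package.
#'
#' @param path CSV path.
#' @return A `data.frame` with at least `month` and `mean_pct_change`.
#' @export
read_clinical_csv <- function(path) {
  df <- read.csv(path)
  need <- c("month", "mean_pct_change")
  if (!all(need %in% names(df)))
    stop("clinical CSV needs columns: ", paste(need, collapse = ", "))
  df[order(df$month), ]
}
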