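#' Summarise an environmental time series
#'
#' Restricts raw measurements to the warm season (October--April by
#' default) and to daylight hours, averages within calendar days, and
#' returns summary statistics of the daily averages. This is the
#' aggregation that produces the per-site AvTemp / MaxTemp / ... style
#' summaries from sonde or logger records.
#'
#' @param datetime POSIXct (or coercible) timestamps
#' @param value numeric measurements
#' @param months integer months to keep (default `c(10:12, 1:4)`, the
#'   southern-hemisphere warm season)
#' @param daylight_only drop measurements outside `daylight_hours`
#' @param daylight_hours inclusive clock-hour window treated as daylight
#' @return list: `mean`, `min`, `max`, `range` (max - min) of the daily
#'   averages, plus `n_days`.
#' @export
summarize_series <- function(datetime, value, months = c(10:12, 1:4),
                             daylight_only = TRUE,
                             daylight_hours = c(6, 18)) {
  datetime <- as.POSIXct(datetime, tz = "UTC")
  stopifnot(length(datetime) == length(value))
  ok <- is.finite(value)
  mth <- as.integer(format(datetime, "%m"))
  hr <- as.integer(format(datetime, "%H"))
  keep <- ok & mth %in% months
  if (daylight_only) {
    keep <- keep & hr >= daylight_hours[1] & hr <= daylight_hours[2]
  }
  if (!any(keep)) stop("no measurements left after month/daylight filtering")
  day <- format(datetime[keep], "%Y-%m-%d")
  daily <- tapply(value[keep], day, mean)
  list(mean = mean(daily), min = min(daily), max = max(daily),
       range = max(daily) - min(daily), n_days = length(daily))
}

#' Annual rate of change from monthly means
#'
#' Slope of a Gaussian identity-link linear fit of monthly means on time
#' expressed in years, i.e. the per-year trend used to project conditions
#' forward.
#'
#' @param month_start Date (or coercible) first day of each month
#' @param monthly_mean numeric monthly averages
#' @return slope in value units per year.
#' @export
annual_rate <- function(month_start, monthly_mean) {
  month_start <- as.Date(month_start)
  ok <- is.finite(monthly_mean)
  month_start <- month_start[ok]
  monthly_mean <- monthly_mean[ok]
  if (length(monthly_mean) < 3) stop("need at least 3 monthly means")
  yrs <- as.numeric(month_start - min(month_start)) / 365.25
  if (max(yrs) <= 1) stop("monthly means must span more than one year")
  fit <- stats::glm(monthly_mean ~ yrs, family = stats::gaussian())
  unname(stats::coef(fit)[2])
}

#' Greedy pruning of correlated predictors
#'
#' Computes all pairwise Pearson correlations over sites and repeatedly
#' resolves the strongest offending pair (|r| above `r_threshold`) by
#' dropping the member with the larger mean absolute correlation to all
#' other remaining variables (ties: the lexicographically later name).
#' Constant (zero-variance) variables are excluded up front with a
#' warning.
#'
#' @param env site x variable data.frame / matrix
#' @param r_threshold absolute Pearson correlation above which a pair is
#'   collinear (default 0.7)
#' @return list `retained`, `dropped` (character vectors) and `cor`
#'   (the full correlation matrix over non-constant variables).
#' @export
prune_correlated <- function(env, r_threshold = 0.7) {
  m <- as.matrix(env)
  if (ncol(m) < 2) stop("need at least 2 variables")
  sds <- apply(m, 2, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning("dropping constant variable(s): ",
            paste(colnames(m)[constant], collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  cm <- stats::cor(m)
  keep <- colnames(m)
  dropped <- setdiff(colnames(as.matrix(env)), keep)
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (length(keep) < 2 || max(sub) <= r_threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- vapply(pair, function(v) {
      others <- setdiff(keep, v)
      mean(abs(cm[v, others]))
    }, 0)
    drop_var <- if (mean_abs[1] > mean_abs[2]) pair[1]
                else if (mean_abs[2] > mean_abs[1]) pair[2]
                else sort(pair)[2]
    keep <- setdiff(keep, drop_var)
    dropped <- c(dropped, drop_var)
  }
  list(retained = keep, dropped = dropped, cor = cm)
}

#' Variance-inflation-factor pruning
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing variable `j` on all others;
#' iteratively drops the largest VIF above `vif_threshold`. A single
#' remaining variable is returned unchanged (VIF undefined).
#'
#' @param env site x variable data.frame / matrix
#' @param vif_threshold conventional cutoff, default 10
#' @return list `vif` (named vector for the retained set), `retained`,
#'   `dropped`.
#' @export
vif_prune <- function(env, vif_threshold = 10) {
  m <- as.matrix(env)
  if (ncol(m) < 2) stop("need at least 2 variables")
  keep <- colnames(m)
  dropped <- character(0)
  vif_of <- function(vars) {
    vapply(vars, function(v) {
      X <- m[, setdiff(vars, v), drop = FALSE]
      fit <- stats::lm.fit(cbind(1, X), m[, v])
      if (any(is.na(fit$coefficients))) {
        stop("singular design; prune correlated predictors first")
      }
      r2 <- 1 - sum(fit$residuals^2) /
        sum((m[, v] - mean(m[, v]))^2)
      1 / max(1 - r2, .Machine$double.eps)
    }, 0)
  }
  repeat {
    if (length(keep) < 2) break
    v <- vif_of(keep)
    if (max(v) <= vif_threshold) break
    worst <- names(v)[which.max(v)]
    keep <- setdiff(keep, worst)
    dropped <- c(dropped, worst)
  }
  vif <- if (length(keep) >= 2) vif_of(keep) else stats::setNames(NA_real_, keep)
  list(vif = vif, retained = keep, dropped = dropped)
}
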