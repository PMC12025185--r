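#' Fit a TNBS lysine standard curve
#'
#' Ordinary least-squares calibration line relating absorbance to lysine
#' concentration (`absorbance = slope * conc + intercept`), used to
#' convert TNBS absorbances into free-lysine concentrations.
#'
#' @param concentrations lysine concentrations (mM), >= 3 points with
#'   >= 2 distinct values.
#' @param absorbances matching absorbance readings.
#' @return object of class `standard_curve`: list with slope, intercept,
#'   r_squared, n.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  stopifnot(is.numeric(concentrations), is.numeric(absorbances),
            length(concentrations) == length(absorbances))
  if (length(concentrations) < 3L) stop("need >= 3 calibration points")
  if (length(unique(concentrations)) < 2L) {
    stop("degenerate design: all concentrations identical")
  }
  fit <- lm(absorbances ~ concentrations)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  out <- list(slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              r_squared = r2, n = length(concentrations))
  if (out$slope <= 0) warning("standard-curve slope is not positive")
  class(out) <- "standard_curve"
  out
}

#' Degree of modification from TNBS-reactive lysine concentrations
#'
#' `DM% = 100 * (1 - C_sample / C_control)` where the concentrations are
#' free (unmodified) lysine per mg protein in the modified sample and the
#' unmodified control. Values are clamped to \[0, 100\]: a sample reading
#' at or above the control reports 0% with `clamped = TRUE`.
#'
#' @param c_sample free-lysine concentration (mM/mg) after modification.
#' @param c_control free-lysine concentration (mM/mg) of the control
#'   (must be > 0).
#' @return object of class `dm_result`: list with c_sample, c_control,
#'   dm_percent, clamped.
#' @export
degree_of_modification <- function(c_sample, c_control) {
  stopifnot(length(c_sample) == 1L, length(c_control) == 1L)
  if (!is.finite(c_control) || c_control <= 0) {
    stop("c_control must be a positive number")
  }
  if (!is.finite(c_sample) || c_sample < 0) {
    stop("c_sample must be non-negative")
  }
  dm <- 100 * (1 - c_sample / c_control)
  clamped <- dm < 0
  dm <- min(100, max(0, dm))
  out <- list(c_sample = c_sample, c_control = c_control,
              dm_percent = dm, clamped = clamped)
  class(out) <- "dm_result"
  out
}

#' Construct a thermal-inactivation decay series
#'
#' @param times sampling times in minutes, strictly increasing, >= 3.
#' @param activities matching non-negative activities (any consistent
#'   unit).
#' @param temperature numeric or text label for the incubation
#'   temperature.
#' @return object of class `decay_series`.
#' @export
decay_series <- function(times, activities, temperature = NA) {
  stopifnot(is.numeric(times), is.numeric(activities),
            length(times) == length(activities))
  if (length(times) < 3L) stop("decay series needs >= 3 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(activities < 0)) stop("activities must be non-negative")
  out <- list(times = as.numeric(times),
              activities = as.numeric(activities),
              temperature = temperature)
  class(out) <- "decay_series"
  out
}

#' First-order thermal-inactivation fit
#'
#' Fits `ln A = ln A0 - kd * t` by unweighted OLS with a free intercept
#' and reports `kd` as a positive inactivation constant together with the
#' half-life `ln(2)/kd`. Zero or negative activity readings cannot enter
#' the log fit and are excluded with a warning (`n_used` reports the
#' points kept). When the fitted slope is non-negative (no decay), `kd`
#' is reported as the non-positive estimate with `no_decay = TRUE` and an
#' infinite half-life. `method = "nonlinear"` instead fits
#' `A = A0 * exp(-kd t)` by least squares (sensitivity analysis;
#' initialized from the log-linear fit).
#'
#' @param series a `decay_series` (or list/data.frame with times and
#'   activities).
#' @param method "log-linear" (default) or "nonlinear".
#' @return object of class `inactivation_fit`: list with kd (min^-1),
#'   ln_A0, r_squared, n_used, t_half (min), no_decay, method.
#' @export
fit_inactivation <- function(series, method = c("log-linear",
                                                "nonlinear")) {
  method <- match.arg(method)
  times <- series$times
  act <- series$activities
  stopifnot(is.numeric(times), is.numeric(act),
            length(times) == length(act))
  pos <- act > 0
  if (any(!pos)) {
    warning(sum(!pos), " non-positive activity reading(s) excluded from ",
            "log-linear fit")
  }
  t_u <- times[pos]; a_u <- act[pos]
  if (length(t_u) < 2L) stop("need >= 2 strictly positive activity points")
  y <- log(a_u)
  fit <- lm(y ~ t_u)
  slope <- unname(coef(fit)[2])
  ln_a0 <- unname(coef(fit)[1])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  kd <- -slope
  if (method == "nonlinear") {
    nl <- try(nls(a_u ~ A0 * exp(-k * t_u),
                  start = list(A0 = exp(ln_a0), k = max(kd, 1e-8))),
              silent = TRUE)
    if (!inherits(nl, "try-error")) {
      kd <- unname(coef(nl)["k"])
      ln_a0 <- log(unname(coef(nl)["A0"]))
      ss_tot_a <- sum((a_u - mean(a_u))^2)
      r2 <- if (ss_tot_a > 0) {
        1 - sum(stats::residuals(nl)^2) / ss_tot_a
      } else 1
    }
  }
  # slopes below floating noise on a flat series count as "no decay"
  no_decay <- kd <= 1e-12
  out <- list(kd = kd, ln_A0 = ln_a0, r_squared = r2,
              n_used = length(t_u),
              t_half = if (no_decay) Inf else log(2) / kd,
              no_decay = no_decay, method = method)
  class(out) <- "inactivation_fit"
  out
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("inactivation_fit (%s): kd = %.4g min^-1, t1/2 = %.1f min, r^2 = %.4f (n = %d)\n",
              x$method, x$kd, x$t_half, x$r_squared, x$n_used))
  invisible(x)
}

#' Half-life of a first-order decay
#'
#' @param kd positive inactivation rate constant(s), min^-1.
#' @return half-life `ln(2)/kd` in minutes.
#' @export
half_life <- function(kd) {
  stopifnot(is.numeric(kd))
  if (any(!is.finite(kd) | kd <= 0)) stop("kd must be positive")
  log(2) / kd
}

#' Thermal stabilization ratio
#'
#' `R = t_half(modified) / t_half(control) = kd_control / kd_modified`.
#' R > 1 means the modification stabilized the enzyme.
#'
#' @param kd_modified,kd_control positive rate constants (min^-1).
#' @return object of class `stability_ratio`: list with t_half_modified,
#'   t_half_control, R.
#' @export
stability_ratio <- function(kd_modified, kd_control) {
  if (any(!is.finite(c(kd_modified, kd_control))) ||
      kd_modified <= 0 || kd_control <= 0) {
    stop("rate constants must be positive")
  }
  out <- list(t_half_modified = log(2) / kd_modified,
              t_half_control = log(2) / kd_control,
              R = kd_control / kd_modified)
  class(out) <- "stability_ratio"
  out
}

#' Optimum-condition summary of an activity profile
#'
#' Reports the measured condition with maximal activity (no
#' interpolation). Ties are broken toward the condition closest to the
#' median of the measured conditions, then toward the lower label. The
#' profile is rescaled so its maximum is 100%.
#'
#' @param table an `assay_table` with numeric condition labels (pH or
#'   temperature) and >= 2 conditions.
#' @return object of class `profile_summary`: list with
#'   optimum_condition, activity_at_optimum, normalized_profile
#'   (data.frame condition/activity_percent).
#' @export
profile_summary <- function(table) {
  stopifnot(inherits(table, "assay_table"))
  cond <- as.numeric(table$condition_labels)
  act <- table$activities
  if (length(cond) < 2L) stop("need >= 2 conditions")
  if (all(act == 0)) stop("all activities are zero")
  mx <- max(act)
  at_max <- which(act == mx)
  if (length(at_max) > 1L) {
    med <- median(cond)
    d <- abs(cond[at_max] - med)
    at_max <- at_max[order(d, cond[at_max])]
  }
  opt <- at_max[1]
  out <- list(optimum_condition = cond[opt],
              activity_at_optimum = act[opt],
              normalized_profile = data.frame(
                condition = cond, activity_percent = 100 * act / mx))
  class(out) <- "profile_summary"
  out
}

#' Residual activity relative to a reference condition
#'
#' Rescales activities (for example across inhibitor concentrations) to
#' percent of the activity at `reference_condition` (typically the 0 mM
#' condition).
#'
#' @param table an `assay_table`.
#' @param reference_condition label of the reference condition; must be
#'   present with activity > 0.
#' @return an `assay_table` of percentages (same condition labels).
#' @export
residual_activity <- function(table, reference_condition) {
  stopifnot(inherits(table, "assay_table"))
  hit <- which(table$condition_labels == reference_condition)
  if (length(hit) == 0L) stop("reference condition not found: ",
                              reference_condition)
  ref <- table$activities[hit[1]]
  if (ref <= 0) stop("reference activity must be > 0")
  assay_table(table$condition_labels, 100 * table$activities / ref,
              metadata = paste0(table$metadata,
                                " [% of reference condition ",
                                reference_condition, "]"))
}
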