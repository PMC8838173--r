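#' Record-level nutrient totals for reference and app records
#'
#' Sums each nutrient over the segments of every record, for both methods,
#' producing the paired record-level values the agreement analysis regresses.
#' App totals include intruded segments and lose omitted ones — the tool is
#' assessed on what it actually reported for the record.
#'
#' @param reference,app Segment tables.
#' @param exclude_records Optional character vector of record ids to drop
#'   (e.g. known transcription errors).
#' @return A tibble with one row per (record, nutrient): `record_id`,
#'   `record_kind`, `nutrient`, `true`, `est`.
#' @export
record_nutrient_totals <- function(reference, app, exclude_records = NULL) {
  tot <- function(seg, value_name) {
    long <- tidyr::pivot_longer(
      seg[, c("record_id", "record_kind", NUTRIENTS)],
      dplyr::all_of(NUTRIENTS), names_to = "nutrient", values_to = "value")
    out <- dplyr::summarise(
      dplyr::group_by(long, .data$record_id, .data$record_kind,
                      .data$nutrient),
      value = sum(.data$value), .groups = "drop")
    names(out)[names(out) == "value"] <- value_name
    out
  }
  ref <- tot(validate_segments(reference), "true")
  est <- tot(validate_segments(app), "est")
  out <- dplyr::left_join(ref, est[, c("record_id", "nutrient", "est")],
                          by = c("record_id", "nutrient"))
  out$est[is.na(out$est)] <- 0  # app reported nothing for the record
  if (!is.null(exclude_records)) {
    out <- out[!out$record_id %in% exclude_records, ]
  }
  out
}

#' Regression calibration of app measurements on gold-standard values
#'
#' Regressing the tool's measurements (y) on the gold-standard controlled
#' values (x) estimates the tool's differential bias (intercept `alpha`) and
#' proportional bias (slope `beta`); an unbiased tool has (0, 1). This is
#' preferred over the Bland-Altman difference plot when the reference method
#' has negligible measurement error.
#'
#' @param x Gold-standard values (not all equal; n >= 3).
#' @param y Tool measurements.
#' @param nutrient Optional label stored on the fit.
#' @return An object of class `agreement_fit`: list with `alpha`, `beta`,
#'   `alpha_se`, `beta_se`, `n`, `x`, `residuals`, and (after
#'   [fit_variance()]) `s0`, `s1`, `sigma_floor`.
#' @export
fit_calibration <- function(x, y, nutrient = NA_character_) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("gold-standard values are constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  structure(list(
    nutrient = nutrient,
    alpha = unname(stats::coef(fit)[1]),
    beta = unname(stats::coef(fit)[2]),
    alpha_se = sm[1, 2], beta_se = sm[2, 2],
    n = length(x), x = x, y = y,
    residuals = unname(stats::residuals(fit)),
    s0 = NA_real_, s1 = NA_real_, sigma_floor = NA_real_
  ), class = "agreement_fit")
}

#' Heteroscedastic variance function of the tool's measurement error
#'
#' Models the residual standard deviation as linear in the true value:
#' `sigma(x) = s0 + s1 x`, estimated by regressing absolute residuals on `x`
#' and scaling the coefficients by `sqrt(pi / 2)` (the factor relating
#' `E|Z|` to `SD(Z)` under normality). The fitted SD is floored at
#' `sigma_floor = 1e-6 * max(|y|)` so that limits of agreement and
#' coefficients of variation stay defined; a warning is raised when the raw
#' line is non-positive over more than 10% of the observed x range.
#'
#' @param fit An `agreement_fit` from [fit_calibration()].
#' @return The fit with `s0`, `s1`, `sigma_floor` filled in.
#' @export
fit_variance <- function(fit) {
  stopifnot(inherits(fit, "agreement_fit"))
  a <- abs(fit$residuals)
  vf <- stats::lm(a ~ fit$x)
  k <- sqrt(pi / 2)
  fit$s0 <- unname(stats::coef(vf)[1]) * k
  fit$s1 <- unname(stats::coef(vf)[2]) * k
  fit$sigma_floor <- 1e-6 * max(abs(fit$y), 1e-12)
  grid <- seq(min(fit$x), max(fit$x), length.out = 101)
  if (mean(fit$s0 + fit$s1 * grid <= 0) > 0.10) {
    warning("fitted SD line non-positive over >10% of the x range; ",
            "values floored at sigma_floor")
  }
  fit
}

#' Fitted measurement SD at given true values
#'
#' @param fit An `agreement_fit` with variance parameters.
#' @param x True values.
#' @return `pmax(s0 + s1 x, sigma_floor)`.
#' @export
sigma_at <- function(fit, x) {
  stopifnot(inherits(fit, "agreement_fit"), is.finite(fit$s0))
  pmax(fit$s0 + fit$s1 * x, fit$sigma_floor)
}

#' Heteroscedastic 95% limits of agreement
#'
#' Wald-type limits with no transformation: `(alpha + beta x) +/- 1.96
#' sigma(x)` on a grid of true values. About 95% of tool measurements at true
#' value x are expected to fall between the curves; for nutrients measured
#' very noisily near zero (alcohol, typically) the lower curve can cross zero.
#'
#' @param fit An `agreement_fit` with variance parameters.
#' @param x_grid True values at which to evaluate (default: 101 points over
#'   the observed range).
#' @return A tibble: `x`, `fit` (regression line), `lower`, `upper`.
#' @export
limits_of_agreement <- function(fit, x_grid = NULL) {
  stopifnot(inherits(fit, "agreement_fit"), is.finite(fit$s0))
  if (is.null(x_grid)) {
    x_grid <- seq(min(fit$x), max(fit$x), length.out = 101)
  }
  mu <- fit$alpha + fit$beta * x_grid
  s <- sigma_at(fit, x_grid)
  tibble::tibble(x = x_grid, fit = mu, lower = mu - 1.96 * s,
                 upper = mu + 1.96 * s)
}

#' Coefficient-of-variation summary of the tool at true-value percentiles
#'
#' `Cv(x) = sigma(x) / (alpha + beta x)`, evaluated at the 25th, 50th and
#' 75th percentiles (linear-interpolation sample quantiles) of the true
#' values, plus the mean Cv over records. Records where the fitted mean
#' `alpha + beta x` is non-positive have no defined Cv and are excluded from
#' the mean, with the count reported.
#'
#' @param fit An `agreement_fit` with variance parameters.
#' @param x True values of the stratum being summarised (defaults to the
#'   fitting values).
#' @param stratum Label stored in the output (e.g. "all", "foods").
#' @return A one-row tibble: `stratum`, `nutrient`, `cv_q25`, `cv_q50`,
#'   `cv_q75`, `mean_cv`, `n`, `n_excluded`.
#' @export
cv_summary <- function(fit, x = fit$x, stratum = "all") {
  stopifnot(inherits(fit, "agreement_fit"), is.finite(fit$s0))
  cv_at <- function(xx) {
    mu <- fit$alpha + fit$beta * xx
    ifelse(mu > 0, sigma_at(fit, xx) / mu, NA_real_)
  }
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  per_record <- cv_at(x)
  n_excl <- sum(is.na(per_record))
  if (n_excl == length(x)) {
    warning("all records have non-positive fitted mean; mean Cv undefined")
  }
  tibble::tibble(
    stratum = stratum, nutrient = fit$nutrient,
    cv_q25 = cv_at(qs[1]), cv_q50 = cv_at(qs[2]), cv_q75 = cv_at(qs[3]),
    mean_cv = mean(per_record, na.rm = TRUE),
    n = length(x), n_excluded = n_excl
  )
}

#' Fit the full agreement model for one nutrient
#'
#' Convenience wrapper: [fit_calibration()] then [fit_variance()].
#'
#' @param x,y,nutrient See [fit_calibration()].
#' @return An `agreement_fit` with variance parameters.
#' @export
fit_agreement <- function(x, y, nutrient = NA_character_) {
  fit_variance(fit_calibration(x, y, nutrient = nutrient))
}
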