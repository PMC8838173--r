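#' Weight errors for exactly classified segments
#'
#' Portion-size accuracy is assessed on exactly classified (`E`-graded)
#' segments only, so that the tool is not penalised a second time for
#' classification errors. For each retained pair: `error_g = est - true`,
#' `pct_error = 100 (est - true) / true`, `abs_pct_error = |pct_error|`.
#' Known transcription errors can be excluded explicitly; additionally,
#' pairs with `|pct_error|` above `flag_threshold` (default 500%) are flagged
#' in the `flagged` column but never removed silently.
#'
#' @param match_table Match table (see [link_segments()]); only `F`-coded rows
#'   with an `E` grade are used.
#' @param grades Tibble with columns `record_id`, `ref_segment_id`, `grade`.
#' @param reference,app Segment tables providing true and estimated weights.
#' @param exclusions Optional tibble with columns `record_id`,
#'   `ref_segment_id` of pairs to drop (echoed in a message).
#' @param flag_threshold Absolute percentage error above which a pair is
#'   flagged as a suspect outlier.
#' @return A tibble with one row per retained exact pair: identifiers, food
#'   type, true/estimated weight, `error_g`, `pct_error`, `abs_pct_error`,
#'   `flagged`.
#' @export
weight_errors <- function(match_table, grades, reference, app,
                          exclusions = NULL, flag_threshold = 500) {
  found <- match_table[match_table$code == "F", ]
  found <- dplyr::inner_join(
    found, grades[, c("record_id", "ref_segment_id", "grade")],
    by = c("record_id", "ref_segment_id")
  )
  found <- found[found$grade == "E", ]
  if (!is.null(exclusions) && nrow(exclusions)) {
    key <- paste(found$record_id, found$ref_segment_id)
    drop <- key %in% paste(exclusions$record_id, exclusions$ref_segment_id)
    message("weight_errors: excluding ", sum(drop), " pair(s): ",
            paste(utils::head(key[drop], 10), collapse = "; "))
    found <- found[!drop, ]
  }
  if (nrow(found) == 0L) stop("no exact pairs left after exclusions",
                              call. = FALSE)
  ref <- validate_segments(reference, require_positive_weight = TRUE)
  est <- validate_segments(app)
  found$true_weight <- ref$weight_g[match(
    paste(found$record_id, found$ref_segment_id),
    paste(ref$record_id, ref$segment_id))]
  found$food_type <- ref$food_type[match(
    paste(found$record_id, found$ref_segment_id),
    paste(ref$record_id, ref$segment_id))]
  found$est_weight <- est$weight_g[match(
    paste(found$record_id, found$app_segment_id),
    paste(est$record_id, est$segment_id))]
  err <- found$est_weight - found$true_weight
  pct <- 100 * err / found$true_weight
  tibble::tibble(
    record_id = found$record_id,
    ref_segment_id = found$ref_segment_id,
    app_segment_id = found$app_segment_id,
    food_type = found$food_type,
    true_weight = found$true_weight,
    est_weight = found$est_weight,
    error_g = err,
    pct_error = pct,
    abs_pct_error = abs(pct),
    flagged = abs(pct) > flag_threshold
  )
}

#' Paired t-test on true vs estimated values
#'
#' Classical paired t-test on the differences `est - true`. Zero-variance
#' differences (all identical) make the statistic undefined; this is returned
#' as `NA` with `degenerate = TRUE` rather than an error.
#'
#' @param true,est Numeric vectors of equal length (n >= 2).
#' @return A list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(true, est) {
  stopifnot(length(true) == length(est), length(true) >= 2)
  d <- est - true
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(est, true, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Portion-size error summary per taxonomy level
#'
#' Aggregates [weight_errors()] output at the food type, group or category
#' level: mean true and estimated weight, mean error, mean absolute
#' percentage error, accuracy ratio (mean estimated / mean true weight) and a
#' paired t-test of estimated vs true weights, plus boxplot quantiles of the
#' per-segment errors (median, quartiles, 1.5 IQR whiskers) for plotting.
#'
#' @param errors Output of [weight_errors()].
#' @param level `"type"`, `"group"` or `"category"`.
#' @param tax A `food_taxonomy` (used to roll types up for coarser levels).
#' @return A tibble with one row per label at the requested level.
#' @export
group_error_summary <- function(errors, level = c("type", "group", "category"),
                                tax) {
  level <- match.arg(level)
  lab <- roll_up(errors$food_type, tax)[[level]]
  errors$label <- lab
  summarise_one <- function(sub) {
    tt <- if (nrow(sub) >= 2) paired_t_test(sub$true_weight, sub$est_weight)
          else list(t = NA_real_, df = NA_real_, p = NA_real_,
                    degenerate = NA)
    q <- stats::quantile(sub$error_g, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    inl <- sub$error_g[sub$error_g >= q[1] - 1.5 * iqr &
                       sub$error_g <= q[3] + 1.5 * iqr]
    tibble::tibble(
      n = nrow(sub),
      mean_true = mean(sub$true_weight),
      mean_est = mean(sub$est_weight),
      mean_error = mean(sub$error_g),
      mean_abs_pct_error = mean(sub$abs_pct_error),
      accuracy_ratio = mean(sub$est_weight) / mean(sub$true_weight),
      t = tt$t, p = tt$p,
      box_q1 = q[1], box_median = q[2], box_q3 = q[3],
      box_lo = min(inl), box_hi = max(inl)
    )
  }
  out <- dplyr::group_modify(dplyr::group_by(errors, label = .data$label),
                             ~ summarise_one(.x))
  dplyr::ungroup(out)
}
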