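GRADES <- c("E", "C", "F", "M")

#' Grade a classification match between reference and app segments
#'
#' Each found segment gets one of four grades: exact (`E`) when the app label
#' maps to the correct food type (or a synonym of it); close (`C`) when the
#' type is correct but the naming is too generic, refers to a slight product
#' variant, or overlooks an ingredient; far (`F`) when the type is wrong but
#' the food group is correct; mismatch (`M`) when both type and group are
#' wrong. The close-match judgements (`too_generic`, `slight_variant`,
#' `overlooked_ingredient`) are analyst-supplied flags, as in manual coding;
#' this function only enforces the taxonomy logic.
#'
#' @param ref_type,app_type Food types of the paired segments (vectors).
#' @param tax A `food_taxonomy`.
#' @param too_generic,slight_variant,overlooked_ingredient,synonym Logical
#'   vectors of analyst flags (recycled; default all `FALSE`).
#' @return Character vector of grades (`"E"`, `"C"`, `"F"`, `"M"`).
#' @examples
#' tax <- fixture_taxonomy()
#' grade_match("fruiting vegetables", "fruiting vegetables", tax,
#'             synonym = TRUE)            # cherry tomatoes vs tomatoes -> E
#' grade_match("red meat", "red meat", tax,
#'             slight_variant = TRUE)     # beef vs veal -> C
#' grade_match("pasta", "rice", tax)      # same group -> F
#' grade_match("root vegetables", "tubers", tax)  # carrot vs potato -> M
#' @export
grade_match <- function(ref_type, app_type, tax,
                        too_generic = FALSE, slight_variant = FALSE,
                        overlooked_ingredient = FALSE, synonym = FALSE) {
  n <- max(length(ref_type), length(app_type))
  ref_type <- rep_len(ref_type, n)
  app_type <- rep_len(app_type, n)
  close_flag <- rep_len(too_generic, n) | rep_len(slight_variant, n) |
    rep_len(overlooked_ingredient, n)
  d <- taxonomy_distance(ref_type, app_type, tax)
  ifelse(d == 0L, ifelse(close_flag, "C", "E"),
         ifelse(d == 1L, "F", "M"))
}

#' Classification accuracy table
#'
#' Percentages of exact, close, far and mismatch grades among found segments,
#' per stratum, with [proportion_halfwidth()] half-widths. The four
#' percentages sum to 100 in every stratum.
#'
#' @param grades Tibble with columns `stratum` and `grade`
#'   (one row per found segment), or columns `stratum`, `E`, `C`, `F`, `M`
#'   of pre-tabulated counts.
#' @return A tibble with one row per stratum (plus `total` when per-segment
#'   input is given): counts, percentages, half-widths per grade.
#' @export
classification_accuracy <- function(grades) {
  grades <- tibble::as_tibble(grades)
  if (all(GRADES %in% names(grades))) {
    counts <- grades
  } else {
    stopifnot(all(c("stratum", "grade") %in% names(grades)))
    stopifnot(all(grades$grade %in% GRADES))
    tab <- table(factor(grades$stratum), factor(grades$grade, levels = GRADES))
    counts <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "stratum")
    counts <- dplyr::bind_rows(
      tibble::tibble(stratum = "total", E = sum(counts$E), C = sum(counts$C),
                     F = sum(counts$F), M = sum(counts$M)),
      counts
    )
  }
  n <- counts$E + counts$C + counts$F + counts$M
  if (any(n == 0)) {
    stop("stratum with no graded segments: ", counts$stratum[n == 0][1],
         call. = FALSE)
  }
  out <- tibble::tibble(stratum = counts$stratum, n = n)
  for (g in GRADES) {
    out[[paste0("n_", g)]] <- counts[[g]]
    out[[paste0("pct_", g)]] <- 100 * counts[[g]] / n
    out[[paste0("hw_", g)]] <- proportion_halfwidth(counts[[g]], n)
  }
  out
}

#' Confusion table between reference and app labels
#'
#' Builds a square contingency table over the union of labels observed on
#' either side, at the requested taxonomy granularity.
#'
#' @param ref_type,app_type Food types of paired (found) segments.
#' @param tax A `food_taxonomy`.
#' @param level `"type"`, `"group"` or `"category"`.
#' @return A square integer matrix with identical row/column label sets
#'   (reference in rows, app in columns).
#' @export
confusion_table <- function(ref_type, app_type, tax,
                            level = c("type", "group", "category")) {
  level <- match.arg(level)
  r <- roll_up(ref_type, tax)[[level]]
  a <- roll_up(app_type, tax)[[level]]
  labs <- sort(unique(c(r, a)))
  table(factor(r, levels = labs), factor(a, levels = labs))
}

#' Cohen's kappa with asymptotic standard error
#'
#' Chance-corrected reliability `kappa = (Po - Pe) / (1 - Pe)` with observed
#' agreement `Po = trace / n` and chance agreement `Pe` from the product of
#' the marginals. The standard error is the large-sample (Fleiss-Cohen-
#' Everitt) form.
#'
#' @param tab Square count matrix (reference in rows, app in columns).
#' @return A list with `kappa`, `se`, `po`, `pe`, `n`.
#' @export
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  n <- sum(tab)
  if (n < 2) stop("need at least 2 rated items", call. = FALSE)
  p <- tab / n
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pi_ * pj_)
  if (abs(1 - pe) < 1e-12) {
    stop("degenerate table: chance agreement is 1", call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  a <- sum(diag(p) * (1 - (pi_ + pj_) * (1 - kappa))^2)
  b <- (1 - kappa)^2 *
    (sum(p * outer(pj_, pi_, "+")^2) - sum(diag(p) * (pj_ + pi_)^2))
  cc <- (kappa - pe * (1 - kappa))^2
  var_k <- (a + b - cc) / (n * (1 - pe)^2)
  list(kappa = kappa, se = sqrt(max(var_k, 0)), po = po, pe = pe, n = n)
}

#' Brennan-Prediger uniform kappa
#'
#' Chance-corrected agreement with uniform chance probability `1/q`:
#' `Ku = (q Po - 1) / (q - 1)`. In the binary case this is `2 Po - 1`. Unlike
#' Cohen's kappa it does not depend on the marginal label distribution, which
#' makes it the agreement (rather than reliability) indicator of choice when
#' categories are sparse.
#'
#' @param po Observed agreement proportion in `[0, 1]`.
#' @param q Number of categories (>= 2).
#' @return The uniform kappa.
#' @examples
#' uniform_kappa(341 / 345, q = 2)   # 0.977
#' uniform_kappa(331 / 345, q = 37)  # 0.958
#' @export
uniform_kappa <- function(po, q) {
  if (any(q < 2)) stop("q must be >= 2", call. = FALSE)
  stopifnot(all(po >= 0 & po <= 1))
  (q * po - 1) / (q - 1)
}

#' Percentile-bootstrap confidence interval for the uniform kappa
#'
#' Resamples the per-segment 0/1 agreement indicators with replacement and
#' returns percentile bounds for `Ku`.
#'
#' @param agree Logical/0-1 vector: one agreement indicator per rated segment.
#' @param q Number of categories (>= 2).
#' @param B Bootstrap replicates (default 2000; < 100 triggers a warning).
#' @param seed Integer seed (the resampling is fully reproducible).
#' @param conf Confidence level (default 0.95).
#' @return A list with `ku`, `lower`, `upper`, `B`.
#' @export
uniform_kappa_ci <- function(agree, q, B = 2000, seed = 1, conf = 0.95) {
  agree <- as.numeric(agree)
  stopifnot(all(agree %in% c(0, 1)), length(agree) >= 2)
  if (B < 100) warning("B < 100 bootstrap replicates; interval is unstable")
  ku <- uniform_kappa(mean(agree), q)
  n <- length(agree)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      uniform_kappa(mean(agree[sample.int(n, n, replace = TRUE)]), q)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ku = ku, lower = qs[1], upper = qs[2], B = B)
}

#' Sensitivity and specificity with exact Clopper-Pearson intervals
#'
#' For one label treated as the positive class: `sens = TP / (TP + FN)`,
#' `spec = TN / (TN + FP)`, each with an exact binomial 95% interval.
#' A zero-denominator arm is returned as `NA` with `undefined = TRUE`.
#'
#' @param tp,fn,fp,tn Counts of the collapsed 2x2 table.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble with estimates (in %) and CI bounds (in %).
#' @examples
#' sensitivity_specificity(13, 0, 4, 328) # sens 100 [75.3; 100]
#' @export
sensitivity_specificity <- function(tp, fn, fp, tn, conf = 0.95) {
  cp <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
    c(100 * x / n, 100 * ci[1], 100 * ci[2])
  }
  s <- cp(tp, tp + fn)
  p <- cp(tn, tn + fp)
  tibble::tibble(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = s[1], sens_lower = s[2], sens_upper = s[3],
    specificity = p[1], spec_lower = p[2], spec_upper = p[3],
    undefined = (tp + fn == 0) | (tn + fp == 0)
  )
}

#' Per-label binary metrics from a confusion table
#'
#' Collapses a multi-class confusion table into one-vs-rest 2x2 tables and
#' computes Cohen's kappa, uniform kappa (binary, with bootstrap CI) and
#' sensitivity/specificity per label.
#'
#' @param tab Square confusion matrix (reference in rows).
#' @param B,seed Bootstrap settings for the uniform-kappa CI.
#' @return A tibble with one row per label.
#' @export
per_label_metrics <- function(tab, B = 2000, seed = 1) {
  tab <- as.matrix(tab)
  labs <- rownames(tab)
  n <- sum(tab)
  rows <- lapply(seq_along(labs), function(i) {
    tp <- tab[i, i]
    fn <- sum(tab[i, -i])
    fp <- sum(tab[-i, i])
    tn <- n - tp - fn - fp
    two <- matrix(c(tp, fn, fp, tn), 2, byrow = TRUE)
    ck <- cohen_kappa(two)
    agree <- rep(c(1, 0), times = c(tp + tn, fn + fp))
    kci <- uniform_kappa_ci(agree, q = 2, B = B, seed = seed + i)
    ss <- sensitivity_specificity(tp, fn, fp, tn)
    dplyr::bind_cols(
      tibble::tibble(label = labs[i], cohen_kappa = ck$kappa,
                     cohen_se = ck$se, uniform_kappa = kci$ku,
                     ku_lower = kci$lower, ku_upper = kci$upper),
      ss
    )
  })
  dplyr::bind_rows(rows)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of all tables (with the observed margins)
#' whose probability does not exceed the observed table's.
#'
#' @param tab 2x2 count matrix (or 4-vector `c(a, b, c, d)` filled by row).
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  stats::fisher.test(tab)$p.value
}
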