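#' Expand a link table into a full match table
#'
#' Given explicit reference-app segment links (e.g. the ground-truth links of
#' a simulation, or an analyst's manual links covering every pair), codes
#' linked pairs `F`, unlinked reference segments `O` and unlinked app
#' segments `I`.
#'
#' @param links Tibble with columns `record_id`, `ref_segment_id`,
#'   `app_segment_id`.
#' @param reference,app Segment tables.
#' @return A match table like [link_segments()]'s.
#' @export
links_to_match_table <- function(links, reference, app) {
  ref_key <- paste(reference$record_id, reference$segment_id)
  app_key <- paste(app$record_id, app$segment_id)
  l_ref <- paste(links$record_id, links$ref_segment_id)
  l_app <- paste(links$record_id, links$app_segment_id)
  if (anyDuplicated(l_ref) || anyDuplicated(l_app)) {
    stop("conflicting links: a segment is linked twice", call. = FALSE)
  }
  if (!all(l_ref %in% ref_key) || !all(l_app %in% app_key)) {
    stop("link refers to unknown record/segment id", call. = FALSE)
  }
  found <- tibble::tibble(record_id = links$record_id,
                          ref_segment_id = links$ref_segment_id,
                          app_segment_id = links$app_segment_id,
                          code = "F")
  om <- reference[!ref_key %in% l_ref, ]
  omitted <- tibble::tibble(record_id = om$record_id,
                            ref_segment_id = om$segment_id,
                            app_segment_id = NA_integer_, code = "O")
  intr <- app[!app_key %in% l_app, ]
  intruded <- tibble::tibble(record_id = intr$record_id,
                             ref_segment_id = NA_integer_,
                             app_segment_id = intr$segment_id, code = "I")
  dplyr::bind_rows(found, omitted, intruded)
}

## grade all found pairs of a match table, using analyst flags where available
.grade_found <- function(match_table, reference, app, tax, flags = NULL) {
  fnd <- match_table[match_table$code == "F", ]
  ref_t <- reference$food_type[match(
    paste(fnd$record_id, fnd$ref_segment_id),
    paste(reference$record_id, reference$segment_id))]
  app_t <- app$food_type[match(
    paste(fnd$record_id, fnd$app_segment_id),
    paste(app$record_id, app$segment_id))]
  fl <- tibble::tibble(too_generic = rep(FALSE, nrow(fnd)),
                       slight_variant = FALSE,
                       overlooked_ingredient = FALSE, synonym = FALSE)
  if (!is.null(flags)) {
    idx <- match(paste(fnd$record_id, fnd$ref_segment_id),
                 paste(flags$record_id, flags$ref_segment_id))
    for (nm in names(fl)) {
      if (nm %in% names(flags)) {
        v <- flags[[nm]][idx]
        fl[[nm]] <- !is.na(v) & v
      }
    }
  }
  fnd$ref_type <- ref_t
  fnd$app_type <- app_t
  fnd$grade <- grade_match(ref_t, app_t, tax,
                           too_generic = fl$too_generic,
                           slight_variant = fl$slight_variant,
                           overlooked_ingredient = fl$overlooked_ingredient,
                           synonym = fl$synonym)
  fnd
}

#' Run the full four-stage validation pipeline
#'
#' Orchestrates segmentation, classification, portion-size and agreement
#' analyses for one paired study and returns all report tables. All report
#' numbers come from the module functions; this wrapper only arranges inputs.
#'
#' @param reference,app Segment tables (gold standard and tool output).
#' @param tax A `food_taxonomy`.
#' @param links Optional explicit link table (with optional analyst flag
#'   columns); when absent, [link_segments()] links automatically.
#' @param exclusions Optional portion-size exclusion list (see
#'   [weight_errors()]).
#' @param exclude_records Optional record ids to drop from the agreement
#'   analysis.
#' @param B,seed Bootstrap settings for uniform-kappa intervals.
#' @return A list of tibbles: `segmentation`, `classification`,
#'   `global_kappa`, `group_metrics`, `portion` (per level),
#'   `agreement_fits`, `loa`, `cv`, plus the intermediate `match_table` and
#'   `grades`.
#' @export
run_pipeline <- function(reference, app, tax, links = NULL,
                         exclusions = NULL, exclude_records = NULL,
                         B = 2000, seed = 1) {
  reference <- validate_segments(reference, require_positive_weight = TRUE)
  app <- validate_segments(app)

  match_table <- if (is.null(links)) {
    link_segments(reference, app, tax)
  } else {
    links_to_match_table(links, reference, app)
  }

  seg_tab <- segmentation_accuracy(segmentation_coding(match_table, reference))

  graded <- .grade_found(match_table, reference, app, tax, flags = links)
  rt <- record_types(reference)
  graded$stratum <- rt$record_type[match(graded$record_id, rt$record_id)]
  cls_tab <- classification_accuracy(graded[, c("stratum", "grade")])

  # global kappas at the three granularities; type-level agreement counts
  # E and C as correct (both are type-correct by definition), group level
  # counts E, C, F; the label-crosstab diagonal is reported alongside
  q_of <- c(type = attr(tax, "q_type"), group = attr(tax, "q_group"),
            category = attr(tax, "q_category"))
  by_def <- list(type = c("E", "C"), group = c("E", "C", "F"),
                 category = c("E", "C", "F"))
  glob <- lapply(c("type", "group", "category"), function(lv) {
    conf <- confusion_table(graded$ref_type, graded$app_type, tax, level = lv)
    ck <- cohen_kappa(conf)
    agree_def <- graded$grade %in% by_def[[lv]]
    if (lv == "category") {
      # mismatches can still share a category; use the crosstab truth
      agree_def <- roll_up(graded$ref_type, tax)$category ==
        roll_up(graded$app_type, tax)$category
    }
    kci <- uniform_kappa_ci(agree_def, q = q_of[[lv]], B = B, seed = seed)
    tibble::tibble(level = lv, n = ck$n,
                   cohen_kappa = ck$kappa, cohen_se = ck$se,
                   po = mean(agree_def),
                   po_crosstab = sum(diag(conf)) / sum(conf),
                   uniform_kappa = kci$ku,
                   uniform_kappa_crosstab =
                     uniform_kappa(sum(diag(conf)) / sum(conf), q_of[[lv]]),
                   ku_lower = kci$lower, ku_upper = kci$upper)
  })
  glob <- dplyr::bind_rows(glob)

  grp_conf <- confusion_table(graded$ref_type, graded$app_type, tax,
                              level = "group")
  grp_metrics <- per_label_metrics(grp_conf, B = B, seed = seed)

  errors <- weight_errors(match_table, graded, reference, app,
                          exclusions = exclusions)
  portion <- lapply(c("type", "group", "category"), function(lv) {
    out <- group_error_summary(errors, level = lv, tax = tax)
    out$level <- lv
    out
  })
  portion <- dplyr::bind_rows(portion)

  totals <- record_nutrient_totals(reference, app,
                                   exclude_records = exclude_records)
  fits <- list()
  loa <- list()
  cvs <- list()
  for (nu in unique(totals$nutrient)) {
    sub <- totals[totals$nutrient == nu, ]
    fit <- tryCatch(fit_agreement(sub$true, sub$est, nutrient = nu),
                    error = function(e) {
                      warning("agreement fit skipped for ", nu, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    fits[[nu]] <- tibble::tibble(nutrient = nu, alpha = fit$alpha,
                                 beta = fit$beta, alpha_se = fit$alpha_se,
                                 beta_se = fit$beta_se, s0 = fit$s0,
                                 s1 = fit$s1, n = fit$n)
    lo <- limits_of_agreement(fit)
    lo$nutrient <- nu
    loa[[nu]] <- lo
    strata <- list(all = sub$true,
                   foods = sub$true[sub$record_kind == "food"],
                   beverages = sub$true[sub$record_kind == "beverage"])
    strata <- strata[lengths(strata) > 0]
    cvs[[nu]] <- dplyr::bind_rows(lapply(names(strata), function(st) {
      cv_summary(fit, x = strata[[st]], stratum = st)
    }))
  }

  list(match_table = match_table, grades = graded,
       segmentation = seg_tab, classification = cls_tab,
       global_kappa = glob, group_metrics = grp_metrics,
       portion = portion, weight_error_detail = errors,
       agreement_fits = dplyr::bind_rows(fits),
       loa = dplyr::bind_rows(loa), cv = dplyr::bind_rows(cvs))
}
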