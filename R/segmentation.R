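#' Normal-approximation half-width for a proportion, in percent
#'
#' The convention used throughout the segmentation and classification report
#' tables: `100 * 1.96 * sqrt(p (1 - p) / (n - 1))` with `p = x / n`. The
#' `n - 1` denominator (the unbiased variance of the 0/1 indicators divided by
#' n, i.e. the sample-SD-based standard error) is what validation reports in
#' this field print next to their proportions.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 2).
#' @return Half-width in percentage points.
#' @examples
#' proportion_halfwidth(345, 352) # 1.5
#' proportion_halfwidth(13, 31)   # 17.7
#' @export
proportion_halfwidth <- function(x, n) {
  stopifnot(length(n) == length(x) || length(n) == 1L || length(x) == 1L)
  if (any(n < 2)) stop("n must be >= 2", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must lie in [0, n]", call. = FALSE)
  p <- x / n
  100 * 1.96 * sqrt(p * (1 - p) / (n - 1))
}

## cost of linking one reference to one app segment: taxonomy distance
## (0 same type, 1 same group, 2 same category, 3 unrelated) plus a
## normalized weight difference in [0, 1) so weight only breaks taxonomy ties
.link_cost <- function(ref_type, app_type, ref_w, app_w, tax) {
  d <- taxonomy_distance(ref_type, app_type, tax)
  nwd <- abs(ref_w - app_w) / pmax(ref_w, app_w, 1e-9)
  d + 0.999 * pmin(nwd, 1)
}

## exact maximum matching (most links, then least total cost) by
## branch-and-bound over reference segments; cost must be <= threshold for a
## pair to be linkable. Returns integer vector: app index per ref (NA = none).
.match_exact <- function(cost, threshold) {
  n_ref <- nrow(cost)
  n_app <- ncol(cost)
  best <- list(links = -1L, cost = Inf, assign = rep(NA_integer_, n_ref))
  assign <- rep(NA_integer_, n_ref)
  used <- rep(FALSE, n_app)

  recurse <- function(i, links, total) {
    if (i > n_ref) {
      if (links > best$links ||
          (links == best$links && total < best$cost - 1e-12)) {
        best <<- list(links = links, cost = total, assign = assign)
      }
      return(invisible())
    }
    # bound: even linking every remaining ref cannot beat best
    if (links + (n_ref - i + 1L) < best$links) return(invisible())
    cand <- which(!used & cost[i, ] <= threshold)
    cand <- cand[order(cost[i, cand], cand)]
    for (j in cand) {
      assign[i] <<- j
      used[j] <<- TRUE
      recurse(i + 1L, links + 1L, total + cost[i, j])
      used[j] <<- FALSE
      assign[i] <<- NA_integer_
    }
    recurse(i + 1L, links, total)
  }
  recurse(1L, 0L, 0)
  best$assign
}

## greedy fallback for implausibly large records
.match_greedy <- function(cost, threshold) {
  n_ref <- nrow(cost)
  assign <- rep(NA_integer_, n_ref)
  used <- rep(FALSE, ncol(cost))
  repeat {
    m <- cost
    m[!is.na(assign), ] <- Inf
    m[, used] <- Inf
    if (all(!is.finite(m)) || min(m) > threshold) break
    ij <- which(m == min(m), arr.ind = TRUE)[1, ]
    assign[ij[1]] <- ij[2]
    used[ij[2]] <- TRUE
  }
  assign
}

#' Link app-detected segments to reference segments
#'
#' Pairs each tool-detected segment with at most one reference segment within
#' the same record (and vice versa), coding linked reference segments as found
#' (`F`), unlinked reference segments as omissions (`O`) and unlinked app
#' segments as intrusions (`I`). Linking minimises a taxonomy-distance cost
#' (exact optimal matching per record; a pair is only linkable when its cost
#' is at most `threshold`). Explicit `manual_links` override the automatic
#' matching for their record, reproducing the manual-linking workflow of a
#' human coder.
#'
#' @param reference,app Segment tables (see [validate_segments()]).
#' @param tax A `food_taxonomy` covering all segment types.
#' @param manual_links Optional tibble with columns `record_id`,
#'   `ref_segment_id`, `app_segment_id`.
#' @param threshold Maximum linking cost (default 2: same category or closer).
#' @return A match table: `record_id`, `ref_segment_id`, `app_segment_id`,
#'   `code` (`F`/`O`/`I`). Every reference and app segment appears exactly
#'   once.
#' @export
link_segments <- function(reference, app, tax, manual_links = NULL,
                          threshold = 2) {
  reference <- validate_segments(reference, require_positive_weight = TRUE)
  app <- validate_segments(app)

  extra <- setdiff(unique(app$record_id), unique(reference$record_id))
  if (length(extra)) {
    stop("app records with no reference counterpart: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  if (!is.null(manual_links) && nrow(manual_links)) {
    k1 <- paste(manual_links$record_id, manual_links$ref_segment_id)
    k2 <- paste(manual_links$record_id, manual_links$app_segment_id)
    if (anyDuplicated(k1) || anyDuplicated(k2)) {
      stop("conflicting manual links (segment linked twice)", call. = FALSE)
    }
    ok_ref <- k1 %in% paste(reference$record_id, reference$segment_id)
    ok_app <- k2 %in% paste(app$record_id, app$segment_id)
    if (!all(ok_ref) || !all(ok_app)) {
      stop("manual link refers to unknown record/segment id", call. = FALSE)
    }
  }

  out <- lapply(unique(reference$record_id), function(id) {
    r <- reference[reference$record_id == id, ]
    a <- app[app$record_id == id, ]
    r <- r[order(r$segment_id), ]
    a <- a[order(a$segment_id), ]

    assign <- rep(NA_integer_, nrow(r))
    locked_app <- rep(FALSE, nrow(a))
    if (!is.null(manual_links) && nrow(manual_links)) {
      ml <- manual_links[manual_links$record_id == id, , drop = FALSE]
      for (k in seq_len(nrow(ml))) {
        i <- match(ml$ref_segment_id[k], r$segment_id)
        j <- match(ml$app_segment_id[k], a$segment_id)
        assign[i] <- j
        locked_app[j] <- TRUE
      }
    }
    free_ref <- which(is.na(assign))
    free_app <- which(!locked_app)
    if (length(free_ref) && length(free_app)) {
      cost <- outer(free_ref, free_app, function(i, j) {
        .link_cost(r$food_type[i], a$food_type[j],
                   r$weight_g[i], a$weight_g[j], tax)
      })
      sub <- if (max(length(free_ref), length(free_app)) <= 8L) {
        .match_exact(cost, threshold)
      } else {
        .match_greedy(cost, threshold)
      }
      assign[free_ref] <- free_app[sub]
    }

    linked_app <- assign[!is.na(assign)]
    tibble::tibble(
      record_id = id,
      ref_segment_id = c(r$segment_id,
                         rep(NA_integer_, sum(!seq_len(nrow(a)) %in% linked_app))),
      app_segment_id = c(a$segment_id[assign],
                         a$segment_id[!seq_len(nrow(a)) %in% linked_app]),
      code = c(ifelse(is.na(assign), "O", "F"),
               rep("I", sum(!seq_len(nrow(a)) %in% linked_app)))
    )
  })
  dplyr::bind_rows(out)
}

#' Count found / omitted / intruded segments per record type
#'
#' @param match_table Output of [link_segments()] (or a ground-truth link
#'   table with the same columns).
#' @param reference Reference segment table (defines record types).
#' @return A tibble with one row per record type plus a `total` row: columns
#'   `stratum`, `found`, `omitted`, `intruded`, `n_true`.
#' @export
segmentation_coding <- function(match_table, reference) {
  types <- record_types(reference)
  mt <- dplyr::left_join(match_table,
                         types[, c("record_id", "record_type")],
                         by = "record_id")
  per <- dplyr::summarise(
    dplyr::group_by(mt, stratum = .data$record_type),
    found = sum(.data$code == "F"),
    omitted = sum(.data$code == "O"),
    intruded = sum(.data$code == "I"),
    .groups = "drop"
  )
  tot <- tibble::tibble(stratum = "total",
                        found = sum(per$found),
                        omitted = sum(per$omitted),
                        intruded = sum(per$intruded))
  out <- dplyr::bind_rows(tot, per)
  out$n_true <- out$found + out$omitted
  out
}

#' Segmentation accuracy table
#'
#' Percentages of found, omitted and intruded segments over the total number
#' of true (reference) segments in each stratum, with the half-width
#' convention of [proportion_halfwidth()]. Intrusions are reported over the
#' same denominator even though they are not a subset of the reference
#' segments, so the three percentages may sum to more than 100.
#'
#' @param coding Tibble with columns `stratum`, `found`, `omitted`,
#'   `intruded` (one row per stratum), e.g. from [segmentation_coding()].
#' @return A tibble with counts, percentages and half-widths per stratum.
#' @export
segmentation_accuracy <- function(coding) {
  coding <- tibble::as_tibble(coding)
  stopifnot(all(c("stratum", "found", "omitted", "intruded") %in% names(coding)))
  n_true <- coding$found + coding$omitted
  if (any(n_true == 0)) {
    stop("stratum with no reference segments: ",
         coding$stratum[n_true == 0][1], call. = FALSE)
  }
  tibble::tibble(
    stratum = coding$stratum,
    n_true = n_true,
    found = coding$found,
    pct_found = 100 * coding$found / n_true,
    hw_found = proportion_halfwidth(coding$found, n_true),
    omitted = coding$omitted,
    pct_omitted = 100 * coding$omitted / n_true,
    hw_omitted = proportion_halfwidth(coding$omitted, n_true),
    intruded = coding$intruded,
    pct_intruded = 100 * coding$intruded / n_true,
    hw_intruded = proportion_halfwidth(pmin(coding$intruded, n_true), n_true)
  )
}
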