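NUTRIENTS <- c("energy_kcal", "fat_g", "carb_g", "protein_g", "fiber_g",
               "alcohol_g")

SEGMENT_COLS <- c("record_id", "record_kind", "entry_mode", "segment_id",
                  "label", "food_type", "weight_g", NUTRIENTS)

#' Validate a segment table
#'
#' Records (one photographed dish/beverage or one scanned product) are held in
#' long form: one row per segment, identified by (`record_id`, `segment_id`),
#' with the record-level fields `record_kind` ("food"/"beverage") and
#' `entry_mode` ("photo"/"scan") repeated on each row. Nutrient columns hold
#' the content of the whole segment (not per 100 g).
#'
#' @param segments Data frame of segments.
#' @param require_positive_weight If `TRUE`, weights must be strictly positive
#'   (reference records); app estimates may be zero.
#' @return The validated segments as a tibble.
#' @export
validate_segments <- function(segments, require_positive_weight = FALSE) {
  segments <- tibble::as_tibble(segments)
  miss <- setdiff(SEGMENT_COLS, names(segments))
  if (length(miss)) {
    stop("segment table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(segments$record_kind), c("food", "beverage"))
  if (length(bad_kind)) stop("unknown record_kind: ", bad_kind[1], call. = FALSE)
  bad_mode <- setdiff(unique(segments$entry_mode), c("photo", "scan"))
  if (length(bad_mode)) stop("unknown entry_mode: ", bad_mode[1], call. = FALSE)
  if (!all(is.finite(segments$weight_g))) {
    stop("non-finite segment weights", call. = FALSE)
  }
  lo <- if (require_positive_weight) 0 else -1e-12
  if (any(segments$weight_g <= lo)) {
    stop("segment weights must be ",
         if (require_positive_weight) "positive" else "non-negative",
         call. = FALSE)
  }
  for (nm in NUTRIENTS) {
    if (!all(is.finite(segments[[nm]])) || any(segments[[nm]] < 0)) {
      stop("nutrient column '", nm, "' must be finite and non-negative",
           call. = FALSE)
    }
  }
  key <- paste(segments$record_id, segments$segment_id)
  if (anyDuplicated(key)) {
    stop("duplicated (record_id, segment_id)", call. = FALSE)
  }
  segments[, SEGMENT_COLS]
}

#' Write records to JSON-lines
#'
#' One JSON object per line: `{record_id, record_kind, entry_mode,
#' segments: [{segment_id, label, food_type, weight_g, nutrients: {...}}]}`.
#'
#' @param segments Segment table (see [validate_segments()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(segments, path) {
  segments <- validate_segments(segments)
  ids <- unique(segments$record_id)
  lines <- vapply(ids, function(id) {
    sub <- segments[segments$record_id == id, ]
    segs <- lapply(seq_len(nrow(sub)), function(i) {
      list(segment_id = sub$segment_id[i],
           label = sub$label[i],
           food_type = sub$food_type[i],
           weight_g = sub$weight_g[i],
           nutrients = as.list(sub[i, NUTRIENTS]))
    })
    jsonlite::toJSON(list(record_id = id,
                          record_kind = sub$record_kind[1],
                          entry_mode = sub$entry_mode[1],
                          segments = segs),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read records from JSON-lines
#'
#' @param path Path to a JSON-lines records file written by [write_records()].
#' @return A validated segment tibble.
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    do.call(rbind, lapply(rec$segments, function(s) {
      data.frame(record_id = rec$record_id,
                 record_kind = rec$record_kind,
                 entry_mode = rec$entry_mode,
                 segment_id = s$segment_id,
                 label = s$label,
                 food_type = s$food_type,
                 weight_g = s$weight_g,
                 energy_kcal = s$nutrients$energy_kcal,
                 fat_g = s$nutrients$fat_g,
                 carb_g = s$nutrients$carb_g,
                 protein_g = s$nutrients$protein_g,
                 fiber_g = s$nutrients$fiber_g,
                 alcohol_g = s$nutrients$alcohol_g)
    }))
  })
  validate_segments(do.call(rbind, rows))
}

#' Classify records into the four study record types
#'
#' Record types are a function of the reference segment count and the
#' food/beverage flag: composite foods have >= 3 segments, simple foods 1-2,
#' composite beverages >= 2, simple beverages exactly 1.
#'
#' @param reference Reference segment table.
#' @return A tibble with one row per record: `record_id`, `record_kind`,
#'   `entry_mode`, `n_segments`, `record_type`.
#' @export
record_types <- function(reference) {
  reference <- validate_segments(reference)
  per <- dplyr::summarise(
    dplyr::group_by(reference, .data$record_id),
    record_kind = .data$record_kind[1],
    entry_mode = .data$entry_mode[1],
    n_segments = dplyr::n(),
    .groups = "drop"
  )
  per$record_type <- ifelse(
    per$record_kind == "food",
    ifelse(per$n_segments >= 3, "composite_food", "simple_food"),
    ifelse(per$n_segments >= 2, "composite_beverage", "simple_beverage")
  )
  per
}

#' Read / write manual segment links
#'
#' A links file is a CSV with columns `record_id`, `ref_segment_id`,
#' `app_segment_id` and optional logical flag columns `too_generic`,
#' `slight_variant`, `overlooked_ingredient`, `synonym` used for match
#' grading.
#'
#' @param path File path.
#' @return For `read_links`, a tibble of links.
#' @export
read_links <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param links Link table.
#' @rdname read_links
#' @export
write_links <- function(links, path) {
  utils::write.csv(links, path, row.names = FALSE)
  invisible(path)
}
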