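#' Synthetic food-composition table
#'
#' A fixture table of ~40 foods and beverages with invented but physiologic
#' per-100 g composition values (energy in kcal; fat, carbohydrate, protein,
#' fiber, alcohol in g), a typical portion weight (geometric mean, g) used by
#' the study generator, and flags marking beverages and beverage additives
#' (milk, sugar) that form the extra segments of composite beverages. This is
#' a synthetic stand-in for the national food-composition databases used in
#' real validation studies.
#'
#' @return A tibble with one row per item.
#' @export
default_composition <- function() {
  c0 <- function(label, type, kcal, fat, carb, prot, fib, alc, w,
                 bev = FALSE, additive = FALSE) {
    tibble::tibble(label = label, food_type = type, energy_kcal_100g = kcal,
                   fat_g_100g = fat, carb_g_100g = carb, protein_g_100g = prot,
                   fiber_g_100g = fib, alcohol_g_100g = alc,
                   typical_weight_g = w, is_beverage = bev,
                   is_additive = additive)
  }
  dplyr::bind_rows(
    c0("spaghetti", "pasta", 157, 0.9, 30, 5.8, 1.8, 0, 180),
    c0("white bread", "bread", 265, 3.2, 49, 9, 2.7, 0, 60),
    c0("boiled rice", "rice", 130, 0.3, 28, 2.7, 0.4, 0, 150),
    c0("risotto", "rice dishes", 166, 5.4, 25, 3.9, 0.9, 0.3, 200),
    c0("boiled potatoes", "tubers", 87, 0.1, 20, 1.9, 1.8, 0, 180),
    c0("lentils", "legumes", 116, 0.4, 20, 9, 7.9, 0, 150),
    c0("green salad", "leafy vegetables", 15, 0.2, 2.9, 1.4, 1.3, 0, 50),
    c0("spinach", "leafy vegetables", 23, 0.4, 3.6, 2.9, 2.2, 0, 120),
    c0("carrots", "root vegetables", 41, 0.2, 10, 0.9, 2.8, 0, 100),
    c0("tomatoes", "fruiting vegetables", 18, 0.2, 3.9, 0.9, 1.2, 0, 90),
    c0("zucchini", "fruiting vegetables", 17, 0.3, 3.1, 1.2, 1, 0, 110),
    c0("apple", "pome & stone fruit", 52, 0.2, 14, 0.3, 2.4, 0, 150),
    c0("strawberries", "berries", 32, 0.3, 7.7, 0.7, 2, 0, 120),
    c0("beef steak", "red meat", 217, 12, 0, 26, 0, 0, 150),
    c0("pork chop", "red meat", 231, 14, 0, 25, 0, 0, 140),
    c0("chicken breast", "poultry", 165, 3.6, 0, 31, 0, 0, 130),
    c0("salmon fillet", "fish & seafood", 208, 13, 0, 20, 0, 0, 125),
    c0("shrimps", "fish & seafood", 99, 0.3, 0.2, 24, 0, 0, 80),
    c0("sausage", "processed meat", 301, 27, 2, 12, 0, 0, 100),
    c0("boiled egg", "eggs", 155, 11, 1.1, 13, 0, 0, 60),
    c0("tofu", "meat substitutes", 76, 4.8, 1.9, 8, 0.3, 0, 100),
    c0("gruyere cheese", "cheese", 413, 32, 0.4, 30, 0, 0, 40),
    c0("plain yogurt", "yogurt", 61, 3.3, 4.7, 3.5, 0, 0, 150),
    c0("almonds", "nuts & seeds", 579, 50, 22, 21, 12.5, 0, 30),
    c0("olive oil", "oils", 884, 100, 0, 0, 0, 0, 10),
    c0("butter", "butter & cream", 717, 81, 0.1, 0.9, 0, 0, 12),
    c0("potato chips", "salty snacks", 536, 35, 53, 7, 4.8, 0, 40),
    c0("chocolate cake", "pastries & desserts", 371, 15, 53, 5.3, 2.2, 0, 90),
    c0("milk chocolate", "chocolate & confectionery", 535, 30, 59, 7.7, 3.4, 0, 25),
    c0("sugar", "sugar & honey", 387, 0, 100, 0, 0, 0, 8, additive = TRUE),
    c0("tomato sauce", "sauces", 82, 4.8, 8.8, 1.5, 1.8, 0, 80),
    c0("salad dressing", "sauces", 449, 45, 7, 1, 0.3, 0, 30),
    c0("mustard", "condiments", 66, 3.3, 5.8, 4.4, 3.3, 0, 10),
    c0("vegetable soup", "soups", 36, 1.2, 5, 1.4, 1.2, 0, 250),
    c0("black tea", "tea", 1, 0, 0.3, 0, 0, 0, 250, bev = TRUE),
    c0("espresso", "coffee", 2, 0, 0, 0.3, 0, 0, 60, bev = TRUE),
    c0("orange juice", "fruit juice", 45, 0.2, 10.4, 0.7, 0.2, 0, 200, bev = TRUE),
    c0("cola", "soft drink", 42, 0, 10.6, 0, 0, 0, 330, bev = TRUE),
    c0("red wine", "beer & wine", 85, 0, 2.6, 0.1, 0, 10.6, 150, bev = TRUE),
    c0("lager beer", "beer & wine", 43, 0, 3.6, 0.5, 0, 3.9, 330, bev = TRUE),
    c0("mojito", "spirits & cocktails", 80, 0, 8, 0, 0, 7, 200, bev = TRUE),
    c0("whole milk", "milk", 64, 3.6, 4.8, 3.3, 0, 0, 200, bev = TRUE,
       additive = TRUE),
    c0("oat drink", "plant milk", 46, 1.5, 6.6, 1, 0.8, 0, 200, bev = TRUE)
  )
}

#' Study design configuration
#'
#' Record counts per type default to the design of a ~190-record validation
#' study: 63 composite foods (>= 3 segments), 63 simple foods (1-2 segments),
#' 30 composite beverages (>= 2 segments), 33 simple beverages (1 segment),
#' with 15 of the simple records entered by barcode scan rather than photo.
#'
#' @param n_composite_food,n_simple_food,n_composite_beverage,n_simple_beverage
#'   Record counts (>= 0).
#' @param n_scan Number of scanned records, drawn from the simple foods then
#'   the simple beverages.
#' @param seed Integer seed fixing the whole generated stream.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_composite_food = 63, n_simple_food = 63,
                         n_composite_beverage = 30, n_simple_beverage = 33,
                         n_scan = 15, seed = 1) {
  counts <- c(n_composite_food, n_simple_food, n_composite_beverage,
              n_simple_beverage)
  stopifnot(all(counts >= 0), n_scan >= 0)
  if (n_scan > n_simple_food + n_simple_beverage) {
    stop("n_scan exceeds the number of simple records", call. = FALSE)
  }
  structure(list(n_composite_food = n_composite_food,
                 n_simple_food = n_simple_food,
                 n_composite_beverage = n_composite_beverage,
                 n_simple_beverage = n_simple_beverage,
                 n_scan = n_scan, seed = as.integer(seed)),
            class = "study_config")
}

#' Measurement-error model of the simulated tool
#'
#' Governs how [simulate_app()] corrupts a reference study: per-segment
#' omission probability, per-record intrusion probability (intrusions are
#' drawn as condiment/sauce segments, the typical spurious detection),
#' per-record-type grade probabilities (exact/close/far/mismatch) emulating
#' the taxonomic confusion structure — composite beverages are hardest, with
#' an exact-match rate near 0.42 — and multiplicative log-normal weight noise
#' with group-specific bias factors (meat and fish portions tend to be
#' overestimated). Scanned records are error-free. An optional heavy-tail
#' mixture reproduces occasional extreme portion errors (roughly -90% to
#' +250%).
#'
#' @param p_omit Per-segment omission probability (photo records).
#' @param p_intrude Per-record intrusion probability (photo food records).
#' @param grade_probs 4x4 matrix of grade probabilities; rows
#'   `composite_food`, `simple_food`, `composite_beverage`, `simple_beverage`;
#'   columns `E`, `C`, `F`, `M`; rows sum to 1.
#' @param weight_sdlog SD of the log multiplicative weight error.
#' @param group_bias Named vector of geometric-mean bias factors per food
#'   group (groups not named get 1).
#' @param heavy_tail If `TRUE`, a fraction `p_heavy` of segments get noise SD
#'   `sdlog_heavy` instead.
#' @param p_heavy,sdlog_heavy Heavy-tail mixture parameters.
#' @return A list of class `error_model`.
#' @export
error_model <- function(p_omit = 0.02, p_intrude = 5 / 189,
                        grade_probs = NULL, weight_sdlog = 0.35,
                        group_bias = c("Meat & poultry" = 1.25,
                                       "Fish & seafood" = 1.25,
                                       "Eggs & meat substitutes" = 1.20,
                                       "Potatoes, legumes & beans" = 1.15),
                        heavy_tail = FALSE, p_heavy = 0.05,
                        sdlog_heavy = 0.9) {
  if (is.null(grade_probs)) {
    grade_probs <- rbind(
      composite_food = c(0.90, 0.07, 0.02, 0.01),
      simple_food = c(0.96, 0.04, 0.00, 0.00),
      composite_beverage = c(0.42, 0.39, 0.00, 0.19),
      simple_beverage = c(0.94, 0.00, 0.00, 0.06)
    )
    colnames(grade_probs) <- GRADES
  }
  stopifnot(p_omit >= 0, p_omit <= 1, p_intrude >= 0, p_intrude <= 1,
            all(grade_probs >= 0),
            all(abs(rowSums(grade_probs) - 1) < 1e-9))
  structure(list(p_omit = p_omit, p_intrude = p_intrude,
                 grade_probs = grade_probs, weight_sdlog = weight_sdlog,
                 group_bias = group_bias, heavy_tail = heavy_tail,
                 p_heavy = p_heavy, sdlog_heavy = sdlog_heavy),
            class = "error_model")
}

#' Error-free tool model
#'
#' All error probabilities zero and zero weight noise; running the pipeline on
#' such a simulation must report perfect segmentation, classification and
#' agreement, which is the round-trip check of the whole framework.
#'
#' @return An `error_model`.
#' @export
noiseless_error_model <- function() {
  gp <- matrix(rep(c(1, 0, 0, 0), each = 4), 4,
               dimnames = list(c("composite_food", "simple_food",
                                 "composite_beverage", "simple_beverage"),
                               GRADES))
  error_model(p_omit = 0, p_intrude = 0, grade_probs = gp, weight_sdlog = 0,
              group_bias = numeric(0))
}

## draw one record's worth of reference segments
.draw_record <- function(id, rtype, mode, comp) {
  foods <- comp[!comp$is_beverage, ]
  bevs <- comp[comp$is_beverage, ]
  adds <- comp[comp$is_additive, ]
  items <- switch(
    rtype,
    composite_food = foods[sample.int(nrow(foods),
                                      min(3 + stats::rpois(1, 0.15),
                                          nrow(foods))), ],
    simple_food = foods[sample.int(nrow(foods),
                                   1 + stats::rbinom(1, 1, 0.2)), ],
    composite_beverage = rbind(
      bevs[sample.int(nrow(bevs), 1), ],
      adds[sample.int(nrow(adds),
                      min(1 + stats::rpois(1, 0.05), nrow(adds))), ]),
    simple_beverage = bevs[sample.int(nrow(bevs), 1), ]
  )
  w <- stats::rlnorm(nrow(items), meanlog = log(items$typical_weight_g),
                     sdlog = 0.3)
  tibble::tibble(
    record_id = id,
    record_kind = if (grepl("beverage", rtype)) "beverage" else "food",
    entry_mode = mode,
    segment_id = seq_len(nrow(items)),
    label = items$label,
    food_type = items$food_type,
    weight_g = w,
    energy_kcal = w * items$energy_kcal_100g / 100,
    fat_g = w * items$fat_g_100g / 100,
    carb_g = w * items$carb_g_100g / 100,
    protein_g = w * items$protein_g_100g / 100,
    fiber_g = w * items$fiber_g_100g / 100,
    alcohol_g = w * items$alcohol_g_100g / 100
  )
}

#' Generate a synthetic reference (weighed-diary) study
#'
#' Draws records of each type with segment items sampled from the composition
#' table, log-normal portion weights around each item's typical weight, and
#' nutrient vectors computed as `weight x per-100g composition / 100`.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [study_config()].
#' @param tax A `food_taxonomy` covering the composition table's types.
#' @param composition Composition table (default [default_composition()]).
#' @return A validated reference segment tibble.
#' @export
generate_reference <- function(cfg, tax = fixture_taxonomy(),
                               composition = default_composition()) {
  stopifnot(inherits(cfg, "study_config"))
  if (nrow(composition) == 0) stop("empty composition table", call. = FALSE)
  roll_up(composition$food_type, tax)  # errors on unknown types

  rtypes <- rep(c("composite_food", "simple_food", "composite_beverage",
                  "simple_beverage"),
                times = c(cfg$n_composite_food, cfg$n_simple_food,
                          cfg$n_composite_beverage, cfg$n_simple_beverage))
  modes <- rep("photo", length(rtypes))
  simple_idx <- which(rtypes %in% c("simple_food", "simple_beverage"))
  modes[simple_idx[seq_len(cfg$n_scan)]] <- "scan"

  withr::with_seed(cfg$seed, {
    recs <- lapply(seq_along(rtypes), function(i) {
      .draw_record(sprintf("R%03d", i), rtypes[i], modes[i], composition)
    })
    validate_segments(dplyr::bind_rows(recs),
                      require_positive_weight = TRUE)
  })
}

## pick a confused food type for far matches / mismatches; only types with a
## composition item are eligible so app nutrients can be computed
.confused_type <- function(true_type, grade, tax, eligible) {
  info <- roll_up(true_type, tax)
  pool <- if (grade == "F") {
    tax$type[tax$group == info$group & tax$type != true_type]
  } else {
    tax$type[tax$group != info$group]
  }
  pool <- intersect(pool, eligible)
  if (!length(pool) && grade == "F") {
    # no within-group sibling with composition data: degrade to mismatch
    pool <- intersect(tax$type[tax$group != info$group], eligible)
  }
  sample(pool, 1)
}

#' Simulate tool observations of a reference study
#'
#' Applies the error model segment by segment: omissions, taxonomic
#' confusions drawn from the per-record-type grade distribution, close-match
#' flags, multiplicative weight noise with group bias, and per-record
#' intrusions (spurious sauce segments on photographed food records). Scanned
#' records are copied through error-free. Alongside the simulated app records
#' it returns the ground-truth link table (with analyst flags and the intended
#' grade), which lets tests bypass automatic linking.
#'
#' @param reference Reference segment table from [generate_reference()].
#' @param em An [error_model()].
#' @param tax A `food_taxonomy`.
#' @param composition Composition table (source of app-side nutrient values).
#' @param seed Integer seed.
#' @return A list with elements `app` (segment tibble) and `links` (tibble
#'   with columns `record_id`, `ref_segment_id`, `app_segment_id`,
#'   `too_generic`, `slight_variant`, `overlooked_ingredient`, `synonym`,
#'   `true_grade`).
#' @export
simulate_app <- function(reference, em, tax = fixture_taxonomy(),
                         composition = default_composition(), seed = 1) {
  stopifnot(inherits(em, "error_model"))
  reference <- validate_segments(reference, require_positive_weight = TRUE)
  rtypes <- record_types(reference)
  eligible <- unique(composition$food_type)
  bias_of <- function(group) {
    b <- em$group_bias[group]
    ifelse(is.na(b), 1, b)
  }
  ref_groups <- roll_up(reference$food_type, tax)$group
  dressing <- composition[composition$label == "salad dressing", ]

  withr::with_seed(seed, {
    app_rows <- list()
    link_rows <- list()
    k <- 0L
    for (id in unique(reference$record_id)) {
      r <- reference[reference$record_id == id, ]
      gr <- ref_groups[reference$record_id == id]
      rt <- rtypes$record_type[rtypes$record_id == id]
      scan <- r$entry_mode[1] == "scan"
      next_app_id <- 0L
      for (i in seq_len(nrow(r))) {
        if (!scan && stats::runif(1) < em$p_omit) next  # omitted
        grade <- if (scan) "E" else {
          sample(GRADES, 1, prob = em$grade_probs[rt, ])
        }
        flags <- c(too_generic = FALSE, slight_variant = FALSE,
                   overlooked_ingredient = FALSE, synonym = FALSE)
        if (grade == "E" && !scan && stats::runif(1) < 0.3) {
          flags["synonym"] <- TRUE
        }
        if (grade == "C") {
          flags[sample(c("too_generic", "slight_variant",
                         "overlooked_ingredient"), 1)] <- TRUE
        }
        if (grade %in% c("E", "C")) {
          app_type <- r$food_type[i]
          item <- r[i, ]
          per100 <- c(item$energy_kcal, item$fat_g, item$carb_g,
                      item$protein_g, item$fiber_g,
                      item$alcohol_g) / item$weight_g * 100
          app_label <- if (grade == "C") paste0(r$label[i], " (generic)")
                       else r$label[i]
        } else {
          app_type <- .confused_type(r$food_type[i], grade, tax, eligible)
          cand <- composition[composition$food_type == app_type, ]
          item <- cand[sample.int(nrow(cand), 1), ]
          per100 <- c(item$energy_kcal_100g, item$fat_g_100g,
                      item$carb_g_100g, item$protein_g_100g,
                      item$fiber_g_100g, item$alcohol_g_100g)
          app_label <- item$label
        }
        w <- if (scan || em$weight_sdlog == 0) {
          r$weight_g[i] * bias_of(gr[i])^(!scan)
        } else {
          sdl <- if (em$heavy_tail && stats::runif(1) < em$p_heavy) {
            em$sdlog_heavy
          } else {
            em$weight_sdlog
          }
          r$weight_g[i] * bias_of(gr[i]) * stats::rlnorm(1, 0, sdl)
        }
        next_app_id <- next_app_id + 1L
        k <- k + 1L
        app_rows[[k]] <- tibble::tibble(
          record_id = id, record_kind = r$record_kind[1],
          entry_mode = r$entry_mode[1], segment_id = next_app_id,
          label = app_label, food_type = app_type, weight_g = w,
          energy_kcal = w * per100[1] / 100, fat_g = w * per100[2] / 100,
          carb_g = w * per100[3] / 100, protein_g = w * per100[4] / 100,
          fiber_g = w * per100[5] / 100, alcohol_g = w * per100[6] / 100)
        link_rows[[k]] <- tibble::tibble(
          record_id = id, ref_segment_id = r$segment_id[i],
          app_segment_id = next_app_id,
          too_generic = unname(flags["too_generic"]),
          slight_variant = unname(flags["slight_variant"]),
          overlooked_ingredient = unname(flags["overlooked_ingredient"]),
          synonym = unname(flags["synonym"]), true_grade = grade)
      }
      if (!scan && r$record_kind[1] == "food" &&
          stats::runif(1) < em$p_intrude) {
        w <- stats::rlnorm(1, log(dressing$typical_weight_g), 0.3)
        next_app_id <- next_app_id + 1L
        k <- k + 1L
        app_rows[[k]] <- tibble::tibble(
          record_id = id, record_kind = "food",
          entry_mode = r$entry_mode[1], segment_id = next_app_id,
          label = dressing$label, food_type = dressing$food_type,
          weight_g = w,
          energy_kcal = w * dressing$energy_kcal_100g / 100,
          fat_g = w * dressing$fat_g_100g / 100,
          carb_g = w * dressing$carb_g_100g / 100,
          protein_g = w * dressing$protein_g_100g / 100,
          fiber_g = w * dressing$fiber_g_100g / 100,
          alcohol_g = w * dressing$alcohol_g_100g / 100)
        # intrusions get no link row
      }
    }
    list(app = validate_segments(dplyr::bind_rows(app_rows)),
         links = dplyr::bind_rows(link_rows))
  })
}

#' Generate a complete synthetic validation study
#'
#' Convenience wrapper: [generate_reference()] then [simulate_app()] (app
#' simulation is seeded with `cfg$seed + 1`).
#'
#' @param cfg A [study_config()].
#' @param em An [error_model()].
#' @param tax,composition Taxonomy and composition table.
#' @return A list with `reference`, `app`, `links`, `tax`.
#' @export
simulate_study <- function(cfg = study_config(), em = error_model(),
                           tax = fixture_taxonomy(),
                           composition = default_composition()) {
  reference <- generate_reference(cfg, tax, composition)
  sim <- simulate_app(reference, em, tax, composition, seed = cfg$seed + 1L)
  list(reference = reference, app = sim$app, links = sim$links, tax = tax)
}
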