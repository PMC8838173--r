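#' Build and validate a hierarchical food taxonomy
#'
#' A food taxonomy is a three-level hierarchy: every food *type* belongs to
#' exactly one food *group*, and every group to exactly one food *category*
#' (the coarsest level, mirroring national food-pyramid categories). Segments
#' of a dietary record are labelled at the type level and rolled up to the
#' group and category levels for coarser-grained agreement analyses.
#'
#' @param table A data frame with character columns `type`, `group`,
#'   `category`, one row per food type.
#' @return A tibble of class `food_taxonomy` with one row per type and
#'   attributes `q_type`, `q_group`, `q_category` (the number of distinct
#'   labels at each level).
#' @examples
#' tax <- load_taxonomy(data.frame(
#'   type = c("pasta", "rice", "tubers"),
#'   group = c("Cereals", "Cereals", "Potatoes"),
#'   category = c("Starches", "Starches", "Starches")
#' ))
#' attr(tax, "q_group")
#' @export
load_taxonomy <- function(table) {
  table <- as.data.frame(table)
  req <- c("type", "group", "category")
  if (!all(req %in% names(table))) {
    stop("taxonomy table must have columns 'type', 'group', 'category'",
         call. = FALSE)
  }
  table <- table[, req]
  if (nrow(table) == 0L) stop("taxonomy table is empty", call. = FALSE)
  if (anyNA(table)) stop("taxonomy table contains missing values", call. = FALSE)

  dup <- unique(table$type[duplicated(table$type)])
  for (t in dup) {
    sub <- unique(table[table$type == t, c("group", "category")])
    if (nrow(sub) > 1L) {
      stop("type '", t, "' is listed under more than one group/category",
           call. = FALSE)
    }
  }
  table <- unique(table)
  gmap <- unique(table[, c("group", "category")])
  if (anyDuplicated(gmap$group)) {
    bad <- gmap$group[duplicated(gmap$group)][1L]
    stop("group '", bad, "' is listed under more than one category",
         call. = FALSE)
  }

  tax <- tibble::as_tibble(table[order(table$type), ])
  class(tax) <- c("food_taxonomy", class(tax))
  attr(tax, "q_type") <- length(unique(tax$type))
  attr(tax, "q_group") <- length(unique(tax$group))
  attr(tax, "q_category") <- length(unique(tax$category))
  tax
}

#' Read a taxonomy from a CSV file
#'
#' Expects a UTF-8 CSV with header `type,group,category`.
#'
#' @param path Path to the CSV file.
#' @return A validated [load_taxonomy()] object.
#' @export
read_taxonomy <- function(path) {
  load_taxonomy(utils::read.csv(path, stringsAsFactors = FALSE,
                                fileEncoding = "UTF-8"))
}

#' Synthetic reference taxonomy (37 types / 23 groups / 7 categories)
#'
#' A fixture taxonomy of the size used in app-validation studies of this kind:
#' 37 food types nested in 23 food groups nested in 7 food categories. Group
#' names follow conventional food-group nomenclature; the types beneath them
#' and the 7 categories are synthetic. Note that a plain "rice" type sits in
#' the cereals group (so e.g. pasta vs. rice is a within-group confusion),
#' while the rice-based-products group holds composed rice dishes.
#'
#' @return A `food_taxonomy` tibble.
#' @export
fixture_taxonomy <- function() {
  g <- function(group, category, types) {
    data.frame(type = types, group = group, category = category)
  }
  bev <- "Non-alcoholic beverages"
  vf <- "Vegetables & fruits"
  st <- "Starches & grains"
  pr <- "Protein foods & dairy"
  fo <- "Fats, oils & nuts"
  sw <- "Sweets, snacks & alcohol"
  pd <- "Prepared dishes & condiments"
  tab <- rbind(
    g("NaNs beverages", bev, c("tea", "coffee")),
    g("Juice", bev, "fruit juice"),
    g("NaS beverages", bev, "soft drink"),
    g("Vegetables", vf, c("leafy vegetables", "root vegetables",
                          "fruiting vegetables")),
    g("Fruit", vf, c("pome & stone fruit", "berries")),
    g("Cereals & cereal-based products", st, c("pasta", "bread", "rice")),
    g("Rice, rice-based products", st, "rice dishes"),
    g("Potatoes, legumes & beans", st, c("tubers", "legumes")),
    g("Meat & poultry", pr, c("red meat", "poultry")),
    g("Fish & seafood", pr, "fish & seafood"),
    g("Unclassified meat", pr, "processed meat"),
    g("Eggs & meat substitutes", pr, c("eggs", "meat substitutes")),
    g("Dairy products (excl. milk)", pr, c("cheese", "yogurt")),
    g("Milk & milk-based beverages", pr, "milk"),
    g("Milk substitutes", pr, "plant milk"),
    g("Seeds & nuts", fo, "nuts & seeds"),
    g("Fats & oils", fo, c("oils", "butter & cream")),
    g("Salty snacks", sw, "salty snacks"),
    g("Sweet dishes", sw, c("pastries & desserts", "chocolate & confectionery")),
    g("Sweeteners", sw, "sugar & honey"),
    g("Alcoholic beverages", sw, c("beer & wine", "spirits & cocktails")),
    g("Condiments & sauces", pd, c("sauces", "condiments")),
    g("Soups", pd, "soups")
  )
  load_taxonomy(tab)
}

#' Classify a mixed segment by its highest-calorie ingredient
#'
#' A segment made of several ingredients (a gratin, a composed salad) is
#' assigned the food type of the ingredient contributing the most energy,
#' i.e. maximising `weight_g * energy_kcal_100g / 100`. Ties are broken by
#' larger weight, then by lexicographically smallest label, so the result does
#' not depend on input order.
#'
#' @param ingredients Data frame with columns `label`, `food_type`,
#'   `weight_g` (> 0) and `energy_kcal_100g` (>= 0).
#' @return The winning food type (length-1 character).
#' @examples
#' assign_mixed_segment(data.frame(
#'   label = c("potato", "cream"), food_type = c("tubers", "butter & cream"),
#'   weight_g = c(200, 50), energy_kcal_100g = c(85, 292)
#' )) # potato gratin -> "tubers" (170 kcal beats 146 kcal)
#' @export
assign_mixed_segment <- function(ingredients) {
  ingredients <- as.data.frame(ingredients)
  if (nrow(ingredients) == 0L) stop("ingredient list is empty", call. = FALSE)
  stopifnot(all(is.finite(ingredients$weight_g)),
            all(ingredients$weight_g > 0),
            all(is.finite(ingredients$energy_kcal_100g)),
            all(ingredients$energy_kcal_100g >= 0))
  kcal <- ingredients$weight_g * ingredients$energy_kcal_100g / 100
  ord <- order(-kcal, -ingredients$weight_g, ingredients$label)
  ingredients$food_type[ord[1L]]
}

#' Roll food types up to their group and category
#'
#' @param types Character vector of food types present in `tax`.
#' @param tax A `food_taxonomy`.
#' @return A tibble with columns `type`, `group`, `category`, one row per
#'   element of `types` (in input order).
#' @export
roll_up <- function(types, tax) {
  stopifnot(inherits(tax, "food_taxonomy"))
  idx <- match(types, tax$type)
  if (anyNA(idx)) {
    stop("unknown food type(s): ",
         paste(unique(types[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(type = types, group = tax$group[idx],
                 category = tax$category[idx])
}

#' Taxonomy distance between two food types
#'
#' 0 if same type, 1 if different types in the same group, 2 if different
#' groups in the same category, 3 otherwise. Used as the linking cost between
#' reference and app segments.
#'
#' @param type_a,type_b Character vectors of food types (recycled).
#' @param tax A `food_taxonomy`.
#' @return Integer vector of distances.
#' @export
taxonomy_distance <- function(type_a, type_b, tax) {
  a <- roll_up(type_a, tax)
  b <- roll_up(type_b, tax)
  ifelse(a$type == b$type, 0L,
         ifelse(a$group == b$group, 1L,
                ifelse(a$category == b$category, 2L, 3L)))
}
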