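test_that("proportion half-width follows the (n-1) convention", {
  # printed report cells this convention reproduces
  expect_equal(round(proportion_halfwidth(345, 352), 1), 1.5)
  expect_equal(round(proportion_halfwidth(302, 345), 1), 3.5)
  expect_equal(round(proportion_halfwidth(10, 345), 1), 1.8)
  expect_equal(round(proportion_halfwidth(13, 31), 1), 17.7)
  expect_equal(round(proportion_halfwidth(12, 31), 1), 17.4)
  expect_equal(proportion_halfwidth(33, 33), 0)

  set.seed(7)
  for (i in 1:20) {  # symmetry hw(x, n) == hw(n - x, n)
    n <- sample(2:500, 1)
    x <- sample(0:n, 1)
    expect_equal(proportion_halfwidth(x, n), proportion_halfwidth(n - x, n))
  }
  expect_error(proportion_halfwidth(1, 1), "n must be >= 2")
  expect_error(proportion_halfwidth(5, 4), "in \\[0, n\\]")
})

test_that("record types follow segment count and food/beverage flag", {
  ref <- dplyr::bind_rows(
    make_segments("R1", c("a", "b", "c"), rep("pasta", 3), c(10, 20, 30)),
    make_segments("R2", "a", "pasta", 50),
    make_segments("R3", c("tea", "sugar"), c("tea", "sugar & honey"),
                  c(200, 5), kind = "beverage"),
    make_segments("R4", "tea", "tea", 200, kind = "beverage")
  )
  rt <- record_types(ref)
  expect_equal(rt$record_type[match(paste0("R", 1:4), rt$record_id)],
               c("composite_food", "simple_food", "composite_beverage",
                 "simple_beverage"))
})

test_that("perfect detection links every segment as found", {
  tax <- fixture_taxonomy()
  ref <- make_segments("R1", c("pasta", "sauce", "salad"),
                       c("pasta", "sauces", "leafy vegetables"),
                       c(180, 80, 50))
  mt <- link_segments(ref, ref, tax)
  expect_equal(sum(mt$code == "F"), 3)
  expect_equal(sum(mt$code != "F"), 0)
})

test_that("an app-only segment is coded as an intrusion", {
  tax <- fixture_taxonomy()
  ref <- make_segments("R1", "green salad", "leafy vegetables", 60)
  app <- make_segments("R1", c("green salad", "salad dressing"),
                       c("leafy vegetables", "sauces"), c(58, 25))
  mt <- link_segments(ref, app, tax)
  expect_equal(sum(mt$code == "F"), 1)
  expect_equal(sum(mt$code == "I"), 1)
  expect_equal(mt$app_segment_id[mt$code == "I"], 2L)
})

test_that("linking is invariant to the order of input rows", {
  tax <- fixture_taxonomy()
  set.seed(11)
  ref <- make_segments("R1", paste0("r", 1:5),
                       sample(tax$type, 5), runif(5, 20, 300))
  app <- make_segments("R1", paste0("a", 1:4),
                       sample(tax$type, 4), runif(4, 20, 300))
  mt1 <- link_segments(ref, app, tax)
  mt2 <- link_segments(ref[sample(5), ], app[sample(4), ], tax)
  key <- function(m) m[order(m$code, m$ref_segment_id, m$app_segment_id), ]
  expect_equal(key(mt1), key(mt2))
})

test_that("linking equals the exhaustive assignment oracle", {
  tax <- fixture_taxonomy()
  set.seed(23)
  for (rep in 1:25) {
    n_ref <- sample(1:4, 1)
    n_app <- sample(1:4, 1)
    ref <- make_segments("R1", paste0("r", 1:n_ref),
                         sample(tax$type, n_ref, replace = TRUE),
                         round(runif(n_ref, 10, 400)))
    app <- make_segments("R1", paste0("a", 1:n_app),
                         sample(tax$type, n_app, replace = TRUE),
                         round(runif(n_app, 10, 400)))
    mt <- link_segments(ref, app, tax)
    expect_equal(sum(mt$code == "F"),
                 unname(oracle_match(ref, app, tax)["links"]),
                 info = paste("rep", rep))
  }
})

test_that("manual links override automatic matching and are validated", {
  tax <- fixture_taxonomy()
  ref <- make_segments("R1", c("rice", "pasta"), c("rice", "pasta"),
                       c(150, 180))
  app <- make_segments("R1", c("rice", "pasta"), c("rice", "pasta"),
                       c(150, 180))
  manual <- tibble::tibble(record_id = "R1", ref_segment_id = 1L,
                           app_segment_id = 2L)
  mt <- link_segments(ref, app, tax, manual_links = manual)
  expect_equal(mt$app_segment_id[mt$ref_segment_id == 1 & mt$code == "F"], 2L)

  clash <- tibble::tibble(record_id = "R1", ref_segment_id = c(1L, 2L),
                          app_segment_id = c(2L, 2L))
  expect_error(link_segments(ref, app, tax, manual_links = clash),
               "conflicting")
  orphan_app <- make_segments("R9", "rice", "rice", 100)
  expect_error(link_segments(ref, orphan_app, tax), "no reference")
})

test_that("segmentation accuracy reproduces counts and identities", {
  coding <- tibble::tibble(stratum = c("total", "simple_beverage"),
                           found = c(345, 33), omitted = c(7, 0),
                           intruded = c(5, 0))
  acc <- segmentation_accuracy(coding)
  expect_equal(round(acc$pct_found[1], 1), 98.0)
  expect_equal(round(acc$hw_found[1], 1), 1.5)
  expect_equal(round(acc$pct_omitted[1], 1), 2.0)
  expect_equal(round(acc$pct_intruded[1], 1), 1.4)
  expect_equal(acc$pct_found[2], 100)
  expect_equal(acc$hw_found[2], 0)
  # %F + %O == 100 in every stratum
  expect_equal(acc$pct_found + acc$pct_omitted, c(100, 100))
  expect_error(segmentation_accuracy(
    tibble::tibble(stratum = "x", found = 0, omitted = 0, intruded = 1)),
    "no reference segments")
})
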