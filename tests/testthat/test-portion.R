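tax <- fixture_taxonomy()

# one-record study with three exactly classified segments
simple_study <- function(est_weights, true_weights = c(100, 100, 100)) {
  ref <- make_segments("R1", c("a", "b", "c"),
                       c("pasta", "red meat", "leafy vegetables"),
                       true_weights)
  app <- make_segments("R1", c("a", "b", "c"),
                       c("pasta", "red meat", "leafy vegetables"),
                       est_weights)
  mt <- tibble::tibble(record_id = "R1", ref_segment_id = 1:3,
                       app_segment_id = 1:3, code = "F")
  grades <- tibble::tibble(record_id = "R1", ref_segment_id = 1:3,
                           grade = "E")
  list(ref = ref, app = app, mt = mt, grades = grades)
}

test_that("weight errors are plain arithmetic on exact pairs", {
  s <- simple_study(c(120, 100, 80))
  err <- weight_errors(s$mt, s$grades, s$ref, s$app)
  expect_equal(err$error_g, c(20, 0, -20))
  expect_equal(err$pct_error, c(20, 0, -20))
  expect_equal(err$abs_pct_error, c(20, 0, 20))
  expect_false(any(err$flagged))

  same <- weight_errors(s$mt, s$grades, s$ref, s$ref)
  expect_true(all(same$error_g == 0))
})

test_that("non-exact grades and exclusions are removed explicitly", {
  s <- simple_study(c(120, 100, 80))
  s$grades$grade <- c("E", "C", "E")
  err <- weight_errors(s$mt, s$grades, s$ref, s$app)
  expect_equal(nrow(err), 2)

  excl <- tibble::tibble(record_id = "R1", ref_segment_id = 3L)
  expect_message(
    err2 <- weight_errors(s$mt, s$grades, s$ref, s$app, exclusions = excl),
    "excluding 1")
  expect_equal(nrow(err2), nrow(err) - nrow(excl))
  expect_error(suppressMessages(weight_errors(
    s$mt, s$grades[s$grades$grade == "E", ][0, ], s$ref, s$app)), "no exact")
})

test_that("mean percentage error matches the generator under known noise", {
  # multiplicative log-normal noise: E[pct_error] = 100 (exp(s^2/2) - 1)
  set.seed(17)
  n <- 2000
  sdlog <- 0.35
  true <- rlnorm(n, log(120), 0.5)
  est <- true * rlnorm(n, 0, sdlog)
  ref <- make_segments("R1", paste0("s", 1:n), rep("pasta", n), true)
  app <- make_segments("R1", paste0("s", 1:n), rep("pasta", n), est)
  mt <- tibble::tibble(record_id = "R1", ref_segment_id = 1:n,
                       app_segment_id = 1:n, code = "F")
  gr <- tibble::tibble(record_id = "R1", ref_segment_id = 1:n, grade = "E")
  err <- weight_errors(mt, gr, ref, app)
  target <- 100 * (exp(sdlog^2 / 2) - 1)
  se <- sd(err$pct_error) / sqrt(n)
  expect_lt(abs(mean(err$pct_error) - target), 3 * se)
})

test_that("group summaries satisfy the aggregation identities", {
  set.seed(3)
  n <- 60
  types <- sample(c("pasta", "red meat", "tubers", "tea"), n, replace = TRUE)
  true <- runif(n, 50, 300)
  est <- true * runif(n, 0.6, 1.6)
  ref <- make_segments("R1", paste0("s", 1:n), types, true)
  app <- make_segments("R1", paste0("s", 1:n), types, est)
  mt <- tibble::tibble(record_id = "R1", ref_segment_id = 1:n,
                       app_segment_id = 1:n, code = "F")
  gr <- tibble::tibble(record_id = "R1", ref_segment_id = 1:n, grade = "E")
  err <- weight_errors(mt, gr, ref, app)
  smry <- group_error_summary(err, level = "group", tax = tax)

  # grand mean error is the n-weighted mean of group means
  expect_equal(sum(smry$mean_error * smry$n) / sum(smry$n),
               mean(err$error_g))
  # |mean pct error| <= mean absolute pct error per group (Jensen)
  agg <- group_error_summary(err, level = "category", tax = tax)
  per_cat <- split(err$pct_error, roll_up(err$food_type, tax)$category)
  expect_true(all(abs(vapply(per_cat, mean, numeric(1)))
                  <= agg$mean_abs_pct_error[match(names(per_cat),
                                                  agg$label)] + 1e-12))
  # accuracy ratio is 1 exactly when the mean error is 0
  s0 <- simple_study(c(110, 100, 90))
  e0 <- weight_errors(s0$mt, s0$grades, s0$ref, s0$app)
  sm0 <- group_error_summary(e0, level = "category", tax = tax)
  expect_equal(sm0$accuracy_ratio[abs(sm0$mean_error) < 1e-12],
               rep(1, sum(abs(sm0$mean_error) < 1e-12)))

  single <- group_error_summary(err[1, ], level = "type", tax = tax)
  expect_equal(single$mean_error, err$error_g[1])
  expect_equal(single$n, 1)
})

test_that("paired t-test matches the closed-form statistic", {
  true <- c(102, 98, 110, 95, 104, 99, 107, 101)
  est <- c(108, 101, 115, 94, 110, 103, 112, 99)
  res <- paired_t_test(true, est)
  d <- est - true
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$df, length(d) - 1)

  degen <- paired_t_test(true, true + 5)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
  expect_equal(degen$mean_diff, 5)
})

test_that("a 25% portion bias at n = 40 is detected in most replicates", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(1000 + s)
    true <- rlnorm(40, log(140), 0.5)
    est <- true * 1.25 * rlnorm(40, 0, 0.35)
    if (paired_t_test(true, est)$p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
})
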