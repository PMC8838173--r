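tax <- fixture_taxonomy()

test_that("match grading enforces the taxonomy logic", {
  # cherry tomatoes vs tomatoes: synonym of the same type -> exact
  expect_equal(grade_match("fruiting vegetables", "fruiting vegetables", tax,
                           synonym = TRUE), "E")
  # beef vs veal: same type, slight product variant -> close
  expect_equal(grade_match("red meat", "red meat", tax,
                           slight_variant = TRUE), "C")
  # pasta vs rice: wrong type, same group -> far
  expect_equal(grade_match("pasta", "rice", tax), "F")
  # carrot vs potato: wrong type and group -> mismatch
  expect_equal(grade_match("root vegetables", "tubers", tax), "M")
  # a close flag never downgrades a type-correct match below C
  expect_equal(grade_match("tea", "tea", tax, too_generic = TRUE,
                           synonym = TRUE), "C")
  expect_error(grade_match("pasta", "noodle soup 3000", tax), "unknown")
})

test_that("classification accuracy reproduces the printed proportions", {
  counts <- tibble::tibble(stratum = c("total", "composite_beverage"),
                           E = c(302, 13), C = c(29, 12), F = c(4, 0),
                           M = c(10, 6))
  acc <- classification_accuracy(counts)
  expect_equal(round(acc$pct_E, 1), c(87.5, 41.9))
  expect_equal(round(acc$pct_C, 1), c(8.4, 38.7))
  expect_equal(round(acc$pct_F, 1), c(1.2, 0.0))
  expect_equal(round(acc$pct_M, 1), c(2.9, 19.4))
  expect_equal(round(acc$hw_E, 1), c(3.5, 17.7))
  expect_equal(round(acc$hw_M, 1), c(1.8, 14.1))
  # the four proportions always sum to 100
  expect_equal(acc$pct_E + acc$pct_C + acc$pct_F + acc$pct_M, c(100, 100))

  all_e <- classification_accuracy(
    tibble::tibble(stratum = rep("scan", 5), grade = rep("E", 5)))
  expect_equal(all_e$pct_E[all_e$stratum == "scan"], 100)
  expect_equal(all_e$pct_M[all_e$stratum == "scan"], 0)
})

test_that("Cohen kappa matches direct evaluation and an independent oracle", {
  # 2x2 table reconstructed from a published sensitivity/specificity row
  two <- matrix(c(13, 0, 4, 328), 2, byrow = TRUE)
  expect_equal(round(cohen_kappa(two)$kappa, 4), 0.8607)

  perfect <- diag(c(5, 7, 9))
  expect_equal(cohen_kappa(perfect)$kappa, 1)

  skip_if_not_installed("e1071")
  set.seed(99)
  for (i in 1:20) {
    tab <- matrix(rpois(16, 8), 4)
    expect_equal(cohen_kappa(tab)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
  expect_error(cohen_kappa(matrix(c(9, 0, 0, 0), 2)), "degenerate")
})

test_that("uniform kappa follows the Brennan-Prediger convention", {
  expect_equal(round(uniform_kappa(341 / 345, 2), 3), 0.977)
  expect_equal(round(uniform_kappa(331 / 345, 37), 3), 0.958)
  for (q in c(2, 7, 23, 37)) {
    expect_equal(uniform_kappa(1 / q, q), 0)  # chance-level agreement
    expect_equal(uniform_kappa(1, q), 1)      # perfect agreement
  }
  # strictly increasing in observed agreement
  po <- seq(0, 1, by = 0.1)
  expect_true(all(diff(uniform_kappa(po, 23)) > 0))
  expect_error(uniform_kappa(0.5, 1), "q must be >= 2")
})

test_that("uniform-kappa bootstrap CI behaves at the anchors", {
  all_agree <- uniform_kappa_ci(rep(1, 30), q = 2, B = 500, seed = 1)
  expect_equal(c(all_agree$lower, all_agree$upper), c(1, 1))
  none <- uniform_kappa_ci(rep(0, 30), q = 5, B = 500, seed = 1)
  expect_equal(c(none$lower, none$upper), c(-0.25, -0.25))  # -1/(q-1)

  # 341 agreements out of 345 binary indicators: interval is stable across
  # seeds and close to the published [0.954; 0.994]
  agree <- rep(c(1, 0), c(341, 4))
  for (s in 1:3) {
    ci <- uniform_kappa_ci(agree, q = 2, B = 2000, seed = s)
    expect_equal(ci$ku, uniform_kappa(341 / 345, 2))
    expect_lt(abs(ci$lower - 0.954), 0.01)
    expect_lt(abs(ci$upper - 0.994), 0.01)
  }
  expect_warning(uniform_kappa_ci(rep(c(1, 0), 10), q = 2, B = 50, seed = 1),
                 "B < 100")
})

test_that("sensitivity/specificity use exact Clopper-Pearson intervals", {
  row <- sensitivity_specificity(13, 0, 4, 328)
  expect_equal(row$sensitivity, 100)
  expect_equal(round(row$sens_lower, 1), 75.3)
  expect_equal(round(row$sens_upper, 1), 100)
  expect_equal(round(row$specificity, 1), 98.8)

  fats <- sensitivity_specificity(6, 1, 1, 300)
  expect_equal(round(fats$sensitivity, 1), 85.7)
  expect_equal(round(fats$sens_lower, 1), 42.1)
  expect_equal(round(fats$sens_upper, 1), 99.6)

  # closed-form beta-quantile anchors
  for (n in c(5, 13, 40)) {
    full <- sensitivity_specificity(n, 0, 1, 10)
    expect_equal(full$sens_lower, 100 * 0.025^(1 / n), tolerance = 1e-9)
    zero <- sensitivity_specificity(0, n, 1, 10)
    expect_equal(zero$sens_upper, 100 * (1 - 0.025^(1 / n)),
                 tolerance = 1e-9)
  }
  und <- sensitivity_specificity(0, 0, 2, 10)
  expect_true(und$undefined)
  expect_true(is.na(und$sensitivity))
})

test_that("Fisher's exact p equals hypergeometric enumeration", {
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-10)
  expect_equal(round(fisher_exact(tab), 5), 0.00276)
  same <- matrix(c(4, 6, 4, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact(same), 1)
  set.seed(5)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-10)
  }
})

test_that("per-group sensitivity recovers the confusion kernel diagonal", {
  # 5000 segments, true kernel: correct group w.p. 0.9, else a random other
  set.seed(31)
  groups <- unique(tax$group)[1:3]  # ~1667 segments per group
  truth <- sample(groups, 5000, replace = TRUE)
  obs <- ifelse(runif(5000) < 0.9, truth,
                vapply(truth, function(g) sample(setdiff(groups, g), 1),
                       character(1)))
  labs <- sort(groups)
  conf <- table(factor(truth, levels = labs), factor(obs, levels = labs))
  met <- per_label_metrics(conf, B = 200, seed = 1)
  expect_true(all(abs(met$sensitivity / 100 - 0.9) < 0.02))
})
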