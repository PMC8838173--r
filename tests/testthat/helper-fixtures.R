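# shared fixtures: tiny segment tables and an independent brute-force
# matching oracle used to validate link_segments

make_segments <- function(record_id, labels, types, weights,
                          kind = "food", mode = "photo") {
  n <- length(labels)
  tibble::tibble(
    record_id = record_id, record_kind = kind, entry_mode = mode,
    segment_id = seq_len(n), label = labels, food_type = types,
    weight_g = weights,
    energy_kcal = weights, fat_g = 0, carb_g = 0, protein_g = 0,
    fiber_g = 0, alcohol_g = 0
  )
}

# exhaustive matching oracle: enumerate every injective assignment of
# reference segments to app segments (within one record), keep pairs with
# cost <= threshold, maximise number of links then minimise total cost
oracle_match <- function(ref, app, tax, threshold = 2) {
  cost <- outer(seq_len(nrow(ref)), seq_len(nrow(app)), function(i, j) {
    d <- taxonomy_distance(ref$food_type[i], app$food_type[j], tax)
    nwd <- abs(ref$weight_g[i] - app$weight_g[j]) /
      pmax(ref$weight_g[i], app$weight_g[j], 1e-9)
    d + 0.999 * pmin(nwd, 1)
  })
  choices <- rep(list(0:nrow(app)), nrow(ref))
  grid <- as.matrix(expand.grid(choices))
  best <- c(links = -1, cost = Inf)
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    ok <- all(vapply(seq_along(a), function(i) {
      a[i] == 0 || cost[i, a[i]] <= threshold
    }, logical(1)))
    if (!ok) next
    links <- sum(a > 0)
    total <- sum(vapply(seq_along(a), function(i) {
      if (a[i] > 0) cost[i, a[i]] else 0
    }, numeric(1)))
    if (links > best["links"] ||
        (links == best["links"] && total < best["cost"] - 1e-12)) {
      best <- c(links = links, cost = total)
    }
  }
  best
}

# independent Fisher oracle: hypergeometric enumeration of all 2x2 tables
# with the observed margins, summing probabilities <= observed
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n2 <- cc + d; k <- a + cc
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
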