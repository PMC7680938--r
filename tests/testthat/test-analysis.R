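# small synthetic results table mimicking the tidy experiment schema
make_results <- function(gains, scheme = "seedling", error_type = "source",
                         rate = 0.2, pop = 4) {
  do.call(rbind, lapply(seq_along(gains), function(r) {
    data.frame(rep = r, scheme = scheme, error_type = error_type,
               rate = rate, pop = pop, cycle = pop, gain = gains[r],
               variance = NA_real_, accuracy = NA_real_,
               sigma_A = NA_real_, n_candidates = NA, n_selected = NA,
               n_mislabeled_selected = NA, n_records = NA)
  }))
}

test_that("gain summaries reproduce direct mean/SD/CV arithmetic", {
  res <- make_results(c(1.0, 1.4, 0.9))
  gs <- gain_summary(res)
  expect_equal(gs$mean, mean(c(1, 1.4, 0.9)))
  expect_equal(gs$sd, sd(c(1, 1.4, 0.9)))
  expect_equal(gs$cv, sd(c(1, 1.4, 0.9)) / mean(c(1, 1.4, 0.9)))
  # equal gains: CV exactly 0
  expect_equal(gain_summary(make_results(c(2, 2)))$cv, 0)
  # single replicate: CV undefined
  expect_true(is.na(gain_summary(make_results(3))$cv))
})

test_that("prediction accuracy restricts to correctly labeled clones", {
  set.seed(44)
  ids <- letters[1:10]
  tv <- setNames(rnorm(10), ids)
  pr <- setNames(tv + rnorm(10, 0, 0.7), ids)
  bad <- c("b", "e", "j")
  keep <- setdiff(ids, bad)
  expect_equal(prediction_accuracy(tv, pr, bad),
               cor(tv[keep], pr[keep]))
  expect_equal(prediction_accuracy(tv, tv, bad), 1)
  expect_equal(prediction_accuracy(tv, -tv, bad), -1)
  # fewer than 3 correctly labeled, or constant vectors: undefined
  expect_true(is.na(prediction_accuracy(tv, pr, ids[1:8])))
  expect_true(is.na(prediction_accuracy(setNames(rep(1, 10), ids), pr)))
})

test_that("the exact binomial selection-bias test behaves at its anchors", {
  # observing exactly 40e mislabeled is as expected: far from significant
  expect_gt(selection_bias_test(20, 40, 0.5), 0.9)
  # zero mislabeled among 40 selected at e = 0.5: p = 2 * 0.5^40
  expect_equal(selection_bias_test(0, 40, 0.5), 2 * 0.5^40,
               tolerance = 1e-10)
  expect_lt(selection_bias_test(0, 40, 0.5), 0.05)
  expect_error(selection_bias_test(1, 40, 0), "undefined")
  # the discrete test is conservative: exact size below the nominal 5%
  for (e in c(0.1, 0.3, 0.5)) {
    sz <- selection_bias_null_rate(40, e)
    expect_lt(sz, 0.05)
    expect_gt(sz, 0)
  }
  # exact size matches brute-force enumeration on a small case
  n <- 8; e <- 0.25
  pv <- vapply(0:n, function(x) binom.test(x, n, e)$p.value, 0)
  expect_equal(selection_bias_null_rate(n, e),
               sum(dbinom(0:n, n, e)[pv < 0.05]))
  # hypergeometric null (fixed number mislabeled in the cohort) is more
  # conservative still, and matches enumeration
  N <- 40; K <- round(e * N)
  expect_equal(selection_bias_null_rate(n, e, n_candidates = N),
               sum(dhyper(0:n, K, N - K, n)[pv < 0.05]))
  expect_lte(selection_bias_null_rate(40, 0.5, n_candidates = 300),
             selection_bias_null_rate(40, 0.5))
})

test_that("two-way ANOVA partitions sums of squares like the textbook formula", {
  # balanced 2 rates x 2 schemes x 3 replicates with a known interaction
  set.seed(7)
  d <- expand.grid(rep = 1:3, rate = c(0, 0.3),
                   scheme = c("seedling", "no_seedling"))
  d$error_type <- ifelse(d$rate == 0, "none", "source")
  d$pop <- 4; d$cycle <- 4
  d$gain <- 2 - d$rate + 0.5 * (d$scheme == "seedling") +
    2 * d$rate * (d$scheme == "seedling") + rnorm(nrow(d), 0, 0.05)
  d$variance <- d$accuracy <- NA_real_
  out <- interaction_anova(d, "gain", cycle = 4, error_type = "source")
  # manual two-way ANOVA partition
  ybar <- mean(d$gain)
  cellm <- with(d, tapply(gain, list(rate, scheme), mean))
  am <- rowMeans(cellm); bm <- colMeans(cellm)
  ss_a <- 6 * sum((am - ybar)^2)
  ss_b <- 6 * sum((bm - ybar)^2)
  ss_ab <- 3 * sum((sweep(sweep(cellm, 1, am), 2, bm) + ybar)^2)
  tab <- out$table
  rn <- trimws(rownames(tab))
  expect_equal(tab[rn == "m", "Sum Sq"], ss_a, tolerance = 1e-8)
  expect_equal(tab[rn == "s", "Sum Sq"], ss_b, tolerance = 1e-8)
  expect_equal(tab[rn == "m:s", "Sum Sq"], ss_ab, tolerance = 1e-8)
  # the built-in interaction is detected
  expect_lt(out$p_interaction, 0.01)
  # purely additive response: interaction F not significant
  d2 <- d
  set.seed(8)
  d2$gain <- 2 - d2$rate + 0.5 * (d2$scheme == "seedling") +
    rnorm(nrow(d2), 0, 0.5)
  out2 <- interaction_anova(d2, "gain", cycle = 4, error_type = "source")
  expect_gt(out2$p_interaction, 0.05)
})

test_that("pairwise gain tests: self-comparison p = 1, known shift matches t.test", {
  set.seed(15)
  base <- rnorm(12, 1, 0.2)
  res <- rbind(make_results(base, rate = 0, error_type = "none"),
               make_results(base - 0.5 + rnorm(12, 0, 0.05), rate = 0.4))
  out <- pairwise_gain_tests(res, cycle = 4, paired = TRUE,
                             error_type = "source")
  self <- out[out$scenario1 == out$scenario2, ]
  expect_true(all(self$p == 1))
  cross <- out[out$scenario1 != out$scenario2, ]
  # closed-form paired t statistic on the same data
  a <- res$gain[res$rate == 0.4]
  b <- res$gain[res$rate == 0]
  dd <- a - b
  tstat <- mean(dd) / (sd(dd) / sqrt(length(dd)))
  p_manual <- 2 * pt(-abs(tstat), length(dd) - 1)
  expect_equal(cross$p[1], p_manual, tolerance = 1e-12)
  expect_equal(cross$p_adj, pmin(cross$p * nrow(cross), 1))
})

test_that("response decomposition arithmetic matches the breeder's equation", {
  expect_equal(expected_response(0.2, 2, 0.5, 0.8), 0.64)
  expect_equal(expected_response(0, 2, 0.5, 0.8), 2 * 0.5 * 0.8)
  expect_equal(expected_response(0.5, 1, 1, 1), 0.5)
  # a hand-built paired experiment: mislabeled run gains exactly 60% of
  # baseline increments; accuracy * sigma_A ratios recomputed directly
  rows <- list()
  for (rp in 1:2) {
    for (e in c(0, 0.3)) {
      sc <- 1 - 0.4 * (e > 0)
      for (p in 0:4) {
        rows[[length(rows) + 1L]] <- data.frame(
          rep = rp, scheme = "seedling",
          error_type = ifelse(e == 0, "none", "source"), rate = e,
          pop = p, cycle = p, gain = sc * (0.5 + p + 0.1 * rp),
          variance = 1, accuracy = ifelse(p >= 1, 0.8 - 0.1 * e * p, NA),
          sigma_A = ifelse(p >= 1, 0.9, NA), n_candidates = 10,
          n_selected = 5, n_mislabeled_selected = 0, n_records = 10)
      }
    }
  }
  res <- do.call(rbind, rows)
  rd <- response_decomposition(res, error_type = "source")
  obs <- rd$response[rd$response$rate == 0.3, ]
  expect_equal(obs$observed_ratio, rep(0.6, 2), tolerance = 1e-10)
  expect_equal(obs$expected_ratio, rep(0.7, 2))
  rs <- rd$rsigma[rd$rsigma$rate == 0.3 & rd$rsigma$cycle == 2, ]
  expect_equal(rs$rsigma_ratio,
               rep((0.8 - 0.1 * 0.3 * 2) / 0.8, 2), tolerance = 1e-10)
})

test_that("selection intensity matches a Monte-Carlo order-statistic oracle", {
  expect_equal(selection_intensity(10, 10), 0)
  i40 <- selection_intensity(40, 600)
  set.seed(99)
  mc <- replicate(3000, mean(sort(rnorm(600), decreasing = TRUE)[1:40]))
  expect_equal(i40, mean(mc), tolerance = 3 * sd(mc) / sqrt(3000))
  # intensity rises as the selected fraction shrinks
  grid <- vapply(c(300, 150, 60, 40, 10), selection_intensity, 0,
                 n_candidates = 600)
  expect_true(all(diff(grid) > 0))
})

test_that("seedling accuracy advantage summarises paired scheme contrasts", {
  rows <- list()
  for (sch in c("seedling", "no_seedling")) {
    for (rp in 1:3) {
      for (cy in 2:4) {
        rows[[length(rows) + 1L]] <- data.frame(
          rep = rp, scheme = sch, error_type = "source", rate = 0.1,
          pop = cy, cycle = cy, gain = 1, variance = 1,
          accuracy = ifelse(sch == "seedling", 0.55, 0.5) + 0.01 * rp,
          sigma_A = 1, n_candidates = 10, n_selected = 5,
          n_mislabeled_selected = 0, n_records = 10)
      }
    }
  }
  res <- do.call(rbind, rows)
  adv <- seedling_accuracy_advantage(res)
  expect_equal(adv$min_improvement_pct, 100 * 0.05 / 0.52, tolerance = 1e-8)
})
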