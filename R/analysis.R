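#' Per-scenario gain summaries across replicates
#'
#' Mean and coefficient of variation (SD/mean) of the gain relative to
#' population 0, per scenario and population, across replicates.  The CV
#' is reported as `NA` when fewer than two replicates are available or
#' the mean is zero.
#'
#' @param x A `gs_experiment` or its tidy `results` data frame.
#' @param response Column to summarise (default `"gain"`).
#' @return Data frame with columns `scheme`, `error_type`, `rate`, `pop`,
#'   `mean`, `sd`, `cv`, `n_reps`.
#' @export
gain_summary <- function(x, response = "gain") {
  res <- if (inherits(x, "gs_experiment")) x$results else x
  stopifnot(response %in% names(res))
  sp <- split(res, res[, c("scheme", "error_type", "rate", "pop")],
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d[[response]][!is.na(d[[response]])]
    m <- mean(v)
    data.frame(scheme = d$scheme[1], error_type = d$error_type[1],
               rate = d$rate[1], pop = d$pop[1], mean = m,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               cv = if (length(v) >= 2 && m != 0) stats::sd(v) / m
                    else NA_real_,
               n_reps = length(v))
  }))
  rownames(out) <- NULL
  out[order(out$scheme, out$error_type, out$rate, out$pop), ]
}

#' Prediction accuracy among correctly labeled clones
#'
#' Pearson correlation between true and predicted genotypic values,
#' restricted to clones that are not in the mislabeled set.  Undefined
#' (returned as `NA` with a warning-free contract) when fewer than three
#' correctly labeled clones remain or either vector is constant.
#'
#' @param true_values Named numeric vector of true genotypic values.
#' @param predicted Named numeric vector of predictions (same clones).
#' @param mislabeled Character vector of mislabeled clone ids to exclude.
#' @return Pearson correlation, or `NA_real_` when undefined.
#' @export
prediction_accuracy <- function(true_values, predicted,
                                mislabeled = character(0)) {
  stopifnot(!is.null(names(true_values)), !is.null(names(predicted)))
  ids <- intersect(names(true_values), names(predicted))
  ids <- setdiff(ids, mislabeled)
  if (length(ids) < 3) return(NA_real_)
  a <- true_values[ids]
  b <- predicted[ids]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Exact binomial test of selection bias
#'
#' Tests whether mislabeled clones are selected at a frequency different
#' from the mislabeling rate: under the null the number of mislabeled
#' clones among the `n_selected` selected is Binomial(n_selected, e).
#' Two-sided exact binomial test.
#'
#' @param n_mislabeled_selected Observed count among the selected.
#' @param n_selected Number selected (40 under default conditions).
#' @param rate Mislabeling rate e, strictly between 0 and 1.
#' @return The two-sided exact p-value.
#' @export
selection_bias_test <- function(n_mislabeled_selected, n_selected, rate) {
  if (rate <= 0 || rate >= 1) stop("test undefined for rate 0 or 1")
  stopifnot(n_mislabeled_selected >= 0, n_mislabeled_selected <= n_selected)
  stats::binom.test(n_mislabeled_selected, n_selected, p = rate,
                    alternative = "two.sided")$p.value
}

#' Exact null rejection rate of the discrete selection-bias test
#'
#' The exact binomial test on a small number of selected clones is
#' discrete and conservative: its true size is below the nominal level.
#' Moreover, in the simulation the cohort contains exactly
#' `round(rate * N)` mislabeled clones, so under unbiased selection the
#' count among the selected is Hypergeometric(N, round(rate N),
#' n_selected) -- underdispersed relative to the Binomial(n_selected,
#' rate) reference the test assumes, which lowers the rejection rate
#' further.  This computes the exact null probability of rejection,
#' `sum over x of P_null(x) * 1[p(x) < alpha]`, under either null; it is
#' the correct calibration reference when counting significant
#' replicates.
#'
#' @param n_selected Number selected.
#' @param rate Mislabeling rate under the null.
#' @param alpha Nominal significance level.
#' @param n_candidates Candidate-cohort size; when supplied, the null is
#'   the exact hypergeometric draw from a cohort with `round(rate *
#'   n_candidates)` mislabeled clones, otherwise Binomial(n_selected,
#'   rate).
#' @return Exact null rejection probability.
#' @export
selection_bias_null_rate <- function(n_selected, rate, alpha = 0.05,
                                     n_candidates = NULL) {
  x <- 0:n_selected
  p <- vapply(x, selection_bias_test, 0, n_selected = n_selected,
              rate = rate)
  w <- if (is.null(n_candidates)) {
    stats::dbinom(x, n_selected, rate)
  } else {
    k <- round(rate * n_candidates)
    stats::dhyper(x, k, n_candidates - k, n_selected)
  }
  sum(w[p < alpha])
}

#' Count significant selection-bias tests per scenario
#'
#' Applies [selection_bias_test()] to every replicate, selection cycle
#' and mislabeled scenario of an experiment and tabulates the number of
#' replicates reaching significance, alongside the exact null
#' expectation for the discrete test drawing from a cohort with a fixed
#' number of mislabeled clones.
#'
#' @param x A `gs_experiment` or its `results` data frame.
#' @param alpha Significance level (5%).
#' @return Data frame per (scheme, error_type, rate, cycle):
#'   `n_significant`, `n_reps`, `null_rate` (exact size of the discrete
#'   test under the hypergeometric null), and `expected_significant`.
#' @export
selection_bias_summary <- function(x, alpha = 0.05) {
  res <- if (inherits(x, "gs_experiment")) x$results else x
  res <- res[res$rate > 0 & !is.na(res$n_mislabeled_selected) &
               res$cycle >= 1, ]
  if (!nrow(res)) stop("no mislabeled scenarios with eligible cycles")
  sp <- split(res, res[, c("scheme", "error_type", "rate", "cycle")],
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    pv <- vapply(seq_len(nrow(d)), function(i) {
      selection_bias_test(d$n_mislabeled_selected[i], d$n_selected[i],
                          d$rate[i])
    }, 0)
    data.frame(scheme = d$scheme[1], error_type = d$error_type[1],
               rate = d$rate[1], cycle = d$cycle[1],
               n_significant = sum(pv < alpha), n_reps = nrow(d),
               null_rate = selection_bias_null_rate(
                 d$n_selected[1], d$rate[1], alpha,
                 n_candidates = d$n_candidates[1]))
  }))
  out$expected_significant <- out$null_rate * out$n_reps
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA for mislabeling-rate by scheme interaction
#'
#' Fits `y = mu + m + s + ms + e` for one response at one selection
#' cycle, with the mislabeling rate `m` (categorical) and the scheme `s`
#' (seedling vs no-seedling) as fixed factors and replicates supplying
#' the error degrees of freedom.  `interaction_anova_all()` runs the full
#' family (three responses x all cycles) and Bonferroni-adjusts the
#' interaction p-values across it.
#'
#' @param x A `gs_experiment` or its `results` data frame.
#' @param response `"gain"`, `"variance"`, or `"accuracy"`.
#' @param cycle Selection cycle (population index for gain/variance).
#' @param error_type Error type analysed (with its rate-0 baseline).
#' @return For `interaction_anova()`: a list with the `aov` fit, the
#'   ANOVA `table`, and `p_interaction`.  For `interaction_anova_all()`:
#'   a data frame of interaction tests with Bonferroni-adjusted p-values.
#' @export
interaction_anova <- function(x, response = c("gain", "variance",
                                              "accuracy"),
                              cycle, error_type = NULL) {
  response <- match.arg(response)
  res <- if (inherits(x, "gs_experiment")) x$results else x
  if (is.null(error_type)) {
    error_type <- setdiff(unique(res$error_type), "none")[1]
  }
  d <- res[res$cycle == cycle & res$error_type %in% c("none", error_type) &
             !is.na(res[[response]]), ]
  if (length(unique(d$rate)) < 2 || length(unique(d$scheme)) < 2) {
    stop("need at least two rates and both schemes")
  }
  counts <- table(d$rate, d$scheme)
  if (length(unique(as.vector(counts))) != 1) {
    stop("unbalanced design: missing cells")
  }
  d$m <- factor(d$rate)
  d$s <- factor(d$scheme)
  fit <- stats::aov(d[[response]] ~ m * s, data = d)
  tab <- summary(fit)[[1]]
  p_int <- tab[trimws(rownames(tab)) == "m:s", "Pr(>F)"]
  list(fit = fit, table = tab, p_interaction = p_int)
}

#' @rdname interaction_anova
#' @param responses Responses included in the Bonferroni family.
#' @param cycles Cycles included in the Bonferroni family.
#' @export
interaction_anova_all <- function(x, responses = c("gain", "variance",
                                                   "accuracy"),
                                  cycles = NULL, error_type = NULL) {
  res <- if (inherits(x, "gs_experiment")) x$results else x
  if (is.null(cycles)) cycles <- sort(unique(res$cycle[res$cycle >= 1]))
  rows <- list()
  for (rsp in responses) {
    for (cy in cycles) {
      ok <- tryCatch(interaction_anova(res, rsp, cy, error_type),
                     error = function(e) NULL)
      if (is.null(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(response = rsp, cycle = cy,
                                              p = ok$p_interaction)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * nrow(out), 1)   # Bonferroni over the family
  out
}

#' Pairwise scenario comparisons of final gain
#'
#' Compares final-population genotypic gains between all scenario pairs
#' within an error type using t tests with Bonferroni correction.  By
#' default the tests are paired by replicate, since scenarios within a
#' replicate share the founder population and random substreams.
#'
#' @param x A `gs_experiment` or its `results` data frame.
#' @param cycle Population compared (default: the final one).
#' @param paired Pair by replicate (default TRUE).
#' @param error_type Error type family (with its rate-0 baseline).
#' @return Data frame with one row per scenario pair: mean difference,
#'   raw and Bonferroni-adjusted p-values.
#' @export
pairwise_gain_tests <- function(x, cycle = NULL, paired = TRUE,
                                error_type = NULL) {
  res <- if (inherits(x, "gs_experiment")) x$results else x
  if (is.null(cycle)) cycle <- max(res$pop)
  if (is.null(error_type)) {
    error_type <- setdiff(unique(res$error_type), "none")[1]
  }
  d <- res[res$pop == cycle & res$error_type %in% c("none", error_type), ]
  d$scenario <- sprintf("%s_e%.2f", d$scheme, d$rate)
  scen <- sort(unique(d$scenario))
  if (length(scen) < 2) stop("need at least two scenarios")
  rows <- list()
  for (i in seq_along(scen)) {
    for (j in seq_len(i)) {
      a <- d[d$scenario == scen[i], ]
      b <- d[d$scenario == scen[j], ]
      if (paired) {
        a <- a[order(a$rep), ]
        b <- b[order(b$rep), ]
        stopifnot(identical(a$rep, b$rep))
      }
      if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 replicates")
      p <- if (i == j) 1 else
        stats::t.test(a$gain, b$gain, paired = paired)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        scenario1 = scen[i], scenario2 = scen[j],
        mean_diff = mean(a$gain) - mean(b$gain), p = p)
    }
  }
  out <- do.call(rbind, rows)
  m <- sum(out$scenario1 != out$scenario2)   # family size: distinct pairs
  out$p_adj <- pmin(out$p * m, 1)
  out
}

#' Response decomposition under mislabeling
#'
#' Under truncation selection on genomic predictions the expected
#' per-cycle response is `R = i r sigma_A`; with a fraction `e` of
#' mislabeled clones selected at random the expectation attenuates to
#' `R = (1 - e) i r sigma_A`.  Because the selection intensity is
#' identical across cycles 2-4, the informative quantities are ratios
#' against the rate-0 baseline of the same scheme and replicate (paired
#' by shared founders): the observed response over cycles 2-4, computed
#' as the mean increment from population 1 to the final population, and
#' the per-cycle \code{r * sigma_A} product.
#'
#' @param x A `gs_experiment` or its `results` data frame.
#' @param error_type Error type analysed.
#' @return A list of two data frames: `response` (per replicate and rate:
#'   observed response, baseline response, `observed_ratio`, and the
#'   `expected_ratio` `1 - e`) and `rsigma` (per replicate, rate and
#'   cycle 2+: the \code{r * sigma_A} ratio against baseline).
#' @export
response_decomposition <- function(x, error_type = NULL) {
  res <- if (inherits(x, "gs_experiment")) x$results else x
  if (is.null(error_type)) {
    error_type <- setdiff(unique(res$error_type), "none")[1]
  }
  res <- res[res$error_type %in% c("none", error_type), ]
  final_pop <- max(res$pop)
  resp_rows <- list()
  rs_rows <- list()
  for (sch in unique(res$scheme)) {
    base <- res[res$scheme == sch & res$rate == 0, ]
    if (!nrow(base)) stop("no rate-0 baseline for scheme ", sch)
    for (e in sort(unique(res$rate))) {
      d <- res[res$scheme == sch & res$rate == e &
                 res$error_type == ifelse(e == 0, "none", error_type), ]
      for (rp in unique(d$rep)) {
        dd <- d[d$rep == rp, ]
        bb <- base[base$rep == rp, ]
        obs <- (dd$gain[dd$pop == final_pop] - dd$gain[dd$pop == 1]) /
          (final_pop - 1)
        ref <- (bb$gain[bb$pop == final_pop] - bb$gain[bb$pop == 1]) /
          (final_pop - 1)
        resp_rows[[length(resp_rows) + 1L]] <- data.frame(
          scheme = sch, rate = e, rep = rp, observed = obs, baseline = ref,
          observed_ratio = if (abs(ref) > 1e-12) obs / ref else NA_real_,
          expected_ratio = 1 - e)
        cyc <- dd$cycle[!is.na(dd$accuracy) & dd$cycle >= 2]
        for (cy in cyc) {
          num <- dd$accuracy[dd$cycle == cy] * dd$sigma_A[dd$cycle == cy]
          den <- bb$accuracy[bb$cycle == cy] * bb$sigma_A[bb$cycle == cy]
          rs_rows[[length(rs_rows) + 1L]] <- data.frame(
            scheme = sch, rate = e, rep = rp, cycle = cy,
            rsigma = num, rsigma_baseline = den,
            rsigma_ratio = if (is.finite(den) && abs(den) > 1e-12)
              num / den else NA_real_)
        }
      }
    }
  }
  list(response = do.call(rbind, resp_rows),
       rsigma = do.call(rbind, rs_rows))
}

#' Expected standardized selection intensity
#'
#' Expected standardized selection differential when the top `n_selected`
#' of `n_candidates` independent standard-normal values are truncated:
#' the mean of the expectations of the top order statistics, computed by
#' numerical integration of the exact order-statistic densities.
#'
#' @param n_selected Number selected (0 < n_selected <= n_candidates).
#' @param n_candidates Number of candidates.
#' @return The selection intensity `i` (0 when everyone is selected).
#' @examples
#' selection_intensity(40, 600)
#' @export
selection_intensity <- function(n_selected, n_candidates) {
  stopifnot(n_selected >= 1, n_candidates >= n_selected)
  if (n_selected == n_candidates) return(0)
  n <- n_candidates
  e_order <- function(j) {
    lc <- lgamma(n + 1) - lgamma(j) - lgamma(n - j + 1)
    stats::integrate(function(z) {
      z * exp(lc + (j - 1) * stats::pnorm(z, log.p = TRUE) +
                (n - j) * stats::pnorm(z, lower.tail = FALSE,
                                       log.p = TRUE)) * stats::dnorm(z)
    }, -10, 10, rel.tol = 1e-9)$value
  }
  mean(vapply(seq(n - n_selected + 1, n), e_order, 0))
}

#' Expected response to selection under mislabeling
#'
#' The breeder's-equation expectation `R = (1 - e) i r sigma_A` for
#' genomic selection with a fraction `e` of mislabeled training clones
#' (mislabeled clones are selected at random and contribute no expected
#' response).  With `e = 0` this reduces to `R = i r sigma_A`, and for
#' phenotypic selection `r` is replaced by the square root `h` of the
#' narrow-sense heritability.
#'
#' @param e Mislabeling rate.
#' @param i Selection intensity.
#' @param r Prediction accuracy (or `h` for phenotypic selection).
#' @param sigma_A Square root of the additive genetic variance.
#' @return Expected response, same units as `sigma_A`.
#' @examples
#' expected_response(0.2, 2, 0.5, 0.8)  # 0.64
#' @export
expected_response <- function(e, i, r, sigma_A) {
  stopifnot(all(e >= 0), all(e <= 1))
  (1 - e) * i * r * sigma_A
}

#' Accuracy advantage of the seedling scheme
#'
#' For each (error type, rate), compares the mean prediction accuracy
#' (among correctly labeled candidates) of the seedling scheme against
#' the no-seedling scheme over selection cycles 2 onward, in paired
#' trajectories sharing founders and seeds, and expresses the advantage
#' as a relative improvement in percent:
#' `100 * mean over cycles of (r_seedling - r_no_seedling) / r_no_seedling`.
#'
#' @param x A `gs_experiment` (must contain both schemes) or its
#'   `results` data frame.
#' @param cycles Cycles averaged over (default: 2 to the last).
#' @return A list with `per_rate` (data frame: `error_type`, `rate`,
#'   `improvement_pct`) and `min_improvement_pct`, the smallest relative
#'   improvement across error types and rates.
#' @export
seedling_accuracy_advantage <- function(x, cycles = NULL) {
  res <- if (inherits(x, "gs_experiment")) x$results else x
  res <- res[!is.na(res$accuracy) & res$cycle >= 2, ]
  if (is.null(cycles)) cycles <- 2:max(res$cycle)
  res <- res[res$cycle %in% cycles, ]
  stopifnot(all(c("seedling", "no_seedling") %in% res$scheme))
  sp <- split(res, res[, c("error_type", "rate")], drop = TRUE)
  per <- do.call(rbind, lapply(sp, function(d) {
    ms <- tapply(d$accuracy[d$scheme == "seedling"],
                 d$cycle[d$scheme == "seedling"], mean)
    mn <- tapply(d$accuracy[d$scheme == "no_seedling"],
                 d$cycle[d$scheme == "no_seedling"], mean)
    cyc <- intersect(names(ms), names(mn))
    data.frame(error_type = d$error_type[1], rate = d$rate[1],
               improvement_pct = 100 * mean((ms[cyc] - mn[cyc]) / mn[cyc]))
  }))
  rownames(per) <- NULL
  list(per_rate = per[order(per$error_type, per$rate), ],
       min_improvement_pct = min(per$improvement_pct))
}
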