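#' Configuration of the recurrent genomic-selection scheme
#'
#' Defaults follow the simulated clonal breeding programme: 200 founder
#' clones with historical records, 40 parents selected per cycle on
#' predicted genotypic value, cohorts of 600 seedlings, four selection
#' cycles, and per-stage clone-mean error variances of 1/36/16/9
#' (historical/seedling/CET/PYT).  `scheme = "seedling"` updates the
#' prediction model with the current cohort's seedling phenotypes before
#' selection; `"no_seedling"` never uses seedling records, so the model
#' used at cycle 2 is the one trained on historical data only.
#'
#' @param n_select Number of clones selected per cycle.
#' @param cohort_size Number of seedlings per progeny cohort.
#' @param n_cycles Number of selection cycles.
#' @param scheme `"seedling"` or `"no_seedling"`.
#' @param error_type `"none"`, `"source"`, or `"substitution"`.
#' @param rate Mislabeling rate e in \[0, 1\] applied to every cohort at
#'   its one-time genotyping, the historical founder cohort included.
#' @param error_variances Named per-stage error variances.
#' @return An object of class `scheme_config`.
#' @export
scheme_config <- function(n_select = 40, cohort_size = 600, n_cycles = 4,
                          scheme = c("seedling", "no_seedling"),
                          error_type = c("none", "source", "substitution"),
                          rate = 0,
                          error_variances = default_error_variances()) {
  scheme <- match.arg(scheme)
  error_type <- match.arg(error_type)
  stopifnot(n_select >= 2, cohort_size > n_select, n_cycles >= 1,
            rate >= 0, rate <= 1,
            all(c("historical", "seedling", "CET", "PYT") %in%
                  names(error_variances)))
  if (rate > 0 && error_type == "none") error_type <- "source"
  structure(list(n_select = as.integer(n_select),
                 cohort_size = as.integer(cohort_size),
                 n_cycles = as.integer(n_cycles), scheme = scheme,
                 error_type = error_type, rate = rate,
                 error_variances = error_variances),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf("Scheme: %s | %d cycles | select %d of %d | %s error at rate %.2f\n",
              x$scheme, x$n_cycles, x$n_select, x$cohort_size,
              x$error_type, x$rate))
  invisible(x)
}

#' Truncation selection on predicted values
#'
#' Returns the ids of the `n` candidates with the largest predicted
#' genotypic values.  Ties are broken by stable id order (the order of
#' `predictions`), so results are reproducible.
#'
#' @param predictions Named numeric vector, candidate id -> predicted value.
#' @param n Number to select.
#' @return Character vector of `n` selected ids.
#' @export
select_top <- function(predictions, n) {
  stopifnot(!is.null(names(predictions)), n >= 1)
  if (length(predictions) < n) stop("fewer candidates than n")
  ord <- order(-predictions, seq_along(predictions))
  names(predictions)[ord[seq_len(n)]]
}

#' Run one trajectory of the breeding scheme
#'
#' Orchestrates the full recurrent-selection programme on a founder
#' population: per cycle it (i) phenotypes cohorts according to the trial
#' schedule (seedlings of the candidate cohort, CET of the previous
#' cohort's nonselected clones, PYT of the cohort before that);
#' (ii) genotypes each new cohort once and injects labeling errors (the
#' founder cohort is genotyped, and mislabeled, at cycle 1 in the same
#' way);
#' (iii) trains the heteroscedastic GBLUP on all accumulated records
#' (seedling records only in the seedling scheme; at cycle 2 the
#' no-seedling scheme therefore reuses the historical-data model);
#' (iv) predicts the candidates from their label-linked genotypes;
#' (v) selects the top `n_select`; and (vi) random-crosses the true
#' genomes of the selected clones to create the next cohort (plus a
#' backup cohort when source errors are simulated).
#'
#' Genotypic values are expressed as gain relative to the founder mean
#' (population 0 has mean 0 by construction).
#'
#' @param founders A `clone_pop` of founders (cohort 0).
#' @param arch A `trait_arch` scaled on these founders.
#' @param config A `scheme_config`.
#' @param seed Master seed of the trajectory; all randomness is drawn from
#'   named substreams of it.
#' @param keep_populations Keep the clone populations in the result
#'   (memory-heavy; default FALSE).
#' @return An object of class `gs_trajectory`: list with `cycles` (data
#'   frame per selection cycle: accuracy among correctly labeled
#'   candidates, sigma_A of the candidate cohort, selection intensity
#'   inputs, mislabeled-selected counts, training-set sizes) and `pops`
#'   (per-population mean gain and genetic variance), plus `config`,
#'   `seed` and the mislabel `audit` log.
#' @export
run_scheme <- function(founders, arch, config, seed,
                       keep_populations = FALSE) {
  stopifnot(inherits(founders, "clone_pop"), inherits(arch, "trait_arch"),
            inherits(config, "scheme_config"))
  founders$gv <- genotypic_value(founders, arch)
  founders <- genotype_cohort(founders)
  ## the historical training population is itself subject to labeling
  ## errors at its one-time genotyping; source errors draw genotypes from
  ## the shadow-germplasm sample of the same coalescent population
  audit <- list()
  if (config$rate > 0) {
    if (config$error_type == "source") {
      if (is.null(founders$founder_backup)) {
        stop("source errors on the founder cohort need a shadow-germplasm ",
             "backup (founder_config(n_backup > 0))")
      }
      founders <- inject_source_error(founders, founders$founder_backup,
                                      config$rate,
                                      seed = substream_seed(seed, 0L,
                                                            "mislabel"))
    } else if (config$error_type == "substitution") {
      founders <- inject_substitution_error(founders, config$rate,
                                            seed = substream_seed(seed, 0L,
                                                                  "mislabel"))
    }
    audit[[1L]] <- mislabel_audit(founders, 0L, config$error_type)
  }
  pops <- list(founders)
  records <- phenotype_cohort(founders, "historical", cycle = 0L,
                              seed = substream_seed(seed, 0L, "pheno"),
                              error_variances = config$error_variances)
  selected <- list()
  cyc_rows <- list()

  for (cycle in seq_len(config$n_cycles)) {
    cand <- pops[[cycle]]
    ## (i) phenotype per schedule (cycle 1 uses historical records only)
    if (cycle >= 2L) {
      if (config$scheme == "seedling") {
        records <- rbind(records,
          phenotype_cohort(cand, "seedling", cycle,
                           seed = substream_seed(seed, cycle, "pheno_seedling"),
                           error_variances = config$error_variances))
      }
      if (cycle >= 3L) {
        prev <- pops[[cycle - 1L]]
        nonsel <- setdiff(prev$ids, selected[[cycle - 1L]])
        j <- match(nonsel, prev$ids)
        records <- rbind(records,
          phenotype_cohort(NULL, "CET", cycle,
                           seed = substream_seed(seed, cycle, "pheno_cet"),
                           error_variances = config$error_variances,
                           ids = nonsel, gv = prev$gv[j]))
      }
      if (cycle >= 4L) {
        pyt <- pops[[cycle - 2L]]
        records <- rbind(records,
          phenotype_cohort(pyt, "PYT", cycle,
                           seed = substream_seed(seed, cycle, "pheno_pyt"),
                           error_variances = config$error_variances))
      }
    }
    ## (iii) kinship over all genotyped clones (label-linked genotypes)
    G <- do.call(cbind, lapply(pops, linked_genotypes))
    K <- compute_kinship(t(G))
    fit <- gblup(value ~ 1, records, K)
    ## (iv) predict candidates from label-linked genotypes
    pred <- predict(fit, ids = cand$ids)
    ## accuracy among correctly labeled candidates
    ok <- !cand$mislabeled
    acc <- if (sum(ok) >= 3 && stats::sd(cand$gv[ok]) > 0 &&
                 stats::sd(pred[ok]) > 0) {
      stats::cor(cand$gv[ok], pred[ok])
    } else NA_real_
    ## (v) select
    sel <- select_top(pred, config$n_select)
    selected[[cycle]] <- sel
    n_mis_sel <- sum(cand$mislabeled[match(sel, cand$ids)])
    cyc_rows[[cycle]] <- data.frame(
      cycle = cycle, accuracy = acc,
      sigma_A = stats::sd(cand$gv),
      n_candidates = length(cand$ids),
      n_selected = config$n_select,
      n_mislabeled_candidates = sum(cand$mislabeled),
      n_mislabeled_selected = n_mis_sel,
      n_records = nrow(records), n_train_ids = fit$n_ids,
      lambda = fit$lambda)
    ## (vi) next cohort from the true genomes of the selected clones
    progeny <- random_cross(cand, sel, config$cohort_size,
                            seed = substream_seed(seed, cycle, "cross"),
                            cohort = cycle)
    progeny$gv <- genotypic_value(progeny, arch)
    if (cycle < config$n_cycles) {
      progeny <- genotype_cohort(progeny)
      if (config$rate > 0) {
        if (config$error_type == "source") {
          backup <- make_backup(cand, sel, config$cohort_size,
                                seed = substream_seed(seed, cycle, "backup"),
                                cohort = cycle)
          progeny <- inject_source_error(progeny, backup, config$rate,
            seed = substream_seed(seed, cycle, "mislabel"))
        } else if (config$error_type == "substitution") {
          progeny <- inject_substitution_error(progeny, config$rate,
            seed = substream_seed(seed, cycle, "mislabel"))
        }
        audit[[length(audit) + 1L]] <-
          mislabel_audit(progeny, cycle, config$error_type)
      }
    }
    pops[[cycle + 1L]] <- progeny
  }

  pop_stats <- data.frame(
    pop = seq_along(pops) - 1L,
    gain = vapply(pops, function(p) mean(p$gv), 0),
    variance = vapply(pops, function(p) stats::var(p$gv), 0))
  out <- list(cycles = do.call(rbind, cyc_rows), pops = pop_stats,
              selected = selected,
              audit = if (length(audit)) do.call(rbind, audit) else NULL,
              config = config, seed = seed,
              populations = if (keep_populations) pops else NULL,
              records = records)
  class(out) <- "gs_trajectory"
  out
}

#' @export
print.gs_trajectory <- function(x, ...) {
  cat(sprintf("GS trajectory: %s scheme, %s error, rate %.2f (seed %d)\n",
              x$config$scheme, x$config$error_type, x$config$rate, x$seed))
  df <- merge(x$pops, transform(x$cycles, pop = cycle), by = "pop",
              all.x = TRUE)
  print(df[, c("pop", "gain", "variance", "accuracy",
               "n_mislabeled_selected")], digits = 3, row.names = FALSE)
  invisible(x)
}
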