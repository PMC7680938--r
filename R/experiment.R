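#' Specify a simulation experiment grid
#'
#' Bundles a founder configuration, a base scheme configuration and a
#' scenario grid (error type x mislabeling rate x scheme) with a
#' replicate count.  Three scale presets are provided:
#' \describe{
#'   \item{`full`}{The full study conditions: 18 x 110 cM genome, 2500
#'     markers, 100 QTL, cohorts of 600, both error types, 100
#'     replicates.  A multi-hour batch run.}
#'   \item{`reduced`}{Desk-scale conditions preserving the design: 6
#'     chromosomes, 500 markers, 50 QTL, cohorts of 300, source errors,
#'     20 replicates.  Reproduces the qualitative orderings in tens of
#'     minutes on one CPU.}
#'   \item{`toy`}{A smoke-test scale for examples and CI (2 chromosomes,
#'     60 markers, cohorts of 50, 2 replicates).}
#' }
#' Within a replicate all scenarios share the founder population, trait
#' architecture, and named random substreams, enabling paired
#' scenario comparisons.
#'
#' @param preset `"reduced"`, `"full"`, or `"toy"`.
#' @param rates Mislabeling rates; rate 0 is the shared baseline.
#' @param error_types Subset of `c("source", "substitution")`.
#' @param schemes Subset of `c("seedling", "no_seedling")`.
#' @param n_reps Number of replicates.
#' @param founder Optional [founder_config()] overriding the preset's.
#' @param n_select,cohort_size,n_cycles Scheme parameters overriding the
#'   preset's.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(preset = c("reduced", "full", "toy"),
                            rates = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                            error_types = NULL, schemes = c("seedling",
                                                            "no_seedling"),
                            n_reps = NULL, founder = NULL, n_select = NULL,
                            cohort_size = NULL, n_cycles = 4) {
  preset <- match.arg(preset)
  base <- switch(preset,
    full = list(founder = founder_config(), n_reps = 100L,
                 cohort_size = 600L, n_select = 40L,
                 error_types = c("source", "substitution")),
    reduced = list(founder = founder_config(n_chrom = 6, n_markers = 500,
                                            n_qtl = 50),
                   n_reps = 20L, cohort_size = 300L, n_select = 40L,
                   error_types = "source"),
    toy = list(founder = founder_config(n_chrom = 2, segments = 2000,
                                        n_markers = 60, n_qtl = 10,
                                        n_founders = 40),
               n_reps = 2L, cohort_size = 50L, n_select = 10L,
               error_types = "source"))
  spec <- list(preset = preset,
               founder = if (is.null(founder)) base$founder else founder,
               n_reps = as.integer(if (is.null(n_reps)) base$n_reps
                                   else n_reps),
               n_select = if (is.null(n_select)) base$n_select
                          else as.integer(n_select),
               cohort_size = if (is.null(cohort_size)) base$cohort_size
                             else as.integer(cohort_size),
               n_cycles = as.integer(n_cycles),
               rates = sort(unique(rates)),
               error_types = if (is.null(error_types)) base$error_types
                             else match.arg(error_types,
                                            c("source", "substitution"),
                                            several.ok = TRUE),
               schemes = match.arg(schemes, c("seedling", "no_seedling"),
                                   several.ok = TRUE))
  stopifnot(spec$n_reps >= 1, length(spec$rates) >= 1)
  class(spec) <- "experiment_spec"
  spec
}

#' @export
print.experiment_spec <- function(x, ...) {
  grid <- scenario_grid(x)
  cat(sprintf("Experiment spec (%s): %d replicates x %d scenarios = %d trajectories\n",
              x$preset, x$n_reps, nrow(grid), x$n_reps * nrow(grid)))
  cat(sprintf("  cohort %d, select %d, %d cycles; rates %s; error types %s; schemes %s\n",
              x$cohort_size, x$n_select, x$n_cycles,
              paste(x$rates, collapse = "/"),
              paste(x$error_types, collapse = "/"),
              paste(x$schemes, collapse = "/")))
  invisible(x)
}

#' Scenario grid of an experiment
#'
#' Expands (scheme x error type x rate) with the zero-rate baseline run
#' once per scheme (labelled error type `"none"`), since a rate of 0 is
#' identical under both error mechanisms.
#'
#' @param spec An `experiment_spec`.
#' @return Data frame with columns `scheme`, `error_type`, `rate`.
#' @export
scenario_grid <- function(spec) {
  rows <- list()
  for (sch in spec$schemes) {
    if (0 %in% spec$rates) {
      rows[[length(rows) + 1L]] <- data.frame(scheme = sch,
                                              error_type = "none", rate = 0)
    }
    for (et in spec$error_types) {
      for (e in setdiff(spec$rates, 0)) {
        rows[[length(rows) + 1L]] <- data.frame(scheme = sch,
                                                error_type = et, rate = e)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run a replicated simulation experiment
#'
#' For each replicate: simulates an independent founder population, draws
#' the marker/QTL panel and trait architecture, then runs every scenario
#' of the grid on those shared founders (paired design).  Results are
#' returned as a tidy table with one row per (replicate, scenario,
#' population), fully deterministic given `(spec, seed)`.
#'
#' @param spec An [experiment_spec()].
#' @param seed Integer master seed.
#' @param dir Optional output directory; when given, writes
#'   `results.tsv` (the tidy table) and `manifest.json` (configuration,
#'   seed, package version).
#' @param verbose Print per-replicate progress.
#' @return An object of class `gs_experiment`: list with `results`
#'   (tidy data frame with columns `rep`, `scheme`, `error_type`, `rate`,
#'   `pop`, `cycle`, `gain`, `variance`, `accuracy`, `sigma_A`,
#'   `n_candidates`, `n_selected`, `n_mislabeled_selected`,
#'   `n_records`), `spec`, and `seed`.
#' @export
run_experiment <- function(spec, seed, dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- scenario_grid(spec)
  rows <- vector("list", spec$n_reps * nrow(grid))
  k <- 0L
  for (rep in seq_len(spec$n_reps)) {
    fseed <- substream_seed(seed, rep, "founders")
    fp <- simulate_founders(spec$founder, seed = fseed)
    fp <- sample_loci(fp, seed = substream_seed(seed, rep, "loci"))
    founders <- as_clone_pop(fp)
    arch <- trait_architecture(founders,
                               seed = substream_seed(seed, rep, "effects"))
    traj_seed_base <- substream_seed(seed, rep, "scheme")
    for (g in seq_len(nrow(grid))) {
      cfg <- scheme_config(n_select = spec$n_select,
                           cohort_size = spec$cohort_size,
                           n_cycles = spec$n_cycles,
                           scheme = grid$scheme[g],
                           error_type = grid$error_type[g],
                           rate = grid$rate[g])
      tr <- run_scheme(founders, arch, cfg, seed = traj_seed_base)
      tab <- merge(tr$pops, transform(tr$cycles, pop = cycle),
                   by = "pop", all.x = TRUE)
      k <- k + 1L
      rows[[k]] <- data.frame(
        rep = rep, scheme = grid$scheme[g],
        error_type = grid$error_type[g], rate = grid$rate[g],
        pop = tab$pop, cycle = tab$pop,
        gain = tab$gain, variance = tab$variance,
        accuracy = tab$accuracy, sigma_A = tab$sigma_A,
        n_candidates = tab$n_candidates, n_selected = tab$n_selected,
        n_mislabeled_selected = tab$n_mislabeled_selected,
        n_records = tab$n_records)
    }
    if (verbose) {
      message(sprintf("replicate %d/%d done (founder seed %d)",
                      rep, spec$n_reps, fseed))
    }
  }
  out <- list(results = do.call(rbind, rows), spec = spec, seed = seed)
  class(out) <- "gs_experiment"
  if (!is.null(dir)) write_experiment(out, dir)
  out
}

#' Backwards-compatible replicate runner
#'
#' Thin wrapper over [run_experiment()] for running a scenario grid with
#' an explicit replicate count.
#'
#' @param spec An [experiment_spec()].
#' @param n_reps Number of replicates (overrides the spec's).
#' @param seed Master seed.
#' @return A `gs_experiment`; see [run_experiment()].
#' @export
run_replicates <- function(spec, n_reps = spec$n_reps, seed) {
  spec$n_reps <- as.integer(n_reps)
  run_experiment(spec, seed = seed)
}

#' @export
print.gs_experiment <- function(x, ...) {
  res <- x$results
  cat(sprintf("GS experiment (%s preset): %d replicates, %d scenarios, seed %d\n",
              x$spec$preset, max(res$rep),
              nrow(unique(res[, c("scheme", "error_type", "rate")])),
              x$seed))
  fin <- res[res$pop == max(res$pop), ]
  agg <- stats::aggregate(cbind(gain, variance) ~ scheme + rate, fin, mean)
  cat("Mean final gain / genetic variance by scenario:\n")
  print(agg, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.gs_experiment <- function(object, ...) {
  gain_summary(object)
}

#' Plot mean trajectories of an experiment
#'
#' Mean gain (or genetic variance, or prediction accuracy) per population
#' across replicates, one line per mislabeling rate, solid for the
#' seedling and dashed for the no-seedling scheme.
#'
#' @param x A `gs_experiment`.
#' @param response One of `"gain"`, `"variance"`, `"accuracy"`.
#' @param error_type Error type to display.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted means.
#' @export
plot.gs_experiment <- function(x, response = c("gain", "variance",
                                               "accuracy"),
                               error_type = NULL, ...) {
  response <- match.arg(response)
  res <- x$results
  if (is.null(error_type)) {
    error_type <- c("none", x$spec$error_types[1])
  } else {
    error_type <- c("none", error_type)
  }
  res <- res[res$error_type %in% error_type & !is.na(res[[response]]), ]
  agg <- stats::aggregate(res[[response]],
                          by = res[, c("pop", "rate", "scheme")], FUN = mean)
  rates <- sort(unique(agg$rate))
  pops <- sort(unique(agg$pop))
  cols <- grDevices::hcl.colors(max(length(rates), 2L), "viridis")
  graphics::matplot(NA, NA, xlim = range(pops), ylim = range(agg$x),
                    xlab = "Population", ylab = response, ...)
  for (i in seq_along(rates)) {
    for (sch in unique(agg$scheme)) {
      sub <- agg[agg$rate == rates[i] & agg$scheme == sch, ]
      sub <- sub[order(sub$pop), ]
      graphics::lines(sub$pop, sub$x, col = cols[i],
                      lty = if (sch == "seedling") 1 else 2)
    }
  }
  graphics::legend("topleft", legend = sprintf("e = %.2f", rates),
                   col = cols[seq_along(rates)], lty = 1, cex = 0.8)
  invisible(agg)
}

#' Deterministic miniature objects for tests and examples
#'
#' @param kind `"founder"` (a small founder population with panel),
#'   `"cohort"` (a progeny cohort with genotypic values), or `"records"`
#'   (a phenotype table plus kinship matrix ready for [gblup()]).
#' @param seed Integer seed.
#' @return The requested object.
#' @export
generate_fixture <- function(kind = c("founder", "cohort", "records"),
                             seed = 1) {
  kind <- match.arg(kind)
  cfg <- founder_config(n_chrom = 2, segments = 2000, n_founders = 20,
                        n_markers = 50, n_qtl = 5)
  fp <- simulate_founders(cfg, seed = substream_seed(seed, "fixture"))
  fp <- sample_loci(fp, seed = substream_seed(seed, "fixture", "loci"))
  if (kind == "founder") return(fp)
  founders <- as_clone_pop(fp)
  arch <- trait_architecture(founders,
                             seed = substream_seed(seed, "fixture", "arch"))
  founders$gv <- genotypic_value(founders, arch)
  if (kind == "cohort") {
    cohort <- random_cross(founders, founders$ids[1:6], 30,
                           seed = substream_seed(seed, "fixture", "cross"))
    cohort$gv <- genotypic_value(cohort, arch)
    return(cohort)
  }
  founders <- genotype_cohort(founders)
  recs <- rbind(
    phenotype_cohort(founders, "historical", 0,
                     seed = substream_seed(seed, "fixture", "ph")),
    phenotype_cohort(founders, "CET", 1,
                     seed = substream_seed(seed, "fixture", "pc")))
  K <- compute_kinship(t(linked_genotypes(founders)))
  list(records = recs, K = K, founders = founders, arch = arch)
}
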