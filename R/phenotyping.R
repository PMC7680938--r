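#' Default per-stage phenotype error variances
#'
#' Clone-mean error variances, in units of the (unit) founder genetic
#' variance, for each phenotyping stage: historical evaluation of the
#' founders (1.0, clone-mean heritability 0.5, reflecting repeated past
#' evaluation), single-plant seedling trials (36.0, heritability 1/37,
#' under 3%), clonal evaluation trials with about 5 plants per clone
#' (16.0), and preliminary yield trials with about 20 plants (9.0).
#' Replicate plants within a trial are already collapsed into these
#' clone-mean variances, so each (clone, stage) yields one record.
#'
#' @return Named numeric vector with elements `historical`, `seedling`,
#'   `CET`, `PYT`.
#' @export
default_error_variances <- function() {
  c(historical = 1.0, seedling = 36.0, CET = 16.0, PYT = 9.0)
}

#' Clone-mean heritability of a phenotyping stage
#'
#' h2 = var_g / (var_g + var_e) on the clone-mean scale.
#'
#' @param error_variance Clone-mean error variance of the stage.
#' @param genetic_variance Genetic variance (default 1, the founder scale).
#' @return Heritability in (0, 1\].
#' @examples
#' clone_mean_heritability(1)   # historical: 0.5
#' clone_mean_heritability(36)  # seedling: < 3%
#' @export
clone_mean_heritability <- function(error_variance, genetic_variance = 1) {
  stopifnot(error_variance >= 0, genetic_variance > 0)
  genetic_variance / (genetic_variance + error_variance)
}

#' Phenotype a cohort at a trial stage
#'
#' Generates one phenotype record per clone: the true genotypic value plus
#' an independent normal deviate with the stage's clone-mean error
#' variance.  Noise draws are independent across clones and across stages.
#'
#' @param pop A `clone_pop` with genotypic values, or `NULL` if `ids` and
#'   `gv` are given directly.
#' @param stage One of `"historical"`, `"seedling"`, `"CET"`, `"PYT"` (or
#'   any stage named in `error_variances`).
#' @param cycle Integer cycle index at which the records are observed.
#' @param seed Integer random seed.
#' @param error_variances Named vector of stage error variances.
#' @param ids,gv Clone ids and genotypic values (used when `pop` is NULL,
#'   e.g. to phenotype a subset of a cohort).
#' @return Data frame with columns `clone_id`, `stage`, `cycle`, `value`,
#'   `error_variance`.
#' @export
phenotype_cohort <- function(pop = NULL, stage, cycle, seed,
                             error_variances = default_error_variances(),
                             ids = NULL, gv = NULL) {
  if (!is.null(pop)) {
    stopifnot(inherits(pop, "clone_pop"), !is.null(pop$gv))
    ids <- pop$ids
    gv <- pop$gv
  }
  stopifnot(length(ids) == length(gv))
  if (!stage %in% names(error_variances)) {
    stop("unknown phenotyping stage: ", stage)
  }
  ve <- unname(error_variances[stage])
  noise <- with_seed(seed, stats::rnorm(length(gv), 0, sqrt(ve)))
  data.frame(clone_id = ids, stage = stage, cycle = as.integer(cycle),
             value = gv + noise, error_variance = ve)
}

#' Phenotyping schedule of the breeding scheme
#'
#' At the cycle when cohort `t-1` is the selection candidate population:
#' cohort `t-1` is at the seedling stage; the nonselected members of
#' cohort `t-2` are in the clonal evaluation trial (selected clones moved
#' to the crossing nursery and are never CET-phenotyped); and all members
#' of cohort `t-3` are in the preliminary yield trial.  Cohort 0 founders
#' carry historical records only.
#'
#' @param cycle Selection cycle index (1-based; cycle 1 selects among the
#'   founders and triggers no new trials).
#' @return Data frame with columns `cohort`, `stage`, `subset`
#'   (`"all"` or `"nonselected"`); zero rows for cycle 1.
#' @examples
#' schedule_trials(3)  # seedlings of cohort 2, CET of cohort 1 nonselected
#' @export
schedule_trials <- function(cycle) {
  cycle <- as.integer(cycle)
  stopifnot(cycle >= 1)
  out <- data.frame(cohort = c(cycle - 1L, cycle - 2L, cycle - 3L),
                    stage = c("seedling", "CET", "PYT"),
                    subset = c("all", "nonselected", "all"))
  out[out$cohort >= 1L, , drop = FALSE]
}
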