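#' Inject source labeling errors into a genotyped cohort
#'
#' A source error arises when the DNA sample analysed under a clone's
#' label was taken from the backup population (extra progeny of the same
#' parents) rather than from the phenotyped breeding population.  A
#' uniformly random subset of `round(rate * n)` cohort clones has its
#' linked genotype replaced by that of a distinct backup clone, one-to-one
#' and without replacement.  Phenotypes, true genomes and crossing
#' behaviour are untouched; because genotyping happens only once, the
#' wrong genotype persists through every later model update.
#'
#' @param pop A genotyped `clone_pop` (see [genotype_cohort()]).
#' @param backup A `backup_pop` from [make_backup()] with at least
#'   `round(rate * n)` clones.
#' @param rate Mislabeling rate in \[0, 1\].
#' @param seed Integer random seed.
#' @return `pop` with `geno`, `linked_id` and `mislabeled` updated.
#' @export
inject_source_error <- function(pop, backup, rate, seed) {
  stopifnot(inherits(pop, "clone_pop"), !is.null(pop$geno),
            rate >= 0, rate <= 1)
  n <- length(pop$ids)
  k <- round(rate * n)
  if (k == 0L) return(pop)
  stopifnot(inherits(backup, "backup_pop"))
  if (ncol(backup$geno) < k) {
    stop("backup population too small: ", ncol(backup$geno),
         " clones for ", k, " errors")
  }
  with_seed(seed, {
    sel <- sample.int(n, k)
    bsel <- sample.int(ncol(backup$geno), k)
    pop$geno[, sel] <- backup$geno[, bsel]
    pop$linked_id[sel] <- backup$ids[bsel]
    pop$mislabeled[sel] <- TRUE
  })
  pop
}

#' Inject substitution labeling errors into a genotyped cohort
#'
#' A substitution error mismatches genotypes and phenotypes *within* the
#' breeding population: the linked genotypes of a random subset of
#' `round(rate * n)` clones are permuted by a derangement of the subset,
#' so every affected clone keeps its own phenotype but carries another
#' clone's marker genotype (no clone in the subset keeps its own).
#'
#' @inheritParams inject_source_error
#' @return `pop` with `geno`, `linked_id` and `mislabeled` updated.
#' @section Errors:
#' A subset of size 1 cannot be deranged and raises an error.
#' @export
inject_substitution_error <- function(pop, rate, seed) {
  stopifnot(inherits(pop, "clone_pop"), !is.null(pop$geno),
            rate >= 0, rate <= 1)
  n <- length(pop$ids)
  k <- round(rate * n)
  if (k == 0L) return(pop)
  if (k == 1L) stop("cannot derange a subset of size 1")
  with_seed(seed, {
    sel <- sample.int(n, k)
    perm <- rderangement(k)
    pop$geno[, sel] <- pop$geno[, sel[perm], drop = FALSE]
    pop$linked_id[sel] <- pop$ids[sel[perm]]
    pop$mislabeled[sel] <- TRUE
  })
  pop
}

## uniform random derangement by rejection (acceptance probability ~ 1/e)
rderangement <- function(k) {
  repeat {
    p <- sample.int(k)
    if (!any(p == seq_len(k))) return(p)
  }
}

#' Create a backup population
#'
#' Extra progeny of the same parents, generated by the same random-cross
#' procedure as the main cohort but with an independent seed.  Backup
#' clones are never phenotyped and never enter the breeding population;
#' only their marker genotypes exist, as the source of erroneously linked
#' genotypes.
#'
#' @param pop The parent `clone_pop`.
#' @param parent_ids Selected parent ids (as used for the main cohort).
#' @param n_progeny Backup size (default: same as the main cohort).
#' @param seed Integer random seed, independent of the main cohort's.
#' @param cohort Cohort index the backup shadows.
#' @return An object of class `backup_pop` with elements `ids` and `geno`
#'   (marker dosage matrix, markers x n).
#' @export
make_backup <- function(pop, parent_ids, n_progeny, seed,
                        cohort = pop$cohort + 1L) {
  bp <- random_cross(pop, parent_ids, n_progeny, seed, cohort = cohort,
                     prefix = sprintf("B%d_", cohort))
  geno <- true_marker_dosage(bp)
  colnames(geno) <- bp$ids
  structure(list(ids = bp$ids, geno = geno, cohort = cohort),
            class = "backup_pop")
}

#' @export
print.backup_pop <- function(x, ...) {
  cat(sprintf("Backup population shadowing cohort %d: %d clones (genotypes only)\n",
              x$cohort, length(x$ids)))
  invisible(x)
}

#' Audit log of injected labeling errors
#'
#' @param pop A genotyped `clone_pop`.
#' @param cycle Cycle at which the cohort was genotyped.
#' @param error_type Label recorded in the log.
#' @return Data frame with columns `cycle`, `clone_id`, `linked_genome_id`,
#'   `error_type`, one row per mislabeled clone.
#' @export
mislabel_audit <- function(pop, cycle, error_type) {
  stopifnot(inherits(pop, "clone_pop"), !is.null(pop$linked_id))
  i <- which(pop$mislabeled)
  data.frame(cycle = as.integer(cycle), clone_id = pop$ids[i],
             linked_genome_id = pop$linked_id[i],
             error_type = if (length(i)) error_type else character(0))
}
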