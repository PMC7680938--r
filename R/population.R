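#' Construct a clone population
#'
#' Low-level constructor for the container used throughout the breeding
#' simulation.  A clone population holds, for each of `n` clones, the
#' *true* phased diploid genome over the panel sites (markers + QTL), and
#' the labeling state: `linked_id` gives the identity of the genome that
#' is associated with the clone's label in training/prediction data.  For
#' a correctly labeled clone `linked_id == id`; mislabeling only ever
#' changes the label linkage (and the stored marker genotype used for
#' modelling), never the true genome, the phenotypes, or crossing
#' behaviour.
#'
#' @param ids Character vector of unique clone labels.
#' @param hapA,hapB Integer matrices, panel sites x n, the two phased
#'   haplotypes of the true genome.
#' @param sites Data frame of panel sites with columns `chrom`, `segment`,
#'   `cM`, `is_marker`, `is_qtl` (rows ordered by genome position).
#' @param map List with `n_chrom` and `chrom_cM` describing the genetic map.
#' @param cohort Integer cohort index (population 0 = founders).
#' @param pedigree Data frame with columns `id`, `mother`, `father`
#'   (NA for founders).
#' @return An object of class `clone_pop`.
#' @export
new_clone_pop <- function(ids, hapA, hapB, sites, map, cohort = 0L,
                          pedigree = NULL) {
  n <- length(ids)
  stopifnot(!anyDuplicated(ids), ncol(hapA) == n, ncol(hapB) == n,
            nrow(hapA) == nrow(sites), nrow(hapB) == nrow(sites),
            all(c("chrom", "segment", "cM", "is_marker", "is_qtl") %in%
                  names(sites)))
  if (is.null(pedigree)) {
    pedigree <- data.frame(id = ids, mother = NA_character_,
                           father = NA_character_)
  }
  structure(list(ids = ids, hapA = hapA, hapB = hapB, sites = sites,
                 map = map, cohort = as.integer(cohort),
                 pedigree = pedigree, gv = NULL,
                 geno = NULL, linked_id = NULL,
                 mislabeled = rep(FALSE, n)),
            class = "clone_pop")
}

#' Restrict a founder population to its locus panel
#'
#' Converts a `founder_pop` (all segregating sites) into the `clone_pop`
#' container used by the breeding simulation, keeping only the sampled
#' marker and QTL sites.
#'
#' @param fp A `founder_pop` with a panel from [sample_loci()].
#' @param prefix Label prefix for founder clone ids.
#' @return A `clone_pop` of the founders (cohort 0).
#' @export
as_clone_pop <- function(fp, prefix = "F") {
  stopifnot(inherits(fp, "founder_pop"), !is.null(fp$marker_idx))
  panel <- sort(c(fp$marker_idx, fp$qtl_idx))
  sites <- fp$sites[panel, c("chrom", "segment", "cM")]
  sites$is_marker <- panel %in% fp$marker_idx
  sites$is_qtl <- panel %in% fp$qtl_idx
  rownames(sites) <- NULL
  n <- fp$config$n_founders
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  H <- fp$H[panel, , drop = FALSE]
  pop <- new_clone_pop(ids = ids,
                       hapA = H[, 2L * seq_len(n) - 1L, drop = FALSE],
                       hapB = H[, 2L * seq_len(n), drop = FALSE],
                       sites = sites,
                       map = list(n_chrom = fp$config$n_chrom,
                                  chrom_cM = fp$config$chrom_cM),
                       cohort = 0L)
  if (!is.null(fp$H_backup)) {
    ## marker genotypes of the shadow-germplasm sample: the source of
    ## erroneously linked genotypes for founder-cohort source errors
    nb <- ncol(fp$H_backup) / 2L
    Hb <- fp$H_backup[panel, , drop = FALSE][sites$is_marker, , drop = FALSE]
    geno <- Hb[, 2L * seq_len(nb) - 1L, drop = FALSE] +
      Hb[, 2L * seq_len(nb), drop = FALSE]
    bids <- sprintf("B0_%04d", seq_len(nb))
    colnames(geno) <- bids
    pop$founder_backup <- structure(list(ids = bids, geno = geno,
                                         cohort = 0L),
                                    class = "backup_pop")
  }
  pop
}

#' @export
print.clone_pop <- function(x, ...) {
  cat(sprintf("Clone population (cohort %d): %d clones, %d panel sites (%d markers, %d QTL)\n",
              x$cohort, length(x$ids), nrow(x$sites),
              sum(x$sites$is_marker), sum(x$sites$is_qtl)))
  if (!is.null(x$geno)) {
    cat(sprintf("  genotyped; %d mislabeled\n", sum(x$mislabeled)))
  }
  if (!is.null(x$gv)) {
    cat(sprintf("  genotypic values: mean %.3f, var %.3f\n",
                mean(x$gv), stats::var(x$gv)))
  }
  invisible(x)
}

## true marker dosage matrix (markers x n) from the clone's own genome
true_marker_dosage <- function(pop) {
  m <- pop$sites$is_marker
  pop$hapA[m, , drop = FALSE] + pop$hapB[m, , drop = FALSE]
}

## QTL dosage matrix (n x q) from the true genome
qtl_dosage <- function(pop) {
  q <- pop$sites$is_qtl
  t(pop$hapA[q, , drop = FALSE] + pop$hapB[q, , drop = FALSE])
}

#' Genotype a cohort (once)
#'
#' Records the marker genotypes that will be linked to each clone's label
#' in all subsequent model training and prediction.  Genotyping happens
#' exactly once per clone: the stored genotype is immutable afterwards, so
#' a labeling error injected at genotyping time persists through every
#' later model update (clonal propagation re-uses the same record).
#'
#' @param pop A `clone_pop`.
#' @return `pop` with `geno` (marker dosage matrix, markers x n),
#'   `linked_id` and `mislabeled` initialised to the correct labeling.
#' @export
genotype_cohort <- function(pop) {
  stopifnot(inherits(pop, "clone_pop"))
  if (!is.null(pop$geno)) stop("cohort is already genotyped; genotyping never repeats")
  pop$geno <- true_marker_dosage(pop)
  colnames(pop$geno) <- pop$ids
  pop$linked_id <- pop$ids
  pop$mislabeled <- rep(FALSE, length(pop$ids))
  pop
}

#' Label-linked marker genotypes of a genotyped cohort
#'
#' Accessor for the marker genotypes used in training and prediction under
#' each clone's label.  For mislabeled clones this is another genome's
#' genotype; the linkage is fixed at genotyping time.
#'
#' @param pop A genotyped `clone_pop`.
#' @return Marker dosage matrix (markers x n) with clone labels as columns.
#' @export
linked_genotypes <- function(pop) {
  stopifnot(inherits(pop, "clone_pop"))
  if (is.null(pop$geno)) stop("cohort has not been genotyped")
  pop$geno
}
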