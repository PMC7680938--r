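#' Define the additive trait architecture
#'
#' Draws one additive effect per QTL from a standard normal distribution
#' and rescales all effects by a common factor so that the sample variance
#' of true genotypic values in the founder population equals 1 exactly.
#' Genotypic values are centred so that the founder (population 0) mean is
#' exactly 0; all later gains are expressed on this scale.  The trait is
#' purely additive: no dominance or epistasis.
#'
#' @param founders A `clone_pop` of founders (cohort 0) carrying QTL sites.
#' @param seed Integer random seed for the effect draws.
#' @return An object of class `trait_arch`: a list with `effects` (scaled
#'   per-QTL allele substitution effects, in genome order of the QTL
#'   sites), `intercept` (founder mean on the scaled raw scale),
#'   `scale` (the common scaling factor applied to the raw draws), and
#'   `qtl_sites` (the `chrom`/`segment` of each QTL, for validation).
#' @export
trait_architecture <- function(founders, seed) {
  stopifnot(inherits(founders, "clone_pop"), founders$cohort == 0L)
  D <- qtl_dosage(founders)
  raw <- with_seed(seed, stats::rnorm(ncol(D)))
  g_raw <- as.vector(D %*% raw)
  s <- stats::sd(g_raw)
  if (!is.finite(s) || s == 0) {
    stop("founder genotypic values have zero variance; cannot scale effects")
  }
  effects <- raw / s
  intercept <- mean(as.vector(D %*% effects))
  structure(list(effects = effects, intercept = intercept, scale = 1 / s,
                 qtl_sites = founders$sites[founders$sites$is_qtl,
                                            c("chrom", "segment")]),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("Additive trait architecture: %d QTL, effects scaled by %.4g\n",
              length(x$effects), x$scale))
  cat(sprintf("  founder mean centred at 0 (intercept %.4f)\n", x$intercept))
  invisible(x)
}

#' True genotypic values of a cohort
#'
#' Sum over QTL of allele dosage times the scaled additive effect, centred
#' on the founder mean (so population 0 has mean exactly 0).  Always uses
#' the clone's *true* genome, regardless of any labeling errors.
#'
#' @param pop A `clone_pop` sharing the panel the architecture was built on.
#' @param arch A `trait_arch`.
#' @return Numeric vector of genotypic values, one per clone.
#' @export
genotypic_value <- function(pop, arch) {
  stopifnot(inherits(pop, "clone_pop"), inherits(arch, "trait_arch"))
  qs <- pop$sites[pop$sites$is_qtl, c("chrom", "segment")]
  stopifnot(identical(unname(as.matrix(qs)),
                      unname(as.matrix(arch$qtl_sites))))
  as.vector(qtl_dosage(pop) %*% arch$effects) - arch$intercept
}

## sites split by chromosome: list of row-index vectors, plus cM positions
chrom_site_index <- function(pop) {
  split(seq_len(nrow(pop$sites)), pop$sites$chrom)
}

## core meiosis for one parent: returns one gamete (integer vector over sites)
## crossovers: Poisson count with mean chrom length in Morgans, uniform
## positions on the map, no interference (Haldane model)
gamete_core <- function(hapA, hapB, site_cM, chrom_index, chrom_cM) {
  gam <- integer(length(hapA))
  for (idx in chrom_index) {
    nx <- stats::rpois(1L, chrom_cM / 100)
    start <- sample.int(2L, 1L) - 1L
    if (nx == 0L) {
      gam[idx] <- if (start == 0L) hapA[idx] else hapB[idx]
    } else {
      xo <- sort(stats::runif(nx, 0, chrom_cM))
      phase <- (start + findInterval(site_cM[idx], xo)) %% 2L
      gam[idx] <- ifelse(phase == 0L, hapA[idx], hapB[idx])
    }
  }
  gam
}

#' Simulate one gamete from a parent clone
#'
#' Produces a recombinant haplotype over the panel sites.  Crossover
#' counts per chromosome are Poisson with mean equal to the chromosome
#' length in Morgans and positions are uniform on the genetic map (no
#' interference), so a 110-cM chromosome carries 1.1 crossovers per gamete
#' on average.  Meiosis always acts on the parent's true genome.
#'
#' @param pop A `clone_pop`.
#' @param parent Clone id or column index of the parent.
#' @param seed Optional integer seed.
#' @return Integer vector of alleles, one per panel site.
#' @export
make_gamete <- function(pop, parent, seed = NULL) {
  stopifnot(inherits(pop, "clone_pop"))
  j <- if (is.character(parent)) match(parent, pop$ids) else as.integer(parent)
  if (is.na(j) || j < 1L || j > length(pop$ids)) stop("unknown parent")
  with_seed(seed,
    gamete_core(pop$hapA[, j], pop$hapB[, j], pop$sites$cM,
                chrom_site_index(pop), pop$map$chrom_cM))
}

#' Random crossing among selected clones
#'
#' Creates `n_progeny` offspring, each from an independently drawn
#' unordered pair of distinct parents (no selfing), by simulating one
#' gamete per parent.  Crossing always uses the parents' true genomes:
#' when a mislabeled clone is selected, the plant that was phenotyped is
#' the one planted in the crossing nursery.
#'
#' @param pop A `clone_pop` containing the parents.
#' @param parent_ids Character vector of selected parent ids (>= 2 distinct).
#' @param n_progeny Number of offspring.
#' @param seed Integer random seed.
#' @param cohort Cohort index of the progeny population.
#' @param prefix Label prefix for progeny ids.
#' @return A new `clone_pop` of the progeny with pedigree records.
#' @export
random_cross <- function(pop, parent_ids, n_progeny, seed,
                         cohort = pop$cohort + 1L, prefix = NULL) {
  stopifnot(inherits(pop, "clone_pop"))
  parent_ids <- unique(parent_ids)
  if (length(parent_ids) < 2L) stop("need at least 2 distinct parents")
  jj <- match(parent_ids, pop$ids)
  if (anyNA(jj)) stop("unknown parent id(s)")
  if (is.null(prefix)) prefix <- sprintf("P%d_", cohort)
  n_sites <- nrow(pop$sites)
  ci <- chrom_site_index(pop)
  hapA <- matrix(0L, n_sites, n_progeny)
  hapB <- matrix(0L, n_sites, n_progeny)
  mo <- fa <- character(n_progeny)
  with_seed(seed, {
    for (k in seq_len(n_progeny)) {
      pr <- sample(jj, 2L)
      hapA[, k] <- gamete_core(pop$hapA[, pr[1L]], pop$hapB[, pr[1L]],
                               pop$sites$cM, ci, pop$map$chrom_cM)
      hapB[, k] <- gamete_core(pop$hapA[, pr[2L]], pop$hapB[, pr[2L]],
                               pop$sites$cM, ci, pop$map$chrom_cM)
      mo[k] <- pop$ids[pr[1L]]
      fa[k] <- pop$ids[pr[2L]]
    }
  })
  ids <- sprintf("%s%04d", prefix, seq_len(n_progeny))
  new_clone_pop(ids = ids, hapA = hapA, hapB = hapB, sites = pop$sites,
                map = pop$map, cohort = cohort,
                pedigree = data.frame(id = ids, mother = mo, father = fa))
}
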