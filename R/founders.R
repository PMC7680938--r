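#' Configuration of the founder coalescent simulation
#'
#' Collects the parameters of the equilibrium coalescent population from
#' which founder clones are drawn: a genome of `n_chrom` chromosomes of
#' `chrom_cM` centimorgans, each divided into `segments` segments of
#' `segment_bp` base pairs with recombination between but not within
#' segments, an effective population size `ne`, and a per-base-pair
#' mutation rate `mu`.  Segregating sites are filtered to minor allele
#' frequency strictly greater than `maf_min`, and `n_markers` marker SNPs
#' plus `n_qtl` causal loci are later drawn from the retained sites.
#'
#' The default genome (18 x 110 cM, 11,000 segments per chromosome,
#' Ne = 100, 200 founders, 2500 markers, 100 QTL, MAF > 0.01) describes a
#' cassava-like clonal outcrosser whose expected adjacent-marker linkage
#' disequilibrium is r-squared of about 0.18 at the average marker spacing
#' of 0.79 cM (see [hill_weir_expected_r2()]).  The default mutation rate
#' of 2e-7 per bp per generation is chosen so that the expected number of
#' post-filter segregating sites (about 7000 by Watterson's formula)
#' comfortably exceeds the 2600 loci the default panel requires; see the
#' package vignette for the reasoning.
#'
#' @param ne Effective population size of the coalescent population.
#' @param n_founders Number of diploid founder clones sampled (census size).
#' @param n_chrom Number of chromosomes.
#' @param chrom_cM Genetic length of each chromosome, centimorgans.
#' @param segments Number of segments per chromosome; recombination occurs
#'   only at segment boundaries.
#' @param segment_bp Physical length of one segment in base pairs.
#' @param mu Mutation rate per base pair per generation.
#' @param maf_min Minimum minor allele frequency (exclusive) for a site to
#'   be retained.
#' @param n_markers Number of SNP markers to draw from retained sites.
#' @param n_qtl Number of causal loci (QTL) to draw, disjoint from markers.
#' @param n_backup Number of extra "shadow germplasm" clones sampled from
#'   the same coalescent population (founders excluded); they supply the
#'   erroneously linked genotypes when source labeling errors are injected
#'   into the historical founder cohort, and never enter any statistic of
#'   the founder population itself (MAF filter, LD, trait scaling).
#' @return An object of class `founder_config` (a validated list).
#' @seealso [simulate_founders()], [sample_loci()]
#' @export
founder_config <- function(ne = 100, n_founders = 200, n_chrom = 18,
                           chrom_cM = 110, segments = 11000,
                           segment_bp = 100, mu = 2e-7, maf_min = 0.01,
                           n_markers = 2500, n_qtl = 100,
                           n_backup = n_founders) {
  cfg <- list(ne = ne, n_founders = as.integer(n_founders),
              n_chrom = as.integer(n_chrom), chrom_cM = chrom_cM,
              segments = as.integer(segments), segment_bp = segment_bp,
              mu = mu, maf_min = maf_min, n_markers = as.integer(n_markers),
              n_qtl = as.integer(n_qtl), n_backup = as.integer(n_backup))
  stopifnot(cfg$ne > 0, cfg$n_founders >= 2, cfg$n_chrom >= 1,
            cfg$chrom_cM > 0, cfg$segments >= 2, cfg$segment_bp > 0,
            cfg$mu >= 0, cfg$maf_min >= 0, cfg$maf_min < 0.5,
            cfg$n_markers >= 2, cfg$n_qtl >= 1, cfg$n_backup >= 0)
  class(cfg) <- "founder_config"
  cfg
}

#' @export
print.founder_config <- function(x, ...) {
  cat("Founder coalescent configuration\n")
  cat(sprintf("  genome : %d chromosomes x %g cM (%d segments of %g bp)\n",
              x$n_chrom, x$chrom_cM, x$segments, x$segment_bp))
  cat(sprintf("  population : Ne = %g, %d diploid founders sampled\n",
              x$ne, x$n_founders))
  cat(sprintf("  mutation : %g per bp per generation, MAF > %g\n",
              x$mu, x$maf_min))
  cat(sprintf("  panel : %d markers + %d QTL\n", x$n_markers, x$n_qtl))
  invisible(x)
}

#' Simulate founder haplotypes by coalescent simulation
#'
#' Runs an equilibrium coalescent with recombination (msprime backend, one
#' independent tree sequence per chromosome) and returns the phased founder
#' haplotypes at all segregating sites that pass the minor-allele-frequency
#' filter.  Recombination occurs between but not within segments at the
#' fraction implied by the uniform genetic map through Haldane's function;
#' mutations follow a binary model at rate `mu * segment_bp` per segment.
#'
#' The same `seed` always reproduces the identical founder population.
#'
#' @param config A [founder_config()] object.
#' @param seed Integer random seed for the backend.
#' @return An object of class `founder_pop`: a list with elements
#'   `config`, `sites` (data frame with `chrom`, 1-based; `segment`,
#'   0-based; `cM` map position), `H` (integer matrix, sites x
#'   `2 * n_founders` phased haplotypes, 0/1 alleles), `H_backup`
#'   (haplotypes of the shadow-germplasm backup clones, or NULL) and
#'   `maf` (founder minor allele frequencies).
#' @section Errors:
#' Fails if fewer post-filter segregating sites are available than the
#' `n_markers + n_qtl` the configuration requires downstream (for example
#' when `mu` is 0, which yields no polymorphism at all).
#' @examples
#' \donttest{
#' fp <- simulate_founders(founder_config(n_chrom = 2, segments = 2000,
#'                                        n_markers = 60, n_qtl = 10,
#'                                        n_founders = 40), seed = 1)
#' fp
#' }
#' @export
simulate_founders <- function(config, seed) {
  stopifnot(inherits(config, "founder_config"))
  py <- find_python()
  script <- system.file("python", "founder_coalescent.py",
                        package = "mislabelGS", mustWork = TRUE)
  out <- tempfile("founders")
  args <- c(shQuote(script),
            "--ne", config$ne, "--n-ind", config$n_founders,
            "--n-backup", config$n_backup,
            "--n-chrom", config$n_chrom, "--segments", config$segments,
            "--chrom-cm", config$chrom_cM, "--segment-bp", config$segment_bp,
            "--mu", config$mu, "--maf-min", config$maf_min,
            "--seed", as.integer(seed) %% 2147483647L, "--out", shQuote(out))
  status <- system2(py, args, stdout = FALSE, stderr = "")
  if (status != 0) {
    stop("coalescent backend failed with exit status ", status)
  }
  sites <- utils::read.table(paste0(out, ".sites"), header = TRUE, sep = "\t")
  need <- config$n_markers + config$n_qtl
  if (nrow(sites) < need) {
    stop("only ", nrow(sites), " segregating sites passed the MAF filter, ",
         "but the panel needs ", need,
         " (markers + QTL); increase the mutation rate or genome size")
  }
  lines <- readLines(paste0(out, ".haps"))
  unlink(paste0(out, c(".sites", ".haps")))
  Hall <- matrix(as.integer(unlist(strsplit(lines, "", fixed = TRUE),
                                   use.names = FALSE)),
                 nrow = length(lines), byrow = TRUE)
  stopifnot(ncol(Hall) == 2L * (config$n_founders + config$n_backup),
            nrow(Hall) == nrow(sites))
  H <- Hall[, seq_len(2L * config$n_founders), drop = FALSE]
  H_backup <- if (config$n_backup > 0) {
    Hall[, -seq_len(2L * config$n_founders), drop = FALSE]
  } else NULL
  freq <- rowMeans(H)
  maf <- pmin(freq, 1 - freq)
  stopifnot(all(maf > config$maf_min))
  d_seg <- config$chrom_cM / (config$segments - 1)
  sites$cM <- sites$segment * d_seg
  fp <- list(config = config, sites = sites, H = H, H_backup = H_backup,
             maf = maf, seed = seed)
  class(fp) <- "founder_pop"
  fp
}

#' @export
print.founder_pop <- function(x, ...) {
  cat(sprintf("Founder population: %d diploid clones, %d segregating sites\n",
              x$config$n_founders, nrow(x$sites)))
  cat(sprintf("  %d chromosomes x %g cM; MAF range %.3f-%.3f\n",
              x$config$n_chrom, x$config$chrom_cM, min(x$maf), max(x$maf)))
  if (!is.null(x$marker_idx)) {
    cat(sprintf("  panel: %d markers + %d QTL (disjoint)\n",
                length(x$marker_idx), length(x$qtl_idx)))
  }
  invisible(x)
}

#' Draw the marker and QTL panel from retained sites
#'
#' Samples `n_markers` marker sites and `n_qtl` causal sites uniformly at
#' random, without replacement and mutually disjoint, from the post-filter
#' segregating sites of a founder population.  Markers therefore tag, but
#' never coincide with, causal loci.
#'
#' @param fp A `founder_pop` from [simulate_founders()].
#' @param seed Integer random seed.
#' @param n_markers,n_qtl Panel sizes; default from the founder config.
#' @return `fp` with integer index vectors `marker_idx` and `qtl_idx`
#'   (rows of `fp$sites`, sorted by genome position) attached.
#' @export
sample_loci <- function(fp, seed, n_markers = fp$config$n_markers,
                        n_qtl = fp$config$n_qtl) {
  stopifnot(inherits(fp, "founder_pop"))
  n_sites <- nrow(fp$sites)
  if (n_sites < n_markers + n_qtl) {
    stop("not enough segregating sites (", n_sites, ") for ",
         n_markers, " markers + ", n_qtl, " QTL")
  }
  with_seed(seed, {
    both <- sample.int(n_sites, n_markers + n_qtl)
    fp$marker_idx <- sort(both[seq_len(n_markers)])
    fp$qtl_idx <- sort(both[n_markers + seq_len(n_qtl)])
  })
  fp
}

#' Expected adjacent-pair linkage disequilibrium (Hill-Weir)
#'
#' Small-sample expectation of the squared correlation of allele
#' frequencies between two loci in an equilibrium population,
#' \deqn{E[r^2] = \frac{10+C}{(2+C)(11+C)}
#'   \left[1 + \frac{(3+C)(12+12C+C^2)}{m(2+C)(11+C)}\right]}
#' with \eqn{C = 4 N_e c} and \eqn{m = 2n} the number of chromosomes
#' sampled from `n` diploid individuals.  This is the ratio-of-expectations
#' form (sigma-squared-d); with the package's default genome it evaluates
#' to 0.18 at the average adjacent-marker spacing of 0.79 cM
#' (Ne = 100, n = 200).  As `C` grows the value approaches the sampling
#' floor `1/(2n)`.
#'
#' @param ne Effective population size (> 0).
#' @param n Number of diploid individuals sampled (> 0).
#' @param c Recombination fraction between the two loci, in \[0, 0.5\]
#'   (vectorised).
#' @return Expected r-squared, same length as `c`.
#' @examples
#' hill_weir_expected_r2(100, 200, haldane_c(0.79))
#' @export
hill_weir_expected_r2 <- function(ne, n, c) {
  if (ne <= 0) stop("ne must be positive")
  if (n <= 0) stop("n must be positive")
  stopifnot(all(c >= 0), all(c <= 0.5))
  m <- 2 * n
  C <- 4 * ne * c
  a <- (10 + C) / ((2 + C) * (11 + C))
  b <- 1 + ((3 + C) * (12 + 12 * C + C^2)) / (m * (2 + C) * (11 + C))
  a * b
}

#' Mean map distance between adjacent markers
#'
#' Returns both the expected marker spacing (total map length divided by
#' the number of markers) and the realized mean of adjacent
#' within-chromosome gaps of the sampled marker panel.
#'
#' @param fp A `founder_pop` with a marker panel ([sample_loci()]), or a
#'   list with elements `n_chrom`, `chrom_cM`, and `marker_cM`/`marker_chrom`
#'   vectors.
#' @return A list with elements `expected` and `realized`, in centimorgans.
#' @examples
#' # 2500 markers on 18 x 110 cM: expected spacing 0.79 cM
#' 18 * 110 / 2500
#' @export
mean_adjacent_marker_distance <- function(fp) {
  if (inherits(fp, "founder_pop")) {
    stopifnot(!is.null(fp$marker_idx))
    chrom <- fp$sites$chrom[fp$marker_idx]
    cM <- fp$sites$cM[fp$marker_idx]
    n_chrom <- fp$config$n_chrom
    chrom_cM <- fp$config$chrom_cM
  } else {
    chrom <- fp$marker_chrom
    cM <- fp$marker_cM
    n_chrom <- fp$n_chrom
    chrom_cM <- fp$chrom_cM
  }
  if (length(cM) < 2) stop("need at least two markers")
  ord <- order(chrom, cM)
  chrom <- chrom[ord]
  cM <- cM[ord]
  gaps <- diff(cM)[diff(chrom) == 0]
  list(expected = n_chrom * chrom_cM / length(cM),
       realized = mean(gaps))
}

#' Observed and expected linkage disequilibrium between adjacent markers
#'
#' For every pair of adjacent markers on the same chromosome, computes the
#' haplotype-based disequilibrium D, the product of heterozygosities
#' w = p1 q1 p2 q2, the per-pair r-squared = D^2 / w, and the Hill-Weir
#' expectation at the pair's realized map distance.  The summary statistic
#' matched to the Hill-Weir quantity (a ratio of expectations) is the
#' ratio-of-sums estimator `sum(D^2) / sum(w)`, returned alongside the
#' w-weighted mean of the per-pair expectations.
#'
#' @param fp A `founder_pop` with a marker panel ([sample_loci()]).
#' @return A list with `pairs` (data frame: `chrom`, `d_cM`, `c`, `D`,
#'   `w`, `r2`, `expected_r2`), `r2_ratio` (ratio-of-sums estimator),
#'   `expected_ratio` (w-weighted mean expectation), and `mean_r2`
#'   (plain mean of per-pair r-squared, reported for reference; it is
#'   systematically below the ratio form under a low MAF filter).
#' @export
adjacent_marker_r2 <- function(fp) {
  stopifnot(inherits(fp, "founder_pop"), !is.null(fp$marker_idx))
  idx <- fp$marker_idx
  chrom <- fp$sites$chrom[idx]
  cM <- fp$sites$cM[idx]
  H <- fp$H[idx, , drop = FALSE]
  keep <- which(diff(chrom) == 0)
  if (!length(keep)) stop("no adjacent within-chromosome marker pairs")
  p1 <- rowMeans(H[keep, , drop = FALSE])
  p2 <- rowMeans(H[keep + 1L, , drop = FALSE])
  p12 <- rowMeans(H[keep, , drop = FALSE] * H[keep + 1L, , drop = FALSE])
  D <- p12 - p1 * p2
  w <- p1 * (1 - p1) * p2 * (1 - p2)
  d_cM <- cM[keep + 1L] - cM[keep]
  cc <- haldane_c(d_cM)
  exp_r2 <- hill_weir_expected_r2(fp$config$ne, fp$config$n_founders, cc)
  pairs <- data.frame(chrom = chrom[keep], d_cM = d_cM, c = cc, D = D,
                      w = w, r2 = D^2 / w, expected_r2 = exp_r2)
  list(pairs = pairs,
       r2_ratio = sum(D^2) / sum(w),
       expected_ratio = sum(exp_r2 * w) / sum(w),
       mean_r2 = mean(pairs$r2))
}
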