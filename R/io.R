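#' Write and read genotype dosage matrices
#'
#' Plain-text exchange format for genotypes: a tab-separated matrix of
#' 0/1/2 dosages, individuals in rows (row names = clone ids), sites in
#' columns, with a companion site-map file (chromosome 1-based, segment
#' 0-based, cM position).
#'
#' @param M Dosage matrix (individuals x sites) with row names.
#' @param file Output path for the dosage table.
#' @param sites Optional site data frame (`chrom`, `segment`, `cM`).
#' @param map_file Output path for the site map (default `<file>.map`).
#' @return `write_dosage()`: the file path, invisibly.  `read_dosage()`:
#'   the dosage matrix with an attribute `sites` when a map is present.
#' @export
write_dosage <- function(M, file, sites = NULL,
                         map_file = paste0(file, ".map")) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  utils::write.table(M, file, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(sites)) {
    utils::write.table(sites[, c("chrom", "segment", "cM")], map_file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(file, map_file = paste0(file, ".map")) {
  M <- as.matrix(utils::read.table(file, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  if (file.exists(map_file)) {
    attr(M, "sites") <- utils::read.table(map_file, sep = "\t",
                                          header = TRUE)
  }
  M
}

#' Export a pedigree table
#'
#' @param pop A `clone_pop`.
#' @param file Optional path; when given, writes a tab-separated table.
#' @return Data frame with columns `id`, `mother`, `father`, `cohort`.
#' @export
export_pedigree <- function(pop, file = NULL) {
  stopifnot(inherits(pop, "clone_pop"))
  out <- cbind(pop$pedigree, cohort = pop$cohort)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Export an experiment's tidy results and manifest
#'
#' Writes `results.tsv` (one row per replicate, scenario and population)
#' and `manifest.json` (scale preset, configuration, master seed, package
#' version) to a directory, so downstream analysis never needs simulator
#' internals.
#'
#' @param x A `gs_experiment`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "gs_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$results, file.path(dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    preset = x$spec$preset, seed = x$seed, n_reps = x$spec$n_reps,
    rates = x$spec$rates, error_types = x$spec$error_types,
    schemes = x$spec$schemes, cohort_size = x$spec$cohort_size,
    n_select = x$spec$n_select, n_cycles = x$spec$n_cycles,
    founder = unclass(x$spec$founder),
    package_version = as.character(utils::packageVersion("mislabelGS")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a tidy results table
#'
#' @param dir Directory written by [write_experiment()].
#' @return Data frame of results (analysable by [gain_summary()] etc.).
#' @export
read_experiment <- function(dir) {
  utils::read.table(file.path(dir, "results.tsv"), sep = "\t",
                    header = TRUE)
}

#' Export a GBLUP model summary as JSON
#'
#' @param fit A `gblup` object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_model_summary <- function(fit, file) {
  stopifnot(inherits(fit, "gblup"))
  s <- list(n_records = fit$n, n_training_clones = fit$n_ids,
            mu = fit$mu, sigma2_u = fit$sigma2_u, sigma2_e = fit$sigma2_e,
            lambda = fit$lambda, logLik = fit$logLik)
  jsonlite::write_json(s, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
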