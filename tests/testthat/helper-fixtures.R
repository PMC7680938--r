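# Shared fixtures, memoised so expensive simulations run once per test_dir.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(kind, seed = 1) {
  key <- paste(kind, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_fixture(kind, seed)
  }
  .fixture_env[[key]]
}

# A tiny hand-built clone population (independent of the coalescent
# backend): 2 chromosomes of 30 cM, 4 sites each, 5 markers + 3 QTL.
make_hand_pop <- function() {
  sites <- data.frame(
    chrom = rep(1:2, each = 4),
    segment = rep(0:3, 2),
    cM = rep(c(0, 10, 20, 30), 2),
    is_marker = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    is_qtl = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  hapA <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0,
                   0, 1, 0, 1, 0, 0, 1, 1,
                   1, 1, 1, 1, 0, 0, 0, 0,
                   0, 0, 0, 0, 1, 1, 1, 1), nrow = 8)
  hapB <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1,
                   1, 1, 0, 0, 1, 0, 1, 0,
                   1, 0, 1, 0, 1, 0, 1, 0,
                   0, 1, 0, 1, 0, 1, 0, 1), nrow = 8)
  new_clone_pop(ids = paste0("H", 1:4), hapA = hapA, hapB = hapB,
                sites = sites, map = list(n_chrom = 2L, chrom_cM = 30))
}

# A founder population dense enough in markers for LD-decay checks.
get_ld_founder <- function() {
  if (is.null(.fixture_env$ld_founder)) {
    cfg <- founder_config(n_chrom = 2, segments = 11000, n_founders = 100,
                          n_markers = 300, n_qtl = 10)
    fp <- simulate_founders(cfg, seed = 77)
    .fixture_env$ld_founder <- sample_loci(fp, seed = 78)
  }
  .fixture_env$ld_founder
}

# Dense mixed-model-equation oracle for GBLUP at fixed variance ratio:
# untransformed GLS/BLUP with V = sigma_e^2 (lambda Z K Z' + R), fully
# independent of the package's spectral solver.
mme_oracle <- function(records, K, lambda) {
  ids <- rownames(K)
  tids <- ids[ids %in% records$clone_id]
  Z <- outer(records$clone_id, tids, `==`) * 1
  R <- diag(records$error_variance, nrow(records))
  X <- matrix(1, nrow(records), 1)
  V <- lambda * Z %*% K[tids, tids] %*% t(Z) + R
  Vin <- solve(V)
  beta <- drop(solve(t(X) %*% Vin %*% X, t(X) %*% Vin %*% records$value))
  u <- drop(lambda * K[, tids] %*% t(Z) %*% Vin %*%
              (records$value - X %*% beta))
  list(mu = beta, u = setNames(u, ids))
}
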