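test_that("kinship has identity-of-state and centering properties", {
  fix <- get_fixture("records")
  M <- t(linked_genotypes(fix$founders))
  # duplicate a clone: its row equals the original's and off-diagonal
  # equals the diagonal entry (clonal copy)
  M2 <- rbind(M, dup = M[1, ])
  rownames(M2) <- c(rownames(M), "dup")
  K <- compute_kinship(M2)
  expect_equal(unname(K["dup", ]), unname(K[1, ]), tolerance = 1e-12)
  expect_equal(K["dup", 1], K[1, 1], tolerance = 1e-12)
  expect_true(isSymmetric(K))
  # observed-frequency centering: mean off-diagonal ~ -diag/(n-1), near 0,
  # by the brute-force identity sum(K) = 0 is not exact for A.mat-type
  # scaling, but row sums of centered scores are 0, so colSums(W) = 0
  # implies sum over all entries of K equals 0.
  expect_equal(sum(compute_kinship(M)), 0, tolerance = 1e-8)
  expect_error(compute_kinship(matrix(2, 3, 4,
                                      dimnames = list(letters[1:3], NULL))),
               "monomorphic")
})

test_that("gblup matches the dense mixed-model-equation oracle (n <= 10)", {
  set.seed(21)
  # tiny kinship: 8 clones, 2 of them unphenotyped candidates
  W <- matrix(rnorm(8 * 6), 8)
  K <- tcrossprod(W) / 6 + diag(0.01, 8)
  dimnames(K) <- list(paste0("c", 1:8), paste0("c", 1:8))
  records <- data.frame(
    clone_id = c("c1", "c2", "c3", "c4", "c5", "c6", "c1", "c3"),
    value = rnorm(8, 1, 2),
    error_variance = c(1, 1, 36, 16, 9, 36, 9, 1))
  for (lam in c(0.25, 1, 4)) {
    fit <- gblup(value ~ 1, records, K, lambda = lam)
    ora <- mme_oracle(records, K, lam)
    expect_equal(fit$mu, ora$mu, tolerance = 1e-6)
    expect_equal(fit$u, ora$u, tolerance = 1e-6)
    # predictions of unphenotyped candidates from the augmented system
    pred <- predict(fit, ids = c("c7", "c8"), K = K)
    expect_equal(unname(pred), unname(ora$mu + ora$u[c("c7", "c8")]),
                 tolerance = 1e-6)
  }
})

test_that("predictions are invariant to rescaling the R matrix", {
  fix <- get_fixture("records")
  fit1 <- gblup(value ~ 1, fix$records, fix$K)
  rec10 <- fix$records
  rec10$error_variance <- rec10$error_variance * 10
  fit10 <- gblup(value ~ 1, rec10, fix$K)
  expect_equal(predict(fit1), predict(fit10), tolerance = 1e-6)
  expect_equal(fit10$lambda, 10 * fit1$lambda, tolerance = 1e-4)
})

test_that("no-noise limit returns the observed phenotypes", {
  set.seed(3)
  K <- diag(5) + 0.1
  dimnames(K) <- list(letters[1:5], letters[1:5])
  rec <- data.frame(clone_id = letters[1:5], value = rnorm(5),
                    error_variance = 1e-8)
  fit <- gblup(value ~ 1, rec, K, lambda = 1)
  expect_equal(unname(predict(fit, ids = letters[1:5])), rec$value,
               tolerance = 1e-4)
})

test_that("K = I with equal weights is ridge shrinkage toward the mean", {
  set.seed(13)
  K <- diag(5)
  dimnames(K) <- list(letters[1:5], letters[1:5])
  rec <- data.frame(clone_id = letters[1:5], value = rnorm(5, 2),
                    error_variance = 1)
  lam <- 0.7
  fit <- gblup(value ~ 1, rec, K, lambda = lam)
  # with K = I and one record per clone, BLUP = lam/(lam+1) * (y - mu_gls)
  shr <- lam / (lam + 1)
  mu <- fit$mu
  expect_equal(unname(fit$u[letters[1:5]]), shr * (rec$value - mu),
               tolerance = 1e-8)
})

test_that("REML recovers a simulated variance ratio", {
  set.seed(101)
  q <- 200
  ids <- sprintf("s%03d", 1:q)
  K <- diag(q)
  dimnames(K) <- list(ids, ids)
  lam_true <- 2
  u <- rnorm(q, 0, sqrt(lam_true))
  rec <- data.frame(
    clone_id = rep(ids, 2),
    value = rep(u, 2) + rnorm(2 * q, 0, sqrt(c(rep(1, q), rep(4, q)))),
    error_variance = c(rep(1, q), rep(4, q)))
  fit <- gblup(value ~ 1, rec, K)
  expect_gt(fit$lambda, lam_true / 2)
  expect_lt(fit$lambda, lam_true * 2)
  expect_equal(fit$sigma2_e, 1, tolerance = 0.35)
})

test_that("low-variance records carry more weight than high-variance ones", {
  fix <- get_fixture("records")
  rec <- fix$records
  target <- fix$founders$ids[1]
  both <- rec[rec$clone_id == target, ]
  low <- which(rec$clone_id == target &
                 rec$error_variance == min(both$error_variance))[1]
  high <- which(rec$clone_id == target &
                  rec$error_variance == max(both$error_variance))[1]
  full <- predict(gblup(value ~ 1, rec, fix$K, lambda = 1))[target]
  no_low <- predict(gblup(value ~ 1, rec[-low, ], fix$K, lambda = 1))[target]
  no_high <- predict(gblup(value ~ 1, rec[-high, ], fix$K, lambda = 1))[target]
  expect_gt(abs(full - no_low), abs(full - no_high))
})

test_that("gblup guards its interface", {
  fix <- get_fixture("records")
  expect_error(gblup(value ~ rate, fix$records, fix$K), "overall-mean")
  bad <- fix$records
  bad$clone_id[1] <- "nope"
  expect_error(gblup(value ~ 1, bad, fix$K), "missing from K")
  fit <- gblup(value ~ 1, fix$records, fix$K)
  expect_error(predict(fit, ids = "nope"), "unknown clone")
  expect_output(print(fit), "sigma2_u")
  expect_output(print(summary(fit)), "variance components")
  expect_equal(length(residuals(fit)), nrow(fix$records))
})
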