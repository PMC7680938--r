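test_that("trait scaling gives founder variance exactly 1 and mean exactly 0", {
  fix <- get_fixture("records")
  founders <- fix$founders
  gv <- genotypic_value(founders, fix$arch)
  expect_equal(var(gv), 1, tolerance = 1e-12)
  expect_equal(mean(gv), 0, tolerance = 1e-12)
})

test_that("genotypic value equals the brute-force dot product over QTL", {
  pop <- make_hand_pop()
  arch <- structure(list(
    effects = c(0.5, -1.2, 0.3),
    intercept = 0.7, scale = 1,
    qtl_sites = pop$sites[pop$sites$is_qtl, c("chrom", "segment")]),
    class = "trait_arch")
  gv <- genotypic_value(pop, arch)
  q <- which(pop$sites$is_qtl)
  manual <- vapply(seq_along(pop$ids), function(j) {
    sum((pop$hapA[q, j] + pop$hapB[q, j]) * arch$effects) - arch$intercept
  }, 0)
  expect_equal(unname(gv), manual, tolerance = 1e-12)
  # all-zero effects: every clone sits at minus the intercept shift (0 here)
  arch0 <- arch
  arch0$effects <- c(0, 0, 0)
  arch0$intercept <- 0
  expect_equal(unname(genotypic_value(pop, arch0)), rep(0, 4))
})

test_that("zero-variance founder values cannot be scaled", {
  pop <- make_hand_pop()
  pop$hapA[pop$sites$is_qtl, ] <- 1L   # monomorphic at every QTL
  pop$hapB[pop$sites$is_qtl, ] <- 1L
  expect_error(trait_architecture(pop, seed = 1), "zero variance")
})

test_that("gametes from a fully homozygous parent equal the parental haplotype", {
  pop <- make_hand_pop()
  pop$hapB <- pop$hapA
  for (s in 1:5) {
    expect_identical(make_gamete(pop, 1, seed = s), pop$hapA[, 1])
  }
})

test_that("crossover process is Poisson with chromosome length in Morgans", {
  # dense-site single chromosome: phase switches approximate crossovers
  n_sites <- 1101
  sites <- data.frame(chrom = 1L, segment = 0:(n_sites - 1),
                      cM = seq(0, 110, length.out = n_sites),
                      is_marker = TRUE, is_qtl = FALSE)
  pop <- new_clone_pop(ids = "X", hapA = matrix(0L, n_sites, 1),
                       hapB = matrix(1L, n_sites, 1), sites = sites,
                       map = list(n_chrom = 1L, chrom_cM = 110))
  set.seed(31)
  n_gam <- 4000
  switches <- integer(n_gam)
  pos_all <- numeric(0)
  for (g in seq_len(n_gam)) {
    gam <- make_gamete(pop, 1)
    flips <- which(diff(gam) != 0)
    switches[g] <- length(flips)
    pos_all <- c(pos_all, sites$cM[flips])
  }
  # mean switch count ~ 1.1 (double crossovers between adjacent dense sites
  # are vanishingly rare); MC standard error ~ sqrt(1.1/4000) = 0.017
  expect_equal(mean(switches), 1.1, tolerance = 0.06)
  # crossover positions uniform along the chromosome
  ct <- table(cut(pos_all, seq(0, 110, length.out = 11)))
  expect_gt(stats::chisq.test(ct)$p.value, 1e-3)
})

test_that("random crossing transmits the parental mean without selection", {
  fix <- get_fixture("records")
  founders <- fix$founders
  founders$gv <- genotypic_value(founders, fix$arch)
  parents <- founders$ids[1:8]
  pmean <- mean(founders$gv[match(parents, founders$ids)])
  prog_means <- vapply(1:4, function(s) {
    prog <- random_cross(founders, parents, 250, seed = 1000 + s)
    mean(genotypic_value(prog, fix$arch))
  }, 0)
  # MC average over 1000 progeny; sd(progeny gv) < 1 so SE < 0.04
  expect_equal(mean(prog_means), pmean, tolerance = 0.12)
})

test_that("random_cross validates parents and records the pedigree", {
  fix <- get_fixture("records")
  founders <- fix$founders
  expect_error(random_cross(founders, founders$ids[1], 10, seed = 1),
               "2 distinct parents")
  prog <- random_cross(founders, founders$ids[1:2], 20, seed = 4)
  # two parents: all progeny are full sibs of the same (unordered) pair
  expect_setequal(unique(c(prog$pedigree$mother, prog$pedigree$father)),
                  founders$ids[1:2])
  expect_true(all(prog$pedigree$mother != prog$pedigree$father))
  expect_equal(prog$cohort, founders$cohort + 1L)
})

test_that("clonal propagation and labeling never alter the true genome", {
  fix <- get_fixture("records")
  founders <- fix$founders
  before <- list(founders$hapA, founders$hapB)
  pop <- inject_substitution_error(founders, rate = 0.3, seed = 8)
  expect_identical(list(pop$hapA, pop$hapB), before)
})
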