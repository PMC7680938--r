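# run_scheme at miniature scale, shared across this file's tests
local_traj <- local({
  env <- new.env()
  function(scheme = "seedling", error_type = "none", rate = 0, seed = 500) {
    key <- paste(scheme, error_type, rate, seed)
    if (is.null(env[[key]])) {
      fix <- get_fixture("records")
      founders <- fix$founders
      founders$geno <- NULL          # run_scheme genotypes afresh
      founders$linked_id <- NULL
      cfg <- scheme_config(n_select = 5, cohort_size = 30, n_cycles = 4,
                           scheme = scheme, error_type = error_type,
                           rate = rate)
      env[[key]] <- run_scheme(founders, fix$arch, cfg, seed = seed,
                               keep_populations = TRUE)
    }
    env[[key]]
  }
})

test_that("truncation selection takes the top n with a stable tie rule", {
  p <- c(a = 1, b = 3, c = 2, d = 3, e = 0)
  expect_equal(select_top(p, 2), c("b", "d"))
  expect_equal(select_top(p, 3), c("b", "d", "c"))
  # all equal: first n in id order
  q <- c(x = 1, y = 1, z = 1)
  expect_equal(select_top(q, 2), c("x", "y"))
  expect_error(select_top(q, 4), "fewer candidates")
  # selecting everyone gives zero selection differential
  expect_equal(sort(select_top(p, 5)), sort(names(p)))
})

test_that("a trajectory starts at gain 0 and unit variance and is deterministic", {
  tr <- local_traj()
  expect_s3_class(tr, "gs_trajectory")
  expect_equal(tr$pops$gain[tr$pops$pop == 0], 0, tolerance = 1e-10)
  expect_equal(tr$pops$variance[tr$pops$pop == 0], 1, tolerance = 1e-10)
  expect_equal(nrow(tr$cycles), 4)
  fix <- get_fixture("records")
  founders <- fix$founders
  founders$geno <- NULL
  founders$linked_id <- NULL
  cfg <- scheme_config(n_select = 5, cohort_size = 30, n_cycles = 4)
  tr2 <- run_scheme(founders, fix$arch, cfg, seed = 500)
  expect_identical(tr$cycles, tr2$cycles)
  expect_identical(tr$pops, tr2$pops)
})

test_that("the no-seedling scheme does not update the model before cycle 2", {
  trs <- local_traj("seedling")
  trn <- local_traj("no_seedling")
  n_found <- length(get_fixture("records")$founders$ids)
  # cycle 1 trains on historical founder records in both schemes
  expect_equal(trs$cycles$n_records[1], n_found)
  expect_equal(trn$cycles$n_records[1], n_found)
  # cycle 2: seedling scheme adds the candidate cohort's seedling records;
  # no-seedling training is identical to cycle 1's
  expect_equal(trs$cycles$n_records[2], n_found + 30)
  expect_equal(trn$cycles$n_records[2], n_found)
  # cycle 3 adds CET of the nonselected (30 - 5); no seedling records ever
  # enter the no-seedling scheme
  expect_equal(trn$cycles$n_records[3], n_found + 25)
  expect_equal(trs$cycles$n_records[3], n_found + 30 + 25 + 30)
  # cycle 4 adds PYT of the full first cohort
  expect_equal(trn$cycles$n_records[4], n_found + 25 + 25 + 30)
  # founders and cycle-1 selection are shared across schemes (paired design)
  expect_equal(trs$pops$gain[2], trn$pops$gain[2], tolerance = 1e-10)
  expect_identical(trs$selected[[1]], trn$selected[[1]])
})

test_that("selected clones are excluded from CET but included in PYT", {
  tr <- local_traj()
  rec <- tr$records
  cet3 <- rec$clone_id[rec$stage == "CET" & rec$cycle == 3]
  expect_length(intersect(cet3, tr$selected[[2]]), 0)
  expect_equal(length(cet3), 30 - 5)
  pyt4 <- rec$clone_id[rec$stage == "PYT" & rec$cycle == 4]
  expect_equal(length(pyt4), 30)
  expect_true(all(tr$selected[[2]] %in% pyt4))
})

test_that("mislabeling propagates through the scheme with intact semantics", {
  tr <- local_traj("seedling", "substitution", 0.2, seed = 640)
  expect_false(is.null(tr$audit))
  # the founder cohort (20 clones, genotyped at cycle 1, logged as cycle
  # 0) carries round(0.2 * 20) = 4 errors; every genotyped progeny
  # cohort carries round(0.2 * 30) = 6
  expect_equal(as.vector(table(tr$audit$cycle)), c(4, 6, 6, 6))
  expect_equal(tr$cycles$n_mislabeled_candidates, c(4, 6, 6, 6))
  for (p in 1:4) {
    pop <- tr$populations[[p]]
    expect_equal(pop$mislabeled, pop$linked_id != pop$ids)
    ok <- !pop$mislabeled
    # correctly labeled clones carry their own marker genotypes
    m <- pop$sites$is_marker
    own <- pop$hapA[m, ok, drop = FALSE] + pop$hapB[m, ok, drop = FALSE]
    expect_equal(unname(pop$geno[, ok]), unname(own))
  }
  # accuracy is computed among correctly labeled candidates only, so it
  # stays defined at every cycle
  expect_true(all(is.finite(tr$cycles$accuracy)))
})

test_that("source errors draw genotypes from outside the breeding population", {
  tr <- local_traj("seedling", "source", 0.3, seed = 641)
  expect_true(all(grepl("^B", tr$audit$linked_genome_id)))
  # the historical cohort's wrong genotypes come from the shadow
  # germplasm (B0_*), progeny cohorts' from their sib backups (B1_* ...)
  expect_true(all(grepl("^B0_",
                        tr$audit$linked_genome_id[tr$audit$cycle == 0])))
  expect_equal(sum(tr$audit$cycle == 0), round(0.3 * 20))
  # mislabeled clones' own ids never appear as their linked genome
  expect_true(all(tr$audit$clone_id != tr$audit$linked_genome_id))
})
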