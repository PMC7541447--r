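test_that("MFE folding handles trivial and known cases", {
  f <- fold_mfe("AAAA")
  expect_identical(f$n_pairs, 0L)
  expect_identical(f$energy, 0)
  expect_identical(f$structure, "....")
  # GGGAAACCC: 3 pairs under min-loop 3 (verified by exhaustive enumeration)
  f2 <- fold_mfe("GGGAAACCC")
  expect_identical(f2$n_pairs, 3L)
  expect_identical(f2$n_pairs, brute_max_pairs("GGGAAACCC"))
  expect_error(fold_mfe("ACGX"), "invalid characters")
})

test_that("fallback MFE equals the brute-force optimum on all short sequences", {
  set.seed(101)
  for (rep in 1:60) {
    L <- sample(5:12, 1)
    sq <- random_rna(L)
    expect_identical(fold_mfe(sq)$n_pairs, brute_max_pairs(sq))
    # the reported structure is consistent with the reported pair count
    expect_identical(nrow(db_pairs(fold_mfe(sq)$structure)),
                     fold_mfe(sq)$n_pairs)
  }
})

test_that("pair probabilities match exhaustive enumeration within 1e-9", {
  set.seed(202)
  for (rep in 1:40) {
    sq <- random_rna(sample(5:12, 1))
    pp <- pair_probabilities(sq)
    expect_lt(max(abs(pp$p - brute_pair_probs(sq))), 1e-9)
  }
  # trivial case: no pairs possible
  pp <- pair_probabilities("AAAA")
  expect_true(all(pp$p == 0))
  expect_true(all(pp$p_unpaired == 1))
})

test_that("pair probabilities conserve probability row-wise", {
  set.seed(303)
  for (rep in 1:50) {
    pp <- pair_probabilities(random_rna(15))
    expect_lt(max(abs(rowSums(pp$p) + pp$p_unpaired - 1)), 1e-9)
    expect_true(all(pp$p >= -1e-12 & pp$p <= 1 + 1e-12))
  }
})

test_that("ensemble defect matches enumeration and handles limit cases", {
  # fully unpaired target on an unpairable sequence: defect 0
  expect_equal(ensemble_defect("AAAA", "...."), 0)
  set.seed(404)
  for (rep in 1:15) {
    sq <- random_rna(12)
    # hairpin-like target: the sequence's own MFE structure, plus a random one
    tgt_mfe <- fold_mfe(sq)$structure
    expect_equal(ensemble_defect(sq, tgt_mfe),
                 brute_ensemble_defect(sq, tgt_mfe), tolerance = 1e-9)
    expect_equal(ensemble_defect(sq, strrep(".", 12)),
                 brute_ensemble_defect(sq, strrep(".", 12)), tolerance = 1e-9)
  }
  expect_error(ensemble_defect("ACGU", "....."), "length")
})

test_that("ensemble defect of the MFE structure beats a random structure on average", {
  # "random structure" = the MFE structure of an unrelated sequence of the
  # same length: the equilibrium ensemble should sit closer to the
  # sequence's own MFE structure than to an unrelated one
  set.seed(55)
  diffs <- replicate(30, {
    sq <- random_rna(15)
    pp <- pair_probabilities(sq)
    d_mfe <- ensemble_defect(sq, fold_mfe(sq)$structure, probs = pp)
    d_rand <- ensemble_defect(sq, fold_mfe(random_rna(15))$structure,
                              probs = pp)
    d_rand - d_mfe
  })
  expect_gt(mean(diffs), 0)
})

test_that("dot-bracket parsing validates balance and strips nicks", {
  expect_identical(nrow(db_pairs("((..))")), 2L)
  pr <- db_pairs("((..))")
  expect_identical(pr[order(pr[, "i"]), , drop = FALSE],
                   matrix(c(1L, 2L, 6L, 5L), 2, 2,
                          dimnames = list(NULL, c("i", "j"))))
  expect_identical(nrow(db_pairs("((+))..")), 2L)
  expect_error(db_pairs("(()"), "unbalanced")
  expect_error(db_pairs("())"), "unbalanced")
  expect_error(db_pairs("(<)"), "invalid")
})

test_that("kinetic trajectories behave at the boundaries and are reproducible", {
  # no possible pairs: flat trajectory, MFE reached at t = 0
  tr <- simulate_trajectory("AAAA", seed = 1)
  expect_true(tr$reached_mfe)
  expect_identical(tr$energies, 0)
  expect_identical(tr$avg_energy, 0)
  # fixed seed reproduces the trajectory exactly
  a <- simulate_trajectory("GGGGAAAACCCC", seed = 42)
  b <- simulate_trajectory("GGGGAAAACCCC", seed = 42)
  expect_identical(a$times, b$times)
  expect_identical(a$energies, b$energies)
  # structural validity: recorded energies are reachable pair counts
  expect_true(all(a$energies == round(a$energies)))
  expect_true(all(a$energies <= 0 & a$energies >= a$mfe_energy))
  expect_true(!is.unsorted(a$times))
  expect_lte(max(a$times), a$t_max)
})

test_that("a short hairpin reliably reaches its MFE within t_max", {
  set.seed(77)
  reached <- replicate(200, simulate_trajectory("GCGCAAAAGCGC")$reached_mfe)
  expect_gte(mean(reached), 0.9)
})

test_that("time-average energy lies between MFE and zero", {
  set.seed(88)
  for (i in 1:10) {
    sq <- random_rna(20)
    tr <- simulate_trajectory(sq)
    expect_gte(tr$avg_energy, tr$mfe_energy)
    expect_lte(tr$avg_energy, 0)
  }
})
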