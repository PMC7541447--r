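toy_construct <- function(seed = 5) {
  assemble_switch(random_triggers(1, seed = seed)$trigger)
}

test_that("segmentation yields the documented regions and lengths", {
  segs <- segment_construct(toy_construct())
  len <- function(rg) segs$length[segs$region == rg]
  # composite regions match their reconstructed ideal structures
  expect_identical(len("Stem"), nchar(ideal_structures()$Stem))
  expect_identical(len("Stem"), 47L)          # 18 + 11 + 18
  expect_identical(len("StemTop"), nchar(ideal_structures()$StemTop))
  expect_identical(len("StemTop"), 23L)       # 6 + 11 + 6
  expect_identical(len("SwitchOFF"), 79L)
  expect_identical(len("SwitchON_GFP"), 148L) # GGG + 145
  # every composite ideal structure length equals its region length
  comp <- segs[segs$kind == "composite", ]
  expect_identical(nchar(comp$ideal), comp$length)
  # trigger slice reproduces the input trigger
  sw <- toy_construct()
  segs2 <- segment_construct(sw)
  expect_identical(segs2$seq[segs2$region == "Trigger"], sw$trigger)
})

test_that("ideal structures encode the designed pairing patterns", {
  st <- ideal_structures()
  # stem: 9 pairs / 3-nt bulge / 6 pairs around an 11-nt loop
  pr <- db_pairs(st$Stem)
  expect_identical(nrow(pr), 15L)
  # ON duplex pairs all 30 trigger nt
  expect_identical(nrow(db_pairs(st$SwitchON)), 30L)
  expect_identical(nrow(db_pairs(st$ToeholdON)), 12L)
  # ideal pairs are complementary in an assembled construct
  sw <- toy_construct(9)
  segs <- segment_construct(sw)
  stem_seq <- seq_chars(segs$seq[segs$region == "Stem"], "rna")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (r in seq_len(nrow(pr))) {
    expect_identical(unname(comp[stem_seq[pr[r, 1]]]), stem_seq[pr[r, 2]])
  }
})

test_that("rational featurizer emits exactly 30 numeric features", {
  rf <- rational_features(toy_construct())
  num <- rf[vapply(rf, is.numeric, logical(1))]
  expect_identical(ncol(num), 30L)
  expect_identical(sum(startsWith(names(num), "mfe_")), 14L)
  expect_identical(sum(startsWith(names(num), "ied_")), 8L)
  expect_identical(sum(startsWith(names(num), "ned_")), 8L)
  expect_identical(rf$engine, "nussinov")
  # defects are non-negative; MFEs non-positive
  expect_true(all(num[startsWith(names(num), "ied_")] >= 0))
  expect_true(all(num[startsWith(names(num), "ned_")] >= 0))
  expect_true(all(num[startsWith(names(num), "mfe_")] <= 0))
})

test_that("rational features hit known limit values", {
  rf <- rational_features(toy_construct(7))
  # NED of a region is computed vs its own MFE structure: for any region the
  # NED cannot exceed the IED plus the region size, and the Trigger MFE
  # equals the fold engine's answer directly
  sw <- toy_construct(7)
  expect_identical(rf$mfe_Trigger, fold_mfe(sw$trigger)$energy)
  segs <- segment_construct(sw)
  stem <- segs$seq[segs$region == "Stem"]
  expect_identical(rf$mfe_Stem, fold_mfe(stem)$energy)
  expect_equal(rf$ned_Stem,
               ensemble_defect(stem, fold_mfe(stem)$structure))
  expect_equal(rf$ied_Stem,
               ensemble_defect(stem, ideal_structures()$Stem))
})

test_that("feature vectors are deterministic given sequence and engine", {
  sw <- toy_construct(11)
  expect_identical(rational_features(sw), rational_features(sw))
})

test_that("kinetic featurizer emits exactly 4 features with coherent values", {
  sw <- toy_construct(3)
  kf <- kinetic_features(sw, n_traj = 10, t_max = 50, seed = 21)
  expect_identical(ncol(kf), 4L)
  expect_identical(names(kf), c("mean_avg_energy", "sd_avg_energy",
                                "ratio_mean_avg_to_mfe",
                                "fraction_reached_mfe"))
  expect_gte(kf$fraction_reached_mfe, 0)
  expect_lte(kf$fraction_reached_mfe, 1)
  # mean average energy cannot beat the minimum
  reg <- substr(sw$model_input, 51, 130)
  expect_gte(kf$mean_avg_energy, fold_mfe(reg)$energy)
  expect_gte(kf$sd_avg_energy, 0)
  # seeded determinism
  kf2 <- kinetic_features(sw, n_traj = 10, t_max = 50, seed = 21)
  expect_identical(kf, kf2)
  expect_error(kinetic_features(sw, n_traj = 1), "sd undefined")
})

test_that("trajectories pinned at the MFE give ratio 1 and fraction 1", {
  # an unpairable kinetic region (override to the all-A linker): MFE = 0,
  # trajectories flat at 0
  k <- design_constants(linker = strrep("A", 20))
  sw <- assemble_switch(strrep("T", 30), constants = k)
  kf <- kinetic_features(sw, n_traj = 5, t_max = 20, seed = 1,
                         region = c(31L, 50L))
  expect_identical(kf$ratio_mean_avg_to_mfe, 1)
  expect_identical(kf$fraction_reached_mfe, 1)
  expect_identical(kf$mean_avg_energy, 0)
})

test_that("time-average energy equals the step-function integral of the record", {
  # piecewise-constant reconstruction from the recorded events must
  # reproduce avg_energy exactly (e.g. 0 on [0,500) and -10 on [500,1000]
  # averages to -5); verified on simulated trajectories
  step_average <- function(times, energies, t_max) {
    dt <- diff(c(times, t_max))
    sum(energies * dt) / t_max
  }
  expect_identical(step_average(c(0, 500), c(0, -10), 1000), -5)
  set.seed(31)
  for (i in 1:10) {
    tr <- simulate_trajectory(random_rna(18), t_max = 100)
    expect_false(tr$truncated)
    expect_equal(step_average(tr$times, tr$energies, tr$t_max),
                 tr$avg_energy, tolerance = 1e-9)
  }
})

test_that("library featurization produces one row per variant", {
  lib <- design_library(random_triggers(3, seed = 2))
  ft <- featurize_library(lib)
  expect_identical(nrow(ft), 3L)
  expect_identical(ncol(ft), 32L)  # id + 30 features + engine
})
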