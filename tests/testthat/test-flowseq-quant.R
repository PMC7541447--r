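toy_table <- function(counts, totals = NULL, ids = NULL) {
  df <- tibble::as_tibble(counts, .name_repair = ~ paste0("bin", 1:ncol(counts)))
  df <- dplyr::bind_cols(
    tibble::tibble(variant_id = ids %||% paste0("v", seq_len(nrow(counts)))), df)
  bin_count_table(df, totals = totals)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("bin weights follow depth normalization then renormalization", {
  # reads only in bin 4 -> weights (0,0,0,1)
  w <- normalize_counts(toy_table(matrix(c(0, 0, 0, 12), 1)))
  expect_equal(unlist(w[1, c("w1", "w2", "w3", "w4")]),
               c(w1 = 0, w2 = 0, w3 = 0, w4 = 1))
  # equal counts and equal totals -> uniform weights
  w2 <- normalize_counts(toy_table(matrix(c(5, 5, 5, 5), 1),
                                   totals = c(100, 100, 100, 100)))
  expect_equal(unname(unlist(w2[1, paste0("w", 1:4)])), rep(0.25, 4))
  # depth-scale invariance: (10,0,0,0) vs (1,0,0,0) under identical totals
  wa <- normalize_counts(toy_table(matrix(c(10, 0, 0, 0), 1),
                                   totals = c(100, 10, 10, 10)))
  wb <- normalize_counts(toy_table(matrix(c(1, 0, 0, 0), 1),
                                   totals = c(100, 10, 10, 10)))
  expect_equal(unlist(wa[1, paste0("w", 1:4)]),
               unlist(wb[1, paste0("w", 1:4)]))
  # all-zero variants are excluded with a message
  expect_message(
    out <- normalize_counts(toy_table(rbind(c(1, 0, 0, 0), c(0, 0, 0, 0)),
                                      totals = c(10, 10, 10, 10))),
    "excluded")
  expect_identical(nrow(out), 1L)
})

test_that("functional value anchors at 0 and 1 and is 0.5 for uniform weights", {
  expect_identical(functional_value(c(0, 0, 0, 1)), 1)
  expect_identical(functional_value(c(1, 0, 0, 0)), 0)
  expect_equal(functional_value(rep(0.25, 4)), 0.5)  # mean of (0,1/3,2/3,1)
  expect_error(functional_value(c(0.5, 0.2)), "sum to 1")
})

test_that("functional value is invariant to count scaling and sequencing depth", {
  set.seed(10)
  for (rep in 1:50) {
    counts <- matrix(rpois(4, 20), 1)
    if (sum(counts) == 0) next
    totals <- rpois(4, 1000) + 100
    v1 <- functional_value(normalize_counts(toy_table(counts, totals)))$value
    v2 <- functional_value(normalize_counts(toy_table(counts * 7L, totals)))$value
    # per-bin depth doubling with proportionally doubled counts
    v3 <- functional_value(normalize_counts(toy_table(counts * 3L, totals * 3)))$value
    expect_equal(v1, v2)
    expect_equal(v1, v3)
    expect_true(v1 >= 0 && v1 <= 1)
  }
})

test_that("moving read mass to a higher bin never decreases the value", {
  set.seed(11)
  for (rep in 1:30) {
    counts <- matrix(rpois(4, 10) + 1L, 1)
    v <- functional_value(normalize_counts(toy_table(counts)))$value
    shifted <- counts
    shifted[1] <- shifted[1] - 1L
    shifted[4] <- shifted[4] + 1L
    v2 <- functional_value(normalize_counts(toy_table(shifted)))$value
    expect_gte(v2, v)
  }
})

test_that("ON/OFF subtraction hits the documented bounds", {
  expect_identical(onoff_ratio(1, 0), 1)
  expect_identical(onoff_ratio(0, 1), -1)
  expect_equal(onoff_ratio(0.8, 0.3), 0.5)
  expect_error(onoff_ratio(1.2, 0))
})

test_that("QC filtering removes low-read variants and flags single-bin artifacts", {
  counts <- rbind(c(3, 0, 0, 0),    # low reads, single bin
                  c(10, 5, 0, 0),   # passes
                  c(0, 0, 0, 50))   # passes but single-bin artifact
  m <- functional_value(normalize_counts(toy_table(counts)))
  q <- apply_qc(m, qc_policy(min_reads = 5))
  expect_identical(nrow(q$retained), 2L)
  expect_identical(q$retained$single_bin_artifact, c(FALSE, TRUE))
  expect_identical(q$report$n_removed, 1L)
  # nested tiers give monotonically non-increasing counts
  set.seed(12)
  big <- toy_table(matrix(rpois(400, 15), 100))
  mb <- functional_value(normalize_counts(big))
  sizes <- vapply(paste0("QC", 1:5), function(tier) {
    nrow(apply_qc(mb, qc_policy(tier))$retained)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("replicate concordance returns exact R2/MAE in closed-form cases", {
  r1 <- tibble::tibble(variant_id = paste0("v", 1:50),
                       value = runif(50))
  expect_equal(replicate_concordance(r1, r1)$r_squared, 1)
  expect_equal(replicate_concordance(r1, r1)$mae, 0)
  r2 <- dplyr::mutate(r1, value = value + 0.1)
  expect_equal(replicate_concordance(r2, r1)$mae, 0.1)
  # uncorrelated replicates: R2 near 0 (can be negative for this estimator)
  set.seed(13)
  ra <- tibble::tibble(variant_id = paste0("v", 1:1000), value = runif(1000))
  rb <- tibble::tibble(variant_id = paste0("v", 1:1000), value = runif(1000))
  cc <- replicate_concordance(ra, rb)
  expect_lt(abs(cor(ra$value, rb$value)^2), 0.05)
  expect_error(replicate_concordance(ra[0, ], rb), ">= 2 shared")
})

test_that("paired quantification joins ON and OFF and excludes unpaired variants", {
  on <- toy_table(rbind(c(0, 0, 0, 10), c(5, 5, 5, 5), c(7, 0, 0, 0)),
                  ids = c("a", "b", "c"))
  off <- toy_table(rbind(c(10, 0, 0, 0), c(5, 5, 5, 5)), ids = c("a", "b"))
  m <- quantify_library(on, off, policy = qc_policy(min_reads = 1))
  expect_identical(m$variant_id, c("a", "b"))
  expect_equal(m$onoff, m$on - m$off)
  expect_equal(m$onoff[1], 1)  # all-top ON, all-bottom OFF
})
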