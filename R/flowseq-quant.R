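# Flow-seq (sort-seq) quantification: per-bin read counts -> normalized
# functional values.
#
# Counts for each variant across the 4 fluorescence-ordered sorting bins are
# first normalized to the per-bin sequencing depth, then renormalized across
# bins to a proper weight distribution per variant. The functional value is
# the weighted mean of the bin representative values (0, 1/3, 2/3, 1 by
# default, configurable): 0 when all reads sit in the lowest bin, 1 when all
# sit in the highest. ON/OFF = ON - OFF, in [-1, 1].

.default_bin_values <- function(n_bins) (seq_len(n_bins) - 1) / (n_bins - 1)

#' Build a bin-count table
#'
#' @param counts A data frame with a `variant_id` column and one integer
#'   count column per bin, ordered low to high fluorescence (e.g.
#'   `bin1..bin4`).
#' @param totals Optional per-bin sequencing totals; defaults to the column
#'   sums of `counts` (i.e. the library accounts for all mapped reads).
#' @param label Library label (`"ON"` or `"OFF"`).
#' @return A `bin_count_table`: tibble of counts with attributes `totals`
#'   and `label`.
#' @export
bin_count_table <- function(counts, totals = NULL, label = "ON") {
  stopifnot(is.data.frame(counts), "variant_id" %in% names(counts))
  bins <- setdiff(names(counts), "variant_id")
  if (length(bins) < 2) stop("need at least 2 bin columns", call. = FALSE)
  cm <- as.matrix(counts[bins])
  if (any(cm < 0) || any(cm != floor(cm))) {
    stop("bin counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(totals)) totals <- colSums(cm)
  stopifnot(length(totals) == length(bins))
  out <- tibble::as_tibble(counts)
  attr(out, "totals") <- as.numeric(totals)
  attr(out, "label") <- label
  class(out) <- c("bin_count_table", class(out))
  out
}

#' Normalize bin counts to per-variant weight distributions
#'
#' Divides each variant's bin counts by the per-bin sequencing totals and
#' renormalizes across bins so the weights sum to 1 per variant. Variants
#' with zero reads in every bin are excluded and reported via a message.
#'
#' @param table A [bin_count_table()] (or plain data frame with
#'   `variant_id` + bin columns).
#' @return A tibble: `variant_id`, one weight column per bin (`w1..wk`),
#'   `total_reads`, `n_bins_occupied`.
#' @export
normalize_counts <- function(table) {
  if (!inherits(table, "bin_count_table")) table <- bin_count_table(table)
  bins <- setdiff(names(table), "variant_id")
  totals <- attr(table, "totals")
  cm <- as.matrix(table[bins])
  total_reads <- rowSums(cm)
  drop <- total_reads == 0
  if (any(drop)) {
    message(sum(drop), " variant(s) with zero reads in all bins excluded")
  }
  cm <- cm[!drop, , drop = FALSE]
  occupied <- totals > 0
  if (any(colSums(cm) > 0 & !occupied)) {
    stop("occupied bin has zero sequencing total", call. = FALSE)
  }
  freq <- sweep(cm, 2, ifelse(occupied, totals, 1), "/")
  w <- freq / rowSums(freq)
  out <- tibble::tibble(variant_id = table$variant_id[!drop])
  colnames(w) <- paste0("w", seq_along(bins))
  out <- dplyr::bind_cols(out, tibble::as_tibble(w))
  out$total_reads <- as.integer(total_reads[!drop])
  out$n_bins_occupied <- as.integer(rowSums(cm > 0))
  out
}

#' Functional value from bin weights
#'
#' Weighted mean of the bin representative values: 0 for the lowest bin,
#' 1 for the highest, equally spaced by default.
#'
#' @param weights A numeric weight vector summing to 1, or the tibble
#'   returned by [normalize_counts()] (adds a `value` column).
#' @param bin_values Representative value per bin (default
#'   `(0, 1/3, 2/3, 1)` for 4 bins).
#' @return A number in `[0, 1]`, or the input tibble with `value` appended.
#' @export
functional_value <- function(weights, bin_values = NULL) {
  if (is.data.frame(weights)) {
    wcols <- grep("^w[0-9]+$", names(weights), value = TRUE)
    bv <- bin_values %||% .default_bin_values(length(wcols))
    weights$value <- as.numeric(as.matrix(weights[wcols]) %*% bv)
    return(weights)
  }
  bv <- bin_values %||% .default_bin_values(length(weights))
  stopifnot(length(bv) == length(weights))
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weights must sum to 1", call. = FALSE)
  }
  sum(weights * bv)
}

#' ON/OFF ratio
#'
#' @param on,off Functional values in `[0, 1]`.
#' @return `on - off`, in `[-1, 1]`.
#' @export
onoff_ratio <- function(on, off) {
  stopifnot(all(on >= 0 & on <= 1, na.rm = TRUE),
            all(off >= 0 & off <= 1, na.rm = TRUE))
  on - off
}

#' Quality-control policies
#'
#' Nested QC tiers ordered by increasing stringency. The numeric read-count
#' thresholds (5/10/20/50/100 for QC1-QC5) are package defaults, not values
#' from any published table; `max_bin_std` optionally caps the standard
#' deviation of a variant's bin-index distribution.
#'
#' @param tier One of `"QC1"`..`"QC5"`, or `NULL` to pass `min_reads`
#'   directly.
#' @param min_reads Minimum total reads per library for a variant.
#' @param max_bin_std Optional cap on the weighted standard deviation of the
#'   occupied bin indices.
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(tier = NULL, min_reads = 5L, max_bin_std = NULL) {
  defaults <- c(QC1 = 5L, QC2 = 10L, QC3 = 20L, QC4 = 50L, QC5 = 100L)
  if (!is.null(tier)) {
    tier <- match.arg(tier, names(defaults))
    min_reads <- defaults[[tier]]
  } else {
    tier <- paste0("custom_minreads_", min_reads)
  }
  structure(list(tier = tier, min_reads = as.integer(min_reads),
                 max_bin_std = max_bin_std), class = "qc_policy")
}

#' Apply a QC policy to quantified measurements
#'
#' Retains variants meeting the read-count (and optional bin-spread)
#' thresholds and flags single-bin variants as potential gate-boundary
#' artifacts (an overrepresentation of variants with reads in only one bin
#' marks sorting-gate artifacts).
#'
#' @param measurements A tibble from [normalize_counts()] +
#'   [functional_value()] (needs `total_reads`, `n_bins_occupied`).
#' @param policy A [qc_policy()].
#' @return A list with `retained` (tibble, extra columns `qc_level`,
#'   `single_bin_artifact`) and `report` (counts of removed/flagged).
#' @export
apply_qc <- function(measurements, policy = qc_policy("QC2")) {
  stopifnot(inherits(policy, "qc_policy"),
            all(c("total_reads", "n_bins_occupied") %in% names(measurements)))
  keep <- measurements$total_reads >= policy$min_reads
  if (!is.null(policy$max_bin_std)) {
    wcols <- grep("^w[0-9]+$", names(measurements), value = TRUE)
    w <- as.matrix(measurements[wcols])
    idx <- seq_along(wcols)
    mu <- as.numeric(w %*% idx)
    bin_std <- sqrt(pmax(as.numeric(w %*% idx^2) - mu^2, 0))
    keep <- keep & bin_std <= policy$max_bin_std
  }
  retained <- measurements[keep, , drop = FALSE]
  retained$qc_level <- policy$tier
  retained$single_bin_artifact <- retained$n_bins_occupied == 1L
  list(retained = retained,
       report = tibble::tibble(
         tier = policy$tier,
         n_input = nrow(measurements),
         n_retained = nrow(retained),
         n_removed = sum(!keep),
         n_flagged_single_bin = sum(retained$single_bin_artifact)
       ))
}

#' Replicate concordance (R-squared and MAE)
#'
#' Coefficient of determination and mean absolute error between two
#' replicate measurement sets on their shared variants.
#'
#' @param rep1,rep2 Tibbles with `variant_id` and `value` columns.
#' @return A tibble: `n_shared`, `r_squared`, `mae`.
#' @export
replicate_concordance <- function(rep1, rep2) {
  shared <- dplyr::inner_join(
    dplyr::select(rep1, "variant_id", v1 = "value"),
    dplyr::select(rep2, "variant_id", v2 = "value"),
    by = "variant_id"
  )
  if (nrow(shared) < 2) stop("need >= 2 shared variants", call. = FALSE)
  ss_res <- sum((shared$v1 - shared$v2)^2)
  ss_tot <- sum((shared$v2 - mean(shared$v2))^2)
  tibble::tibble(
    n_shared = nrow(shared),
    r_squared = 1 - ss_res / ss_tot,
    mae = mean(abs(shared$v1 - shared$v2))
  )
}

#' Quantify paired ON/OFF libraries
#'
#' Full quantification path: normalize both count tables, compute functional
#' values, apply QC, and join ON and OFF into paired measurements with
#' ON/OFF ratios. Variants missing either library are excluded from the
#' paired set.
#'
#' @param on,off [bin_count_table()]s for the ON and OFF libraries.
#' @param policy A [qc_policy()].
#' @param bin_values Passed to [functional_value()].
#' @return A tibble: `variant_id`, `on`, `off`, `onoff`, `total_reads_on`,
#'   `total_reads_off`, `n_bins_occupied_on`, `n_bins_occupied_off`,
#'   `qc_level`, `single_bin_artifact`.
#' @export
quantify_library <- function(on, off, policy = qc_policy("QC2"),
                             bin_values = NULL) {
  q1 <- apply_qc(functional_value(normalize_counts(on), bin_values), policy)
  q2 <- apply_qc(functional_value(normalize_counts(off), bin_values), policy)
  a <- dplyr::select(q1$retained, "variant_id", on = "value",
                     total_reads_on = "total_reads",
                     n_bins_occupied_on = "n_bins_occupied",
                     artifact_on = "single_bin_artifact")
  b <- dplyr::select(q2$retained, "variant_id", off = "value",
                     total_reads_off = "total_reads",
                     n_bins_occupied_off = "n_bins_occupied",
                     artifact_off = "single_bin_artifact")
  dplyr::inner_join(a, b, by = "variant_id") |>
    dplyr::mutate(
      onoff = onoff_ratio(.data$on, .data$off),
      qc_level = policy$tier,
      single_bin_artifact = .data$artifact_on | .data$artifact_off
    ) |>
    dplyr::select(-"artifact_on", -"artifact_off") |>
    dplyr::relocate("onoff", .after = "off")
}
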