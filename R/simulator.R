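# Synthetic flow-seq world: sequence -> function landscapes with known,
# structure-driven ground truth, plus a generative model of the sorting and
# sequencing measurement.
#
# Ground-truth rule (logistic link, truncation to [0, 1]):
#   OFF* = plogis(off_intercept + w_off * d_v) + noise, where d_v is the
#     planted competing-duplex strength: the number of MFE base pairs of the
#     variant's SwitchOFF region that are NOT part of the designed hairpin
#     (off-target structure competing with the repressive stem -> leak).
#   ON* = plogis(on_intercept - w_on * a_v) + noise, where a_v is the
#     toehold self-structure: the number of MFE pairs internal to the
#     trigger, which sequesters the toehold of the fused ON transcript.
# Both mechanisms are computed with the built-in fold engine so the world is
# hermetic. Noise is additive Gaussian after the link, then truncated.
#
# Measurement model: each cell's log10 fluorescence is Normal around the
# variant's mean (log-normal cell-to-cell noise; a clonal population spans
# roughly one decade, sd 0.3 decades); four sorting gates at decade spacing
# split the signal range; reads are drawn per bin by multinomial sampling
# proportional to the variants' cell occupancy of that bin.

#' Landscape generator configuration
#'
#' @param n_variants Number of variants.
#' @param w_on,w_off Ground-truth rule coefficients (per base pair) for the
#'   toehold-accessibility (ON) and competing-duplex (OFF) mechanisms.
#' @param on_intercept,off_intercept Logistic-link intercepts. The defaults
#'   center the link at the mechanism strength of a typical random-trigger
#'   variant under this architecture (about 9.4 trigger self-pairs and about
#'   21 off-target pairs), so the generated ON*/OFF* values span the full
#'   functional range the way the real library does.
#' @param noise_sd Additive noise sd after the link (default 0.05).
#' @param seed Seed for trigger generation and noise.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_variants = 2000L, w_on = 1.2, w_off = 0.35,
                             on_intercept = 11.3, off_intercept = -7.3,
                             noise_sd = 0.05, seed = 1L) {
  structure(list(n_variants = as.integer(n_variants), w_on = w_on,
                 w_off = w_off, on_intercept = on_intercept,
                 off_intercept = off_intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Generate a synthetic sequence-to-function landscape
#'
#' Draws random triggers, assembles switches, computes the planted
#' structural mechanisms with the fold engine and returns ground-truth
#' ON*/OFF* values in `[0, 1]`.
#'
#' @param cfg A [landscape_config()].
#' @param triggers Optional trigger tibble (defaults to
#'   `random_triggers(cfg$n_variants, cfg$seed)`).
#' @param constants Design constants.
#' @return A tibble: `id`, `trigger`, `model_input`, `duplex_strength`,
#'   `toehold_self_structure`, `on_true`, `off_true`, `onoff_true`.
#' @export
generate_landscape <- function(cfg = landscape_config(), triggers = NULL,
                               constants = design_constants()) {
  stopifnot(inherits(cfg, "landscape_config"))
  triggers <- triggers %||% random_triggers(cfg$n_variants, seed = cfg$seed)
  lib <- design_library(triggers, constants)
  ideal_off <- ideal_structures()$SwitchOFF
  ideal_pairs <- db_pairs(ideal_off)
  ideal_key <- paste(ideal_pairs[, 1], ideal_pairs[, 2])
  feats <- purrr::map_dfr(seq_len(nrow(lib)), function(i) {
    mi <- lib$model_input[i]
    off_region <- substr(mi, 31, 109)            # SwitchOFF region
    mfe_off <- fold_mfe(off_region)
    pr <- db_pairs(mfe_off$structure)
    off_target <- if (nrow(pr)) {
      sum(!(paste(pr[, 1], pr[, 2]) %in% ideal_key))
    } else 0L
    self_trigger <- fold_mfe(lib$trigger[i])$n_pairs
    tibble::tibble(duplex_strength = off_target,
                   toehold_self_structure = self_trigger)
  })
  set.seed(cfg$seed + 1L)
  n <- nrow(lib)
  on_true <- stats::plogis(cfg$on_intercept -
                             cfg$w_on * feats$toehold_self_structure) +
    rnorm(n, sd = cfg$noise_sd)
  off_true <- stats::plogis(cfg$off_intercept +
                              cfg$w_off * feats$duplex_strength) +
    rnorm(n, sd = cfg$noise_sd)
  dplyr::bind_cols(lib, feats) |>
    dplyr::mutate(
      on_true = pmin(pmax(on_true, 0), 1),
      off_true = pmin(pmax(off_true, 0), 1),
      onoff_true = .data$on_true - .data$off_true
    )
}

#' Sort-seq measurement configuration
#'
#' @param cells_per_variant Cells sorted per variant (default 160, roughly the
#'   per-variant event count of a 10M-events-per-gate sort of a 240k library).
#' @param log_sd Cell-to-cell log10-fluorescence sd in decades (default 0.3;
#'   a clonal population spans roughly one order of magnitude).
#' @param gates Gate boundaries on the log10 scale; 4 bins at decade
#'   spacing by default, exhaustive over the signal range (the outer gates
#'   absorb everything beyond them).
#' @param reads_per_variant Expected sequencing reads per variant
#'   (default 150); total depth is split across bins in proportion to the
#'   cells they receive.
#' @param seed Seed for cell draws and read sampling.
#' @return A `sortseq_config` list.
#' @export
sortseq_config <- function(cells_per_variant = 160L, log_sd = 0.3,
                           gates = c(1, 2, 3), reads_per_variant = 150L,
                           seed = 1L) {
  stopifnot(!is.unsorted(gates))
  structure(list(cells_per_variant = as.integer(cells_per_variant),
                 log_sd = log_sd, gates = gates,
                 reads_per_variant = as.integer(reads_per_variant),
                 seed = as.integer(seed)),
            class = "sortseq_config")
}

#' Simulate a flow-seq experiment for one library
#'
#' Maps each variant's ground-truth value onto a mean log10 fluorescence
#' (truth 0 = center of the lowest bin, truth 1 = center of the highest),
#' draws log-normal cell fluorescence, assigns cells to the four gates and
#' samples reads per bin multinomially in proportion to cell occupancy.
#'
#' @param truth Tibble with `id` and the truth column named by `value_col`.
#' @param cfg A [sortseq_config()].
#' @param value_col Which truth column to measure (`"on_true"` or
#'   `"off_true"`).
#' @param label Library label for the count table.
#' @return A [bin_count_table()] with columns `variant_id`, `bin1..bin4`.
#' @export
simulate_flowseq <- function(truth, cfg = sortseq_config(),
                             value_col = "on_true", label = "ON") {
  stopifnot(is.data.frame(truth), "id" %in% names(truth),
            value_col %in% names(truth))
  set.seed(cfg$seed)
  v <- truth[[value_col]]
  n <- length(v)
  n_bins <- length(cfg$gates) + 1L
  lo <- cfg$gates[1] - 0.5                      # center of lowest bin
  hi <- cfg$gates[length(cfg$gates)] + 0.5      # center of highest bin
  mu <- lo + v * (hi - lo)
  # cell occupancy of each gate per variant
  occ <- matrix(0, n, n_bins)
  for (i in seq_len(n)) {
    cells <- rnorm(cfg$cells_per_variant, mean = mu[i], sd = cfg$log_sd)
    b <- findInterval(cells, cfg$gates) + 1L
    occ[i, ] <- tabulate(b, nbins = n_bins)
  }
  # per-bin sequencing: depth proportional to cells in the bin
  bin_cells <- colSums(occ)
  total_reads <- cfg$reads_per_variant * n
  counts <- matrix(0L, n, n_bins)
  for (b in seq_len(n_bins)) {
    if (bin_cells[b] == 0) next
    depth <- round(total_reads * bin_cells[b] / sum(bin_cells))
    if (depth == 0) next
    counts[, b] <- as.integer(rmultinom(1, depth, prob = occ[, b] + 1e-12))
  }
  df <- tibble::as_tibble(counts, .name_repair = ~ paste0("bin", seq_len(n_bins)))
  df <- dplyr::bind_cols(tibble::tibble(variant_id = truth$id), df)
  bin_count_table(df, label = label)
}

#' Simulate a complete paired ON/OFF flow-seq dataset
#'
#' @param landscape A [generate_landscape()] tibble.
#' @param cfg A [sortseq_config()]; the OFF library reuses it with
#'   `seed + 1`.
#' @return A list: `on`, `off` ([bin_count_table()]s), `truth` (the
#'   landscape).
#' @export
simulate_flowseq_pair <- function(landscape, cfg = sortseq_config()) {
  on <- simulate_flowseq(landscape, cfg, value_col = "on_true", label = "ON")
  cfg_off <- cfg
  cfg_off$seed <- cfg$seed + 1L
  off <- simulate_flowseq(landscape, cfg_off, value_col = "off_true",
                          label = "OFF")
  list(on = on, off = off, truth = landscape)
}
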