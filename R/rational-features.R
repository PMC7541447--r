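# Rational (thermodynamic) and kinetic feature computation.
#
# Per switch: 14 MFE values (the 8 composite regions + 6 primary segments:
# Trigger, Switch, Stem1, Stem2, Linker, Post_linker), 8 ideal ensemble
# defects (IED, vs the designed structure) and 8 native ensemble defects
# (NED, vs the region's own MFE structure) over the same 8 composite
# regions: 14 + 8 + 8 = 30 features. Four kinetic features summarize 100
# folding trajectories of the OFF-switch kinetic region (toehold start
# through AA-linker end).

#' Compute the 30 thermodynamic rational features for one construct
#'
#' @param construct A [assemble_switch()] result.
#' @param min_loop,beta Fold-engine parameters (see [fold_mfe()]).
#' @return A one-row tibble with 30 numeric feature columns
#'   (`mfe_*` x 14, `ied_*` x 8, `ned_*` x 8) plus `engine`.
#' @export
rational_features <- function(construct, min_loop = 3L, beta = 1) {
  segs <- segment_construct(construct)
  mfe_regions <- c(.PRIMARY_MFE_REGIONS, .COMPOSITE_REGIONS)
  out <- list()
  for (rg in mfe_regions) {
    s <- segs$seq[segs$region == rg]
    out[[paste0("mfe_", rg)]] <- tryCatch(
      fold_mfe(s, min_loop = min_loop)$energy,
      error = function(e) {
        warning("MFE failed for region ", rg, ": ", conditionMessage(e),
                call. = FALSE)
        NA_real_
      })
  }
  for (rg in .COMPOSITE_REGIONS) {
    s <- segs$seq[segs$region == rg]
    res <- tryCatch({
      pp <- pair_probabilities(s, min_loop = min_loop, beta = beta)
      native <- fold_mfe(s, min_loop = min_loop)$structure
      c(ied = ensemble_defect(s, segs$ideal[segs$region == rg], probs = pp),
        ned = ensemble_defect(s, native, probs = pp))
    }, error = function(e) {
      warning("ensemble defect failed for region ", rg, ": ",
              conditionMessage(e), call. = FALSE)
      c(ied = NA_real_, ned = NA_real_)
    })
    out[[paste0("ied_", rg)]] <- unname(res["ied"])
    out[[paste0("ned_", rg)]] <- unname(res["ned"])
  }
  # order: 14 MFE, 8 IED, 8 NED
  nm <- c(paste0("mfe_", mfe_regions),
          paste0("ied_", .COMPOSITE_REGIONS),
          paste0("ned_", .COMPOSITE_REGIONS))
  tibble::as_tibble(out)[, nm] |>
    dplyr::mutate(engine = "nussinov")
}

#' Compute the 4 kinetic trajectory features for one construct
#'
#' Runs `n_traj` kinetic Monte-Carlo folding trajectories of the kinetic
#' region (default: toehold start through AA-linker end, 80 nt) and reports
#' the mean and standard deviation of the per-trajectory time-average
#' energies, the ratio of the mean average energy to the region MFE, and the
#' fraction of trajectories that reached the MFE within `t_max`.
#'
#' @param construct A [assemble_switch()] result.
#' @param n_traj Number of trajectories (default 100; must be >= 2).
#' @param t_max Maximum simulated time in arbitrary units (default 1e3).
#' @param seed Optional integer seed.
#' @param region Two model-input coordinates `c(start, end)` for the kinetic
#'   region; default `c(51, 130)`.
#' @param min_loop,beta Fold-engine parameters.
#' @return A one-row tibble: `mean_avg_energy`, `sd_avg_energy`,
#'   `ratio_mean_avg_to_mfe`, `fraction_reached_mfe`.
#' @export
kinetic_features <- function(construct, n_traj = 100L, t_max = 1e3,
                             seed = NULL, region = c(51L, 130L),
                             min_loop = 3L, beta = 1) {
  stopifnot(inherits(construct, "switch_construct"))
  if (n_traj < 2L) stop("n_traj must be >= 2 (sd undefined)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- substr(construct$model_input, region[1], region[2])
  mfe <- fold_mfe(s, min_loop = min_loop)$energy
  traj <- purrr::map(seq_len(n_traj), function(i) {
    tr <- simulate_trajectory(s, t_max = t_max, min_loop = min_loop,
                              beta = beta)
    c(avg = tr$avg_energy, reached = as.numeric(tr$reached_mfe))
  })
  avg <- vapply(traj, `[[`, numeric(1), "avg")
  reached <- vapply(traj, `[[`, numeric(1), "reached")
  m <- mean(avg)
  tibble::tibble(
    mean_avg_energy = m,
    sd_avg_energy = sd(avg),
    ratio_mean_avg_to_mfe = if (mfe == 0) 1 else m / mfe,
    fraction_reached_mfe = mean(reached)
  )
}

#' Featurize a designed library
#'
#' Applies [rational_features()] (and optionally [kinetic_features()]) to
#' every variant of a design tibble.
#'
#' @param library A tibble from [design_library()] (needs `id`, `trigger`).
#' @param kinetic Also compute the 4 kinetic features (slower).
#' @param constants Design constants used during assembly.
#' @param ... Passed to [kinetic_features()].
#' @return A tibble with `id` plus 30 (or 34) feature columns and `engine`.
#' @export
featurize_library <- function(library, kinetic = FALSE,
                              constants = design_constants(), ...) {
  stopifnot(is.data.frame(library), all(c("id", "trigger") %in% names(library)))
  purrr::map_dfr(seq_len(nrow(library)), function(i) {
    cons <- assemble_switch(library$trigger[i], constants)
    row <- dplyr::bind_cols(tibble::tibble(id = library$id[i]),
                            rational_features(cons))
    if (kinetic) row <- dplyr::bind_cols(row, kinetic_features(cons, ...))
    row
  })
}
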