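# RNA secondary-structure engine.
#
# The package ships a deterministic fallback backend: a Nussinov-style
# maximum base-pairing model (minimum hairpin loop 3 nt, G-U wobble allowed)
# whose "energy" is -1 score unit per pair, together with the matching
# partition function (Boltzmann weight exp(beta) per pair, beta = 1 by
# default) and a simplified kinetic Monte-Carlo folding simulator. All
# downstream features record which engine produced them; a nearest-neighbour
# thermodynamic backend can be plugged in by implementing the same two
# primitives (`mfe`, `pair_probs`), but none is available in this
# environment, so the fallback is the active backend throughout.

#' Dot-bracket utilities
#'
#' `db_pairs()` parses a dot-bracket structure (Vienna dialect; `+` strand
#' nicks are accepted and stripped) into a two-column matrix of 1-based pair
#' indices. `db_validate()` checks balance and alphabet.
#'
#' @param structure A dot-bracket string over `. ( ) +`.
#' @return `db_pairs()`: an integer matrix with columns `i`, `j` (`i < j`).
#' @export
db_pairs <- function(structure) {
  s <- gsub("+", "", structure, fixed = TRUE)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) && !all(chars %in% c(".", "(", ")"))) {
    stop("invalid dot-bracket characters", call. = FALSE)
  }
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  pairs <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string", call. = FALSE)
      pairs[[length(pairs) + 1L]] <- c(open[length(open)], k)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string", call. = FALSE)
  if (length(pairs)) out <- do.call(rbind, pairs)
  colnames(out) <- c("i", "j")
  out
}

#' @rdname db_pairs
#' @export
db_validate <- function(structure) {
  db_pairs(structure)
  invisible(TRUE)
}

#' Minimum free energy structure
#'
#' Folds an RNA (or DNA, mapped T to U) sequence under the active backend.
#' The built-in fallback maximizes base pairs (Nussinov dynamic programme)
#' and reports energy in score units of -1 per pair.
#'
#' @param seq Nucleotide string.
#' @param min_loop Minimum hairpin loop length in nt (default 3).
#' @param scoring `"pairs"` (default; -1 per base pair) or `"stacks"`
#'   (-1 per stacked pair, so a helix of length h scores -(h-1) and isolated
#'   pairs are free; rewards contiguous helices the way nearest-neighbour
#'   models do).
#' @return An object of class `fold_result`: list with `structure`
#'   (dot-bracket), `energy`, `n_pairs`, `engine`.
#' @examples
#' fold_mfe("GGGAAACCC")
#' @export
fold_mfe <- function(seq, min_loop = 3L, scoring = c("pairs", "stacks")) {
  scoring <- match.arg(scoring)
  s <- seq_to_int(seq)
  if (!length(s)) stop("empty sequence", call. = FALSE)
  if (scoring == "pairs") {
    res <- cpp_nussinov(s, as.integer(min_loop))
    energy <- -as.numeric(res$n_pairs)
    struct <- res$structure
    npairs <- res$n_pairs
  } else {
    res <- cpp_stack_mfe(s, as.integer(min_loop))
    energy <- -as.numeric(res$n_stacks)
    struct <- res$structure
    npairs <- nrow(db_pairs(struct))
  }
  structure(
    list(structure = struct, energy = energy,
         n_pairs = npairs, seq = normalize_seq(seq, "rna"),
         engine = paste0("nussinov_", scoring)),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "  (", x$energy, " score units, ",
      x$engine, ")\n", sep = "")
  invisible(x)
}

#' Equilibrium base-pair probabilities
#'
#' Computes the Boltzmann-weighted probability that positions i and j are
#' paired at equilibrium under the fallback score model (weight `exp(beta)`
#' per pair).
#'
#' @inheritParams fold_mfe
#' @param beta Inverse temperature in score units (default 1).
#' @return An object of class `pair_prob`: list with the symmetric matrix
#'   `p`, the vector `p_unpaired`, the partition function `Z` and `engine`.
#' @export
pair_probabilities <- function(seq, min_loop = 3L, beta = 1) {
  s <- seq_to_int(seq)
  if (!length(s)) stop("empty sequence", call. = FALSE)
  res <- cpp_partition(s, as.integer(min_loop), beta)
  p <- res$p
  structure(
    list(p = p, p_unpaired = 1 - rowSums(p), Z = res$Z,
         seq = normalize_seq(seq, "rna"), engine = "nussinov"),
    class = "pair_prob"
  )
}

#' Ensemble defect relative to a target structure
#'
#' The expected number of nucleotides paired incorrectly at equilibrium:
#' `N - sum over target pairs of 2 p(i,j) - sum over target-unpaired i of
#' p_unpaired(i)`.
#'
#' @inheritParams fold_mfe
#' @param target Dot-bracket target structure, same length as `seq`.
#' @param probs Optional precomputed [pair_probabilities()] result.
#' @return A single non-negative number in `[0, N]`.
#' @export
ensemble_defect <- function(seq, target, probs = NULL) {
  s <- normalize_seq(seq, "rna")
  tgt <- gsub("+", "", target, fixed = TRUE)
  n <- nchar(s)
  if (nchar(tgt) != n) {
    stop("target structure length (", nchar(tgt),
         ") does not match sequence length (", n, ")", call. = FALSE)
  }
  if (is.null(probs)) probs <- pair_probabilities(s)
  pairs <- db_pairs(tgt)
  paired_idx <- c(pairs[, "i"], pairs[, "j"])
  unpaired_idx <- setdiff(seq_len(n), paired_idx)
  got <- 0
  if (nrow(pairs)) {
    got <- got + 2 * sum(probs$p[pairs])
  }
  got <- got + sum(probs$p_unpaired[unpaired_idx])
  defect <- n - got
  max(defect, 0)
}

#' Simulate a kinetic folding trajectory
#'
#' Kinetic Monte-Carlo over single-pair addition/removal moves with
#' Metropolis acceptance on fallback energies (unit attempt frequency per
#' candidate move; time in dimensionless arbitrary units). If the MFE energy
#' is reached within `t_max`, the molecule is assumed to remain there and the
#' post-MFE energy is clamped to the MFE.
#'
#' Randomness is drawn from R's RNG: call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @inheritParams pair_probabilities
#' @param t_max Maximum simulated time (default 1e3 arbitrary units).
#' @param seed Optional integer seed applied via `set.seed()`.
#' @param record_limit Maximum number of recorded events; the time-average
#'   energy stays exact even when the event record is truncated.
#' @return An object of class `fold_trajectory`: list with `times`,
#'   `energies`, `avg_energy` (time-average over `[0, t_max]`),
#'   `reached_mfe`, `t_reach`, `mfe_energy`, `t_max`.
#' @export
simulate_trajectory <- function(seq, t_max = 1e3, min_loop = 3L, beta = 1,
                                seed = NULL, record_limit = 20000L) {
  s <- seq_to_int(seq)
  if (!length(s)) stop("empty sequence", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mfe <- cpp_nussinov(s, as.integer(min_loop))
  res <- cpp_kinetic(s, as.integer(min_loop), beta, t_max,
                     mfe$n_pairs, as.integer(record_limit))
  structure(
    list(times = res$times, energies = res$energies,
         avg_energy = res$avg_energy, reached_mfe = res$reached_mfe,
         t_reach = res$t_reach, mfe_energy = -mfe$n_pairs,
         t_max = t_max, truncated = res$truncated, engine = "nussinov"),
    class = "fold_trajectory"
  )
}

#' @export
tidy.fold_trajectory <- function(x, ...) {
  tibble::tibble(time = x$times, energy = x$energies)
}

#' @export
print.fold_trajectory <- function(x, ...) {
  cat("kinetic folding trajectory: ", length(x$times), " events, ",
      "avg energy ", signif(x$avg_energy, 4), ", reached MFE: ",
      x$reached_mfe, "\n", sep = "")
  invisible(x)
}
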