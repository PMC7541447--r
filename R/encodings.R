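# Model input encodings.
#
# One-hot sequence: L x 4 matrix, channel order (A, C, G, U), T mapped to U.
# Complementarity map: L x L x 7 one-hot tensor; cell (i, j) encodes the
# pair-type of the ordered nucleotide pair (base_i, base_j):
#   G-C = 6, C-G = 5, A-U = 4, U-A = 3, G-U = 2, U-G = 1, any other = 0.
# The encoding is directional (row = first base of the ordered pair, both
# axes 5' to 3') and positional: the diagonal is encoded like any other cell
# and no minimum-loop masking is applied (configurable via `mask_diag`).

.PAIR_CATEGORY <- local({
  bases <- c("A", "C", "G", "U")
  m <- matrix(0L, 4, 4, dimnames = list(bases, bases))
  m["G", "C"] <- 6L; m["C", "G"] <- 5L
  m["A", "U"] <- 4L; m["U", "A"] <- 3L
  m["G", "U"] <- 2L; m["U", "G"] <- 1L
  m
})

#' One-hot encode a nucleotide sequence
#'
#' @param seq Nucleotide string (DNA or RNA; T maps to the U channel).
#'   Ambiguity codes are rejected.
#' @return An `L x 4` numeric matrix with columns `A, C, G, U`; each row
#'   sums to 1.
#' @export
onehot <- function(seq) {
  idx <- seq_to_int(seq) + 1L
  m <- matrix(0, length(idx), 4, dimnames = list(NULL, .BASES_RNA))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a one-hot matrix back to an RNA string
#'
#' @param m A matrix produced by [onehot()].
#' @return The RNA sequence string.
#' @export
onehot_decode <- function(m) {
  paste(.BASES_RNA[max.col(m)], collapse = "")
}

#' Pair-type category matrix of a sequence
#'
#' @inheritParams onehot
#' @return An `L x L` integer matrix of category codes 0..6 for every
#'   ordered position pair.
#' @export
pair_categories <- function(seq) {
  idx <- seq_to_int(seq) + 1L
  .PAIR_CATEGORY[idx, idx, drop = FALSE]
}

#' Directional complementarity map
#'
#' One-hot encoded categorical 2D complementarity tensor: for every ordered
#' position pair (i, j) the 7-channel one-hot of its pair-type category
#' (see module header for the category table).
#'
#' @inheritParams onehot
#' @param mask_diag Optionally zero all channels on the diagonal
#'   (default `FALSE`: no masking).
#' @return An `L x L x 7` numeric array of class `complementarity_map`;
#'   channel `k` corresponds to category `k - 1`.
#' @examples
#' m <- complementarity_map("GC")
#' which(m[1, 2, ] == 1) - 1  # category 6: G-C
#' @export
complementarity_map <- function(seq, mask_diag = FALSE) {
  cat <- pair_categories(seq)
  L <- nrow(cat)
  arr <- array(0, dim = c(L, L, 7))
  ij <- as.matrix(expand.grid(i = seq_len(L), j = seq_len(L)))
  arr[cbind(ij, cat[ij] + 1L)] <- 1
  if (mask_diag && L > 0) {
    for (k in 1:7) arr[cbind(seq_len(L), seq_len(L), k)] <- 0
  }
  structure(arr, class = c("complementarity_map", "array"),
            seq = normalize_seq(seq, "rna"))
}

#' Stack complementarity maps for a set of sequences
#'
#' Pads every sequence's map into a common `L_max x L_max` frame
#' (zero-padded bottom/right) and stacks them into an `n x L x L x 7`
#' array suitable for the 2D-map CNN.
#'
#' @param seqs Character vector of sequences.
#' @param L Frame size; default the maximum sequence length.
#' @return An `n x L x L x 7` array.
#' @export
stack_complementarity_maps <- function(seqs, L = NULL) {
  L <- L %||% max(nchar(seqs))
  n <- length(seqs)
  out <- array(0, dim = c(n, L, L, 7))
  for (v in seq_len(n)) {
    m <- complementarity_map(seqs[v])
    l <- dim(m)[1]
    if (l > L) stop("sequence longer than frame size L", call. = FALSE)
    out[v, seq_len(l), seq_len(l), ] <- m
  }
  out
}

#' Stack one-hot encodings for a set of equal-length sequences
#'
#' @param seqs Character vector of sequences (equal length).
#' @return An `n x L x 4` array.
#' @export
stack_onehot <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have equal length", call. = FALSE)
  n <- length(seqs)
  out <- array(0, dim = c(n, L, 4))
  for (v in seq_len(n)) out[v, , ] <- onehot(seqs[v])
  out
}
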