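# Nucleotide string helpers. Sequences are stored in the DNA alphabet
# (synthesis space) and converted to RNA on demand (folding space).

.BASES_DNA <- c("A", "C", "G", "T")
.BASES_RNA <- c("A", "C", "G", "U")

#' Validate and normalize a nucleotide string
#'
#' Uppercases the input and checks the alphabet. Accepts DNA (`ACGT`) or RNA
#' (`ACGU`); mixed `T`/`U` input is rejected only if characters outside
#' `ACGTU` appear.
#'
#' @param seq A single nucleotide string.
#' @param to Target alphabet, `"dna"` or `"rna"`.
#' @return The normalized string in the requested alphabet.
#' @export
normalize_seq <- function(seq, to = c("rna", "dna")) {
  to <- match.arg(to)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single nucleotide string", call. = FALSE)
  }
  s <- toupper(seq)
  bad <- gsub("[ACGTU]", "", s)
  if (nchar(bad) > 0) {
    stop("invalid characters in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  if (to == "rna") chartr("T", "U", s) else chartr("U", "T", s)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string (DNA or RNA); the output stays in the input
#'   alphabet (`U` in implies `U` out).
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  s <- normalize_seq(seq, to = if (grepl("U", toupper(seq))) "rna" else "dna")
  comp <- if (grepl("U", s)) chartr("ACGU", "UGCA", s) else chartr("ACGT", "TGCA", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# integer encoding used by the C++ engine: A=0, C=1, G=2, U=3
seq_to_int <- function(seq) {
  s <- normalize_seq(seq, to = "rna")
  match(strsplit(s, "")[[1]], .BASES_RNA) - 1L
}

seq_chars <- function(seq, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  strsplit(normalize_seq(seq, to = alphabet), "")[[1]]
}

random_dna <- function(n_nt) {
  paste(sample(.BASES_DNA, n_nt, replace = TRUE), collapse = "")
}
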