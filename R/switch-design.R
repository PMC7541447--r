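# First-generation fused-trigger toehold-switch design.
#
# Construct layout (5' to 3', 145 nt of model input):
#   trigger(30) linker(20) toehold(12) ascending_stem(18) loop(11)
#   descending_stem(18) aa_linker(21) gfp_head(15)
# The 30-nt sensor region (toehold + ascending stem) is the reverse
# complement of the trigger, so the trigger fully unwinds the hairpin.
# The descending stem pairs back onto the ascending stem in a
# 9-pair / 3-unpaired / 6-pair pattern, with the start codon sitting as the
# 3-nt bulge on the descending side.
#
# Constant segments (linker, SD loop, AA linker, GFP head, promoter,
# backbone) are package defaults taken from first-generation switch
# conventions -- the study's exact constants are not printed -- and are fully
# configurable through `design_constants()`.

#' Design constants for the fused-trigger switch architecture
#'
#' Returns the constant segments used by [assemble_switch()] and
#' [build_oligo()]. All sequences are DNA-alphabet; defaults are
#' first-generation toehold-switch conventions (the SD-containing loop
#' carries the canonical `AGAGGAGA` Shine-Dalgarno core; the 21-nt AA linker
#' is the common low-structure linker; the GFP head is the first 15 nt of
#' GFPmut3b after the start codon).
#'
#' @param linker 20-nt unstructured linker between fused trigger and toehold.
#' @param loop 11-nt SD-containing hairpin loop.
#' @param aa_linker 21-nt amino-acid linker downstream of the stem.
#' @param gfp_head First 15 nt of the GFP reporter gene.
#' @param t7_promoter T7 promoter; transcription adds `ggg_leader`.
#' @param ggg_leader Transcription-start leader (GGG).
#' @param backbone_5p 20-nt common 5' backbone on the synthesis oligo.
#' @param oligo_len Total synthesis oligo length (default 230 nt); the 3'
#'   adapter is auto-sized to reach it.
#' @return A named list of constants.
#' @export
design_constants <- function(linker = "AACACAAACCAACAAACCAA",
                             loop = "AACAGAGGAGA",
                             aa_linker = "AACCTGGCGGCAGCGCAAAAG",
                             gfp_head = "AGTAAAGGAGAAGAA",
                             t7_promoter = "TAATACGACTCACTATAG",
                             ggg_leader = "GGG",
                             backbone_5p = "CTGTCACCGGATGTGCTTTC",
                             oligo_len = 230L) {
  stopifnot(nchar(linker) == 20L, nchar(loop) == 11L,
            nchar(aa_linker) == 21L, nchar(gfp_head) == 15L)
  list(linker = normalize_seq(linker, "dna"),
       loop = normalize_seq(loop, "dna"),
       aa_linker = normalize_seq(aa_linker, "dna"),
       gfp_head = normalize_seq(gfp_head, "dna"),
       t7_promoter = normalize_seq(t7_promoter, "dna"),
       ggg_leader = normalize_seq(ggg_leader, "dna"),
       backbone_5p = normalize_seq(backbone_5p, "dna"),
       oligo_len = as.integer(oligo_len))
}

#' Tile a source sequence into 30-nt trigger windows
#'
#' Slides a `window`-nt window along `source` with the given stride
#' (viral genomes were tiled at stride 5, transcription-factor coding
#' regions at stride 10). Coordinates are 0-based, half-open.
#'
#' @param source Nucleotide string (DNA or RNA).
#' @param stride Step between window starts, in nt (>= 1).
#' @param window Window length (default 30 nt, the trigger length).
#' @param source_id Identifier recorded for each window.
#' @param origin Trigger origin label (`"viral"`, `"transcription_factor"`,
#'   or `"random"`).
#' @return A tibble with columns `source_id`, `start` (0-based), `trigger`
#'   (DNA), `origin`.
#' @export
tile_triggers <- function(source, stride, window = 30L,
                          source_id = "source",
                          origin = c("viral", "transcription_factor", "random")) {
  origin <- match.arg(origin)
  src <- normalize_seq(source, "dna")
  stopifnot(stride >= 1L)
  L <- nchar(src)
  if (L < window) {
    stop("source (", L, " nt) is shorter than the trigger window (",
         window, " nt); no triggers can be tiled", call. = FALSE)
  }
  starts <- seq(0L, L - window, by = as.integer(stride))
  tibble::tibble(
    source_id = source_id,
    start = as.integer(starts),
    trigger = substring(src, starts + 1L, starts + window),
    origin = origin
  )
}

#' Generate random 30-nt triggers
#'
#' @param n Number of triggers (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param window Trigger length (default 30).
#' @return A tibble like [tile_triggers()], with `origin = "random"` and
#'   `source_id = "random"`; `start` is the 0-based index within the batch.
#' @export
random_triggers <- function(n, seed = NULL, window = 30L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    source_id = "random",
    start = seq_len(n) - 1L,
    trigger = vapply(seq_len(n), function(i) random_dna(window), character(1)),
    origin = "random"
  )
}

#' Assemble a trigger into a fused-trigger switch construct
#'
#' Builds the sensor region as the reverse complement of the trigger
#' (12-nt toehold + 18-nt ascending stem) and a descending stem that pairs
#' back onto the ascending stem except for the 3-nt start-codon bulge
#' (descending positions 7-9), then concatenates the 145-nt model input.
#'
#' @param trigger A 30-nt trigger (DNA or RNA string).
#' @param constants Design constants from [design_constants()].
#' @return An object of class `switch_construct`: named list of DNA segments
#'   (`trigger`, `linker`, `toehold`, `ascending_stem`, `loop`,
#'   `descending_stem`, `aa_linker`, `gfp_head`) plus `model_input` (145 nt).
#' @examples
#' sw <- assemble_switch(strrep("A", 30))
#' nchar(sw$model_input)  # 145
#' @export
assemble_switch <- function(trigger, constants = design_constants()) {
  trg <- normalize_seq(trigger, "dna")
  if (nchar(trg) != 30L) {
    stop("trigger must be exactly 30 nt, got ", nchar(trg), call. = FALSE)
  }
  sensor <- revcomp(trg)                      # 30 nt, toehold + ascending stem
  toehold <- substr(sensor, 1L, 12L)
  asc <- substr(sensor, 13L, 30L)
  desc <- paste0(revcomp(substr(asc, 13L, 18L)),  # pairs ascending 13..18
                 "ATG",                           # start-codon bulge
                 revcomp(substr(asc, 1L, 9L)))    # pairs ascending 1..9
  segs <- list(trigger = trg, linker = constants$linker, toehold = toehold,
               ascending_stem = asc, loop = constants$loop,
               descending_stem = desc, aa_linker = constants$aa_linker,
               gfp_head = constants$gfp_head)
  model_input <- paste(unlist(segs), collapse = "")
  stopifnot(nchar(model_input) == 145L)
  structure(c(segs, list(model_input = model_input, constants = constants)),
            class = "switch_construct")
}

#' @export
print.switch_construct <- function(x, ...) {
  cat("toehold-switch construct (", nchar(x$model_input), " nt model input)\n",
      "  trigger: ", x$trigger, "\n  sensor : ", x$toehold, "|",
      x$ascending_stem, "\n", sep = "")
  invisible(x)
}

#' Build the full-length synthesis oligo for a construct
#'
#' Layout: 20-nt backbone, T7 promoter, GGG leader, the 145-nt construct,
#' then a 3' adapter auto-sized so the default total is 230 nt (the printed
#' segment list sums to less than the synthesis length; the remaining
#' constant is not specified, so the adapter is a configurable filler).
#'
#' @param construct A [assemble_switch()] result.
#' @param adapter_3p Optional explicit 3' adapter; when `NULL` a poly-`T`
#'   filler of the required length is used.
#' @return A list with `oligo`, `total_len`, and the component segments.
#' @export
build_oligo <- function(construct, adapter_3p = NULL) {
  stopifnot(inherits(construct, "switch_construct"))
  k <- construct$constants
  body <- paste0(k$backbone_5p, k$t7_promoter, k$ggg_leader,
                 construct$model_input)
  need <- k$oligo_len - nchar(body)
  if (is.null(adapter_3p)) {
    adapter_3p <- if (need > 0) strrep("T", need) else ""
  }
  oligo <- paste0(body, adapter_3p)
  if (nchar(oligo) != k$oligo_len) {
    warning("oligo length ", nchar(oligo), " differs from configured ",
            k$oligo_len, " nt", call. = FALSE)
  }
  list(oligo = oligo, total_len = nchar(oligo),
       backbone_5p = k$backbone_5p, t7_promoter = k$t7_promoter,
       ggg_leader = k$ggg_leader, adapter_3p = adapter_3p)
}

#' OFF-state insert (switch without the fused trigger)
#'
#' The OFF amplification primes on the 20-nt unstructured linker, so the
#' OFF insert is the construct minus its trigger.
#'
#' @inheritParams build_oligo
#' @return The 115-nt OFF insert sequence (DNA).
#' @export
build_off_insert <- function(construct) {
  stopifnot(inherits(construct, "switch_construct"))
  sub("^.{30}", "", construct$model_input)
}

#' Design a switch library from a trigger table
#'
#' Vectorized assembly: takes a trigger tibble (from [tile_triggers()],
#' [random_triggers()], or [read_trigger_fasta()] + tiling) and returns one
#' row per variant with its 145-nt model input.
#'
#' @param triggers A tibble with at least a `trigger` column; `source_id`,
#'   `start`, `origin` are carried through when present.
#' @param constants Design constants from [design_constants()].
#' @return A tibble with columns `id`, `origin`, `source_id`, `start`,
#'   `trigger`, `model_input`.
#' @export
design_library <- function(triggers, constants = design_constants()) {
  stopifnot(is.data.frame(triggers), "trigger" %in% names(triggers))
  model_input <- vapply(triggers$trigger,
                        function(t) assemble_switch(t, constants)$model_input,
                        character(1), USE.NAMES = FALSE)
  tibble::tibble(
    id = sprintf("sw%06d", seq_len(nrow(triggers))),
    origin = triggers$origin %||% "random",
    source_id = triggers$source_id %||% "unknown",
    start = triggers$start %||% NA_integer_,
    trigger = triggers$trigger,
    model_input = model_input
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
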