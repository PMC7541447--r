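# Construct segmentation and ideal (designed) secondary structures.
#
# Region coordinates are fixed by the architecture (1-based within the
# 145-nt model input):
#   Trigger 1-30, Loop1 (unstructured linker) 31-50, Toehold 51-62,
#   Stem1 (ascending stem) 63-80, Loop2 (SD loop) 81-91,
#   Stem2 (descending stem) 92-109 with the AUG start codon at 98-100,
#   Linker (AA linker) 110-130, Post_linker (GFP head) 131-145.
# ON-state composite regions are prefixed by the GGG transcription leader.
#
# The ideal dot-bracket strings below are reconstructed from the designed
# pairing pattern (the publication's ellipsis glyphs garble runs of dots):
# stem = 9 pairs / 3-nt internal bulge / 6 pairs closing an 11-nt loop, with
# the start codon as the 3-nt bulge on the descending side; the ON duplex
# pairs all 30 trigger nt against toehold + ascending stem. Every
# reconstruction is validated against its region length.

.dots <- function(n) strrep(".", n)

.STEM_IDEAL <- paste0(strrep("(", 9), .dots(3), strrep("(", 6), .dots(11),
                      strrep(")", 6), .dots(3), strrep(")", 9))        # 47 nt
.TAIL_IDEAL <- paste0("..", "(((", .dots(7), "(((((", .dots(5), ")))))",
                      "..", ")))", .dots(4))                           # 36 nt
.ON_DUPLEX  <- paste0(.dots(3), strrep("(", 30), .dots(20),
                      strrep(")", 30), .dots(29))                      # 112 nt

.IDEAL_STRUCTURES <- list(
  SwitchOFF      = paste0(.dots(32), .STEM_IDEAL),
  SwitchOFF_GFP  = paste0(.dots(32), .STEM_IDEAL, .TAIL_IDEAL),
  SwitchOFF_NoTo = paste0(.STEM_IDEAL, .TAIL_IDEAL),
  SwitchON       = .ON_DUPLEX,
  SwitchON_GFP   = paste0(.ON_DUPLEX, .TAIL_IDEAL),
  ToeholdON      = paste0(.dots(18), strrep("(", 12), .dots(20), strrep(")", 12)),
  Stem           = .STEM_IDEAL,
  StemTop        = paste0(strrep("(", 6), .dots(11), strrep(")", 6))
)

# model-input coordinates [start, end] for regions that are plain slices;
# ON regions additionally take the GGG leader prefix
.REGION_COORDS <- list(
  Trigger        = c(1L, 30L),
  Loop1          = c(31L, 50L),
  Toehold        = c(51L, 62L),
  Switch         = c(51L, 109L),
  Stem1          = c(63L, 80L),
  Loop2          = c(81L, 91L),
  AUG            = c(98L, 100L),
  Stem2          = c(92L, 109L),
  Linker         = c(110L, 130L),
  Post_linker    = c(131L, 145L),
  SwitchOFF      = c(31L, 109L),
  SwitchOFF_GFP  = c(31L, 145L),
  SwitchOFF_NoTo = c(63L, 145L),
  SwitchON       = c(1L, 109L),
  SwitchON_GFP   = c(1L, 145L),
  ToeholdON      = c(1L, 62L),
  Stem           = c(63L, 109L),
  StemTop        = c(75L, 97L)
)

.GGG_PREFIXED <- c("SwitchON", "SwitchON_GFP")
.COMPOSITE_REGIONS <- names(.IDEAL_STRUCTURES)
.PRIMARY_MFE_REGIONS <- c("Trigger", "Switch", "Stem1", "Stem2",
                          "Linker", "Post_linker")

#' Segment a switch construct into named regions
#'
#' Slices the 145-nt model input into the architecture's primary segments
#' (GGG leader, Trigger, Loop1, Toehold, Switch, Loop2, Stem1, AUG, Stem2,
#' Linker, Post_linker) and the eight composite folding regions that carry
#' printed ideal structures (SwitchOFF, SwitchOFF_GFP, SwitchOFF_NoTo,
#' SwitchON, SwitchON_GFP, ToeholdON, Stem, StemTop). ON-state composites
#' are prefixed with the GGG transcription leader.
#'
#' @param construct A [assemble_switch()] result.
#' @return A tibble with columns `region`, `kind` (`"primary"` or
#'   `"composite"`), `start`, `end` (1-based model-input coordinates,
#'   `NA` for the GGG leader), `seq`, `ideal` (dot-bracket or `NA`), `length`.
#' @export
segment_construct <- function(construct) {
  stopifnot(inherits(construct, "switch_construct"))
  mi <- construct$model_input
  if (nchar(mi) != 145L) {
    stop("construct model input must be 145 nt, got ", nchar(mi), call. = FALSE)
  }
  ggg <- construct$constants$ggg_leader
  rows <- purrr::map(names(.REGION_COORDS), function(rg) {
    co <- .REGION_COORDS[[rg]]
    s <- substr(mi, co[1], co[2])
    if (rg %in% .GGG_PREFIXED) s <- paste0(ggg, s)
    ideal <- .IDEAL_STRUCTURES[[rg]]
    tibble::tibble(
      region = rg,
      kind = if (rg %in% .COMPOSITE_REGIONS) "composite" else "primary",
      start = co[1], end = co[2], seq = s,
      ideal = ideal %||% NA_character_
    )
  })
  out <- dplyr::bind_rows(
    tibble::tibble(region = "GGG", kind = "primary", start = NA_integer_,
                   end = NA_integer_, seq = ggg, ideal = NA_character_),
    rows
  )
  out$length <- nchar(out$seq)
  bad <- !is.na(out$ideal) & nchar(out$ideal) != out$length
  if (any(bad)) {
    stop("internal error: ideal structure length mismatch for ",
         paste(out$region[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Ideal (designed) dot-bracket structures for the composite regions
#'
#' @return A named list of dot-bracket strings.
#' @export
ideal_structures <- function() .IDEAL_STRUCTURES
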