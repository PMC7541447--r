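# Shared format readers/writers. FASTA goes through Biostrings; tabular
# data through readr with a pinned dialect (UTF-8, comma, header row).

#' Read trigger source sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file; CRLF and LF line
#'   endings are both accepted.
#' @return A tibble: `source_id`, `seq` (DNA alphabet).
#' @export
read_trigger_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("no FASTA records in ", path, call. = FALSE)
  tibble::tibble(
    source_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x))
  )
}

#' Write / read a designed library as CSV
#'
#' Columns: `id, origin, source_id, start, trigger, model_input`.
#'
#' @param library A [design_library()] tibble.
#' @param path Output/input CSV path.
#' @return `read_library_csv()` returns the tibble; the writer returns the
#'   path invisibly.
#' @export
write_library_csv <- function(library, path) {
  readr::write_csv(library, path)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  need <- c("id", "origin", "source_id", "start", "trigger", "model_input")
  df <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write / read a bin-count table as CSV
#'
#' Per-bin totals travel in a `#totals:` comment line so the round trip is
#' lossless.
#'
#' @param table A [bin_count_table()].
#' @param path CSV path.
#' @param label Library label on read (overrides the stored one if given).
#' @export
write_counts_csv <- function(table, path) {
  totals <- attr(table, "totals")
  label <- attr(table, "label")
  writeLines(c(paste0("#label:", label),
               paste0("#totals:", paste(totals, collapse = ","))), path)
  df <- as.data.frame(table)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path, label = NULL) {
  lines <- readr::read_lines(path, n_max = 2)
  stored_label <- sub("^#label:", "", lines[grepl("^#label:", lines)])
  totals_line <- lines[grepl("^#totals:", lines)]
  totals <- if (length(totals_line)) {
    as.numeric(strsplit(sub("^#totals:", "", totals_line), ",")[[1]])
  } else NULL
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!"variant_id" %in% names(df)) {
    stop("missing required column: variant_id", call. = FALSE)
  }
  bin_count_table(df, totals = totals,
                  label = label %||% stored_label %||% "ON")
}

#' Write / read a measurement or feature table as CSV
#'
#' Thin readr wrappers with the pinned dialect, provided so scripted
#' pipelines have one entry point per artifact.
#'
#' @param x A tibble (measurements from [quantify_library()] or features
#'   from [featurize_library()]).
#' @param path CSV path.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
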