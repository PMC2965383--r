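# Plain-text interchange: pileup TSV, call TSV, BED windows/regions.

#' Read and write pileup tables
#'
#' Pileups are stored as TSV with columns `position`, `ref`, `bases`,
#' `quals`; bases and qualities are comma-joined per site (empty string
#' for zero-depth sites).
#'
#' @param pileups Pileup tibble (see [simulate_pileups()]).
#' @param path File path.
#' @return `write_pileups()` returns `pileups` invisibly;
#'   `read_pileups()` returns a pileup tibble.
#' @export
write_pileups <- function(pileups, path) {
  flat <- tibble(
    position = pileups$position,
    ref = pileups$ref,
    bases = vapply(pileups$bases, paste, character(1L), collapse = ","),
    quals = vapply(pileups$quals, paste, character(1L), collapse = ",")
  )
  readr::write_tsv(flat, path)
  invisible(pileups)
}

#' @rdname write_pileups
#' @export
read_pileups <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(),
    ref = readr::col_character(),
    bases = readr::col_character(),
    quals = readr::col_character()
  ), na = character())
  split_chr <- function(x) {
    ifelse_empty <- function(s) if (nzchar(s)) strsplit(s, ",")[[1L]] else
      character(0)
    lapply(x, ifelse_empty)
  }
  bases <- split_chr(flat$bases)
  quals <- lapply(split_chr(flat$quals), as.integer)
  tibble(
    position = flat$position,
    ref = flat$ref,
    depth = vapply(bases, length, integer(1L)),
    bases = bases,
    quals = quals
  )
}

#' Write genotype calls as a minimal VCF-like TSV
#'
#' Columns: `position`, `ref`, `alt`, `genotype`, `posterior`,
#' `quality`, `filter`, `mode`.
#'
#' @param calls Call tibble.
#' @param path File path.
#' @return `calls`, invisibly.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(
    calls[, c("position", "ref", "alt", "genotype", "posterior",
              "quality", "filter", "mode")],
    path
  )
  invisible(calls)
}

#' Write intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based
#' half-open, so `start` is decremented on write and restored on read.
#'
#' @param intervals Tibble with `chromosome`, `start`, `end` (1-based
#'   inclusive) and optionally a `score` column (e.g. D).
#' @param path File path.
#' @param score Optional name of a column to write as the BED score
#'   field.
#' @return `intervals`, invisibly.
#' @export
write_bed <- function(intervals, path, score = NULL) {
  bed <- data.frame(
    chrom = intervals$chromosome,
    chromStart = intervals$start - 1L,
    chromEnd = intervals$end
  )
  if (!is.null(score)) {
    bed$name <- sprintf("%s_%d", intervals$chromosome, intervals$start)
    bed$score <- intervals[[score]]
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(intervals)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- tibble(
    chromosome = as.character(bed[[1L]]),
    start = as.integer(bed[[2L]]) + 1L,
    end = as.integer(bed[[3L]])
  )
  if (ncol(bed) >= 5L) out$score <- bed[[5L]]
  out
}
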