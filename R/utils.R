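#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join count n row_number across all_of if_else rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap
#' @importFrom stats median rbinom runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA
#'
#' Uniform i.i.d. bases; used by the simulator to build synthetic reference
#' sequences with prescribed lengths.
#'
#' @param n Sequence length in bp.
#' @return A single uppercase character string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

str_sub1 <- function(x, start, end) {
  # 1-based inclusive substring, clamped to the sequence
  n <- nchar(x)
  start <- max(1L, as.integer(start))
  end <- min(n, as.integer(end))
  if (end < start) return("")
  substr(x, start, end)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return Tibble with columns `name`, `seq`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), seq = as.character(x))
}

#' Write sequences to FASTA
#'
#' @param tbl Tibble with columns `name`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(tbl, path) {
  x <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Qualities are retained as strings but never interpreted downstream.
#'
#' @param path Path to a (optionally gzipped) FASTQ file.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads to FASTQ
#'
#' @param tbl Tibble with columns `read_id`, `seq` and optionally `qual`
#'   (constant Q12 emitted when absent).
#' @param path Output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq_tbl <- function(tbl, path) {
  qual <- if ("qual" %in% names(tbl)) tbl$qual else strrep("-", nchar(tbl$seq))
  x <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$read_id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Write a tibble as TSV
#'
#' List-columns are flattened to comma-separated strings so every exported
#' table is plain text.
#'
#' @param tbl A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_flat <- function(tbl, path) {
  flat <- tbl
  for (nm in names(flat)[vapply(flat, is.list, logical(1))]) {
    flat[[nm]] <- map_chr(flat[[nm]], function(v) paste(unlist(v), collapse = ","))
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
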