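empty_gaps <- function() tibble(start = integer(), end = integer())

merge_gap_ranges <- function(g) {
  # collapse overlapping/adjacent gap intervals so depth is subtracted once
  if (nrow(g) <= 1) return(g)
  g <- g[order(g$start), ]
  out_s <- g$start[1]
  out_e <- g$end[1]
  for (j in seq_len(nrow(g))[-1]) {
    k <- length(out_s)
    if (g$start[j] <= out_e[k] + 1L) {
      out_e[k] <- max(out_e[k], g$end[j])
    } else {
      out_s <- c(out_s, g$start[j])
      out_e <- c(out_e, g$end[j])
    }
  }
  tibble(start = out_s, end = out_e)
}

#' Align reads to the wild-type amplicon and extract deletion gaps
#'
#' Global alignment of each read against the wild-type amplicon reference,
#' so deleted reference bases must open a gap rather than being clipped
#' away (read overhangs such as the barcode+primer prefix simply become
#' read-side insertions and are ignored by the gap extraction). Gaps in
#' the read relative to the reference are reported as deletions in
#' reference coordinates. Affine gap scoring keeps scattered 1-bp
#' sequencing indels from chaining into spurious large gaps.
#'
#' @param reads Tibble with columns `read_id`, `seq`.
#' @param reference Wild-type amplicon sequence.
#' @param gap_opening,gap_extension Affine gap penalties. The default
#'   opening penalty of 24 keeps a long deletion from being split at short
#'   coincidental matches inside the gap (a split must gain at least 12
#'   matched bases to pay for itself).
#' @param trim_prefix Number of leading bases (barcode + primer) to strip
#'   from each read before alignment; leaving a long random prefix on a
#'   read whose left flank is heavily deleted lets the aligner weave the
#'   prefix into the gap.
#' @return Alignment tibble: `read_id`, `ref_start`, `ref_end`, `gaps`
#'   (list of tibbles with `start`, `end` in reference coordinates).
#' @export
align_to_amplicon <- function(reads, reference, gap_opening = 24, gap_extension = 0.5,
                              trim_prefix = 0) {
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(), ref_start = integer(), ref_end = integer(), gaps = list()))
  }
  seqs <- if (trim_prefix > 0) substring(reads$seq, trim_prefix + 1) else reads$seq
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = nuc_mat(),
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  ref_start <- S4Vectors::start(Biostrings::subject(aln))
  ref_end <- S4Vectors::end(Biostrings::subject(aln))
  gaps <- map(seq_along(pat), function(i) {
    p <- strsplit(pat[i], "")[[1]]
    s <- strsplit(sub[i], "")[[1]]
    is_del <- p == "-" & s != "-"
    if (!any(is_del)) return(empty_gaps())
    ref_pos <- cumsum(s != "-") + ref_start[i] - 1L
    r <- rle(is_del)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    del <- which(r$values)
    tibble(
      start = as.integer(ref_pos[starts[del]]),
      end = as.integer(ref_pos[ends[del]])
    )
  })
  tibble(
    read_id = reads$read_id,
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    gaps = gaps
  )
}

#' Read gapped alignments from a SAM file
#'
#' Minimal text-mode SAM ingestion for the per-amplicon setting: mapped
#' primary records are converted to reference intervals with deletion gaps
#' taken from `D`/`N` CIGAR operations.
#'
#' @param path Path to a SAM file.
#' @param reference Optional reference name; records mapped elsewhere are
#'   an error when supplied.
#' @return Alignment tibble as in [align_to_amplicon()].
#' @export
read_alignments_sam <- function(path, reference = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  rows <- map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0 || f[6] == "*") return(NULL) # unmapped
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 2048L) > 0) return(NULL) # secondary/supplementary
    if (!is.null(reference) && f[3] != reference) {
      abort(paste0("alignment to unknown reference: ", f[3]))
    }
    pos <- as.integer(f[4])
    ops <- regmatches(f[6], gregexpr("\\d+[MIDNSHP=X]", f[6]))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    ref_consuming <- op %in% c("M", "D", "N", "=", "X")
    ref_off <- cumsum(ifelse(ref_consuming, n, 0L))
    ref_starts <- pos + c(0L, head(ref_off, -1))
    del <- which(op %in% c("D", "N"))
    gaps <- if (length(del)) {
      tibble(start = ref_starts[del], end = ref_starts[del] + n[del] - 1L)
    } else {
      empty_gaps()
    }
    tibble(
      read_id = f[1], ref_start = pos,
      ref_end = pos + sum(n[ref_consuming]) - 1L, gaps = list(gaps)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(read_id = character(), ref_start = integer(), ref_end = integer(), gaps = list()))
  }
  out
}

#' Per-position coverage over the amplicon
#'
#' Depth at each reference position is the number of reads whose alignment
#' covers it, with deletion gaps excluded.
#'
#' @param alignments Alignment tibble (`read_id`, `ref_start`, `ref_end`,
#'   `gaps`), from [align_to_amplicon()], [read_alignments_sam()] or the
#'   simulator truth.
#' @param ref_length Reference (amplicon) length in bp.
#' @return A `coverage_profile` list: `depth` (integer vector of length
#'   `ref_length`), `n_reads`.
#' @export
coverage_from_alignments <- function(alignments, ref_length) {
  diffs <- numeric(ref_length + 1L)
  for (i in seq_len(nrow(alignments))) {
    s <- max(1L, alignments$ref_start[i])
    e <- min(ref_length, alignments$ref_end[i])
    if (e < s) next
    diffs[s] <- diffs[s] + 1
    diffs[e + 1L] <- diffs[e + 1L] - 1
    g <- merge_gap_ranges(alignments$gaps[[i]])
    for (j in seq_len(nrow(g))) {
      gs <- max(s, g$start[j])
      ge <- min(e, g$end[j])
      if (ge < gs) next
      diffs[gs] <- diffs[gs] - 1
      diffs[ge + 1L] <- diffs[ge + 1L] + 1
    }
  }
  structure(
    list(depth = as.integer(cumsum(diffs[seq_len(ref_length)])), n_reads = nrow(alignments)),
    class = "coverage_profile"
  )
}

#' Deletion index of a coverage profile
#'
#' `(R - mean(depth)) / R` with `R` the number of anchored reads: the mean
#' per-base fraction of the amplicon missing from the aligned reads. Zero
#' for gap-free full coverage; if every read deletes the same fraction `f`
#' of the interval the index is exactly `f`.
#'
#' @param profile A [coverage_from_alignments()] result.
#' @return Proportion in `[0, 1]`; `NA` (flagged by warning) for zero reads.
#' @export
deletion_index <- function(profile) {
  if (profile$n_reads == 0) {
    warn("deletion index undefined: no anchored reads")
    return(NA_real_)
  }
  (profile$n_reads - mean(profile$depth)) / profile$n_reads
}

#' D100: fraction of reads with a large deletion at the cut site
#'
#' A read counts when its largest deletion gap overlapping the window
#' around the cut position exceeds `threshold` (default 100 bp).
#'
#' @param alignments Alignment tibble with `gaps`.
#' @param cut_position 1-based cut offset on the reference.
#' @param threshold Deletion size threshold in bp (default 100).
#' @param window Half-width of the cut-site window in bp (default 50).
#' @return Proportion of reads counted.
#' @export
d100 <- function(alignments, cut_position, threshold = 100, window = 50) {
  if (nrow(alignments) == 0) return(NA_real_)
  lo <- cut_position - window
  hi <- cut_position + window + 1L # the cut sits between cut_position and cut_position+1
  counted <- map_lgl(alignments$gaps, function(g) {
    if (nrow(g) == 0) return(FALSE)
    at_cut <- g$start <= hi & g$end >= lo
    any(at_cut & (g$end - g$start + 1L) > threshold)
  })
  mean(counted)
}

#' Deletion report for one amplicon
#'
#' @param alignments Alignment tibble.
#' @param ref_length Amplicon length.
#' @param cut_position 1-based cut offset.
#' @inheritParams d100
#' @return A `deletion_report` list: `deletion_index`, `d100`, `n_reads`,
#'   `max_gap` (per-read largest-gap tibble).
#' @export
deletion_report <- function(alignments, ref_length, cut_position,
                            threshold = 100, window = 50) {
  profile <- coverage_from_alignments(alignments, ref_length)
  max_gap <- tibble(
    read_id = alignments$read_id,
    max_gap = map_int(alignments$gaps, function(g) {
      if (nrow(g) == 0) 0L else as.integer(max(g$end - g$start + 1L))
    })
  )
  structure(
    list(
      deletion_index = deletion_index(profile),
      d100 = d100(alignments, cut_position, threshold, window),
      n_reads = profile$n_reads,
      threshold = threshold,
      max_gap = max_gap
    ),
    class = "deletion_report"
  )
}

#' @export
print.deletion_report <- function(x, ...) {
  cat(sprintf(
    "<deletion_report> %d reads; deletion index %.4f; D%d %.4f\n",
    x$n_reads, x$deletion_index, x$threshold, x$d100
  ))
  invisible(x)
}

#' Read-length histogram
#'
#' @param reads Tibble with a `seq` column, or a numeric vector of lengths.
#' @param binwidth Bin width in bp (default 1: one bin per distinct length).
#' @return Tibble `bin` (bin start), `n`; total `n` equals the read count.
#' @export
length_distribution <- function(reads, binwidth = 1) {
  lens <- if (is.numeric(reads)) reads else nchar(reads$seq)
  if (length(lens) == 0) return(tibble(bin = numeric(), n = integer()))
  bin <- floor((lens - 1) / binwidth) * binwidth + 1
  if (binwidth == 1) bin <- lens
  as_tibble(table(bin = bin)) |>
    mutate(bin = as.numeric(.data$bin)) |>
    arrange(.data$bin)
}
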