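nuc_mat <- function() {
  # BLAST-like scoring for short nucleotide local alignments
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = TRUE)
}

alignment_identity <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Scan a subject for repeated local matches of a query
#'
#' Finds every non-overlapping local alignment of `query` in `subject`
#' with identity (matches over alignment columns) at least `min_identity`
#' and alignment span at least `min_len`, by iteratively taking the best
#' local alignment and re-scanning the flanking subject segments. Both
#' strands are searched when `both_strands`.
#'
#' @param query Query sequence (e.g. a homology arm or an extracted insert).
#' @param subject Subject sequence searched for copies of `query`.
#' @param min_identity Percent identity threshold (default 80).
#' @param min_len Minimum alignment span on the subject, bp (default 30).
#' @param both_strands Also search the reverse complement of `query`.
#' @param max_matches Safety cap on reported matches.
#' @return Tibble: `s_start`, `s_end` (subject interval, 1-based
#'   inclusive), `q_start`, `q_end` (query interval), `identity`, `strand`.
#' @export
scan_local_matches <- function(query, subject, min_identity = 80, min_len = 30,
                               both_strands = FALSE, max_matches = 20) {
  mat <- nuc_mat()
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    q <- if (strand == "-") revcomp(query) else query
    segments <- list(c(1L, nchar(subject)))
    while (length(segments) > 0 && length(out) < max_matches) {
      seg <- segments[[1]]
      segments <- segments[-1]
      if (seg[2] - seg[1] + 1 < min_len) next
      sub_seq <- substr(subject, seg[1], seg[2])
      aln <- Biostrings::pairwiseAlignment(
        q, sub_seq, type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2
      )
      if (Biostrings::score(aln) <= 0) next
      s_start <- seg[1] + S4Vectors::start(Biostrings::subject(aln)) - 1L
      s_end <- seg[1] + S4Vectors::end(Biostrings::subject(aln)) - 1L
      idy <- alignment_identity(aln)
      span <- s_end - s_start + 1L
      if (idy >= min_identity && span >= min_len) {
        qs <- S4Vectors::start(Biostrings::pattern(aln))
        qe <- S4Vectors::end(Biostrings::pattern(aln))
        if (strand == "-") {
          tmp <- qs
          qs <- nchar(query) - qe + 1L
          qe <- nchar(query) - tmp + 1L
        }
        out[[length(out) + 1]] <- tibble(
          s_start = unname(as.integer(s_start)), s_end = unname(as.integer(s_end)),
          q_start = unname(as.integer(qs)), q_end = unname(as.integer(qe)),
          identity = unname(idy), strand = strand
        )
        segments <- c(segments, list(c(seg[1], s_start - 1L)), list(c(s_end + 1L, seg[2])))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(
      s_start = integer(), s_end = integer(), q_start = integer(),
      q_end = integer(), identity = double(), strand = character()
    ))
  }
  arrange(bind_rows(out), .data$s_start)
}

merge_copy_matches <- function(matches, max_overlap = 10) {
  # matches overlapping by more than max_overlap bp collapse into one copy;
  # adjacent or lightly overlapping matches stay distinct (tandem copies)
  if (nrow(matches) == 0) return(matches)
  matches <- arrange(matches, .data$s_start)
  keep <- matches[1, ]
  for (i in seq_len(nrow(matches))[-1]) {
    last <- nrow(keep)
    overlap <- keep$s_end[last] - matches$s_start[i] + 1
    if (overlap > max_overlap) {
      keep$s_end[last] <- max(keep$s_end[last], matches$s_end[i])
      keep$identity[last] <- max(keep$identity[last], matches$identity[i])
    } else {
      keep <- bind_rows(keep, matches[i, ])
    }
  }
  keep
}

#' Find homology-arm copies near the expected junction
#'
#' Local alignments of an arm against the read with identity >= 80 by
#' default, restricted to a window around the expected junction so that
#' only arm copies at the target site are counted. Overlapping alignments
#' are merged; distinct (including directly adjacent, tandem) alignments
#' count as distinct copies.
#'
#' @param read Oriented read sequence.
#' @param arm Homology-arm sequence (empty arm gives an empty result).
#' @param expected_at Read coordinate of the expected junction.
#' @param min_identity Percent identity threshold (default 80).
#' @param window_pad Junction window half-width beyond the arm length
#'   (default 200 bp each side).
#' @param min_frac Minimum alignment span as a fraction of the arm length
#'   (default 0.5), rejecting incidental micro-matches.
#' @return Tibble of merged arm matches in read coordinates.
#' @export
find_arm_matches <- function(read, arm, expected_at, min_identity = 80,
                             window_pad = 200, min_frac = 0.5) {
  if (!nzchar(arm)) {
    return(tibble(
      s_start = integer(), s_end = integer(), q_start = integer(),
      q_end = integer(), identity = double(), strand = character()
    ))
  }
  arm_len <- nchar(arm)
  lo <- max(1L, as.integer(expected_at - arm_len - window_pad))
  hi <- min(nchar(read), as.integer(expected_at + arm_len + window_pad))
  win <- substr(read, lo, hi)
  m <- scan_local_matches(arm, win,
    min_identity = min_identity,
    min_len = max(20, ceiling(min_frac * arm_len))
  )
  if (nrow(m) > 0) {
    m$s_start <- m$s_start + lo - 1L
    m$s_end <- m$s_end + lo - 1L
  }
  merge_copy_matches(m)
}

#' Classify one donor insertion as NHEJ or HDR
#'
#' End-joining capture of the intact donor duplicates the homology arm
#' (one genomic copy, one donor copy in tandem), while homology-directed
#' repair collapses the two into a single copy. Per evaluable arm: two or
#' more copies are NHEJ evidence, exactly one is HDR evidence, zero is
#' neither. Any arm with two copies makes the read NHEJ; all evaluable
#' arms single-copy make it HDR; anything else (including no evaluable
#' arms) is Other.
#'
#' @param read Oriented read sequence.
#' @param locus A [locus_model()] carrying the arm sequences.
#' @param albLr,albRl Inner flank edges on the read (junction anchors).
#' @inheritParams find_arm_matches
#' @return Tibble row: `verdict` (`"NHEJ"`, `"HDR"`, `"Other"`),
#'   `left_copies`, `right_copies` (NA when not evaluable), `reason`.
#' @export
classify_repair <- function(read, locus, albLr, albRl, min_identity = 80,
                            window_pad = 200, min_frac = 0.5) {
  arms <- list(left = locus$left_arm, right = locus$right_arm)
  junctions <- list(left = albLr, right = albRl)
  copies <- map(c("left", "right"), function(side) {
    arm <- arms[[side]]
    if (!nzchar(arm)) return(NA_integer_)
    nrow(find_arm_matches(read, arm, junctions[[side]],
      min_identity = min_identity, window_pad = window_pad, min_frac = min_frac
    ))
  })
  copies <- setNames(as.integer(copies), c("left", "right"))
  evaluable <- !is.na(copies)
  verdict <- if (!any(evaluable)) {
    "Other"
  } else if (any(copies[evaluable] >= 2)) {
    "NHEJ"
  } else if (all(copies[evaluable] == 1)) {
    "HDR"
  } else {
    "Other"
  }
  tibble(
    verdict = verdict,
    left_copies = copies[["left"]], right_copies = copies[["right"]],
    reason = if (!any(evaluable)) "not evaluable" else NA_character_
  )
}

#' Classify repair pathway for forward single-donor calls
#'
#' Applies [classify_repair()] to every read called as a forward
#' single-cassette insertion and summarises NHEJ/HDR/Other counts. Repair
#' classification is only meaningful for correctly oriented single-donor
#' insertions, so other calls are passed through untouched.
#'
#' @param calls A `read_calls` tibble from [call_patterns()].
#' @param locus A [locus_model()].
#' @param cassette Donor cassette component name (default `"F"`).
#' @inheritParams find_arm_matches
#' @return A `repair_calls` tibble: `read_id`, `verdict`, `left_copies`,
#'   `right_copies`, `reason`, with the per-sample summary in the
#'   `"summary"` attribute.
#' @export
classify_repairs <- function(calls, locus, cassette = "F", min_identity = 80,
                             window_pad = 200, min_frac = 0.5) {
  target <- paste0(cassette, "f")
  sel <- which(calls$category == cassette & !is.na(calls$pattern) & calls$pattern == target)
  rows <- map(sel, function(i) {
    res <- classify_repair(
      calls$oriented_seq[i], locus,
      albLr = calls$albLr[i], albRl = calls$albRl[i],
      min_identity = min_identity, window_pad = window_pad, min_frac = min_frac
    )
    mutate(res, read_id = calls$read_id[i], .before = 1)
  })
  out <- if (length(rows)) bind_rows(rows) else tibble(
    read_id = character(), verdict = character(),
    left_copies = integer(), right_copies = integer(), reason = character()
  )
  n_eval <- sum(out$verdict %in% c("NHEJ", "HDR"))
  smry <- tibble(
    n_forward_donor = nrow(out),
    n_nhej = sum(out$verdict == "NHEJ"),
    n_hdr = sum(out$verdict == "HDR"),
    n_other = sum(out$verdict == "Other"),
    hdr_fraction = if (n_eval > 0) sum(out$verdict == "HDR") / n_eval else NA_real_
  )
  attr(out, "summary") <- smry
  class(out) <- c("repair_calls", class(out))
  out
}
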