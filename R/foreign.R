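#' Extract the insert between the flank anchors
#'
#' Refines the inner flank edges (the rightmost matched position of the
#' left flank, Alb-L-r, and the leftmost matched position of the right
#' flank, Alb-R-l) by local alignment of each flank against the oriented
#' read, then returns the read subsequence strictly between them. A
#' background read yields an empty insert; anchors in the wrong order
#' (deletion through the cut, or scrambled read) yield an empty, flagged
#' result.
#'
#' @param read Oriented read sequence with both flanks present.
#' @param locus A [locus_model()].
#' @param min_identity Flank alignment identity threshold (default 80).
#' @return List: `insert`, `albLr`, `albRl`, `flagged`.
#' @export
extract_insert <- function(read, locus, min_identity = 80) {
  left <- scan_local_matches(locus$left_flank, read,
    min_identity = min_identity,
    min_len = min(50, nchar(locus$left_flank)), max_matches = 4
  )
  right <- scan_local_matches(locus$right_flank, read,
    min_identity = min_identity,
    min_len = min(50, nchar(locus$right_flank)), max_matches = 4
  )
  if (nrow(left) == 0 || nrow(right) == 0) {
    return(list(insert = "", albLr = NA_integer_, albRl = NA_integer_, flagged = TRUE))
  }
  albLr <- max(left$s_end)
  albRl <- min(right$s_start)
  if (albLr >= albRl) {
    return(list(insert = "", albLr = albLr, albRl = albRl, flagged = albLr > albRl))
  }
  list(
    insert = str_sub1(read, albLr + 1L, albRl - 1L),
    albLr = albLr, albRl = albRl, flagged = FALSE
  )
}

empty_segments <- function() {
  tibble(
    class = character(), contig = character(), s_start = integer(),
    s_end = integer(), q_start = integer(), q_end = integer(),
    identity = double(), strand = character(), n_hits = integer()
  )
}

probe_hit_segment <- function(insert, probes, k, class, min_hits = 1) {
  # approximate insert interval covered by exact probe hits (both strands)
  if (!nzchar(insert) || nrow(probes) == 0) return(NULL)
  subject <- Biostrings::DNAString(insert)
  starts_f <- unlist(map(probes$probe, function(p) {
    S4Vectors::start(Biostrings::matchPattern(p, subject))
  }))
  starts_r <- unlist(map(revcomp(probes$probe), function(p) {
    S4Vectors::start(Biostrings::matchPattern(p, subject))
  }))
  starts <- c(starts_f, starts_r)
  if (length(starts) < min_hits) return(NULL)
  tibble(
    class = class,
    contig = NA_character_,
    s_start = NA_integer_, s_end = NA_integer_,
    q_start = as.integer(min(starts)),
    q_end = as.integer(max(starts) + k - 1L),
    identity = NA_real_,
    strand = if (length(starts_f) >= length(starts_r)) "+" else "-",
    n_hits = length(starts)
  )
}

#' Scan an insert for circular editing-plasmid remnants
#'
#' Exact k-mer probes from the unique regions of the Cas9 expression
#' plasmid (17-mers, step 100) and the sgRNA/U6 plasmid (17-mers, step 40)
#' are matched on both strands of the insert; a class is called with at
#' least `min_hits` probe hits. Intended for reads already excluded from
#' the full-length donor categories.
#'
#' @param insert Insert sequence from [extract_insert()].
#' @param cas9_probes,u6_probes Probe tibbles from [generate_probes()].
#' @param min_hits Minimum exact hits per class (default 1; the probes are
#'   screened unique, so a single exact 17-mer is already strong evidence).
#' @param k Probe length (default 17).
#' @return Tibble of insert segments (possibly empty).
#' @export
scan_plasmid_fragments <- function(insert, cas9_probes, u6_probes, min_hits = 1, k = 17) {
  bind_rows(
    empty_segments(),
    probe_hit_segment(insert, cas9_probes, k, "Cas9-plasmid", min_hits),
    probe_hit_segment(insert, u6_probes, k, "sgRNA-plasmid", min_hits)
  )
}

#' Detect degraded (short) donor fragment insertions
#'
#' A degraded insertion carries less than 80% of the full fragment length.
#' Following the published gates: a short-backbone call requires read
#' length < 2000 bp, backbone probe hits in the insert, and an insert
#' shorter than 1700 bp; a short-cassette call requires read length
#' < 5000 bp, cassette probe hits, and an insert shorter than 4400 bp.
#'
#' @param read_length Full read length in bp.
#' @param insert Insert sequence between the flank anchors.
#' @param panel A [build_probe_panel()] result (its screened component
#'   probes are reused).
#' @param cassette,backbone Component names (defaults `"F"`, `"B"`).
#' @param backbone_read_max,backbone_insert_max,cassette_read_max,cassette_insert_max
#'   The length gates in bp (defaults 2000, 1700, 5000, 4400).
#' @param min_hits Minimum probe hits (default 1).
#' @return Tibble of `short-F` / `short-B` segments (possibly empty).
#' @export
detect_degraded_donor <- function(read_length, insert, panel,
                                  cassette = "F", backbone = "B",
                                  backbone_read_max = 2000, backbone_insert_max = 1700,
                                  cassette_read_max = 5000, cassette_insert_max = 4400,
                                  min_hits = 1) {
  pr <- panel$probes
  fwd <- pr[pr$orientation == "forward", ]
  ins_len <- nchar(insert)
  out <- list(empty_segments())
  if (read_length < backbone_read_max && ins_len < backbone_insert_max) {
    seg <- probe_hit_segment(insert, fwd[fwd$group == backbone, ], panel$k, "short-B", min_hits)
    if (!is.null(seg)) out <- c(out, list(seg))
  }
  if (read_length < cassette_read_max && ins_len < cassette_insert_max) {
    seg <- probe_hit_segment(insert, fwd[fwd$group == cassette, ], panel$k, "short-F", min_hits)
    if (!is.null(seg)) out <- c(out, list(seg))
  }
  bind_rows(out)
}

overlaps_exclusion <- function(contig, s_start, s_end, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(FALSE)
  # exclusions are BED-style 0-based half-open; matches are 1-based inclusive
  any(exclusions$contig == contig &
    exclusions$start < s_end &
    exclusions$end >= s_start)
}

resolve_overlaps <- function(segments) {
  # competing segments overlapping on the insert: highest identity wins,
  # ties broken by longer alignment
  if (nrow(segments) <= 1) return(segments)
  segments <- segments |>
    mutate(span = .data$q_end - .data$q_start + 1) |>
    arrange(dplyr::desc(.data$identity), dplyr::desc(.data$span))
  keep <- segments[1, ]
  for (i in seq_len(nrow(segments))[-1]) {
    cand <- segments[i, ]
    clash <- any(keep$q_start <= cand$q_end & keep$q_end >= cand$q_start)
    if (!clash) keep <- bind_rows(keep, cand)
  }
  arrange(keep, .data$q_start) |> select(-"span")
}

#' Align an insert to a (mini-)genome
#'
#' Local alignment of the insert against every contig on both strands.
#' Matches shorter than `min_len` (default 50 bp) or overlapping an
#' exclusion region are discarded; where alignments from several contigs
#' explain the same stretch of the insert, the highest-identity contig
#' wins. Segments are reported in insert order.
#'
#' @param insert Insert sequence.
#' @param genome Tibble with columns `name`, `seq` (e.g. from
#'   [read_fasta_tbl()]), or `NULL` to skip with a notice.
#' @param exclusions Tibble `contig`, `start`, `end` (BED, 0-based
#'   half-open) or `NULL`.
#' @param min_len Minimum match length in bp (default 50).
#' @param min_identity Percent identity threshold (default 80).
#' @return Tibble of `genomic` insert segments with source coordinates.
#' @export
align_insert_to_genome <- function(insert, genome, exclusions = NULL,
                                   min_len = 50, min_identity = 80) {
  empty <- tibble(
    class = character(), contig = character(), s_start = integer(),
    s_end = integer(), q_start = integer(), q_end = integer(),
    identity = double(), strand = character(), n_hits = integer()
  )
  if (is.null(genome)) {
    inform("no genome reference supplied; genomic insert scan skipped")
    return(empty)
  }
  if (!nzchar(insert) || nchar(insert) < min_len) return(empty)
  # seed-and-extend: only align to contigs sharing an exact seed k-mer with
  # the insert (either strand); random contigs share none, so most of the
  # genome is skipped without any alignment work
  seed_k <- 13L
  seed_starts <- unique(c(
    seq.int(1L, max(1L, nchar(insert) - seed_k + 1L), by = max(1L, min(20L, nchar(insert) %/% 4L))),
    max(1L, nchar(insert) - seed_k + 1L)
  ))
  seeds <- unique(substring(insert, seed_starts, seed_starts + seed_k - 1L))
  seeds <- c(seeds, revcomp(seeds))
  seeds <- seeds[nchar(seeds) == seed_k]
  has_seed <- function(contig_seq) {
    any(vapply(seeds, grepl, logical(1), x = contig_seq, fixed = TRUE))
  }
  segs <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    if (!has_seed(genome$seq[i])) return(NULL)
    m <- scan_local_matches(insert, genome$seq[i],
      min_identity = min_identity, min_len = min_len, both_strands = FALSE
    )
    mrc <- scan_local_matches(revcomp(insert), genome$seq[i],
      min_identity = min_identity, min_len = min_len, both_strands = FALSE
    )
    if (nrow(mrc) > 0) {
      n <- nchar(insert)
      tmp <- mrc$q_start
      mrc$q_start <- n - mrc$q_end + 1L
      mrc$q_end <- n - tmp + 1L
      mrc$strand <- "-"
    }
    m <- bind_rows(m, mrc)
    if (nrow(m) == 0) return(NULL)
    mutate(m, contig = genome$name[i])
  })
  if (nrow(segs) == 0) return(empty)
  segs <- segs[segs$q_end - segs$q_start + 1 >= min_len, ]
  if (nrow(segs) > 0) {
    excl <- map_lgl(seq_len(nrow(segs)), ~ overlaps_exclusion(
      segs$contig[.x], segs$s_start[.x], segs$s_end[.x], exclusions
    ))
    segs <- segs[!excl, ]
  }
  if (nrow(segs) == 0) return(empty)
  segs |>
    mutate(class = "genomic", n_hits = NA_integer_) |>
    select("class", "contig", "s_start", "s_end", "q_start", "q_end",
      "identity", "strand", "n_hits") |>
    resolve_overlaps()
}

#' Detect LINE-1 fragments in an insert
#'
#' Same contract as [align_insert_to_genome()] against a single LINE-1
#' consensus; captured LINE-1 fragments are typically 3'-truncated.
#'
#' @param insert Insert sequence.
#' @param line1 Consensus sequence (character) or `NULL` to skip.
#' @inheritParams align_insert_to_genome
#' @return Tibble of `LINE-1` insert segments.
#' @export
detect_line1 <- function(insert, line1, min_len = 50, min_identity = 80) {
  if (is.null(line1)) {
    return(tibble(
      class = character(), contig = character(), s_start = integer(),
      s_end = integer(), q_start = integer(), q_end = integer(),
      identity = double(), strand = character(), n_hits = integer()
    ))
  }
  out <- align_insert_to_genome(insert, tibble(name = "LINE1_consensus", seq = line1),
    exclusions = NULL, min_len = min_len, min_identity = min_identity
  )
  if (nrow(out) > 0) out$class <- "LINE-1"
  out
}

#' Scan non-canonical reads for foreign insert content
#'
#' Runs the full foreign-content cascade on every read that carries both
#' flank anchors but was not called as a full-length donor category:
#' degraded donor fragments, editing-plasmid remnants, endogenous genomic
#' fragments and LINE-1, in insert order, with a compound flag when two or
#' more distinct classes co-occur in one read.
#'
#' @param calls A `read_calls` tibble from [call_patterns()].
#' @param panel A [build_probe_panel()] result.
#' @param cas9_probes,u6_probes Plasmid probe tibbles (or `NULL` to skip).
#' @param genome Mini-genome tibble (`name`, `seq`) or `NULL`.
#' @param line1 LINE-1 consensus sequence or `NULL`.
#' @param exclusions Exclusion regions (BED-style tibble) or `NULL`.
#' @param min_genomic_len Minimum genomic/LINE-1 segment length (default 50).
#' @param min_identity Alignment identity threshold (default 80).
#' @param include Categories of calls to scan (default the unclassified and
#'   background routes; full-length donor categories are excluded).
#' @return A `foreign_calls` tibble: `read_id`, `category`, `insert_len`,
#'   `segments` (list of segment tibbles), `classes`, `compound`,
#'   `flagged`.
#' @export
scan_foreign <- function(calls, panel, cas9_probes = NULL, u6_probes = NULL,
                         genome = NULL, line1 = NULL, exclusions = NULL,
                         min_genomic_len = 50, min_identity = 80,
                         include = c("unclassified", "background")) {
  locus <- panel$locus
  exclusions <- exclusions %||% locus$exclusion_regions
  sel <- which(calls$category %in% include & calls$has_left_flank & calls$has_right_flank)
  rows <- map(sel, function(i) {
    ext <- extract_insert(calls$oriented_seq[i], locus, min_identity = min_identity)
    segs <- list()
    if (nzchar(ext$insert)) {
      segs <- c(segs, list(detect_degraded_donor(calls$length[i], ext$insert, panel)))
      if (!is.null(cas9_probes) || !is.null(u6_probes)) {
        segs <- c(segs, list(scan_plasmid_fragments(
          ext$insert,
          cas9_probes %||% tibble(probe = character()),
          u6_probes %||% tibble(probe = character())
        )))
      }
      if (!is.null(genome)) {
        segs <- c(segs, list(align_insert_to_genome(
          ext$insert, genome, exclusions,
          min_len = min_genomic_len, min_identity = min_identity
        )))
      }
      if (!is.null(line1)) {
        segs <- c(segs, list(detect_line1(
          ext$insert, line1,
          min_len = min_genomic_len, min_identity = min_identity
        )))
      }
    }
    segs <- bind_rows(segs)
    if (nrow(segs) > 0) segs <- arrange(segs, .data$q_start)
    seg_classes <- if (nrow(segs) > 0) unique(segs$class) else character()
    is_compound <- nrow(segs) >= 2 && length(seg_classes) >= 2
    tibble(
      read_id = calls$read_id[i],
      category = calls$category[i],
      insert_len = nchar(ext$insert),
      segments = list(segs),
      classes = list(seg_classes),
      compound = is_compound,
      flagged = ext$flagged
    )
  })
  out <- if (length(rows)) bind_rows(rows) else tibble(
    read_id = character(), category = character(), insert_len = integer(),
    segments = list(), classes = list(), compound = logical(), flagged = logical()
  )
  class(out) <- c("foreign_calls", class(out))
  out
}

#' Summarise foreign-insert calls by class
#'
#' @param foreign A `foreign_calls` tibble from [scan_foreign()].
#' @return Tibble `class`, `n_reads`, `n_segments`.
#' @export
summarise_foreign <- function(foreign) {
  if (nrow(foreign) == 0) {
    return(tibble(class = character(), n_reads = integer(), n_segments = integer()))
  }
  per_class <- purrr::map_dfr(seq_len(nrow(foreign)), function(i) {
    segs <- foreign$segments[[i]]
    if (nrow(segs) == 0) return(NULL)
    tibble(read_id = foreign$read_id[i], class = segs$class)
  })
  if (nrow(per_class) == 0) {
    return(tibble(class = character(), n_reads = integer(), n_segments = integer()))
  }
  per_class |>
    group_by(.data$class) |>
    summarise(
      n_reads = dplyr::n_distinct(.data$read_id),
      n_segments = dplyr::n(), .groups = "drop"
    )
}
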