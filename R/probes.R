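#' Generate a k-mer probe set from a source sequence
#'
#' Exact-match probes ("grepseqs") taken at a fixed step along a source:
#' starts 1, 1+step, 1+2*step, ... while the probe still fits. These short
#' exact probes are the workhorse for content filtering of noisy long
#' reads: at ~5% per-base error an individual 17-mer survives intact with
#' probability 0.95^17 (about 0.42), so a handful of probes per target
#' yields near-certain detection while chance exact matches are negligible
#' (4^-17 per position).
#'
#' @param source DNA sequence the probes derive from.
#' @param k Probe length (bp).
#' @param step Spacing between successive probe starts (bp).
#' @param source_name Label recorded with each probe.
#' @param anchor_end Also emit a probe anchored to the source end when the
#'   regular progression stops short of it (default FALSE).
#' @return Tibble with columns `probe`, `source_name`, `source_start`,
#'   `source_end`.
#' @export
generate_probes <- function(source, k, step = 1, source_name = "source",
                            anchor_end = FALSE) {
  source <- toupper(source)
  if (nchar(source) < k) abort("probe source is shorter than k")
  if (step < 1) abort("step must be >= 1")
  starts <- seq.int(1L, nchar(source) - k + 1L, by = step)
  if (anchor_end && tail(starts, 1) != nchar(source) - k + 1L) {
    starts <- c(starts, nchar(source) - k + 1L)
  }
  tibble(
    probe = substring(source, starts, starts + k - 1L),
    source_name = source_name,
    source_start = as.integer(starts),
    source_end = as.integer(starts + k - 1L)
  )
}

#' Evenly spaced, uniqueness-screened probes for a fragment component
#'
#' Draws up to `n` probes evenly spaced across the component after
#' discarding k-mers that also occur (on either strand) in any of the
#' `screen_against` sequences, so that probe hits unambiguously indicate
#' this component. Reverse-orientation probes are the reverse complements
#' of the forward probes.
#'
#' @param seq Component sequence.
#' @param n Number of probes to keep (default 20).
#' @param k Probe length (default 17).
#' @param screen_against Character vector of sequences the probes must not
#'   occur in.
#' @param source_name Label recorded with each probe.
#' @return Tibble as in [generate_probes()] plus column `orientation`; the
#'   reverse rows carry the same source coordinates as their forward
#'   counterparts.
#' @export
component_probes <- function(seq, n = 20, k = 17, screen_against = character(),
                             source_name = "component") {
  all_probes <- generate_probes(seq, k = k, step = 1, source_name = source_name)
  if (length(screen_against) > 0) {
    screen <- paste(c(screen_against, revcomp(screen_against)), collapse = "N")
    keep <- !vapply(all_probes$probe, grepl, logical(1), x = screen, fixed = TRUE)
    all_probes <- all_probes[keep, ]
  }
  all_probes <- all_probes[!duplicated(all_probes$probe), ]
  if (nrow(all_probes) == 0) abort("no unique probes left after screening")
  n_keep <- min(n, nrow(all_probes))
  idx <- unique(round(seq(1, nrow(all_probes), length.out = n_keep)))
  fwd <- all_probes[idx, ]
  fwd$orientation <- "forward"
  rev <- fwd
  rev$probe <- revcomp(fwd$probe)
  rev$orientation <- "reverse"
  bind_rows(fwd, rev)
}

#' Barcode specification with indel-tolerant probe set
#'
#' BCseqs are the 11-mers taken at step 1 from the concatenation of the
#' 11-nt barcode and the first `prefix_len` nt of the (shared) primer. With
#' the default 6-nt prefix this yields 7 probes; any single edit in the
#' outer parts of the region leaves at least one 11-mer intact, while edits
#' falling in the central overlap of all windows (positions 7--11 of the
#' 17-nt region) cannot be rescued by exact matching. A `prefix_len` of 11
#' (22-nt region, 12 probes) shrinks the blind spot to the last two barcode
#' bases, which remain rescuable only when the barcodes differ there.
#'
#' @param id Sample identifier.
#' @param barcode 11-nt barcode sequence.
#' @param primer Primer sequence following the barcode (>= `prefix_len` nt).
#' @param k Probe length (default 11).
#' @param prefix_len Number of primer bases appended to the barcode before
#'   probe generation (default 6).
#' @return A `barcode_spec` list with the derived `bcseqs` probe tibble.
#' @export
barcode_spec <- function(id, barcode, primer, k = 11, prefix_len = 6) {
  barcode <- toupper(barcode)
  primer <- toupper(primer)
  if (nchar(primer) < prefix_len) abort("primer shorter than prefix_len")
  region <- paste0(barcode, substr(primer, 1, prefix_len))
  structure(
    list(
      id = id, barcode = barcode, primer = primer,
      region = region,
      bcseqs = generate_probes(region, k = k, step = 1, source_name = id)
    ),
    class = "barcode_spec"
  )
}

count_probe_hits <- function(seq, probes) {
  # total exact occurrences of all probes in one sequence
  if (length(probes) == 0 || !nzchar(seq)) return(0L)
  subject <- Biostrings::DNAString(seq)
  sum(vapply(
    probes,
    function(p) Biostrings::countPattern(p, subject),
    integer(1)
  ))
}

#' Assign one read to a barcode
#'
#' Counts exact BCseq occurrences of each barcode within the first
#' `search_prefix_bp` of the read and of its reverse complement; the unique
#' spec with the most hits (and at least `min_hits`) wins. Ties or no
#' qualifying spec give `"unassigned"`.
#'
#' @param read Read sequence.
#' @param specs List of [barcode_spec()] objects.
#' @param min_hits Minimum BCseq hits to accept an assignment (default 1).
#' @param search_prefix_bp Length of the prefix searched on each strand
#'   (default 200; barcodes sit at read starts).
#' @return Tibble row: `barcode`, `strand` (`"forward"`, `"reverse"` or
#'   `NA`), `hits`.
#' @export
assign_read <- function(read, specs, min_hits = 1, search_prefix_bp = 200) {
  if (length(specs) == 0) abort("no barcode specs supplied")
  barcodes <- map_chr(specs, "barcode")
  if (anyDuplicated(barcodes)) abort("duplicate barcode sequences across specs")
  # probes occurring in more than one spec (e.g. pure-primer 11-mers when a
  # long prefix is used) carry no sample information and are not counted
  all_probes <- unlist(map(specs, function(s) unique(s$bcseqs$probe)))
  shared <- unique(all_probes[duplicated(all_probes)])
  fwd_prefix <- str_sub1(read, 1, search_prefix_bp)
  rev_prefix <- str_sub1(revcomp(read), 1, search_prefix_bp)
  probes_of <- function(s) setdiff(s$bcseqs$probe, shared)
  hits_f <- vapply(specs, function(s) count_probe_hits(fwd_prefix, probes_of(s)), integer(1))
  hits_r <- vapply(specs, function(s) count_probe_hits(rev_prefix, probes_of(s)), integer(1))
  hits <- pmax(hits_f, hits_r)
  best <- max(hits)
  if (best < min_hits || sum(hits == best) != 1) {
    return(tibble(barcode = "unassigned", strand = NA_character_, hits = as.integer(best)))
  }
  i <- which.max(hits)
  tibble(
    barcode = map_chr(specs, "id")[i],
    strand = if (hits_f[i] >= hits_r[i]) "forward" else "reverse",
    hits = as.integer(best)
  )
}

#' Demultiplex a read table by barcode
#'
#' Every read is assigned to exactly one barcode or to `"unassigned"`, and
#' re-oriented to the forward amplicon strand when the barcode was found on
#' the reverse strand. The per-barcode summary is attached as the
#' `"summary"` attribute (and printed to stderr when `verbose`).
#'
#' @param reads Tibble with columns `read_id`, `seq` (e.g. from
#'   [read_fastq_tbl()] or [simulate_reads()]).
#' @param specs List of [barcode_spec()] objects.
#' @inheritParams assign_read
#' @param verbose Log per-barcode counts to stderr.
#' @return `reads` with added columns `barcode`, `strand_used`, the
#'   sequence re-oriented to the forward strand.
#' @export
demultiplex <- function(reads, specs, min_hits = 1, search_prefix_bp = 200,
                        verbose = FALSE) {
  if (nrow(reads) == 0) {
    out <- mutate(reads, barcode = character(), strand_used = character())
    attr(out, "summary") <- tibble(barcode = character(), n_reads = integer(), fraction = double())
    return(out)
  }
  asg <- purrr::map_dfr(reads$seq, assign_read,
    specs = specs, min_hits = min_hits, search_prefix_bp = search_prefix_bp
  )
  out <- reads
  out$barcode <- asg$barcode
  out$strand_used <- asg$strand
  flip <- !is.na(asg$strand) & asg$strand == "reverse"
  out$seq[flip] <- revcomp(out$seq[flip])
  smry <- out |>
    count(.data$barcode, name = "n_reads") |>
    mutate(fraction = .data$n_reads / sum(.data$n_reads))
  if (verbose) {
    for (i in seq_len(nrow(smry))) {
      message(sprintf("demux: %s -> %d reads", smry$barcode[i], smry$n_reads[i]))
    }
  }
  attr(out, "summary") <- smry
  out
}

#' Demultiplex a FASTQ file to per-barcode FASTQ files
#'
#' @param fastq Input FASTQ path (optionally gzipped).
#' @param specs List of [barcode_spec()] objects.
#' @param outdir Output directory.
#' @inheritParams assign_read
#' @return The summary tibble (`barcode`, `n_reads`, `fraction`), invisibly
#'   written to `demux_summary.tsv` alongside the per-barcode FASTQ files.
#' @export
demultiplex_fastq <- function(fastq, specs, outdir, min_hits = 1,
                              search_prefix_bp = 200) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reads <- read_fastq_tbl(fastq)
  dm <- demultiplex(reads, specs, min_hits = min_hits, search_prefix_bp = search_prefix_bp)
  for (bc in unique(dm$barcode)) {
    write_fastq_tbl(dm[dm$barcode == bc, ], file.path(outdir, paste0(bc, ".fastq.gz")))
  }
  smry <- attr(dm, "summary")
  write_tsv_flat(smry, file.path(outdir, "demux_summary.tsv"))
  invisible(smry)
}

#' Export a probe set as FASTA
#'
#' @param probes Probe tibble (from [generate_probes()] or
#'   [component_probes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probes_fasta <- function(probes, path) {
  nm <- paste0(
    probes$source_name, "_", probes$source_start,
    if ("orientation" %in% names(probes)) paste0("_", substr(probes$orientation, 1, 1)) else ""
  )
  write_fasta_tbl(tibble(name = nm, seq = probes$probe), path)
}
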