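#' Build a synthetic reference set
#'
#' Random-DNA references with the amplicon architecture of the target
#' locus: 146/186-bp retained flanks (332-bp background product), a
#' 2174-bp plasmid backbone ("B", single-insert product 2506 bp) and a
#' 5526-bp donor cassette ("F", single-insert product 5858 bp) whose left
#' end carries the left homology arm (default 85 bp, an HA85-0 design:
#' the arm is the terminal 85 bp of the left flank, the right side is
#' armless). Also emits unique regions of the two editing plasmids, a
#' mini-genome with embedded locus/cassette homology (covered by BED
#' exclusion regions), and a LINE-1 consensus stand-in. All sequences are
#' synthetic; only the lengths and the sharing structure matter.
#'
#' @param left_flank_len,right_flank_len Flank lengths (bp).
#' @param backbone_len,cassette_len Fragment lengths (bp).
#' @param left_arm_len,right_arm_len Homology-arm lengths (bp).
#' @param cas9_region_len,u6_region_len Unique-region lengths of the Cas9
#'   and sgRNA plasmids.
#' @param genome_contig_lens Named integer vector of mini-genome contig
#'   lengths.
#' @param line1_len LINE-1 consensus stand-in length.
#' @return List: `locus`, `library` (components `F`, `B` insertable;
#'   `cas9`, `u6` scan-only), `genome`, `line1`, `exclusions`, `primer`.
#' @export
sim_references <- function(left_flank_len = 146, right_flank_len = 186,
                           backbone_len = 2174, cassette_len = 5526,
                           left_arm_len = 85, right_arm_len = 0,
                           cas9_region_len = 3000, u6_region_len = 1200,
                           genome_contig_lens = c(
                             chr1 = 9000, chr2 = 8000, chr3 = 10000,
                             chr4 = 12000, chr5 = 9000, chrX = 9000
                           ),
                           line1_len = 6300) {
  left_flank <- random_dna(left_flank_len)
  right_flank <- random_dna(right_flank_len)
  left_arm <- if (left_arm_len > 0) {
    substr(left_flank, left_flank_len - left_arm_len + 1, left_flank_len)
  } else ""
  right_arm <- if (right_arm_len > 0) substr(right_flank, 1, right_arm_len) else ""
  core_len <- cassette_len - nchar(left_arm) - nchar(right_arm)
  cassette_core <- random_dna(core_len)
  cassette <- paste0(left_arm, cassette_core, right_arm)
  backbone <- random_dna(backbone_len)
  cas9 <- random_dna(cas9_region_len)
  u6 <- random_dna(u6_region_len)
  line1 <- random_dna(line1_len)

  # mini-genome; chr5 carries the locus (flank homology), chrX carries
  # cassette homology -- both masked by exclusion regions, as the real
  # pipeline masks Alb on chr5 and F8 on chrX
  genome <- tibble(
    name = names(genome_contig_lens),
    seq = map_chr(genome_contig_lens, random_dna)
  )
  embed <- function(seq, insert, at) {
    paste0(substr(seq, 1, at - 1), insert, substr(seq, at + nchar(insert), nchar(seq)))
  }
  locus_seq <- paste0(left_flank, right_flank)
  i5 <- match("chr5", genome$name)
  ix <- match("chrX", genome$name)
  exclusions <- NULL
  if (!is.na(i5)) {
    genome$seq[i5] <- embed(genome$seq[i5], locus_seq, 3001)
    exclusions <- bind_rows(exclusions, tibble(
      contig = "chr5", start = 3000 - 100, end = 3000 + nchar(locus_seq) + 100
    ))
  }
  if (!is.na(ix)) {
    chunk <- substr(cassette_core, 1001, 3000)
    genome$seq[ix] <- embed(genome$seq[ix], chunk, 2001)
    exclusions <- bind_rows(exclusions, tibble(
      contig = "chrX", start = 2000 - 100, end = 2000 + nchar(chunk) + 100
    ))
  }
  list(
    locus = locus_model(left_flank, right_flank, left_arm, right_arm, exclusions),
    library = fragment_library(
      F = cassette, B = backbone, cas9 = cas9, u6 = u6,
      insertable = c("F", "B")
    ),
    genome = genome,
    line1 = line1,
    exclusions = exclusions,
    primer = random_dna(20)
  )
}

#' Default pattern mixture
#'
#' The single-fragment and complete-donor shares measured for the HA85-0
#' donor (single-F 40.24%, single-B 44.47%, complete donor 14.16%), with
#' 38% of cassette insertions in the correct (forward) orientation, the
#' complete-donor mass spread evenly over the eight two-piece
#' order/orientation chains, and the residual 1.13% spread over
#' representative compound patterns.
#'
#' @return Named numeric vector of orientation-pattern weights (sums to 1).
#' @export
study_pattern_weights <- function() {
  bf <- c("Ff,Bf", "Ff,Br", "Fr,Bf", "Fr,Br", "Bf,Ff", "Bf,Fr", "Br,Ff", "Br,Fr")
  compound <- c("Bf,Bf", "Fr,Fr", "Bf,Bf,Bf", "Ff,Ff,Ff", "Br,Bf,Fr", "Ff,Br,Ff")
  w <- c(
    setNames(c(0.4024 * 0.38, 0.4024 * 0.62), c("Ff", "Fr")),
    setNames(c(0.4447 * 0.5, 0.4447 * 0.5), c("Bf", "Br")),
    setNames(rep(0.1416 / length(bf), length(bf)), bf),
    setNames(rep((1 - 0.4024 - 0.4447 - 0.1416) / length(compound), length(compound)), compound)
  )
  w / sum(w)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: ~5% indel-dominated
#' sequencing error, HA85-0 donor mixture, HDR in about 55% of forward
#' cassette insertions, degraded-donor capture at ~1% each, editing
#' plasmid remnants at 0.1%, endogenous genomic fragments at 1%, LINE-1
#' at 0.05%, large (>100 bp) deletions in 1.5% of background reads, and
#' random read strand.
#'
#' @param refs A [sim_references()] result.
#' @param n_reads Number of reads.
#' @param weights Named pattern-mixture weights over chain labels (e.g.
#'   `"Ff"`, `"Br"`, `"Ff,Br"`) plus optionally `"background"`; must be
#'   non-negative and sum to 1.
#' @param barcodes Number of barcodes, or a character vector of 11-nt
#'   barcode sequences.
#' @param error_rate Per-base total error rate (default 0.05).
#' @param indel_fraction Fraction of errors that are indels (default
#'   0.75, split evenly between 1-bp insertions and deletions).
#' @param hdr_fraction HDR fraction among forward single-cassette
#'   insertions (default 0.55).
#' @param truncation_prob Per-fragment truncation probability in pattern
#'   reads (default 0).
#' @param truncation_min_frac Minimum retained fraction on truncation.
#' @param genomic_rate,line1_rate,cas9_rate,u6_rate,short_B_rate,short_F_rate
#'   Per-read probabilities of the foreign/degraded read classes; the
#'   remaining mass follows `weights`.
#' @param large_deletion_rate Probability that a background read carries a
#'   deletion > 100 bp through the cut (default 0.015).
#' @param deletion_len_range,genomic_len_range,line1_len_range,cas9_len_range,u6_len_range,short_B_len_range,short_F_len_range
#'   Insert/deletion length ranges (uniform sampling).
#' @param strand_flip_prob Probability a read is emitted reverse
#'   complemented (default 0.5).
#' @param seed Integer seed fixing the whole output, or `NULL` to use the
#'   current RNG state.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(refs, n_reads = 1000,
                              weights = study_pattern_weights(),
                              barcodes = 4,
                              error_rate = 0.05, indel_fraction = 0.75,
                              hdr_fraction = 0.55,
                              truncation_prob = 0, truncation_min_frac = 0.25,
                              genomic_rate = 0.01, line1_rate = 0.0005,
                              cas9_rate = 0.001, u6_rate = 0.001,
                              short_B_rate = 0.01, short_F_rate = 0.01,
                              large_deletion_rate = 0.015,
                              deletion_len_range = c(110, 250),
                              genomic_len_range = c(50, 400),
                              line1_len_range = c(100, 1505),
                              cas9_len_range = c(150, 3000),
                              u6_len_range = c(100, 500),
                              short_B_len_range = c(350, 1600),
                              short_F_len_range = c(600, 4200),
                              strand_flip_prob = 0.5,
                              seed = NULL) {
  if (any(weights < 0)) abort("mixture weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) abort("mixture weights must sum to 1")
  rates <- c(genomic_rate, line1_rate, cas9_rate, u6_rate, short_B_rate, short_F_rate)
  if (any(rates < 0 | rates > 1)) abort("foreign-insert rates must be in [0, 1]")
  if (is.numeric(barcodes) && length(barcodes) == 1) {
    barcodes <- map_chr(seq_len(barcodes), function(i) random_dna(11))
  }
  specs <- imap(barcodes, function(bc, i) {
    barcode_spec(paste0("bc", if (is.character(i)) i else sprintf("%02d", i)), bc, refs$primer)
  })
  structure(
    list(
      refs = refs, n_reads = n_reads, weights = weights, specs = specs,
      error_rate = error_rate, indel_fraction = indel_fraction,
      hdr_fraction = hdr_fraction,
      truncation_prob = truncation_prob, truncation_min_frac = truncation_min_frac,
      genomic_rate = genomic_rate, line1_rate = line1_rate,
      cas9_rate = cas9_rate, u6_rate = u6_rate,
      short_B_rate = short_B_rate, short_F_rate = short_F_rate,
      large_deletion_rate = large_deletion_rate,
      deletion_len_range = deletion_len_range,
      genomic_len_range = genomic_len_range,
      line1_len_range = line1_len_range,
      cas9_len_range = cas9_len_range,
      u6_len_range = u6_len_range,
      short_B_len_range = short_B_len_range,
      short_F_len_range = short_F_len_range,
      strand_flip_prob = strand_flip_prob,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Apply nanopore-like sequencing noise
#'
#' Independent per-base errors; among errors, `indel_fraction` are split
#' evenly between 1-bp insertions and 1-bp deletions, the remainder are
#' substitutions to a different base.
#'
#' @param seq DNA sequence.
#' @param error_rate Per-base error probability (`0 <= rate < 1`).
#' @param indel_fraction Fraction of errors that are indels.
#' @return The noisy sequence.
#' @export
apply_noise <- function(seq, error_rate = 0.05, indel_fraction = 0.75) {
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  if (error_rate == 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  err <- runif(n) < error_rate
  if (!any(err)) return(seq)
  idx <- which(err)
  u <- runif(length(idx))
  is_sub <- u < 1 - indel_fraction
  is_ins <- !is_sub & u < 1 - indel_fraction / 2
  is_del <- !is_sub & !is_ins
  out <- chars
  if (any(is_sub)) {
    i <- idx[is_sub]
    # rotate to one of the three other bases, vectorized
    shift <- sample.int(3, length(i), replace = TRUE)
    out[i] <- DNA_BASES[((match(chars[i], DNA_BASES) - 1L + shift) %% 4L) + 1L]
  }
  if (any(is_ins)) {
    i <- idx[is_ins]
    out[i] <- paste0(sample(DNA_BASES, length(i), replace = TRUE), chars[i])
  }
  out[idx[is_del]] <- ""
  paste(out, collapse = "")
}

sample_len <- function(range) {
  as.integer(round(runif(1, range[1], range[2])))
}

sub_fragment <- function(seq, len) {
  start <- sample.int(nchar(seq) - len + 1L, 1)
  list(seq = substr(seq, start, start + len - 1L), start = start, end = start + len - 1L)
}

maybe_flip <- function(seq, orientation) {
  if (orientation == "reverse") revcomp(seq) else seq
}

#' Assemble an insert for an orientation pattern
#'
#' Concatenates the pattern's fragments in order and orientation, with
#' optional per-fragment truncation (uniform breakpoint, one retained
#' end), recording exact source intervals as truth segments.
#'
#' @param chain Chain tibble (`component`, `orientation`) or label.
#' @param library A [fragment_library()].
#' @param truncation_prob Per-fragment truncation probability.
#' @param truncation_min_frac Minimum retained fraction.
#' @param .rc_cache Optional named vector of precomputed fragment reverse
#'   complements (internal speed-up for large simulations).
#' @return List: `seq`, `segments` (truth tibble with `component`,
#'   `orientation`, `src_start`, `src_end`).
#' @export
make_insert <- function(chain, library, truncation_prob = 0, truncation_min_frac = 0.25,
                        .rc_cache = NULL) {
  if (is.character(chain)) chain <- parse_chain_label(chain)
  parts <- map(seq_len(nrow(chain)), function(i) {
    s <- fragment_seq(library, chain$component[i])
    src <- c(1L, nchar(s))
    truncated <- FALSE
    if (truncation_prob > 0 && runif(1) < truncation_prob) {
      truncated <- TRUE
      keep <- sample_len(c(ceiling(truncation_min_frac * nchar(s)), nchar(s)))
      if (runif(1) < 0.5) {
        src <- c(1L, keep)
      } else {
        src <- c(nchar(s) - keep + 1L, nchar(s))
      }
      s <- substr(s, src[1], src[2])
    }
    oriented <- if (chain$orientation[i] == "reverse") {
      if (!truncated && !is.null(.rc_cache)) {
        .rc_cache[[chain$component[i]]]
      } else {
        revcomp(s)
      }
    } else {
      s
    }
    list(
      seq = oriented,
      truth = tibble(
        component = chain$component[i], orientation = chain$orientation[i],
        src_start = src[1], src_end = src[2]
      )
    )
  })
  list(
    seq = paste(map_chr(parts, "seq"), collapse = ""),
    segments = bind_rows(map(parts, "truth"))
  )
}

empty_truth_segments <- function() {
  tibble(
    class = character(), contig = character(),
    src_start = integer(), src_end = integer(), orientation = character()
  )
}

sample_genomic_insert <- function(refs, len) {
  # avoid the excluded (locus/cassette homologous) regions so that every
  # simulated genomic capture is recoverable by the masked detector
  repeat {
    ci <- sample.int(nrow(refs$genome), 1)
    contig <- refs$genome$name[ci]
    frag <- sub_fragment(refs$genome$seq[ci], len)
    if (!overlaps_exclusion(contig, frag$start, frag$end, refs$exclusions)) {
      return(list(contig = contig, frag = frag))
    }
  }
}

#' Simulate a barcoded nanopore-like amplicon dataset
#'
#' Each read is `barcode + primer + left flank + insert + right flank`,
#' reverse complemented with probability `strand_flip_prob`, then passed
#' through the error model. The insert follows the sampled class: an
#' orientation pattern (with HDR removing the donor's left-arm copy and
#' NHEJ retaining it, hence duplicating the arm), background (optionally
#' with a large deletion through the cut), a degraded donor fragment, an
#' editing-plasmid remnant, an endogenous genomic fragment, or a
#' 3'-anchored LINE-1 fragment. The truth table records everything the
#' pipeline is later asked to recover.
#'
#' @param config A [simulation_config()].
#' @return List: `reads` (tibble `read_id`, `seq`, `qual`), `truth`
#'   (tibble per read: `read_id`, `barcode`, `strand`, `class`, `pattern`,
#'   `repair`, `insert_len`, `pre_noise_length`, `segments` list,
#'   `del_start`, `del_end`), `config`.
#' @export
simulate_reads <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  refs <- config$refs
  locus <- refs$locus
  lib <- refs$library
  cut <- locus$cut_position
  arm_len <- nchar(locus$left_arm)
  classes <- c("genomic", "line1", "cas9", "u6", "short_B", "short_F")
  class_rates <- c(
    config$genomic_rate, config$line1_rate, config$cas9_rate,
    config$u6_rate, config$short_B_rate, config$short_F_rate
  )
  mix_mass <- 1 - sum(class_rates)
  if (mix_mass <= 0) abort("foreign-class rates leave no probability mass for the pattern mixture")
  all_classes <- c(classes, names(config$weights))
  all_probs <- c(class_rates, mix_mass * config$weights / sum(config$weights))
  rc_cache <- setNames(revcomp(lib$seq), lib$name)

  rows <- map(seq_len(config$n_reads), function(i) {
    spec <- config$specs[[sample.int(length(config$specs), 1)]]
    cls <- sample(all_classes, 1, prob = all_probs)
    segments <- empty_truth_segments()
    pattern <- NA_character_
    repair <- NA_character_
    del <- c(NA_integer_, NA_integer_)
    insert <- ""
    class_out <- cls
    if (cls == "background") {
      pattern <- ""
      if (runif(1) < config$large_deletion_rate) {
        d <- sample_len(config$deletion_len_range)
        ds <- sample(seq.int(max(1L, cut + 2L - d), cut), 1)
        # clamp to the amplicon: a deletion running off the right end is
        # recorded as the reference interval it actually removes
        del <- c(ds, min(ds + d - 1L, background_length(locus)))
      }
    } else if (cls %in% classes) {
      len <- sample_len(config[[paste0(
        c(
          genomic = "genomic_len", line1 = "line1_len", cas9 = "cas9_len",
          u6 = "u6_len", short_B = "short_B_len", short_F = "short_F_len"
        )[cls], "_range"
      )]])
      ori <- sample(c("forward", "reverse"), 1)
      if (cls == "genomic") {
        g <- sample_genomic_insert(refs, len)
        insert <- maybe_flip(g$frag$seq, ori)
        segments <- tibble(
          class = "genomic", contig = g$contig,
          src_start = g$frag$start, src_end = g$frag$end, orientation = ori
        )
      } else if (cls == "line1") {
        # 3'-anchored truncation, as captured LINE-1 fragments are
        n <- nchar(refs$line1)
        insert <- maybe_flip(substr(refs$line1, n - len + 1L, n), ori)
        segments <- tibble(
          class = "LINE-1", contig = "LINE1_consensus",
          src_start = n - len + 1L, src_end = n, orientation = ori
        )
      } else {
        src_name <- c(cas9 = "cas9", u6 = "u6", short_B = "B", short_F = "F")[[cls]]
        frag <- sub_fragment(fragment_seq(lib, src_name), len)
        insert <- maybe_flip(frag$seq, ori)
        segments <- tibble(
          class = c(
            cas9 = "Cas9-plasmid", u6 = "sgRNA-plasmid",
            short_B = "short-B", short_F = "short-F"
          )[[cls]],
          contig = src_name, src_start = frag$start, src_end = frag$end,
          orientation = ori
        )
      }
    } else {
      # orientation-pattern read
      class_out <- "pattern"
      pattern <- cls
      chain <- parse_chain_label(cls)
      hdr <- FALSE
      if (identical(chain$component, "F") && identical(chain$orientation, "forward") &&
        arm_len > 0) {
        hdr <- runif(1) < config$hdr_fraction
        repair <- if (hdr) "HDR" else "NHEJ"
      }
      mi <- make_insert(chain, lib, config$truncation_prob, config$truncation_min_frac,
        .rc_cache = rc_cache
      )
      insert <- mi$seq
      if (hdr) insert <- substr(insert, arm_len + 1L, nchar(insert))
      segments <- mutate(mi$segments, class = "donor", contig = .data$component) |>
        select("class", "contig", "src_start", "src_end", "orientation")
    }
    left <- locus$left_flank
    right <- locus$right_flank
    if (!anyNA(del)) {
      amplicon <- paste0(left, right)
      amplicon <- paste0(substr(amplicon, 1, del[1] - 1L), substr(amplicon, del[2] + 1L, nchar(amplicon)))
      body <- amplicon
    } else {
      body <- paste0(left, insert, right)
    }
    read <- paste0(spec$barcode, spec$primer, body)
    pre_noise_length <- nchar(read)
    strand <- if (runif(1) < config$strand_flip_prob) "reverse" else "forward"
    list(
      seq = read, barcode = spec$id, strand = strand, class = class_out,
      pattern = pattern, repair = repair, insert_len = nchar(insert),
      pre_noise_length = pre_noise_length, segments = segments,
      del_start = del[1], del_end = del[2]
    )
  })
  ids <- sprintf("read%06d", seq_len(config$n_reads))
  seqs <- map_chr(rows, "seq")
  strands <- map_chr(rows, "strand")
  flip <- strands == "reverse"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip]) # batch strand flip
  if (config$error_rate > 0) {
    seqs <- vapply(seqs, apply_noise, character(1),
      error_rate = config$error_rate, indel_fraction = config$indel_fraction,
      USE.NAMES = FALSE
    )
  }
  truth <- tibble(
    read_id = ids,
    barcode = map_chr(rows, "barcode"),
    strand = map_chr(rows, "strand"),
    class = map_chr(rows, "class"),
    pattern = map_chr(rows, "pattern"),
    repair = map_chr(rows, "repair"),
    insert_len = map_int(rows, "insert_len"),
    pre_noise_length = map_int(rows, "pre_noise_length"),
    segments = map(rows, "segments"),
    del_start = map_int(rows, "del_start"),
    del_end = map_int(rows, "del_end")
  )
  reads <- tibble(
    read_id = ids,
    seq = seqs,
    qual = strrep("-", nchar(seqs)) # constant Q12 placeholder
  )
  list(reads = reads, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' FASTQ (gzipped), truth TSV, and the reference FASTAs and exclusion BED
#' needed to run the pipeline on the output.
#'
#' @param sim A [simulate_reads()] result.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fastq_tbl(sim$reads, file.path(outdir, "reads.fastq.gz"))
  write_tsv_flat(
    mutate(sim$truth, segments = map(.data$segments, function(s) {
      paste(sprintf("%s:%s:%d-%d:%s", s$class, s$contig, s$src_start, s$src_end, s$orientation),
        collapse = ";"
      )
    })),
    file.path(outdir, "truth.tsv")
  )
  refs <- sim$config$refs
  write_fasta_tbl(
    tibble(
      name = c("left_flank", "right_flank", refs$library$name, "LINE1_consensus"),
      seq = c(refs$locus$left_flank, refs$locus$right_flank, refs$library$seq, refs$line1)
    ),
    file.path(outdir, "references.fasta")
  )
  write_fasta_tbl(refs$genome, file.path(outdir, "genome.fasta"))
  if (!is.null(refs$exclusions)) {
    utils::write.table(refs$exclusions, file.path(outdir, "exclusions.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(outdir)
}
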