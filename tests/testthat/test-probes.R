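test_that("probe generation matches a naive sliding-window oracle", {
  withr::with_seed(11, {
    for (k in c(11, 17)) {
      for (step in c(1, 20, 40, 100)) {
        src <- random_dna(sample(c(150, 205, 500), 1))
        got <- generate_probes(src, k = k, step = step)
        expect_equal(got$probe, oracle_probes(src, k, step))
        expect_equal(got$source_start, seq(1, nchar(src) - k + 1, by = step))
      }
    }
  })
  # printed designs: 7 BCseqs from 17 nt, 10 probes from a 205-nt source
  expect_equal(nrow(generate_probes(random_dna(17), k = 11, step = 1)), 7)
  src205 <- random_dna(205)
  p205 <- generate_probes(src205, k = 17, step = 20)
  expect_equal(nrow(p205), 10)
  expect_equal(p205$source_start, seq(1, 181, by = 20))
  expect_equal(nrow(generate_probes(random_dna(17), k = 17, step = 5)), 1)
  expect_error(generate_probes("ACGT", k = 17), "shorter")
})

test_that("component probes are unique, screened and cover both orientations", {
  refs <- test_refs()
  lib <- refs$library
  pr <- component_probes(
    fragment_seq(lib, "F"),
    screen_against = c(
      refs$locus$left_flank, refs$locus$right_flank,
      lib$seq[lib$name != "F"]
    ),
    source_name = "F"
  )
  expect_equal(nrow(pr), 40)
  expect_setequal(unique(pr$orientation), c("forward", "reverse"))
  fwd <- pr[pr$orientation == "forward", ]
  expect_equal(revcomp(fwd$probe), pr$probe[pr$orientation == "reverse"])
  # no probe occurs in the flanks or in the backbone (either strand)
  screen <- c(
    refs$locus$left_flank, refs$locus$right_flank,
    fragment_seq(lib, "B")
  )
  screen <- paste(c(screen, revcomp(screen)), collapse = "N")
  expect_false(any(vapply(pr$probe, grepl, logical(1), x = screen, fixed = TRUE)))
})

test_that("barcode assignment is exact on clean reads and most-hits-wins with ties unassigned", {
  withr::with_seed(5, {
    primer <- random_dna(20)
    specs <- lapply(1:4, function(i) barcode_spec(paste0("bc", i), random_dna(11), primer))
    body <- random_dna(400)
    read <- paste0(specs[[2]]$barcode, primer, body)
    got <- assign_read(read, specs)
    expect_equal(got$barcode, "bc2")
    expect_equal(got$hits, 7) # all seven BCseqs intact
    expect_equal(got$strand, "forward")
    # reverse-complemented read assigns on the reverse strand
    got_rc <- assign_read(revcomp(read), specs)
    expect_equal(got_rc$barcode, "bc2")
    expect_equal(got_rc$strand, "reverse")
    # no barcode material
    expect_equal(assign_read(random_dna(400), specs)$barcode, "unassigned")
    # duplicate barcodes are a configuration error
    dup <- c(specs, list(barcode_spec("bc5", specs[[1]]$barcode, primer)))
    expect_error(assign_read(read, dup), "duplicate")
  })
})

test_that("single edits outside the central window overlap are always corrected; the correctable set is exactly positions 1-6 and 12-17", {
  # with k = 11 over the 17-nt barcode+prefix region the seven probe
  # windows share the intersection 7..11; edits there break every probe
  withr::with_seed(13, {
    primer <- random_dna(20)
    specs <- lapply(1:4, function(i) barcode_spec(paste0("bc", i), random_dna(11), primer))
    body <- random_dna(300)
    for (si in 1:4) {
      spec <- specs[[si]]
      region <- spec$region
      rest <- paste0(substr(primer, 7, 20), body)
      for (pos in seq_len(17)) {
        for (type in c("sub", "del", "ins")) {
          read <- paste0(mutate_seq(region, pos, type, base = "C"), rest)
          got <- assign_read(read, specs)$barcode
          if (pos <= 6 || pos >= 12) {
            expect_equal(got, spec$id)
          }
          # central positions may or may not rescue by chance homology;
          # what must never happen is assignment to a different sample
          expect_true(got %in% c(spec$id, "unassigned"))
        }
      }
    }
  })
})

test_that("an 11-nt primer prefix shrinks the uncorrectable window to the final barcode base", {
  # with a 22-nt region every position has a surviving 11-mer, but a probe
  # that discriminates between samples must overlap the barcode; windows
  # avoiding positions 10-11 overlap it in at most the final base, which
  # random barcode sets may share, so only 1-9 and 12-22 are guaranteed
  withr::with_seed(17, {
    primer <- random_dna(20)
    specs <- lapply(1:4, function(i) {
      barcode_spec(paste0("bc", i), random_dna(11), primer, prefix_len = 11)
    })
    body <- random_dna(300)
    for (si in 1:4) {
      spec <- specs[[si]]
      rest <- paste0(substr(primer, 12, 20), body)
      for (pos in setdiff(seq_len(22), c(10, 11))) {
        for (type in c("sub", "del", "ins")) {
          read <- paste0(mutate_seq(spec$region, pos, type, base = "C"), rest)
          expect_equal(assign_read(read, specs)$barcode, spec$id)
        }
      }
    }
  })
})

test_that("demultiplexing partitions reads exactly and splits clean reads perfectly", {
  withr::with_seed(23, {
    refs <- test_refs()
    cfg <- simulation_config(refs,
      n_reads = 100, error_rate = 0, barcodes = 2,
      genomic_rate = 0, line1_rate = 0, cas9_rate = 0, u6_rate = 0,
      short_B_rate = 0, short_F_rate = 0, seed = 31
    )
    sim <- simulate_reads(cfg)
    dm <- demultiplex(sim$reads, cfg$specs)
    expect_equal(dm$barcode, sim$truth$barcode)
    smry <- attr(dm, "summary")
    expect_equal(sum(smry$n_reads), nrow(sim$reads))
    expect_equal(sum(smry$fraction), 1)
    # re-orientation puts the barcode at the read start
    bc_of <- setNames(
      vapply(cfg$specs, function(s) s$barcode, character(1)),
      vapply(cfg$specs, function(s) s$id, character(1))
    )
    expect_true(all(startsWith(dm$seq, bc_of[dm$barcode])))
    # empty input
    empty <- demultiplex(sim$reads[0, ], cfg$specs)
    expect_equal(nrow(empty), 0)
    expect_equal(nrow(attr(empty, "summary")), 0)
  })
})

test_that("demultiplexing at 5% indel-dominated error loses only central-edit reads and never cross-assigns", {
  # exact 11-mer matching cannot rescue edits in the shared centre of the
  # BCseq windows, so a fraction of noisy reads goes to "unassigned"; the
  # essential guarantee is that assigned reads are assigned correctly
  withr::with_seed(29, {
    refs <- test_refs()
    cfg <- simulation_config(refs,
      n_reads = 400, error_rate = 0.05, barcodes = 4,
      genomic_rate = 0, line1_rate = 0, cas9_rate = 0, u6_rate = 0,
      short_B_rate = 0, short_F_rate = 0, seed = 37
    )
    sim <- simulate_reads(cfg)
    dm <- demultiplex(sim$reads, cfg$specs)
    assigned <- dm$barcode != "unassigned"
    expect_gte(mean(assigned), 0.70)
    expect_gte(mean(dm$barcode[assigned] == sim$truth$barcode[assigned]), 0.99)
    # partition invariant holds with noise too
    expect_equal(sum(attr(dm, "summary")$n_reads), nrow(sim$reads))
  })
})

test_that("FASTQ round trip preserves reads and demultiplex_fastq writes one file per barcode", {
  withr::with_seed(41, {
    refs <- test_refs()
    cfg <- simulation_config(refs,
      n_reads = 40, error_rate = 0, barcodes = 2,
      genomic_rate = 0, line1_rate = 0, cas9_rate = 0, u6_rate = 0,
      short_B_rate = 0, short_F_rate = 0, seed = 43
    )
    sim <- simulate_reads(cfg)
    fq <- withr::local_tempfile(fileext = ".fastq.gz")
    write_fastq_tbl(sim$reads, fq)
    back <- read_fastq_tbl(fq)
    expect_equal(back$read_id, sim$reads$read_id)
    expect_equal(back$seq, sim$reads$seq)
    outdir <- withr::local_tempdir()
    smry <- demultiplex_fastq(fq, cfg$specs, outdir)
    expect_equal(sum(smry$n_reads), 40)
    for (bc in smry$barcode) {
      expect_true(file.exists(file.path(outdir, paste0(bc, ".fastq.gz"))))
    }
    expect_true(file.exists(file.path(outdir, "demux_summary.tsv")))
  })
})
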