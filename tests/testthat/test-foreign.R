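test_that("insert extraction returns exactly the spiked sequence and flags scrambled flanks", {
  refs <- test_refs()
  locus <- refs$locus
  withr::with_seed(51, {
    spike <- random_dna(300)
    read <- paste0(locus$left_flank, spike, locus$right_flank)
    ext <- extract_insert(read, locus)
    expect_equal(ext$insert, spike)
    expect_equal(ext$albLr, nchar(locus$left_flank))
    expect_equal(ext$albRl, nchar(locus$left_flank) + 301)
    expect_false(ext$flagged)
    # background read -> empty insert
    bg <- extract_insert(paste0(locus$left_flank, locus$right_flank), locus)
    expect_equal(bg$insert, "")
    expect_false(bg$flagged)
    # flanks in the wrong order -> flagged, no insert
    wrong <- extract_insert(paste0(locus$right_flank, locus$left_flank), locus)
    expect_equal(wrong$insert, "")
    expect_true(wrong$flagged)
  })
})

test_that("genomic length filter keeps exactly the >= 50 bp spikes", {
  refs <- test_refs()
  withr::with_seed(53, {
    # spikes copied from a non-excluded contig
    contig <- "chr3"
    cseq <- refs$genome$seq[refs$genome$name == contig]
    for (len in c(30, 49, 50, 51, 400, 5912)) {
      start <- 500
      insert <- substr(cseq, start, start + len - 1)
      segs <- align_insert_to_genome(insert, refs$genome, refs$exclusions)
      if (len >= 50) {
        expect_equal(nrow(segs), 1)
        expect_equal(segs$contig, contig)
        expect_equal(segs$s_start, start)
        expect_equal(segs$s_end, start + len - 1)
        expect_equal(segs$identity, 100)
      } else {
        expect_equal(nrow(segs), 0)
      }
    }
  })
})

test_that("matches in exclusion regions are discarded and the best chromosome wins", {
  refs <- test_refs()
  withr::with_seed(59, {
    # the locus sequence is embedded on chr5 inside an exclusion region:
    # an insert matching it must yield no genomic call
    excluded <- substr(refs$genome$seq[refs$genome$name == "chr5"], 3101, 3300)
    expect_equal(nrow(align_insert_to_genome(excluded, refs$genome, refs$exclusions)), 0)
    # without the exclusion list the same insert is found
    expect_gt(nrow(align_insert_to_genome(excluded, refs$genome, NULL)), 0)
    # duplicated segment across two contigs: the higher-identity source wins
    seg <- substr(refs$genome$seq[refs$genome$name == "chr1"], 1000, 1199)
    genome2 <- refs$genome
    degraded <- apply_noise(seg, 0.1, 0.3)
    genome2$seq[genome2$name == "chr2"] <- paste0(
      substr(genome2$seq[genome2$name == "chr2"], 1, 4000), degraded,
      substr(genome2$seq[genome2$name == "chr2"], 4001, nchar(genome2$seq[genome2$name == "chr2"]))
    )
    segs <- align_insert_to_genome(seg, genome2, refs$exclusions)
    expect_equal(unique(segs$contig), "chr1")
    expect_equal(max(segs$identity), 100)
  })
})

test_that("degraded-donor gates honour the published length thresholds on boundary instances", {
  refs <- test_refs()
  panel <- test_panel()
  lib <- refs$library
  bg <- 332
  mk <- function(comp, ins_len) {
    substr(fragment_seq(lib, comp), 200, 199 + ins_len)
  }
  # backbone insert gate at a read length inside the read gate: 1699
  # passes (< 1700), 1700 fails (the read gate alone already excludes a
  # full-flank read with a 1699 bp insert, so the gates are tested
  # independently)
  expect_equal(
    detect_degraded_donor(1999, mk("B", 1699), panel)$class, "short-B"
  )
  expect_equal(nrow(detect_degraded_donor(1999, mk("B", 1700), panel)), 0)
  expect_equal(
    detect_degraded_donor(bg + 1000, mk("B", 1000), panel)$class, "short-B"
  )
  # full-length backbone (2174, >= 80% of itself) is not degraded
  expect_equal(
    nrow(detect_degraded_donor(bg + 2174, fragment_seq(lib, "B"), panel)), 0
  )
  # cassette: 4399 passes (<4400, read < 5000); 4400 fails
  expect_equal(
    detect_degraded_donor(bg + 4399, mk("F", 4399), panel)$class, "short-F"
  )
  expect_equal(nrow(detect_degraded_donor(bg + 4400, mk("F", 4400), panel)), 0)
  # a 2500 bp cassette fragment is degraded short-F
  expect_equal(
    detect_degraded_donor(bg + 2500, mk("F", 2500), panel)$class, "short-F"
  )
  # read-length gate: a 1000 bp backbone fragment in an implausibly long
  # read is not called short-B
  expect_equal(nrow(detect_degraded_donor(2500, mk("B", 1000), panel)), 0)
})

test_that("plasmid remnant probes classify editing-plasmid inserts and LINE-1 detection finds truncated fragments", {
  refs <- test_refs()
  lib <- refs$library
  cas9p <- generate_probes(fragment_seq(lib, "cas9"), 17, 100, "cas9")
  u6p <- generate_probes(fragment_seq(lib, "u6"), 17, 40, "u6")
  withr::with_seed(61, {
    u6_insert <- substr(fragment_seq(lib, "u6"), 301, 600)
    segs <- scan_plasmid_fragments(u6_insert, cas9p, u6p)
    expect_equal(segs$class, "sgRNA-plasmid")
    donor_only <- substr(fragment_seq(lib, "F"), 1001, 2000)
    expect_equal(nrow(scan_plasmid_fragments(donor_only, cas9p, u6p)), 0)
    # reverse-orientation remnant still detected
    segs_rc <- scan_plasmid_fragments(revcomp(u6_insert), cas9p, u6p)
    expect_equal(segs_rc$class, "sgRNA-plasmid")
    expect_equal(segs_rc$strand, "-")
    # LINE-1: a 1505 bp 3' fragment of the consensus
    n <- nchar(refs$line1)
    l1 <- substr(refs$line1, n - 1504, n)
    l1segs <- detect_line1(l1, refs$line1)
    expect_equal(nrow(l1segs), 1)
    expect_equal(l1segs$class, "LINE-1")
    expect_equal(l1segs$s_end - l1segs$s_start + 1, 1505)
    expect_equal(nrow(detect_line1(random_dna(800), refs$line1)), 0)
  })
})

test_that("compound inserts report ordered segments of multiple classes with the compound flag", {
  refs <- test_refs()
  panel <- test_panel()
  cats <- test_categories()
  locus <- refs$locus
  lib <- refs$library
  withr::with_seed(67, {
    backbone_piece <- substr(fragment_seq(lib, "B"), 101, 500)
    genomic_piece <- substr(refs$genome$seq[refs$genome$name == "chr2"], 2001, 2300)
    n <- nchar(refs$line1)
    line1_piece <- substr(refs$line1, n - 599, n)
    insert <- paste0(backbone_piece, genomic_piece, line1_piece)
    read <- paste0(random_dna(31), locus$left_flank, insert, locus$right_flank)
    calls <- call_patterns(tibble::tibble(read_id = "cmpd", seq = read), panel, cats)
    fr <- scan_foreign(calls, panel,
      genome = refs$genome, line1 = refs$line1,
      exclusions = refs$exclusions
    )
    expect_equal(nrow(fr), 1)
    expect_true(fr$compound)
    segs <- fr$segments[[1]]
    expect_true(all(c("short-B", "genomic", "LINE-1") %in% segs$class))
    # ordered along the insert
    expect_equal(segs$q_start, sort(segs$q_start))
    # flanking rule: every segment lies strictly inside the insert
    expect_true(all(segs$q_start >= 1 & segs$q_end <= nchar(insert)))
  })
})

test_that("foreign spikes seeded at study rates are recovered within the binomial 95% CI", {
  refs <- test_refs()
  panel <- test_panel()
  cats <- test_categories()
  withr::with_seed(71, {
    n <- 800
    gr <- 0.02
    lr <- 0.005 # scaled-up rates keep the check informative at test size
    cfg <- simulation_config(refs,
      n_reads = n, error_rate = 0.05, seed = 73,
      genomic_rate = gr, line1_rate = lr,
      cas9_rate = 0, u6_rate = 0, short_B_rate = 0, short_F_rate = 0
    )
    sim <- simulate_reads(cfg)
    calls <- call_patterns(sim$reads, panel, cats)
    fr <- scan_foreign(calls, panel,
      genome = refs$genome, line1 = refs$line1,
      exclusions = refs$exclusions
    )
    smry <- summarise_foreign(fr)
    got_g <- sum(smry$n_reads[smry$class == "genomic"])
    got_l <- sum(smry$n_reads[smry$class == "LINE-1"])
    ci <- function(p) n * p + c(-1, 1) * 1.96 * sqrt(n * p * (1 - p))
    expect_gte(got_g, floor(ci(gr)[1]))
    expect_lte(got_g, ceiling(ci(gr)[2]))
    expect_gte(got_l, floor(ci(lr)[1]))
    expect_lte(got_l, ceiling(ci(lr)[2]))
  })
})
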