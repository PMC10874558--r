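test_that("probe search ranges shrink the perfect insert span and fall back when collapsed", {
  locus <- test_refs()$locus
  expect_equal(unname(probe_search_range(2506, locus, margin = 300)), c(447, 2020))
  expect_equal(unname(probe_search_range(2506, locus, margin = 0)), c(147, 2320))
  # margin at least half the span collapses the range -> full span
  expect_warning(
    r <- probe_search_range(2506, locus, margin = 1200),
    "collapsed"
  )
  expect_equal(unname(r), c(147, 2320))
  # fractional margin
  expect_equal(
    unname(probe_search_range(2506, locus, margin = 0.1)),
    c(147 + round(0.1 * 2174), 2320 - round(0.1 * 2174))
  )
})

test_that("flank checking detects presence, strand and anchors on clean and random reads", {
  refs <- test_refs()
  panel <- test_panel()
  locus <- refs$locus
  withr::with_seed(3, {
    amplicon <- paste0(random_dna(31), locus$left_flank, locus$right_flank)
    fl <- check_flanks(amplicon, panel)
    expect_true(fl$has_left)
    expect_true(fl$has_right)
    expect_equal(fl$strand, "forward")
    expect_equal(fl$albLr, 31 + nchar(locus$left_flank))
    expect_equal(fl$albRl, 31 + nchar(locus$left_flank) + 1)
    # reverse-complemented amplicon: detected on reverse strand and
    # re-oriented back to the forward sequence
    flr <- check_flanks(revcomp(amplicon), panel)
    expect_true(flr$has_left && flr$has_right)
    expect_equal(flr$strand, "reverse")
    expect_equal(flr$oriented_seq, amplicon)
    # random DNA: nothing found
    fl0 <- check_flanks(random_dna(400), panel)
    expect_false(fl0$has_left)
    expect_false(fl0$has_right)
    expect_true(is.na(fl0$strand))
  })
})

test_that("pattern calls on clean constructed reads match the built-in chains, including order and repeats", {
  refs <- test_refs()
  panel <- test_panel()
  cats <- test_categories()
  locus <- refs$locus
  withr::with_seed(5, {
    labels <- c(
      "Bf", "Br", "Ff", "Fr",
      "Ff,Br", "Br,Ff", "Bf,Ff", "Fr,Bf",
      "Bf,Bf", "Ff,Ff", "Ff,Fr",
      "Bf,Bf,Bf", "Ff,Br,Ff", "Br,Bf,Fr", "Fr,Fr,Fr"
    )
    reads <- tibble::tibble(
      read_id = labels,
      seq = purrr::map_chr(labels, function(l) {
        paste0(random_dna(31), pattern_reference(l, locus, refs$library))
      })
    )
    calls <- call_patterns(reads, panel, cats)
    expect_equal(calls$pattern, labels)
    expect_equal(
      calls$category,
      purrr::map_chr(labels, function(l) {
        paste(sort(sub("[fr]$", "", strsplit(l, ",")[[1]])), collapse = "")
      })
    )
    expect_true(all(calls$has_left_flank & calls$has_right_flank))
    # strand invariance: reverse-complemented reads call identically
    calls_rc <- call_patterns(mutate(reads, seq = revcomp(seq)), panel, cats)
    expect_equal(calls_rc$pattern, calls$pattern)
    expect_equal(calls_rc$category, calls$category)
  })
})

test_that("every called pattern's multiset equals its called category", {
  withr::with_seed(7, {
    refs <- test_refs()
    cfg <- simulation_config(refs,
      n_reads = 300, error_rate = 0.05, seed = 17,
      genomic_rate = 0, line1_rate = 0, cas9_rate = 0, u6_rate = 0,
      short_B_rate = 0, short_F_rate = 0
    )
    sim <- simulate_reads(cfg)
    calls <- call_patterns(sim$reads, test_panel(), test_categories())
    called <- calls[!calls$category %in%
      c("background", "ambiguous", "unclassified", "no_flanks"), ]
    expect_gt(nrow(called), 200)
    for (i in seq_len(nrow(called))) {
      expect_equal(
        paste(sort(sub("[fr]$", "", strsplit(called$pattern[i], ",")[[1]])), collapse = ""),
        called$category[i]
      )
    }
  })
})

test_that("background reads are called background and window overlaps resolve by probe content", {
  refs <- test_refs()
  panel <- test_panel()
  cats <- test_categories()
  locus <- refs$locus
  withr::with_seed(9, {
    bg <- paste0(random_dna(31), locus$left_flank, locus$right_flank)
    calls <- call_patterns(tibble::tibble(read_id = "bg", seq = bg), panel, cats)
    expect_equal(calls$category, "background")
    expect_equal(calls$pattern, "")
    # a read in overlapping BB / F windows with only F content resolves to F:
    # a cassette truncated to ~4700 bp product length sits in both windows
    keep <- 4700 - 332
    frag <- substr(fragment_seq(refs$library, "F"), 400, 399 + keep)
    read <- paste0(random_dna(31), locus$left_flank, frag, locus$right_flank)
    stopifnot(nchar(read) - 31 >= 3780, nchar(read) - 31 <= 5580) # in BB window too
    call2 <- call_patterns(tibble::tibble(read_id = "ovl", seq = read), panel, cats)
    expect_true(all(c("BB", "F") %in% call2$candidates[[1]]))
    expect_equal(call2$category, "F")
    expect_equal(call2$pattern, "Ff")
  })
})

test_that("proportions use the both-flank denominator and define the four report groups", {
  refs <- test_refs()
  withr::with_seed(11, {
    cfg <- simulation_config(refs,
      n_reads = 250, error_rate = 0, seed = 23,
      genomic_rate = 0, line1_rate = 0, cas9_rate = 0, u6_rate = 0,
      short_B_rate = 0, short_F_rate = 0
    )
    sim <- simulate_reads(cfg)
    calls <- call_patterns(sim$reads, test_panel(), test_categories())
    pr <- compute_proportions(calls)
    expect_equal(pr$denominator, sum(calls$has_left_flank & calls$has_right_flank))
    expect_lte(sum(pr$patterns$proportion), 1)
    expect_equal(sum(pr$patterns$n_reads) +
      sum(calls$category %in% c("background", "ambiguous", "unclassified")),
    pr$denominator)
    # groups partition the called reads
    expect_equal(sum(pr$groups$n_reads), sum(pr$patterns$n_reads))
    tr <- sim$truth
    expect_equal(
      pr$groups$n_reads[pr$groups$group == "single_F"],
      sum(calls$category == "F")
    )
    # error-free: called groups equal truth groups exactly
    expect_equal(
      sum(calls$category == "BF"),
      sum(tr$class == "pattern" & vapply(tr$pattern, is_complete_donor, logical(1)))
    )
    # tidy/glance accessors
    td <- tidy(pr)
    expect_true(all(c("category", "pattern", "group", "n_reads", "proportion") %in% names(td)))
    gl <- glance(pr)
    expect_equal(gl$denominator, pr$denominator)
    # zero-denominator flagging
    none <- calls[calls$category == "no_flanks", ]
    pr0 <- compute_proportions(none)
    expect_true(pr0$undefined)
  })
})

test_that("pattern references concatenate flanks and oriented fragments", {
  refs <- test_refs()
  locus <- refs$locus
  lib <- refs$library
  ref_bf <- pattern_reference("Ff,Br", locus, lib)
  expect_equal(nchar(ref_bf), 8032)
  expect_equal(
    ref_bf,
    paste0(
      locus$left_flank, fragment_seq(lib, "F"),
      revcomp(fragment_seq(lib, "B")), locus$right_flank
    )
  )
  expect_equal(nchar(pattern_reference("", locus, lib)), 332)
})
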