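#' Build the probe panel for a locus and fragment library
#'
#' Bundles every exact-match probe set the classifier needs: flank probes
#' (k = 17, step = 20 along each retained flank) used to verify that an
#' insertion sits at the target site, and per-component orientation probes
#' (default 20 evenly spaced 17-mers per component, reverse probes are
#' reverse complements) screened for uniqueness against the flanks, the
#' other components and any extra references.
#'
#' @param locus A [locus_model()].
#' @param library A [fragment_library()].
#' @param n_probes Probes per component orientation (default 20).
#' @param k Probe length (default 17).
#' @param flank_step Step between flank probe starts (default 20).
#' @param screen_extra Additional sequences component probes must not occur
#'   in (e.g. editing-plasmid references).
#' @return A `probe_panel` list with the probe tibble and a prebuilt
#'   `Biostrings::PDict` for fast exact matching.
#' @export
build_probe_panel <- function(locus, library, n_probes = 20, k = 17,
                              flank_step = 20, screen_extra = character()) {
  insertable <- library$name[library$insertable]
  comp_probes <- purrr::map_dfr(insertable, function(nm) {
    others <- library$seq[library$name != nm]
    pr <- component_probes(
      fragment_seq(library, nm),
      n = n_probes, k = k,
      screen_against = c(locus$left_flank, locus$right_flank, others, screen_extra),
      source_name = nm
    )
    pr$group <- nm
    pr
  })
  flank_l <- generate_probes(locus$left_flank,
    k = k, step = flank_step, "flank_left", anchor_end = TRUE
  )
  flank_l$orientation <- "forward"
  flank_l$group <- "flank_left"
  flank_r <- generate_probes(locus$right_flank,
    k = k, step = flank_step, "flank_right", anchor_end = TRUE
  )
  flank_r$orientation <- "forward"
  flank_r$group <- "flank_right"
  probes <- bind_rows(flank_l, flank_r, comp_probes)
  structure(
    list(
      probes = probes,
      pdict = Biostrings::PDict(Biostrings::DNAStringSet(probes$probe)),
      k = k, locus = locus, library = library
    ),
    class = "probe_panel"
  )
}

panel_hits <- function(seq, panel) {
  # exact probe hit start positions in one sequence
  m <- Biostrings::matchPDict(panel$pdict, Biostrings::DNAString(seq))
  si <- Biostrings::startIndex(m)
  lens <- lengths(si)
  list(idx = rep.int(seq_along(si), lens), start = as.integer(unlist(si)))
}

panel_hits_batch <- function(seqs, panel) {
  # one matchPDict call over all reads joined with N separators (probes are
  # N-free, so matches never cross a boundary); returns a per-read list of
  # hit tibbles in read-local coordinates
  n <- length(seqs)
  if (n == 0) return(list())
  lens <- nchar(seqs)
  offsets <- cumsum(c(0, head(lens + 1L, -1))) # start of each read - 1
  joined <- Biostrings::DNAString(paste(seqs, collapse = "N"))
  m <- Biostrings::matchPDict(panel$pdict, joined)
  si <- Biostrings::startIndex(m)
  k <- lengths(si)
  idx <- rep.int(seq_along(si), k)
  start <- as.integer(unlist(si))
  read <- findInterval(start, offsets + 1L)
  local <- start - offsets[read]
  ord <- order(read)
  split_read <- factor(read[ord], levels = seq_len(n))
  idx_by <- split(idx[ord], split_read)
  start_by <- split(local[ord], split_read)
  map(seq_len(n), function(i) list(idx = idx_by[[i]], start = start_by[[i]]))
}

flank_stats <- function(hits, panel) {
  pr <- panel$probes
  grp <- pr$group[hits$idx]
  li <- grp == "flank_left"
  ri <- grp == "flank_right"
  # project each hit back to the flank start it implies. Homology-arm
  # copies inside the insert also hit flank probes, but always downstream
  # (left arm) / upstream (right arm) of the genuine flank, so the genuine
  # flank is the leftmost (left) / rightmost (right) projection cluster.
  left_proj <- hits$start[li] - pr$source_start[hits$idx[li]] + 1L
  right_proj <- hits$start[ri] - pr$source_start[hits$idx[ri]] + 1L
  edge_cluster <- function(proj, side) {
    proj <- sort(proj)
    grp <- cumsum(c(1, diff(proj) > 150))
    keep <- if (side == "left") proj[grp == 1] else proj[grp == max(grp)]
    as.integer(round(median(keep)))
  }
  list(
    n_left = sum(li), n_right = sum(ri),
    med_left = if (any(li)) median(hits$start[li]) else NA_real_,
    med_right = if (any(ri)) median(hits$start[ri]) else NA_real_,
    # inner flank edges (Alb-L-r / Alb-R-l) from the projected flank starts
    albLr = if (any(li)) {
      edge_cluster(left_proj, "left") + nchar(panel$locus$left_flank) - 1L
    } else NA_integer_,
    albRl = if (any(ri)) edge_cluster(right_proj, "right") else NA_integer_
  )
}

#' Check flank anchors and strand of a read
#'
#' A flank is present when at least `min_hits` of its probes match on a
#' consistent strand; the strand is the orientation in which both flanks
#' appear in correct order (left before right). Absence is a result, not an
#' error.
#'
#' @param read Read sequence.
#' @param panel A [build_probe_panel()] result.
#' @param min_hits Minimum probe hits per flank (default 1).
#' @param .keep_hits Attach the oriented-strand probe hit table as the
#'   `"hits"` attribute (internal use by [call_patterns()]).
#' @return Tibble row: `has_left`, `has_right`, `strand` (`"forward"`,
#'   `"reverse"` or `NA`), `albLr`, `albRl` (projected inner flank edges on
#'   the oriented read), `oriented_seq`.
#' @export
check_flanks <- function(read, panel, min_hits = 1, .keep_hits = FALSE) {
  rc <- revcomp(read)
  f <- choose_strand(
    panel_hits(read, panel), panel_hits(rc, panel),
    read, rc, panel, min_hits,
    keep_hits = .keep_hits
  )
  out <- tibble(
    has_left = f$has_left, has_right = f$has_right, strand = f$strand,
    albLr = f$albLr, albRl = f$albRl, oriented_seq = f$oriented_seq
  )
  if (.keep_hits) attr(out, "hits") <- f$hits
  out
}

choose_strand <- function(hits_fwd, hits_rev, read, rc, panel, min_hits,
                          keep_hits = FALSE) {
  fwd <- flank_stats(hits_fwd, panel)
  rev <- flank_stats(hits_rev, panel)
  score <- function(s) {
    both <- s$n_left >= min_hits && s$n_right >= min_hits
    ordered <- both && s$med_left < s$med_right
    c(ordered, (s$n_left >= min_hits) + (s$n_right >= min_hits), s$n_left + s$n_right)
  }
  sf <- score(fwd)
  sr <- score(rev)
  use_rev <- (sr[1] > sf[1]) || (sr[1] == sf[1] && (sr[2] > sf[2] ||
    (sr[2] == sf[2] && sr[3] > sf[3])))
  s <- if (use_rev) rev else fwd
  has_left <- s$n_left >= min_hits
  has_right <- s$n_right >= min_hits
  list(
    has_left = has_left, has_right = has_right,
    strand = if (!has_left && !has_right) {
      NA_character_
    } else if (use_rev) "reverse" else "forward",
    albLr = s$albLr, albRl = s$albRl,
    oriented_seq = if (use_rev) rc else read,
    hits = if (keep_hits) {
      if (use_rev) hits_rev else hits_fwd
    }
  )
}

#' Probe search range for a category
#'
#' The perfect insert of a category spans amplicon positions
#' `len(left_flank) + 1` to `expected_length - len(right_flank)`. To avoid
#' retrieving erroneous probe hits near the junctions the span is shrunk
#' inward by `margin` bp per side (default 300, reproducing the published
#' single-backbone range 447--2020 from the perfect span 147--2320). A
#' margin that empties the range falls back to the full span with a
#' warning.
#'
#' @param expected_length Category expected product length (bp).
#' @param locus A [locus_model()].
#' @param margin Inward shrink per side in bp, or a fraction of the insert
#'   span when `< 1`.
#' @return Integer vector `c(lo, hi)` in amplicon coordinates.
#' @export
probe_search_range <- function(expected_length, locus, margin = 300) {
  lo0 <- nchar(locus$left_flank) + 1L
  hi0 <- expected_length - nchar(locus$right_flank)
  m <- if (margin < 1) round(margin * (hi0 - lo0 + 1)) else margin
  lo <- lo0 + m
  hi <- hi0 - m
  if (lo >= hi) {
    warn("probe search range collapsed; falling back to full insert span")
    return(c(lo = as.integer(lo0), hi = as.integer(hi0)))
  }
  c(lo = as.integer(lo), hi = as.integer(hi))
}

split_copies <- function(positions, copies) {
  # partition sorted hit positions into `copies` groups at the largest gaps
  positions <- sort(positions)
  if (copies <= 1 || length(positions) <= copies) {
    if (copies <= 1) return(list(positions))
    # too few hits to split informatively: replicate the median
    return(rep(list(positions), copies))
  }
  gaps <- diff(positions)
  cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(copies - 1)])
  grp <- findInterval(seq_along(positions), cuts + 1L) + 1L
  unname(split(positions, grp))
}

call_one_category <- function(comp_hits, composition, range_lo, range_hi, min_hits) {
  # comp_hits: list(group, orientation, start) of component probe hits
  inr <- comp_hits$start >= range_lo & comp_hits$start <= range_hi
  g <- comp_hits$group[inr]
  o <- comp_hits$orientation[inr]
  s <- comp_hits$start[inr]
  key <- paste(g, o)
  tab <- table(key)
  present_keys <- names(tab)[tab >= min_hits]
  present_group <- sub(" .*$", "", present_keys)
  present_ori <- sub("^.* ", "", present_keys)
  comp_counts <- table(composition)
  if (!setequal(unique(present_group), names(comp_counts))) return(NULL)
  chain_comp <- character()
  chain_ori <- character()
  chain_pos <- numeric()
  for (comp in names(comp_counts)) {
    copies <- comp_counts[[comp]]
    ori_present <- present_ori[present_group == comp]
    if (length(ori_present) > copies) return(NULL)
    pos_by_ori <- map(ori_present, function(oo) s[g == comp & o == oo])
    if (length(ori_present) == 1) {
      copies_by_ori <- copies
    } else {
      h <- map_int(pos_by_ori, length)
      c1 <- min(max(1L, round(copies * h[1] / sum(h))), copies - 1L)
      copies_by_ori <- c(c1, copies - c1)
    }
    for (j in seq_along(ori_present)) {
      for (grp in split_copies(pos_by_ori[[j]], copies_by_ori[j])) {
        chain_comp <- c(chain_comp, comp)
        chain_ori <- c(chain_ori, ori_present[j])
        chain_pos <- c(chain_pos, median(grp))
      }
    }
  }
  ord <- order(chain_pos)
  list(
    chain = tibble(component = chain_comp[ord], orientation = chain_ori[ord]),
    hits = tibble(
      group = sub(" .*$", "", names(tab)),
      orientation = sub("^.* ", "", names(tab)),
      hits = as.integer(tab)
    )
  )
}

#' Call insertion patterns for a read table
#'
#' The core classifier. For each read: verify both flank anchors and the
#' strand, bin the read length into candidate category windows, scan each
#' component-orientation probe set within the category's restricted
#' position range, and emit one orientation-pattern call. A read matching
#' more than one candidate category is `"ambiguous"`; a read in the
#' background window whose extracted insert is (near-)empty is
#' `"background"`; a read with both flanks matching no candidate is
#' `"unclassified"` and is a candidate for the foreign-insert scan.
#'
#' @param reads Tibble with columns `read_id`, `seq` (typically one
#'   demultiplexed barcode).
#' @param panel A [build_probe_panel()] result.
#' @param categories Category table from [enumerate_categories()].
#' @param min_hits Probe hits required to declare a component orientation
#'   present (default 2; exact 17-mers make chance double hits negligible).
#' @param margin Inward probe-range margin, see [probe_search_range()].
#' @param flank_min_hits Probe hits required per flank (default 1).
#' @param background_fraction,background_rounding Window rule for the
#'   background (no-insert) length window.
#' @param background_max_insert Maximum projected insert length (bp) for a
#'   background call (default 30).
#' @return Tibble of class `read_calls`: `read_id`, `length`, `strand`,
#'   `has_left_flank`, `has_right_flank`, `insert_est`, `candidates`
#'   (list), `category`, `pattern`, `albLr`, `albRl`, `oriented_seq`,
#'   `hits` (list).
#' @export
call_patterns <- function(reads, panel, categories, min_hits = 2, margin = 300,
                          flank_min_hits = 1,
                          background_fraction = 0.20,
                          background_rounding = "nearest100",
                          background_max_insert = 30) {
  locus <- panel$locus
  bg_len <- background_length(locus)
  bg_win <- grouping_window(bg_len, background_fraction, background_rounding)
  ranges <- map(categories$expected_length, probe_search_range, locus = locus, margin = margin)

  # pass 1: flank anchors for every read (batched exact probe matching)
  rc_seqs <- if (nrow(reads) > 0) revcomp(reads$seq) else character()
  hits_f <- panel_hits_batch(reads$seq, panel)
  hits_r <- panel_hits_batch(rc_seqs, panel)
  flanks <- map(seq_len(nrow(reads)), function(i) {
    choose_strand(hits_f[[i]], hits_r[[i]], reads$seq[i], rc_seqs[i],
      panel, flank_min_hits,
      keep_hits = TRUE
    )
  })
  # Homology-arm copies inside the insert can capture an anchor when every
  # probe at the genuine flank is destroyed by noise. Such anchors imply an
  # absurd pre-flank prefix (left) or post-flank suffix (right); estimate
  # the typical prefix/suffix from consistent reads and re-derive anomalous
  # anchors from the opposite flank and the read length.
  lenL <- nchar(locus$left_flank)
  lenR <- nchar(locus$right_flank)
  pre <- map_dbl(flanks, function(f) {
    if (isTRUE(f$has_left)) f$albLr - lenL else NA_real_
  })
  suf <- map_dbl(seq_along(flanks), function(i) {
    f <- flanks[[i]]
    if (isTRUE(f$has_right)) nchar(f$oriented_seq) - (f$albRl + lenR - 1L) else NA_real_
  })
  p_hat <- median(pre[!is.na(pre) & pre >= -20 & pre <= 300], na.rm = TRUE)
  s_hat <- median(suf[!is.na(suf) & suf >= -20 & suf <= 300], na.rm = TRUE)
  if (is.na(p_hat)) p_hat <- 0
  if (is.na(s_hat)) s_hat <- 0
  flanks <- map(seq_along(flanks), function(i) {
    f <- flanks[[i]]
    if (!isTRUE(f$has_left) || !isTRUE(f$has_right)) return(f)
    len_i <- nchar(f$oriented_seq)
    ins_len <- len_i - bg_len - p_hat - s_hat
    if (!is.na(pre[i]) && pre[i] > p_hat + 200) {
      f$albLr <- as.integer(round(f$albRl - 1L - max(0, ins_len)))
    }
    if (!is.na(suf[i]) && suf[i] > s_hat + 200) {
      f$albRl <- as.integer(round(f$albLr + 1L + max(0, ins_len)))
    }
    f
  })

  n <- nrow(reads)
  pr <- panel$probes
  v_len <- integer(n)
  v_strand <- character(n)
  v_hl <- logical(n)
  v_hr <- logical(n)
  v_ins <- rep(NA_integer_, n)
  v_cat <- rep("unclassified", n)
  v_pat <- rep(NA_character_, n)
  v_albLr <- rep(NA_integer_, n)
  v_albRl <- rep(NA_integer_, n)
  v_seq <- character(n)
  l_cand <- rep(list(character()), n)
  l_hits <- rep(list(NULL), n)
  for (i in seq_len(n)) {
    fl <- flanks[[i]]
    len <- nchar(reads$seq[i])
    v_len[i] <- len
    v_strand[i] <- fl$strand
    v_hl[i] <- fl$has_left
    v_hr[i] <- fl$has_right
    v_albLr[i] <- fl$albLr %||% NA_integer_
    v_albRl[i] <- fl$albRl %||% NA_integer_
    v_seq[i] <- fl$oriented_seq
    if (!(fl$has_left && fl$has_right)) {
      v_cat[i] <- "no_flanks"
      next
    }
    insert_est <- max(0L, fl$albRl - fl$albLr - 1L)
    v_ins[i] <- insert_est
    # amplicon coordinate offset: read position where the left flank starts
    offset <- fl$albLr - nchar(locus$left_flank)
    cand_idx <- which(len >= categories$lo & len <= categories$hi)
    l_cand[[i]] <- categories$category[cand_idx]
    is_bg_len <- len >= bg_win[1] && len <= bg_win[2]
    if (is_bg_len && insert_est <= background_max_insert) {
      v_cat[i] <- "background"
      v_pat[i] <- ""
      next
    }
    if (length(cand_idx) == 0) next
    h <- fl$hits
    comp_sel <- !(pr$group[h$idx] %in% c("flank_left", "flank_right"))
    comp_hits <- list(
      group = pr$group[h$idx[comp_sel]],
      orientation = pr$orientation[h$idx[comp_sel]],
      start = h$start[comp_sel]
    )
    matches <- list()
    for (ci in cand_idx) {
      r <- ranges[[ci]]
      res <- call_one_category(
        comp_hits, categories$composition[[ci]],
        range_lo = r[1] + offset, range_hi = r[2] + offset,
        min_hits = min_hits
      )
      if (!is.null(res)) matches[[categories$category[ci]]] <- res
    }
    if (length(matches) == 1) {
      v_cat[i] <- names(matches)
      v_pat[i] <- chain_label(matches[[1]]$chain)
      l_hits[[i]] <- matches[[1]]$hits
    } else if (length(matches) > 1) {
      v_cat[i] <- "ambiguous"
    }
  }
  out <- tibble(
    read_id = reads$read_id, length = v_len, strand = v_strand,
    has_left_flank = v_hl, has_right_flank = v_hr, insert_est = v_ins,
    candidates = l_cand, category = v_cat, pattern = v_pat,
    albLr = v_albLr, albRl = v_albRl, oriented_seq = v_seq,
    hits = map(l_hits, function(x) x %||% tibble())
  )
  class(out) <- c("read_calls", class(out))
  out
}

#' Pattern and category proportions for one sample
#'
#' The denominator is the number of reads carrying both flank anchors
#' (default), or all reads. Report groups follow the field's convention:
#' single-F, single-B, complete donor (exactly one F and one B) and
#' compound (all other called categories).
#'
#' @param calls A `read_calls` tibble from [call_patterns()].
#' @param denominator `"both_flanks"` (default) or `"all"`.
#' @param cassette,backbone Component names of the donor cassette and the
#'   plasmid backbone used to form the report groups.
#' @return A `proportion_table` list with tibbles `patterns`, `categories`,
#'   `groups` and fields `denominator`, `denominator_mode`.
#' @export
compute_proportions <- function(calls, denominator = c("both_flanks", "all"),
                                cassette = "F", backbone = "B") {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "both_flanks") {
    sum(calls$has_left_flank & calls$has_right_flank)
  } else {
    nrow(calls)
  }
  called <- calls[!calls$category %in% c("no_flanks", "background", "ambiguous", "unclassified"), ]
  pat <- called |>
    count(.data$category, .data$pattern, name = "n_reads") |>
    mutate(proportion = if (denom > 0) .data$n_reads / denom else NA_real_)
  cat_tab <- calls |>
    count(.data$category, name = "n_reads") |>
    mutate(proportion = if (denom > 0) .data$n_reads / denom else NA_real_)
  grp_of <- function(category) {
    dplyr::case_when(
      category == cassette ~ "single_F",
      category == backbone ~ "single_B",
      category == canonical_category_name(c(cassette, backbone)) ~ "complete_donor",
      TRUE ~ "compound"
    )
  }
  groups <- called |>
    mutate(group = grp_of(.data$category)) |>
    count(.data$group, name = "n_reads") |>
    mutate(proportion = if (denom > 0) .data$n_reads / denom else NA_real_)
  structure(
    list(
      patterns = pat, categories = cat_tab, groups = groups,
      denominator = denom, denominator_mode = denominator,
      undefined = denom == 0
    ),
    class = "proportion_table"
  )
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("<proportion_table> denominator (", x$denominator_mode, "): ",
    x$denominator, " reads\n",
    sep = ""
  )
  print(x$groups)
  invisible(x)
}

#' Reference sequence for an orientation pattern
#'
#' Left flank, then each chain component in its orientation, then the right
#' flank; suitable for external alignment and inspection of grouped reads.
#'
#' @param pattern Pattern label (e.g. `"Ff,Br"`) or chain tibble.
#' @param locus A [locus_model()].
#' @param library A [fragment_library()].
#' @return A single DNA character string.
#' @export
pattern_reference <- function(pattern, locus, library) {
  chain <- if (is.character(pattern)) parse_chain_label(pattern) else pattern
  mids <- map_chr(seq_len(nrow(chain)), function(i) {
    s <- fragment_seq(library, chain$component[i])
    if (chain$orientation[i] == "reverse") revcomp(s) else s
  })
  paste0(locus$left_flank, paste(mids, collapse = ""), locus$right_flank)
}

#' Write per-pattern reference FASTA
#'
#' @param patterns Character vector of pattern labels.
#' @param locus,library Locus model and fragment library.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pattern_references <- function(patterns, locus, library, path) {
  tbl <- tibble(
    name = gsub(",", "_", patterns),
    seq = map_chr(patterns, pattern_reference, locus = locus, library = library)
  )
  write_fasta_tbl(tbl, path)
}
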