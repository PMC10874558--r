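#' Describe the edited locus
#'
#' A locus model holds the retained genomic flanks on either side of the
#' CRISPR cut, the homology arms of the donor (either may be empty), and
#' optional excluded genomic regions for the foreign-insert scan. The
#' background (no-insert) amplicon is `left_flank` followed directly by
#' `right_flank`; the cut position is the 1-based offset of the break in
#' that concatenation, i.e. `nchar(left_flank)`.
#'
#' @param left_flank,right_flank Retained genomic DNA left/right of the cut.
#' @param left_arm,right_arm Homology-arm sequences carried by the donor;
#'   `""` for an armless side (e.g. an HA85-0 design's right side).
#' @param exclusion_regions Tibble with columns `contig`, `start`, `end`
#'   (0-based half-open, BED convention) of genomic regions to ignore when
#'   aligning inserts to a genome, or `NULL`.
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(left_flank, right_flank, left_arm = "", right_arm = "",
                        exclusion_regions = NULL) {
  if (!nzchar(left_flank) || !nzchar(right_flank)) {
    abort("left_flank and right_flank must be non-empty DNA sequences")
  }
  structure(
    list(
      left_flank = toupper(left_flank),
      right_flank = toupper(right_flank),
      cut_position = nchar(left_flank),
      left_arm = toupper(left_arm),
      right_arm = toupper(right_arm),
      exclusion_regions = exclusion_regions
    ),
    class = "locus_model"
  )
}

#' @export
print.locus_model <- function(x, ...) {
  cat(
    "<locus_model> flanks ", nchar(x$left_flank), "+", nchar(x$right_flank),
    " bp (background ", background_length(x), " bp), arms ",
    nchar(x$left_arm), "/", nchar(x$right_arm), " bp\n",
    sep = ""
  )
  invisible(x)
}

#' Background amplicon length
#'
#' @param locus A [locus_model()].
#' @return Integer length of the no-insert product in bp.
#' @export
background_length <- function(locus) {
  nchar(locus$left_flank) + nchar(locus$right_flank)
}

#' Build a fragment library
#'
#' Named insertable components (e.g. the donor cassette `"F"` and the
#' plasmid backbone `"B"`) plus scan-only references such as circular
#' editing-plasmid unique regions.
#'
#' @param ... Named DNA sequences.
#' @param insertable Character vector of names treated as insertable donor
#'   pieces; defaults to all.
#' @return Tibble of class `fragment_library` with columns `name`, `seq`,
#'   `length`, `insertable`.
#' @export
fragment_library <- function(..., insertable = NULL) {
  seqs <- list(...)
  if (length(seqs) == 1 && is.list(seqs[[1]]) && is.null(names(seqs))) {
    seqs <- seqs[[1]]
  }
  if (length(seqs) == 0) abort("fragment library must contain at least one component")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))) || anyDuplicated(names(seqs))) {
    abort("fragment components must have unique non-empty names")
  }
  insertable <- insertable %||% names(seqs)
  out <- tibble(
    name = names(seqs),
    seq = toupper(unlist(seqs, use.names = FALSE)),
    length = nchar(unlist(seqs, use.names = FALSE)),
    insertable = names(seqs) %in% insertable
  )
  class(out) <- c("fragment_library", class(out))
  out
}

#' Look up a fragment component
#'
#' @param library A [fragment_library()].
#' @param name Component name(s).
#' @return Sequence(s) / length(s); unknown names are an error.
#' @export
fragment_seq <- function(library, name) {
  i <- match(name, library$name)
  if (anyNA(i)) abort(paste0("unknown fragment component: ", paste(name[is.na(i)], collapse = ", ")))
  library$seq[i]
}

#' @rdname fragment_seq
#' @export
fragment_len <- function(library, name) {
  i <- match(name, library$name)
  if (anyNA(i)) abort(paste0("unknown fragment component: ", paste(name[is.na(i)], collapse = ", ")))
  library$length[i]
}

canonical_category_name <- function(composition) {
  paste(sort(composition), collapse = "")
}

#' Enumerate insertion categories
#'
#' Every unordered multiset of 1..`max_pieces` insertable components, each
#' with its expected second-PCR product length (background plus component
#' lengths) and a read-length grouping window. With the two donor pieces
#' released by a double-cut donor and up to three captured pieces this is
#' the nine-category scheme B, F, BF, BB, FF, BBF, BFF, BBB, FFF.
#'
#' @param library A [fragment_library()].
#' @param locus A [locus_model()].
#' @param max_pieces Maximum number of co-integrated pieces (default 3).
#' @param fraction Half-width of the grouping window as a fraction of the
#'   expected product length (default 0.20).
#' @param rounding Window rounding rule, `"nearest100"` (default) or
#'   `"exact"`; see [grouping_window()].
#' @return Tibble with columns `category`, `composition` (list), `n_pieces`,
#'   `expected_length`, `lo`, `hi`.
#' @export
enumerate_categories <- function(library, locus, max_pieces = 3,
                                 fraction = 0.20, rounding = c("nearest100", "exact")) {
  rounding <- match.arg(rounding)
  if (max_pieces < 1) abort("max_pieces must be >= 1")
  comp_names <- library$name[library$insertable]
  if (length(comp_names) == 0) abort("fragment library has no insertable components")
  multisets <- function(k) {
    if (k == 1) return(as.list(comp_names))
    combos <- utils::combn(length(comp_names) + k - 1, k, simplify = FALSE)
    map(combos, function(idx) comp_names[idx - seq_len(k) + 1L])
  }
  comps <- purrr::flatten(map(seq_len(max_pieces), multisets))
  out <- tibble(
    category = map_chr(comps, canonical_category_name),
    composition = map(comps, sort),
    n_pieces = map_int(comps, length),
    expected_length = map_int(comps, ~ expected_length(.x, library, locus))
  )
  win <- map(out$expected_length, ~ grouping_window(.x, fraction, rounding))
  out$lo <- map_dbl(win, 1)
  out$hi <- map_dbl(win, 2)
  out
}

#' Expected product length of a composition
#'
#' Background amplicon length plus the summed lengths of the composition's
#' components. The empty composition gives the background length itself.
#'
#' @param composition Character vector of component names (a multiset).
#' @param library A [fragment_library()].
#' @param locus A [locus_model()].
#' @return Integer expected length in bp.
#' @export
expected_length <- function(composition, library, locus) {
  bg <- background_length(locus)
  if (length(composition) == 0) return(as.integer(bg))
  as.integer(bg + sum(fragment_len(library, composition)))
}

#' Read-length grouping window
#'
#' Symmetric window around an expected product length. The half-width is
#' `fraction` of the expected length; with `rounding = "nearest100"` it is
#' rounded to the nearest 100 bp (so the single-backbone 2506 bp product at
#' 20% gives the window 2006--3006), with `"exact"` the bounds are rounded
#' to the nearest bp.
#'
#' @param expected_length Expected product length in bp.
#' @param fraction Half-width as a fraction of `expected_length`
#'   (`0 <= fraction < 1`).
#' @param rounding `"nearest100"` or `"exact"`.
#' @return Numeric vector `c(lo, hi)`; `lo` never drops below 1.
#' @export
grouping_window <- function(expected_length, fraction = 0.20,
                            rounding = c("nearest100", "exact")) {
  rounding <- match.arg(rounding)
  if (fraction < 0 || fraction >= 1) abort("fraction must be in [0, 1)")
  pad <- fraction * expected_length
  if (rounding == "nearest100") {
    pad <- round(pad / 100) * 100
    lo <- expected_length - pad
    hi <- expected_length + pad
  } else {
    lo <- round(expected_length - pad)
    hi <- round(expected_length + pad)
  }
  c(lo = max(1, lo), hi = hi)
}

#' Enumerate orientation-resolved insertion patterns
#'
#' All ordered chains of `n_pieces` (component, orientation) elements over
#' the insertable components, each in forward (`f`) or reverse (`r`)
#' orientation: `(2 * n_components) ^ n_pieces` patterns. Two components and
#' three pieces give the 64 three-element integration patterns.
#'
#' @param n_pieces Chain length (0 gives the single empty chain).
#' @param library A [fragment_library()].
#' @return Tibble with columns `pattern` (e.g. `"Ff,Br"`), `chain` (list of
#'   tibbles with `component`, `orientation`), `n_pieces`, `category`.
#' @export
enumerate_orientation_patterns <- function(n_pieces, library) {
  if (n_pieces < 0) abort("n_pieces must be >= 0")
  comp_names <- library$name[library$insertable]
  elements <- as.vector(outer(comp_names, c("f", "r"), paste0))
  if (n_pieces == 0) {
    return(tibble(
      pattern = "", chain = list(tibble(component = character(), orientation = character())),
      n_pieces = 0L, category = ""
    ))
  }
  grids <- do.call(expand.grid, c(
    rep(list(elements), n_pieces),
    list(stringsAsFactors = FALSE)
  ))
  chains <- pmap(grids, function(...) {
    el <- c(...)
    tibble(
      component = sub("[fr]$", "", el),
      orientation = if_else(grepl("f$", el), "forward", "reverse")
    )
  })
  tibble(
    pattern = map_chr(chains, chain_label),
    chain = chains,
    n_pieces = as.integer(n_pieces),
    category = map_chr(chains, ~ canonical_category_name(.x$component))
  )
}

#' Compact label for an ordered fragment chain
#'
#' @param chain Tibble with columns `component`, `orientation`.
#' @return A string such as `"Ff,Br"`; `""` for the empty chain.
#' @export
chain_label <- function(chain) {
  if (nrow(chain) == 0) return("")
  paste(paste0(chain$component, substr(chain$orientation, 1, 1)), collapse = ",")
}

parse_chain_label <- function(label) {
  if (is.na(label) || !nzchar(label)) {
    return(tibble(component = character(), orientation = character()))
  }
  el <- strsplit(label, ",", fixed = TRUE)[[1]]
  tibble(
    component = sub("[fr]$", "", el),
    orientation = if_else(grepl("f$", el), "forward", "reverse")
  )
}

#' Export the category table as TSV
#'
#' @param categories Result of [enumerate_categories()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(categories, path) {
  write_tsv_flat(categories, path)
}
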