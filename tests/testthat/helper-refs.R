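# Shared synthetic references and small utilities for the test suite.
# Everything is generated in code under fixed seeds; no fixture files.

suppressPackageStartupMessages(library(dplyr))

test_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      withr::with_seed(20260922, cache <<- sim_references())
    }
    cache
  }
})

test_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_probe_panel(test_refs()$locus, test_refs()$library)
    cache
  }
})

test_categories <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- enumerate_categories(test_refs()$library, test_refs()$locus)
    }
    cache
  }
})

# naive sliding-window oracle for probe generation
oracle_probes <- function(source, k, step) {
  starts <- seq(1, nchar(source), by = step)
  starts <- starts[starts + k - 1 <= nchar(source)]
  substring(source, starts, starts + k - 1)
}

# brute-force multiset enumeration oracle (sorted, deduplicated tuples)
oracle_multisets <- function(elements, max_pieces) {
  out <- character()
  for (k in seq_len(max_pieces)) {
    grids <- do.call(expand.grid, c(rep(list(elements), k), list(stringsAsFactors = FALSE)))
    out <- c(out, unique(apply(grids, 1, function(r) paste(sort(r), collapse = ""))))
  }
  unique(out)
}

# simple Levenshtein distance via base R (adist) for noise-model checks
edit_distance <- function(a, b) as.integer(utils::adist(a, b))

# mutate one position of a sequence
mutate_seq <- function(seq, pos, type, base = "A") {
  chars <- strsplit(seq, "")[[1]]
  if (type == "sub") {
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
  } else if (type == "del") {
    chars <- chars[-pos]
  } else if (type == "ins") {
    chars <- append(chars, base, after = pos - 1)
  }
  paste(chars, collapse = "")
}

is_complete_donor <- function(pattern) {
  el <- strsplit(pattern, ",")[[1]]
  length(el) == 2 && setequal(sub("[fr]$", "", el), c("F", "B"))
}
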