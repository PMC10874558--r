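#' Assemble a run configuration
#'
#' All stage parameters with their defaults, fully serializable to YAML;
#' [run_pipeline()] writes the effective configuration next to its outputs
#' so a run can be reproduced byte-for-byte.
#'
#' @param ... Overrides of the default parameters.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    max_pieces = 3,
    window_fraction = 0.20,
    window_rounding = "nearest100",
    probe_k = 17,
    flank_probe_step = 20,
    n_component_probes = 20,
    min_hits = 2,
    flank_min_hits = 1,
    margin = 300,
    demux_min_hits = 1,
    search_prefix_bp = 200,
    background_max_insert = 30,
    min_identity = 80,
    min_genomic_len = 50,
    d100_threshold = 100,
    d100_window = 50,
    cas9_probe_step = 100,
    u6_probe_step = 40,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown run_config parameters: ", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = c("run_config", "list"))
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML path.
#' @return `path` / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a read set
#'
#' Demultiplexing, per-barcode pattern calling, repair classification,
#' foreign-insert scanning and deletion metrics, aggregated into a single
#' report bundle. Per-stage read counts are logged to stderr so the
#' partition invariants (every read in exactly one bin) can be audited
#' from the logs.
#'
#' @param reads Read tibble (`read_id`, `seq`) or a FASTQ path.
#' @param specs List of [barcode_spec()] objects (or `NULL` to skip
#'   demultiplexing and treat all reads as one sample).
#' @param locus A [locus_model()].
#' @param library A [fragment_library()].
#' @param genome,line1,exclusions Optional foreign-scan references.
#' @param config A [run_config()].
#' @param outdir Optional output directory for report files (TSV + JSON +
#'   effective config).
#' @param verbose Log per-stage counts (default TRUE).
#' @return A `pipeline_report` list: per-barcode `calls`, `proportions`,
#'   `repair`, `foreign`, `deletion`, plus `demux_summary` and `config`.
#' @export
run_pipeline <- function(reads, specs, locus, library, genome = NULL,
                         line1 = NULL, exclusions = NULL,
                         config = run_config(), outdir = NULL, verbose = TRUE) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq_tbl(reads)
  say <- function(...) if (verbose) message(sprintf(...))
  say("parsed %d reads", nrow(reads))

  categories <- enumerate_categories(
    library, locus,
    max_pieces = config$max_pieces,
    fraction = config$window_fraction, rounding = config$window_rounding
  )
  scan_only <- library$seq[!library$insertable]
  panel <- build_probe_panel(locus, library,
    n_probes = config$n_component_probes, k = config$probe_k,
    flank_step = config$flank_probe_step
  )
  cas9_probes <- if ("cas9" %in% library$name) {
    generate_probes(fragment_seq(library, "cas9"), config$probe_k,
      step = config$cas9_probe_step, source_name = "cas9"
    )
  }
  u6_probes <- if ("u6" %in% library$name) {
    generate_probes(fragment_seq(library, "u6"), config$probe_k,
      step = config$u6_probe_step, source_name = "u6"
    )
  }

  if (!is.null(specs)) {
    dm <- demultiplex(reads, specs,
      min_hits = config$demux_min_hits,
      search_prefix_bp = config$search_prefix_bp
    )
    demux_summary <- attr(dm, "summary")
    say(
      "demux: %d assigned / %d unassigned",
      sum(dm$barcode != "unassigned"), sum(dm$barcode == "unassigned")
    )
  } else {
    dm <- mutate(reads, barcode = "sample", strand_used = NA_character_)
    demux_summary <- tibble(barcode = "sample", n_reads = nrow(reads), fraction = 1)
  }

  wt_amplicon <- paste0(locus$left_flank, locus$right_flank)
  bg_win <- grouping_window(nchar(wt_amplicon), config$window_fraction, config$window_rounding)
  bcs <- if (is.null(specs)) "sample" else setdiff(unique(dm$barcode), "unassigned")
  per_barcode <- map(bcs, function(bc) {
    sub <- dm[dm$barcode == bc, ]
    calls <- call_patterns(sub, panel, categories,
      min_hits = config$min_hits, margin = config$margin,
      flank_min_hits = config$flank_min_hits,
      background_fraction = config$window_fraction,
      background_rounding = config$window_rounding,
      background_max_insert = config$background_max_insert
    )
    say(
      "%s: %d called / %d background / %d ambiguous / %d unclassified / %d no-flank",
      bc,
      sum(!calls$category %in% c("background", "ambiguous", "unclassified", "no_flanks")),
      sum(calls$category == "background"), sum(calls$category == "ambiguous"),
      sum(calls$category == "unclassified"), sum(calls$category == "no_flanks")
    )
    props <- compute_proportions(calls)
    repair <- classify_repairs(calls, locus, min_identity = config$min_identity)
    foreign <- scan_foreign(calls, panel,
      cas9_probes = cas9_probes, u6_probes = u6_probes,
      genome = genome, line1 = line1,
      exclusions = exclusions %||% locus$exclusion_regions,
      min_genomic_len = config$min_genomic_len,
      min_identity = config$min_identity
    )
    bg_reads <- calls[calls$category == "background" |
      (calls$has_left_flank & calls$has_right_flank &
        calls$length <= bg_win[2] & calls$category == "unclassified" &
        calls$insert_est <= config$background_max_insert), ]
    deln <- if (nrow(bg_reads) > 0) {
      # typical barcode+primer prefix length, from the flank anchors of
      # confidently anchored reads
      p_trim <- stats::median(calls$albLr - nchar(locus$left_flank), na.rm = TRUE)
      p_trim <- if (is.finite(p_trim)) max(0, round(p_trim)) else 0
      aln <- align_to_amplicon(
        tibble(read_id = bg_reads$read_id, seq = bg_reads$oriented_seq), wt_amplicon,
        trim_prefix = p_trim
      )
      deletion_report(aln, nchar(wt_amplicon), locus$cut_position,
        threshold = config$d100_threshold, window = config$d100_window
      )
    }
    list(
      barcode = bc, calls = calls, proportions = props,
      repair = repair, foreign = foreign, deletion = deln
    )
  })
  names(per_barcode) <- map_chr(per_barcode, "barcode")

  report <- structure(
    list(
      samples = per_barcode, demux_summary = demux_summary,
      categories = categories, config = config,
      n_reads = nrow(reads), schema_version = "1.0"
    ),
    class = "pipeline_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(
    "<pipeline_report> ", x$n_reads, " reads, ",
    length(x$samples), " sample(s)\n",
    sep = ""
  )
  for (s in x$samples) {
    cat("--", s$barcode, "--\n")
    print(s$proportions)
  }
  invisible(x)
}

report_json_list <- function(report) {
  list(
    schema_version = report$schema_version,
    n_reads = report$n_reads,
    demux = report$demux_summary,
    samples = map(report$samples, function(s) {
      list(
        barcode = s$barcode,
        denominator = s$proportions$denominator,
        groups = s$proportions$groups,
        categories = s$proportions$categories,
        patterns = s$proportions$patterns,
        repair = attr(s$repair, "summary"),
        foreign = summarise_foreign(s$foreign),
        deletion = if (!is.null(s$deletion)) {
          list(
            deletion_index = s$deletion$deletion_index,
            d100 = s$deletion$d100, n_reads = s$deletion$n_reads
          )
        }
      )
    })
  )
}

#' Write a pipeline report bundle
#'
#' Per-read calls, proportion tables and foreign segments as TSV, the
#' aggregate report as versioned JSON, and the effective run configuration
#' as YAML.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_flat(report$demux_summary, file.path(outdir, "demux_summary.tsv"))
  write_tsv_flat(
    select(report$categories, -"composition") |>
      mutate(composition = map_chr(report$categories$composition, paste, collapse = "+")),
    file.path(outdir, "categories.tsv")
  )
  for (s in report$samples) {
    pre <- file.path(outdir, s$barcode)
    write_tsv_flat(
      select(s$calls, -"oriented_seq", -"hits", -"candidates"),
      paste0(pre, "_calls.tsv")
    )
    write_tsv_flat(s$proportions$patterns, paste0(pre, "_patterns.tsv"))
    write_tsv_flat(s$proportions$groups, paste0(pre, "_groups.tsv"))
    write_tsv_flat(s$repair, paste0(pre, "_repair.tsv"))
    segs <- purrr::map_dfr(seq_len(nrow(s$foreign)), function(i) {
      f <- s$foreign$segments[[i]]
      if (nrow(f) == 0) return(NULL)
      mutate(f, read_id = s$foreign$read_id[i], .before = 1)
    })
    if (is.null(segs) || nrow(segs) == 0) {
      segs <- tibble(
        read_id = character(), class = character(), contig = character(),
        s_start = integer(), s_end = integer(), q_start = integer(),
        q_end = integer(), identity = double(), strand = character()
      )
    }
    write_tsv_flat(segs, paste0(pre, "_foreign_segments.tsv"))
  }
  jsonlite::write_json(report_json_list(report), file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  write_run_config(report$config, file.path(outdir, "effective_config.yaml"))
  invisible(outdir)
}
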