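#' Run the profiling stage: trim, filter, collapse, assign, count
#'
#' Composes the read-level operations over a set of stage libraries and the
#' reference catalogs, producing the per-stage class accounting (raw reads,
#' post-trim, length-window reads, per-class mapped totals) and the
#' per-feature count table that feeds the expression stage.
#'
#' @param libraries Named list (by stage) of read tibbles or FASTA/FASTQ
#'   paths. Tibbles may be raw (`seq`) or collapsed (`seq`, `count`).
#' @param catalogs List of [sequence_catalog()] tibbles (known miRNA, ncRNA,
#'   CDS, genome, any subset).
#' @param adapter 3' adapter to trim; `NULL` skips trimming.
#' @param min_len,max_len Length window (defaults 18-30).
#' @param max_flank IsomiR tolerance for known-miRNA matching.
#' @return List: `counts` (long feature count tibble), `library_totals`
#'   (named vector of post-trim total RNA reads per stage -- the TPM
#'   denominator), `window_totals` (reads inside the length window),
#'   `assigned` (per-stage assigned collapsed reads), `log` (per-stage
#'   class accounting tibble).
#' @export
run_profile <- function(libraries, catalogs, adapter = NULL, min_len = 18L,
                        max_len = 30L, max_flank = 3L) {
  stopifnot(length(names(libraries)) == length(libraries))
  out_counts <- list(); out_log <- list(); out_assigned <- list()
  totals <- numeric(0); win_totals <- numeric(0)
  for (st in names(libraries)) {
    lib <- libraries[[st]]
    if (is.character(lib)) lib <- read_sequences(lib, stage = st)
    n_raw <- sum(lib[["count"]] %||% rep(1L, nrow(lib)))
    if (!is.null(adapter)) lib <- trim_adapters(lib, adapter)
    n_total <- sum(lib[["count"]] %||% rep(1L, nrow(lib)))
    lib <- filter_by_length(lib, min_len, max_len)
    collapsed <- collapse_reads(lib)
    n_window <- sum(collapsed$count)
    asg <- assign_reads(collapsed, catalogs, max_flank = max_flank)
    cls_tot <- asg |>
      dplyr::summarise(reads = sum(.data$count), .by = "assigned_class")
    out_log[[st]] <- tibble::tibble(stage = st, raw_reads = n_raw,
                                    window_reads = n_window) |>
      dplyr::bind_cols(tidyr::pivot_wider(cls_tot,
                                          names_from = "assigned_class",
                                          values_from = "reads"))
    out_counts[[st]] <- count_features(asg, st)
    out_assigned[[st]] <- asg
    totals[st] <- n_total
    win_totals[st] <- n_window
  }
  list(counts = dplyr::bind_rows(out_counts), library_totals = totals,
       window_totals = win_totals, assigned = out_assigned,
       log = dplyr::bind_rows(out_log))
}

#' Run novel miRNA discovery over profiled libraries
#'
#' Pools the genome-assigned reads of all libraries and applies
#' [discover_novel()].
#'
#' @param profile Output of [run_profile()].
#' @param genome Genome catalog.
#' @param known Known mature catalog.
#' @param ... Passed to [discover_novel()].
#' @return Novel miRNA call tibble.
#' @export
run_novel <- function(profile, genome, known = NULL, ...) {
  pool <- dplyr::bind_rows(profile$assigned) |>
    dplyr::filter(.data$assigned_class == "genome") |>
    dplyr::summarise(count = sum(.data$count), .by = "seq")
  discover_novel(pool, genome, known = known, ...)
}

#' Run the expression stage over profiled counts
#'
#' Restricts the count table to known-miRNA (and optionally novel) features
#' and runs [run_contrasts()].
#'
#' @param profile Output of [run_profile()].
#' @param contrasts Contrast spec, see [run_contrasts()].
#' @param classes Feature classes to test (default known miRNA).
#' @param ... Passed to [run_contrasts()].
#' @return A `mir_de` object.
#' @export
run_de <- function(profile, contrasts, classes = "known_mirna", ...) {
  counts <- dplyr::filter(profile$counts, .data$assigned_class %in% classes)
  run_contrasts(counts, profile$library_totals, contrasts, ...)
}

#' Run target prediction
#'
#' Thin orchestration over [predict_targets()].
#'
#' @inheritParams predict_targets
#' @return Target hit tibble.
#' @export
run_targets <- function(mirnas, utrs, ...) {
  predict_targets(mirnas, utrs, ...)
}

#' Run the degradome stage across conditions
#'
#' Maps each condition's tags, finds and categorizes cleavage sites for
#' every miRNA x transcript pair, and assembles the per-target condition
#' comparison.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Transcript catalog tibble.
#' @param tags_by_condition Named list of tag tibbles (`seq`, `count`).
#' @param max_score Alignment score cap (default 4).
#' @return List: `calls` (long, categorized, per condition), `comparison`
#'   (wide per-target table), `profiles` (per-condition profiles).
#' @export
run_degradome <- function(mirnas, transcripts, tags_by_condition,
                          max_score = 4) {
  profiles <- lapply(tags_by_condition, map_tags, transcripts = transcripts)
  calls <- lapply(names(profiles), function(cond) {
    prof <- profiles[[cond]]
    res <- list()
    for (m in seq_along(mirnas)) {
      for (t in seq_len(nrow(transcripts))) {
        if (!transcripts$name[t] %in% prof$transcript_id) next
        cc <- find_cleavage_sites(mirnas[[m]], transcripts$seq[t],
                                  transcripts$name[t], prof,
                                  max_score = max_score,
                                  mirna_name = names(mirnas)[m])
        if (nrow(cc) == 0) next
        cc$category <- vapply(cc$cleavage_position, function(pos) {
          classify_category(prof[prof$transcript_id == transcripts$name[t], ],
                            pos)
        }, integer(1))
        cc$condition <- cond
        res[[length(res) + 1]] <- cc
      }
    }
    dplyr::bind_rows(res)
  })
  names(calls) <- names(profiles)
  comparison <- compare_conditions(calls)
  list(calls = dplyr::bind_rows(calls), comparison = comparison,
       profiles = profiles)
}
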