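#' Read a small-RNA library from FASTA or FASTQ
#'
#' Records become rows of a tibble, in file order, with sequences
#' canonicalized to the DNA alphabet (see [canonical_seq()]). Gzipped files
#' are read transparently.
#'
#' @param path File path.
#' @param format `"fasta"` or `"fastq"`; default guesses from the extension.
#' @param stage Optional stage label (e.g. `"AM"`) stored in a `stage` column.
#' @return A tibble with columns `read_id`, `seq`, and (FASTQ) `qual`; one
#'   row per read. `sum(nrow)` is the library's total read count.
#' @export
read_sequences <- function(path, format = NULL, stage = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  if (!format %in% c("fasta", "fastq")) {
    stop("unknown format: ", format, call. = FALSE)
  }
  if (format == "fasta") {
    xs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e) stop("FASTA parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
    tb <- tibble::tibble(
      read_id = names(xs) %||% as.character(seq_along(xs)),
      seq = canonical_seq(as.character(xs)),
      stage = stage
    )
  } else {
    lines <- readLines(path)
    if (length(lines) %% 4 != 0) {
      stop("FASTQ parse error at record ", length(lines) %/% 4 + 1, " in ",
           path, ": truncated record", call. = FALSE)
    }
    n <- length(lines) %/% 4
    if (n > 0) {
      hdr <- lines[seq(1, length(lines), by = 4)]
      sq <- lines[seq(2, length(lines), by = 4)]
      plus <- lines[seq(3, length(lines), by = 4)]
      ql <- lines[seq(4, length(lines), by = 4)]
      bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                     nchar(sq) != nchar(ql))[1]
      if (!is.na(bad)) {
        stop("FASTQ parse error at record ", bad, " in ", path, call. = FALSE)
      }
      tb <- tibble::tibble(read_id = sub("^@", "", hdr),
                           seq = canonical_seq(sq), qual = ql, stage = stage)
    } else {
      tb <- tibble::tibble(read_id = character(), seq = character(),
                           qual = character(), stage = character())
    }
  }
  tb
}

#' Write a read library to FASTA or FASTQ
#'
#' Collapsed libraries (with a `count` column) are written as one record per
#' unique sequence with the count embedded in the identifier
#' (`seq1_x<count>`), the conventional collapsed-FASTA form.
#'
#' @param library Tibble with `seq` and optionally `read_id`, `qual`, `count`.
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param rna Write in the RNA alphabet (default DNA).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(library, path, format = c("fasta", "fastq"),
                            rna = FALSE) {
  format <- match.arg(format)
  seqs <- if (rna) as_rna(library$seq) else library$seq
  ids <- library[["read_id"]] %||%
    if (!is.null(library$count)) {
      paste0("seq", seq_len(nrow(library)), "_x", library$count)
    } else {
      paste0("read", seq_len(nrow(library)))
    }
  if (format == "fasta") {
    writeLines(c(rbind(paste0(">", ids), seqs)), path)
  } else {
    qual <- library[["qual"]] %||% strrep("I", nchar(seqs))
    writeLines(c(rbind(paste0("@", ids), seqs, "+", qual)), path)
  }
  invisible(path)
}

#' Trim the 3' adapter from reads
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at least `min_overlap` bases and at most `max_mismatch_rate` mismatches
#' per overlapped base. Reads without a qualifying suffix are returned
#' unchanged; qualities are trimmed in step. 5' adapters are assumed to have
#' been handled upstream by demultiplexing.
#'
#' @param library Tibble with a `seq` column (and optionally `qual`).
#' @param adapter Adapter sequence (5' end is what ligates to the read 3'
#'   end). Must be supplied; there is no universal default.
#' @param min_overlap Minimum suffix/prefix overlap (default 5).
#' @param max_mismatch_rate Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return The library with trimmed `seq` (and `qual`).
#' @export
trim_adapters <- function(library, adapter, min_overlap = 5L,
                          max_mismatch_rate = 0.1) {
  stopifnot(nchar(adapter) >= 1, min_overlap >= 1)
  adapter <- canonical_seq(adapter)
  keep <- .trim_adapter_cpp(library$seq, adapter, as.integer(min_overlap),
                            max_mismatch_rate)
  library$seq <- substr(library$seq, 1L, keep)
  if (!is.null(library[["qual"]])) {
    library$qual <- substr(library$qual, 1L, keep)
  }
  library
}

#' Filter reads by length
#'
#' @param library Tibble with a `seq` column.
#' @param min_len,max_len Inclusive length window; the defaults, 18-30 nt,
#'   are the conventional small-RNA analysis window.
#' @return The filtered library.
#' @export
filter_by_length <- function(library, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) {
    stop("min_len must be <= max_len", call. = FALSE)
  }
  dplyr::filter(library, nchar(.data$seq) >= min_len,
                nchar(.data$seq) <= max_len)
}

#' Collapse a read library to unique sequences with counts
#'
#' @param library Tibble with a `seq` column; a pre-existing `count` column
#'   is summed (re-collapsing is a no-op on totals).
#' @return Tibble with `seq` and `count`, one row per unique sequence,
#'   ordered by decreasing count then sequence. Counts sum to the library
#'   total.
#' @export
collapse_reads <- function(library) {
  if (nrow(library) == 0) {
    return(tibble::tibble(seq = character(), count = integer()))
  }
  w <- library[["count"]]
  if (is.null(w)) {                 # unweighted fast path: radix sort + rle
    r <- rle(sort(library$seq, method = "radix"))
    out <- tibble::tibble(seq = r$values, count = r$lengths)
  } else {
    out <- tibble::tibble(seq = library$seq, count = w) |>
      dplyr::summarise(count = sum(.data$count), .by = "seq")
  }
  dplyr::arrange(out, dplyr::desc(.data$count), .data$seq)
}

#' Read-length histogram
#'
#' @param library Tibble with `seq` (and optionally `count`).
#' @param lengths Lengths to report; defaults to the observed range. Absent
#'   lengths report zero.
#' @return Tibble with `length` and `reads`; `sum(reads)` equals the library
#'   total.
#' @export
size_histogram <- function(library, lengths = NULL) {
  w <- library[["count"]] %||% rep(1L, nrow(library))
  L <- nchar(library$seq)
  if (is.null(lengths)) {
    lengths <- if (length(L) == 0) integer(0) else seq(min(L), max(L))
  }
  counts <- vapply(lengths, function(x) sum(w[L == x]), numeric(1))
  tibble::tibble(length = as.integer(lengths), reads = counts)
}

#' Plot a read-length distribution
#'
#' Column plot of the read-length histogram; stage-resolved libraries in
#' these data typically show a 20-23 nt miRNA peak and a 32-35 nt
#' piRNA-like peak.
#'
#' @param library Read library tibble.
#' @param ... Passed to [size_histogram()].
#' @return A ggplot object.
#' @export
plot_size_histogram <- function(library, ...) {
  h <- size_histogram(library, ...)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "read length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}
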