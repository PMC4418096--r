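#' Build a sequence catalog
#'
#' A catalog is a tibble of named reference sequences of one class:
#' `known_mirna` (mature miRNAs), `ncrna`, `cds` or `genome` (contigs).
#' Sequences are canonicalized to the DNA alphabet; names must be unique.
#'
#' @param x Named character vector of sequences, a tibble with `name`/`seq`
#'   columns, or a FASTA path.
#' @param class Catalog class.
#' @param species Optional per-entry source species.
#' @return A tibble with columns `name`, `seq`, `class` (+ `species`).
#' @export
sequence_catalog <- function(x, class = c("known_mirna", "ncrna", "cds",
                                          "genome"), species = NULL) {
  class <- match.arg(class)
  if (is.character(x) && length(x) == 1 && file.exists(x) && is.null(names(x))) {
    tb <- read_sequences(x, format = "fasta")
    tb <- tibble::tibble(name = tb$read_id, seq = tb$seq)
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named", call. = FALSE)
    tb <- tibble::tibble(name = names(x), seq = canonical_seq(unname(x)))
  } else {
    tb <- tibble::tibble(name = x$name, seq = canonical_seq(x$seq))
  }
  if (anyDuplicated(tb$name)) stop("duplicate names in catalog", call. = FALSE)
  if (any(nchar(tb$seq) == 0)) stop("empty sequence in catalog", call. = FALSE)
  tb$class <- class
  if (!is.null(species)) tb$species <- species
  tb
}

#' Merge mature catalog entries with identical sequences
#'
#' Mature miRNA catalogs pooled across species contain distinct names for
#' identical sequences; counting each sequence once requires merging them.
#' The lexicographically smallest name wins, deterministically.
#'
#' @param catalog A `known_mirna` catalog tibble.
#' @return The deduplicated catalog.
#' @export
dedupe_mature <- function(catalog) {
  catalog |>
    dplyr::arrange(.data$name) |>
    dplyr::distinct(.data$seq, .keep_all = TRUE) |>
    dplyr::arrange(.data$name)
}

#' Match a read against the mature miRNA catalog
#'
#' Zero-mismatch matching: a read matches a mature sequence if it is
#' identical to it, is a substring of it, or contains it with at most
#' `max_flank` extra flanking bases in total (isomiR tolerance). Set
#' `max_flank = 0` and `substring = FALSE` for strict identity.
#'
#' @param seqs Character vector of read sequences (canonical alphabet).
#' @param catalog `known_mirna` catalog tibble (deduplicate first with
#'   [dedupe_mature()]).
#' @param max_flank Maximum total extra bases when the read contains a
#'   mature sequence (default 3).
#' @param substring Allow the read to be a substring of the mature
#'   (default TRUE).
#' @return Character vector of matched feature names (NA where unmatched);
#'   ties broken by the lexicographically smallest name.
#' @export
match_known_mirna <- function(seqs, catalog, max_flank = 3L,
                              substring = TRUE) {
  cat_sorted <- dplyr::arrange(catalog, .data$name)
  ## identity (match() hits the first = lexicographically smallest name)
  hit <- cat_sorted$name[match(seqs, cat_sorted$seq)]
  ## read contained in a mature
  if (substring && anyNA(hit)) {
    lens <- sort(unique(nchar(seqs[is.na(hit)])))
    subs <- character(0); subnm <- character(0)
    for (i in seq_len(nrow(cat_sorted))) {
      s <- cat_sorted$seq[i]
      n <- nchar(s)
      for (L in lens[lens < n]) {
        st <- 1:(n - L + 1)
        subs <- c(subs, substring(s, st, st + L - 1))
        subnm <- c(subnm, rep(cat_sorted$name[i], length(st)))
      }
    }
    miss <- which(is.na(hit))
    hit[miss] <- subnm[match(seqs[miss], subs)]
  }
  ## read contains a mature with <= max_flank extra bases (smallest
  ## extension wins, then smallest name)
  if (max_flank > 0 && anyNA(hit)) {
    for (extra in seq_len(max_flank)) {
      miss <- which(is.na(hit))
      if (length(miss) == 0) break
      for (st in 1:(extra + 1)) {
        cand <- substr(seqs[miss], st, nchar(seqs[miss]) - (extra - st + 1))
        nm <- cat_sorted$name[match(cand, cat_sorted$seq)]
        better <- !is.na(nm) & (is.na(hit[miss]) | nm < hit[miss])
        hit[miss][better] <- nm[better]
      }
    }
  }
  hit
}

## exact substring lookup of reads inside catalog entries (sense strand;
## genome also antisense). Returns feature name or NA per read.
match_substring <- function(seqs, catalog, both_strands = FALSE) {
  hit <- rep(NA_character_, length(seqs))
  lens <- sort(unique(nchar(seqs)))
  if (length(lens) == 0) return(hit)
  cat_sorted <- dplyr::arrange(catalog, .data$name)
  targets <- cat_sorted$seq
  if (both_strands) targets <- c(targets, revcomp(cat_sorted$seq))
  names_t <- rep(cat_sorted$name, if (both_strands) 2 else 1)
  ord <- order(names_t)                 # first match() hit = smallest name
  targets <- targets[ord]; names_t <- names_t[ord]
  for (L in lens) {
    subs <- character(0); subnm <- character(0)
    for (i in seq_along(targets)) {
      n <- nchar(targets[i])
      if (n < L) next
      st <- 1:(n - L + 1)
      subs <- c(subs, substring(targets[i], st, st + L - 1))
      subnm <- c(subnm, rep(names_t[i], n - L + 1))
    }
    sel <- which(is.na(hit) & nchar(seqs) == L)
    if (length(sel)) hit[sel] <- subnm[match(seqs[sel], subs)]
  }
  hit
}

#' Hierarchically assign collapsed reads to reference classes
#'
#' Reads are assigned to the first catalog they match, in the fixed priority
#' order known miRNA > ncRNA > CDS > genome (zero-mismatch throughout,
#' replacing an alignment step by exact hash/substring indexing). Known-miRNA
#' matching uses [match_known_mirna()]; ncRNA/CDS are sense-strand substring
#' matches; the genome is searched on both strands. Reads matching nothing
#' are `unassigned` -- on real data the unassigned and genome classes feed
#' novel-miRNA discovery.
#'
#' @param reads Collapsed read tibble (`seq`, `count`).
#' @param catalogs List of catalog tibbles; priority follows their class.
#' @param max_flank,substring IsomiR tolerance, see [match_known_mirna()].
#' @return `reads` with `assigned_class` and `feature_name` columns.
#' @export
assign_reads <- function(reads, catalogs, max_flank = 3L, substring = TRUE) {
  cls <- vapply(catalogs, function(x) x$class[1], character(1))
  ord <- order(match(cls, c("known_mirna", "ncrna", "cds", "genome")))
  catalogs <- catalogs[ord]
  cls <- cls[ord]
  assigned <- rep("unassigned", nrow(reads))
  feature <- rep(NA_character_, nrow(reads))
  for (k in seq_along(catalogs)) {
    todo <- which(assigned == "unassigned")
    if (length(todo) == 0) break
    hit <- switch(cls[k],
      known_mirna = match_known_mirna(reads$seq[todo], catalogs[[k]],
                                      max_flank = max_flank,
                                      substring = substring),
      genome = match_substring(reads$seq[todo], catalogs[[k]],
                               both_strands = TRUE),
      match_substring(reads$seq[todo], catalogs[[k]])
    )
    got <- !is.na(hit)
    assigned[todo[got]] <- cls[k]
    feature[todo[got]] <- hit[got]
  }
  reads$assigned_class <- assigned
  reads$feature_name <- feature
  reads
}

#' Count reads per feature for one stage library
#'
#' @param assignments Output of [assign_reads()] for one library.
#' @param stage Stage label for the resulting column.
#' @return Tibble `feature_name`, `assigned_class`, `stage`, `count`; feature
#'   counts are sums of collapsed read counts, so class totals plus the
#'   unassigned count reproduce the library total.
#' @export
count_features <- function(assignments, stage) {
  assignments |>
    dplyr::filter(.data$assigned_class != "unassigned") |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("feature_name", "assigned_class")) |>
    dplyr::mutate(stage = stage, .before = "count") |>
    dplyr::arrange(.data$assigned_class, .data$feature_name)
}
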