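#' Extract a candidate precursor around a mapped read
#'
#' Takes the mapped read locus plus `flank` nt on either side (clipped at
#' contig bounds), reverse-complemented for minus-strand loci, mirroring the
#' flank-extraction step of hairpin-based novel miRNA discovery.
#'
#' @param genome A `genome` [sequence_catalog()] tibble.
#' @param locus One-row tibble/list with `contig`, `start`, `end` (0-based,
#'   half-open) and `strand` (`"+"`/`"-"`).
#' @param flank Flank size in nt (default 75).
#' @return A one-row tibble: `contig`, `start`, `end`, `strand`,
#'   `precursor` (sequence, 5'->3' on the locus strand) and `mature_offset`
#'   (0-based offset of the read within the precursor).
#' @export
extract_precursor <- function(genome, locus, flank = 75L) {
  ctg <- genome$seq[match(locus$contig, genome$name)]
  if (is.na(ctg)) stop("unknown contig: ", locus$contig, call. = FALSE)
  n <- nchar(ctg)
  if (locus$start < 0 || locus$end > n || locus$start >= locus$end) {
    stop("locus outside contig bounds", call. = FALSE)
  }
  s0 <- max(0L, locus$start - flank)
  e0 <- min(n, locus$end + flank)
  seq <- substr(ctg, s0 + 1L, e0)
  if (identical(locus$strand, "-")) {
    seq <- revcomp(seq)
    offset <- e0 - locus$end
  } else {
    offset <- locus$start - s0
  }
  tibble::tibble(contig = locus$contig, start = s0, end = e0,
                 strand = locus$strand %||% "+",
                 precursor = seq, mature_offset = as.integer(offset))
}

#' Classify a candidate precursor as a miRNA-like hairpin
#'
#' A candidate passes when (i) its minimum free energy is below
#' `mfe_threshold`, (ii) the stem system covering the mature read -- the
#' substructure under the innermost base pair enclosing the mature's paired
#' bases -- contains exactly one terminal (hairpin) loop, and (iii) the
#' mature lies entirely 5' (`arm = "5p"`) or entirely 3' (`arm = "3p"`) of
#' that loop. Side bulges and internal loops along the stem are permitted;
#' multiloops under the mature's stem are rejected. Failures carry a reason
#' code (`energy`, `no_stem`, `multi_loop`, `loop_overlap`).
#'
#' @param precursor Precursor sequence.
#' @param mature_offset 0-based offset of the mature within the precursor.
#' @param mature_length Mature length (clipped to the precursor end).
#' @param mfe_threshold Pass requires MFE strictly below this (default -20
#'   kcal/mol).
#' @param par Energy parameters.
#' @param fold_fun Folding engine, `function(seq, par)` returning
#'   `list(structure, mfe)`; defaults to [fold_mfe()]. Supplying a wrapper
#'   around an external folder gives an independent cross-check.
#' @return A one-row tibble: `pass`, `arm` (NA unless pass), `mfe`,
#'   `structure`, `reason`.
#' @export
classify_hairpin <- function(precursor, mature_offset, mature_length,
                             mfe_threshold = -20, par = rna_energy_params(),
                             fold_fun = fold_mfe) {
  n <- nchar(precursor)
  if (mature_offset < 0 || mature_offset >= n || mature_length < 1) {
    stop("mature outside precursor", call. = FALSE)
  }
  m1 <- mature_offset + 1L
  m2 <- min(mature_offset + mature_length, n)
  fold <- fold_fun(precursor, par)
  res <- function(pass, arm, reason) {
    tibble::tibble(pass = pass, arm = arm, mfe = fold$mfe,
                   structure = fold$structure, reason = reason)
  }
  if (!(fold$mfe < mfe_threshold)) return(res(FALSE, NA_character_, "energy"))
  p <- pair_table(fold$structure)
  mat <- m1:m2
  paired <- mat[p[mat] > 0]
  if (length(paired) == 0) return(res(FALSE, NA_character_, "no_stem"))
  ## innermost pair enclosing the mature's paired span
  ii <- which(p > seq_along(p))                 # opening positions
  enc <- ii[ii <= min(paired) & p[ii] >= max(paired)]
  if (length(enc) == 0) return(res(FALSE, NA_character_, "no_stem"))
  i0 <- max(enc); j0 <- p[i0]
  ## terminal loops inside the stem system
  closes_hairpin <- function(i) all(p[(i + 1):(p[i] - 1)] == 0)
  hp <- ii[ii >= i0 & p[ii] <= j0]
  hp <- hp[vapply(hp, closes_hairpin, logical(1))]
  if (length(hp) != 1) return(res(FALSE, NA_character_, "multi_loop"))
  hi <- hp; hj <- p[hp]                         # loop spans (hi+1)..(hj-1)
  if (m2 <= hi) return(res(TRUE, "5p", "ok"))
  if (m1 >= hj) return(res(TRUE, "3p", "ok"))
  res(FALSE, NA_character_, "loop_overlap")
}

#' Screen candidate matures against the known catalog
#'
#' @param mature Character vector of candidate mature sequences.
#' @param known A `known_mirna` catalog.
#' @param max_dist Maximum edit distance to call "known-like" (default 3).
#' @return `"known-like"` or `"novel"` per candidate.
#' @export
check_not_known <- function(mature, known, max_dist = 3L) {
  if (nrow(known) == 0) return(rep("novel", length(mature)))
  d <- utils::adist(canonical_seq(mature), known$seq)
  ifelse(apply(d, 1, min) <= max_dist, "known-like", "novel")
}

#' Name accepted novel miRNAs
#'
#' Precursors are numbered in order of genomic coordinate (contig, start,
#' then sequence), and matures suffixed `-5p`/`-3p` by arm; two matures from
#' one precursor share the precursor number. Naming is deterministic under
#' re-runs.
#'
#' @param accepted Tibble of accepted candidates with `contig`, `start`,
#'   `end`, `strand`, `mature`, `arm`.
#' @param prefix Name prefix (default `"ast-Novel"`).
#' @return `accepted` with a `name` column.
#' @export
name_novel <- function(accepted, prefix = "ast-Novel") {
  if (nrow(accepted) == 0) {
    return(dplyr::mutate(accepted, name = character(0)))
  }
  accepted <- dplyr::arrange(accepted, .data$contig, .data$start, .data$mature)
  key <- paste(accepted$contig, accepted$start, accepted$end, accepted$strand)
  num <- match(key, unique(key))
  accepted$name <- paste0(prefix, "-", num, "-", accepted$arm)
  accepted
}

## locate read sequences on the genome (first hit; both strands)
locate_reads <- function(seqs, genome) {
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    hit <- NULL
    for (i in seq_len(nrow(genome))) {
      pos <- regexpr(seqs[k], genome$seq[i], fixed = TRUE)
      if (pos > 0) {
        hit <- tibble::tibble(contig = genome$name[i], start = pos - 1L,
                              end = pos - 1L + nchar(seqs[k]), strand = "+")
        break
      }
      pos <- regexpr(revcomp(seqs[k]), genome$seq[i], fixed = TRUE)
      if (pos > 0) {
        hit <- tibble::tibble(contig = genome$name[i], start = pos - 1L,
                              end = pos - 1L + nchar(seqs[k]), strand = "-")
        break
      }
    }
    out[[k]] <- hit %||% tibble::tibble(contig = NA_character_, start = NA_integer_,
                                        end = NA_integer_, strand = NA_character_)
  }
  dplyr::bind_rows(out)
}

#' Discover novel miRNAs from genome-assigned reads
#'
#' The genome-matched, otherwise-unannotated reads are located on the
#' genome, overlapping reads on one strand are merged into loci keeping the
#' most abundant read as the mature candidate, a precursor is extracted with
#' [extract_precursor()], folded and classified with [classify_hairpin()],
#' screened against the known catalog with [check_not_known()], and named
#' with [name_novel()].
#'
#' @param reads Collapsed reads assigned to the genome class (`seq`,
#'   `count`).
#' @param genome Genome catalog.
#' @param known Known mature catalog (for the similarity screen).
#' @param flank Flank size (default 75).
#' @param mfe_threshold MFE pass threshold (default -20 kcal/mol).
#' @param min_count Minimum collapsed read count per locus (default 1).
#' @param par,fold_fun Folding model, see [classify_hairpin()].
#' @return Tibble of accepted novel miRNAs: `name`, `mature`, `arm`, `mfe`,
#'   `structure`, `precursor`, locus columns.
#' @export
discover_novel <- function(reads, genome, known = NULL, flank = 75L,
                           mfe_threshold = -20, min_count = 1L,
                           par = rna_energy_params(), fold_fun = fold_mfe) {
  reads <- dplyr::filter(reads, .data$count >= min_count)
  if (nrow(reads) == 0) return(empty_novel())
  loc <- dplyr::bind_cols(reads, locate_reads(reads$seq, genome)) |>
    dplyr::filter(!is.na(.data$contig))
  if (nrow(loc) == 0) return(empty_novel())
  ## merge overlapping reads per contig/strand; most abundant read wins
  loc <- dplyr::arrange(loc, .data$contig, .data$strand, .data$start)
  grp <- integer(nrow(loc)); g <- 0L; last_end <- -1L; last_key <- ""
  for (k in seq_len(nrow(loc))) {
    key <- paste(loc$contig[k], loc$strand[k])
    if (key != last_key || loc$start[k] >= last_end) {
      g <- g + 1L
      last_end <- loc$end[k]
    } else {
      last_end <- max(last_end, loc$end[k])
    }
    last_key <- key
    grp[k] <- g
  }
  loc$locus_group <- grp
  cand <- loc |>
    dplyr::arrange(.data$locus_group, dplyr::desc(.data$count), .data$seq) |>
    dplyr::distinct(.data$locus_group, .keep_all = TRUE)
  rows <- purrr::pmap(
    list(cand$seq, cand$count, cand$contig, cand$start, cand$end, cand$strand),
    function(sq, ct, contig, start, end, strand) {
      prec <- extract_precursor(genome, list(contig = contig, start = start,
                                             end = end, strand = strand),
                                flank = flank)
      cl <- classify_hairpin(prec$precursor, prec$mature_offset, nchar(sq),
                             mfe_threshold = mfe_threshold, par = par,
                             fold_fun = fold_fun)
      dplyr::bind_cols(
        tibble::tibble(mature = sq, count = ct, contig = contig,
                       start = start, end = end, strand = strand,
                       precursor = prec$precursor,
                       mature_offset = prec$mature_offset),
        cl
      )
    }
  ) |> dplyr::bind_rows()
  acc <- dplyr::filter(rows, .data$pass)
  if (!is.null(known) && nrow(acc) > 0) {
    acc <- dplyr::filter(acc, check_not_known(.data$mature, known) == "novel")
  }
  if (nrow(acc) == 0) return(empty_novel())
  name_novel(acc) |>
    dplyr::select("name", "mature", "arm", "mfe", "structure", "precursor",
                  "mature_offset", "contig", "start", "end", "strand", "count")
}

empty_novel <- function() {
  tibble::tibble(name = character(), mature = character(), arm = character(),
                 mfe = numeric(), structure = character(),
                 precursor = character(), mature_offset = integer(),
                 contig = character(), start = integer(), end = integer(),
                 strand = character(), count = integer())
}
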