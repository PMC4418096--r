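#' Map degradome tags onto transcripts
#'
#' Each 20-25 nt degradome tag is exact-matched (sense strand) to the
#' transcript catalog; its count is added at the 1-based position of its 5'
#' end. Tags matching several transcripts contribute to each and are
#' flagged; tags matching nowhere contribute to no profile. Total profile
#' mass equals total mapped tag mass.
#'
#' @param tags Tibble with `seq` and `count` (collapsed degradome tags).
#' @param transcripts Catalog tibble (`name`, `seq`) of sense-strand cDNA.
#' @param min_len,max_len Tag length window retained (defaults 20 and 25).
#' @return Tibble `transcript_id`, `position`, `abundance`, `multi_mapped`.
#' @export
map_tags <- function(tags, transcripts, min_len = 20L, max_len = 25L) {
  tags <- dplyr::filter(tags, nchar(.data$seq) >= min_len,
                        nchar(.data$seq) <= max_len)
  rows <- list()
  for (k in seq_len(nrow(tags))) {
    hits <- list()
    for (t in seq_len(nrow(transcripts))) {
      pos <- gregexpr(tags$seq[k], transcripts$seq[t], fixed = TRUE)[[1]]
      if (pos[1] == -1) next
      hits[[length(hits) + 1]] <- tibble::tibble(
        transcript_id = transcripts$name[t], position = as.integer(pos)
      )
    }
    if (length(hits) == 0) next
    h <- dplyr::bind_rows(hits)
    h$abundance <- tags$count[k]
    h$multi_mapped <- nrow(h) > 1
    rows[[length(rows) + 1]] <- h
  }
  if (length(rows) == 0) {
    return(tibble::tibble(transcript_id = character(), position = integer(),
                          abundance = numeric(), multi_mapped = logical()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::summarise(abundance = sum(.data$abundance),
                     multi_mapped = any(.data$multi_mapped),
                     .by = c("transcript_id", "position")) |>
    dplyr::arrange(.data$transcript_id, .data$position)
}

#' Score a miRNA:target-site alignment
#'
#' Penalty score over a transcript window of miRNA length: each mismatch
#' +1, each G:U pair +0.5, penalties doubled at miRNA positions 2-13, and a
#' mismatch at positions 10-11 (the cleavage-defining positions) is
#' disallowed (infinite penalty). Lower is better; a perfect complement
#' scores 0. The window is given 5'->3' on the transcript and is paired
#' antiparallel to the miRNA.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param window Transcript window, 5'->3', same length as the miRNA.
#' @return Penalty score (possibly `Inf`).
#' @export
score_site <- function(mirna, window) {
  m <- strsplit(as_rna(canonical_seq(mirna)), "")[[1]]
  w <- strsplit(as_rna(canonical_seq(window)), "")[[1]]
  if (length(w) != length(m)) {
    stop("window length must equal miRNA length", call. = FALSE)
  }
  ## miRNA position i pairs transcript window position (L - i + 1)
  t_al <- rev(w)
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  score <- 0
  for (i in seq_along(m)) {
    pen <- if (t_al[i] == wc[[m[i]]]) {
      0
    } else if ((m[i] == "G" && t_al[i] == "U") ||
               (m[i] == "U" && t_al[i] == "G")) {
      0.5
    } else {
      1
    }
    if (pen == 1 && i >= 10 && i <= 11) return(Inf)
    if (i >= 2 && i <= 13) pen <- pen * 2
    score <- score + pen
  }
  score
}

#' Find candidate cleavage sites on a transcript
#'
#' Every transcript window whose [score_site()] penalty is at most
#' `max_score` proposes the canonical cleavage position: the transcript
#' nucleotide paired to miRNA position 10. A call is emitted only when the
#' degradome profile has abundance >= 1 exactly at that position.
#'
#' @param mirna miRNA sequence (named element or plain string).
#' @param transcript One transcript sequence.
#' @param transcript_id Its identifier (used to filter `profile`).
#' @param profile Degradome profile tibble from [map_tags()].
#' @param max_score Alignment score cap (default 4).
#' @param mirna_name Optional display name for the miRNA (defaults to the
#'   sequence).
#' @return Tibble `mirna`, `transcript_id`, `cleavage_position`,
#'   `alignment_score`, `abundance` (uncategorized).
#' @export
find_cleavage_sites <- function(mirna, transcript, transcript_id, profile,
                                max_score = 4, mirna_name = NULL) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  prof <- dplyr::filter(profile, .data$transcript_id == !!transcript_id)
  out <- list()
  if (n >= L) {
    for (s in 1:(n - L + 1)) {
      win <- substr(transcript, s, s + L - 1)
      sc <- score_site(mirna, win)
      if (!is.finite(sc) || sc > max_score) next
      ## miRNA pos 10 pairs window position L - 9 (window end = s + L - 1)
      cleave <- s + L - 10L
      ab <- prof$abundance[prof$position == cleave]
      if (length(ab) == 0 || ab < 1) next
      out[[length(out) + 1]] <- tibble::tibble(
        mirna = mirna_name %||% mirna, transcript_id = transcript_id,
        cleavage_position = cleave, alignment_score = sc, abundance = ab
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mirna = character(), transcript_id = character(),
                          cleavage_position = integer(),
                          alignment_score = numeric(), abundance = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Classify a cleavage position into degradome categories 0-4
#'
#' With `a` the abundance at the position, `M` the maximum abundance over
#' occupied positions of the transcript and `med` their median: category 4
#' if `a == 1`; else 0 if `a == M` attained at a single position; 1 if
#' `a == M` shared by several positions; 2 if `a > med`; else 3. The median
#' is taken over occupied positions only, with the even-cardinality median
#' the mean of the two central values.
#'
#' @param profile Profile tibble (`position`, `abundance`) for one
#'   transcript.
#' @param position Cleavage position (must have abundance >= 1).
#' @return Integer category in 0-4.
#' @export
classify_category <- function(profile, position) {
  a <- profile$abundance[profile$position == position]
  if (length(a) == 0 || a < 1) {
    stop("no degradome abundance at position ", position, call. = FALSE)
  }
  if (a == 1) return(4L)
  M <- max(profile$abundance)
  if (a == M) {
    if (sum(profile$abundance == M) == 1) return(0L) else return(1L)
  }
  med <- median(profile$abundance)
  if (a > med) 2L else 3L
}

#' T-plot series for a transcript
#'
#' Full-length position/abundance series with cleavage-call positions
#' flagged, ready for plotting degradome evidence along the transcript.
#'
#' @param profile Profile tibble for one transcript.
#' @param calls Cleavage-call tibble (needs `cleavage_position`).
#' @param transcript_length Full transcript length; zero-abundance
#'   positions are filled in.
#' @return Tibble `position`, `abundance`, `is_call`.
#' @export
tplot_data <- function(profile, calls = NULL, transcript_length = NULL) {
  if (is.null(transcript_length)) {
    transcript_length <- if (nrow(profile)) max(profile$position) else 0L
  }
  if (transcript_length == 0) {
    return(tibble::tibble(position = integer(), abundance = numeric(),
                          is_call = logical()))
  }
  out <- tibble::tibble(position = seq_len(transcript_length),
                        abundance = 0)
  out$abundance[profile$position] <- profile$abundance
  out$is_call <- out$position %in% (calls$cleavage_position %||% integer(0))
  out
}

#' Plot a degradome T-plot
#'
#' @param profile,calls,transcript_length See [tplot_data()].
#' @return A ggplot object: degradome 5'-end abundance by transcript
#'   position, cleavage calls highlighted.
#' @export
plot_tplot <- function(profile, calls = NULL, transcript_length = NULL) {
  dat <- tplot_data(profile, calls, transcript_length)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$abundance)) +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$abundance > 0),
                        color = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$is_call),
                        color = "red", size = 2) +
    ggplot2::labs(x = "transcript position (nt)", y = "degradome reads") +
    ggplot2::theme_minimal()
}

#' Combine categorized calls across injection conditions
#'
#' One row per (miRNA, transcript) with the category per condition (NA
#' where the target was not called), in the shape of the published
#' degradome comparison across PBS, scrambled-RNA and antagomir libraries.
#'
#' @param calls_by_condition Named list of categorized call tibbles (each
#'   with `mirna`, `transcript_id`, `category`).
#' @return Wide tibble `mirna`, `transcript_id`, one category column per
#'   condition.
#' @export
compare_conditions <- function(calls_by_condition) {
  stopifnot(length(names(calls_by_condition)) == length(calls_by_condition))
  long <- purrr::imap(calls_by_condition, function(x, nm) {
    if (nrow(x) == 0) return(NULL)
    x |>
      dplyr::summarise(category = min(.data$category),
                       .by = c("mirna", "transcript_id")) |>
      dplyr::mutate(condition = nm)
  }) |> dplyr::bind_rows()
  if (nrow(long) == 0) {
    out <- tibble::tibble(mirna = character(), transcript_id = character())
    for (nm in names(calls_by_condition)) out[[nm]] <- integer(0)
    return(out)
  }
  out <- tidyr::pivot_wider(long, names_from = "condition",
                            values_from = "category") |>
    dplyr::arrange(.data$mirna, .data$transcript_id)
  for (nm in setdiff(names(calls_by_condition), names(out))) {
    out[[nm]] <- NA_integer_            # conditions with no calls at all
  }
  out[c("mirna", "transcript_id", names(calls_by_condition))]
}
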