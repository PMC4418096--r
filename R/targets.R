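#' Find perfect seed-complementary sites on a 3'UTR
#'
#' The seed is miRNA positions 2-8 (a 7-mer); a site is every UTR window
#' whose sequence is the exact Watson-Crick reverse complement of the seed
#' (no G:U). Positions are 1-based starts of the 7-nt match on the UTR.
#'
#' @param mirna miRNA sequence, 5'->3' (length >= 8).
#' @param utr UTR sequence, 5'->3'.
#' @param seed_from,seed_to Seed span on the miRNA (defaults 2 and 8).
#' @return Integer vector of site start positions (possibly empty).
#' @export
find_seed_sites <- function(mirna, utr, seed_from = 2L, seed_to = 8L) {
  mirna <- canonical_seq(mirna)
  utr <- canonical_seq(utr)
  if (nchar(mirna) < seed_to) stop("miRNA shorter than the seed span",
                                   call. = FALSE)
  target <- revcomp(substr(mirna, seed_from, seed_to))
  hits <- gregexpr(target, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

## window on the UTR for duplex evaluation, centered on the seed match
site_window <- function(utr, site, window = 40L) {
  n <- nchar(utr)
  half <- window %/% 2L
  s <- max(1L, site + 3L - half)
  substr(utr, s, min(n, s + window - 1L))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence while preserving its exact
#' dinucleotide (and therefore mononucleotide) composition, the standard
#' null for RNA-RNA interaction energies.
#'
#' @param x A single sequence.
#' @return A shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(x) {
  s <- strsplit(x, "")[[1]]
  n <- length(s)
  if (n < 3) return(x)
  letters_u <- unique(s)
  ## edge lists of the dinucleotide multigraph
  edges <- lapply(setNames(letters_u, letters_u),
                  function(a) s[which(s[-n] == a) + 1L])
  last <- s[n]
  repeat {
    perm <- lapply(edges, function(e) if (length(e)) sample(e) else e)
    ## Eulerian condition: keep, per vertex (except the last), the final
    ## edge pointing toward the end vertex via a random arborescence; the
    ## simple rejection form below just walks and retries on dead ends.
    out <- character(n)
    out[1] <- s[1]
    idx <- setNames(rep(1L, length(edges)), names(edges))
    ok <- TRUE
    for (k in 2:n) {
      a <- out[k - 1]
      i <- idx[[a]]
      if (i > length(perm[[a]])) { ok <- FALSE; break }
      out[k] <- perm[[a]][i]
      idx[[a]] <- i + 1L
    }
    if (ok && all(idx - 1L == lengths(perm))) break
  }
  paste(out, collapse = "")
}

#' Empirical p-value for a duplex site
#'
#' Compares the observed site energy against the best attainable duplex
#' energy on dinucleotide-preserving shuffles of the UTR: `p = (1 + #{
#' shuffles with best energy <= observed}) / (n_shuffles + 1)`. The best
#' energy of a shuffled UTR is the minimum of [duplex_energy()] over all
#' windows, so the statistic is exchangeable with the observed best site
#' under the null.
#'
#' @param observed_energy Energy of the candidate site (kcal/mol).
#' @param mirna miRNA sequence.
#' @param utr UTR sequence (>= 20 nt).
#' @param n_shuffles Number of shuffles (>= 99).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param par Energy parameters.
#' @param window Window width for energy evaluation (default 40).
#' @return p-value in (0, 1].
#' @export
site_pvalue <- function(observed_energy, mirna, utr, n_shuffles = 99L,
                        seed = 1L, par = rna_energy_params(), window = 40L) {
  if (nchar(utr) < 20) stop("UTR too short to shuffle (< 20 nt)",
                            call. = FALSE)
  if (n_shuffles < 99) stop("n_shuffles must be >= 99", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_shuffles)) {
    null_utr <- dinucleotide_shuffle(utr)
    e <- best_window_energy(mirna, null_utr, par, window)
    if (e <= observed_energy) hits <- hits + 1L
  }
  (1 + hits) / (n_shuffles + 1)
}

## best duplex energy over sliding windows (stride = window/2 covers every
## possible full window at half-overlap)
best_window_energy <- function(mirna, utr, par = rna_energy_params(),
                               window = 40L) {
  n <- nchar(utr)
  if (n <= window) return(duplex_energy(mirna, utr, par))
  starts <- unique(c(seq(1L, n - window + 1L, by = max(1L, window %/% 2L)),
                     n - window + 1L))
  min(vapply(starts, function(s) {
    duplex_energy(mirna, substr(utr, s, s + window - 1L), par)
  }, numeric(1)))
}

#' Predict miRNA targets on a 3'UTR catalog
#'
#' A target site must satisfy all three criteria: perfect seed
#' complementarity ([find_seed_sites()]), duplex energy strictly below
#' `energy_threshold` ([duplex_energy()] over a window centered on the seed
#' match), and an empirical shuffle p-value below `p_threshold`
#' ([site_pvalue()]).
#'
#' @param mirnas Named character vector (or `known_mirna` catalog tibble) of
#'   mature miRNA sequences.
#' @param utrs Tibble with `gene_id`, `utr` columns, or named character
#'   vector.
#' @param p_threshold,energy_threshold Criteria (defaults 0.05 and -20
#'   kcal/mol, both strict).
#' @param n_shuffles,seed Permutation-null settings.
#' @param par Energy parameters.
#' @param window Energy window width (default 40).
#' @return Tibble of hits: `mirna`, `gene_id`, `site_start`,
#'   `duplex_energy`, `p_value`, sorted by miRNA then energy.
#' @export
predict_targets <- function(mirnas, utrs, p_threshold = 0.05,
                            energy_threshold = -20, n_shuffles = 99L,
                            seed = 1L, par = rna_energy_params(),
                            window = 40L) {
  if (is.data.frame(mirnas)) mirnas <- setNames(mirnas$seq, mirnas$name)
  if (is.character(utrs)) {
    utrs <- tibble::tibble(gene_id = names(utrs), utr = unname(utrs))
  }
  out <- list()
  for (m in seq_along(mirnas)) {
    for (g in seq_len(nrow(utrs))) {
      sites <- find_seed_sites(mirnas[[m]], utrs$utr[g])
      for (s in sites) {
        e <- duplex_energy(mirnas[[m]], site_window(utrs$utr[g], s, window),
                           par)
        if (!(e < energy_threshold)) next
        p <- site_pvalue(e, mirnas[[m]], utrs$utr[g], n_shuffles = n_shuffles,
                         seed = seed + g, par = par, window = window)
        if (!(p < p_threshold)) next
        out[[length(out) + 1]] <- tibble::tibble(
          mirna = names(mirnas)[m] %||% paste0("mirna", m),
          gene_id = utrs$gene_id[g], site_start = s,
          duplex_energy = e, p_value = p
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mirna = character(), gene_id = character(),
                          site_start = integer(), duplex_energy = numeric(),
                          p_value = numeric()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$mirna, .data$duplex_energy)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
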