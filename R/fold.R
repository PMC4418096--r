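#' Minimum-free-energy RNA secondary structure
#'
#' Folds a single RNA (or DNA; T is read as U) sequence into its
#' minimum-free-energy pseudoknot-free secondary structure under the package's
#' nearest-neighbor model: stacking energies, hairpin/bulge/internal-loop
#' penalties with asymmetry, and a linear multiloop model (see
#' [rna_energy_params()]). G:U wobble pairs are allowed; hairpin loops have a
#' minimum of three unpaired bases; an entirely unpaired structure has energy
#' zero, so the MFE is always <= 0.
#'
#' @param seq A single sequence (length >= 10 for meaningful folds; shorter
#'   sequences are accepted and simply fold to the open chain when no pairs
#'   fit).
#' @param par Energy parameters, as returned by [rna_energy_params()].
#' @return A list with `structure` (dot-bracket string) and `mfe` (kcal/mol).
#' @examples
#' fold_mfe("GGGGGGAAAACCCCCC")
#' @export
fold_mfe <- function(seq, par = rna_energy_params()) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- as_rna(canonical_seq(seq))
  res <- .fold_mfe_cpp(s, par)
  res$mfe <- min(res$mfe, 0)
  res
}

#' Parse a dot-bracket string into a pair table
#'
#' @param db Dot-bracket string.
#' @return Integer vector `p` with `p[i]` = partner of position `i`, 0 if
#'   unpaired.
#' @export
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  p <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0) stop("unbalanced dot-bracket string")
      j <- open[length(open)]
      open <- open[-length(open)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(open) > 0) stop("unbalanced dot-bracket string")
  p
}

#' Free energy of a given secondary structure
#'
#' Evaluates the package's nearest-neighbor model on an explicit structure by
#' loop decomposition (hairpin, stack, bulge, internal, multiloop, exterior).
#' This is the definitional form of the model: [fold_mfe()] minimizes exactly
#' this function over all pseudoknot-free structures, which is what the
#' enumeration-based tests verify.
#'
#' @param seq Sequence (RNA or DNA alphabet).
#' @param db Dot-bracket structure of the same length.
#' @param par Energy parameters.
#' @return Energy in kcal/mol; `Inf` for forbidden loops (e.g. hairpin < 3).
#' @export
structure_energy <- function(seq, db, par = rna_energy_params()) {
  s <- strsplit(as_rna(canonical_seq(seq)), "")[[1]]
  stopifnot(nchar(db) == length(s))
  p <- pair_table(db)
  codes <- c(AU = 1, UA = 2, CG = 3, GC = 4, GU = 5, UG = 6)
  ptype <- function(i, j) {
    cd <- codes[paste0(s[i], s[j])]
    if (is.na(cd)) Inf else cd
  }
  hairpinE <- function(n) {
    if (n < par$min_hairpin) return(Inf)
    if (n <= length(par$hairpin)) return(par$hairpin[n])
    nm <- length(par$hairpin)
    par$hairpin[nm] + par$lxc * log(n / nm)
  }
  bulgeE <- function(n) {
    if (n <= length(par$bulge)) return(par$bulge[n])
    nm <- length(par$bulge)
    par$bulge[nm] + par$lxc * log(n / nm)
  }
  internalE <- function(n) {
    if (n <= length(par$internal)) return(par$internal[n])
    nm <- length(par$internal)
    par$internal[nm] + par$lxc * log(n / nm)
  }
  two_sided <- function(pout, pin, n1, n2) {
    if (n1 == 0 && n2 == 0) return(par$stack[pout, pin])
    ntot <- n1 + n2
    if (ntot > par$max_interior) return(Inf)
    if (n1 == 0 || n2 == 0) {
      e <- bulgeE(ntot)
      if (ntot == 1) e <- e + par$stack[pout, pin]
      return(e)
    }
    internalE(ntot) + min(par$ninio_m * abs(n1 - n2), par$ninio_max)
  }
  total <- 0
  n <- length(s)
  for (i in seq_len(n)) {
    j <- p[i]
    if (j <= i) next            # closing pair (i, j), i < j
    pij <- ptype(i, j)
    if (!is.finite(pij)) return(Inf)
    ## children: pairs directly enclosed by (i, j)
    kids <- list()
    k <- i + 1
    unpaired <- 0
    while (k < j) {
      if (p[k] > k) {
        kids[[length(kids) + 1]] <- c(k, p[k])
        k <- p[k] + 1
      } else {
        unpaired <- unpaired + 1
        k <- k + 1
      }
    }
    if (length(kids) == 0) {
      total <- total + hairpinE(j - i - 1)
    } else if (length(kids) == 1) {
      kk <- kids[[1]]
      pin <- ptype(kk[1], kk[2])
      if (!is.finite(pin)) return(Inf)
      total <- total + two_sided(pij, pin, kk[1] - i - 1, j - kk[2] - 1)
    } else {
      total <- total + par$ml_close + par$ml_branch * (length(kids) + 1) +
        par$ml_unpaired * unpaired
    }
    if (!is.finite(total)) return(Inf)
  }
  total
}

#' Intermolecular duplex minimum free energy
#'
#' Minimum free energy of the hybrid between a short RNA (typically a miRNA)
#' and a target window, with intramolecular pairs forbidden: only antiparallel
#' inter-strand stacks, bulges and internal loops contribute, under the same
#' parameter table as [fold_mfe()]. An unpaired duplex has energy zero, so the
#' result is always <= 0.
#'
#' @param x Query sequence, 5'->3' (e.g. the miRNA).
#' @param y Target window, 5'->3'.
#' @param par Energy parameters.
#' @param max_loop Maximum unpaired stretch per strand between consecutive
#'   pairs (default 15).
#' @return Energy in kcal/mol.
#' @examples
#' duplex_energy("ACGUACGUACGUACGUACGUAC", revcomp("ACGUACGUACGUACGUACGUAC"))
#' @export
duplex_energy <- function(x, y, par = rna_energy_params(), max_loop = 15L) {
  stopifnot(length(x) == 1, length(y) == 1)
  .duplex_energy_cpp(as_rna(canonical_seq(x)), as_rna(canonical_seq(y)),
                     par, as.integer(max_loop))
}

#' Free energy of a given intermolecular duplex pairing
#'
#' Definitional scorer behind [duplex_energy()]: `pairs` lists the paired
#' positions (i on `x`, j on `y`), which must be monotone (increasing i,
#' decreasing j). Consecutive pairs contribute a stack when adjacent or a
#' bulge/internal-loop penalty otherwise; a lone pair scores zero.
#'
#' @param x,y Sequences, 5'->3'.
#' @param pairs Two-column matrix of (i, j) 1-based paired positions.
#' @param par Energy parameters.
#' @return Energy in kcal/mol, `Inf` for invalid pairings.
#' @export
duplex_structure_energy <- function(x, y, pairs, par = rna_energy_params()) {
  if (NROW(pairs) == 0) return(0)
  sx <- strsplit(as_rna(canonical_seq(x)), "")[[1]]
  sy <- strsplit(as_rna(canonical_seq(y)), "")[[1]]
  codes <- c(AU = 1, UA = 2, CG = 3, GC = 4, GU = 5, UG = 6)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  pt <- codes[paste0(sx[pairs[, 1]], sy[pairs[, 2]])]
  if (anyNA(pt)) return(Inf)
  if (NROW(pairs) > 1 &&
      (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) >= 0))) return(Inf)
  e <- 0
  if (NROW(pairs) > 1) {
    for (k in 2:NROW(pairs)) {
      n1 <- pairs[k, 1] - pairs[k - 1, 1] - 1
      n2 <- pairs[k - 1, 2] - pairs[k, 2] - 1
      if (n1 == 0 && n2 == 0) {
        e <- e + par$stack[pt[k - 1], pt[k]]
      } else {
        ntot <- n1 + n2
        if (ntot > par$max_interior) return(Inf)
        if (n1 == 0 || n2 == 0) {
          nm <- length(par$bulge)
          be <- if (ntot <= nm) par$bulge[ntot] else par$bulge[nm] + par$lxc * log(ntot / nm)
          if (ntot == 1) be <- be + par$stack[pt[k - 1], pt[k]]
          e <- e + be
        } else {
          nm <- length(par$internal)
          ie <- if (ntot <= nm) par$internal[ntot] else par$internal[nm] + par$lxc * log(ntot / nm)
          e <- e + ie + min(par$ninio_m * abs(n1 - n2), par$ninio_max)
        }
      }
    }
  }
  e
}
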