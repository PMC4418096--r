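## Independent brute-force oracles for folding, duplex energy, the exact
## count test and degradome categories. These enumerate/sum directly and
## never reuse the package's dynamic-programming paths.

random_seq <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

## all pseudoknot-free pairings of positions i..j (min hairpin 3, pairs
## AU/UA/CG/GC/GU/UG); returns list of 2-col matrices
enumerate_structures <- function(seq) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(s[a], s[b]) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    out <- lapply(rec(i + 1, j), identity)          # i unpaired
    for (k in (i + 4):j) {
      if (k > j || !ok(i, k)) next
      left <- rec(i + 1, k - 1)
      right <- rec(k + 1, j)
      for (L in left) for (R in right) {
        out[[length(out) + 1]] <- rbind(c(i, k), L, R)
      }
    }
    assign(key, out, envir = memo)
    out
  }
  rec(1, length(s))
}

pairs_to_db <- function(pairs, n) {
  db <- rep(".", n)
  if (NROW(pairs) > 0) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

## brute-force MFE: minimum of structure_energy over every structure
brute_force_mfe <- function(seq, par = rna_energy_params()) {
  n <- nchar(seq)
  structs <- enumerate_structures(seq)
  energies <- vapply(structs, function(p) {
    stagemir::structure_energy(seq, pairs_to_db(p, n), par)
  }, numeric(1))
  k <- which.min(energies)
  list(mfe = min(0, energies[k]),
       structure = pairs_to_db(structs[[k]], n))
}

## all monotone inter-strand pairings of x vs y (antiparallel)
enumerate_duplexes <- function(x, y) {
  m <- nchar(x); n <- nchar(y)
  out <- list(matrix(integer(0), ncol = 2))
  rec <- function(i, jmax, acc) {
    if (i > m) return()
    rec(i + 1, jmax, acc)                 # skip position i on x
    for (j in seq_len(jmax)) {
      acc2 <- rbind(acc, c(i, j))
      out[[length(out) + 1]] <<- acc2
      rec(i + 1, j - 1, acc2)
    }
  }
  rec(1, n, matrix(integer(0), ncol = 2))
  out
}

brute_force_duplex <- function(x, y, par = rna_energy_params()) {
  cands <- enumerate_duplexes(x, y)
  min(vapply(cands, function(p) {
    stagemir::duplex_structure_energy(x, y, p, par)
  }, numeric(1)), 0)
}

## direct-summation two-sided conditional binomial p-value
direct_binom_p <- function(a, ta, b, tb) {
  n <- a + b
  if (n == 0) return(1)
  pr <- ta / (ta + tb)
  logd <- lchoose(n, 0:n) + (0:n) * log(pr) + (n - (0:n)) * log1p(-pr)
  obs <- logd[a + 1]
  min(1, sum(exp(logd[logd <= obs + log1p(1e-7)])))
}

## literal re-check of the five degradome category rules
literal_category <- function(abundances, position_index) {
  a <- abundances[position_index]
  M <- max(abundances)
  med <- stats::median(abundances)
  if (a == 1) return(4L)
  if (a == M && sum(abundances == M) == 1) return(0L)
  if (a == M) return(1L)
  if (a > med) return(2L)
  3L
}
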