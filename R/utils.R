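#' Canonicalize nucleotide sequences
#'
#' Sequences are stored internally in the DNA alphabet (U converted to T,
#' everything uppercased) so that catalogs mixing RNA and DNA conventions
#' compare equal. [as_rna()] converts back for display or folding.
#'
#' @param x Character vector of sequences.
#' @return Character vector in the canonical (DNA, uppercase) alphabet.
#' @examples
#' canonical_seq(c("augc", "ATGC"))
#' @export
canonical_seq <- function(x) {
  x <- unname(chartr("u", "U", toupper(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(head(which(bad), 3), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname canonical_seq
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement
#'
#' @param x Character vector of DNA/RNA sequences.
#' @return Reverse complement in the canonical DNA alphabet.
#' @export
revcomp <- function(x) {
  x <- canonical_seq(x)
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

## all substrings of `x` with lengths in `lens`, for exact-match indexing
substr_index <- function(x, lens) {
  out <- lapply(lens, function(L) {
    keep <- nchar(x) >= L
    if (!any(keep)) return(character(0))
    unlist(lapply(which(keep), function(i) {
      n <- nchar(x[i])
      substring(x[i], 1:(n - L + 1), L:n)
    }), use.names = FALSE)
  })
  unique(unlist(out, use.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
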