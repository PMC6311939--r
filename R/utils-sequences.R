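# Internal sequence helpers. All pipeline logic works on uppercase RNA
# (A/C/G/U); DNA (T) is accepted on input and converted once at the boundary.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and converts T to U. Ambiguity codes are left untouched (they
#' count as mismatches downstream and against the low-quality filter during
#' trimming).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over the RNA alphabet.
#' @export
rna <- function(x) {
  chartr("tT", "uU", toupper(x))
}

#' Convert to the DNA alphabet (U to T)
#'
#' Used at the boundary with Biostrings matching, which operates on
#' `DNAString` objects.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over the DNA alphabet.
#' @export
dna <- function(x) {
  chartr("uU", "tT", toupper(x))
}

#' Reverse complement in the RNA alphabet
#'
#' @param x character vector of RNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", rna(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# complement of single characters, RNA
comp_base <- function(b) chartr("ACGU", "UGCA", b)

# integer encoding A=1 C=2 G=3 U=4, anything else 5
seq_to_int <- function(x) {
  idx <- match(strsplit(rna(x), "", fixed = TRUE)[[1]], RNA_BASES)
  idx[is.na(idx)] <- 5L
  idx
}

# split into single characters (RNA normalized)
seq_chars <- function(x) strsplit(rna(x), "", fixed = TRUE)[[1]]

# fraction of characters outside A/C/G/U
ambig_frac <- function(x) {
  ch <- seq_chars(x)
  if (length(ch) == 0L) return(0)
  mean(!ch %in% RNA_BASES)
}

# random RNA string(s) from the current RNG stream; len is recycled
random_rna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# stopifnot-style check with a clean message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
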