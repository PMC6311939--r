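# Secondary-structure prediction for precursor candidates.

#' Fold an RNA sequence by maximum base pairing
#'
#' Predicts a pseudoknot-free structure with pairs restricted to
#' Watson-Crick plus G:U and a minimum hairpin loop of `min_loop` unpaired
#' bases, maximizing the number of pairs (Nussinov). The score is the paired
#' count sign-flipped so that lower is better, comparable in spirit (not in
#' units) to a free-energy estimate.
#'
#' @param sequence RNA string, length <= 400.
#' @param min_loop minimum number of unpaired bases enclosed by a pair.
#' @return list with `structure` (dot-bracket string), `npairs`,
#'   `score` (`-npairs`), `partner` (integer vector, 0 = unpaired) and
#'   `engine` (`"nussinov"`).
#' @export
fold <- function(sequence, min_loop = 3L) {
  s <- rna(sequence)
  ch <- seq_chars(s)
  check_that(length(ch) > 0L, "cannot fold an empty sequence")
  check_that(all(ch %in% RNA_BASES),
             "sequence contains characters outside A/C/G/U")
  check_that(length(ch) <= 400L, "fold() accepts sequences up to 400 nt")
  res <- .nussinov_fold(seq_to_int(s), as.integer(min_loop))
  list(structure = res$structure, npairs = res$npairs,
       score = -res$npairs, partner = res$partner, engine = "nussinov")
}

#' Partner map of a dot-bracket structure
#'
#' @param structure dot-bracket string (balanced round brackets).
#' @return integer vector; `partner[i]` is the position paired with i, 0 if
#'   unpaired.
#' @export
db_partner <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      check_that(length(stack) > 0L, "unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  check_that(length(stack) == 0L, "unbalanced dot-bracket structure")
  partner
}
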