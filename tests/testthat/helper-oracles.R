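# Independent oracles used to validate the package's algorithms. These are
# deliberately naive (character-by-character, exhaustive) and share no code
# with the implementation paths they check.

# --- adapter trimming: scan every offset by character comparison ------------
oracle_trim <- function(read, adapter, min_overlap = 5L) {
  norm <- function(x) chartr("tT", "uU", toupper(x))
  r <- strsplit(norm(read), "")[[1]]
  a <- strsplit(norm(adapter), "")[[1]]
  n <- length(r); al <- length(a)
  for (start in seq_len(n)) {
    len <- min(al, n - start + 1L)
    full <- len == al
    at_end <- (start + len - 1L) == n
    if (!full && !(at_end && len >= min_overlap)) next
    if (all(r[start:(start + len - 1L)] == a[seq_len(len)])) {
      return(start - 1L)  # trimmed length
    }
  }
  NA_integer_
}

# --- maximum base pairing: exhaustive recursion over all structures ---------
oracle_pairable <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!oracle_pairable(ch[i], ch[k])) next
      cand <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
      if (cand > best) best <- cand
    }
    best
  }
  rec(1L, length(ch))
}

# --- target-site scoring: per-window lookup built from first principles -----
ORACLE_PAIR_TABLE <- local({
  keys <- c(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  cls <- rep("mismatch", 16)
  names(cls) <- keys
  cls[c("AU", "UA", "CG", "GC")] <- "match"
  cls[c("GU", "UG")] <- "wobble"
  cls
})

oracle_score_window <- function(mirna, window) {
  m <- strsplit(mirna, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])
  cls <- ORACLE_PAIR_TABLE[paste0(m, w)]
  cls[is.na(cls)] <- "mismatch"
  sum(cls == "mismatch") + 0.5 * sum(cls == "wobble")
}

oracle_find_sites <- function(mirna, transcript, max_score = 4) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  if (n < L) {
    return(data.frame(site_start = integer(0), mismatch_score = numeric(0)))
  }
  starts <- 1:(n - L + 1L)
  scores <- vapply(starts, function(s) {
    oracle_score_window(mirna, substr(transcript, s, s + L - 1L))
  }, numeric(1))
  keep <- scores <= max_score
  out <- data.frame(site_start = starts[keep], mismatch_score = scores[keep])
  out[order(out$mismatch_score, out$site_start), , drop = FALSE]
}

# --- miRNA/miRNA* duplex: exhaustive ungapped pairing over all offsets ------
# Aligns the mature (5'->3') against the reversed star; returns, for the
# offset with the most Watson-Crick/G:U pairs, the fraction of mature bases
# paired and the star 3' overhang implied by that offset.
oracle_duplex <- function(mature, star) {
  m <- strsplit(mature, "")[[1]]
  srev <- rev(strsplit(star, "")[[1]])
  Lm <- length(m); Ls <- length(srev)
  best <- list(pairs = -1L, offset = NA_integer_)
  for (d in (-(Lm - 1L)):(Ls - 1L)) {
    pairs <- 0L
    for (i in seq_len(Lm)) {
      j <- i + d
      if (j >= 1L && j <= Ls && oracle_pairable(m[i], srev[j])) {
        pairs <- pairs + 1L
      }
    }
    if (pairs > best$pairs) best <- list(pairs = pairs, offset = d)
  }
  list(paired_frac = best$pairs / Lm, overhang = best$offset,
       unpaired = Lm - best$pairs)
}

# --- genome scan by regex on both strands -----------------------------------
oracle_map_tag <- function(tag, genome) {
  rc <- mirseek::revcomp(tag)
  rows <- list()
  for (chrom in names(genome)) {
    g <- mirseek::rna(genome[[chrom]])
    for (x in list(c(tag, "+"), c(rc, "-"))) {
      hits <- gregexpr(x[1], g, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = as.integer(hits),
        end = as.integer(hits) + nchar(tag) - 1L, strand = x[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# random RNA helper for tests (independent of package internals)
rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
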