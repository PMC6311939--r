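# Degradome (PARE) target identification: wobble-aware complementarity
# scoring, site search, and the valid-reads-at-cleavage-site statistic.

# 4x5 lookup tables on codes A=1 C=2 G=3 U=4, other=5; rows are the miRNA
# base, columns the target base
PAIR_MATCH_M <- local({
  m <- matrix(FALSE, 4, 5)
  m[1, 4] <- m[4, 1] <- m[2, 3] <- m[3, 2] <- TRUE  # WC: A:U U:A C:G G:C
  m
})
PAIR_WOBBLE_M <- local({
  m <- matrix(FALSE, 4, 5)
  m[3, 4] <- m[4, 3] <- TRUE                         # G:U and U:G
  m
})

#' Classify one miRNA/target base pair
#'
#' @param mirna_base,target_base single bases in A/C/G/U.
#' @return `"match"` (Watson-Crick), `"wobble"` (G:U or U:G) or
#'   `"mismatch"`.
#' @export
pair_class <- function(mirna_base, target_base) {
  a <- match(rna(mirna_base), RNA_BASES)
  b <- match(rna(target_base), RNA_BASES)
  check_that(!is.na(a) && !is.na(b), "bases must be one of A/C/G/U")
  if (PAIR_MATCH_M[a, b]) "match" else if (PAIR_WOBBLE_M[a, b]) "wobble"
  else "mismatch"
}

#' Score a miRNA against one transcript window
#'
#' The alignment is ungapped and antiparallel: miRNA position 1 (5' end)
#' pairs the last base of the window. The score counts each mismatch as 1
#' and each G:U wobble as `wobble_weight`.
#'
#' @param mirna_seq miRNA sequence.
#' @param transcript_window transcript window of the same length.
#' @param wobble_weight contribution of a wobble pair (default 0.5, giving
#'   the half-unit scores seen in degradome target tables).
#' @return numeric mismatch score.
#' @export
score_site <- function(mirna_seq, transcript_window, wobble_weight = 0.5) {
  m <- seq_to_int(mirna_seq)
  w <- seq_to_int(transcript_window)
  check_that(length(m) == length(w), "window length must equal miRNA length")
  tb <- w[length(w):1]
  idx <- cbind(m, tb)
  mism <- sum(!(PAIR_MATCH_M[idx] | PAIR_WOBBLE_M[idx]))
  wob <- sum(PAIR_WOBBLE_M[idx])
  mism + wobble_weight * wob
}

#' Find miRNA complementary sites on a transcript
#'
#' Scans every window of miRNA length and keeps windows whose wobble-aware
#' mismatch score is at most `max_score`. The expected cleavage position is
#' the transcript base paired to miRNA position 10, i.e. `site_start +
#' (L - 10)`, so that cleavage falls opposite the bond between miRNA
#' positions 10 and 11.
#'
#' @param mirna_seq miRNA sequence (length L).
#' @param transcript_seq transcript sequence.
#' @param max_score maximum accepted score (default 4).
#' @param mirna_id,transcript_id identifiers copied into the result.
#' @param wobble_weight passed to the scoring (default 0.5).
#' @return data.frame with `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end`, `mismatch_score`, `expected_cleavage_pos`, sorted by score
#'   then position; zero rows when the transcript is shorter than the miRNA.
#' @export
find_sites <- function(mirna_seq, transcript_seq, max_score = 4,
                       mirna_id = NA_character_,
                       transcript_id = NA_character_, wobble_weight = 0.5) {
  m <- seq_to_int(mirna_seq)
  t <- seq_to_int(transcript_seq)
  L <- length(m)
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      mismatch_score = numeric(0),
                      expected_cleavage_pos = integer(0),
                      stringsAsFactors = FALSE)
  if (length(t) < L) return(empty)
  starts <- seq_len(length(t) - L + 1L)
  mism <- numeric(length(starts))
  wob <- numeric(length(starts))
  for (k in seq_len(L)) {
    tb <- t[starts + (L - k)]
    idx <- cbind(m[k], tb)
    mism <- mism + !(PAIR_MATCH_M[idx] | PAIR_WOBBLE_M[idx])
    wob <- wob + PAIR_WOBBLE_M[idx]
  }
  score <- mism + wobble_weight * wob
  keep <- which(score <= max_score)
  if (length(keep) == 0L) return(empty)
  out <- data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
                    site_start = starts[keep],
                    site_end = starts[keep] + L - 1L,
                    mismatch_score = score[keep],
                    expected_cleavage_pos = starts[keep] + (L - 10L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mismatch_score, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count degradome reads at a site's expected cleavage position
#'
#' @param site one-row data.frame (or list) with `transcript_id` and
#'   `expected_cleavage_pos`.
#' @param reads degradome reads data.frame (`transcript_id`,
#'   `five_prime_pos`, `count`).
#' @param window reads with 5' ends within `expected_cleavage_pos +/-
#'   window` count as valid (default 1; 0 demands the exact position).
#' @return list with `valid_reads` and `total_reads` (all reads on the
#'   transcript).
#' @export
tally_reads <- function(site, reads, window = 1L) {
  on_tx <- reads[reads$transcript_id == site$transcript_id, , drop = FALSE]
  total <- sum(on_tx$count)
  valid <- sum(on_tx$count[abs(on_tx$five_prime_pos -
                                 site$expected_cleavage_pos) <= window])
  list(valid_reads = as.integer(valid), total_reads = as.integer(total))
}

# half-up rounding to `digits` decimals
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage of degradome reads at the expected cleavage site
#'
#' @param valid_reads,total_reads read counts with `0 <= valid_reads <=
#'   total_reads` and `total_reads >= 1`.
#' @return `100 * valid_reads / total_reads`, rounded half-up to one
#'   decimal.
#' @export
percent_at_cleavage <- function(valid_reads, total_reads) {
  check_that(all(total_reads >= 1), "total_reads must be >= 1")
  check_that(all(valid_reads >= 0 & valid_reads <= total_reads),
             "need 0 <= valid_reads <= total_reads")
  round_half_up(100 * valid_reads / total_reads, 1L)
}

#' Format a cleavage percentage in report style
#'
#' Whole numbers print bare (`"50"`), others with one decimal (`"17.4"`).
#'
#' @param p percentage value(s) from [percent_at_cleavage()].
#' @return character vector.
#' @export
format_percent <- function(p) {
  ifelse(p == round(p), as.character(as.integer(round(p))),
         formatC(p, format = "f", digits = 1))
}

#' Build the per-genotype target report
#'
#' For every complementary site and genotype, tallies valid and total
#' degradome reads and emits rows with at least `min_valid` valid reads.
#' Sites of non-conserved miRNAs are additionally required to show cleavage
#' (valid reads >= 1) for the same (miRNA family, target gene) pair in at
#' least `require_genotypes` genotypes; conserved families are exempt.
#'
#' @param sites data.frame of complementary sites as from [find_sites()].
#' @param reads_by_genotype named list of degradome read data.frames, one
#'   per genotype.
#' @param min_valid minimum valid reads for a reported row.
#' @param require_genotypes cross-genotype support demanded of non-conserved
#'   miRNAs.
#' @param conserved character vector of conserved family names (`NULL`
#'   treats every family as conserved).
#' @param window passed to [tally_reads()].
#' @param family_of function mapping a miRNA id to its family (default
#'   strips species prefix, arm and letter suffix).
#' @param annotations named character vector of gene annotations (by
#'   transcript id).
#' @return data.frame with `genotype`, `mirna_id`, `target_gene`,
#'   `mismatch_score`, `valid_reads`, `total_reads`, `percent`,
#'   `annotation`, sorted by genotype, miRNA, gene.
#' @export
build_target_report <- function(sites, reads_by_genotype, min_valid = 1L,
                                require_genotypes = 2L, conserved = NULL,
                                window = 1L, family_of = NULL,
                                annotations = NULL) {
  if (is.null(family_of)) {
    family_of <- function(id) parse_mirbase_name(id)$family
  }
  rows <- list()
  for (g in names(reads_by_genotype)) {
    reads <- reads_by_genotype[[g]]
    for (i in seq_len(nrow(sites))) {
      site <- sites[i, ]
      tal <- tally_reads(site, reads, window)
      if (tal$total_reads < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, mirna_id = site$mirna_id,
        target_gene = site$transcript_id,
        mismatch_score = site$mismatch_score,
        valid_reads = tal$valid_reads, total_reads = tal$total_reads,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_target_report())
  df <- do.call(rbind, rows)
  df$family <- family_of(df$mirna_id)
  # cross-genotype support on (family, gene) pairs with any cleavage signal
  cleaved <- df[df$valid_reads >= 1L, , drop = FALSE]
  support <- tapply(cleaved$genotype, paste(cleaved$family, cleaved$target_gene),
                    function(x) length(unique(x)))
  df$n_genotypes <- as.integer(support[paste(df$family, df$target_gene)])
  df$n_genotypes[is.na(df$n_genotypes)] <- 0L
  is_cons <- if (is.null(conserved)) rep(TRUE, nrow(df)) else
    df$family %in% conserved
  keep <- df$valid_reads >= min_valid &
    (is_cons | df$n_genotypes >= require_genotypes)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(empty_target_report())
  df$percent <- percent_at_cleavage(df$valid_reads, df$total_reads)
  df$annotation <- if (is.null(annotations)) "" else {
    a <- annotations[df$target_gene]
    ifelse(is.na(a), "", a)
  }
  df <- df[order(df$genotype, df$mirna_id, df$target_gene),
           c("genotype", "mirna_id", "target_gene", "mismatch_score",
             "valid_reads", "total_reads", "percent", "annotation")]
  rownames(df) <- NULL
  df
}

empty_target_report <- function() {
  data.frame(genotype = character(0), mirna_id = character(0),
             target_gene = character(0), mismatch_score = numeric(0),
             valid_reads = integer(0), total_reads = integer(0),
             percent = numeric(0), annotation = character(0),
             stringsAsFactors = FALSE)
}

#' Find sites for many miRNAs across a transcriptome
#'
#' Convenience wrapper over [find_sites()].
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param max_score,wobble_weight passed to [find_sites()].
#' @return combined site data.frame.
#' @export
find_sites_all <- function(mirnas, transcripts, max_score = 4,
                           wobble_weight = 0.5) {
  rows <- list()
  for (mi in names(mirnas)) {
    for (tx in names(transcripts)) {
      s <- find_sites(mirnas[[mi]], transcripts[[tx]], max_score,
                      mirna_id = mi, transcript_id = tx,
                      wobble_weight = wobble_weight)
      if (nrow(s) > 0L) rows[[length(rows) + 1L]] <- s
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- find_sites("ACGU", "A")  # canonical empty frame
  rownames(out) <- NULL
  out
}
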