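# Novel miRNA discovery: genome mapping of unannotated tags, precursor
# excision, fold-back prediction, miRNA/miRNA* duplex checking, and the
# multi-library support filter.

#' Map tag sequences to a genome by exact (or near-exact) matching
#'
#' Reports all occurrences on both strands in 1-based plus-strand
#' coordinates. Tags hitting more loci than `max_loci` are flagged
#' (`multimapped`) so discovery can exclude them.
#'
#' @param sequences character vector of tag sequences (RNA or DNA).
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatches allowed substitutions (default 0, exact; the tags
#'   may come from a sister species of the reference genome, so 1 is a
#'   reasonable relaxation).
#' @param max_loci multi-mapping cap.
#' @return list with `loci` (data.frame `sequence`, `chrom`, `start`, `end`,
#'   `strand`) and `multimapped` (character vector of excluded sequences).
#' @export
map_tags_to_genome <- function(sequences, genome, max_mismatches = 0L,
                               max_loci = 20L) {
  subj <- Biostrings::DNAStringSet(dna(genome))
  chroms <- names(genome)
  rows <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    pat <- Biostrings::DNAString(dna(sequences[i]))
    fwd <- Biostrings::vmatchPattern(pat, subj, max.mismatch = max_mismatches)
    rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(pat), subj,
                                     max.mismatch = max_mismatches)
    fs <- IRanges::start(fwd); rs <- IRanges::start(rev)
    n_f <- lengths(fs); n_r <- lengths(rs)
    w <- nchar(sequences[i])
    if (sum(n_f) + sum(n_r) == 0L) next
    rows[[i]] <- data.frame(
      sequence = rna(sequences[i]),
      chrom = c(rep(chroms, n_f), rep(chroms, n_r)),
      start = c(unlist(fs, use.names = FALSE), unlist(rs, use.names = FALSE)),
      strand = c(rep("+", sum(n_f)), rep("-", sum(n_r))),
      stringsAsFactors = FALSE)
    rows[[i]]$end <- rows[[i]]$start + w - 1L
  }
  loci <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(loci)) {
    loci <- data.frame(sequence = character(0), chrom = character(0),
                       start = integer(0), strand = character(0),
                       end = integer(0), stringsAsFactors = FALSE)
  }
  nhits <- table(loci$sequence)
  multi <- names(nhits)[nhits > max_loci]
  loci <- loci[!loci$sequence %in% multi,
               c("sequence", "chrom", "start", "end", "strand")]
  rownames(loci) <- NULL
  list(loci = loci, multimapped = multi)
}

#' Excise candidate precursor windows around a mapped tag locus
#'
#' Two windows are returned so the tag can sit on either precursor arm: one
#' with `flank_short` bases on the tag's 5' side and `flank_long` on its 3'
#' side (tag on the 5p arm), and the mirror (tag on the 3p arm). Windows are
#' clipped at chromosome ends and strand-corrected, so the returned sequence
#' reads 5' to 3' along the precursor.
#'
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome named character vector of chromosome sequences.
#' @param flank_short,flank_long excision flanks in nt.
#' @return data.frame with `arm` ("5p"/"3p" for the tag's assumed arm),
#'   `gstart`, `gend` (plus-strand coordinates), `strand`, `sequence` (RNA).
#' @export
excise_precursor <- function(locus, genome, flank_short = 15L,
                             flank_long = 200L) {
  chrom <- genome[[locus$chrom]]
  check_that(!is.null(chrom), "locus chromosome not found in genome")
  n <- nchar(chrom)
  check_that(locus$start >= 1L && locus$end <= n && locus$start <= locus$end,
             "locus outside chromosome")
  check_that(flank_short >= 0L && flank_long >= 0L, "flanks must be >= 0")
  # flanks are in transcript orientation; swap on the minus strand
  up <- if (locus$strand == "+") c(flank_short, flank_long) else
    c(flank_long, flank_short)
  win <- rbind(
    c(max(1L, locus$start - up[1]), min(n, locus$end + up[2])),
    c(max(1L, locus$start - up[2]), min(n, locus$end + up[1])))
  arms <- c("5p", "3p")
  seqs <- substr(rep(rna(chrom), 2L), win[, 1], win[, 2])
  if (locus$strand == "-") seqs <- revcomp(seqs)
  data.frame(arm = arms, gstart = win[, 1], gend = win[, 2],
             strand = locus$strand, sequence = seqs, stringsAsFactors = FALSE)
}

#' Check that observed mature and star tags form a proper duplex
#'
#' On the predicted precursor structure, requires that (a) mature and star
#' occupy disjoint spans on opposite arms and pair with each other, (b) at
#' least `min_paired_frac` of mature bases pair with star bases, (c) the star
#' shows the canonical 2-nt 3' overhang within `overhang_tol`, and (d) at
#' most `max_unpaired` mature bases are unpaired.
#'
#' @param hairpin list with `precursor_seq`, `structure` (dot-bracket; if
#'   `NULL` the precursor is folded with [fold()]), `mature_span` and
#'   `star_span` (length-2 integer vectors, 1-based closed intervals on the
#'   precursor).
#' @param min_paired_frac minimum fraction of mature bases paired to star.
#' @param max_unpaired maximum unpaired mature bases.
#' @param overhang expected star 3' overhang in nt.
#' @param overhang_tol tolerated deviation from `overhang`.
#' @return list with `pass` (logical), `reason` (`"ok"` or the first failed
#'   check), `paired_frac`, `n_unpaired`, `overhang`.
#' @export
check_duplex <- function(hairpin, min_paired_frac = 0.6, max_unpaired = 5L,
                         overhang = 2L, overhang_tol = 1L) {
  ms <- hairpin$mature_span
  ss <- hairpin$star_span
  fail <- function(reason) list(pass = FALSE, reason = reason,
                                paired_frac = NA_real_,
                                n_unpaired = NA_integer_,
                                overhang = NA_integer_)
  if (max(ms[1], ss[1]) <= min(ms[2], ss[2])) return(fail("same_arm"))
  structure <- hairpin$structure
  if (is.null(structure)) structure <- fold(hairpin$precursor_seq)$structure
  partner <- db_partner(structure)
  n <- length(partner)
  check_that(ms[1] >= 1L && ms[2] <= n && ss[1] >= 1L && ss[2] <= n,
             "spans outside precursor")
  mpos <- ms[1]:ms[2]
  p <- partner[mpos]
  in_star <- p >= ss[1] & p <= ss[2]
  if (!any(in_star)) return(fail("no_duplex_pairing"))
  paired_frac <- mean(in_star)
  n_unpaired <- sum(p == 0L)
  # duplex register: in an antiparallel duplex, position + partner is
  # constant; the modal antidiagonal is robust to slipped terminal pairs
  antidiag <- mpos[in_star] + p[in_star]
  tab <- table(antidiag)
  reg <- as.integer(names(tab)[which.max(tab)])
  oh <- ss[2] - (reg - ms[1])
  out <- list(pass = TRUE, reason = "ok", paired_frac = paired_frac,
              n_unpaired = n_unpaired, overhang = oh)
  if (paired_frac < min_paired_frac) {
    out$pass <- FALSE; out$reason <- "low_pairing"
  } else if (abs(oh - overhang) > overhang_tol) {
    out$pass <- FALSE; out$reason <- "bad_overhang"
  } else if (n_unpaired > max_unpaired) {
    out$pass <- FALSE; out$reason <- "too_many_unpaired"
  }
  out
}

# assemble per-library count matrix for a set of sequences
count_matrix <- function(sequences, libraries) {
  libs <- vapply(libraries, function(x) x$library_id[1], character(1))
  m <- matrix(0L, nrow = length(sequences), ncol = length(libraries),
              dimnames = list(sequences, libs))
  for (j in seq_along(libraries)) {
    idx <- match(sequences, libraries[[j]]$sequence)
    m[, j] <- ifelse(is.na(idx), 0L, libraries[[j]]$count[idx])
  }
  m
}

#' Discover novel miRNA candidates from multi-library tag sets
#'
#' Maps candidate tags to the genome, pairs loci of two tags lying close
#' together on one strand, folds the genomic segment spanning both arms, and
#' applies the duplex check with the more abundant arm taken as the mature.
#' Candidates then pass the support filter of [call_novel()].
#'
#' @param libraries list of collapsed tag data.frames (`sequence`, `count`,
#'   `library_id`), one per library.
#' @param genome named character vector of chromosome sequences.
#' @param genotype_of named character vector mapping library_id to genotype;
#'   defaults to one genotype per library.
#' @param exclude character vector of sequences to skip (e.g. known mature
#'   miRNAs).
#' @param min_len,max_len tag length window considered.
#' @param max_span maximum genomic span of a hairpin (mature start to star
#'   end).
#' @param min_gap minimum loop gap between the two arms.
#' @param pad extra bases folded on each side of the arm-spanning segment.
#' @param max_mismatches,max_loci passed to [map_tags_to_genome()].
#' @param min_libraries,min_count passed to [call_novel()].
#' @param ... further arguments passed to [check_duplex()].
#' @return data.frame of novel calls (see [call_novel()]).
#' @export
discover_novel <- function(libraries, genome, genotype_of = NULL,
                           exclude = character(0), min_len = 20L,
                           max_len = 24L, max_span = 250L, min_gap = 3L,
                           pad = 0L, max_mismatches = 0L, max_loci = 20L,
                           min_libraries = 3L, min_count = 5L, ...) {
  all_seqs <- unique(unlist(lapply(libraries, `[[`, "sequence")))
  len <- nchar(all_seqs)
  cand <- setdiff(all_seqs[len >= min_len & len <= max_len], rna(exclude))
  if (length(cand) == 0L) return(empty_novel_calls(libraries))
  mapped <- map_tags_to_genome(cand, genome, max_mismatches, max_loci)
  loci <- mapped$loci
  if (nrow(loci) == 0L) return(empty_novel_calls(libraries))
  counts <- count_matrix(unique(loci$sequence), libraries)

  hairpins <- list()
  for (chrom in unique(loci$chrom)) {
    for (strand in c("+", "-")) {
      sub <- loci[loci$chrom == chrom & loci$strand == strand, , drop = FALSE]
      if (nrow(sub) < 2L) next
      sub <- sub[order(sub$start), , drop = FALSE]
      for (i in seq_len(nrow(sub) - 1L)) {
        for (j in (i + 1L):nrow(sub)) {
          gap <- sub$start[j] - sub$end[i] - 1L
          span <- sub$end[j] - sub$start[i] + 1L
          if (span > max_span) break
          if (gap < min_gap) next
          if (sub$sequence[i] == sub$sequence[j]) next
          hairpins[[length(hairpins) + 1L]] <-
            build_hairpin(sub[i, ], sub[j, ], genome, pad, counts, ...)
        }
      }
    }
  }
  hairpins <- hairpins[!vapply(hairpins, is.null, logical(1))]
  call_novel(hairpins, libraries, genotype_of,
             min_libraries = min_libraries, min_count = min_count)
}

# fold the segment spanning two same-strand loci and run the duplex check;
# returns a candidate record or NULL
build_hairpin <- function(a, b, genome, pad, counts, ...) {
  chrom <- genome[[a$chrom]]
  gstart <- max(1L, a$start - pad)
  gend <- min(nchar(chrom), b$end + pad)
  seg <- rna(substr(chrom, gstart, gend))
  if (a$strand == "-") seg <- revcomp(seg)
  # precursor coordinates of the two arms (transcript orientation)
  if (a$strand == "+") {
    span_a <- c(a$start, a$end) - gstart + 1L
    span_b <- c(b$start, b$end) - gstart + 1L
  } else {
    span_a <- gend - c(a$end, a$start) + 1L
    span_b <- gend - c(b$end, b$start) + 1L
  }
  # 5p arm = the one nearer the precursor 5' end
  if (span_a[1] <= span_b[1]) {
    arm5 <- list(seq = a$sequence, span = span_a)
    arm3 <- list(seq = b$sequence, span = span_b)
  } else {
    arm5 <- list(seq = b$sequence, span = span_b)
    arm3 <- list(seq = a$sequence, span = span_a)
  }
  tot5 <- sum(counts[arm5$seq, ])
  tot3 <- sum(counts[arm3$seq, ])
  mature_arm <- if (tot5 >= tot3) "5p" else "3p"  # tie prefers 5p
  f <- fold(seg)
  hp <- list(precursor_seq = seg, structure = f$structure,
             mfe_score = f$score,
             mature_span = if (mature_arm == "5p") arm5$span else arm3$span,
             star_span = if (mature_arm == "5p") arm3$span else arm5$span,
             mature_arm = mature_arm,
             locus = list(chrom = a$chrom, start = gstart, end = gend,
                          strand = a$strand))
  chk <- check_duplex(hp, ...)
  if (!chk$pass) return(NULL)
  hp$duplex <- chk
  hp$seq_5p <- arm5$seq
  hp$seq_3p <- arm3$seq
  hp
}

empty_novel_calls <- function(libraries) {
  libs <- vapply(libraries, function(x) x$library_id[1], character(1))
  out <- data.frame(seq_5p = character(0), seq_3p = character(0),
                    dominant_arm = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
  for (l in libs) {
    out[[paste0(l, "_5p")]] <- integer(0)
    out[[paste0(l, "_3p")]] <- integer(0)
  }
  attr(out, "hairpins") <- list()
  out
}

#' Apply the multi-library support filter to duplex-passing candidates
#'
#' A candidate is called when its mature arm was sequenced with at least
#' `min_count` reads in at least `min_libraries` genotypes and its star arm
#' was sequenced (count >= 1) in at least one library. The dominant arm is
#' the arm with the greater summed count (ties prefer 5p).
#'
#' @param hairpins list of duplex-passing hairpin candidates (as built by
#'   [discover_novel()]).
#' @param libraries list of collapsed tag data.frames.
#' @param genotype_of named character vector mapping library_id to genotype
#'   (default: each library is its own genotype).
#' @param min_libraries minimum number of genotypes with mature support.
#' @param min_count minimum mature count per supporting genotype.
#' @return data.frame with one row per called miRNA: `seq_5p`, `seq_3p`,
#'   `dominant_arm`, locus columns, and per-library counts for both arms;
#'   the `hairpins` attribute keeps the underlying precursor records.
#' @export
call_novel <- function(hairpins, libraries, genotype_of = NULL,
                       min_libraries = 3L, min_count = 5L) {
  libs <- vapply(libraries, function(x) x$library_id[1], character(1))
  if (is.null(genotype_of)) genotype_of <- stats::setNames(libs, libs)
  if (length(hairpins) == 0L) return(empty_novel_calls(libraries))
  key <- vapply(hairpins, function(h) paste(h$seq_5p, h$seq_3p), character(1))
  hairpins <- hairpins[!duplicated(key)]
  seqs <- unique(unlist(lapply(hairpins, function(h) c(h$seq_5p, h$seq_3p))))
  cm <- count_matrix(seqs, libraries)
  genos <- genotype_of[colnames(cm)]
  rows <- list()
  kept <- list()
  for (h in hairpins) {
    c5 <- cm[h$seq_5p, ]; c3 <- cm[h$seq_3p, ]
    dominant <- if (sum(c5) >= sum(c3)) "5p" else "3p"
    mat <- if (dominant == "5p") c5 else c3
    star <- if (dominant == "5p") c3 else c5
    geno_support <- tapply(mat, genos, max)
    if (sum(geno_support >= min_count) < min_libraries) next
    if (sum(star) < 1L) next
    row <- data.frame(seq_5p = h$seq_5p, seq_3p = h$seq_3p,
                      dominant_arm = dominant, chrom = h$locus$chrom,
                      start = h$locus$start, end = h$locus$end,
                      strand = h$locus$strand, stringsAsFactors = FALSE)
    for (l in colnames(cm)) {
      row[[paste0(l, "_5p")]] <- cm[h$seq_5p, l]
      row[[paste0(l, "_3p")]] <- cm[h$seq_3p, l]
    }
    rows[[length(rows) + 1L]] <- row
    kept[[length(kept) + 1L]] <- h
  }
  if (length(rows) == 0L) return(empty_novel_calls(libraries))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hairpins") <- kept
  out
}

#' Render a hairpin candidate as annotated text
#'
#' Prints the precursor, its dot-bracket structure, and a track marking the
#' mature (`M`) and star (`S`) arms — the usual fold-back figure in text
#' form.
#'
#' @param hairpin hairpin record with `precursor_seq`, `structure`,
#'   `mature_span`, `star_span`.
#' @param width wrap width.
#' @return character vector of lines (also printed invisibly usable via
#'   `cat`).
#' @export
render_hairpin <- function(hairpin, width = 60L) {
  n <- nchar(hairpin$precursor_seq)
  marks <- rep(" ", n)
  marks[hairpin$mature_span[1]:hairpin$mature_span[2]] <- "M"
  marks[hairpin$star_span[1]:hairpin$star_span[2]] <- "S"
  marks <- paste(marks, collapse = "")
  lines <- character(0)
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    lines <- c(lines,
               substr(hairpin$precursor_seq, s, e),
               substr(hairpin$structure, s, e),
               substr(marks, s, e), "")
  }
  lines
}
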