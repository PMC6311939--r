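# Reading, trimming and collapsing of small-RNA and degradome reads, plus the
# collapsed-FASTA dialect used between pipeline stages.

#' Trim the 3' sequencing adapter from a single read
#'
#' Finds the leftmost adapter occurrence — either the full adapter anywhere in
#' the read, or an adapter prefix of at least `min_overlap` bases running to
#' the read end — and returns the read prefix preceding it. Reads whose
#' trimmed length falls outside `[min_len, max_len]`, that contain no adapter,
#' that are empty, or that carry too many ambiguous bases are rejected with a
#' reason.
#'
#' @param read nucleotide string (RNA or DNA alphabet).
#' @param adapter 3' adapter sequence, non-empty.
#' @param min_overlap minimum adapter prefix length accepted at the read end
#'   (>= 5).
#' @param min_len,max_len accepted trimmed-length window. The default 18-26 nt
#'   admits the 21/22/24-nt small-RNA size classes; raise `max_len` (up to 34)
#'   for raw accounting.
#' @param max_ambig maximum tolerated fraction of ambiguous (non-ACGU) bases.
#' @return list with elements `status` ("ok" or a rejection reason among
#'   "empty", "low_quality", "no_adapter", "too_short", "too_long") and
#'   `sequence` (trimmed RNA string for "ok", otherwise `NA`).
#' @export
trim_adapter <- function(read, adapter, min_overlap = 5L,
                         min_len = 18L, max_len = 26L, max_ambig = 0.1) {
  check_that(nchar(adapter) > 0L, "adapter must be non-empty")
  check_that(min_overlap >= 5L, "min_overlap must be >= 5")
  r <- rna(read)
  n <- nchar(r)
  if (n == 0L) return(list(status = "empty", sequence = NA_character_))
  if (ambig_frac(r) > max_ambig) {
    return(list(status = "low_quality", sequence = NA_character_))
  }
  a <- rna(adapter)
  al <- nchar(a)

  hit <- NA_integer_
  # full adapter match, leftmost
  full <- regexpr(a, r, fixed = TRUE)
  if (full > 0L) hit <- as.integer(full)
  # adapter prefix reaching the read end, leftmost qualifying start
  max_ov <- min(al - 1L, n)
  if (max_ov >= min_overlap) {
    for (ov in max_ov:min_overlap) {
      start <- n - ov + 1L
      if (substr(r, start, n) == substr(a, 1L, ov)) {
        if (is.na(hit) || start < hit) hit <- start
        break
      }
    }
  }
  if (is.na(hit)) return(list(status = "no_adapter", sequence = NA_character_))
  trimmed <- substr(r, 1L, hit - 1L)
  tl <- nchar(trimmed)
  if (tl < min_len) return(list(status = "too_short", sequence = NA_character_))
  if (tl > max_len) return(list(status = "too_long", sequence = NA_character_))
  list(status = "ok", sequence = trimmed)
}

#' Trim a vector of reads and account for every rejection
#'
#' @param reads character vector of raw reads.
#' @inheritParams trim_adapter
#' @return list with `trimmed` (character vector of retained RNA sequences)
#'   and `rejected` (named integer vector of counts per rejection reason).
#'   `length(trimmed) + sum(rejected) == length(reads)` always holds.
#' @export
trim_reads <- function(reads, adapter, min_overlap = 5L,
                       min_len = 18L, max_len = 26L, max_ambig = 0.1) {
  res <- lapply(reads, trim_adapter, adapter = adapter,
                min_overlap = min_overlap, min_len = min_len,
                max_len = max_len, max_ambig = max_ambig)
  status <- vapply(res, `[[`, character(1), "status")
  trimmed <- vapply(res[status == "ok"], `[[`, character(1), "sequence")
  rej <- table(status[status != "ok"])
  list(trimmed = as.character(trimmed),
       rejected = stats::setNames(as.integer(rej), names(rej)))
}

#' Collapse trimmed reads into unique tags with counts
#'
#' @param reads character vector of trimmed reads (one entry per read).
#' @param library_id identifier attached to every tag.
#' @return data.frame with columns `sequence`, `count`, `library_id`, sorted
#'   by descending count then sequence; the counts sum to `length(reads)`.
#' @export
collapse_reads <- function(reads, library_id = "lib1") {
  if (length(reads) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0),
                      library_id = character(0), stringsAsFactors = FALSE))
  }
  tab <- table(rna(reads))
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    library_id = library_id, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tags as collapsed FASTA with `>id_xCOUNT` headers
#'
#' @param tags data.frame as returned by [collapse_reads()]; an optional `id`
#'   column supplies tag identifiers, otherwise `t1, t2, ...` in table order.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_collapsed_fasta <- function(tags, path) {
  ids <- if ("id" %in% names(tags)) tags$id else paste0("t", seq_len(nrow(tags)))
  lines <- character(2L * nrow(tags))
  lines[c(TRUE, FALSE)] <- sprintf(">%s_x%d", ids, tags$count)
  lines[c(FALSE, TRUE)] <- tags$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Read collapsed FASTA with `>id_xCOUNT` headers
#'
#' @param path collapsed FASTA file.
#' @param library_id library identifier attached to the tags (defaults to the
#'   file name without extension).
#' @return data.frame with columns `id`, `sequence`, `count`, `library_id`.
#' @export
read_collapsed_fasta <- function(path, library_id = NULL) {
  if (is.null(library_id)) {
    library_id <- sub("\\.[^.]*$", "", basename(path))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  m <- regmatches(headers, regexec("^(.*)_x([0-9]+)$", headers))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed collapsed-FASTA header (expected 'id_xCOUNT'): ",
         headers[bad][1], call. = FALSE)
  }
  data.frame(id = vapply(m, `[[`, character(1), 2L),
             sequence = rna(as.character(set)),
             count = as.integer(vapply(m, `[[`, character(1), 3L)),
             library_id = library_id,
             stringsAsFactors = FALSE)
}

#' Read plain FASTA into a named character vector
#'
#' @param path FASTA file.
#' @param alphabet "rna" (default) normalizes to A/C/G/U; "dna" to A/C/G/T.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  x <- as.character(set)
  names(x) <- sub("\\s.*$", "", names(set))
  if (alphabet == "rna") rna(x) else dna(x)
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width for wrapping.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read raw reads from FASTQ (sequences only)
#'
#' Qualities are not interpreted beyond Biostrings' parsing; the pipeline
#' applies no base-quality thresholds.
#'
#' @param path FASTQ file (4-line records).
#' @return character vector of reads in the RNA alphabet.
#' @export
read_fastq_reads <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  rna(as.character(set))
}

#' Read degradome 5'-end positions from a 3-column TSV
#'
#' Columns: `transcript_id`, `five_prime_pos` (1-based position of the read
#' 5' end on the transcript), `count`.
#'
#' @param path TSV file with a header line.
#' @return data.frame of degradome reads.
#' @export
read_degradome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_that(all(c("transcript_id", "five_prime_pos", "count") %in% names(df)),
             "degradome TSV must have columns transcript_id, five_prime_pos, count")
  df$five_prime_pos <- as.integer(df$five_prime_pos)
  df$count <- as.integer(df$count)
  check_that(all(df$five_prime_pos >= 1L), "five_prime_pos must be >= 1")
  check_that(all(df$count >= 1L), "count must be >= 1")
  df
}

#' Write degradome 5'-end positions as TSV
#'
#' @param reads data.frame with columns `transcript_id`, `five_prime_pos`,
#'   `count`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_degradome <- function(reads, path) {
  utils::write.table(reads[, c("transcript_id", "five_prime_pos", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map fixed-length degradome reads to transcripts by exact match
#'
#' Alternative input route to the positional TSV: each read (a fixed-length
#' 5' tag, as produced by MmeI-based protocols) is located on the transcript
#' set by exact substring match; the match start is the 5'-end position.
#' Reads hitting several transcripts are counted once per transcript.
#'
#' @param reads character vector of degradome read sequences.
#' @param transcripts named character vector of transcript sequences.
#' @return data.frame of degradome reads (`transcript_id`, `five_prime_pos`,
#'   `count`), aggregated over identical positions.
#' @export
map_degradome_reads <- function(reads, transcripts) {
  subj <- Biostrings::DNAStringSet(dna(transcripts))
  tab <- table(dna(reads))
  rows <- vector("list", length(tab))
  for (i in seq_along(tab)) {
    hits <- Biostrings::vmatchPattern(names(tab)[i], subj)
    starts <- IRanges::start(hits)
    nh <- lengths(starts)
    if (sum(nh) == 0L) next
    rows[[i]] <- data.frame(
      transcript_id = rep(names(transcripts), nh),
      five_prime_pos = unlist(starts, use.names = FALSE),
      count = as.integer(tab[[i]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(transcript_id = character(0),
                      five_prime_pos = integer(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(count ~ transcript_id + five_prime_pos, out, sum)
  agg[order(agg$transcript_id, agg$five_prime_pos), ]
}
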