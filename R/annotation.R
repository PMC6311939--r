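# Hierarchical tag classification against reference sets, conserved miRNA
# family assignment, and RPTM family profiling.

CLASSIFY_ORDER <- c("ncRNAs", "pre-miRBase", "repeats", "cdna", "genome")

# categories searched on both strands; mature-miRNA identity stays
# strand-defined and ncRNA/precursor fragments are sense reads
RC_CATEGORIES <- c("repeats", "cdna", "genome")

#' Parse a miRBase-style mature miRNA header
#'
#' Accepts names like `mtr-miR166a-3p`, `msa-miR156`, `ath-miR390a*`.
#' The family is the `miR` number without species prefix, letter suffix or
#' arm; the arm is taken from a trailing `-5p`/`-3p` (defaulting to `5p`
#' when unannotated); a trailing `*` (or `-star`) marks the star strand.
#'
#' @param name character vector of mature miRNA names.
#' @return data.frame with columns `name`, `family`, `arm`, `is_star`.
#' @export
parse_mirbase_name <- function(name) {
  x <- name
  is_star <- grepl("\\*$", x) | grepl("-star$", x, ignore.case = TRUE)
  x2 <- sub("\\*$", "", x)
  x2 <- sub("-star$", "", x2, ignore.case = TRUE)
  arm <- ifelse(grepl("-5p$", x2), "5p", ifelse(grepl("-3p$", x2), "3p", "5p"))
  x2 <- sub("-(5p|3p)$", "", x2)
  x2 <- sub("^[A-Za-z]{3,4}-", "", x2)           # species prefix
  fam <- sub("^((mi|MI)R[-]?[0-9]+).*$", "\\1", x2)
  fam <- sub("^miR-", "miR", fam)
  data.frame(name = name, family = fam, arm = arm, is_star = is_star,
             stringsAsFactors = FALSE)
}

#' Load the reference bundle used for classification and family assignment
#'
#' @param ncrna,premirna,repeats,cdna,genome paths to FASTA files (any may be
#'   `NULL`; the corresponding category is then skipped).
#' @param mature path to a mature miRNA FASTA with miRBase-style headers.
#' @return list of class `reference_bundle` with per-category
#'   `DNAStringSet`s and a `mature` data.frame (`name`, `family`, `arm`,
#'   `is_star`, `sequence` in RNA).
#' @export
load_reference_bundle <- function(ncrna = NULL, premirna = NULL,
                                  repeats = NULL, cdna = NULL,
                                  genome = NULL, mature = NULL) {
  load_set <- function(p) {
    if (is.null(p)) return(NULL)
    Biostrings::DNAStringSet(dna(read_fasta(p, "dna")))
  }
  mat <- NULL
  if (!is.null(mature)) {
    seqs <- read_fasta(mature, "rna")
    mat <- parse_mirbase_name(names(seqs))
    mat$sequence <- unname(seqs)
    check_that(!anyDuplicated(mat$name), "mature miRNA names must be unique")
  }
  structure(list(ncRNAs = load_set(ncrna), `pre-miRBase` = load_set(premirna),
                 repeats = load_set(repeats), cdna = load_set(cdna),
                 genome = load_set(genome), mature = mat),
            class = "reference_bundle")
}

#' Build a reference bundle from in-memory sequences
#'
#' @param ncrna,premirna,repeats,cdna,genome named character vectors of
#'   reference sequences (or `NULL`).
#' @param mature data.frame with columns `name`, `family`, `arm`, `is_star`,
#'   `sequence` (or `NULL`).
#' @return `reference_bundle` list.
#' @export
reference_bundle <- function(ncrna = NULL, premirna = NULL, repeats = NULL,
                             cdna = NULL, genome = NULL, mature = NULL) {
  as_set <- function(x) if (is.null(x)) NULL else Biostrings::DNAStringSet(dna(x))
  structure(list(ncRNAs = as_set(ncrna), `pre-miRBase` = as_set(premirna),
                 repeats = as_set(repeats), cdna = as_set(cdna),
                 genome = as_set(genome), mature = mature),
            class = "reference_bundle")
}

# does `tag` occur in `set` (DNAStringSet), forward and optionally revcomp,
# with at most max_mismatches substitutions?
occurs_in <- function(tag, set, max_mismatches = 0L, rc = FALSE) {
  if (is.null(set) || length(set) == 0L) return(FALSE)
  pat <- Biostrings::DNAString(dna(tag))
  n <- sum(Biostrings::vcountPattern(pat, set, max.mismatch = max_mismatches))
  if (n > 0L) return(TRUE)
  if (rc) {
    n <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                       set, max.mismatch = max_mismatches))
    if (n > 0L) return(TRUE)
  }
  FALSE
}

#' Classify one tag into the first matching reference category
#'
#' Categories are tried in priority order (`ncRNAs`, `pre-miRBase`,
#' `repeats`, `cdna`, `genome`); a match is an exact substring occurrence
#' (allowing `max_mismatches` substitutions), on both strands for the
#' repeat/cdna/genome categories. Tags matching nothing are `"unmapped"`.
#'
#' @param sequence tag sequence.
#' @param refs `reference_bundle`.
#' @param max_mismatches allowed substitutions (default 0, exact).
#' @param order category priority order (a permutation of the default).
#' @return category label, one of the categories or `"unmapped"`.
#' @export
classify_tag <- function(sequence, refs, max_mismatches = 0L,
                         order = CLASSIFY_ORDER) {
  for (cat in order) {
    if (occurs_in(sequence, refs[[cat]], max_mismatches,
                  rc = cat %in% RC_CATEGORIES)) {
      return(cat)
    }
  }
  "unmapped"
}

#' Classify a whole collapsed library and produce per-category accounting
#'
#' @param tags data.frame with columns `sequence` and `count`.
#' @inheritParams classify_tag
#' @return data.frame with one row per category (priority order plus
#'   `unmapped`): `category`, `total_reads`, `unique_reads`; the attribute
#'   `total_clean_reads` holds `sum(tags$count)`.
#' @export
classify_library <- function(tags, refs, max_mismatches = 0L,
                             order = CLASSIFY_ORDER) {
  cats <- vapply(tags$sequence, classify_tag, character(1), refs = refs,
                 max_mismatches = max_mismatches, order = order,
                 USE.NAMES = FALSE)
  levels <- c(order, "unmapped")
  f <- factor(cats, levels = levels)
  out <- data.frame(
    category = levels,
    total_reads = as.integer(tapply(tags$count, f, sum, default = 0L)),
    unique_reads = as.integer(table(f)),
    stringsAsFactors = FALSE)
  attr(out, "total_clean_reads") <- sum(tags$count)
  out
}

#' Assign a tag to conserved miRNA families by mature-sequence identity
#'
#' A tag is assigned when it is identical to a mature reference sequence.
#' With `three_prime_variants > 0`, 3'-end length variants are also accepted:
#' the tag and the mature sequence must be identical over their common
#' prefix and differ in length by at most that many bases (isomiR-style
#' 3' trimming/extension). A tag matching k distinct families is assigned to
#' each with weight 1/k (the ambiguity is reported in the result).
#'
#' @param sequence tag sequence.
#' @param mature mature data.frame (`name`, `family`, `arm`, `is_star`,
#'   `sequence`).
#' @param three_prime_variants maximum 3'-length difference accepted
#'   (default 0, strict identity).
#' @return data.frame with columns `name`, `family`, `arm`, `is_star`,
#'   `weight` (zero rows when unassigned).
#' @export
match_mirbase <- function(sequence, mature, three_prime_variants = 0L) {
  check_that(!is.null(mature) && nrow(mature) > 0L, "mature mapping is empty")
  s <- rna(sequence)
  ls <- nchar(s)
  lm <- nchar(mature$sequence)
  if (three_prime_variants == 0L) {
    hit <- mature$sequence == s
  } else {
    dl <- abs(lm - ls)
    common <- pmin(lm, ls)
    hit <- dl <= three_prime_variants &
      substr(mature$sequence, 1L, common) == substr(s, 1L, common)
  }
  m <- mature[hit, c("name", "family", "arm", "is_star"), drop = FALSE]
  if (nrow(m) == 0L) return(cbind(m, weight = numeric(0)))
  # one row per (family, arm, star) group; weight splits across families
  grp <- !duplicated(m[c("family", "arm", "is_star")])
  m <- m[grp, , drop = FALSE]
  k <- length(unique(m$family))
  m$weight <- 1 / k
  rownames(m) <- NULL
  m
}

#' Reads-per-ten-million normalization
#'
#' @param raw_count raw read count (vectorized).
#' @param denominator library normalization denominator (> 0); by convention
#'   the library's total clean reads.
#' @param round round to the nearest integer for reporting (half-up), as in
#'   published family tables.
#' @return RPTM value(s).
#' @export
rptm_normalize <- function(raw_count, denominator, round = FALSE) {
  check_that(all(denominator > 0), "denominator must be > 0")
  x <- raw_count * 1e7 / denominator
  if (round) x <- floor(x + 0.5)
  x
}

#' Profile one library's tags into per-family raw counts
#'
#' @param tags data.frame with `sequence`, `count` (and optionally
#'   `library_id`).
#' @param mature mature data.frame.
#' @param three_prime_variants passed to [match_mirbase()]; the default 2
#'   aggregates 3' isomiRs into their family.
#' @return data.frame with `family`, `arm`, `is_star`, `raw_count` (possibly
#'   fractional when a tag is ambiguous between families), `library_id`.
#' @export
profile_library <- function(tags, mature, three_prime_variants = 2L) {
  lib <- if ("library_id" %in% names(tags) && nrow(tags) > 0L) {
    tags$library_id[1]
  } else "lib1"
  rows <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    m <- match_mirbase(tags$sequence[i], mature, three_prime_variants)
    if (nrow(m) == 0L) next
    m$raw_count <- m$weight * tags$count[i]
    rows[[i]] <- m[, c("family", "arm", "is_star", "raw_count")]
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(family = character(0), arm = character(0),
                      is_star = logical(0), raw_count = numeric(0),
                      library_id = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(raw_count ~ family + arm + is_star, df, sum)
  agg$library_id <- lib
  agg
}

#' Build the per-family RPTM table across libraries
#'
#' Rows are (family, arm, star) combinations; columns are libraries; entries
#' are RPTM values rounded to integers, 0 where a family was not observed.
#'
#' @param libraries list of tag data.frames (one per library, with
#'   `sequence`, `count`, `library_id`).
#' @param mature mature data.frame.
#' @param denominators named numeric vector of per-library normalization
#'   denominators; defaults to each library's total clean reads.
#' @param three_prime_variants passed to [profile_library()].
#' @return data.frame with `family`, `arm`, `is_star` and one RPTM column per
#'   library.
#' @export
build_family_table <- function(libraries, mature, denominators = NULL,
                               three_prime_variants = 2L) {
  profs <- lapply(libraries, profile_library, mature = mature,
                  three_prime_variants = three_prime_variants)
  lib_ids <- vapply(seq_along(libraries), function(i) {
    if (nrow(libraries[[i]]) > 0L && "library_id" %in% names(libraries[[i]])) {
      libraries[[i]]$library_id[1]
    } else paste0("lib", i)
  }, character(1))
  if (is.null(denominators)) {
    denominators <- stats::setNames(
      vapply(libraries, function(x) sum(x$count), numeric(1)), lib_ids)
  }
  all <- do.call(rbind, profs)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(family = character(0), arm = character(0),
                      is_star = logical(0), stringsAsFactors = FALSE))
  }
  keys <- unique(all[, c("family", "arm", "is_star")])
  keys <- keys[order(keys$family, keys$arm, keys$is_star), , drop = FALSE]
  rownames(keys) <- NULL
  out <- keys
  for (i in seq_along(lib_ids)) {
    p <- profs[[i]]
    idx <- match(paste(keys$family, keys$arm, keys$is_star),
                 paste(p$family, p$arm, p$is_star))
    raw <- ifelse(is.na(idx), 0, p$raw_count[idx])
    out[[lib_ids[i]]] <- rptm_normalize(raw, denominators[[lib_ids[i]]],
                                        round = TRUE)
  }
  out
}
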