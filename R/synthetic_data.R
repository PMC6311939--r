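# Seeded generator of a complete toy study: genome with planted fold-back
# precursors, multi-genotype small-RNA libraries, transcriptome with planted
# cleavage sites, and degradome libraries — with full ground truth.

# star strand of a mature sequence: star[j] = complement(mature[20 - j]) for
# j = 1..(L-2), i.e. revcomp of mature[1..(L-2)], plus 2 random 3' bases.
# This yields the canonical duplex with 2-nt 3' overhangs on both strands.
# `wobbles` converts complementary pairs into G:U wobbles (only possible
# opposite mature G or U); `mismatches` breaks pairs outright.
star_of <- function(mature, wobbles = 0L, mismatches = 0L) {
  ch <- seq_chars(mature)
  L <- length(ch)
  core <- L - 2L
  s <- rev(comp_base(ch[seq_len(core)]))            # s[j] pairs mature[core+1-j]
  mpos_of <- function(j) core + 1L - j
  editable <- seq_len(core)
  if (wobbles > 0L) {
    cand <- editable[ch[mpos_of(editable)] %in% c("G", "U")]
    pick <- utils::head(sample(cand), wobbles)
    for (j in pick) s[j] <- if (ch[mpos_of(j)] == "G") "U" else "G"
    editable <- setdiff(editable, pick)
  }
  if (mismatches > 0L) {
    pick <- utils::head(sample(editable), mismatches)
    for (j in pick) {
      m <- ch[mpos_of(j)]
      bad <- setdiff(RNA_BASES, c(comp_base(m),
                                  if (m == "G") "U" else if (m == "U") "G"))
      s[j] <- sample(bad, 1L)
    }
  }
  paste(c(s, sample(RNA_BASES, 2L, replace = TRUE)), collapse = "")
}

#' Generate a toy genome with planted miRNA precursors and decoy loci
#'
#' Each precursor is built as mature arm + loop + star arm (or the mirror,
#' when the mature is placed on the 3p arm), with the star constructed so
#' the miRNA/miRNA* duplex has a canonical 2-nt 3' overhang and at most a
#' couple of injected wobbles/mismatches — a valid duplex is guaranteed by
#' construction. Decoy loci are random tag-length sequences embedded without
#' any star arm.
#'
#' @param n_precursors number of planted miRNA precursors (>= 1).
#' @param n_decoy_loci number of decoy loci.
#' @param seed integer seed; identical seeds give identical output.
#' @param mature_len mature/star length in nt.
#' @param chrom_length background chromosome length (grown automatically if
#'   the planted loci need more room).
#' @param n_chroms number of chromosomes.
#' @return list with `genome` (named character vector, RNA alphabet),
#'   `truth` (data.frame of planted miRNAs: family, seq_5p, seq_3p,
#'   mature_arm, chrom, start, end, strand), and `decoys` (data.frame of
#'   decoy tags and loci).
#' @export
make_genome <- function(n_precursors = 10L, n_decoy_loci = 50L, seed = 1L,
                        mature_len = 21L, chrom_length = 20000L,
                        n_chroms = 3L) {
  check_that(n_precursors >= 1L, "need n_precursors >= 1")
  set.seed(seed)
  # build planted elements; each precursor is redrawn until its fold passes
  # the duplex check, so the truth contract (planted hairpins are valid)
  # holds by construction
  elements <- list()
  truth <- list()
  for (i in seq_len(n_precursors)) {
    ok <- FALSE
    for (attempt in seq_len(50L)) {
      mature <- random_rna(1L, mature_len)
      star <- star_of(mature, wobbles = sample(0:2, 1L),
                      mismatches = sample(0:1, 1L))
      loop <- random_rna(1L, sample(9:15, 1L))
      mature_arm <- sample(c("5p", "3p"), 1L)
      if (mature_arm == "5p") {
        prec <- paste0(mature, loop, star)
        seq_5p <- mature; seq_3p <- star
        m_span <- c(1L, nchar(mature))
        s_span <- c(nchar(prec) - nchar(star) + 1L, nchar(prec))
      } else {
        prec <- paste0(star, loop, mature)
        seq_5p <- star; seq_3p <- mature
        m_span <- c(nchar(prec) - nchar(mature) + 1L, nchar(prec))
        s_span <- c(1L, nchar(star))
      }
      hp <- list(precursor_seq = prec, structure = NULL,
                 mature_span = m_span, star_span = s_span)
      if (check_duplex(hp)$pass) { ok <- TRUE; break }
    }
    check_that(ok, "infeasible parameters: no valid hairpin in 50 draws")
    elements[[length(elements) + 1L]] <- prec
    truth[[i]] <- data.frame(
      family = sprintf("miR%d", 900L + i), seq_5p = seq_5p, seq_3p = seq_3p,
      mature_arm = mature_arm, stringsAsFactors = FALSE)
  }
  decoy_seqs <- random_rna(n_decoy_loci, mature_len)
  elements <- c(elements, as.list(decoy_seqs))
  n_elem <- length(elements)
  elem_len <- nchar(unlist(elements))

  # one element per slot, with >= 300 nt left free at each slot end, so any
  # two planted loci are at least 300 nt apart (candidate hairpins then
  # contain at most one planted element)
  per_chrom <- ceiling(n_elem / n_chroms)
  need <- per_chrom * (max(elem_len) + 600L)
  chrom_length <- max(chrom_length, need)
  genome <- stats::setNames(random_rna(n_chroms, chrom_length),
                            sprintf("chr%d", seq_len(n_chroms)))
  chrom_of <- rep(seq_len(n_chroms), length.out = n_elem)
  slot_of <- stats::ave(seq_len(n_elem), chrom_of, FUN = seq_along)
  slot_width <- floor(chrom_length / per_chrom)
  loci <- data.frame(chrom = names(genome)[chrom_of], start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     stringsAsFactors = FALSE)
  for (e in seq_len(n_elem)) {
    offset <- sample.int(max(1L, slot_width - elem_len[e] - 300L), 1L)
    start <- (slot_of[e] - 1L) * slot_width + offset
    strand <- sample(c("+", "-"), 1L)
    placed <- if (strand == "+") elements[[e]] else revcomp(elements[[e]])
    g <- genome[[loci$chrom[e]]]
    substr(g, start, start + elem_len[e] - 1L) <- placed
    genome[[loci$chrom[e]]] <- g
    loci$start[e] <- start
    loci$end[e] <- start + elem_len[e] - 1L
    loci$strand[e] <- strand
  }
  truth <- do.call(rbind, truth)
  truth <- cbind(truth, loci[seq_len(n_precursors), ])
  decoys <- data.frame(sequence = decoy_seqs,
                       loci[n_precursors + seq_len(n_decoy_loci), ],
                       stringsAsFactors = FALSE)
  rownames(truth) <- rownames(decoys) <- NULL
  list(genome = genome, truth = truth, decoys = decoys)
}

#' Simulate multi-library small-RNA tag libraries from planted truth
#'
#' Family abundances follow a log-normal law across families (the dominant
#' feature of published family tables); per-library counts add log-normal
#' library-to-library jitter and Poisson sampling noise. Star reads are a
#' configurable fraction of mature reads; decoy tags are sequenced at low
#' abundance; a `noise_rate` fraction of reads are random sequences.
#'
#' @param truth output of [make_genome()] (list with `truth` and `decoys`).
#' @param n_libraries number of libraries (one genotype each by default).
#' @param depth expected clean reads per library (>= 1000).
#' @param star_fraction expected star/mature count ratio.
#' @param noise_rate fraction of reads that are random noise tags.
#' @param seed integer seed.
#' @param library_ids library identifiers (default `G1..Gn`).
#' @param contaminants optional data.frame (`sequence`, `weight`) of
#'   non-miRNA reads (e.g. rRNA/repeat/cDNA fragments) to spike in.
#' @param family_sdlog spread of the log-normal family abundance law.
#' @param library_sdlog library-to-library jitter.
#' @return list with `libraries` (list of collapsed tag data.frames),
#'   `denominators` (named total clean reads), and `weights` (the planted
#'   relative family abundances).
#' @export
make_small_rna_libraries <- function(truth, n_libraries = 3L, depth = 1e4,
                                     star_fraction = 0.25, noise_rate = 0.05,
                                     seed = 1L, library_ids = NULL,
                                     contaminants = NULL,
                                     family_sdlog = 1.25,
                                     library_sdlog = 0.3) {
  check_that(depth >= 1000, "depth must be >= 1000")
  set.seed(seed)
  if (is.null(library_ids)) library_ids <- sprintf("G%d", seq_len(n_libraries))
  tt <- truth$truth
  n_fam <- nrow(tt)
  fam_w <- stats::rlnorm(n_fam, meanlog = 0, sdlog = family_sdlog)
  mature_seq <- ifelse(tt$mature_arm == "5p", tt$seq_5p, tt$seq_3p)
  star_seq <- ifelse(tt$mature_arm == "5p", tt$seq_3p, tt$seq_5p)
  pool <- data.frame(sequence = c(mature_seq, star_seq, truth$decoys$sequence),
                     weight = c(fam_w, fam_w * star_fraction,
                                stats::rlnorm(nrow(truth$decoys),
                                              log(0.08), 0.5)),
                     stringsAsFactors = FALSE)
  if (!is.null(contaminants)) pool <- rbind(pool, contaminants)

  libraries <- vector("list", n_libraries)
  for (l in seq_len(n_libraries)) {
    jitter <- stats::rlnorm(nrow(pool), 0, library_sdlog)
    w <- pool$weight * jitter
    mu <- depth * (1 - noise_rate) * w / sum(w)
    counts <- stats::rpois(nrow(pool), mu)
    n_noise <- stats::rpois(1L, depth * noise_rate)
    noise <- random_rna(n_noise, 21L)
    tags <- rbind(
      data.frame(sequence = pool$sequence[counts > 0L],
                 count = counts[counts > 0L], stringsAsFactors = FALSE),
      collapse_reads(noise)[, c("sequence", "count")])
    tags <- stats::aggregate(count ~ sequence, tags, sum)
    tags$library_id <- library_ids[l]
    tags <- tags[order(-tags$count, tags$sequence), ]
    rownames(tags) <- NULL
    libraries[[l]] <- tags
  }
  den <- vapply(libraries, function(x) sum(x$count), numeric(1))
  list(libraries = libraries,
       denominators = stats::setNames(den, library_ids),
       weights = stats::setNames(fam_w, tt$family))
}

# complementary target window for a mature miRNA with a prescribed
# wobble/mismatch composition: window[j] pairs mirna[L + 1 - j]
target_window_of <- function(mature, wobbles = 0L, mismatches = 0L) {
  ch <- seq_chars(mature)
  L <- length(ch)
  w <- rev(comp_base(ch))
  mpos_of <- function(j) L + 1L - j
  editable <- seq_len(L)
  if (wobbles > 0L) {
    cand <- editable[ch[mpos_of(editable)] %in% c("G", "U")]
    pick <- utils::head(sample(cand), wobbles)
    for (j in pick) w[j] <- if (ch[mpos_of(j)] == "G") "U" else "G"
    editable <- setdiff(editable, pick)
  }
  if (mismatches > 0L) {
    pick <- utils::head(sample(editable), mismatches)
    for (j in pick) {
      m <- ch[mpos_of(j)]
      bad <- setdiff(RNA_BASES, c(comp_base(m),
                                  if (m == "G") "U" else if (m == "U") "G"))
      w[j] <- sample(bad, 1L)
    }
  }
  paste(w, collapse = "")
}

#' Simulate a transcriptome with planted target sites and degradome reads
#'
#' Each planted miRNA receives one target transcript carrying a
#' complementary window of known wobble/mismatch composition. In every
#' genotype, a `signal_fraction` share of that transcript's degradome reads
#' have their 5' ends at the expected cleavage position; the remainder (and
#' all reads on background transcripts) are uniform over the transcript.
#'
#' @param truth output of [make_genome()].
#' @param transcriptome_size number of transcripts (targets + background).
#' @param depth expected degradome reads per transcript per genotype.
#' @param signal_fraction fraction of a target transcript's reads at the
#'   cleavage site (0 < x <= 1).
#' @param seed integer seed.
#' @param genotypes genotype identifiers (default `G1..G3`).
#' @param tx_len_range transcript length range.
#' @return list with `transcripts` (named character vector),
#'   `degradome` (named list of read data.frames per genotype), and
#'   `targets` (data.frame of planted sites: family, mirna_id,
#'   transcript_id, site_start, site_end, mismatch_score, cleavage_pos,
#'   signal_fraction).
#' @export
make_degradome <- function(truth, transcriptome_size = 30L, depth = 200L,
                           signal_fraction = 0.7, seed = 1L,
                           genotypes = sprintf("G%d", 1:3),
                           tx_len_range = c(500L, 1500L)) {
  check_that(signal_fraction > 0 && signal_fraction <= 1,
             "signal_fraction must be in (0, 1]")
  set.seed(seed)
  tt <- truth$truth
  n_mir <- nrow(tt)
  check_that(transcriptome_size >= n_mir,
             "transcriptome_size must be >= number of planted miRNAs")
  tx_ids <- sprintf("TX%03d", seq_len(transcriptome_size))
  lens <- sample(tx_len_range[1]:tx_len_range[2], transcriptome_size,
                 replace = TRUE)
  transcripts <- stats::setNames(random_rna(transcriptome_size, lens), tx_ids)

  mature_seq <- ifelse(tt$mature_arm == "5p", tt$seq_5p, tt$seq_3p)
  mirna_id <- paste0(tt$family, "-", tt$mature_arm)
  targets <- list()
  for (i in seq_len(n_mir)) {
    L <- nchar(mature_seq[i])
    nw <- sample(0:2, 1L)
    nm <- sample(0:2, 1L)
    win <- target_window_of(mature_seq[i], wobbles = nw, mismatches = nm)
    pos <- sample(seq(50L, lens[i] - L - 50L), 1L)
    tx <- transcripts[[i]]
    substr(tx, pos, pos + L - 1L) <- win
    transcripts[[i]] <- tx
    targets[[i]] <- data.frame(
      family = tt$family[i], mirna_id = mirna_id[i], transcript_id = tx_ids[i],
      site_start = pos, site_end = pos + L - 1L,
      mismatch_score = nm + 0.5 * nw,
      cleavage_pos = pos + (L - 10L),
      signal_fraction = signal_fraction, stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, targets)

  degradome <- stats::setNames(vector("list", length(genotypes)), genotypes)
  for (g in genotypes) {
    rows <- list()
    for (j in seq_len(transcriptome_size)) {
      n_reads <- stats::rpois(1L, depth)
      if (n_reads == 0L) next
      is_target <- j <= n_mir
      n_sig <- if (is_target) stats::rbinom(1L, n_reads, signal_fraction) else 0L
      pos <- c(rep(targets$cleavage_pos[j], n_sig),
               sample.int(lens[j], n_reads - n_sig, replace = TRUE))
      tab <- table(pos)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx_ids[j],
        five_prime_pos = as.integer(names(tab)),
        count = as.integer(tab), stringsAsFactors = FALSE)
    }
    degradome[[g]] <- do.call(rbind, rows)
  }
  list(transcripts = transcripts, degradome = degradome, targets = targets)
}

#' Simulate a complete study and write it to disk
#'
#' Orchestrates [make_genome()], [make_degradome()] and
#' [make_small_rna_libraries()], writes `genome.fa`, `cdna.fa`, `mature.fa`,
#' `ncrna.fa`, `repeats.fa`, per-library collapsed FASTA, per-genotype
#' degradome TSVs and `truth.json`, and returns everything in memory.
#'
#' @param out_dir output directory (created if needed); `NULL` keeps the
#'   study in memory only.
#' @param seed master seed; component seeds are derived deterministically.
#' @param n_precursors,n_decoy_loci passed to [make_genome()].
#' @param n_libraries,depth,star_fraction,noise_rate passed to
#'   [make_small_rna_libraries()].
#' @param transcriptome_size,degradome_depth,signal_fraction passed to
#'   [make_degradome()].
#' @return list with `genome`, `truth`, `decoys`, `libraries`,
#'   `denominators`, `transcripts`, `degradome`, `targets`, `mature`,
#'   `refs` (a `reference_bundle`), and `params`.
#' @export
simulate_study <- function(out_dir = NULL, seed = 1L, n_precursors = 10L,
                           n_decoy_loci = 50L, n_libraries = 3L, depth = 1e4,
                           star_fraction = 0.25, noise_rate = 0.05,
                           transcriptome_size = 30L, degradome_depth = 200L,
                           signal_fraction = 0.7) {
  gen <- make_genome(n_precursors, n_decoy_loci, seed = seed)
  genotypes <- sprintf("G%d", seq_len(n_libraries))
  deg <- make_degradome(gen, transcriptome_size, degradome_depth,
                        signal_fraction, seed = seed + 1L,
                        genotypes = genotypes)

  # contaminant reads from structural RNA / repeat / cDNA references
  set.seed(seed + 2L)
  ncrna <- stats::setNames(random_rna(2L, 300L), c("rRNA-1", "tRNA-1"))
  repeats <- stats::setNames(random_rna(2L, 400L), c("rep-1", "rep-2"))
  frag <- function(src, n) {
    vapply(seq_len(n), function(i) {
      s <- src[[sample.int(length(src), 1L)]]
      len <- sample(20:24, 1L)
      at <- sample.int(nchar(s) - len, 1L)
      substr(s, at, at + len - 1L)
    }, character(1))
  }
  contaminants <- data.frame(
    sequence = c(frag(ncrna, 4L), frag(repeats, 3L), frag(deg$transcripts, 3L)),
    weight = stats::rlnorm(10L, log(0.3), 0.5), stringsAsFactors = FALSE)

  libs <- make_small_rna_libraries(gen, n_libraries, depth, star_fraction,
                                   noise_rate, seed = seed + 3L,
                                   library_ids = genotypes,
                                   contaminants = contaminants)

  tt <- gen$truth
  mature_names <- paste0("msy-", tt$family, "-", tt$mature_arm)
  star_names <- paste0("msy-", tt$family, "-",
                       ifelse(tt$mature_arm == "5p", "3p", "5p"), "*")
  mature_fa <- stats::setNames(
    c(ifelse(tt$mature_arm == "5p", tt$seq_5p, tt$seq_3p),
      ifelse(tt$mature_arm == "5p", tt$seq_3p, tt$seq_5p)),
    c(mature_names, star_names))
  precursors <- stats::setNames(vapply(seq_len(nrow(tt)), function(i) {
    g <- gen$genome[[tt$chrom[i]]]
    s <- substr(g, tt$start[i], tt$end[i])
    if (tt$strand[i] == "-") s <- revcomp(s) else s <- rna(s)
    s
  }, character(1)), paste0("msy-", tt$family, "-precursor"))

  refs <- reference_bundle(
    ncrna = ncrna, premirna = precursors, repeats = repeats,
    cdna = deg$transcripts, genome = gen$genome,
    mature = data.frame(parse_mirbase_name(names(mature_fa)),
                        sequence = unname(mature_fa),
                        stringsAsFactors = FALSE))

  study <- list(genome = gen$genome, truth = tt, decoys = gen$decoys,
                libraries = libs$libraries, denominators = libs$denominators,
                weights = libs$weights, transcripts = deg$transcripts,
                degradome = deg$degradome, targets = deg$targets,
                mature = mature_fa, precursors = precursors, refs = refs,
                genotypes = genotypes,
                params = list(seed = seed, n_precursors = n_precursors,
                              n_decoy_loci = n_decoy_loci,
                              n_libraries = n_libraries, depth = depth,
                              star_fraction = star_fraction,
                              noise_rate = noise_rate,
                              transcriptome_size = transcriptome_size,
                              degradome_depth = degradome_depth,
                              signal_fraction = signal_fraction))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(dna(study$genome), file.path(out_dir, "genome.fa"))
    write_fasta(dna(study$transcripts), file.path(out_dir, "cdna.fa"))
    write_fasta(study$mature, file.path(out_dir, "mature.fa"))
    write_fasta(ncrna, file.path(out_dir, "ncrna.fa"))
    write_fasta(repeats, file.path(out_dir, "repeats.fa"))
    write_fasta(precursors, file.path(out_dir, "premirna.fa"))
    for (l in study$libraries) {
      write_collapsed_fasta(l, file.path(out_dir,
                                         paste0("lib_", l$library_id[1], ".fa")))
    }
    for (g in names(study$degradome)) {
      write_degradome(study$degradome[[g]],
                      file.path(out_dir, paste0("degradome_", g, ".tsv")))
    }
    write_truth(study, file.path(out_dir, "truth.json"))
  }
  study
}

#' Serialize the ground truth of a simulated study to JSON
#'
#' @param study output of [simulate_study()].
#' @param path output JSON file.
#' @return invisibly, the path.
#' @export
write_truth <- function(study, path) {
  truth <- list(planted_mirnas = study$truth,
                planted_targets = study$targets,
                decoys = study$decoys,
                weights = as.list(study$weights),
                denominators = as.list(study$denominators),
                params = study$params)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reload a serialized ground truth
#'
#' @param path JSON file written by [write_truth()].
#' @return list with `planted_mirnas`, `planted_targets`, `decoys`,
#'   `weights`, `denominators`, `params`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- unlist(x$weights)
  x$denominators <- unlist(x$denominators)
  x
}
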