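test_that("maximum-pairing fold handles forced and pairless sequences", {
  f <- fold("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$npairs, 3L)
  expect_equal(f$score, -3L)
  f0 <- fold("AAAAAAA")
  expect_equal(f0$structure, ".......")
  expect_equal(f0$npairs, 0L)
  expect_error(fold("ACGXU"), "A/C/G/U")
  expect_error(fold(paste(rep("A", 401), collapse = "")), "400")
  # the reported structure is balanced and consistent with the pair count
  set.seed(4)
  s <- rand_rna(80)
  f <- fold(s)
  partner <- db_partner(f$structure)
  expect_equal(sum(partner > 0) / 2, f$npairs)
  idx <- which(partner > 0)
  expect_equal(partner[partner[idx]], idx)
})

test_that("fold pair count equals exhaustive enumeration for short RNAs", {
  set.seed(100)
  for (i in 1:60) {
    s <- rand_rna(sample(5:16, 1))
    expect_equal(fold(s)$npairs, oracle_max_pairs(s),
                 info = paste("sequence", s))
  }
})

test_that("genome mapping reports all loci on both strands", {
  set.seed(55)
  genome <- c(chr1 = rand_rna(3000), chr2 = rand_rna(2000))
  tag <- substr(genome[["chr1"]], 101, 121)
  got <- map_tags_to_genome(tag, genome)$loci
  want <- oracle_map_tag(tag, genome)
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$chrom, want$chrom)

  expect_equal(nrow(map_tags_to_genome(rand_rna(21), genome)$loci), 0L)

  # palindromic tag: one interval, both strands
  pal <- "ACGUACGUACGUACGUACGU"
  g2 <- c(chr1 = paste0(rand_rna(50), pal, rand_rna(50)))
  hits <- map_tags_to_genome(pal, g2)$loci
  expect_equal(nrow(hits), 2L)
  expect_equal(unique(hits$start), 51L)
  expect_setequal(hits$strand, c("+", "-"))

  # multi-mapping tags are flagged and excluded
  rep_tag <- rand_rna(21)
  g3 <- c(chr1 = paste(rep(c(rep_tag, rand_rna(30)), 25), collapse = ""))
  m <- map_tags_to_genome(rep_tag, g3, max_loci = 20)
  expect_equal(m$multimapped, rep_tag)
  expect_equal(nrow(m$loci), 0L)
})

test_that("precursor excision clips, strand-corrects and spans the hairpin", {
  set.seed(66)
  genome <- c(chr1 = rand_rna(1000))
  # locus near the chromosome start: the long upstream window is clipped
  loc <- list(chrom = "chr1", start = 5L, end = 25L, strand = "+")
  win <- excise_precursor(loc, genome)
  expect_equal(min(win$gstart), 1L)
  # minus-strand excision equals the reverse complement of the plus window
  loc2 <- list(chrom = "chr1", start = 300L, end = 320L, strand = "-")
  win2 <- excise_precursor(loc2, genome)
  plus <- substr(rna(genome[["chr1"]]), win2$gstart[1], win2$gend[1])
  expect_equal(win2$sequence[1], revcomp(plus))
  expect_error(excise_precursor(list(chrom = "chr1", start = 990L,
                                     end = 1010L, strand = "+"), genome),
               "outside")
  # a planted precursor is contained in the excision window
  gen <- make_genome(n_precursors = 1, n_decoy_loci = 0, seed = 7)
  tt <- gen$truth
  mstart <- if (tt$mature_arm == "5p" && tt$strand == "+") tt$start else NULL
  prec <- substr(gen$genome[[tt$chrom]], tt$start, tt$end)
  loc3 <- list(chrom = tt$chrom, start = tt$start,
               end = tt$start + 20L, strand = "+")
  win3 <- excise_precursor(loc3, gen$genome)
  expect_true(any(grepl(rna(prec), win3$sequence, fixed = TRUE) |
                    grepl(revcomp(prec), win3$sequence, fixed = TRUE)))
})

test_that("the duplex check enforces geometry and pairing thresholds", {
  # perfect 21/21 duplex with exact 2-nt overhangs, by construction
  m <- "UGACAGAAGAGAGUGAGCACA"
  star <- paste0(revcomp(substr(m, 1, 19)), "GU")
  hp <- list(precursor_seq = paste0(m, "GCAUGGGAUUU", star),
             structure = NULL, mature_span = c(1L, 21L),
             star_span = c(33L, 53L))
  res <- check_duplex(hp)
  expect_true(res$pass)
  expect_equal(res$overhang, 2L)
  expect_gte(res$paired_frac, 19 / 21)

  # overlapping spans fail as same-arm
  bad <- hp
  bad$star_span <- c(10L, 30L)
  expect_equal(check_duplex(bad)$reason, "same_arm")

  # unrelated "star" fails for lack of duplex pairing
  set.seed(8)
  hp2 <- list(precursor_seq = paste0(m, "GCAUGGGAUUU", rand_rna(21)),
              structure = NULL, mature_span = c(1L, 21L),
              star_span = c(33L, 53L))
  r2 <- check_duplex(hp2)
  expect_false(r2$pass)
})

test_that("support filtering excludes weak candidates and breaks ties to 5p", {
  gen <- make_genome(n_precursors = 1, n_decoy_loci = 0, seed = 12)
  tt <- gen$truth
  lib_of <- function(counts, id) {
    data.frame(sequence = c(tt$seq_5p, tt$seq_3p), count = counts,
               library_id = id, stringsAsFactors = FALSE)
  }
  # arm counts equal overall: dominant arm must be 5p
  libs <- list(lib_of(c(50L, 50L), "G1"), lib_of(c(40L, 40L), "G2"),
               lib_of(c(30L, 30L), "G3"))
  calls <- discover_novel(libs, gen$genome, min_libraries = 3, min_count = 5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$dominant_arm, "5p")

  # supported in only one genotype: excluded at min_libraries = 3
  libs1 <- list(lib_of(c(50L, 10L), "G1"),
                data.frame(sequence = "A", count = 1L, library_id = "G2",
                           stringsAsFactors = FALSE),
                data.frame(sequence = "A", count = 1L, library_id = "G3",
                           stringsAsFactors = FALSE))
  expect_equal(nrow(discover_novel(libs1, gen$genome, min_libraries = 3,
                                   min_count = 5)), 0L)

  # star never sequenced: excluded
  libs2 <- lapply(list("G1", "G2", "G3"), function(g) {
    data.frame(sequence = if (tt$mature_arm == "5p") tt$seq_5p else tt$seq_3p,
               count = 50L, library_id = g, stringsAsFactors = FALSE)
  })
  expect_equal(nrow(discover_novel(libs2, gen$genome, min_libraries = 3,
                                   min_count = 5)), 0L)
})

test_that("raising support thresholds never adds calls", {
  study <- simulate_study(seed = 31, n_precursors = 4, n_decoy_loci = 5,
                          depth = 3000, transcriptome_size = 6,
                          degradome_depth = 50)
  key <- function(calls) paste(calls$seq_5p, calls$seq_3p)
  base <- discover_novel(study$libraries, study$genome,
                         min_libraries = 2, min_count = 2)
  stricter_count <- discover_novel(study$libraries, study$genome,
                                   min_libraries = 2, min_count = 10)
  stricter_libs <- discover_novel(study$libraries, study$genome,
                                  min_libraries = 3, min_count = 2)
  expect_true(all(key(stricter_count) %in% key(base)))
  expect_true(all(key(stricter_libs) %in% key(base)))
})

test_that("discovery is strand-consistent under genome reverse complement", {
  study <- simulate_study(seed = 29, n_precursors = 3, n_decoy_loci = 3,
                          depth = 3000, transcriptome_size = 4,
                          degradome_depth = 50)
  fwd <- discover_novel(study$libraries, study$genome,
                        min_libraries = 3, min_count = 5)
  rc_genome <- vapply(study$genome, revcomp, character(1))
  rev <- discover_novel(study$libraries, rc_genome,
                        min_libraries = 3, min_count = 5)
  expect_equal(nrow(fwd), nrow(rev))
  key <- function(x) sort(paste(x$seq_5p, x$seq_3p))
  expect_equal(key(fwd), key(rev))
  # strands flip, except where the arms themselves map to both strands
  # (a miRNA/miRNA* pair is near-palindromic, so this can genuinely occur)
  flip <- c(`+` = "-", `-` = "+")
  ord_f <- order(paste(fwd$seq_5p, fwd$seq_3p))
  ord_r <- order(paste(rev$seq_5p, rev$seq_3p))
  fs <- fwd[ord_f, ]; rs <- rev[ord_r, ]
  for (i in seq_len(nrow(fs))) {
    if (identical(unname(flip[fs$strand[i]]), rs$strand[i])) next
    loci <- map_tags_to_genome(c(fs$seq_5p[i], fs$seq_3p[i]),
                               study$genome)$loci
    expect_setequal(unique(loci$strand), c("+", "-"))
  }
})

test_that("hairpin rendering marks both arms over the structure", {
  m <- "UGACAGAAGAGAGUGAGCACA"
  star <- paste0(revcomp(substr(m, 1, 19)), "GU")
  prec <- paste0(m, "GCAUGGGAUUU", star)
  hp <- list(precursor_seq = prec, structure = fold(prec)$structure,
             mature_span = c(1L, 21L), star_span = c(33L, 53L))
  lines <- render_hairpin(hp, width = 60)
  expect_equal(lines[1], prec)
  expect_match(lines[3], "^M+ +S+$")
})
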