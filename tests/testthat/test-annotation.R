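make_refs <- function(seed = 5) {
  # small synthetic reference bundle with one sequence per category
  set.seed(seed)
  list(ncrna = c(rRNA1 = rand_rna(300)),
       premirna = c(pre1 = rand_rna(120)),
       repeats = c(rep1 = rand_rna(250)),
       cdna = c(tx1 = rand_rna(400)),
       genome = c(chr1 = rand_rna(2000)))
}

test_that("miRBase-style names parse into family, arm and star status", {
  p <- parse_mirbase_name(c("mtr-miR166a-3p", "msa-miR156", "ath-miR390a*",
                            "mtr-miR2118b-5p"))
  expect_equal(p$family, c("miR166", "miR156", "miR390", "miR2118"))
  expect_equal(p$arm, c("3p", "5p", "5p", "5p"))
  expect_equal(p$is_star, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("classification follows the category priority order", {
  r <- make_refs()
  shared <- substr(r$ncrna[[1]], 10, 30)
  # plant the same 21-mer into the genome as well
  g <- r$genome[[1]]
  substr(g, 1000, 1020) <- shared
  r$genome <- c(chr1 = g)
  refs <- reference_bundle(ncrna = r$ncrna, premirna = r$premirna,
                           repeats = r$repeats, cdna = r$cdna,
                           genome = r$genome)
  expect_equal(classify_tag(shared, refs), "ncRNAs")
  genome_only <- substr(g, 500, 520)
  expect_equal(classify_tag(genome_only, refs), "genome")
  expect_equal(classify_tag(rand_rna(21), refs), "unmapped")
  # reverse complement matches count for genome but not for ncRNA
  expect_equal(classify_tag(revcomp(genome_only), refs), "genome")
  ncrna_only <- substr(r$ncrna[[1]], 100, 120)
  expect_equal(classify_tag(ncrna_only, refs), "ncRNAs")
  expect_equal(classify_tag(revcomp(ncrna_only), refs), "unmapped")
})

test_that("planted tags of every category are recovered exactly", {
  r <- make_refs(9)
  refs <- do.call(reference_bundle, r[c("ncrna", "premirna", "repeats",
                                        "cdna", "genome")])
  set.seed(10)
  draw <- function(src, n) {
    vapply(seq_len(n), function(i) {
      at <- sample.int(nchar(src) - 21L, 1)
      substr(src, at, at + 20L)
    }, character(1))
  }
  tags <- data.frame(
    sequence = c(draw(r$ncrna[[1]], 10), draw(r$premirna[[1]], 10),
                 draw(r$repeats[[1]], 10), draw(r$cdna[[1]], 10),
                 draw(r$genome[[1]], 10)),
    count = rep(2L, 50), stringsAsFactors = FALSE)
  cls <- classify_library(tags, refs)
  expect_equal(cls$unique_reads[match(c("ncRNAs", "pre-miRBase", "repeats",
                                        "cdna", "genome"), cls$category)],
               rep(10L, 5))
  # partition: unique counts sum to the number of tags
  expect_equal(sum(cls$unique_reads), nrow(tags))
  expect_equal(sum(cls$total_reads), sum(tags$count))
  expect_equal(attr(cls, "total_clean_reads"), sum(tags$count))
})

test_that("classification agrees with a brute-force substring oracle", {
  set.seed(21)
  r <- list(ncrna = c(n1 = rand_rna(150)), premirna = c(p1 = rand_rna(100)),
            repeats = c(r1 = rand_rna(150)), cdna = c(c1 = rand_rna(200)),
            genome = c(g1 = rand_rna(500)))
  refs <- do.call(reference_bundle, r)
  oracle_classify <- function(tag) {
    rc <- revcomp(tag)
    hit <- function(src, use_rc) {
      any(grepl(tag, src, fixed = TRUE)) ||
        (use_rc && any(grepl(rc, src, fixed = TRUE)))
    }
    if (hit(r$ncrna, FALSE)) return("ncRNAs")
    if (hit(r$premirna, FALSE)) return("pre-miRBase")
    if (hit(r$repeats, TRUE)) return("repeats")
    if (hit(r$cdna, TRUE)) return("cdna")
    if (hit(r$genome, TRUE)) return("genome")
    "unmapped"
  }
  srcs <- c(r$ncrna, r$premirna, r$repeats, r$cdna, r$genome)
  tags <- c(vapply(1:30, function(i) {
    s <- srcs[[sample.int(length(srcs), 1)]]
    at <- sample.int(nchar(s) - 20L, 1)
    w <- substr(s, at, at + 20L)
    if (runif(1) < 0.3) w <- revcomp(w)
    w
  }, character(1)), vapply(1:10, function(i) rand_rna(21), character(1)))
  got <- vapply(tags, classify_tag, character(1), refs = refs,
                USE.NAMES = FALSE)
  want <- vapply(tags, oracle_classify, character(1), USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("removing the ncRNA reference only moves tags to later categories", {
  set.seed(33)
  r <- make_refs(33)
  # tag present in both ncRNA and genome
  g <- r$genome[[1]]
  shared <- substr(r$ncrna[[1]], 50, 70)
  substr(g, 100, 120) <- shared
  r$genome <- c(chr1 = g)
  full <- do.call(reference_bundle, r)
  reduced <- do.call(reference_bundle, c(r[c("premirna", "repeats", "cdna",
                                             "genome")], list(ncrna = NULL)))
  order_levels <- c("ncRNAs", "pre-miRBase", "repeats", "cdna", "genome",
                    "unmapped")
  tags <- c(shared, substr(r$ncrna[[1]], 200, 220), rand_rna(21))
  for (tag in tags) {
    before <- match(classify_tag(tag, full), order_levels)
    after <- match(classify_tag(tag, reduced), order_levels)
    expect_gte(after, before)
  }
})

test_that("mature identity assignment handles variants and ambiguity", {
  mature <- data.frame(
    name = c("mtr-miR166a-3p", "mtr-miR166b-3p", "mtr-miR156a-5p",
             "mtr-miR157a-5p"),
    family = c("miR166", "miR166", "miR156", "miR157"),
    arm = c("3p", "3p", "5p", "5p"),
    is_star = FALSE,
    sequence = c("UCGGACCAGGCUUCAUUCCCC", "UCGGACCAGGCUUCAUUCCCC",
                 "UGACAGAAGAGAGUGAGCACA", "UGACAGAAGAGAGUGAGCACA"),
    stringsAsFactors = FALSE)
  # exact identity
  hit <- match_mirbase("UCGGACCAGGCUUCAUUCCCC", mature)
  expect_equal(unique(hit$family), "miR166")
  expect_equal(hit$weight, 1)
  # one internal substitution: no assignment
  expect_equal(nrow(match_mirbase("UCGGACCAGGCAUCAUUCCCC", mature)), 0L)
  # ambiguity between two families splits the weight
  amb <- match_mirbase("UGACAGAAGAGAGUGAGCACA", mature)
  expect_equal(sort(amb$family), c("miR156", "miR157"))
  expect_equal(amb$weight, c(0.5, 0.5))
  # 3' length variants only under the variant rule
  short <- substr("UCGGACCAGGCUUCAUUCCCC", 1, 19)
  expect_equal(nrow(match_mirbase(short, mature)), 0L)
  expect_equal(match_mirbase(short, mature, three_prime_variants = 2)$family,
               "miR166")
  expect_equal(nrow(match_mirbase(substr("UCGGACCAGGCUUCAUUCCCC", 1, 18),
                                  mature, three_prime_variants = 2)), 0L)
})

test_that("RPTM normalization is exact, linear and guarded", {
  expect_equal(rptm_normalize(12008892, 12008892), 1e7)
  expect_equal(rptm_normalize(0, 1000), 0)
  expect_equal(rptm_normalize(347, 12008892, round = TRUE), 289)
  expect_error(rptm_normalize(10, 0), "denominator")
  # linearity before rounding
  set.seed(2)
  raw <- sample(1:1000, 20)
  expect_equal(rptm_normalize(2 * raw, 5e6), 2 * rptm_normalize(raw, 5e6))
})

test_that("the family table assembles RPTM across libraries", {
  mature <- data.frame(name = c("syn-miR1-5p", "syn-miR2-5p"),
                       family = c("miR1", "miR2"), arm = "5p",
                       is_star = FALSE,
                       sequence = c("UGACAGAAGAGAGUGAGCACA",
                                    "UUGGACUGAAGGGAGCUCCCU"),
                       stringsAsFactors = FALSE)
  libA <- data.frame(sequence = "UGACAGAAGAGAGUGAGCACA", count = 500L,
                     library_id = "A", stringsAsFactors = FALSE)
  tabA <- build_family_table(list(libA), mature)
  expect_equal(tabA$A, 1e7)

  libB <- data.frame(sequence = "UUGGACUGAAGGGAGCUCCCU", count = 250L,
                     library_id = "B", stringsAsFactors = FALSE)
  tab <- build_family_table(list(libA, libB), mature)
  expect_equal(dim(tab), c(2L, 5L))
  expect_equal(sort(c(tab$A, tab$B)), c(0, 0, 1e7, 1e7))
})

test_that("simulated family abundances are recovered within sampling error", {
  gen <- make_genome(n_precursors = 5, n_decoy_loci = 0, seed = 17)
  libs <- make_small_rna_libraries(gen, n_libraries = 1, depth = 1e4,
                                   star_fraction = 0.2, noise_rate = 0,
                                   seed = 18, library_sdlog = 0)
  tt <- gen$truth
  mature_seq <- ifelse(tt$mature_arm == "5p", tt$seq_5p, tt$seq_3p)
  mature <- data.frame(name = paste0("syn-", tt$family, "-", tt$mature_arm),
                       family = tt$family, arm = tt$mature_arm,
                       is_star = FALSE, sequence = mature_seq,
                       stringsAsFactors = FALSE)
  tab <- build_family_table(libs$libraries, mature,
                            denominators = libs$denominators)
  w <- libs$weights
  total_w <- sum(w) + sum(w) * 0.2      # mature + star pool weight
  depth <- sum(libs$libraries[[1]]$count)
  for (i in seq_len(nrow(tt))) {
    mu <- 1e4 * w[[tt$family[i]]] / total_w          # expected raw count
    expect_lt(abs(tab$G1[tab$family == tt$family[i]] -
                    rptm_normalize(mu, depth)),
              3 * sqrt(mu) * 1e7 / depth + 1)
  }
})
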