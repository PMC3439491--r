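test_that("built-in patterns encode the four consensus classes", {
  pats <- builtinPatterns()
  expect_named(pats, c("canonical", "srf_like", "n10_like",
                       "intermediate"))
  canon <- pats$canonical
  expect_length(canon@positions, 10)
  expect_setequal(canon@positions[[2]], c("C", "T"))
  expect_setequal(canon@positions[[9]], c("A", "G"))
  n10 <- pats$n10_like
  expect_length(n10@positions, 10)
  expect_equal(unlist(n10@positions[c(1, 2, 3, 8, 9, 10)]),
               c("C", "T", "A", "T", "A", "G"), ignore_attr = TRUE)
  srf <- pats$srf_like
  expect_length(srf@positions, 10)
  for (j in 3:8) expect_setequal(srf@positions[[j]], c("A", "T"))
  # C(A/T)6AG as printed: 1 + 6 + 2 = 9 positions
  expect_length(pats$intermediate@positions, 9)
})

test_that("classifyCarg matches brute-force deviation counts", {
  # SRE core, an atypical LeACS4 site, an atypical LeEXP1 site
  cases <- list(
    list("CCATATTAGG", "canonical", 0L),
    list("CTAGTTAAAG", "canonical", 1L),
    list("CATTTATATG", "canonical", 2L))
  for (cs in cases) {
    got <- classifyCarg(cs[[1]])
    expect_equal(got$patternName, cs[[2]])
    expect_equal(got$nAtypical, cs[[3]])
    expect_equal(got$nAtypical,
                 oracle_count_mismatch(cs[[1]],
                                       oracle_pattern_sets("canonical")))
  }
  expect_equal(classifyCarg("GGGGGGGGGG")$patternName, "none")
  expect_error(classifyCarg("CCATATTAG"), "length")
  expect_error(classifyCarg("CCATATTAGN"), "alphabet")
})

test_that("all five printed tomato atypical decamers are atypical canonical", {
  decamers <- c("CATTTATATG", "CAATTTAAAG", "CAAATATAAG",
                "CAATTTTAAG", "CTAGTTAAAG")
  for (d in decamers) {
    got <- classifyCarg(d, maxAtypical = 2)
    expect_equal(got$patternName, "canonical")
    expect_gte(got$nAtypical, 1)
    expect_lte(got$nAtypical, 2)
  }
})

test_that("scanSequence finds the printed probe cores at offset 4", {
  h1 <- scanSequence("p1", "AAAACTATTTATAGATCA",
                     builtinPatterns()["n10_like"], maxAtypical = 0,
                     bothStrands = FALSE)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$start, 4L)
  expect_equal(h1$end, 14L)
  expect_equal(h1$matchedSeq, "CTATTTATAG")

  h2 <- scanSequence("p2", "ATGTCCATATTAGGACAT",
                     builtinPatterns()["srf_like"], maxAtypical = 0,
                     bothStrands = FALSE)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$start, 4L)
  expect_equal(h2$matchedSeq, "CCATATTAGG")

  # sequence shorter than the pattern
  expect_equal(nrow(scanSequence("p3", "ACGT",
                                 builtinPatterns()["canonical"],
                                 maxAtypical = 0, bothStrands = FALSE)),
               0L)
  expect_equal(nrow(scanSequence("p4", "")), 0L)
  expect_error(scanSequence("p5", "ACGTNACGTACGT"), "alphabet")
})

test_that("scanSequence equals the brute-force oracle on random sequences", {
  set.seed(42)
  patNames <- c("canonical", "srf_like", "n10_like", "intermediate")
  for (rep in 1:12) {
    n <- sample(20:200, 1)
    seq <- random_dna(n)
    budget <- sample(0:2, 1)
    got <- scanSequence("s", seq, builtinPatterns()[patNames],
                        maxAtypical = budget, bothStrands = TRUE)
    want <- oracle_scan("s", seq, patNames, budget, bothStrands = TRUE)
    expect_equal(got, want)
  }
})

test_that("scanSequence agrees with Biostrings degenerate matching", {
  # canonical class as IUPAC: C Y W W W W W W R G, plus strand, budget 0
  set.seed(7)
  seq <- random_dna(400)
  got <- scanSequence("s", seq, builtinPatterns()["canonical"],
                      maxAtypical = 0, bothStrands = FALSE)
  m <- Biostrings::matchPattern("CYWWWWWWRG", Biostrings::DNAString(seq),
                                fixed = "subject")
  expect_equal(got$start, BiocGenerics::start(m) - 1L)
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(60:150, 1)
    seq <- random_dna(n)
    fwd <- scanSequence("s", seq, maxAtypical = 1)
    rev <- scanSequence("s", revcomp(seq), maxAtypical = 1)
    mapped <- fwd
    mapped$start <- n - fwd$end
    mapped$end <- n - fwd$start
    mapped$strand <- ifelse(fwd$strand == "+", "-", "+")
    # palindromic dedupe keeps "+": re-canonicalize palindromes
    pal <- mapped$matchedSeq ==
      vapply(mapped$matchedSeq, oracle_revcomp, character(1))
    mapped$strand[pal] <- "+"
    mapped <- mapped[order(mapped$start, mapped$strand,
                           mapped$patternName), ]
    rownames(mapped) <- NULL
    expect_equal(rev, mapped)
  }
})

test_that("palindromic matches are reported once on the plus strand", {
  # CCATATTAGG is not palindromic; CCATTAATGG is (revcomp equals itself)
  h <- scanSequence("s", "CCATTAATGG", builtinPatterns()["srf_like"],
                    maxAtypical = 0, bothStrands = TRUE)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
})

test_that("hits export as BED6 with 0-based half-open coordinates", {
  h <- scanSequence("p1", "AAAACTATTTATAGATCA",
                    builtinPatterns()["n10_like"], maxAtypical = 0,
                    bothStrands = FALSE)
  tf <- withr::local_tempfile(fileext = ".bed")
  writeHitsBed(h, tf)
  bed <- read.delim(tf, header = FALSE)
  expect_equal(bed$V2, 4L)
  expect_equal(bed$V3, 14L)
  expect_equal(bed$V4, "n10_like/0")
  expect_equal(bed$V6, "+")
})
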