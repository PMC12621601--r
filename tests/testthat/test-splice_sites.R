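test_that("classification splits GT-AG from everything else", {
  expect_equal(classify_intron(c("GTAAGTCTCAG", "GCAAAAAAAG", "CTAAAAAACG")),
               c("canonical", "noncanonical", "noncanonical"))
  expect_error(classify_intron("GTA"), "shorter than 4")
  # partition property: fractions always sum to 1
  set.seed(5)
  seqs <- replicate(50, random_dna(sample(10:60, 1)))
  cl <- classify_intron(seqs)
  expect_equal(mean(cl == "canonical") + mean(cl == "noncanonical"), 1)
})

test_that("dinucleotide spectrum counts transcript-oriented termini", {
  g <- as_genome(list(
    c1 = paste0("AAA", "GTAAAAAAAG", "CCC"),
    c2 = paste0("AAA", "GTAAAAAAAG", "CCC"),
    c3 = paste0("AAA", "CTAAAAAACG", "CCC")
  ))
  introns <- intron_records(c("c1", "c2", "c3"), 3, 13, "+")
  sp <- dinucleotide_spectrum(introns, g)
  expect_equal(sp$count, c(2L, 1L))
  expect_equal(sp$fraction, c(2 / 3, 1 / 3))
  expect_equal(sum(sp$fraction), 1)
  expect_equal(sp$d5[1], "GT"); expect_equal(sp$d3[1], "AG")

  # a minus-strand intron is counted by its transcript-orientation ends:
  # plus twin GTxxAG placed revcomp'd on the contig reads the same
  body <- "GTAAACCCAG"
  gm <- as_genome(list(cm = paste0("TTT", revcomp(body), "GGG")))
  im <- intron_records("cm", 3, 13, "-")
  spm <- dinucleotide_spectrum(im, gm)
  expect_equal(spm$d5, "GT"); expect_equal(spm$d3, "AG")

  empty <- intron_records(character(0), integer(0), integer(0))
  expect_equal(nrow(dinucleotide_spectrum(empty, g)), 0L)
})

test_that("splice-site windows are cut at the documented offsets", {
  set.seed(9)
  up <- random_dna(100); dn <- random_dna(100)
  intron <- paste0("GT", random_dna(46), "AG")  # length 50
  case <- one_intron_case(up, intron, dn)
  w <- extract_windows(case$introns, case$genome, "logo")
  # donor: 3 exonic + 6 intronic; acceptor: 20 intronic + 3 exonic
  expect_identical(w$donor, paste0(substr(up, 98, 100), substr(intron, 1, 6)))
  expect_identical(w$acceptor, paste0(substr(intron, 31, 50), substr(dn, 1, 3)))
  wp <- extract_windows(case$introns, case$genome, "phylo")
  expect_identical(wp$donor, paste0(substr(up, 98, 100), substr(intron, 1, 9)))
  expect_equal(nchar(wp$donor), 12L)
  expect_equal(nchar(wp$acceptor), 23L)

  # mirrored minus-strand case yields identical transcript-oriented windows
  casem <- one_intron_case(up, intron, dn, strand = "-")
  wm <- extract_windows(casem$introns, casem$genome, "logo")
  expect_identical(wm$donor, w$donor)
  expect_identical(wm$acceptor, w$acceptor)

  # intron of length 10: donor fine (logo), acceptor skipped with tally
  short <- one_intron_case(up, "GTAAAAAAAG", dn)
  ws <- extract_windows(short$introns, short$genome, "logo")
  expect_false(is.na(ws$donor))
  expect_true(is.na(ws$acceptor))
  expect_equal(attr(ws, "skipped")[["acceptor_short"]], 1L)

  # contig edge: no upstream exon context
  edge <- intron_records("c1", 1, 40, "+")
  g <- as_genome(list(c1 = random_dna(60)))
  we <- extract_windows(edge, g, "logo")
  expect_true(is.na(we$donor))
  expect_equal(attr(we, "skipped")[["donor_edge"]], 1L)

  # N inside a window: skipped and tallied as ambiguous
  gn <- as_genome(list(c1 = paste0(strrep("A", 20), "GTN",
                                   strrep("A", 30), "AG", strrep("C", 20))))
  wn <- extract_windows(intron_records("c1", 20, 55, "+"), gn, "logo")
  expect_true(is.na(wn$donor))
  expect_false(is.na(wn$acceptor))
  expect_equal(attr(wn, "skipped")[["donor_ambiguous"]], 1L)
})

test_that("PWM frequencies follow the pseudocount formula", {
  p <- build_pwm(c("GT", "GT"))
  expect_equal(unclass(p)[, 1], c(A = 0, C = 0, G = 1, T = 0))
  expect_equal(unclass(p)[, 2], c(A = 0, C = 0, G = 0, T = 1))
  p2 <- build_pwm(c("GA", "GC"))
  expect_equal(unclass(p2)[, 2], c(A = 0.5, C = 0.5, G = 0, T = 0))
  p3 <- build_pwm("A", pseudocount = 1)
  expect_equal(unclass(p3)[, 1], c(A = 2 / 5, C = 1 / 5, G = 1 / 5, T = 1 / 5))
  expect_error(build_pwm(character(0)), "no sequences")
  expect_error(build_pwm(c("AC", "A")), "ragged")
  expect_error(build_pwm("ANA"), "A,C,G,T")

  # columns sum to 1, and the reverse-complement mirror has mirrored columns
  set.seed(3)
  seqs <- replicate(40, random_dna(9))
  pw <- build_pwm(seqs)
  expect_true(all(abs(colSums(unclass(pw)) - 1) < 1e-9))
  pr <- build_pwm(revcomp(seqs))
  expect_equal(unclass(pr)[c("A", "C", "G", "T"), ],
               unclass(pw)[c("T", "G", "C", "A"), 9:1], ignore_attr = TRUE)
})

test_that("information content spans 0 to 2 bits", {
  p <- structure(matrix(c(0.25, 0.25, 0.25, 0.25,
                          1, 0, 0, 0,
                          0.5, 0.5, 0, 0), 4,
                        dimnames = list(c("A", "C", "G", "T"), NULL)),
                 class = c("pwm", "matrix"), n_sequences = 4)
  lm <- logo_matrix(p)
  expect_equal(lm$ic, c(0, 2, 1))
  expect_equal(unname(lm$heights[1, 2]), 2)  # one-hot A letter height = IC
  lc <- logo_matrix(p, small_sample_correction = TRUE)
  expect_true(all(lc$ic <= lm$ic))
})

test_that("branch-point scanning honours the IUPAC motif and the window", {
  # CTAAC with its last base 20 nt from the 3' end of a 60-nt intron: hit
  pre <- strrep("A", 60 - 24)  # motif start at position 37 (1-based)
  s <- paste0(pre, "CTAAC", strrep("G", 19))
  expect_equal(nchar(s), 60)
  expect_equal(scan_branchpoint(s), 37L)
  # same motif with last base 3 nt from the end: outside the window
  s2 <- paste0(strrep("A", 52), "CTAAC", "GGG")
  expect_equal(length(scan_branchpoint(s2)), 0L)
  # CTGAC matches YTRAY (R = G, A required at position 4); CTGGC does not
  s3 <- paste0(strrep("A", 36), "CTGAC", strrep("G", 19))
  expect_equal(scan_branchpoint(s3), 37L)
  s4 <- paste0(strrep("A", 36), "CTGGC", strrep("G", 19))
  expect_equal(length(scan_branchpoint(s4)), 0L)

  # agreement with an independent regex + window oracle
  set.seed(13)
  for (i in 1:200) {
    seq <- random_dna(sample(60:200, 1), gc = runif(1, 0.3, 0.7))
    expect_identical(scan_branchpoint(seq), oracle_branchpoint(seq))
  }
})

test_that("branchpoint_fraction counts introns with at least one hit", {
  hit <- paste0(strrep("A", 30), "CTAAC", strrep("G", 15))
  miss <- strrep("A", 50)
  bf <- branchpoint_fraction(c(hit, hit, miss, miss))
  expect_equal(bf$fraction, 0.5)
  expect_equal(branchpoint_fraction(rep(miss, 4))$fraction, 0)
  expect_error(branchpoint_fraction(character(0)), "no introns")
})

test_that("length statistics use the standard median", {
  expect_equal(length_stats(c(37, 91, 41))$median, 41)
  expect_equal(length_stats(c(10, 20))$median, 15)
  expect_error(length_stats(numeric(0)), "no introns")
  # log-normal generator medians concentrate near exp(meanlog)
  set.seed(21)
  sp <- species_spec("x", "canonical", median_length = 60, seed = 21)
  d <- sample_introns(sp, 2000)
  expect_lt(abs(median(nchar(d$seq)) - 60) / 60, 0.05)
})

test_that("PPT composition reduces to a PWM over the intronic 20-mer", {
  wins <- rep(paste0(strrep("C", 20), "CAG"), 5)
  pc <- ppt_composition(wins)
  expect_equal(dim(unclass(pc)), c(4L, 20L))
  expect_true(all(unclass(pc)["C", ] == 1))
  expect_error(ppt_composition(character(0)), "no acceptor")
  expect_error(ppt_composition("CAG"), "23 nt")
  # generator with an A-rich tract recovers the configured A frequency
  set.seed(2)
  sp <- species_spec("a", "canonical", canonical_fraction = 1,
                     median_length = 80,
                     ppt_weights = c(A = 0.4, C = 0.3, G = 0.1, T = 0.2),
                     seed = 2)
  d <- sample_introns(sp, 1500)
  acc <- substr(d$seq, nchar(d$seq) - 19, nchar(d$seq))
  pa <- build_pwm(acc)
  # central tract columns (implanted branch points perturb a few)
  afreq <- mean(unclass(pa)["A", 4:15])
  se <- sqrt(0.4 * 0.6 / 1500)
  expect_lt(abs(afreq - 0.4), 4 * se + 0.02)
})
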