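test_that("end concatenation takes first and last k with T->U", {
  s30 <- paste0(strrep("GC", 5), strrep("A", 10), strrep("CG", 5))
  expect_equal(concat_ends(s30),
               chartr("T", "U", paste0(substr(s30, 1, 9), substr(s30, 22, 30))))
  s18 <- paste0("GT", random_dna(14), "AG")
  expect_equal(concat_ends(s18), chartr("T", "U", s18))  # boundary: itself
  expect_true(is.na(concat_ends(random_dna(17))))
})

test_that("maximum pairing fold reproduces worked values", {
  expect_equal(max_pairing_fold("AAAAAAAAAAAAAAAAAA")$paired_nt, 0L)
  # innermost candidate pair forbidden by the min-loop constraint: 7 pairs
  gc <- max_pairing_fold("GGGGGGGGGCCCCCCCCC")
  expect_equal(gc$paired_nt, 14L)
  expect_equal(oracle_max_pairs("GGGGGGGGGCCCCCCCCC"), 7L)
  expect_error(max_pairing_fold("GGTT"), "A,C,G,U")
})

test_that("fold count matches exhaustive enumeration on random 18-mers", {
  set.seed(17)
  for (i in 1:60) {
    s <- random_rna18()
    f <- max_pairing_fold(s)
    expect_equal(f$paired_nt, 2L * oracle_max_pairs(s), info = s)
  }
  # shorter and adversarial sequences
  for (s in c("GCGCGCGCGCGC", "AUAUAUAUAUAUAUAUAU", "GGGGGGGGGGGGGGGGGG",
              "GUGUGUGUGUGUGUGUGU", "ACGUACGUACGUACGUAC", "A", "GC")) {
    expect_equal(max_pairing_fold(s)$paired_nt, 2L * oracle_max_pairs(s),
                 info = s)
  }
})

test_that("returned dot-bracket structures are valid and consistent", {
  set.seed(23)
  cfg <- fold_config()
  for (i in 1:40) {
    s <- random_rna18()
    f <- max_pairing_fold(s, cfg)
    db <- strsplit(f$structure, "")[[1]]
    expect_equal(length(db), 18L)
    expect_equal(sum(db == "("), sum(db == ")"))
    expect_equal(2L * sum(db == "("), f$paired_nt)
    # recover pairs from the brackets; each must be allowed and loop-legal
    stack <- integer(0)
    chars <- strsplit(chartr("T", "U", s), "")[[1]]
    for (p in seq_along(db)) {
      if (db[p] == "(") stack <- c(stack, p)
      else if (db[p] == ")") {
        q <- stack[length(stack)]; stack <- stack[-length(stack)]
        expect_true(paste0(chars[q], chars[p]) %in% cfg$allowed_pairs)
        expect_gt(p - q, cfg$min_loop)
      }
    }
    expect_length(stack, 0)
  }
})

test_that("dropping GU wobble never increases the pair count", {
  set.seed(29)
  no_gu <- fold_config(allowed_pairs = c("AU", "UA", "GC", "CG"))
  for (i in 1:40) {
    s <- random_rna18()
    expect_lte(max_pairing_fold(s, no_gu)$paired_nt,
               max_pairing_fold(s)$paired_nt)
  }
})

test_that("intron-end statistic hits its analytic extremes", {
  set.seed(31)
  # last 9 nt the reverse complement of the first 9: 14/18 under min_loop 3
  first9 <- "GATCCGTAC"
  intron <- paste0(first9, random_dna(20), revcomp(first9))
  case <- one_intron_case(random_dna(40), intron, random_dna(40))
  r <- intron_bpp(case$introns, case$genome)
  expect_equal(r$paired_nt, 14L)
  expect_equal(r$bpp, 14 / 18)
  # poly-A intron: nothing pairs
  pa <- one_intron_case(random_dna(40), strrep("A", 30), random_dna(40))
  expect_equal(intron_bpp(pa$introns, pa$genome)$bpp, 0)
  # the statistic never exceeds 14/18 under the default loop constraint
  for (i in 1:100) {
    ci <- one_intron_case(random_dna(20), random_dna(sample(18:60, 1)),
                          random_dna(20))
    expect_lte(intron_bpp(ci$introns, ci$genome)$paired_nt, 14L)
  }
  # introns shorter than 18 nt are skipped and tallied
  g <- as_genome(list(c1 = random_dna(100)))
  two <- intron_records("c1", c(20, 50), c(37, 80), "+")
  r2 <- intron_bpp(two, g)
  expect_equal(nrow(r2), 1L)
  expect_equal(attr(r2, "skipped"), 1L)
})

test_that("exon-flank statistic mirrors the intron-end construction", {
  set.seed(37)
  intron <- paste0("GT", random_dna(30), "AG")
  up <- paste0(random_dna(31), "GGGGGGGGG")
  dn <- paste0("CCCCCCCCC", random_dna(31))
  case <- one_intron_case(up, intron, dn)
  r <- exon_flank_bpp(case$introns, case$genome)
  expect_equal(r$end5, "GGGGGGGGG")
  expect_equal(r$end3, "CCCCCCCCC")
  expect_equal(r$paired_nt, 14L)
  # all-A flanks: zero
  casea <- one_intron_case(strrep("A", 40), intron, strrep("A", 40))
  expect_equal(exon_flank_bpp(casea$introns, casea$genome)$bpp, 0)
  # mirrored strands give identical values
  casem <- one_intron_case(up, intron, dn, strand = "-")
  rm_ <- exon_flank_bpp(casem$introns, casem$genome)
  expect_equal(rm_$bpp, r$bpp)
  expect_equal(rm_$end5, r$end5)
  # contig edge: flank unavailable, skipped with tally
  gshort <- as_genome(list(c1 = paste0(random_dna(5), intron, random_dna(40))))
  redge <- exon_flank_bpp(intron_records("c1", 5, 5 + nchar(intron), "+"),
                          gshort)
  expect_equal(nrow(redge), 0L)
  expect_equal(attr(redge, "skipped"), 1L)
})

test_that("bpp symmetry: reverse-complementing both ends with swap", {
  # holds for Watson-Crick rules: a pair (a, b) maps to (comp(b), comp(a)),
  # which is again Watson-Crick; GU wobble breaks this (GU -> AC), so the
  # property is stated for the WC-restricted configuration
  set.seed(41)
  wc <- fold_config(allowed_pairs = c("AU", "UA", "GC", "CG"))
  for (i in 1:25) {
    e5 <- random_dna(9); e3 <- random_dna(9)
    a <- max_pairing_fold(chartr("T", "U", paste0(e5, e3)), wc)$paired_nt
    b <- max_pairing_fold(chartr("T", "U", paste0(revcomp(e3), revcomp(e5))),
                          wc)$paired_nt
    expect_equal(a, b)
  }
})

test_that("distribution summary applies the notch rule and bookkeeping", {
  d <- bpp_distribution(rep(0.5, 10))
  expect_equal(d$median, 0.5)
  expect_equal(d$q3 - d$q1, 0)
  expect_equal(d$notch_lo, 0.5)
  x <- c(0.1, 0.2, 0.3, 0.6, 0.9)
  dx <- bpp_distribution(x)
  iqr <- unname(quantile(x, 0.75) - quantile(x, 0.25))
  expect_equal(dx$notch_hi - dx$median, 1.58 * iqr / sqrt(5))
  expect_error(bpp_distribution(numeric(0)), "no base-pairing")
  # skipped count propagates from the per-intron table
  g <- as_genome(list(c1 = random_dna(200)))
  introns <- intron_records("c1", c(20, 60, 100), c(37, 90, 130), "+")
  summ <- bpp_distribution(intron_bpp(introns, g))
  expect_equal(summ$skipped, 1L)  # the 17-nt intron
  expect_equal(summ$n, 2L)
})
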