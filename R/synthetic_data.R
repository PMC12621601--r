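# Seeded generator of diplonemid-like study systems: genomes, intron truth
# annotations, and spliced SAM reads for "canonical-mode" species (GT-AG
# introns dominate, as in Diplonemidae) and "hemistasiid-mode" species
# (noncanonical splice sites dominate, GC-rich, with reverse-complementary
# intron ends, as in Hemistasiidae). Every pipeline stage is testable against
# the recorded ground truth without any external data.

default_donor_consensus <- function() {
  m <- matrix(c(
    0.0, 0.0, 1.0, 0.0,   # +1 G
    0.0, 0.0, 0.0, 1.0,   # +2 T
    0.7, 0.1, 0.1, 0.1,   # +3 A
    0.1, 0.1, 0.1, 0.7,   # +4 T
    0.1, 0.1, 0.7, 0.1,   # +5 G
    0.2, 0.2, 0.2, 0.4    # +6 T
  ), nrow = 4, dimnames = list(DNA_BASES, NULL))
  m
}

default_noncanonical_dinuc_weights <- function() {
  c("CT-CG" = 0.11, "TG-GC" = 0.11, "CG-AG" = 0.11, "GC-CA" = 0.11,
    "GC-GC" = 0.08, "CC-GG" = 0.08, "CG-CG" = 0.08, "GG-CC" = 0.08,
    "AT-AC" = 0.06, "GC-AG" = 0.06, "CA-TG" = 0.06, "TC-GA" = 0.06)
}

#' Specify a synthetic species
#'
#' The defaults encode the two intron landscapes the generator emulates:
#' `"canonical"` mode (98% GT-AG introns, GTATG-like donor consensus, C-rich
#' polypyrimidine tract, CAG acceptor) and `"hemistasiid"` mode (3% canonical
#' introns; noncanonical terminal dinucleotides drawn from a CT-CG / TG-GC /
#' CG-AG / GC-CA-enriched spectrum, each below 12%; GC-rich intron bodies;
#' and, with probability `revcomp_end_prob`, a 3' terminal 9-mer that is the
#' mutated reverse complement of the 5' terminal 9-mer). Intron lengths are
#' log-normal, truncated to `[min_len, max_len]`.
#'
#' @param name Species label (unique within a cohort).
#' @param mode `"canonical"` or `"hemistasiid"`; sets mode-specific defaults.
#' @param n_genes,introns_per_gene Gene count and introns per gene.
#' @param canonical_fraction Probability an intron is canonical
#'   (default 0.98 canonical mode, 0.03 hemistasiid mode).
#' @param median_length Target median intron length in nt (the log-normal
#'   location is `log(median_length)`).
#' @param length_sdlog Log-normal scale parameter.
#' @param min_len,max_len Truncation bounds on intron length.
#' @param exon_len Length-2 integer range of exon lengths.
#' @param exon_gc,intron_gc GC content of exons and intron bodies
#'   (intron default 0.45 canonical mode, 0.60 hemistasiid mode).
#' @param donor_consensus 4 x 6 column-stochastic weight matrix for the first
#'   six intronic donor bases of canonical introns.
#' @param ppt_weights Named base weights for the polypyrimidine tract
#'   (set A-rich to emulate an A-preferring tract).
#' @param noncanonical_dinuc_weights Named probability vector over
#'   `"XX-YY"` terminal dinucleotide pairs (must exclude `GT-AG`).
#' @param revcomp_end_prob Probability that a noncanonical intron's last 9 nt
#'   are the mutated reverse complement of its first 9 nt.
#' @param revcomp_mut_rate Per-base mutation rate applied to the
#'   reverse-complemented end.
#' @param branchpoint_rate Probability of implanting a YTRAY pentamer at a
#'   uniformly drawn legal offset (>5 and <50 nt upstream of the 3' end).
#' @param depth_mean,depth_dispersion Negative-binomial split-read depth per
#'   intron (`depth_dispersion = NULL` gives constant depth `depth_mean`).
#' @param minus_strand_fraction Fraction of genes placed on the minus strand.
#' @param seed Integer seed controlling all randomness for this species.
#' @return A list of class `species_spec`.
#' @export
species_spec <- function(name, mode = c("canonical", "hemistasiid"),
                         n_genes = 50L, introns_per_gene = 3L,
                         canonical_fraction = NULL,
                         median_length = NULL, length_sdlog = 0.45,
                         min_len = 20L, max_len = 2000L,
                         exon_len = c(80L, 150L),
                         exon_gc = 0.5, intron_gc = NULL,
                         donor_consensus = default_donor_consensus(),
                         ppt_weights = NULL,
                         noncanonical_dinuc_weights =
                           default_noncanonical_dinuc_weights(),
                         revcomp_end_prob = 0.9, revcomp_mut_rate = 0.1,
                         branchpoint_rate = NULL,
                         depth_mean = 20, depth_dispersion = 8,
                         minus_strand_fraction = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  hemi <- mode == "hemistasiid"
  canonical_fraction <- canonical_fraction %||% (if (hemi) 0.03 else 0.98)
  median_length <- median_length %||% (if (hemi) 37 else 60)
  intron_gc <- intron_gc %||% (if (hemi) 0.60 else 0.45)
  ppt_weights <- ppt_weights %||% c(A = 0.10, C = 0.50, G = 0.10, T = 0.30)
  branchpoint_rate <- branchpoint_rate %||% (if (hemi) 0.05 else 0.13)
  probs <- c(canonical_fraction, revcomp_end_prob, revcomp_mut_rate,
             branchpoint_rate, exon_gc, intron_gc, minus_strand_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (min_len < 4L) stop("min_len must be >= 4")
  if (depth_mean < 0) stop("depth_mean must be >= 0")
  w <- noncanonical_dinuc_weights
  if ("GT-AG" %in% names(w)) stop("GT-AG cannot be a noncanonical pair")
  w <- w / sum(w)
  structure(list(
    name = name, mode = mode, n_genes = as.integer(n_genes),
    introns_per_gene = as.integer(introns_per_gene),
    canonical_fraction = canonical_fraction,
    length_meanlog = log(median_length), length_sdlog = length_sdlog,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    exon_len = as.integer(exon_len), exon_gc = exon_gc,
    intron_gc = intron_gc, donor_consensus = donor_consensus,
    ppt_weights = ppt_weights[DNA_BASES],
    noncanonical_dinuc_weights = w,
    revcomp_end_prob = revcomp_end_prob,
    revcomp_mut_rate = revcomp_mut_rate,
    branchpoint_rate = branchpoint_rate,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    minus_strand_fraction = minus_strand_fraction,
    seed = as.integer(seed)
  ), class = "species_spec")
}

sample_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

mutate_bases <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  chars
}

# One intron + truth record; uses the current RNG stream.
sample_intron_one <- function(spec) {
  klass <- if (stats::runif(1) < spec$canonical_fraction) "canonical"
           else "noncanonical"
  repeat {
    L <- as.integer(round(stats::rlnorm(1, spec$length_meanlog,
                                        spec$length_sdlog)))
    if (L >= spec$min_len && L <= spec$max_len) break
  }
  chars <- sample_bases(L, spec$intron_gc)
  revcomp_ends <- FALSE
  if (klass == "canonical") {
    for (j in 1:6) {
      chars[j] <- sample(DNA_BASES, 1L, prob = spec$donor_consensus[, j])
    }
    avail <- L - 6L - 3L
    ppt_len <- min(17L, avail)
    if (ppt_len > 0L) {
      ppt <- sample(DNA_BASES, ppt_len, replace = TRUE,
                    prob = spec$ppt_weights)
      chars[(L - 2L - ppt_len):(L - 3L)] <- ppt
    }
    chars[L - 2L] <- sample(DNA_BASES, 1L, prob = c(0.1, 0.7, 0.1, 0.1))
    chars[L - 1L] <- "A"; chars[L] <- "G"
    d5 <- paste0(chars[1L], chars[2L]); d3 <- "AG"
  } else {
    pair <- sample(names(spec$noncanonical_dinuc_weights), 1L,
                   prob = spec$noncanonical_dinuc_weights)
    d5 <- substr(pair, 1L, 2L); d3 <- substr(pair, 4L, 5L)
    chars[1L] <- substr(d5, 1L, 1L); chars[2L] <- substr(d5, 2L, 2L)
    if (L >= 18L && stats::runif(1) < spec$revcomp_end_prob) {
      rc <- strsplit(revcomp(paste(chars[1:9], collapse = "")), "")[[1]]
      chars[(L - 8L):L] <- mutate_bases(rc, spec$revcomp_mut_rate)
      revcomp_ends <- TRUE
    }
    # drawn terminal dinucleotides overwrite whatever the ends hold
    chars[L - 1L] <- substr(d3, 1L, 1L); chars[L] <- substr(d3, 2L, 2L)
  }
  bp_implanted <- FALSE; bp_offset <- NA_integer_
  if (stats::runif(1) < spec$branchpoint_rate) {
    lo <- max(7L, L - 48L); hi <- L - 9L
    if (revcomp_ends) { lo <- max(lo, 10L); hi <- min(hi, L - 13L) }
    if (lo <= hi) {
      m <- if (lo == hi) lo else sample(lo:hi, 1L)
      chars[m:(m + 4L)] <- c(sample(c("C", "T"), 1L), "T",
                             sample(c("A", "G"), 1L), "A",
                             sample(c("C", "T"), 1L))
      bp_implanted <- TRUE; bp_offset <- m
    }
  }
  list(seq = paste(chars, collapse = ""), class = klass, d5 = d5, d3 = d3,
       revcomp_ends = revcomp_ends, bp_implanted = bp_implanted,
       bp_offset = bp_offset)
}

#' Sample intron sequences with ground truth
#'
#' Draws `n` introns from a species specification without placing them in a
#' genome; used for large-sample recovery checks of classification,
#' branch-point, and base-pairing behavior.
#'
#' @param spec A [species_spec()].
#' @param n Number of introns.
#' @param seed Seed (defaults to the seed stored in the species
#'   specification).
#' @return `data.frame` with columns `seq`, `class`, `d5`, `d3`,
#'   `revcomp_ends`, `bp_implanted`, `bp_offset`.
#' @export
sample_introns <- function(spec, n, seed = spec$seed) {
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) rows[[i]] <- sample_intron_one(spec)
  data.frame(
    seq = vapply(rows, `[[`, character(1), "seq"),
    class = vapply(rows, `[[`, character(1), "class"),
    d5 = vapply(rows, `[[`, character(1), "d5"),
    d3 = vapply(rows, `[[`, character(1), "d3"),
    revcomp_ends = vapply(rows, `[[`, logical(1), "revcomp_ends"),
    bp_implanted = vapply(rows, `[[`, logical(1), "bp_implanted"),
    bp_offset = vapply(rows, `[[`, integer(1), "bp_offset"),
    stringsAsFactors = FALSE
  )
}

#' Build one synthetic species bundle
#'
#' Lays genes (alternating exons and introns) onto one contig per gene,
#' assigns each gene a strand, draws per-intron split-read depth, and writes
#' four mutually consistent files: genome FASTA, truth intron GTF, spliced
#' SAM reads (each read spans one intron with a `20M<len>N20M` CIGAR and an
#' `XS:A:` strand tag), and a ground-truth TSV. All randomness comes from
#' `spec$seed`, so rebuilding with the same spec is byte-identical.
#'
#' @param spec A [species_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `spec`, `genome`, `truth` (intron records plus truth
#'   columns), and `paths` (fasta/gtf/sam/truth).
#' @export
build_species <- function(spec, dir) {
  stopifnot(inherits(spec, "species_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  anchor <- 20L
  contigs <- character(spec$n_genes)
  names(contigs) <- sprintf("%s_g%03d", spec$name, seq_len(spec$n_genes))
  truth <- list()
  sam_reads <- list()
  for (g in seq_len(spec$n_genes)) {
    k <- spec$introns_per_gene
    exlen <- sample(spec$exon_len[1]:spec$exon_len[2], k + 1L, replace = TRUE)
    intr <- lapply(seq_len(k), function(i) sample_intron_one(spec))
    ilen <- vapply(intr, function(x) nchar(x$seq), integer(1))
    # design (transcript-forward) coordinates
    segs <- character(2L * k + 1L)
    pos <- 0L
    istart <- integer(k); iend <- integer(k)
    for (i in seq_len(k)) {
      segs[2L * i - 1L] <- paste(sample_bases(exlen[i], spec$exon_gc),
                                 collapse = "")
      pos <- pos + exlen[i]
      istart[i] <- pos
      segs[2L * i] <- intr[[i]]$seq
      pos <- pos + ilen[i]
      iend[i] <- pos
    }
    segs[2L * k + 1L] <- paste(sample_bases(exlen[k + 1L], spec$exon_gc),
                               collapse = "")
    design <- paste(segs, collapse = "")
    Lc <- nchar(design)
    minus <- stats::runif(1) < spec$minus_strand_fraction
    cname <- names(contigs)[g]
    if (minus) {
      contigs[g] <- revcomp(design)
      gstart <- Lc - iend; gend <- Lc - istart
      strand <- "-"
    } else {
      contigs[g] <- design
      gstart <- istart; gend <- iend
      strand <- "+"
    }
    depth <- if (is.null(spec$depth_dispersion)) {
      rep(as.integer(spec$depth_mean), k)
    } else {
      stats::rnbinom(k, mu = spec$depth_mean, size = spec$depth_dispersion)
    }
    for (i in seq_len(k)) {
      truth[[length(truth) + 1L]] <- data.frame(
        contig = cname, start = gstart[i], end = gend[i], strand = strand,
        support = depth[i], species = spec$name, class = intr[[i]]$class,
        d5 = intr[[i]]$d5, d3 = intr[[i]]$d3,
        revcomp_ends = intr[[i]]$revcomp_ends,
        bp_implanted = intr[[i]]$bp_implanted,
        bp_offset = intr[[i]]$bp_offset,
        stringsAsFactors = FALSE
      )
      if (depth[i] > 0L) {
        s <- gstart[i]; e <- gend[i]
        seq40 <- paste0(substr(contigs[g], s - anchor + 1L, s),
                        substr(contigs[g], e + 1L, e + anchor))
        cigar <- sprintf("%dM%dN%dM", anchor, e - s, anchor)
        reads <- sprintf(
          "%s_i%02d_r%03d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tXS:A:%s",
          cname, i, seq_len(depth[i]), cname, s - anchor + 1L, cigar,
          seq40, strand)
        sam_reads[[length(sam_reads) + 1L]] <- reads
      }
    }
  }
  genome <- structure(contigs, class = "genome_seq")
  truth <- do.call(rbind, truth)
  paths <- list(
    fasta = file.path(dir, paste0(spec$name, ".fa")),
    gtf = file.path(dir, paste0(spec$name, ".gtf")),
    sam = file.path(dir, paste0(spec$name, ".sam")),
    truth = file.path(dir, paste0(spec$name, "_truth.tsv"))
  )
  write_fasta(genome, paths$fasta)
  write_introns(truth, paths$gtf, "gtf")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  writeLines(c(header, unlist(sam_reads)), paths$sam)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(spec = spec, genome = genome, truth = truth, paths = paths)
}

#' Default six-species cohort
#'
#' Four canonical-mode species (median intron lengths 107, 41, 42 and 74 nt;
#' one with an A-rich polypyrimidine tract) and two hemistasiid-mode species
#' (medians 37 and 91 nt), echoing the contrast between the Diplonemidae and
#' Hemistasiidae intron landscapes. Per-species seeds are derived
#' deterministically from `seed`.
#'
#' @param seed Master integer seed.
#' @return Named list of [species_spec()] objects.
#' @export
default_cohort_specs <- function(seed = 1L) {
  specs <- list(
    species_spec("diplo_A", "canonical", median_length = 107,
                 branchpoint_rate = 0.158, seed = derive_seed(seed, 1L)),
    species_spec("diplo_B", "canonical", median_length = 41,
                 branchpoint_rate = 0.139,
                 ppt_weights = c(A = 0.40, C = 0.25, G = 0.10, T = 0.25),
                 seed = derive_seed(seed, 2L)),
    species_spec("diplo_C", "canonical", median_length = 42,
                 branchpoint_rate = 0.083, seed = derive_seed(seed, 3L)),
    species_spec("diplo_D", "canonical", median_length = 74,
                 branchpoint_rate = 0.131, seed = derive_seed(seed, 4L)),
    species_spec("hemi_A", "hemistasiid", median_length = 37,
                 branchpoint_rate = 0.024, seed = derive_seed(seed, 5L)),
    species_spec("hemi_B", "hemistasiid", median_length = 91,
                 branchpoint_rate = 0.068, seed = derive_seed(seed, 6L))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Build a cohort of synthetic species
#'
#' @param specs Named list of [species_spec()] objects with unique names.
#' @param dir Output directory.
#' @return List with `bundles` (per-species [build_species()] results) and
#'   `manifest` (path to a YAML manifest listing files and seeds).
#' @export
build_cohort <- function(specs, dir) {
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate species names: ", paste(nm[duplicated(nm)], collapse = ", "))
  }
  bundles <- lapply(specs, build_species, dir = dir)
  names(bundles) <- nm
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(
    list(species = lapply(bundles, function(b) {
      c(list(name = b$spec$name, mode = b$spec$mode, seed = b$spec$seed),
        lapply(b$paths, basename))
    })),
    manifest)
  list(bundles = bundles, manifest = manifest)
}
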