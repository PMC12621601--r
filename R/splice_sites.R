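# Splice-site characterization: canonical/noncanonical classification,
# terminal dinucleotide spectra, donor/acceptor windows, PWMs and logo
# matrices, YTRAY branch-point scanning, polypyrimidine-tract composition,
# and intron length statistics. All windows are in transcript orientation.

#' Classify introns as canonical or noncanonical
#'
#' An intron is canonical iff it begins with `GT` and ends with `AG` in
#' transcript orientation; every other terminal combination (GC-AG, CT-CG,
#' TG-GC, ...) is noncanonical.
#'
#' @param intron_seq Character vector of intron sequences (transcript
#'   orientation), each at least 4 nt.
#' @return Character vector, `"canonical"` or `"noncanonical"`.
#' @export
classify_intron <- function(intron_seq) {
  if (length(intron_seq) == 0L) return(character(0))
  if (any(nchar(intron_seq) < 4L)) {
    stop("intron shorter than 4 nt cannot be classified (record ",
         which(nchar(intron_seq) < 4L)[1], ")")
  }
  d5 <- substr(intron_seq, 1L, 2L)
  d3 <- substr(intron_seq, nchar(intron_seq) - 1L, nchar(intron_seq))
  ifelse(d5 == "GT" & d3 == "AG", "canonical", "noncanonical")
}

#' Terminal dinucleotide spectrum
#'
#' Tabulates the 5' and 3' terminal dinucleotide combination of each intron
#' in transcript orientation (so a minus-strand intron is counted by its
#' reverse-complemented ends).
#'
#' @param introns Intron record `data.frame`.
#' @param genome Genome as returned by [read_fasta()].
#' @return `data.frame` with columns `d5`, `d3`, `count`, `fraction`, sorted
#'   by decreasing count; fractions sum to 1.
#' @export
dinucleotide_spectrum <- function(introns, genome) {
  if (nrow(introns) == 0L) {
    return(data.frame(d5 = character(0), d3 = character(0),
                      count = integer(0), fraction = numeric(0)))
  }
  seqs <- intron_sequence(introns, genome)
  d5 <- substr(seqs, 1L, 2L)
  d3 <- substr(seqs, nchar(seqs) - 1L, nchar(seqs))
  tab <- as.data.frame(table(d5 = d5, d3 = d3), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab <- tab[order(-tab$Freq, tab$d5, tab$d3), , drop = FALSE]
  rownames(tab) <- NULL
  data.frame(d5 = tab$d5, d3 = tab$d3, count = tab$Freq,
             fraction = tab$Freq / sum(tab$Freq))
}

#' Extract donor and acceptor splice-site windows
#'
#' Donor windows span 3 exonic + 6 intronic nt in `"logo"` mode or 3 exonic +
#' 9 intronic nt in `"phylo"` mode; acceptor windows always span 20 intronic +
#' 3 exonic nt. Windows are returned in transcript orientation. A window is
#' `NA` (and tallied) when the intron is too short to supply its intronic
#' segment without borrowing bases from the other end, when the required
#' exonic context runs off the contig edge, or when the window contains `N`.
#'
#' @param introns Intron record `data.frame` (strands must be determined).
#' @param genome Genome as returned by [read_fasta()].
#' @param mode `"logo"` (donor 3+6) or `"phylo"` (donor 3+9).
#' @return `data.frame` with columns `donor`, `acceptor`; attribute `skipped`
#'   is a named integer vector with tallies `donor_short`, `acceptor_short`,
#'   `donor_edge`, `acceptor_edge`, `donor_ambiguous`, `acceptor_ambiguous`.
#' @export
extract_windows <- function(introns, genome, mode = c("logo", "phylo")) {
  mode <- match.arg(mode)
  kd <- if (mode == "logo") 6L else 9L
  validate_introns(introns, genome)
  if (any(introns$strand == "*")) stop("windows need determined strands")
  n <- nrow(introns)
  donor <- rep(NA_character_, n)
  acceptor <- rep(NA_character_, n)
  skipped <- c(donor_short = 0L, acceptor_short = 0L, donor_edge = 0L,
               acceptor_edge = 0L, donor_ambiguous = 0L,
               acceptor_ambiguous = 0L)
  seqs <- unclass(genome)[introns$contig]
  clen <- nchar(seqs)
  len <- introns$end - introns$start
  for (i in seq_len(n)) {
    s <- introns$start[i]; e <- introns$end[i]
    if (introns$strand[i] == "+") {
      # donor: genomic [s-3, s+kd); acceptor: genomic [e-20, e+3)
      if (len[i] < kd) skipped["donor_short"] <- skipped["donor_short"] + 1L
      else if (s < 3L) skipped["donor_edge"] <- skipped["donor_edge"] + 1L
      else donor[i] <- substr(seqs[i], s - 2L, s + kd)
      if (len[i] < 20L) skipped["acceptor_short"] <- skipped["acceptor_short"] + 1L
      else if (e + 3L > clen[i]) skipped["acceptor_edge"] <- skipped["acceptor_edge"] + 1L
      else acceptor[i] <- substr(seqs[i], e - 19L, e + 3L)
    } else {
      # donor: revcomp of genomic [e-kd, e+3); acceptor: revcomp of [s-3, s+20)
      if (len[i] < kd) skipped["donor_short"] <- skipped["donor_short"] + 1L
      else if (e + 3L > clen[i]) skipped["donor_edge"] <- skipped["donor_edge"] + 1L
      else donor[i] <- revcomp(substr(seqs[i], e - kd + 1L, e + 3L))
      if (len[i] < 20L) skipped["acceptor_short"] <- skipped["acceptor_short"] + 1L
      else if (s < 3L) skipped["acceptor_edge"] <- skipped["acceptor_edge"] + 1L
      else acceptor[i] <- revcomp(substr(seqs[i], s - 2L, s + 20L))
    }
  }
  amb_d <- !is.na(donor) & grepl("N", donor, fixed = TRUE)
  amb_a <- !is.na(acceptor) & grepl("N", acceptor, fixed = TRUE)
  skipped["donor_ambiguous"] <- sum(amb_d)
  skipped["acceptor_ambiguous"] <- sum(amb_a)
  donor[amb_d] <- NA_character_
  acceptor[amb_a] <- NA_character_
  out <- data.frame(donor = donor, acceptor = acceptor,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "skipped") <- skipped
  out
}

#' Build a position weight matrix
#'
#' Column `j`, base `b` holds `(count(b, j) + pseudocount) / (n + 4 *
#' pseudocount)`; columns sum to 1. Counting uses
#' [Biostrings::consensusMatrix()].
#'
#' @param window_seqs Character vector of equal-length sequences over
#'   A, C, G, T (exclude N-containing windows upstream).
#' @param pseudocount Non-negative pseudocount added per base.
#' @return A 4 x L numeric matrix of class `pwm` with rownames A, C, G, T and
#'   attributes `n_sequences` and `pseudocount`.
#' @export
build_pwm <- function(window_seqs, pseudocount = 0) {
  window_seqs <- window_seqs[!is.na(window_seqs)]
  if (length(window_seqs) == 0L) stop("no sequences to build a PWM from")
  L <- unique(nchar(window_seqs))
  if (length(L) != 1L) stop("ragged window lengths: ", paste(L, collapse = ", "))
  if (any(grepl("[^ACGT]", window_seqs))) {
    stop("PWM windows must be over A,C,G,T only")
  }
  counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(window_seqs),
                                        baseOnly = TRUE)[DNA_BASES, , drop = FALSE]
  n <- length(window_seqs)
  p <- (counts + pseudocount) / (n + 4 * pseudocount)
  structure(p, class = c("pwm", "matrix"), n_sequences = n,
            pseudocount = pseudocount)
}

#' Per-column information content and letter heights
#'
#' For column `j` with frequencies `p`, entropy `H_j = -sum(p * log2(p))`
#' (with `0 * log2(0) = 0`) and information content `IC_j = 2 - H_j` bits;
#' the logo letter height of base `b` is `p_bj * IC_j`. A small-sample
#' correction `(4 - 1) / (2 * ln(2) * n)` can be subtracted on request.
#'
#' @param pwm A [build_pwm()] matrix.
#' @param small_sample_correction Apply the correction term (default off).
#' @return List with `ic` (length-L numeric) and `heights` (4 x L matrix).
#' @export
logo_matrix <- function(pwm, small_sample_correction = FALSE) {
  p <- unclass(pwm)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)
  if (small_sample_correction) {
    n <- attr(pwm, "n_sequences")
    if (is.null(n)) stop("PWM lacks n_sequences; cannot correct")
    ic <- pmax(0, ic - 3 / (2 * log(2) * n))
  }
  list(ic = ic, heights = sweep(p, 2, ic, `*`))
}

#' Branch-point scan configuration
#'
#' The canonical branch-point context is the IUPAC pentamer `YTRAY`
#' (Y = C/T, R = A/G), searched in the region whose distance upstream of the
#' intron 3' end is strictly greater than `min_upstream` and strictly smaller
#' than `max_upstream` nt; the constraint applies to every base of the
#' matched pentamer.
#'
#' @param motif IUPAC motif string.
#' @param min_upstream,max_upstream Exclusive window bounds (nt upstream of
#'   the 3' splice site).
#' @return A list of class `branchpoint_config`.
#' @export
branchpoint_config <- function(motif = "YTRAY", min_upstream = 5L,
                               max_upstream = 50L) {
  min_upstream <- as.integer(min_upstream)
  max_upstream <- as.integer(max_upstream)
  if (min_upstream < 0L || min_upstream >= max_upstream) {
    stop("need 0 <= min_upstream < max_upstream")
  }
  motif <- toupper(motif)
  if (!all(strsplit(motif, "")[[1]] %in% names(IUPAC_CLASSES))) {
    stop("motif contains unsupported IUPAC codes")
  }
  structure(list(motif = motif, min_upstream = min_upstream,
                 max_upstream = max_upstream),
            class = "branchpoint_config")
}

#' Scan one intron for branch-point motif hits
#'
#' Matches are found by direct per-position IUPAC class comparison (all
#' overlapping occurrences). A match at 1-based start `m` in an intron of
#' length `L` is a hit iff every matched base lies strictly more than
#' `min_upstream` and strictly fewer than `max_upstream` nt upstream of the
#' intron 3' end (the last intron base being 1 nt upstream).
#'
#' @param intron_seq A single intron sequence (transcript orientation).
#' @param config A [branchpoint_config()].
#' @return Integer vector of 1-based hit start positions (possibly empty).
#' @export
scan_branchpoint <- function(intron_seq, config = branchpoint_config()) {
  stopifnot(length(intron_seq) == 1L)
  motif <- strsplit(config$motif, "")[[1]]
  w <- length(motif)
  L <- nchar(intron_seq)
  if (L < w) return(integer(0))
  # whole pentamer inside the window: distance of base at position p from the
  # 3' end is L - p + 1; require min_upstream < dist < max_upstream for all.
  lo <- max(1L, L - config$max_upstream + 2L)
  hi <- L - config$min_upstream - w + 1L
  if (hi < lo) return(integer(0))
  chars <- strsplit(intron_seq, "")[[1]]
  cand <- lo:hi
  ok <- rep(TRUE, length(cand))
  for (j in seq_len(w)) {
    ok <- ok & chars[cand + j - 1L] %in% IUPAC_CLASSES[[motif[j]]]
  }
  cand[ok]
}

#' Fraction of introns with a branch-point hit
#'
#' @param intron_seqs Character vector of intron sequences.
#' @param config A [branchpoint_config()].
#' @return List with `fraction` (introns with >= 1 hit), `n`, and `n_hit`.
#' @export
branchpoint_fraction <- function(intron_seqs, config = branchpoint_config()) {
  if (length(intron_seqs) == 0L) stop("no introns supplied")
  hits <- vapply(intron_seqs,
                 function(s) length(scan_branchpoint(s, config)) > 0L,
                 logical(1), USE.NAMES = FALSE)
  list(fraction = mean(hits), n = length(hits), n_hit = sum(hits))
}

#' Intron length summary
#'
#' @param introns Intron record `data.frame` or a numeric vector of lengths.
#' @return List with `median`, `q1`, `q3`, `n`.
#' @export
length_stats <- function(introns) {
  len <- if (is.data.frame(introns)) introns$end - introns$start else introns
  if (length(len) == 0L) stop("no introns supplied")
  q <- stats::quantile(len, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(len))
}

#' Polypyrimidine-tract composition
#'
#' Per-position base frequencies over the 20 intronic positions of the
#' acceptor window (positions -20..-1 relative to the 3' splice site);
#' equivalent to a PWM restricted to the intronic acceptor columns.
#'
#' @param acceptor_windows Character vector of 23-nt acceptor windows
#'   (20 intronic + 3 exonic).
#' @param pseudocount Passed to [build_pwm()].
#' @return A `pwm` over 20 columns.
#' @export
ppt_composition <- function(acceptor_windows, pseudocount = 0) {
  acceptor_windows <- acceptor_windows[!is.na(acceptor_windows)]
  if (length(acceptor_windows) == 0L) stop("no acceptor windows supplied")
  if (any(nchar(acceptor_windows) != 23L)) {
    stop("acceptor windows must be 23 nt (20 intronic + 3 exonic)")
  }
  build_pwm(substr(acceptor_windows, 1L, 20L), pseudocount)
}

#' Write a PWM as plain text
#'
#' 4 x L tab-separated matrix with a header row of 1-based column positions.
#'
#' @param pwm A `pwm` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  m <- unclass(pwm)
  lines <- c(paste(c("base", seq_len(ncol(m))), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
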