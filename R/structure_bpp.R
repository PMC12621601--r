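# Base-pairing statistic between intron (or exon-flank) ends: the first and
# last 9 nt of each intron are concatenated into an 18-mer, folded with a
# maximum base-pairing dynamic program (nested structures, minimum hairpin
# loop, Watson-Crick + GU wobble), and the statistic is the number of paired
# nucleotides divided by 18.

#' Folding configuration
#'
#' @param k Length of each terminal segment (default 9, giving 18-mers).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (a pair (i, j) requires `j - i > min_loop`).
#' @param allowed_pairs Character vector of allowed pairs over A, C, G, U.
#' @param engine `"max-pairing"` for the built-in dynamic program, or a
#'   function `f(seq)` returning `list(structure =, paired_nt =)` to plug in
#'   an external thermodynamic folder.
#' @return A list of class `fold_config`.
#' @export
fold_config <- function(k = 9L, min_loop = 3L,
                        allowed_pairs = c("AU", "UA", "GC", "CG", "GU", "UG"),
                        engine = "max-pairing") {
  k <- as.integer(k); min_loop <- as.integer(min_loop)
  if (k < 1L) stop("k must be >= 1")
  if (min_loop < 0L) stop("min_loop must be >= 0")
  structure(list(k = k, min_loop = min_loop,
                 allowed_pairs = toupper(allowed_pairs), engine = engine),
            class = "fold_config")
}

#' Concatenate intron ends into a foldable 18-mer
#'
#' Takes the first `k` and last `k` nucleotides of the intron (transcript
#' orientation), pastes them, and maps T to U. Introns shorter than `2k`
#' would have overlapping ends and return `NA` (callers tally the skip).
#'
#' @param intron_seq Character vector of intron sequences.
#' @param k Segment length (default 9).
#' @return Character vector of `2k`-mers over A, C, G, U (`NA` where skipped).
#' @export
concat_ends <- function(intron_seq, k = 9L) {
  L <- nchar(intron_seq)
  out <- rep(NA_character_, length(intron_seq))
  ok <- L >= 2L * k
  out[ok] <- chartr("T", "U", paste0(substr(intron_seq[ok], 1L, k),
                                     substr(intron_seq[ok], L[ok] - k + 1L,
                                            L[ok])))
  out
}

#' Maximum base-pairing fold
#'
#' Nussinov-style dynamic program over nested secondary structures: maximizes
#' the number of base pairs with `j - i > min_loop` drawn from
#' `allowed_pairs`, and returns one maximizing structure in dot-bracket
#' notation. `paired_nt` is twice the number of pairs. The count is exactly
#' testable against brute-force enumeration; it deliberately trades the
#' thermodynamic energy model for a self-contained, deterministic statistic
#' that preserves the qualitative contrast between complementary and
#' non-complementary intron ends.
#'
#' @param seq A single RNA string over A, C, G, U.
#' @param config A [fold_config()].
#' @return List with `structure` (dot-bracket) and `paired_nt` (even integer).
#' @export
max_pairing_fold <- function(seq, config = fold_config()) {
  if (is.function(config$engine)) return(config$engine(seq))
  s <- strsplit(toupper(seq), "")[[1]]
  if (any(!s %in% c("A", "C", "G", "U"))) {
    stop("fold input must be over A,C,G,U; got: ", seq)
  }
  n <- length(s)
  ml <- config$min_loop
  pairable <- outer(s, s, function(a, b) paste0(a, b)) # n x n pair labels
  can <- matrix(pairable %in% config$allowed_pairs, n, n)
  M <- matrix(0L, n, n)
  if (n > ml + 1L) {
    for (span in (ml + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]
        for (k in i:(j - ml - 1L)) {
          if (can[k, j]) {
            left <- if (k > i) M[i, k - 1L] else 0L
            inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
            cand <- left + 1L + inner
            if (cand > best) best <- cand
          }
        }
        M[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (M[i, j] == 0L) return()
      if (M[i, j] == M[i, j - 1L]) { j <- j - 1L; next }
      for (k in i:(j - ml - 1L)) {
        if (can[k, j]) {
          left <- if (k > i) M[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
          if (left + 1L + inner == M[i, j]) {
            db[k] <<- "("; db[j] <<- ")"
            if (k > i) trace(i, k - 1L)
            i <- k + 1L; j <- j - 1L
            break
          }
        }
      }
    }
  }
  trace(1L, n)
  list(structure = paste(db, collapse = ""), paired_nt = 2L * M[1L, n])
}

#' Base-pairing statistic for intron ends
#'
#' For each intron: concatenate the terminal `k`-mers ([concat_ends()]), fold
#' ([max_pairing_fold()]), and report `bpp = paired_nt / (2k)`. Introns
#' shorter than `2k` or whose ends contain `N` are skipped and tallied.
#'
#' @param introns Intron record `data.frame`.
#' @param genome Genome as returned by [read_fasta()].
#' @param config A [fold_config()].
#' @return `data.frame` with columns `contig`, `start`, `end`, `end5`,
#'   `end3`, `structure`, `paired_nt`, `bpp`; attribute `skipped` counts the
#'   excluded introns.
#' @export
intron_bpp <- function(introns, genome, config = fold_config()) {
  seqs <- intron_sequence(introns, genome)
  bpp_from_concat(introns, concat_ends(seqs, config$k), config)
}

#' Base-pairing statistic for exon flanks
#'
#' Same statistic computed on the exonic context: the last `k` nt of the
#' upstream exon concatenated with the first `k` nt of the downstream exon
#' (transcript orientation). Introns whose flanks run off the contig edge or
#' contain `N` are skipped and tallied.
#'
#' @inheritParams intron_bpp
#' @return As [intron_bpp()], with `end5`/`end3` holding the exonic segments.
#' @export
exon_flank_bpp <- function(introns, genome, config = fold_config()) {
  validate_introns(introns, genome)
  if (any(introns$strand == "*")) stop("flank extraction needs determined strands")
  k <- config$k
  seqs <- unclass(genome)[introns$contig]
  clen <- nchar(seqs)
  n <- nrow(introns)
  concat <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- introns$start[i]; e <- introns$end[i]
    if (introns$strand[i] == "+") {
      if (s < k || e + k > clen[i]) next
      up <- substr(seqs[i], s - k + 1L, s)
      dn <- substr(seqs[i], e + 1L, e + k)
    } else {
      if (e + k > clen[i] || s < k) next
      up <- revcomp(substr(seqs[i], e + 1L, e + k))
      dn <- revcomp(substr(seqs[i], s - k + 1L, s))
    }
    concat[i] <- chartr("T", "U", paste0(up, dn))
  }
  bpp_from_concat(introns, concat, config)
}

bpp_from_concat <- function(introns, concat, config) {
  k <- config$k
  amb <- !is.na(concat) & grepl("N", concat, fixed = TRUE)
  concat[amb] <- NA_character_
  keep <- which(!is.na(concat))
  folds <- lapply(concat[keep], max_pairing_fold, config = config)
  out <- data.frame(
    contig = introns$contig[keep],
    start = introns$start[keep],
    end = introns$end[keep],
    end5 = substr(concat[keep], 1L, k),
    end3 = substr(concat[keep], k + 1L, 2L * k),
    structure = vapply(folds, `[[`, character(1), "structure"),
    paired_nt = vapply(folds, `[[`, integer(1), "paired_nt"),
    stringsAsFactors = FALSE
  )
  out$bpp <- out$paired_nt / (2L * k)
  attr(out, "skipped") <- nrow(introns) - length(keep)
  out
}

#' Summarize a base-pairing distribution
#'
#' Median, quartiles and the standard box-plot notch interval
#' `median +/- 1.58 * IQR / sqrt(n)` (an approximate 95% confidence interval
#' for the median).
#'
#' @param bpp A `data.frame` from [intron_bpp()]/[exon_flank_bpp()] or a
#'   numeric vector of values in `[0, 1]`.
#' @param skipped Skip count to report (taken from the `skipped` attribute
#'   when `bpp` is a data frame).
#' @return List with `median`, `q1`, `q3`, `notch_lo`, `notch_hi`, `n`,
#'   `skipped`.
#' @export
bpp_distribution <- function(bpp, skipped = 0L) {
  if (is.data.frame(bpp)) {
    skipped <- attr(bpp, "skipped") %||% skipped
    bpp <- bpp$bpp
  }
  if (length(bpp) == 0L) stop("no base-pairing values supplied")
  q <- stats::quantile(bpp, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  half <- 1.58 * iqr / sqrt(length(bpp))
  list(median = q[2], q1 = q[1], q3 = q[3],
       notch_lo = q[2] - half, notch_hi = q[2] + half,
       n = length(bpp), skipped = as.integer(skipped))
}
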