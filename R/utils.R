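#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC classes used by the branch-point scanner
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  Y = c("C", "T"), R = c("A", "G"),
  W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-component seeds derived from one master seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

# fixed-format numbers for byte-stable TSV output
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}
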