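# Coordinate model: all intron records use 0-based half-open intervals on the
# forward genomic strand (BED convention). Biological windows are computed after
# orienting to transcript direction. Strand "*" means undetermined.

#' Read a genome FASTA file
#'
#' Loads a multi-record FASTA into a named character vector of uppercase DNA
#' sequences. Only the characters A, C, G, T, N are accepted; anything else
#' (including IUPAC ambiguity codes other than N) is rejected, so downstream
#' window arithmetic never meets surprises. Contig ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (contig id -> uppercase sequence) of class
#'   `genome_seq`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for contig(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("invalid characters (outside A,C,G,T,N) in contig(s): ",
         paste(ids[bad], collapse = ", "))
  }
  structure(seqs, class = "genome_seq")
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a table of intron records
#'
#' The internal container for introns is a plain `data.frame` with columns
#' `contig`, `start`, `end` (0-based half-open), `strand` (`"+"`, `"-"`, or
#' `"*"` for undetermined), `support` (split-read count) and `species`.
#'
#' @param contig Character vector of contig ids.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Character vector in `c("+", "-", "*")`.
#' @param support Non-negative integer vector of split-read support.
#' @param species Species label (recycled).
#' @param genome Optional genome for bounds checking.
#' @return A `data.frame` of intron records.
#' @export
intron_records <- function(contig, start, end, strand = "*", support = 0L,
                           species = NA_character_, genome = NULL) {
  n <- max(length(contig), length(start), length(end))
  rec <- function(x) rep_len(x, n)
  df <- data.frame(contig = rec(as.character(contig)),
                   start = rec(as.integer(start)),
                   end = rec(as.integer(end)),
                   strand = rec(as.character(strand)),
                   support = rec(as.integer(support)),
                   species = rec(as.character(species)),
                   stringsAsFactors = FALSE)
  validate_introns(df, genome)
  df
}

#' Validate an intron record table
#'
#' @param introns Intron `data.frame` (see [intron_records()]).
#' @param genome Optional genome for bounds checking.
#' @return `introns`, invisibly; errors describe the first offending record.
#' @export
validate_introns <- function(introns, genome = NULL) {
  needed <- c("contig", "start", "end", "strand", "support")
  miss <- setdiff(needed, names(introns))
  if (length(miss)) stop("intron table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(introns$end <= introns$start)
  if (length(bad)) {
    stop("record ", bad[1], ": end (", introns$end[bad[1]],
         ") must exceed start (", introns$start[bad[1]], ")")
  }
  if (any(introns$start < 0L)) stop("negative start coordinate")
  if (!all(introns$strand %in% c("+", "-", "*"))) {
    stop("strand values must be one of '+', '-', '*'")
  }
  if (any(introns$support < 0L)) stop("negative support")
  if (!is.null(genome)) {
    clen <- nchar(genome)[introns$contig]
    if (anyNA(clen)) {
      stop("contig(s) absent from genome: ",
           paste(unique(introns$contig[is.na(clen)]), collapse = ", "))
    }
    over <- which(introns$end > clen)
    if (length(over)) {
      stop("record ", over[1], ": interval exceeds contig ",
           introns$contig[over[1]], " length ", clen[over[1]])
    }
  }
  invisible(introns)
}

#' Read intron coordinates from GTF or BED
#'
#' GTF is 1-based inclusive and converted to the internal 0-based half-open
#' convention (`start - 1`, `end`); BED passes through. GTF records are
#' restricted to feature type `"intron"` when a `type` column is present.
#' Strand `"."` becomes `"*"` (undetermined). Split-read support is taken from
#' the GTF `support` attribute or the BED score column when present.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"bed"` (must be declared by the caller).
#' @return Intron record `data.frame` (see [intron_records()]).
#' @export
read_introns <- function(path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = dialect)
  if (dialect == "gtf" && !is.null(gr$type)) {
    gr <- gr[as.character(gr$type) == "intron"]
  }
  strand <- as.character(GenomicRanges::strand(gr))
  support <- rep(0L, length(gr))
  if (!is.null(gr$support)) {
    support <- as.integer(as.character(gr$support))
  } else if (!is.null(gr$score) && !all(is.na(gr$score))) {
    support <- as.integer(gr$score)
  }
  species <- if (!is.null(gr$species)) as.character(gr$species) else NA_character_
  # GRanges is 1-based inclusive for both dialects once parsed
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  bad <- which(end0 <= start0)
  if (length(bad)) {
    stop("record ", bad[1], " in ", path, ": degenerate interval after ",
         dialect, " coordinate conversion")
  }
  intron_records(as.character(GenomicRanges::seqnames(gr)), start0, end0,
                 strand, support, species)
}

#' Write intron coordinates to GTF or BED6
#'
#' Inverse of [read_introns()]: the round trip read -> write -> read preserves
#' internal coordinates exactly under either dialect. GTF carries support and
#' species as attributes; BED6 stores support in the score column.
#'
#' @param introns Intron record `data.frame`.
#' @param path Output path.
#' @param dialect `"gtf"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_introns <- function(introns, path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  validate_introns(introns)
  if (dialect == "gtf") {
    gr <- GenomicRanges::GRanges(
      introns$contig,
      IRanges::IRanges(start = introns$start + 1L, end = introns$end),
      strand = ifelse(introns$strand == "*", "*", introns$strand)
    )
    gr$source <- "diplointron"
    gr$type <- "intron"
    gr$support <- introns$support
    gr$species <- ifelse(is.na(introns$species), "NA", introns$species)
    rtracklayer::export(gr, path, format = "gtf")
  } else {
    # written directly: BED6 is a fixed-column TSV and scores may exceed 1000
    lines <- data.frame(
      contig = introns$contig,
      start = introns$start,
      end = introns$end,
      name = ifelse(is.na(introns$species), "intron", introns$species),
      score = introns$support,
      strand = ifelse(introns$strand == "*", ".", introns$strand)
    )
    utils::write.table(lines, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Extract intron sequences in transcript orientation
#'
#' For `"+"` records the genomic substring `[start, end)`; for `"-"` records
#' its reverse complement. Undetermined strands are an error: every
#' orientation-dependent analysis requires strand information.
#'
#' @param introns Intron record `data.frame`.
#' @param genome Genome as returned by [read_fasta()].
#' @return Character vector of intron sequences, one per record.
#' @export
intron_sequence <- function(introns, genome) {
  validate_introns(introns, genome)
  und <- introns$strand == "*"
  if (any(und)) {
    stop("record ", which(und)[1],
         ": strand undetermined; cannot orient intron sequence")
  }
  seqs <- substr(unclass(genome)[introns$contig], introns$start + 1L, introns$end)
  neg <- introns$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  unname(seqs)
}
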