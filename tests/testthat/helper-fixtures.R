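# In-code fixtures: tiny genomes, hand-built SAM text, constructed introns.

tmp_fasta <- function(records) {
  f <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), f)
  f
}

as_genome <- function(records) {
  structure(unlist(records), class = "genome_seq")
}

# A SAM file from a list of reads; each read is list(rname, pos, cigar, xs)
tmp_sam <- function(reads, contigs) {
  f <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  body <- vapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    tag <- if (is.null(r$xs)) "" else paste0("\tXS:A:", r$xs)
    sprintf("r%04d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*%s",
            i, r$flag %||% 0L, r$rname, r$pos, r$cigar, tag)
  }, character(1))
  writeLines(c(header, body), f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contig holding one plus-strand intron (s0, e0) 0-based, embedded in given
# exonic context; returns list(genome, introns)
one_intron_case <- function(upstream, intron, downstream, strand = "+",
                            contig = "c1") {
  seq <- paste0(upstream, intron, downstream)
  if (strand == "-") {
    seq <- revcomp(seq)
    s0 <- nchar(downstream)
    e0 <- nchar(downstream) + nchar(intron)
  } else {
    s0 <- nchar(upstream)
    e0 <- nchar(upstream) + nchar(intron)
  }
  g <- as_genome(stats::setNames(list(seq), contig))
  list(genome = g,
       introns = intron_records(contig, s0, e0, strand, 20L, "sp"))
}
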