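# Split-read junction calling from SAM text. Each N operation in a CIGAR marks
# a skipped reference interval (an intron candidate); support for a junction is
# the number of reads whose CIGAR skips exactly that interval.

#' Junction filter configuration
#'
#' Defaults reflect a conservative short-read splice-evidence protocol:
#' junctions supported by fewer than 15 split reads are discarded, and skipped
#' intervals must span 12-10000 nt. A stricter `min_intron = 20` is a sensible
#' second-pass choice for genomes dense in short noncanonical introns.
#'
#' @param min_support Minimum split-read support to keep a junction.
#' @param min_intron,max_intron Inclusive bounds on junction length applied at
#'   extraction time.
#' @param require_strand Drop junctions whose strand stays undetermined.
#' @return A list of class `junction_filter_config`.
#' @export
junction_filter_config <- function(min_support = 15L, min_intron = 12L,
                                   max_intron = 10000L, require_strand = TRUE) {
  min_support <- as.integer(min_support)
  min_intron <- as.integer(min_intron)
  max_intron <- as.integer(max_intron)
  if (min_intron <= 0L || min_intron >= max_intron) {
    stop("need 0 < min_intron < max_intron")
  }
  if (min_support < 0L) stop("min_support must be non-negative")
  structure(list(min_support = min_support, min_intron = min_intron,
                 max_intron = max_intron,
                 require_strand = isTRUE(require_strand)),
            class = "junction_filter_config")
}

#' Read a SAM text file
#'
#' Minimal reader for the fields the junction caller needs: flag, reference,
#' 1-based position, CIGAR, and the `XS:A:` strand tag when present. Header
#' lines are skipped.
#'
#' @param path Path to a SAM file (text).
#' @return `data.frame` with columns `qname`, `flag`, `rname`, `pos`, `cigar`,
#'   `xs` (strand tag or `NA`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      cigar = character(0), xs = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 11L)) stop("SAM line ", which(n < 11L)[1], " has fewer than 11 fields")
  xs <- vapply(parts, function(p) {
    hit <- grep("^XS:A:", p[-(1:11)], value = TRUE)
    if (length(hit)) substring(hit[1], 6L, 6L) else NA_character_
  }, character(1))
  data.frame(
    qname = vapply(parts, `[[`, character(1), 1L),
    flag = as.integer(vapply(parts, `[[`, character(1), 2L)),
    rname = vapply(parts, `[[`, character(1), 3L),
    pos = as.integer(vapply(parts, `[[`, character(1), 4L)),
    cigar = vapply(parts, `[[`, character(1), 6L),
    xs = xs,
    stringsAsFactors = FALSE
  )
}

# Parse one CIGAR into (lengths, ops); NULL if malformed.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1L) return(NULL)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) return(NULL)  # unconsumed characters
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  op <- substr(toks, nchar(toks), nchar(toks))
  list(len = len, op = op)
}

#' Extract junctions from spliced alignments
#'
#' Walks each alignment's CIGAR along the reference (M, =, X, D and N advance
#' the reference; I, S, H, P do not) and emits one junction per N operation
#' whose length falls inside `[min_intron, max_intron]`. Unmapped records are
#' skipped; malformed CIGARs are skipped with a warning and counted. Junction
#' coordinates are 0-based half-open.
#'
#' @param sam Alignment `data.frame` from [read_sam()].
#' @param config A [junction_filter_config()].
#' @return `data.frame` with columns `contig`, `start`, `end`, `support`,
#'   `tag` (consensus `XS` strand or `NA`) and `tag_conflict`; attributes
#'   `n_malformed` and `n_unmapped` carry skip tallies.
#' @export
extract_junctions <- function(sam, config = junction_filter_config()) {
  stopifnot(inherits(config, "junction_filter_config"))
  contig <- character(0); start <- integer(0); end <- integer(0); xs <- character(0)
  n_malformed <- 0L
  unmapped <- bitwAnd(sam$flag, 4L) > 0L | sam$rname == "*" | sam$cigar == "*"
  n_unmapped <- sum(unmapped)
  for (i in which(!unmapped)) {
    cg <- parse_cigar(sam$cigar[i])
    if (is.null(cg)) {
      warning("skipping record ", sam$qname[i], ": malformed CIGAR '",
              sam$cigar[i], "'")
      n_malformed <- n_malformed + 1L
      next
    }
    ref <- sam$pos[i] - 1L  # 0-based reference cursor
    for (j in seq_along(cg$op)) {
      op <- cg$op[j]; len <- cg$len[j]
      if (op == "N") {
        if (len >= config$min_intron && len <= config$max_intron) {
          contig <- c(contig, sam$rname[i])
          start <- c(start, ref)
          end <- c(end, ref + len)
          xs <- c(xs, sam$xs[i])
        }
        ref <- ref + len
      } else if (op %in% c("M", "=", "X", "D")) {
        ref <- ref + len
      }
      # I, S, H, P consume no reference
    }
  }
  if (length(contig) == 0L) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), support = integer(0),
                      tag = character(0), tag_conflict = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(contig, start, end, sep = "\r")
    grp <- split(seq_along(key), key)
    ord <- order(vapply(grp, `[[`, integer(1), 1L))
    grp <- grp[ord]
    first <- vapply(grp, `[[`, integer(1), 1L)
    tags <- lapply(grp, function(ii) unique(xs[ii][!is.na(xs[ii])]))
    out <- data.frame(
      contig = contig[first],
      start = start[first],
      end = end[first],
      support = lengths(grp),
      tag = vapply(tags, function(t) if (length(t) == 1L) t else NA_character_,
                   character(1)),
      tag_conflict = lengths(tags) > 1L,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_malformed") <- n_malformed
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Assign a strand to each junction
#'
#' An alignment strand tag, when available and unambiguous, wins. Otherwise
#' the strand is inferred from the terminal motif of the skipped interval:
#' `GT...AG` on the forward strand implies `"+"`, its reverse complement
#' `CT...AC` implies `"-"`, anything else stays undetermined (`"*"`).
#' Noncanonical junctions therefore need tags to survive a
#' `require_strand` filter.
#'
#' @param junctions Junction `data.frame` from [extract_junctions()].
#' @param genome Genome as returned by [read_fasta()].
#' @return The junctions with added columns `strand` and `strand_evidence`
#'   (one of `"tag"`, `"forward-motif"`, `"reverse-motif"`, `"ambiguous"`).
#' @export
assign_strand <- function(junctions, genome) {
  n <- nrow(junctions)
  strand <- rep("*", n)
  evidence <- rep("ambiguous", n)
  tagged <- !is.na(junctions$tag) & junctions$tag %in% c("+", "-") &
    !junctions$tag_conflict
  strand[tagged] <- junctions$tag[tagged]
  evidence[tagged] <- "tag"
  rest <- which(!tagged)
  if (length(rest)) {
    seqs <- substr(unclass(genome)[junctions$contig[rest]],
                   junctions$start[rest] + 1L, junctions$end[rest])
    d5 <- substr(seqs, 1L, 2L)
    d3 <- substr(seqs, nchar(seqs) - 1L, nchar(seqs))
    fw <- d5 == "GT" & d3 == "AG"
    rv <- d5 == "CT" & d3 == "AC"
    strand[rest[fw]] <- "+"
    evidence[rest[fw]] <- "forward-motif"
    strand[rest[rv]] <- "-"
    evidence[rest[rv]] <- "reverse-motif"
  }
  junctions$strand <- strand
  junctions$strand_evidence <- evidence
  junctions
}

#' Filter junctions into intron records
#'
#' Keeps junctions with `support >= min_support`, and (when
#' `require_strand`) a determined strand; the survivors become intron records
#' sorted by (contig, start, end).
#'
#' @param junctions Stranded junction `data.frame` (see [assign_strand()]).
#' @param config A [junction_filter_config()].
#' @param species Optional species label for the records.
#' @return Intron record `data.frame`.
#' @export
filter_junctions <- function(junctions, config = junction_filter_config(),
                             species = NA_character_) {
  stopifnot(inherits(config, "junction_filter_config"))
  keep <- junctions$support >= config$min_support
  if (config$require_strand) keep <- keep & junctions$strand != "*"
  kept <- junctions[keep, , drop = FALSE]
  kept <- kept[order(kept$contig, kept$start, kept$end), , drop = FALSE]
  intron_records(kept$contig, kept$start, kept$end, kept$strand,
                 kept$support, species)
}

#' Resolve overlapping introns
#'
#' Identical intervals on the same strand are first merged with summed
#' support. Then, within each maximal set of mutually overlapping same-strand
#' introns, only the record with the highest support is retained; ties prefer
#' the longer intron, then the smaller start.
#'
#' @param introns Intron record `data.frame`, sorted by (contig, start, end).
#' @return Intron record `data.frame` with no two same-strand records
#'   overlapping.
#' @export
resolve_overlaps <- function(introns) {
  if (nrow(introns) == 0L) return(introns)
  validate_introns(introns)
  # merge exact duplicates, summing support
  key <- paste(introns$contig, introns$start, introns$end, introns$strand,
               sep = "\r")
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(support ~ key, data =
                              data.frame(key = key, support = introns$support),
                            FUN = sum)
    first <- introns[!duplicated(key), , drop = FALSE]
    first$support <- agg$support[match(key[!duplicated(key)], agg$key)]
    introns <- first
  }
  introns <- introns[order(introns$contig, introns$strand, introns$start,
                           introns$end), , drop = FALSE]
  keep <- logical(nrow(introns))
  groups <- split(seq_len(nrow(introns)),
                  paste(introns$contig, introns$strand, sep = "\r"))
  for (ii in groups) {
    # sweep: maximal connected overlap clusters within one contig+strand
    cluster <- list()
    cmax <- -1L
    flush <- function(cl) {
      if (!length(cl)) return()
      idx <- unlist(cl)
      sub <- introns[idx, , drop = FALSE]
      len <- sub$end - sub$start
      best <- order(-sub$support, -len, sub$start)[1]
      keep[idx[best]] <<- TRUE
    }
    for (i in ii) {
      if (length(cluster) && introns$start[i] >= cmax) {
        flush(cluster); cluster <- list()
      }
      cluster <- c(cluster, list(i))
      cmax <- max(cmax, introns$end[i])
    }
    flush(cluster)
  }
  out <- introns[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call introns from a SAM file in one step
#'
#' Convenience wrapper: [read_sam()] then [extract_junctions()],
#' [assign_strand()], [filter_junctions()], [resolve_overlaps()].
#'
#' @param sam_path Path to a SAM file.
#' @param genome Genome as returned by [read_fasta()].
#' @param config A [junction_filter_config()].
#' @param species Optional species label.
#' @return Intron record `data.frame`.
#' @export
call_junctions <- function(sam_path, genome,
                           config = junction_filter_config(),
                           species = NA_character_) {
  sam <- read_sam(sam_path)
  jx <- extract_junctions(sam, config)
  jx <- assign_strand(jx, genome)
  resolve_overlaps(filter_junctions(jx, config, species))
}
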