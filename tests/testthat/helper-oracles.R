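# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Exhaustive enumeration of nested secondary structures: recursive, no
# memoisation, no DP table. Returns the maximum number of pairs.
oracle_max_pairs <- function(seq, min_loop = 3L,
                             allowed = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)  # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (paste0(s[i], s[k]) %in% allowed) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(s) < 2L) return(0L)
  rec(1L, length(s))
}

# Regex + window arithmetic branch-point oracle (overlapping matches via
# lookahead); returns 1-based start positions.
oracle_branchpoint <- function(seq, min_up = 5L, max_up = 50L) {
  m <- gregexpr("(?=((C|T)T(A|G)A(C|T)))", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  starts <- as.integer(m)
  L <- nchar(seq)
  dist_first <- L - starts + 1L
  dist_last <- L - (starts + 4L) + 1L
  starts[dist_first < max_up & dist_last > min_up]
}

# Brute-force UPGMA returning the cophenetic matrix (leaf-to-leaf tree
# distance). Straightforward cluster-list implementation.
oracle_upgma_cophenetic <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  clusters <- as.list(labels)
  active <- d
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (active[i, j] < bestd) { bestd <- active[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bestd
    }
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    merged_d <- (active[i, ] * ni + active[j, ] * nj) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    new_active <- matrix(0, m - 1L, m - 1L)
    if (length(keep)) {
      new_active[seq_along(keep), seq_along(keep)] <-
        active[keep, keep, drop = FALSE]
      new_active[m - 1L, seq_along(keep)] <-
        new_active[seq_along(keep), m - 1L] <- merged_d[keep]
    }
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    active <- new_active
  }
  coph
}

# Brute-force recount of N operations passing the length gate in a SAM file,
# one count per read per operation (regex pass, no reference walking).
oracle_count_n_ops <- function(sam_path, min_intron = 12L, max_intron = 10000L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  total <- 0L
  for (ln in lines) {
    cigar <- strsplit(ln, "\t", fixed = TRUE)[[1]][6]
    toks <- regmatches(cigar, gregexpr("\\d+N", cigar))[[1]]
    if (length(toks)) {
      lens <- as.integer(sub("N", "", toks))
      total <- total + sum(lens >= min_intron & lens <= max_intron)
    }
  }
  total
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_rna18 <- function() {
  paste(sample(c("A", "C", "G", "U"), 18, replace = TRUE), collapse = "")
}
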