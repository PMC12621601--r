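# Species-level comparison of splice-site composition: per-species,
# per-class PWMs from phylo-mode windows with the conserved terminal
# dinucleotide columns removed, a PWM distance matrix, and UPGMA clustering
# serialized as newick.

#' Strip the conserved terminal dinucleotide columns
#'
#' Phylo-mode donor windows (3 exonic + 9 intronic = 12 nt) lose intronic
#' positions +1, +2; acceptor windows (20 intronic + 3 exonic = 23 nt) lose
#' intronic positions -2, -1. Removing the near-invariant termini prevents
#' them from masking the signal at the remaining positions.
#'
#' @param windows Character vector of phylo-mode windows.
#' @param site `"5ss"` (donor) or `"3ss"` (acceptor).
#' @return Character vector of reduced windows (10 nt for 5ss, 21 for 3ss).
#' @export
strip_terminal_dinucs <- function(windows, site = c("5ss", "3ss")) {
  site <- match.arg(site)
  windows <- windows[!is.na(windows)]
  want <- if (site == "5ss") 12L else 23L
  if (any(nchar(windows) != want)) {
    stop(site, " windows must be ", want, " nt (phylo mode); got length ",
         paste(unique(nchar(windows)[nchar(windows) != want]), collapse = ","))
  }
  if (site == "5ss") {
    paste0(substr(windows, 1L, 3L), substr(windows, 6L, 12L))
  } else {
    paste0(substr(windows, 1L, 18L), substr(windows, 21L, 23L))
  }
}

#' Distance between two PWMs
#'
#' Default is the Frobenius norm of the element-wise difference (symmetric,
#' zero iff equal, satisfies the triangle inequality). `"jsd"` sums the
#' per-column Jensen-Shannon divergence (base 2) as an alternative.
#'
#' @param a,b PWMs of identical dimensions.
#' @param method `"frobenius"` or `"jsd"`.
#' @return Non-negative scalar.
#' @export
pwm_distance <- function(a, b, method = c("frobenius", "jsd")) {
  method <- match.arg(method)
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b))) {
    stop("PWM shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  if (method == "frobenius") {
    sqrt(sum((a - b)^2))
  } else {
    m <- (a + b) / 2
    kl <- function(p, q) {
      ifelse(p > 0, p * (log2(p) - log2(ifelse(q > 0, q, 1))), 0)
    }
    sum(colSums(kl(a, m)) / 2 + colSums(kl(b, m)) / 2)
  }
}

#' Distance matrix over a list of PWMs
#'
#' @param pwms Named list of PWMs with identical dimensions.
#' @param method Passed to [pwm_distance()].
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   `names(pwms)`.
#' @export
pwm_distance_matrix <- function(pwms, method = c("frobenius", "jsd")) {
  method <- match.arg(method)
  n <- length(pwms)
  if (n < 2L) stop("need at least 2 PWMs")
  if (is.null(names(pwms)) || anyDuplicated(names(pwms))) {
    stop("PWMs must be uniquely named")
  }
  m <- matrix(0, n, n, dimnames = list(names(pwms), names(pwms)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- pwm_distance(pwms[[i]], pwms[[j]], method)
    }
  }
  m
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration; the resulting rooted tree is ultrametric,
#' with each merge placed at half the inter-cluster average distance. Labels
#' are sorted lexicographically before clustering so that exact ties are
#' broken by the lexicographically smallest member, independent of input
#' order.
#'
#' @param d Symmetric distance matrix with labels (or a `dist`).
#' @param linkage Agglomeration method (default `"average"` = UPGMA).
#' @return An [ape::as.phylo()] tree (`phylo` object).
#' @export
upgma <- function(d, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must carry labels")
  if (nrow(d) < 2L) stop("need at least 2 labels to cluster")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ape::as.phylo(hc)
}

#' Cluster species splice-site PWMs into a tree
#'
#' For each species profile and intron class, phylo-mode windows of the
#' requested site are stripped of their terminal dinucleotide columns and
#' turned into a PWM; classes represented by fewer than `min_count` windows
#' are excluded (poorly represented classes contribute noise rather than
#' signal). The PWM distance matrix is clustered with [upgma()] and the tree
#' serialized as newick. Leaf labels are `species|class` (`|` replaces `:`,
#' which newick reserves).
#'
#' @param profiles List of species profiles from [characterize_species()],
#'   or any list of lists with elements `species`, `class`, and `windows`
#'   (with `$phylo$donor` / `$phylo$acceptor`).
#' @param site `"5ss"` or `"3ss"`.
#' @param classes Intron classes to consider.
#' @param min_count Minimum windows for a class to be included.
#' @param method,linkage Passed to [pwm_distance_matrix()] and [upgma()].
#' @return List with `tree` (`phylo`), `distances` (matrix), `pwms` (list)
#'   and `newick` (string).
#' @export
splice_site_tree <- function(profiles, site = c("5ss", "3ss"),
                             classes = c("canonical", "noncanonical"),
                             min_count = 50L,
                             method = c("frobenius", "jsd"),
                             linkage = c("average", "single", "complete")) {
  site <- match.arg(site)
  pwms <- list()
  for (pr in profiles) {
    windows <- if (site == "5ss") pr$windows$phylo$donor else pr$windows$phylo$acceptor
    for (cl in classes) {
      w <- windows[!is.na(windows) & pr$class == cl]
      if (length(w) < min_count) next
      pwms[[paste(pr$species, cl, sep = "|")]] <-
        build_pwm(strip_terminal_dinucs(w, site))
    }
  }
  if (length(pwms) < 2L) {
    stop("fewer than 2 species/class PWMs pass min_count = ", min_count)
  }
  dm <- pwm_distance_matrix(pwms, method)
  tree <- upgma(dm, linkage)
  list(tree = tree, distances = dm, pwms = pwms,
       newick = ape::write.tree(tree))
}

#' Test whether a set of leaves forms a clade
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of leaf labels.
#' @return `TRUE` iff `leaves` are exactly the tips descending from their
#'   most recent common ancestor.
#' @export
is_clade <- function(tree, leaves) {
  stopifnot(all(leaves %in% tree$tip.label))
  if (length(leaves) <= 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, leaves)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  setequal(desc, leaves)
}
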