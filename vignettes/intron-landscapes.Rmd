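---
title: "Characterizing canonical and noncanonical intron landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing canonical and noncanonical intron landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diplointron)
```

## The problem

Spliceosomal introns in most eukaryotes begin with `GT` and end with `AG`.
Diplonemid flagellates break this rule spectacularly: in some lineages
(hemistasiids) the overwhelming majority of introns carry *noncanonical*
terminal dinucleotides — CT-CG, TG-GC, CG-AG, GC-CA and many others — while
their close relatives keep the canonical GT-AG landscape. Noncanonical
introns in these organisms tend to be GC-rich, and their 5′ and 3′ ends are
often near reverse complements of each other, so the two ends can base-pair
and bring the splice sites into physical proximity. Characterizing such a
landscape from a draft genome requires a chain of small, well-defined
analyses:

1. **Junction calling** — derive intron intervals from spliced read
   alignments (the `N` operations of SAM CIGAR strings), keep only intervals
   with strong split-read support and a determined strand.
2. **Splice-site characterization** — classify introns as canonical or
   noncanonical, tabulate terminal dinucleotides, extract donor and acceptor
   windows, summarize them as position weight matrices (PWMs) and
   information-content logos, scan for branch-point motifs, and summarize
   the polypyrimidine tract and intron lengths.
3. **End base-pairing** — quantify how well the two ends of each intron (or
   the flanking exonic ends) can base-pair.
4. **Species comparison** — turn per-species, per-class splice-site PWMs
   into a distance matrix and an ultrametric clustering tree.

This package implements that chain, together with a fully seeded synthetic
data generator so every stage can be validated against known ground truth.

## Coordinate and orientation conventions

All intron records use 0-based half-open intervals on the forward genomic
strand (the BED convention); GTF input (1-based inclusive) is converted on
read. Every biological window — intron sequence, donor/acceptor windows,
end segments — is computed *after* orienting to transcript direction, so a
minus-strand intron contributes its reverse-complemented sequence. Records
whose strand cannot be determined are excluded from orientation-dependent
analyses rather than guessed; `N` characters are permitted in genomes, and
any analysis window containing `N` causes that intron to be skipped for that
analysis and counted in a `skipped` tally (draft assemblies contain gaps;
silently padded or guessed windows would distort the PWMs).

## Junction calling

`extract_junctions()` walks each alignment's CIGAR along the reference
(`M`, `=`, `X`, `D` and `N` advance the reference; `I`, `S`, `H`, `P` do
not, following SAM semantics) and emits one junction per `N` operation
whose length falls within `[min_intron, max_intron]` (defaults 12 and
10000 nt). Support is the number of reads skipping exactly that interval.
The filtering defaults — discard junctions with fewer than `min_support =
15` split reads, and drop junctions whose strand stays undetermined — are
deliberately conservative: with draft assemblies, high-confidence intron
models matter more than sensitivity. A stricter `min_intron = 20` is
available for second-pass analyses of genomes dense in very short introns.

Strand comes from an `XS:A:` tag when the aligner provides one; otherwise
it is inferred from the terminal motif (`GT...AG` forward, `CT...AC`
reverse). Noncanonical junctions have no informative motif, so a tag-less
noncanonical junction stays undetermined and is excluded — which is why the
synthetic generator always writes strand tags.

Overlap resolution is a genuinely open design point: overlapping introns
must be reduced to a consistent set, but there is no single standard rule.
We retain, within each maximal set of mutually overlapping same-strand
introns, the record with the highest support (ties: longer intron, then
smaller start), after merging identical intervals with summed support.
Support is the only evidence metric the caller tracks, so it is the only
defensible ranking key.

## Splice-site characterization

An intron is **canonical** iff its first two and last two transcript-
oriented bases are `GT` and `AG`. Donor windows span 3 exonic + 6 intronic
nt for logo display, or 3 exonic + 9 intronic nt for the species
comparison; acceptor windows span 20 intronic + 3 exonic nt. Both donor
modes are first-class because they serve different purposes: the short
window is the classical logo view of the donor site, the long window gives
the species comparison more intronic signal. Introns too short to supply a
full window from their own sequence are skipped per-analysis and tallied,
never padded.

PWMs are per-column base frequencies `(count + pseudocount) / (n + 4 *
pseudocount)` with a default pseudocount of 0; counting is delegated to
`Biostrings::consensusMatrix()`. Logo information content is `IC_j = 2 -
H_j` bits with `H_j` the column Shannon entropy; the small-sample
correction `3 / (2 ln 2 n)` is available but off by default, matching the
common default behavior of logo tools.

### Branch points

The branch-point scanner looks for the IUPAC pentamer `YTRAY` in the
region strictly more than 5 and strictly fewer than 50 nt upstream of the
intron 3′ end. Two readings of such a window are possible — constraining
only the motif start, or the whole motif; we constrain the **whole
pentamer** (every base at distance 6–49 from the 3′ end), the stricter and
more operational reading, and expose both bounds in
`branchpoint_config()`. Matching is by direct per-position IUPAC class
comparison and finds all overlapping occurrences; the test suite checks it
against an independent lookahead-regex oracle.

A subtlety worth spelling out: `YTRAY` is a permissive pattern, so random
intronic sequence produces hits at a substantial background rate. The
fraction of introns with at least one hit therefore *overstates* any
implantation rate: if a fraction `r` of introns carry a deliberate motif
and background hits occur with probability `b`, the observed fraction is
`r + (1 - r) b`. When the generator's implantation rate is recovered in the
tests, the background is estimated from an identically configured
zero-implantation run and removed as `(frac - b) / (1 - b)`. For real
genomes this means the reported branch-point fractions are upper bounds on
deliberate branch-point usage, not estimates of it.

## The end base-pairing statistic

For each intron the first 9 and last 9 nt are concatenated into an 18-mer
(T mapped to U) and folded; the statistic is the number of paired
nucleotides divided by 18. Introns shorter than 18 nt are skipped (their
ends would overlap) and tallied.

The folding engine is a **maximum base-pairing dynamic program**
(Nussinov-style): nested structures only, pairs restricted to
Watson-Crick + GU wobble, and a pair `(i, j)` requires `j - i > min_loop`
with `min_loop = 3`, the standard minimal hairpin loop. This engine is a
deliberate design choice over a thermodynamic minimum-free-energy folder:
it is self-contained, deterministic, and *exactly* testable against
brute-force enumeration of all nested structures, while preserving the
qualitative contrast that motivates the statistic — complementary ends pair
extensively, random ends pair less. Its numbers are systematically more
generous than an energy model's (maximum matching has no stacking or
destabilization terms), so absolute values should not be compared across
engines; `fold_config(engine = )` accepts a substitute function for anyone
wanting a thermodynamic backend.

Under the loop constraint an 18-mer can form at most 7 pairs, so the
statistic's ceiling is 14/18 ≈ 0.78, not 1: a perfectly
reverse-complementary end pair reaches exactly 14/18. The per-species
summary reports median, quartiles and the standard box-plot notch
`median ± 1.58 · IQR / sqrt(n)` as an approximate 95% confidence interval
for the median.

## Species comparison

For each species and intron class, phylo-mode windows are stripped of the
conserved terminal dinucleotide columns (donor: intronic +1, +2; acceptor:
intronic −2, −1) so the near-invariant termini do not mask the signal at
other positions, and turned into a PWM. Classes represented by fewer than
`min_count = 50` windows are excluded — a class that rare contributes
sampling noise, not evolutionary signal.

Two further open choices are made explicit and config-exposed:

* **Distance** between PWMs defaults to the Frobenius norm of the
  element-wise difference: symmetric, zero iff equal, a true metric, and
  parameter-free. A summed per-column Jensen-Shannon divergence is
  available as `method = "jsd"`.
* **Linkage** defaults to average (UPGMA), which yields the ultrametric
  rooted trees that newick serialization and cophenetic comparison expect;
  single and complete linkage are available. Labels are sorted
  lexicographically before clustering so exact ties break by the smallest
  member label, independent of input order. Merge heights are half the
  inter-cluster average distance, so cophenetic leaf-to-leaf distances
  reproduce the UPGMA merge distances.

Leaf labels are `species|class`; `|` stands in for `:`, which newick
reserves.

## The synthetic study system

`species_spec()` fixes the conditions the generator emulates, once:

* **canonical mode** — 98% canonical introns, a `GTATG`-like donor
  consensus, a C-rich polypyrimidine tract (an A-rich variant is used for
  one default cohort species, mirroring the occasional A-preferring
  tract), and a `CAG` acceptor.
* **hemistasiid mode** — 3% canonical introns; noncanonical terminal
  dinucleotides drawn from a spectrum enriched for CT-CG, TG-GC, CG-AG and
  GC-CA (each below 12%, so no combination dominates); GC-rich intron
  bodies (GC 0.60 vs 0.45); and, with probability 0.9, a 3′ terminal
  9-mer that is the reverse complement of the 5′ terminal 9-mer mutated at
  rate 0.1 per base.

Intron lengths are log-normal (scale 0.45) truncated to [20, 2000] nt with
per-species medians; the default six-species cohort uses medians 107, 41,
42 and 74 nt for the four canonical-mode species and 37 and 91 nt for the
two hemistasiid-mode species, and per-species branch-point implantation
rates between 0.024 and 0.158. Split-read depth per intron is negative
binomial (mean 20, dispersion 8) by default. Genes are laid one per contig
(exon lengths 80–150 nt, half the genes on the minus strand), and reads
are emitted directly as aligned SAM records with `20M<len>N20M` CIGARs and
`XS` strand tags.

Two generator details interact and deserve a note. The drawn terminal
dinucleotides always overwrite the intron ends, *including*
reverse-complement-generated ends, so that the dinucleotide spectrum and
the end-complementarity are controllable independently. The cost is that
an arbitrary dinucleotide pair breaks perfect terminal complementarity
even at mutation rate 0; the pairing ceiling of 14/18 is guaranteed only
when the drawn 3′ dinucleotide is itself the reverse complement of the
drawn 5′ dinucleotide (e.g. CG-CG), which is how the corresponding test
pins the value.

What the generator does **not** emulate: sequencing errors and alignment
ambiguity (reads are emitted pre-aligned — the unit under test is junction
counting, not alignment), assembly gaps, trans-splicing, repeat content,
overlapping gene models, and any realistic background dinucleotide
composition around splice sites. Passing tests therefore demonstrate the
correctness of the analysis logic under controlled conditions, not
robustness to the full messiness of real draft assemblies. One visible
consequence: because generator intron bodies are random-composition,
background `YTRAY` hits make the raw branch-point fractions on synthetic
species much higher than the implantation rates (see above), and the
maximum-pairing engine gives random canonical-mode introns a median
statistic near 10/18 — both are properties of the statistic, not bugs.

## Numerical and degenerate-input choices

* Medians and quartiles use R's default quantile definition (type 7);
  the median of two middle values is their mean.
* PWM columns must sum to 1 within 1e-9; pseudocount 0 by default.
* UPGMA ultrametricity is asserted to 1e-9 in the tests.
* Empty inputs error early and explicitly (no silent empty summaries);
  degenerate intervals (end ≤ start) error with the record index.
* Malformed CIGARs warn, are skipped, and are counted; unmapped records
  are skipped and counted.
* All randomness flows from a single integer seed per species or cohort;
  derived seeds stay below 2^31. Rebuilding a species with the same spec
  is byte-identical, and a full pipeline rerun with the same configuration
  reproduces its output files byte-for-byte.

## Problem sizes

The shipped tests and the acceptance script run the default cohort (six
species × 50 genes × 3 introns), 10,000-intron samples for fraction
recovery, 200 random 18-mers plus adversarial repeats against the folding
oracle, 1,000 random sequences against the branch-point oracle, and 100
random 4-leaf matrices against a brute-force UPGMA oracle. These sizes
were chosen so the statistical tolerances (binomial standard errors at
n = 10,000, ±0.01 on recovered fractions) are meaningful while the whole
suite stays comfortably interactive.

## Known limitations

* The junction caller consumes SAM text only; BAM input should be
  converted upstream (e.g. `samtools view`).
* The maximum-pairing statistic is not comparable in absolute terms to
  thermodynamic folding output (see above).
* The branch-point fraction is an upper bound in the presence of
  background matches.
* PWM distances treat columns independently; positional covariation is
  invisible to the species comparison.
* The support threshold is applied per junction; evidence aggregated
  across transcript models is out of scope.
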