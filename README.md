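# diplointron

Characterization of canonical and noncanonical intron landscapes from
split-read evidence, motivated by diplonemid flagellates — marine protists in
which some lineages (hemistasiids) carry almost exclusively *noncanonical*
introns lacking the GT-AG terminal dinucleotides, while their relatives keep
the usual canonical landscape. The package is aimed at anyone who has a draft
genome plus spliced RNA-seq alignments (or wants a fully controlled synthetic
stand-in) and needs a reproducible chain from split reads to species-level
splice-site comparisons.

## What it computes

* **Junction calling.** Each `N` operation in a SAM CIGAR marks a skipped
  reference interval; support for a junction is the number of reads skipping
  exactly that interval. Junctions are kept iff support ≥ 15 (configurable),
  length within [12, 10000] nt, and strand determined (from an `XS` tag or,
  failing that, the GT…AG / CT…AC terminal motif). Overlapping same-strand
  introns are resolved to the highest-support member.
* **Splice-site characterization.** An intron is canonical iff it begins
  `GT` and ends `AG` in transcript orientation. The package tabulates
  terminal dinucleotide spectra, extracts donor windows (3 exonic + 6 or 9
  intronic nt) and acceptor windows (20 intronic + 3 exonic nt), builds
  position weight matrices ``p(b, j) = (n_bj + c) / (n + 4c)`` and logo
  matrices ``IC_j = 2 - H_j`` bits, scans for the branch-point pentamer
  `YTRAY` strictly 6–49 nt upstream of the 3′ splice site, and summarizes
  polypyrimidine-tract composition and intron lengths.
* **End base-pairing (BPP).** The first and last 9 nt of each intron (or of
  the flanking exons) are concatenated into an 18-mer and folded with a
  maximum base-pairing dynamic program (nested structures, Watson-Crick + GU
  pairs, minimum hairpin loop 3); the statistic is
  ``BPP = paired nucleotides / 18``. Under the loop constraint its ceiling
  is 14/18, attained by perfectly reverse-complementary ends.
* **Species comparison.** Per-species, per-class splice-site PWMs (terminal
  dinucleotide columns removed) are compared by Frobenius distance and
  clustered with UPGMA into an ultrametric tree, written as newick.
* **Synthetic study system.** A seeded generator emits genomes, truth
  annotations (GTF), spliced SAM reads and ground-truth TSVs for
  "canonical-mode" and "hemistasiid-mode" species, so every stage is
  testable against known truth.

## Worked example

Simulate one hemistasiid-mode species, call its junctions from the SAM file,
and characterize the result:

```r
library(diplointron)

spec   <- species_spec("hemi_demo", "hemistasiid", n_genes = 30, seed = 42)
bundle <- build_species(spec, file.path(tempdir(), "demo"))
genome <- read_fasta(bundle$paths$fasta)

introns <- call_junctions(bundle$paths$sam, genome,
                          junction_filter_config(), "hemi_demo")
nrow(introns)          # 61 of the 90 simulated introns pass support >= 15
profile <- characterize_species(introns, genome, "hemi_demo")

round(profile$class_fractions, 3)
#>    canonical noncanonical
#>        0.066        0.934
head(profile$spectrum, 4)
#>   d5 d3 count   fraction
#> 1 CG AG     8 0.13114754
#> 2 CC GG     6 0.09836066
#> 3 CT CG     6 0.09836066
#> 4 GC AG     6 0.09836066
profile$lengths$median             # 38
round(profile$branchpoint$fraction, 3)  # 0.197
s <- profile$bpp_summary
sprintf("median BPP %.3f (notch %.3f-%.3f, n=%d)",
        s$median, s$notch_lo, s$notch_hi, s$n)
#> "median BPP 0.667 (notch 0.644-0.689, n=61)"
```

Reading the numbers: 93% of the surviving introns are noncanonical with a
flat dinucleotide spectrum (no combination above ~13%), the median intron is
short (38 nt), and the median end base-pairing statistic of 0.667 (12 of 18
nt paired) is close to the 14/18 ceiling — the signature of
reverse-complementary intron ends. A canonical-mode species run the same way
gives a canonical fraction near 0.98 and a distinctly lower median BPP.

`run_pipeline(list(seed = 1))` chains everything over the default
six-species cohort and writes a cohort summary TSV, per-species junction
BED files, and 5′ss/3′ss newick trees.

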