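# End-to-end orchestration: simulate (or load) a cohort, call junctions,
# characterize splice sites, compute base-pairing distributions, and cluster
# species splice-site PWMs. Stage boundaries serialize to plain TSV/newick so
# each stage can be re-run in isolation.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "diplointron_out",
    cohort = "default",
    junctions = list(min_support = 15L, min_intron = 12L,
                     max_intron = 10000L, require_strand = TRUE),
    windows = list(mode = "logo"),
    branchpoint = list(motif = "YTRAY", min_upstream = 5L, max_upstream = 50L),
    fold = list(k = 9L, min_loop = 3L),
    phylo = list(distance = "frobenius", linkage = "average",
                 min_class_count = 50L)
  )
}

merge_checked <- function(defaults, given, path = "") {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key: ", path, unknown[1])
  }
  for (key in names(given)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(given[[key]])) {
        stop("configuration key ", path, key, " must be a block")
      }
      defaults[[key]] <- merge_checked(defaults[[key]], given[[key]],
                                       paste0(path, key, "."))
    } else {
      defaults[[key]] <- given[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills defaults (min_support 15,
#' min_intron 12, max_intron 10000, fold k 9, min_loop 3, branch-point window
#' (5, 50), logo windows, Frobenius/average clustering), rejects unknown keys
#' by full path, and type-checks each block through the corresponding
#' constructor.
#'
#' @param config Path to a YAML file, a list of overrides, or `NULL` for all
#'   defaults.
#' @return Normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  if (!is.list(config)) stop("configuration must be a list or YAML mapping")
  cfg <- merge_checked(pipeline_defaults(), config)
  cfg$seed <- as.integer(cfg$seed)
  # constructors own the invariant checks
  cfg$junction_config <- junction_filter_config(
    cfg$junctions$min_support, cfg$junctions$min_intron,
    cfg$junctions$max_intron, cfg$junctions$require_strand)
  cfg$branchpoint_config <- branchpoint_config(
    cfg$branchpoint$motif, cfg$branchpoint$min_upstream,
    cfg$branchpoint$max_upstream)
  cfg$fold_config <- fold_config(cfg$fold$k, cfg$fold$min_loop)
  if (!cfg$windows$mode %in% c("logo", "phylo")) {
    stop("windows.mode must be 'logo' or 'phylo'")
  }
  structure(cfg, class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Characterize one species' intron set
#'
#' Bundles the per-species analyses: transcript-oriented sequences,
#' canonical/noncanonical classification, terminal dinucleotide spectrum,
#' splice-site windows in both logo and phylo modes, branch-point fraction,
#' length summary, and the intron-end base-pairing distribution.
#'
#' @param introns Intron record `data.frame` (determined strands).
#' @param genome Genome as returned by [read_fasta()].
#' @param species Species label.
#' @param branchpoint A [branchpoint_config()].
#' @param fold A [fold_config()].
#' @return A list of class `species_profile`.
#' @export
characterize_species <- function(introns, genome, species,
                                 branchpoint = branchpoint_config(),
                                 fold = fold_config()) {
  seqs <- intron_sequence(introns, genome)
  class <- classify_intron(seqs)
  bpp <- intron_bpp(introns, genome, fold)
  structure(list(
    species = species,
    introns = introns,
    seqs = seqs,
    class = class,
    class_fractions = c(canonical = mean(class == "canonical"),
                        noncanonical = mean(class == "noncanonical")),
    spectrum = dinucleotide_spectrum(introns, genome),
    windows = list(logo = extract_windows(introns, genome, "logo"),
                   phylo = extract_windows(introns, genome, "phylo")),
    branchpoint = branchpoint_fraction(seqs, branchpoint),
    lengths = length_stats(introns),
    bpp = bpp,
    bpp_summary = bpp_distribution(bpp)
  ), class = "species_profile")
}

#' Run the full pipeline
#'
#' Stages, in order: simulate the synthetic cohort; call junctions from each
#' species' SAM; characterize splice sites; compute base-pairing
#' distributions; cluster species splice-site PWMs into 5'ss and 3'ss trees.
#' Outputs are deterministic given the configuration seed. Written files:
#' per-species junction BED6, a cohort `summary.tsv` (one row per species:
#' intron count, canonical fraction, top-4 dinucleotide pairs, branch-point
#' fraction, median length, median base-pairing), and `tree_5ss.nwk` /
#' `tree_3ss.nwk`.
#'
#' @param config Anything [validate_config()] accepts.
#' @param outdir Output directory (default from the configuration).
#' @return List with `summary` (data.frame), `profiles`, `trees`, `cohort`,
#'   and `paths`.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cohort <- with_stage("simulate", {
    specs <- if (identical(cfg$cohort, "default")) {
      default_cohort_specs(cfg$seed)
    } else cfg$cohort
    build_cohort(specs, file.path(outdir, "sim"))
  })

  profiles <- list()
  for (nm in names(cohort$bundles)) {
    b <- cohort$bundles[[nm]]
    introns <- with_stage("call-junctions", {
      called <- call_junctions(b$paths$sam, b$genome, cfg$junction_config, nm)
      write_introns(called, file.path(outdir, paste0(nm, "_junctions.bed")),
                    "bed")
      called
    })
    profiles[[nm]] <- with_stage("characterize",
      characterize_species(introns, b$genome, nm, cfg$branchpoint_config,
                           cfg$fold_config))
  }

  summary <- with_stage("summarize", {
    rows <- lapply(profiles, function(pr) {
      top <- utils::head(pr$spectrum, 4L)
      data.frame(
        species = pr$species,
        n_introns = nrow(pr$introns),
        canonical_fraction = pr$class_fractions[["canonical"]],
        top_dinucs = paste(sprintf("%s-%s:%s", top$d5, top$d3,
                                   fmt_num(top$fraction, 4)), collapse = ";"),
        branchpoint_fraction = pr$branchpoint$fraction,
        median_length = pr$lengths$median,
        median_bpp = pr$bpp_summary$median,
        bpp_skipped = pr$bpp_summary$skipped,
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })

  trees <- with_stage("phylo", {
    lapply(c(`5ss` = "5ss", `3ss` = "3ss"), function(site) {
      splice_site_tree(profiles, site,
                       min_count = cfg$phylo$min_class_count,
                       method = cfg$phylo$distance,
                       linkage = cfg$phylo$linkage)
    })
  })

  paths <- list(summary = file.path(outdir, "summary.tsv"),
                tree_5ss = file.path(outdir, "tree_5ss.nwk"),
                tree_3ss = file.path(outdir, "tree_3ss.nwk"))
  out <- summary
  for (col in c("canonical_fraction", "branchpoint_fraction", "median_bpp")) {
    out[[col]] <- fmt_num(summary[[col]])
  }
  out$median_length <- fmt_num(summary$median_length, 1)
  utils::write.table(out, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(trees$`5ss`$newick, paths$tree_5ss)
  writeLines(trees$`3ss`$newick, paths$tree_3ss)

  list(summary = summary, profiles = profiles, trees = trees,
       cohort = cohort, paths = paths)
}
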