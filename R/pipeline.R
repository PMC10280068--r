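#' Read a pipeline run configuration
#'
#' A flat YAML (or `key: value`) file with fields: `fastq`, `primer_fwd`,
#' `primer_rev`, `mode` (`tissue`/`single_cell`), `reference` (FASTA with the
#' locus/insert reference, optional), `gene_model` (GFF3 or interval TSV,
#' optional), `out_dir`, and thresholds `min_prop` (default 0.01), `top_n`
#' (10), `q_min` (20), `chimera_factor` (2), plus `seed` (1).
#'
#' @param path YAML file.
#' @return validated named list of settings.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(mode = "tissue", min_prop = 0.01, top_n = 10L,
                   q_min = 20L, chimera_factor = 2, seed = 1L,
                   out_dir = "ighap_out", reference = NULL,
                   gene_model = NULL, frame = 0L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("fastq", "primer_fwd", "primer_rev"))
    if (is.null(cfg[[k]])) stop("run config is missing required field '", k, "'")
  if (!cfg$mode %in% c("tissue", "single_cell"))
    stop("mode must be 'tissue' or 'single_cell'")
  if (cfg$min_prop < 0 || cfg$min_prop > 1) stop("min_prop must be in [0, 1]")
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full amplicon haplotype pipeline
#'
#' Executes read QC (quality trim, exact primer match, dereplication,
#' chimera removal), haplotype calling in the configured mode, alignment,
#' neighbor-joining, SNP site calling with region partition and Ts/Tv
#' summary (when a gene model is supplied), codon impact and haplotype
#' collapse. All analysis stages are deterministic; identical inputs yield
#' byte-identical outputs. Per-stage failures are reported with the stage
#' name.
#'
#' @param config a config list from [readRunConfig()] or a path to the YAML.
#' @return the summary list (also written to `summary.json`), invisibly:
#'   read counts at every filter stage, the haplotype table, and -- with a
#'   gene model -- densities, Ts/Tv, per-region counts, effect tallies and
#'   the DNA/exon/protein collapse.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  reads <- stageTry("readqc", {
    r <- readFastq(config$fastq)
    if (length(r) == 0) stop("no reads in ", config$fastq)
    r
  })
  nRaw <- length(reads)

  trimmed <- stageTry("readqc", qualityTrim(reads, qMin = config$q_min))
  nonEmpty <- sum(Biostrings::width(trimmed) > 0)
  inserts <- stageTry("readqc",
    matchPrimers(trimmed, config$primer_fwd, config$primer_rev))
  nMatched <- length(inserts)
  if (nMatched == 0) stop("[readqc] no read matched both primers exactly")

  uniques <- stageTry("readqc", dereplicate(inserts))
  uniques <- stageTry("readqc",
    removeChimeras(uniques, parentFactor = config$chimera_factor))
  nPostChimera <- sum(uniques$count)
  write.table(uniques, file.path(config$out_dir, "uniques.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  set <- stageTry("haplotypes", {
    if (config$mode == "tissue") {
      s <- callTissueHaplotypes(uniques, minProp = config$min_prop)
      if (nrow(s@entries)) {
        reference <- if (!is.null(config$reference))
          as.character(Biostrings::readDNAStringSet(config$reference)[[1]])
        else NULL
        s <- alignHaplotypes(s, reference = reference)
      }
      s
    } else {
      callSingleCellHaplotypes(uniques, topN = config$top_n,
                               minProp = config$min_prop)
    }
  })

  tab <- haplotypeTable(set)
  if (nrow(tab)) {
    hdr <- sprintf("%s_%d_%d_%s_%s", tab$id, tab$count, set@total,
                   format(tab$proportion, nsmall = 4, trim = TRUE),
                   ifelse(tab$valid, "valid", "invalid"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(tab$sequence, hdr)),
      file.path(config$out_dir, "haplotypes.fasta"))
    aln <- haplotypeAlignment(set)
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(c(alignmentAnchor(set), aln),
                                      c("reference", names(aln)))),
      file.path(config$out_dir, "aligned.fasta"))
    if (nrow(tab) >= 2)
      stageTry("haplotypes", njTree(set, file.path(config$out_dir, "tree.nwk")))
  }

  summary <- list(
    readCounts = list(raw = nRaw, qualityPassing = nonEmpty,
                      primerMatched = nMatched, postChimera = nPostChimera),
    mode = config$mode,
    thresholds = list(minProp = config$min_prop, topN = config$top_n,
                      qMin = config$q_min, chimeraFactor = config$chimera_factor),
    haplotypes = tab)

  if (!is.null(config$gene_model) && sum(tab$valid) >= 2) {
    model <- stageTry("snpstats",
      readGeneModel(config$gene_model, frame = config$frame))
    sites <- stageTry("snpstats", callSnpSites(set))
    part <- stageTry("snpstats", partitionByRegion(sites, model))
    reference <- degap(alignmentAnchor(set))
    write.table(part$sites, file.path(config$out_dir, "snps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeSnpVcf(part$sites, model, reference,
                file.path(config$out_dir, "snps.vcf"))
    summary$snp <- list(
      nSites = nrow(sites),
      densityPerKb = snpDensity(sites, nchar(reference)),
      regionCounts = as.list(part$counts),
      regionDensityPerKb = as.list(part$density))
    if (any(sites$class != "indel")) {
      ts <- stageTry("snpstats", tstvSummary(sites))
      summary$snp$tstv <- ts[c("typeProportions", "transitions",
                               "transversions", "ratio")]
    }
    changes <- stageTry("codon", codonChanges(set, model))
    write.table(changes, file.path(config$out_dir, "codon_changes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    collapse <- stageTry("codon", collapseLevels(set, model))
    summary$codon <- list(effects = as.list(countEffects(changes)),
                          collapse = as.list(collapse))
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows")
  writeLines(json, file.path(config$out_dir, "summary.json"))
  invisible(summary)
}
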