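#' Gene model of an amplified locus
#'
#' Ordered exon/intron features tiling a locus, with strand and reading frame.
#' Intervals are 1-based and closed (the R/Bioconductor convention); the first
#' base of an exon feature is exonic.
#'
#' @slot locusId single locus identifier.
#' @slot strand `"+"` or `"-"`.
#' @slot features `data.frame` with columns `kind` (`"exon"`/`"intron"`),
#'   `start`, `end` (1-based, closed), sorted and tiling `[1, locusLength]`.
#' @slot frame integer offset (0--2) of the first coding base within the
#'   spliced exon sequence.
#' @slot locusLength locus length in bases.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(locusId = "character", strand = "character",
                 features = "data.frame", frame = "integer",
                 locusLength = "integer"))

setValidity("GeneModel", function(object) {
  f <- object@features
  msg <- character(0)
  if (!all(c("kind", "start", "end") %in% names(f)))
    msg <- c(msg, "features must have columns kind, start, end")
  else {
    if (!all(f$kind %in% c("exon", "intron")))
      msg <- c(msg, "feature kind must be 'exon' or 'intron'")
    if (nrow(f) > 0) {
      if (f$start[1] != 1L || f$end[nrow(f)] != object@locusLength ||
          (nrow(f) > 1 && any(f$start[-1] != f$end[-nrow(f)] + 1L)))
        msg <- c(msg, "features must tile [1, locusLength] without gaps or overlap")
      if (any(f$end < f$start)) msg <- c(msg, "feature end < start")
    }
  }
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (object@frame < 0L || object@frame > 2L) msg <- c(msg, "frame must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Simulation settings for a mosaic amplicon population
#'
#' Parameters of the synthetic mosaic cell population: number and frequencies
#' of true haplotypes, region-specific substitution rates, transition bias,
#' intron deletion rate, sequencing depth and per-base error, chimera rate,
#' the primer pair, and the RNG seed.
#'
#' @slot nHaplotypes number of true haplotypes K (haplotype 1 is the
#'   unmutated reference).
#' @slot haplotypeFreqs probability vector of length K summing to 1.
#' @slot snpRateExon,snpRateIntron expected substitutions per base in exons
#'   and introns.
#' @slot tstvKappa ratio of transition to transversion probability for a
#'   mutated site; a substitution is a transition with probability
#'   `kappa / (kappa + 1)`.
#' @slot indelRateIntron expected single-base deletions per intron base
#'   (exonic deletions are never simulated).
#' @slot readDepth number of reads to emit.
#' @slot perBaseError i.i.d. sequencing error probability per base.
#' @slot chimeraRate probability a read is a two-parent PCR chimera.
#' @slot primerFwd,primerRev forward and reverse primer sequences (the read
#'   is `primerFwd + insert + reverseComplement(primerRev)`).
#' @slot seed RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nHaplotypes = "integer", haplotypeFreqs = "numeric",
                 snpRateExon = "numeric", snpRateIntron = "numeric",
                 tstvKappa = "numeric", indelRateIntron = "numeric",
                 readDepth = "integer", perBaseError = "numeric",
                 chimeraRate = "numeric", primerFwd = "character",
                 primerRev = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nHaplotypes < 1L) msg <- c(msg, "nHaplotypes must be >= 1")
  if (length(object@haplotypeFreqs) != object@nHaplotypes)
    msg <- c(msg, "haplotypeFreqs must have length nHaplotypes")
  if (abs(sum(object@haplotypeFreqs) - 1) > 1e-9)
    msg <- c(msg, "haplotypeFreqs must sum to 1")
  if (any(object@haplotypeFreqs < 0)) msg <- c(msg, "haplotypeFreqs must be >= 0")
  rates <- c(object@snpRateExon, object@snpRateIntron, object@indelRateIntron,
             object@perBaseError, object@chimeraRate)
  if (any(rates < 0) || any(rates > 1)) msg <- c(msg, "all rates must lie in [0, 1]")
  if (object@tstvKappa < 0) msg <- c(msg, "tstvKappa must be >= 0")
  if (object@readDepth < 1L) msg <- c(msg, "readDepth must be >= 1")
  if (nchar(object@primerFwd) < 1L || nchar(object@primerRev) < 1L)
    msg <- c(msg, "primers must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated mosaic population
#'
#' @slot reference the unmutated locus sequence.
#' @slot haplotypes `data.frame` with columns `id`, `frequency`, `sequence`.
#' @slot events `data.frame` of planted mutations with columns `id`, `pos`
#'   (1-based reference coordinate), `ref`, `alt` (`"-"` for deletions),
#'   `class` (`transition`/`transversion`/`deletion`) and `region`
#'   (`exon`/`intron`).
#' @exportClass TruthTable
setClass("TruthTable",
  representation(reference = "character", haplotypes = "data.frame",
                 events = "data.frame"))

setValidity("TruthTable", function(object) {
  msg <- character(0)
  if (!all(c("id", "frequency", "sequence") %in% names(object@haplotypes)))
    msg <- c(msg, "haplotypes needs columns id, frequency, sequence")
  if (nrow(object@events) &&
      !all(object@events$class %in% c("transition", "transversion", "deletion")))
    msg <- c(msg, "event class must be transition, transversion or deletion")
  if (length(msg)) msg else TRUE
})

#' A called haplotype set
#'
#' Haplotypes called from dereplicated unique sequences under the bulk-tissue
#' (proportion threshold) or single-cell (top-N plus validity) rule, together
#' with their reference-anchored gapped alignment.
#'
#' @slot mode `"tissue"` or `"single_cell"`.
#' @slot entries `data.frame` with columns `id` ("H1", "H2", ... by rank),
#'   `sequence`, `count`, `proportion`, `valid`, `errorFlag`.
#' @slot alignment gapped sequences (one per entry, same order); each row
#'   degaps to its entry's sequence. Empty until [alignHaplotypes()] runs.
#' @slot referenceRow gapped anchor row of the alignment (the alignment
#'   reference; gaps mark columns where some entry carries an insertion).
#' @slot columnLocusPos 1-based reference coordinate of every alignment
#'   column (`NA` for insertion columns).
#' @slot total total retained reads behind the proportions.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(mode = "character", entries = "data.frame",
                 alignment = "character", referenceRow = "character",
                 columnLocusPos = "integer", total = "integer"))

setValidity("HaplotypeSet", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("tissue", "single_cell"))
    msg <- c(msg, "mode must be 'tissue' or 'single_cell'")
  need <- c("id", "sequence", "count", "proportion", "valid", "errorFlag")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries needs columns", paste(need, collapse = ", ")))
  if (length(object@alignment)) {
    if (length(object@alignment) != nrow(object@entries))
      msg <- c(msg, "alignment must have one row per entry")
    else if (!all(degap(object@alignment) == object@entries$sequence))
      msg <- c(msg, "alignment rows must degap to entry sequences")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneModel", function(object) {
  ex <- sum(object@features$kind == "exon")
  cat(sprintf("GeneModel '%s': %d bp (%s strand), %d exon(s), %d intron(s), frame %d\n",
              object@locusId, object@locusLength, object@strand,
              ex, nrow(object@features) - ex, object@frame))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: K=%d haplotypes, depth %d\n",
    "  freqs: %s\n  snp rate exon/intron: %g/%g, kappa %g, intron indel %g\n",
    "  per-base error %g, chimera rate %g, seed %d\n"),
    object@nHaplotypes, object@readDepth,
    paste(signif(object@haplotypeFreqs, 3), collapse = ", "),
    object@snpRateExon, object@snpRateIntron, object@tstvKappa,
    object@indelRateIntron, object@perBaseError, object@chimeraRate,
    object@seed))
})

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable: %d haplotypes over a %d bp locus, %d planted events\n",
              nrow(object@haplotypes), nchar(object@reference),
              nrow(object@events)))
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet (%s mode): %d entries, %d valid, total %d reads%s\n",
              object@mode, nrow(object@entries), sum(object@entries$valid),
              object@total,
              if (length(object@alignment))
                sprintf("; alignment %d columns", nchar(object@alignment[1]))
              else "; unaligned"))
  print(head(object@entries[, c("id", "count", "proportion", "valid", "errorFlag")], 10))
  invisible(NULL)
})
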