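# Standard genetic code (translation table 1), written out here so the
# translator is self-contained and externally tabulated codes can serve as
# independent cross-checks.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a CDS under the standard genetic code
#'
#' Translation table 1. The trailing partial codon is dropped; internal stops
#' are retained as `*` (with a warning); codons containing a non-ACGT symbol
#' translate to `X` with a warning.
#'
#' @param cds character vector of coding sequences.
#' @param frame offset 0--2 of the first codon (bases before it are skipped).
#' @return character vector of protein sequences.
#' @examples
#' translateCDS("ATTTTGCAG")  # "ILQ"
#' @export
translateCDS <- function(cds, frame = 0L) {
  vapply(as.character(cds), function(s) {
    s <- toupper(s)
    s <- substr(s, frame + 1L, nchar(s))
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- CODON_TABLE[codons]
    if (anyNA(aa)) {
      warning("codon(s) with non-ACGT symbols translated as 'X'")
      aa[is.na(aa)] <- "X"
    }
    if (n > 1L && any(aa[-n] == "*"))
      warning("internal stop codon retained as '*'")
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a codon change as synonymous or nonsynonymous
#'
#' @param refCodon,altCodon 3-base codons differing at >= 1 position. For
#'   multi-position differences the effect is computed on the whole codons.
#' @param siteIndex optional site label carried through to the output.
#' @return one-row `data.frame`: `site`, `refCodon`, `altCodon`,
#'   `codonOffset` (0--2, first differing base), `refAa`, `altAa`, `effect`
#'   (`synonymous` iff the amino acids are equal).
#' @examples
#' codonEffect("AGA", "ATA")  # nonsynonymous R/I, offset 1
#' @export
codonEffect <- function(refCodon, altCodon, siteIndex = NA_integer_) {
  refCodon <- toupper(refCodon); altCodon <- toupper(altCodon)
  stopifnot(nchar(refCodon) == 3, nchar(altCodon) == 3)
  if (refCodon == altCodon) stop("codons are identical")
  rc <- strsplit(refCodon, "")[[1]]
  ac <- strsplit(altCodon, "")[[1]]
  refAa <- translateCDS(refCodon)
  altAa <- translateCDS(altCodon)
  data.frame(site = siteIndex, refCodon = refCodon, altCodon = altCodon,
             codonOffset = which(rc != ac)[1] - 1L,
             refAa = refAa, altAa = altAa,
             effect = if (refAa == altAa) "synonymous" else "nonsynonymous",
             stringsAsFactors = FALSE)
}

#' Tally synonymous and nonsynonymous changes
#'
#' @param changes `data.frame` of [codonEffect()] rows.
#' @return named integer vector `c(synonymous = , nonsynonymous = )`;
#'   the two always sum to `nrow(changes)`.
#' @export
countEffects <- function(changes) {
  c(synonymous = sum(changes$effect == "synonymous"),
    nonsynonymous = sum(changes$effect == "nonsynonymous"))
}

# map each alignment column to its role for splicing: the exon/intron kind of
# its reference coordinate; insertion columns take the kind of the left
# flanking reference base
columnRegions <- function(set, model) {
  colPos <- set@columnLocusPos
  leftAnchor <- cummax(ifelse(is.na(colPos), 0L, colPos))
  leftAnchor[leftAnchor == 0L] <- 1L
  regionOf(model, leftAnchor)
}

#' Splice exons out of aligned haplotypes
#'
#' Lifts the gene model's exon intervals through the alignment anchor and
#' concatenates each haplotype's exon-projected, degapped bases in feature
#' order (reverse-complemented for minus-strand models). Haplotypes whose
#' indels disrupt the reading frame -- a deletion or insertion of
#' non-multiple-of-3 length within exons, or a gap run spanning a splice
#' boundary -- are excluded with a warning.
#'
#' @param set an aligned [HaplotypeSet-class] (anchored on the locus
#'   reference the model describes).
#' @param model a [GeneModel-class].
#' @param validOnly restrict to valid entries (default `TRUE`).
#' @return `data.frame` with columns `id`, `cds`, `excluded`, `reason`.
#' @export
spliceExons <- function(set, model, validOnly = TRUE) {
  stopifnot(is(set, "HaplotypeSet"), is(model, "GeneModel"))
  if (length(set@alignment) == 0)
    stop("alignment must be computed first (alignHaplotypes)")
  rows <- if (validOnly) which(set@entries$valid) else seq_len(nrow(set@entries))
  m <- gappedToMatrix(set@alignment)[rows, , drop = FALSE]
  ids <- set@entries$id[rows]
  colReg <- columnRegions(set, model)
  colPos <- set@columnLocusPos
  exonCols <- which(colReg == "exon" & !is.na(colPos))
  exonInsCols <- which(colReg == "exon" & is.na(colPos))
  refExonLen <- length(exonCols)

  out <- lapply(seq_along(ids), function(i) {
    chars <- m[i, ]
    exonDel <- sum(chars[exonCols] == "-")
    exonIns <- sum(chars[exonInsCols] != "-")
    # gap runs crossing an exon/intron boundary break splicing
    gapRuns <- rle(chars == "-")
    boundarySpan <- FALSE
    if (any(gapRuns$values)) {
      stops <- cumsum(gapRuns$lengths)
      starts <- stops - gapRuns$lengths + 1L
      for (r in which(gapRuns$values)) {
        kinds <- unique(colReg[starts[r]:stops[r]])
        if (length(kinds) > 1) { boundarySpan <- TRUE; break }
      }
    }
    frameshift <- ((exonIns - exonDel) %% 3L) != 0L
    if (boundarySpan || frameshift) {
      reason <- if (boundarySpan) "deletion spans a splice boundary"
                else "indel disrupts the reading frame"
      return(data.frame(id = ids[i], cds = NA_character_, excluded = TRUE,
                        reason = reason, stringsAsFactors = FALSE))
    }
    keep <- sort(c(exonCols, exonInsCols[chars[exonInsCols] != "-"]))
    cds <- paste(chars[keep][chars[keep] != "-"], collapse = "")
    if (model@strand == "-") cds <- revComp(cds)
    data.frame(id = ids[i], cds = cds, excluded = FALSE, reason = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(res$excluded))
    warning(sum(res$excluded), " haplotype(s) excluded from codon analysis: ",
            paste(res$id[res$excluded], collapse = ", "))
  attr(res, "refExonLen") <- refExonLen
  res
}

#' Codon changes at variable exon sites
#'
#' Builds the codon-impact table: every spliced-CDS position where a valid
#' haplotype differs from the reference CDS becomes a sequentially numbered
#' site (1-based over variable exon sites), with the reference and observed
#' alternate codon and its effect. One row per distinct alternate codon.
#'
#' @param set an aligned [HaplotypeSet-class].
#' @param model a [GeneModel-class].
#' @param referenceCds optional explicit reference CDS; defaults to the CDS
#'   spliced from the alignment anchor, i.e. the locus reference.
#' @return `data.frame` of [codonEffect()] rows (with a `cdsPos` column);
#'   zero rows when the exons are invariant.
#' @export
codonChanges <- function(set, model, referenceCds = NULL) {
  spl <- spliceExons(set, model)
  if (is.null(referenceCds)) {
    anchorSet <- set
    anchorSet@entries <- data.frame(id = "ref", sequence = degap(set@referenceRow),
                                    count = 0L, proportion = 0, valid = TRUE,
                                    errorFlag = FALSE, stringsAsFactors = FALSE)
    anchorSet@alignment <- set@referenceRow
    referenceCds <- spliceExons(anchorSet, model)$cds
  }
  kept <- spl[!spl$excluded & nchar(spl$cds) == nchar(referenceCds), ,
              drop = FALSE]
  frame <- model@frame
  nCodon <- (nchar(referenceCds) - frame) %/% 3L
  varPos <- sort(unique(unlist(lapply(kept$cds, function(s) {
    which(strsplit(s, "")[[1]] != strsplit(referenceCds, "")[[1]])
  }))))
  varPos <- varPos[varPos > frame & varPos <= frame + 3L * nCodon]
  rowsOut <- list()
  siteIdx <- 0L
  for (p in varPos) {
    siteIdx <- siteIdx + 1L
    codonIdx <- (p - frame - 1L) %/% 3L
    cStart <- frame + codonIdx * 3L + 1L
    refCodon <- substr(referenceCds, cStart, cStart + 2L)
    altCodons <- unique(vapply(kept$cds, substr, "", cStart, cStart + 2L,
                               USE.NAMES = FALSE))
    for (alt in setdiff(altCodons, refCodon)) {
      eff <- codonEffect(refCodon, alt, siteIndex = siteIdx)
      eff$cdsPos <- p
      rowsOut[[length(rowsOut) + 1L]] <- eff
    }
  }
  if (!length(rowsOut))
    return(data.frame(site = integer(0), refCodon = character(0),
                      altCodon = character(0), codonOffset = integer(0),
                      refAa = character(0), altAa = character(0),
                      effect = character(0), cdsPos = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rowsOut)
  rownames(res) <- NULL
  res
}

#' Collapse haplotype counts from DNA to exons to protein
#'
#' Counts distinct sequences among the valid haplotypes at three levels:
#' full (genomic DNA) sequences, spliced exon (CDS) strings, and their
#' translations. Frame-disrupted haplotypes are excluded from the exon and
#' protein levels (and reported). The counts are monotone:
#' `protein <= exon <= dna`.
#'
#' @param set an aligned [HaplotypeSet-class].
#' @param model a [GeneModel-class].
#' @return named integer vector `c(dna = , exon = , protein = )`, with
#'   attribute `"excluded"` listing frame-disrupted haplotype ids.
#' @export
collapseLevels <- function(set, model) {
  valid <- validHaplotypes(set)
  spl <- spliceExons(set, model)
  kept <- spl[!spl$excluded, , drop = FALSE]
  prot <- translateCDS(kept$cds, frame = model@frame)
  out <- c(dna = length(unique(valid$sequence)),
           exon = length(unique(kept$cds)),
           protein = length(unique(prot)))
  attr(out, "excluded") <- spl$id[spl$excluded]
  out
}
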