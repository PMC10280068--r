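#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (T/C) exchanges are
#' transitions; purine-pyrimidine exchanges (A/T, A/C, G/T, G/C) are
#' transversions. Symmetric in its arguments.
#'
#' @param a,b distinct bases in `{A, C, G, T}` (vectorised).
#' @return character vector, `"transition"` or `"transversion"`.
#' @examples
#' classifySubstitution("A", "G")  # transition
#' classifySubstitution("A", "T")  # transversion
#' @export
classifySubstitution <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("arguments must be bases A, C, G or T")
  if (any(a == b)) stop("a and b must differ")
  purine <- function(x) x %in% c("A", "G")
  ifelse(purine(a) == purine(b), "transition", "transversion")
}

#' Call SNP sites from an aligned haplotype set
#'
#' Every alignment column with two or more distinct symbols among the valid
#' (non-error-flagged) rows yields a site. Substitution columns are classed
#' `transition`/`transversion` (two bases) or `multiallelic` (more). Maximal
#' runs of consecutive gap-bearing columns affecting the same subset of rows
#' collapse into a single `indel` site, so an extended deletion is recorded
#' as one single-nucleotide deletion event; runs whose row subset changes
#' split at the change point. Total SNPs = transitions + transversions +
#' multiallelic + indel sites.
#'
#' @param set an aligned [HaplotypeSet-class].
#' @param validOnly use only valid entries (default `TRUE`).
#' @return `data.frame` with columns `column` (first alignment column of the
#'   site, 1-based), `locusPos` (anchor/reference coordinate; for insertion
#'   columns the left flanking reference base), `insertion` (logical),
#'   `class`, and `alleles` (per-haplotype symbols in entry order, comma
#'   separated). Empty (with a warning) when fewer than two valid rows.
#' @export
callSnpSites <- function(set, validOnly = TRUE) {
  stopifnot(is(set, "HaplotypeSet"))
  if (length(set@alignment) == 0)
    stop("alignment must be computed first (alignHaplotypes)")
  rows <- if (validOnly) which(set@entries$valid) else seq_len(nrow(set@entries))
  empty <- data.frame(column = integer(0), locusPos = integer(0),
                      insertion = logical(0), class = character(0),
                      alleles = character(0), stringsAsFactors = FALSE)
  if (length(rows) < 2) {
    warning("fewer than 2 valid haplotypes; no SNP sites can be called")
    return(empty)
  }
  m <- gappedToMatrix(set@alignment)[rows, , drop = FALSE]
  nc <- ncol(m)
  colPos <- set@columnLocusPos
  # reference coordinate of the nearest anchored column at or left of c
  leftAnchor <- cummax(ifelse(is.na(colPos), 0L, colPos))
  leftAnchor[leftAnchor == 0L] <- 1L  # insertions before base 1 count with it

  sites <- list()
  # substitution sites: distinct non-gap symbols
  for (cc in seq_len(nc)) {
    sym <- m[, cc]
    bases <- unique(sym[sym != "-"])
    if (length(bases) >= 2) {
      cls <- if (length(bases) == 2) classifySubstitution(bases[1], bases[2])
             else "multiallelic"
      sites[[length(sites) + 1L]] <- data.frame(
        column = cc, locusPos = leftAnchor[cc], insertion = is.na(colPos[cc]),
        class = cls, alleles = paste(sym, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  # indel sites: collapse runs of gap columns with identical row subsets
  gapSet <- apply(m == "-", 2, function(g) paste(which(g), collapse = ","))
  runStart <- which(gapSet != "" &
                    (seq_len(nc) == 1L | gapSet != c("", gapSet[-nc])))
  for (cc in runStart) {
    sites[[length(sites) + 1L]] <- data.frame(
      column = cc, locusPos = leftAnchor[cc], insertion = is.na(colPos[cc]),
      class = "indel", alleles = paste(m[, cc], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(sites)) return(empty)
  out <- do.call(rbind, sites)
  out <- out[order(out$column, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNP density per kilobase
#'
#' `sites / span * 1000`, with the span taken as the ungapped reference
#' length of the analysed fragment.
#'
#' @param sites a site `data.frame` from [callSnpSites()] or an integer count.
#' @param spanBases ungapped reference span (> 0).
#' @return SNPs per kilobase.
#' @examples
#' snpDensity(10, 500)  # 20
#' @export
snpDensity <- function(sites, spanBases) {
  if (spanBases <= 0) stop("spanBases must be positive")
  n <- if (is.data.frame(sites)) nrow(sites) else as.numeric(sites)
  n / spanBases * 1000
}

#' Partition SNP sites by gene region
#'
#' Assigns each site to `exon` or `intron` through its reference coordinate
#' (insertion sites through the flanking reference base to the left) and
#' reports counts and per-kilobase densities per region. The assignment is
#' exhaustive and disjoint: exon + intron counts equal the total.
#'
#' @param sites site `data.frame` from [callSnpSites()].
#' @param model a [GeneModel-class] in the same coordinates as the alignment
#'   anchor.
#' @return list with `sites` (the input plus a `region` column), `counts`
#'   (named integer vector) and `density` (SNPs/kb per region).
#' @export
partitionByRegion <- function(sites, model) {
  stopifnot(is(model, "GeneModel"))
  if (nrow(sites) && any(sites$locusPos < 1 | sites$locusPos > model@locusLength))
    stop("site position outside the gene model span")
  region <- if (nrow(sites)) regionOf(model, sites$locusPos) else character(0)
  sites$region <- region
  f <- model@features
  spans <- c(exon = sum(f$end[f$kind == "exon"] - f$start[f$kind == "exon"] + 1L),
             intron = sum(f$end[f$kind == "intron"] - f$start[f$kind == "intron"] + 1L))
  counts <- c(exon = sum(region == "exon"), intron = sum(region == "intron"))
  dens <- c(exon = if (spans["exon"] > 0) snpDensity(counts[["exon"]], spans[["exon"]]) else NA_real_,
            intron = if (spans["intron"] > 0) snpDensity(counts[["intron"]], spans[["intron"]]) else NA_real_)
  list(sites = sites, counts = counts, density = dens)
}

SUBSTITUTION_TYPES <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
TRANSITION_TYPES <- c("A/G", "C/T")

#' Transition/transversion spectrum and ratio
#'
#' Tallies the six unordered substitution types over all substitution sites
#' (indels excluded); a multiallelic site contributes each observed unordered
#' allele pair once. Proportions are over all pairs and sum to 1; the Ts/Tv
#' ratio is transitions over transversions.
#'
#' @param sites site `data.frame` from [callSnpSites()].
#' @return list with `typeCounts` and `typeProportions` (named by
#'   `"A/G", "C/T", "A/C", "A/T", "C/G", "G/T"`), `transitions`,
#'   `transversions`, `ratio` (`Inf` when there are no transversions) and
#'   `tvZero` flag.
#' @export
tstvSummary <- function(sites) {
  sub <- sites[sites$class != "indel", , drop = FALSE]
  if (nrow(sub) == 0) stop("no substitution sites")
  pairs <- character(0)
  for (al in strsplit(sub$alleles, ",", fixed = TRUE)) {
    bases <- sort(unique(al[al %in% c("A", "C", "G", "T")]))
    if (length(bases) >= 2) {
      cmb <- utils::combn(bases, 2)
      pairs <- c(pairs, paste(cmb[1, ], cmb[2, ], sep = "/"))
    }
  }
  counts <- table(factor(pairs, levels = SUBSTITUTION_TYPES))
  ts <- sum(counts[TRANSITION_TYPES])
  tv <- sum(counts) - ts
  list(typeCounts = setNames(as.integer(counts), SUBSTITUTION_TYPES),
       typeProportions = setNames(as.numeric(counts) / sum(counts),
                                  SUBSTITUTION_TYPES),
       transitions = as.integer(ts), transversions = as.integer(tv),
       ratio = if (tv == 0) Inf else ts / tv, tvZero = tv == 0)
}

#' Minimal VCF-flavoured export of SNP sites
#'
#' Writes `CHROM` (locus id), 1-based `POS`, `REF`, `ALT` and
#' `INFO=REGION;CLASS` for each site -- a flat text export for quick
#' inspection, not a fully validated VCF.
#'
#' @param sites regioned site `data.frame` (from [partitionByRegion()]).
#' @param model a [GeneModel-class] (for the locus id).
#' @param reference ungapped reference sequence (for REF alleles).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(sites, model, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", model@locusId,
                       model@locusLength),
               "##INFO=<ID=REGION,Number=1,Type=String,Description=\"exon or intron\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"site class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(sites))) {
    pos <- sites$locusPos[i]
    ref <- substr(reference, pos, pos)
    al <- strsplit(sites$alleles[i], ",", fixed = TRUE)[[1]]
    alt <- setdiff(unique(al), c(ref, ","))
    alt[alt == "-"] <- "*"
    reg <- if ("region" %in% names(sites)) sites$region[i] else "."
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tREGION=%s;CLASS=%s",
                       model@locusId, pos, ref,
                       paste(alt, collapse = ","), reg, sites$class[i]), con)
  }
  invisible(path)
}
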