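#' Construct a gene model from exon intervals
#'
#' Builds an exon/intron [GeneModel-class] for a locus from its exon
#' intervals; every base not covered by an exon becomes intron. Intervals are
#' 1-based and closed.
#'
#' @param locusId locus identifier.
#' @param locusLength locus length in bases.
#' @param exons `data.frame` (or 2-column matrix) with columns `start`, `end`;
#'   non-overlapping. May be empty for an intron-only (non-coding) model.
#' @param strand `"+"` (default) or `"-"`.
#' @param frame offset (0--2) of the first coding base in the spliced exon
#'   sequence; default 0.
#' @return a [GeneModel-class].
#' @examples
#' gm <- geneModel("locus1", 300, data.frame(start = c(1, 181), end = c(90, 300)))
#' geneFeatures(gm)
#' @export
geneModel <- function(locusId, locusLength, exons, strand = "+", frame = 0L) {
  locusLength <- as.integer(locusLength)
  exons <- as.data.frame(exons)
  if (nrow(exons)) {
    exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
    if (any(exons$start[-1] <= exons$end[-nrow(exons)]))
      stop("exon intervals overlap")
    if (exons$start[1] < 1L || exons$end[nrow(exons)] > locusLength)
      stop("exon intervals outside [1, locusLength]")
  }
  feats <- list()
  cursor <- 1L
  for (i in seq_len(nrow(exons))) {
    if (exons$start[i] > cursor)
      feats[[length(feats) + 1L]] <-
        data.frame(kind = "intron", start = cursor, end = exons$start[i] - 1L)
    feats[[length(feats) + 1L]] <-
      data.frame(kind = "exon", start = exons$start[i], end = exons$end[i])
    cursor <- exons$end[i] + 1L
  }
  if (cursor <= locusLength)
    feats[[length(feats) + 1L]] <-
      data.frame(kind = "intron", start = cursor, end = locusLength)
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(0), start = integer(0), end = integer(0))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  new("GeneModel", locusId = as.character(locusId), strand = strand,
      features = features, frame = as.integer(frame),
      locusLength = locusLength)
}

#' Region (exon/intron) of locus positions
#'
#' @param model a [GeneModel-class].
#' @param pos integer vector of 1-based locus coordinates.
#' @return character vector, `"exon"` or `"intron"`, one per position.
#' @export
regionOf <- function(model, pos) {
  stopifnot(is(model, "GeneModel"))
  if (any(pos < 1L | pos > model@locusLength, na.rm = TRUE))
    stop("position outside the locus span")
  f <- model@features
  idx <- findInterval(pos, f$start)
  out <- f$kind[idx]
  out[is.na(pos)] <- NA_character_
  out
}

#' Read a gene model from GFF3 or an interval TSV
#'
#' GFF3 input (requires the rtracklayer package) takes `exon` features of one
#' sequence region; a TSV needs columns `kind`, `start`, `end` (1-based,
#' closed) or just exon rows from which introns are inferred.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or tab-separated interval file.
#' @param locusLength locus length; for GFF3 defaults to the maximum feature
#'   end.
#' @param strand,frame overrides; defaults taken from the file where present,
#'   else `"+"` and 0.
#' @return a [GeneModel-class].
#' @export
readGeneModel <- function(path, locusLength = NULL, strand = NULL, frame = NULL) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package; ",
           "use the TSV format otherwise")
    gr <- rtracklayer::import(path)
    ex <- gr[tolower(gr$type) == "exon"]
    if (length(ex) == 0) stop("no exon features in ", path)
    if (is.null(strand)) {
      s <- unique(as.character(BiocGenerics::strand(ex)))
      strand <- if (length(s) == 1 && s %in% c("+", "-")) s else "+"
    }
    if (is.null(locusLength)) locusLength <- max(BiocGenerics::end(gr))
    exons <- data.frame(start = BiocGenerics::start(ex), end = BiocGenerics::end(ex))
    id <- as.character(GenomeInfoDb::seqnames(ex))[1]
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("start", "end") %in% names(tab)))
      stop("interval TSV needs 'start' and 'end' columns")
    exons <- if ("kind" %in% names(tab))
      tab[tab$kind == "exon", c("start", "end"), drop = FALSE]
    else tab[, c("start", "end"), drop = FALSE]
    if (is.null(locusLength)) locusLength <- max(tab$end)
    if (is.null(strand))
      strand <- if ("strand" %in% names(tab)) tab$strand[1] else "+"
    id <- if ("locus_id" %in% names(tab)) tab$locus_id[1] else
      sub("\\.[^.]*$", "", basename(path))
  }
  geneModel(id, locusLength, exons, strand = strand,
            frame = if (is.null(frame)) 0L else frame)
}
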