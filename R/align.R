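#' Global pairwise alignment with affine gaps
#'
#' Needleman--Wunsch/Gotoh global alignment at fixed scores (match +1,
#' mismatch -1, gap open -4, gap extend -1; a length-k gap costs
#' `gapOpen + (k-1) * gapExtend`). Tie-breaking is deterministic: the
#' traceback prefers substitutions over gaps and places gaps leftmost.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gapOpen,gapExtend alignment scores.
#' @return list with gapped strings `a` and `b` and the alignment `score`.
#' @examples
#' nwAlign("ACGTT", "ACTT")
#' @export
nwAlign <- function(a, b, match = 1, mismatch = -1, gapOpen = -4,
                    gapExtend = -1) {
  .nwAlign(as.character(a), as.character(b), match, mismatch, gapOpen,
           gapExtend)
}

# Reference-anchored star alignment. Each sequence is aligned pairwise to the
# reference; pairwise gaps are then projected into one shared coordinate
# system: an insertion against the reference at offset o (by any sequence)
# opens a shared column block of the maximal insertion length seen at o.
# Returns gapped rows, the gapped reference row and per-column reference
# coordinates (NA at insertion columns).
starAlign <- function(sequences, reference, ...) {
  L <- nchar(reference)
  n <- length(sequences)
  perRef <- vector("list", n)   # entry char over each reference base
  insAt <- vector("list", n)    # offset (0..L, after that many ref bases) -> string
  for (k in seq_len(n)) {
    if (sequences[k] == reference) {
      perRef[[k]] <- strsplit(reference, "")[[1]]
      insAt[[k]] <- list()
      next
    }
    al <- nwAlign(reference, sequences[k], ...)
    ra <- strsplit(al$a, "")[[1]]
    rb <- strsplit(al$b, "")[[1]]
    pr <- character(L)
    ins <- list()
    refPos <- 0L
    for (i in seq_along(ra)) {
      if (ra[i] == "-") {
        key <- as.character(refPos)
        ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]], rb[i])
      } else {
        refPos <- refPos + 1L
        pr[refPos] <- rb[i]
      }
    }
    perRef[[k]] <- pr
    insAt[[k]] <- ins
  }
  insLen <- integer(L + 1L)  # block length at offset 0..L
  for (k in seq_len(n)) {
    for (key in names(insAt[[k]])) {
      o <- as.integer(key) + 1L
      insLen[o] <- max(insLen[o], nchar(insAt[[k]][[key]]))
    }
  }
  refChars <- strsplit(reference, "")[[1]]
  buildRow <- function(pr, ins) {
    parts <- character(0)
    for (o in 0:L) {
      bl <- insLen[o + 1L]
      if (bl > 0L) {
        s <- ins[[as.character(o)]]
        if (is.null(s)) s <- ""
        parts <- c(parts, paste0(s, strrep("-", bl - nchar(s))))
      }
      if (o < L) parts <- c(parts, pr[o + 1L])
    }
    paste(parts, collapse = "")
  }
  rows <- vapply(seq_len(n), function(k) buildRow(perRef[[k]], insAt[[k]]),
                 character(1))
  refRow <- buildRow(refChars, list())
  colPos <- integer(0)
  for (o in 0:L) {
    colPos <- c(colPos, rep(NA_integer_, insLen[o + 1L]))
    if (o < L) colPos <- c(colPos, o + 1L)
  }
  list(rows = rows, referenceRow = refRow, columnLocusPos = colPos)
}

#' Align the haplotypes of a set to a common coordinate system
#'
#' Reference-anchored star alignment: every entry is globally aligned to the
#' anchor (by default the rank-1 entry, or an explicit locus reference) with
#' [nwAlign()] at the fixed scores, and pairwise gaps are merged into shared
#' columns -- an insertion against the anchor at a given offset opens one
#' shared column block of the maximal length observed there. Rows degap to
#' the original sequences; the anchor row carries gaps only where some entry
#' has an insertion.
#'
#' @param x a [HaplotypeSet-class] (alignment slots are filled in) or a
#'   character vector of sequences (a list is returned).
#' @param reference optional anchor sequence; defaults to the rank-1 entry
#'   (or the first element of `x`).
#' @param ... scores passed on to [nwAlign()].
#' @return the updated `HaplotypeSet`, or for character input a list with
#'   `rows`, `referenceRow` and `columnLocusPos`.
#' @export
alignHaplotypes <- function(x, reference = NULL, ...) {
  if (is(x, "HaplotypeSet")) {
    if (nrow(x@entries) == 0) return(x)
    if (is.null(reference)) reference <- x@entries$sequence[1]
    st <- starAlign(x@entries$sequence, reference, ...)
    x@alignment <- st$rows
    x@referenceRow <- st$referenceRow
    x@columnLocusPos <- st$columnLocusPos
    validObject(x)
    x
  } else {
    seqs <- as.character(x)
    stopifnot(length(seqs) >= 1)
    if (is.null(reference)) reference <- seqs[1]
    starAlign(seqs, reference, ...)
  }
}
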