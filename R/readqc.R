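#' Read and write amplicon FASTQ (Sanger Phred+33)
#'
#' Thin wrappers around Biostrings FASTQ I/O keeping qualities attached.
#'
#' @param path FASTQ file.
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return `readFastq` returns a `QualityScaledDNAStringSet`; `writeFastq`
#'   returns `path` invisibly.
#' @export
readFastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      # the description line is kept as names; dropping mcols is expected
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Quality-trim reads from the 3' end
#'
#' Bases are removed from the 3' end inward while their quality is below
#' `qMin`; trimming stops at the first base with quality >= `qMin`, so
#' internal low-quality bases are retained. With `bothEnds = TRUE` the same
#' anchored scan is also applied from the 5' end. A read may trim to length
#' zero; empty reads are kept here and dropped at primer matching.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param qMin minimum Phred quality (default 20).
#' @param bothEnds also trim the 5' end (default `FALSE`).
#' @return the trimmed `QualityScaledDNAStringSet`.
#' @export
qualityTrim <- function(reads, qMin = 20L, bothEnds = FALSE) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  if (length(reads) == 0) return(reads)
  quals <- as(Biostrings::quality(reads), "IntegerList")
  ends <- vapply(quals, function(q) {
    ok <- which(q >= qMin)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  starts <- if (bothEnds) {
    vapply(quals, function(q) {
      ok <- which(q >= qMin)
      if (length(ok)) min(ok) else 1L
    }, integer(1))
  } else rep(1L, length(reads))
  starts <- pmin(starts, pmax(ends, 1L))
  withCallingHandlers(
    Biostrings::subseq(reads, start = starts, end = ends),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Extract inserts by exact primer matching
#'
#' A read is accepted iff it begins exactly with the forward primer and ends
#' exactly with the reverse complement of the reverse primer; otherwise its
#' reverse complement is tested (orientation rescue). Matching is literal, so
#' any `N` in a primer region rejects the read. Accepted reads are returned
#' as their insert, primers stripped, in forward orientation; inserts must be
#' at least one base long.
#'
#' @param reads a `QualityScaledDNAStringSet`, `DNAStringSet` or character
#'   vector of read sequences.
#' @param fwd,rev the primer pair (non-empty DNA strings).
#' @return character vector of accepted inserts, in input order; attribute
#'   `"accepted"` is the per-read logical acceptance mask.
#' @export
matchPrimers <- function(reads, fwd, rev) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 1 || nchar(rev) < 1) stop("primers must be non-empty")
  seqs <- if (is.character(reads)) toupper(reads) else as.character(reads)
  revTail <- revComp(rev)
  nf <- nchar(fwd); nr <- nchar(revTail)

  hit <- function(x) {
    w <- nchar(x)
    ok <- w >= nf + nr + 1L &
      substr(x, 1L, nf) == fwd &
      substr(x, w - nr + 1L, w) == revTail
    ok
  }
  okF <- hit(seqs)
  rcSeqs <- revComp(seqs)
  okR <- !okF & hit(rcSeqs)
  oriented <- ifelse(okR, rcSeqs, seqs)
  accepted <- okF | okR
  w <- nchar(oriented)
  inserts <- substr(oriented, nf + 1L, w - nr)[accepted]
  attr(inserts, "accepted") <- accepted
  inserts
}

#' Dereplicate inserts into counted unique sequences
#'
#' Exact string grouping: one row per distinct insert with its read count,
#' abundance rank (ties broken lexicographically by sequence) and proportion
#' of the total, rounded half-up to four decimals.
#'
#' @param inserts character vector of insert sequences (at least one).
#' @return `data.frame` with columns `rank`, `count`, `total`, `proportion`,
#'   `chimera` (all `FALSE`; see [removeChimeras()]), `sequence`, ordered by
#'   rank.
#' @examples
#' dereplicate(c("AC", "AC", "AG"))
#' @export
dereplicate <- function(inserts) {
  if (length(inserts) == 0) stop("no inserts to dereplicate")
  tab <- table(inserts)
  seqs <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, seqs, method = "radix")
  counts <- counts[ord]; seqs <- seqs[ord]
  total <- sum(counts)
  data.frame(rank = seq_along(counts), count = counts, total = total,
             proportion = haplotypeProportion(counts, total),
             chimera = FALSE, sequence = seqs, stringsAsFactors = FALSE)
}

#' Flag and remove de novo chimeras
#'
#' A unique sequence is flagged chimeric iff two distinct, equal-length
#' parents exist, each at least `parentFactor` times more abundant, and a
#' breakpoint such that the candidate equals one parent over the prefix and
#' the other over the suffix (ungapped end-to-end comparison; sequences of a
#' different length than a candidate are never its parents). The most
#' abundant sequence is never flagged. After flagging, ranks and proportions
#' are recomputed over the non-chimeric reads so downstream thresholds see
#' chimera-free proportions.
#'
#' @param uniques `data.frame` from [dereplicate()] (sorted by rank).
#' @param parentFactor minimum parent/candidate abundance ratio (default 2).
#' @param maxParents cap on the number of most-abundant eligible parents
#'   examined per candidate (default 32).
#' @param drop if `TRUE` (default) flagged rows are removed from the result;
#'   otherwise they are kept with `chimera = TRUE` and `NA` rank/proportion.
#' @return `data.frame` like `uniques`, re-ranked, with recomputed
#'   proportions over non-chimeric reads; attribute `"removed"` holds the
#'   flagged rows.
#' @export
removeChimeras <- function(uniques, parentFactor = 2, maxParents = 32L,
                           drop = TRUE) {
  stopifnot(is.data.frame(uniques), !is.unsorted(-uniques$count))
  flag <- .chimeraScan(uniques$sequence, uniques$count,
                       parentFactor = parentFactor,
                       maxParents = as.integer(maxParents))
  removed <- uniques[flag, , drop = FALSE]
  removed$chimera <- rep(TRUE, nrow(removed))
  keep <- uniques[!flag, , drop = FALSE]
  total <- sum(keep$count)
  keep$rank <- seq_len(nrow(keep))
  keep$total <- total
  keep$proportion <- haplotypeProportion(keep$count, total)
  out <- if (drop) keep else {
    removed$rank <- rep(NA_integer_, nrow(removed))
    removed$proportion <- rep(NA_real_, nrow(removed))
    rbind(keep, removed)
  }
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
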