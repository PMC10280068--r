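newHaplotypeSet <- function(mode, entries, total) {
  new("HaplotypeSet", mode = mode, entries = entries, alignment = character(0),
      referenceRow = character(0), columnLocusPos = integer(0),
      total = as.integer(total))
}

emptyEntries <- function() {
  data.frame(id = character(0), sequence = character(0), count = integer(0),
             proportion = numeric(0), valid = logical(0),
             errorFlag = logical(0), stringsAsFactors = FALSE)
}

#' Call haplotypes from bulk-tissue amplicon data
#'
#' Retains unique sequences whose proportion is strictly greater than
#' `minProp` (default 1%; a proportion of exactly 0.0100 is excluded, while
#' 0.0182 passes as "over 1%"). Entries are numbered H1, H2, ... by abundance
#' rank and all marked valid.
#'
#' @param uniques ranked, chimera-filtered `data.frame` from
#'   [dereplicate()] / [removeChimeras()].
#' @param minProp proportion threshold (strict, on the rounded proportion).
#' @return a [HaplotypeSet-class] in `"tissue"` mode (unaligned; run
#'   [alignHaplotypes()] next).
#' @export
callTissueHaplotypes <- function(uniques, minProp = 0.01) {
  keep <- uniques[uniques$proportion > minProp, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("no unique sequence exceeds the ", minProp, " proportion threshold")
    return(newHaplotypeSet("tissue", emptyEntries(),
                           if (nrow(uniques)) uniques$total[1] else 0L))
  }
  entries <- data.frame(id = paste0("H", seq_len(nrow(keep))),
                        sequence = keep$sequence, count = keep$count,
                        proportion = keep$proportion, valid = TRUE,
                        errorFlag = FALSE, stringsAsFactors = FALSE)
  newHaplotypeSet("tissue", entries, keep$total[1])
}

#' Call haplotypes from single-cell amplicon data
#'
#' Keeps the top `topN` unique sequences by count for alignment and
#' reporting. An entry is valid iff its proportion is strictly greater than
#' `minProp` *and* it is not flagged as a singleton-site error by
#' [flagSingletonSiteErrors()] (a variant whose distinguishing alleles occur
#' in no other sequence is treated as a sequencing artifact).
#'
#' @inheritParams callTissueHaplotypes
#' @param topN number of top sequences to retain (default 10).
#' @return an aligned [HaplotypeSet-class] in `"single_cell"` mode.
#' @export
callSingleCellHaplotypes <- function(uniques, topN = 10L, minProp = 0.01) {
  if (nrow(uniques) < topN)
    message("only ", nrow(uniques), " unique sequences available (top ",
            topN, " requested); keeping all")
  keep <- head(uniques, topN)
  entries <- data.frame(id = paste0("H", seq_len(nrow(keep))),
                        sequence = keep$sequence, count = keep$count,
                        proportion = keep$proportion,
                        valid = keep$proportion > minProp,
                        errorFlag = FALSE, stringsAsFactors = FALSE)
  set <- newHaplotypeSet("single_cell", entries, keep$total[1])
  set <- alignHaplotypes(set)
  set <- flagSingletonSiteErrors(set)
  set@entries$valid <- set@entries$valid & !set@entries$errorFlag
  set
}

#' Flag entries supported only by private alleles
#'
#' An entry (other than rank 1) is error-flagged iff every alignment column
#' where it differs from the rank-1 entry is private to it -- i.e. no other
#' entry differs from rank 1 in that column. Such variants, distinguished
#' only by alleles seen nowhere else, are treated as sequencing errors rather
#' than haplotypes.
#'
#' @param set an aligned [HaplotypeSet-class].
#' @return the set with `errorFlag` updated (validity is not changed here;
#'   [callSingleCellHaplotypes()] combines both).
#' @export
flagSingletonSiteErrors <- function(set) {
  stopifnot(is(set, "HaplotypeSet"))
  n <- nrow(set@entries)
  if (n < 2) return(set)
  if (length(set@alignment) == 0)
    stop("alignment must be computed first (alignHaplotypes)")
  m <- gappedToMatrix(set@alignment)
  top <- m[1, ]
  diffs <- sweep(m, 2, top, FUN = "!=")  # n x columns
  nDiff <- colSums(diffs)
  flag <- logical(n)
  for (i in seq(2, n)) {
    cols <- which(diffs[i, ])
    if (length(cols) == 0) next
    flag[i] <- all(nDiff[cols] == 1L)  # every differing column is private
  }
  set@entries$errorFlag <- flag
  set
}

#' Neighbor-joining tree of a haplotype set
#'
#' Pairwise p-distances over shared non-gap alignment columns feed a standard
#' neighbor-joining agglomeration. Identical sequences sit at distance 0 and
#' appear as zero-length cherries -- these clusters are the haplotype groups.
#'
#' @param set an aligned [HaplotypeSet-class] with at least one entry.
#' @param file optional path; when given, the tree is also written in newick
#'   format.
#' @return an [ape::nj()]-style `phylo` object (a degenerate single-leaf
#'   `phylo` for one entry).
#' @export
njTree <- function(set, file = NULL) {
  stopifnot(is(set, "HaplotypeSet"))
  n <- nrow(set@entries)
  if (n == 0) stop("empty haplotype set")
  ids <- set@entries$id
  if (n == 1) {
    tr <- ape::read.tree(text = paste0("(", ids, ":0);"))
  } else {
    d <- pDistance(set@alignment)
    dimnames(d) <- list(ids, ids)
    tr <- if (n == 2)
      ape::read.tree(text = sprintf("(%s:%f,%s:%f);", ids[1], d[1, 2] / 2,
                                    ids[2], d[1, 2] / 2))
    else ape::nj(stats::as.dist(d))
  }
  if (!is.null(file)) ape::write.tree(tr, file)
  tr
}

#' Pairwise p-distance matrix of gapped sequences
#'
#' Proportion of differing positions over columns where neither sequence has
#' a gap; 0 when no columns are shared.
#'
#' @param gapped character vector of equal-length gapped sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistance <- function(gapped) {
  m <- gappedToMatrix(gapped)
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      d[i, j] <- d[j, i] <-
        if (any(shared)) mean(m[i, shared] != m[j, shared]) else 0
    }
  }
  d
}

#' Haplotype count as a function of sequence length
#'
#' For each window end (windows share the fixed start at base 1 of the
#' insert), the truncated inserts are re-dereplicated and re-thresholded, and
#' the number of distinct sequences before (`nDistinct`) and after
#' (`nHaplotypes`, proportion > `minProp`) thresholding is reported. The
#' pre-threshold count is non-decreasing in window length.
#'
#' @param inserts character vector of primer-stripped reads.
#' @param windowEnds integer vector of window end positions.
#' @param minProp tissue-mode proportion threshold.
#' @return `data.frame` with columns `length`, `nDistinct`, `nHaplotypes`.
#' @export
haplotypeLengthCurve <- function(inserts, windowEnds, minProp = 0.01) {
  shortest <- min(nchar(inserts))
  windowEnds <- as.integer(windowEnds)
  if (any(windowEnds > shortest)) {
    warning("window end beyond the shortest insert (", shortest,
            " bases); truncating")
    windowEnds[windowEnds > shortest] <- shortest
  }
  res <- lapply(windowEnds, function(e) {
    u <- dereplicate(substr(inserts, 1L, e))
    data.frame(length = e, nDistinct = nrow(u),
               nHaplotypes = sum(u$proportion > minProp))
  })
  do.call(rbind, res)
}
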