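# Independent oracles and small fixture builders used across the suite.

# Top-down memoized best global alignment score with affine gaps
# (gap of length k costs open + (k-1) * ext). Written independently of the
# package's dynamic-programming kernel.
oracleAlignScore <- function(a, b, match = 1, mismatch = -1,
                             open = -4, ext = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, (if (A[i] == B[j]) match else mismatch) +
                          rec(i + 1, j + 1, "M"))
    if (i <= length(A))
      best <- max(best, (if (prev == "X") ext else open) + rec(i + 1, j, "X"))
    if (j <= length(B))
      best <- max(best, (if (prev == "Y") ext else open) + rec(i, j + 1, "Y"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# score of a concrete gapped alignment pair under the same cost model
scoreAlignment <- function(ra, rb, match = 1, mismatch = -1,
                           open = -4, ext = -1) {
  A <- strsplit(ra, "")[[1]]
  B <- strsplit(rb, "")[[1]]
  s <- 0
  prev <- "M"
  for (i in seq_along(A)) {
    if (A[i] == "-" || B[i] == "-") {
      cur <- if (A[i] == "-") "Y" else "X"
      s <- s + (if (prev == cur) ext else open)
      prev <- cur
    } else {
      s <- s + (if (A[i] == B[i]) match else mismatch)
      prev <- "M"
    }
  }
  s
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reads with explicit per-base Phred qualities
qreads <- function(seqs, quals) {
  q <- vapply(quals, function(v) rawToChar(as.raw(v + 33L)), character(1))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(q))
}

# a dereplicated-uniques table from explicit sequences and counts
makeUniques <- function(seqs, counts) {
  ord <- order(-counts, seqs, method = "radix")
  seqs <- seqs[ord]; counts <- counts[ord]
  total <- sum(counts)
  data.frame(rank = seq_along(seqs), count = counts, total = total,
             proportion = haplotypeProportion(counts, total),
             chimera = FALSE, sequence = seqs, stringsAsFactors = FALSE)
}

# a HaplotypeSet straight from sequences (equal weights, all valid)
makeHapSet <- function(seqs, counts = NULL, mode = "tissue",
                       reference = NULL) {
  if (is.null(counts)) counts <- rev(seq_along(seqs)) * 10L
  u <- makeUniques(seqs, counts)
  set <- callTissueHaplotypes(u, minProp = 0)
  set@mode <- mode
  alignHaplotypes(set, reference = reference)
}

# shared locus + gene model for simulation-based tests: 300 bp with a
# central 90 bp intron (exons 1-90 and 181-300); the spliced exons are built
# from non-stop codons so the fragment behaves like a real coding region
refLocus <- local({
  set.seed(990)
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  cds <- paste(sample(setdiff(codons, c("TAA", "TAG", "TGA")), 70,
                      replace = TRUE), collapse = "")
  paste0(substr(cds, 1, 90), randomSeq(90), substr(cds, 91, 210))
})
refModel <- geneModel("locus1", 300,
                      data.frame(start = c(1, 181), end = c(90, 300)))

# one simulator -> QC -> tissue-haplotype recovery run; returns diagnostics
recoveryRun <- function(seed, perBaseError = 0.002, readDepth = 20000L) {
  cfg <- simulationConfig(seed = seed, perBaseError = perBaseError,
                          readDepth = readDepth)
  truth <- spawnHaplotypes(refLocus, refModel, cfg)
  reads <- simulateReads(truth, cfg)
  trimmed <- qualityTrim(reads)
  inserts <- matchPrimers(trimmed, cfg@primerFwd, cfg@primerRev)
  uniques <- removeChimeras(dereplicate(inserts))
  set <- callTissueHaplotypes(uniques)
  valid <- validHaplotypes(set)
  truthSeqs <- truthHaplotypes(truth)$sequence
  hit <- match(truthSeqs, valid$sequence)
  allRecovered <- !anyNA(hit)
  noFalse <- all(valid$sequence %in% truthSeqs)
  freqOk <- FALSE
  if (allRecovered && noFalse) {
    # per-base errors deflate every exact-sequence count by the same
    # factor, so compare frequencies renormalised over the valid calls
    n <- sum(valid$count)
    phat <- valid$count[hit] / n
    p <- truthHaplotypes(truth)$frequency
    freqOk <- all(abs(phat - p) < 3 * sqrt(p * (1 - p) / n))
  }
  list(allRecovered = allRecovered, noFalse = noFalse, freqOk = freqOk,
       ok = allRecovered && noFalse && freqOk)
}
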