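#' Simulation configuration constructor
#'
#' Defaults describe the mosaic structure this package is designed around: a
#' handful of haplotypes at uneven frequencies, a several-fold higher
#' substitution rate in introns than exons, a two-fold transition bias
#' (kappa = 2), rare intron-only single-base deletions, deep MiSeq-style
#' coverage of one merged ~300 bp amplicon, and a 0.2% per-base error.
#'
#' @param nHaplotypes number of true haplotypes K (>= 1).
#' @param haplotypeFreqs frequencies, length K, summing to 1.
#' @param snpRateExon,snpRateIntron expected substitutions per base.
#' @param tstvKappa transition/transversion rate ratio per mutated site.
#' @param indelRateIntron expected single-base deletions per intron base.
#' @param readDepth reads to emit.
#' @param perBaseError sequencing error probability per base.
#' @param chimeraRate probability a read is a two-parent chimera.
#' @param primerFwd,primerRev primer pair flanking the insert.
#' @param seed RNG seed (< 2^31).
#' @return a [SimulationConfig-class].
#' @examples
#' simulationConfig(nHaplotypes = 2, haplotypeFreqs = c(0.8, 0.2), seed = 7)
#' @export
simulationConfig <- function(nHaplotypes = 5L,
                             haplotypeFreqs = c(0.40, 0.30, 0.15, 0.10, 0.05),
                             snpRateExon = 0.005, snpRateIntron = 0.02,
                             tstvKappa = 2, indelRateIntron = 0.002,
                             readDepth = 20000L, perBaseError = 0.002,
                             chimeraRate = 0,
                             primerFwd = "ACAGTGGTCGTTACGCTAGT",
                             primerRev = "TGCATCCTAGGTTGAGCACT",
                             seed = 1L) {
  new("SimulationConfig", nHaplotypes = as.integer(nHaplotypes),
      haplotypeFreqs = haplotypeFreqs, snpRateExon = snpRateExon,
      snpRateIntron = snpRateIntron, tstvKappa = tstvKappa,
      indelRateIntron = indelRateIntron, readDepth = as.integer(readDepth),
      perBaseError = perBaseError, chimeraRate = chimeraRate,
      primerFwd = toupper(primerFwd), primerRev = toupper(primerRev),
      seed = as.integer(seed))
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# draw an alternate base: transition with prob kappa/(kappa+1), else one of
# the two transversion partners uniformly
drawAlt <- function(ref, kappa) {
  ts <- stats::runif(length(ref)) < kappa / (kappa + 1)
  alt <- TRANSITION_PARTNER[ref]
  tv <- !ts
  if (any(tv)) {
    pur <- ref[tv] %in% c("A", "G")
    pick <- stats::runif(sum(tv)) < 0.5
    # transversion partners: purines -> C/T, pyrimidines -> A/G
    alt[tv] <- ifelse(pur, ifelse(pick, "C", "T"), ifelse(pick, "A", "G"))
  }
  alt
}

#' Spawn a truth table of mosaic haplotypes
#'
#' Haplotype 1 is the unmutated reference. Each further haplotype carries a
#' Poisson number of substitutions per region (rate x region length), each a
#' transition with probability `kappa/(kappa + 1)`, plus Poisson single-base
#' deletions restricted to introns. Haplotypes are redrawn until distinct, so
#' K haplotypes are K different sequences. All events are recorded with their
#' reference position, class and region.
#'
#' @param reference locus DNA string (the amplicon insert).
#' @param model a [GeneModel-class] for the reference.
#' @param cfg a [SimulationConfig-class].
#' @return a [TruthTable-class].
#' @export
spawnHaplotypes <- function(reference, model, cfg) {
  stopifnot(is(model, "GeneModel"), is(cfg, "SimulationConfig"))
  validObject(cfg)
  reference <- toupper(as.character(reference))
  L <- nchar(reference)
  if (L != model@locusLength)
    stop("reference length does not match the gene model span")
  set.seed(cfg@seed)
  refChars <- strsplit(reference, "")[[1]]
  region <- regionOf(model, seq_len(L))
  exonPos <- which(region == "exon")
  intronPos <- which(region == "intron")
  K <- cfg@nHaplotypes

  haps <- data.frame(id = paste0("hap", seq_len(K)),
                     frequency = cfg@haplotypeFreqs,
                     sequence = rep(reference, K),
                     stringsAsFactors = FALSE)
  events <- list()
  seen <- reference
  for (h in seq_len(K)[-1]) {
    for (attempt in seq_len(1000L)) {
      nex <- rpois(1, cfg@snpRateExon * length(exonPos))
      nin <- rpois(1, cfg@snpRateIntron * length(intronPos))
      ndel <- rpois(1, cfg@indelRateIntron * length(intronPos))
      sub <- c(if (length(exonPos)) sample(exonPos, min(nex, length(exonPos))),
               if (length(intronPos)) sample(intronPos, min(nin, length(intronPos))))
      delPool <- setdiff(intronPos, sub)
      del <- if (length(delPool)) sample(delPool, min(ndel, length(delPool))) else integer(0)
      if (length(sub) + length(del) == 0) next  # must differ from the reference
      chars <- refChars
      alt <- character(0)
      if (length(sub)) {
        alt <- drawAlt(refChars[sub], cfg@tstvKappa)
        chars[sub] <- alt
      }
      if (length(del)) chars <- chars[-del]
      seqh <- paste(chars, collapse = "")
      if (seqh %in% seen) next
      seen <- c(seen, seqh)
      haps$sequence[h] <- seqh
      ev <- data.frame(
        id = haps$id[h],
        pos = as.integer(c(sub, del)),
        ref = refChars[c(sub, del)],
        alt = c(alt, rep("-", length(del))),
        class = c(if (length(sub))
                    ifelse(alt == TRANSITION_PARTNER[refChars[sub]],
                           "transition", "transversion"),
                  rep("deletion", length(del))),
        region = region[c(sub, del)],
        stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <- ev[order(ev$pos), ]
      break
    }
    if (haps$sequence[h] == reference && K > 1)
      stop("could not draw a distinct haplotype; increase mutation rates")
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(id = character(0), pos = integer(0), ref = character(0),
               alt = character(0), class = character(0), region = character(0),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  new("TruthTable", reference = reference, haplotypes = haps, events = events)
}

#' Simulate amplicon reads from a truth table
#'
#' Each read is `primerFwd + insert + reverseComplement(primerRev)`. Inserts
#' are drawn i.i.d. from the haplotype frequencies (multinomial counts at the
#' stated seed); with probability `chimeraRate` the insert is instead a
#' two-parent splice at a uniform breakpoint. I.i.d. per-base errors (uniform
#' over the three alternative bases) are applied across the whole read,
#' primers included. Qualities are flat at the Phred score of `perBaseError`.
#'
#' @param truth a [TruthTable-class].
#' @param cfg a [SimulationConfig-class].
#' @return a [Biostrings::QualityScaledDNAStringSet] of `readDepth` reads;
#'   attribute `"assignment"` holds the source haplotype id per read
#'   (`"chimera"` for chimeric inserts).
#' @seealso [writeFastq()] to serialise byte-identically for a given seed.
#' @export
simulateReads <- function(truth, cfg) {
  stopifnot(is(truth, "TruthTable"), is(cfg, "SimulationConfig"))
  validObject(cfg)
  N <- cfg@readDepth
  haps <- truth@haplotypes
  K <- nrow(haps)
  set.seed(cfg@seed)

  pick <- sample.int(K, N, replace = TRUE, prob = haps$frequency)
  inserts <- haps$sequence[pick]
  src <- haps$id[pick]

  if (cfg@chimeraRate > 0 && K >= 2) {
    isChim <- stats::runif(N) < cfg@chimeraRate
    nC <- sum(isChim)
    if (nC > 0) {
      pa <- sample.int(K, nC, replace = TRUE, prob = haps$frequency)
      shift <- sample.int(K - 1L, nC, replace = TRUE)
      pb <- ((pa - 1L + shift) %% K) + 1L  # uniform among the other parents
      la <- nchar(haps$sequence[pa]); lb <- nchar(haps$sequence[pb])
      lmin <- pmin(la, lb)
      b <- vapply(lmin, function(l) sample.int(l - 1L, 1L), integer(1))
      inserts[isChim] <- paste0(substr(haps$sequence[pa], 1L, b),
                                substr(haps$sequence[pb], b + 1L, lb))
      src[isChim] <- "chimera"
    }
  }

  reads <- paste0(cfg@primerFwd, inserts, revComp(cfg@primerRev))

  if (cfg@perBaseError > 0) {
    wid <- nchar(reads)
    nerr <- rbinom(length(reads), wid, cfg@perBaseError)
    pass <- 1L
    while (any(nerr >= pass)) {
      idx <- which(nerr >= pass)
      pos <- floor(stats::runif(length(idx)) * wid[idx]) + 1L
      cur <- substr(reads[idx], pos, pos)
      substr(reads[idx], pos, pos) <- drawError(cur)
      pass <- pass + 1L
    }
  }

  ids <- sprintf("read%06d", seq_len(N))
  qual <- vapply(nchar(reads),
                 function(w) strrep(phredChar(cfg@perBaseError), w), character(1))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads, ids)),
    Biostrings::PhredQuality(qual))
  attr(out, "assignment") <- src
  out
}

# uniform substitution among the three non-ref bases: draw the k-th (k in
# 1..3) alternative, skipping the index of the current base
drawError <- function(ref) {
  bases <- c("A", "C", "G", "T")
  refIdx <- match(ref, bases)
  k <- floor(stats::runif(length(ref)) * 3) + 1L
  bases[k + (k >= refIdx)]
}

#' Write or read a truth table TSV
#'
#' One row per haplotype: `haplotype_id`, `frequency`, `sequence`, and the
#' planted events as semicolon-joined `pos:ref>alt:class:region` tokens.
#'
#' @param truth a [TruthTable-class].
#' @param path output (input) file path.
#' @return `writeTruthTable` returns `path` invisibly; `readTruthTable`
#'   returns a [TruthTable-class] (with an empty reference slot when the
#'   reference is not stored; haplotype 1 is taken as the reference).
#' @export
writeTruthTable <- function(truth, path) {
  stopifnot(is(truth, "TruthTable"))
  ev <- truth@events
  evStr <- vapply(truth@haplotypes$id, function(h) {
    e <- ev[ev$id == h, , drop = FALSE]
    if (!nrow(e)) return("")
    paste(sprintf("%d:%s>%s:%s:%s", e$pos, e$ref, e$alt, e$class, e$region),
          collapse = ";")
  }, character(1))
  tab <- data.frame(haplotype_id = truth@haplotypes$id,
                    frequency = truth@haplotypes$frequency,
                    sequence = truth@haplotypes$sequence,
                    events = evStr)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  haps <- data.frame(id = tab$haplotype_id,
                     frequency = as.numeric(tab$frequency),
                     sequence = tab$sequence, stringsAsFactors = FALSE)
  evs <- lapply(seq_len(nrow(tab)), function(i) {
    s <- tab$events[i]
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[:>]")
    data.frame(id = tab$haplotype_id[i],
               pos = as.integer(vapply(parts, `[`, "", 1)),
               ref = vapply(parts, `[`, "", 2),
               alt = vapply(parts, `[`, "", 3),
               class = vapply(parts, `[`, "", 4),
               region = vapply(parts, `[`, "", 5),
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(id = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         class = character(0), region = character(0))
  new("TruthTable", reference = haps$sequence[1], haplotypes = haps,
      events = events)
}
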