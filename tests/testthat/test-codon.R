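test_that("translation agrees with an independently tabulated genetic code", {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  stopifnot(length(codons) == 64)
  mine <- translateCDS(codons)
  oracle <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)),
    character(1), USE.NAMES = FALSE)
  expect_identical(mine, oracle)
})

test_that("translation handles frames, partial codons, stops and ambiguity", {
  expect_equal(translateCDS("ATTTTGCAG"), "ILQ")
  expect_equal(translateCDS("AGA"), "R")
  expect_equal(translateCDS("ATA"), "I")
  expect_equal(translateCDS("ATTTTGCAGAA"), "ILQ")  # trailing bases dropped
  expect_equal(translateCDS("AATTTTGCAG", frame = 1), "ILQ")
  expect_equal(translateCDS("AT"), "")
  expect_warning(p <- translateCDS("ATTTAAATT"), "stop")
  expect_equal(p, "I*I")
  expect_warning(px <- translateCDS("ATNTTG"), "X")
  expect_equal(px, "XL")
})

test_that("codon effects are classified by translation equality", {
  syn <- codonEffect("ATT", "ATC")
  expect_equal(syn$effect, "synonymous")
  expect_equal(c(syn$refAa, syn$altAa), c("I", "I"))
  ns <- codonEffect("AGA", "ATA")
  expect_equal(ns$effect, "nonsynonymous")
  expect_equal(c(ns$refAa, ns$altAa), c("R", "I"))
  expect_equal(ns$codonOffset, 1L)
  ns2 <- codonEffect("GCT", "ACT")
  expect_equal(ns2$effect, "nonsynonymous")
  expect_equal(c(ns2$refAa, ns2$altAa), c("A", "T"))
  expect_equal(ns2$codonOffset, 0L)
  # multi-position differences are judged on whole codons
  expect_equal(codonEffect("TTA", "CTG")$effect, "synonymous")  # L/L
  expect_error(codonEffect("ATT", "ATT"), "identical")
})

test_that("effect tallies match a per-pair oracle on random codon pairs", {
  set.seed(71)
  bases <- c("A", "C", "G", "T")
  changes <- do.call(rbind, lapply(1:60, function(i) {
    ref <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    alt <- ref
    while (alt == ref) {
      p <- sample(3, 1)
      substr(alt, p, p) <- sample(bases, 1)
    }
    suppressWarnings(codonEffect(ref, alt, siteIndex = i))  # stops are fine here
  }))
  tally <- countEffects(changes)
  oracle <- sum(vapply(seq_len(nrow(changes)), function(i)
    as.character(Biostrings::translate(Biostrings::DNAString(changes$refCodon[i]),
                                       no.init.codon = TRUE)) !=
    as.character(Biostrings::translate(Biostrings::DNAString(changes$altCodon[i]),
                                       no.init.codon = TRUE)),
    logical(1)))
  expect_equal(tally[["nonsynonymous"]], oracle)
  expect_equal(sum(tally), nrow(changes))
  # a change is synonymous iff the two codons translate identically
  expect_identical(changes$effect == "synonymous",
                   changes$refAa == changes$altAa)
})

test_that("splicing lifts exons through the alignment", {
  set.seed(72)
  ref <- randomSeq(60)
  gm <- geneModel("l", 60, data.frame(start = c(1, 41), end = c(20, 60)))
  # single full-span exon: CDS equals the degapped sequence
  gmAll <- geneModel("l", 60, data.frame(start = 1, end = 60))
  setAll <- makeHapSet(ref)
  expect_equal(spliceExons(setAll, gmAll)$cds, ref)
  # intron-only SNPs leave every CDS identical
  v1 <- ref; substr(v1, 25, 25) <- if (substr(ref, 25, 25) == "A") "G" else "A"
  set1 <- makeHapSet(c(ref, v1))
  cds1 <- spliceExons(set1, gm)$cds
  expect_equal(length(unique(cds1)), 1L)
  # a planted exon SNP lands at its spliced offset
  v2 <- ref; substr(v2, 45, 45) <- if (substr(ref, 45, 45) == "C") "T" else "C"
  set2 <- makeHapSet(c(ref, v2))
  cds2 <- spliceExons(set2, gm)$cds
  diffAt <- which(strsplit(cds2[1], "")[[1]] != strsplit(cds2[2], "")[[1]])
  expect_equal(diffAt, 20L + (45L - 41L + 1L))  # exon1 (20 bp) + offset in exon2
  # minus-strand models reverse-complement the spliced CDS
  gmMinus <- geneModel("l", 60, data.frame(start = 1, end = 60), strand = "-")
  expect_equal(spliceExons(setAll, gmMinus)$cds, revComp(ref))
})

test_that("frame-disrupting indels are excluded from codon analysis", {
  set.seed(73)
  ref <- randomSeq(60)
  gm <- geneModel("l", 60, data.frame(start = c(1, 41), end = c(20, 60)))
  # one-base deletion inside an exon shifts the frame
  delExon <- paste0(substr(ref, 1, 9), substr(ref, 11, 60))
  # deletion spanning the exon1/intron boundary
  delBoundary <- paste0(substr(ref, 1, 18), substr(ref, 24, 60))
  # intron deletion is harmless
  delIntron <- paste0(substr(ref, 1, 29), substr(ref, 31, 60))
  set <- makeHapSet(c(ref, delExon, delBoundary, delIntron))
  expect_warning(spl <- spliceExons(set, gm), "excluded")
  expect_equal(spl$excluded, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(spl$cds[4], spl$cds[1])  # intron deletion leaves the CDS intact
})

test_that("haplotypes collapse monotonically from DNA to exons to protein", {
  ref <- "ATGGCTGCAACCTTTCCCGGG"  # 21 bp, single exon
  gm <- geneModel("l", 21, data.frame(start = 1, end = 21))
  gmHalf <- geneModel("l", 21, data.frame(start = 1, end = 12))
  # intron-only difference collapses at the exon level
  vIntron <- ref; substr(vIntron, 15, 15) <- "A"
  c1 <- collapseLevels(makeHapSet(c(ref, vIntron)), gmHalf)
  expect_equal(unname(c1), c(2L, 1L, 1L), ignore_attr = TRUE)
  # synonymous exon SNP collapses at the protein level (GCT -> GCC, both A)
  vSyn <- ref; substr(vSyn, 6, 6) <- "C"
  c2 <- collapseLevels(makeHapSet(c(ref, vSyn)), gm)
  expect_equal(unname(c2), c(2L, 2L, 1L), ignore_attr = TRUE)
  # nonsynonymous SNP survives to the protein (GCT -> ACT, A -> T)
  vNs <- ref; substr(vNs, 4, 4) <- "A"
  c3 <- collapseLevels(makeHapSet(c(ref, vNs)), gm)
  expect_equal(unname(c3), c(2L, 2L, 2L), ignore_attr = TRUE)
})

test_that("collapse counts are monotone on random synthetic sets", {
  set.seed(74)
  for (i in 1:100) {
    L <- 30L
    ref <- randomSeq(L)
    exonEnd <- sample(6:(L - 6), 1)
    gm <- geneModel("l", L, data.frame(start = 1, end = exonEnd))
    k <- sample(2:6, 1)
    seqs <- unique(c(ref, vapply(seq_len(k), function(j) {
      s <- ref
      for (p in sample(L, sample(1:3, 1)))
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      s
    }, "")))
    cl <- suppressWarnings(collapseLevels(makeHapSet(seqs), gm))
    expect_lte(cl[["protein"]], cl[["exon"]])
    expect_lte(cl[["exon"]], cl[["dna"]])
    expect_equal(cl[["dna"]], length(seqs))
  }
})

test_that("codon change tables recover planted effects", {
  # reference with a two-exon coding region; one synonymous and one
  # nonsynonymous exon SNP plus one intron SNP
  ex1 <- "ATGGCT"          # M A
  intr <- "GTAAGTTTTCAG"
  ex2 <- "ACCTTTCCCTAA"    # T F P *
  ref <- paste0(ex1, intr, ex2)
  gm <- geneModel("l", nchar(ref),
                  data.frame(start = c(1, 7 + nchar(intr)),
                             end = c(6, nchar(ref))))
  vSyn <- ref; substr(vSyn, 6, 6) <- "C"          # GCT -> GCC (A/A)
  vNs <- ref; substr(vNs, 19, 19) <- "G"          # ACC -> GCC (T/A)
  vIntron <- ref; substr(vIntron, 10, 10) <- "C"
  set <- makeHapSet(c(ref, vSyn, vNs, vIntron))
  changes <- codonChanges(set, gm)
  expect_equal(nrow(changes), 2L)
  expect_setequal(changes$effect, c("synonymous", "nonsynonymous"))
  tal <- countEffects(changes)
  expect_equal(unname(tal), c(1L, 1L))
  ns <- changes[changes$effect == "nonsynonymous", ]
  expect_equal(c(ns$refCodon, ns$altCodon), c("ACC", "GCC"))
  expect_equal(c(ns$refAa, ns$altAa), c("T", "A"))
})
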