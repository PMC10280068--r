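test_that("substitution classes match exhaustive purine/pyrimidine logic", {
  bases <- c("A", "C", "G", "T")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (a in bases) for (b in setdiff(bases, a)) {
    expected <- if (purine[a] == purine[b]) "transition" else "transversion"
    expect_equal(classifySubstitution(a, b), expected, info = paste(a, b))
    expect_equal(classifySubstitution(a, b), classifySubstitution(b, a))
  }
  expect_equal(classifySubstitution("A", "G"), "transition")
  expect_equal(classifySubstitution("A", "T"), "transversion")
  expect_error(classifySubstitution("A", "A"), "differ")
  expect_error(classifySubstitution("A", "-"), "bases")
})

test_that("identical haplotypes yield no SNP sites", {
  set <- makeHapSet(rep("ACGTACGTACGT", 3))
  expect_equal(nrow(callSnpSites(set)), 0L)
  one <- makeHapSet("ACGT")
  expect_warning(out <- callSnpSites(one), "fewer than 2")
  expect_equal(nrow(out), 0L)
})

test_that("variable columns become sites with the right class", {
  ref <- "AAACCCGGGTTT"
  v1 <- ref; substr(v1, 2, 2) <- "G"   # transition A/G
  v2 <- ref; substr(v2, 5, 5) <- "A"   # transversion C/A
  v3 <- ref; substr(v3, 2, 2) <- "G"   # shares the A/G site
  set <- makeHapSet(c(ref, v1, v2, v3))
  sites <- callSnpSites(set)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$class[sites$locusPos == 2], "transition")
  expect_equal(sites$class[sites$locusPos == 5], "transversion")
  # 3 rows A, 2 rows G at one column is still a single (transition) site
  m <- makeHapSet(c(ref, v1, v1, ref, ref), counts = c(50L, 40L, 30L, 20L, 10L))
  s2 <- callSnpSites(m)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$class, "transition")
  # three alleles in one column: one multiallelic site
  v4 <- ref; substr(v4, 2, 2) <- "C"
  s3 <- callSnpSites(makeHapSet(c(ref, v1, v4)))
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$class, "multiallelic")
})

test_that("an extended deletion collapses to a single indel site", {
  ref <- "ACGTACGTACGTACGTACGT"
  del5 <- paste0(substr(ref, 1, 7), substr(ref, 13, 20))  # drop 8..12
  set <- makeHapSet(c(ref, del5))
  sites <- callSnpSites(set)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$class, "indel")
  # two haplotypes sharing part of a gap region split at the subset change
  set.seed(61)
  refB <- randomSeq(40)
  delA <- paste0(substr(refB, 1, 10), substr(refB, 17, 40))   # gaps 11..16
  delB <- paste0(substr(refB, 1, 10), substr(refB, 14, 40))   # gaps 11..13
  set2 <- makeHapSet(c(refB, delA, delB))
  s2 <- callSnpSites(set2)
  expect_equal(sum(s2$class == "indel"), 2L)
})

test_that("snp density is sites per kilobase of reference span", {
  expect_equal(snpDensity(0, 500), 0)
  expect_equal(snpDensity(10, 500), 20)
  expect_error(snpDensity(3, 0), "positive")
})

test_that("region partition is exhaustive and respects interval edges", {
  gm <- geneModel("l", 100, data.frame(start = c(11, 61), end = c(40, 90)))
  sites <- data.frame(column = c(11, 10, 41, 61, 95), locusPos = c(11, 10, 41, 61, 95),
                      insertion = FALSE, class = "transition",
                      alleles = "A,G", stringsAsFactors = FALSE)
  part <- partitionByRegion(sites, gm)
  expect_equal(part$sites$region, c("exon", "intron", "intron", "exon", "intron"))
  expect_equal(sum(part$counts), nrow(sites))
  expect_equal(part$counts[["exon"]], 2L)
  expect_equal(part$density[["exon"]], 2 / 60 * 1000)
  expect_error(partitionByRegion(transform(sites, locusPos = 101), gm), "span")
})

test_that("planted substitutions are recovered exactly from clean reads", {
  cfg <- simulationConfig(indelRateIntron = 0, perBaseError = 0,
                          readDepth = 5000, seed = 51)
  truth <- spawnHaplotypes(refLocus, refModel, cfg)
  reads <- simulateReads(truth, cfg)
  inserts <- matchPrimers(reads, cfg@primerFwd, cfg@primerRev)
  set <- alignHaplotypes(callTissueHaplotypes(removeChimeras(dereplicate(inserts))),
                         reference = refLocus)
  sites <- callSnpSites(set)
  part <- partitionByRegion(sites, refModel)
  # expected sites derived independently from the truth table
  ev <- truthEvents(truth)
  expByPos <- split(ev, ev$pos)
  expect_setequal(sites$locusPos, as.integer(names(expByPos)))
  for (p in names(expByPos)) {
    e <- expByPos[[p]]
    alleles <- unique(c(e$ref[1], e$alt))
    expClass <- if (length(alleles) > 2) "multiallelic" else
      classifySubstitution(alleles[1], alleles[2])
    row <- part$sites[part$sites$locusPos == as.integer(p), ]
    expect_equal(row$class, expClass, info = paste("pos", p))
    expect_equal(row$region, e$region[1], info = paste("pos", p))
  }
  # density bookkeeping matches the planted count exactly
  expect_equal(snpDensity(sites, 300), nrow(sites) / 300 * 1000)
})

test_that("Ts/Tv spectrum sums to one and reproduces simple tallies", {
  ref <- "AAAATTTTCCCC"
  v1 <- ref; substr(v1, 1, 1) <- "G"   # A/G transition
  v2 <- ref; substr(v2, 5, 5) <- "C"   # T/C transition
  v3 <- ref; substr(v3, 2, 2) <- "T"   # A/T transversion
  set <- makeHapSet(c(ref, v1, v2, v3))
  ts <- tstvSummary(callSnpSites(set))
  expect_equal(ts$transitions, 2L)
  expect_equal(ts$transversions, 1L)
  expect_equal(ts$ratio, 2)
  expect_equal(sum(ts$typeProportions), 1)
  expect_equal(ts$typeCounts[["A/G"]], 1L)
  # all-transition input flags the infinite ratio
  setTs <- makeHapSet(c(ref, v1, v2))
  tsOnly <- tstvSummary(callSnpSites(setTs))
  expect_true(tsOnly$tvZero)
  expect_equal(tsOnly$ratio, Inf)
  expect_error(tstvSummary(data.frame(class = character(0), alleles = character(0))),
               "no substitution")
})

test_that("multiallelic sites contribute each observed pair once", {
  ref <- "AAAACCCC"
  v1 <- ref; substr(v1, 1, 1) <- "G"
  v2 <- ref; substr(v2, 1, 1) <- "T"
  set <- makeHapSet(c(ref, v1, v2))
  ts <- tstvSummary(callSnpSites(set))
  # pairs at the site: A/G (ts), A/T (tv), G/T (tv)
  expect_equal(ts$transitions, 1L)
  expect_equal(ts$transversions, 2L)
})

test_that("total SNPs = transitions + transversions + indels", {
  cfg <- simulationConfig(seed = 52, perBaseError = 0, readDepth = 3000,
                          indelRateIntron = 0.01)
  truth <- spawnHaplotypes(refLocus, refModel, cfg)
  set <- alignHaplotypes(
    callTissueHaplotypes(makeUniques(truthHaplotypes(truth)$sequence,
                                     c(500L, 400L, 300L, 200L, 100L)),
                         minProp = 0),
    reference = refLocus)
  sites <- callSnpSites(set)
  nSub <- sum(sites$class %in% c("transition", "transversion", "multiallelic"))
  nIndel <- sum(sites$class == "indel")
  expect_equal(nSub + nIndel, nrow(sites))
  expect_gt(nrow(sites), 0)
})

test_that("the VCF-flavoured export round-trips positions and alleles", {
  ref <- "AAACCCGGGTTT"
  v1 <- ref; substr(v1, 2, 2) <- "G"
  set <- makeHapSet(c(ref, v1))
  gm <- geneModel("locusX", 12, data.frame(start = 1, end = 6))
  part <- partitionByRegion(callSnpSites(set), gm)
  f <- tempfile(fileext = ".vcf")
  writeSnpVcf(part$sites, gm, ref, f)
  lines <- grep("^[^#]", readLines(f), value = TRUE)
  expect_length(lines, 1L)
  fields <- strsplit(lines, "\t")[[1]]
  expect_equal(fields[1], "locusX")
  expect_equal(fields[2], "2")
  expect_equal(fields[4], "A")
  expect_equal(fields[5], "G")
  expect_match(fields[8], "REGION=exon;CLASS=transition")
  unlink(f)
})
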