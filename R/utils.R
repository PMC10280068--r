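#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.00005 -> 0.0001), unlike base
#' [round()]'s round-half-even. Used for all reported haplotype proportions so
#' printed values match `rank_count_total_proportion` style labels.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, half-up.
#' @examples
#' roundHalfUp(0.00015, 4)  # 0.0002
#' @export
roundHalfUp <- function(x, digits = 4) {
  p <- 10^digits
  # tiny epsilon guards against decimal values that sit just under .5 in binary
  floor(x * p + 0.5 + 1e-9) / p
}

#' Haplotype proportion from read counts
#'
#' The proportion of a unique sequence among all retained reads, rounded
#' half-up to four decimals -- the encoding used in `TopR_count_total_prop`
#' sequence labels (e.g. 52745 of 66819 reads is 0.7894).
#'
#' @param count reads supporting the sequence.
#' @param total total retained reads.
#' @param digits decimal places (default 4).
#' @return numeric proportion(s).
#' @examples
#' haplotypeProportion(52745, 66819)  # 0.7894
#' haplotypeProportion(1219, 66819)   # 0.0182
#' @export
haplotypeProportion <- function(count, total, digits = 4) {
  stopifnot(total > 0, all(count >= 0), all(count <= total))
  roundHalfUp(count / total, digits)
}

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (IUPAC letters).
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred quality character for an error probability, capped to [2, 40]
phredChar <- function(errorProb) {
  q <- if (errorProb <= 0) 40L else as.integer(round(-10 * log10(errorProb)))
  q <- max(2L, min(40L, q))
  rawToChar(as.raw(q + 33L))
}

# random DNA string(s); relies on the caller's RNG state
randomDna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# alignment strings -> character matrix (rows = sequences, cols = columns)
gappedToMatrix <- function(gapped) {
  if (length(gapped) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  wid <- unique(nchar(gapped))
  stopifnot(length(wid) == 1)
  m <- matrix(unlist(strsplit(gapped, "", fixed = TRUE), use.names = FALSE),
              nrow = length(gapped), byrow = TRUE)
  rownames(m) <- names(gapped)
  m
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)
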