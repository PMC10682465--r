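# Small shared helpers: sequences, block strings, exact tests.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character DNA
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_tags <- function(n, width) {
  # distinct random fixed-width tags (barcodes, UMIs)
  tags <- character(0)
  while (length(tags) < n) {
    need <- n - length(tags)
    new <- vapply(seq_len(need * 2L), function(i) random_dna(width), "")
    tags <- unique(c(tags, new))
  }
  tags[seq_len(n)]
}

# comma-separated 0-based half-open block coordinates <-> integer vectors
blocks_to_string <- function(starts, ends) {
  list(starts = paste(starts, collapse = ","), ends = paste(ends, collapse = ","))
}

string_to_blocks <- function(starts, ends) {
  s <- as.integer(strsplit(starts, ",", fixed = TRUE)[[1]])
  e <- as.integer(strsplit(ends, ",", fixed = TRUE)[[1]])
  stopifnot(length(s) == length(e), all(e > s))
  cbind(start = s, end = e)
}

block_width <- function(starts, ends) {
  b <- string_to_blocks(starts, ends)
  sum(b[, "end"] - b[, "start"])
}

# junction chain "donor-acceptor,donor-acceptor" from a block matrix
blocks_to_chain <- function(blocks) {
  k <- nrow(blocks)
  if (k < 2L) return("")
  paste(blocks[-k, "end"], blocks[-1L, "start"], sep = "-", collapse = ",")
}

chain_junctions <- function(chain) {
  if (is.na(chain) || chain == "") {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("donor", "acceptor"))))
  }
  parts <- strsplit(strsplit(chain, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("donor", "acceptor")
  m
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] used by both the
#' alternative-polyadenylation and the fusion contingency tests.
#'
#' @param a,b,c,d non-negative integer cells, row-wise: `[[a, b], [c, d]]`.
#' @return two-sided p-value.
#' @export
fisher2x2 <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L))$p.value
}

# nearest integer, halves away from zero (coverage means are >= 0)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

seq_substr <- function(genome, chrom, start, end) {
  # genome: DNAStringSet; 0-based half-open coordinates
  as.character(Biostrings::subseq(genome[[chrom]], start = start + 1L, width = end - start))
}

a_fraction_of <- function(seq) {
  if (nchar(seq) == 0L) return(0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(chars == "A")
}
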