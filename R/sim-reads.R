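# Rendering of concatenated reads: each read carries k ~ truncated-Poisson
# cDNA segments; each segment is 5'primer + barcode(16) + UMI(12) + polyT
# tract + reverse-complemented cDNA + reverse primer, in either orientation.

#' Default library primers
#'
#' Plain-nucleotide 5' (Read-1 side) and 3' (TSO side) primer sequences used
#' by the generator and, by default, by [deconcat_reads()].
#' @export
LRISO_FWD_PRIMER <- "CTACACGACGCTCTTCCGATCT"

#' @rdname LRISO_FWD_PRIMER
#' @export
LRISO_REV_PRIMER <- "AAGCAGTGGTATCAACGCAGAG"

POLYA_TAIL_LEN <- 30L  # fixed tail/tract length; only presence matters downstream

# lambda of a zero-truncated Poisson with the requested mean
trunc_pois_lambda <- function(mean_k) {
  if (mean_k <= 1 + 1e-9) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - mean_k,
          interval = c(1e-9, mean_k * 2 + 10))$root
}

rtrunc_pois <- function(n, lambda) {
  if (lambda == 0) return(rep(1L, n))
  k <- rpois(n, lambda)
  while (any(k == 0L)) k[k == 0L] <- rpois(sum(k == 0L), lambda)
  k
}

#' Render raw concatenated reads from simulated molecules
#'
#' @param sim output of [simulate_molecules()].
#' @param config the [sim_config()] used to create `sim`.
#' @param fwd_primer,rev_primer primer sequences flanking each segment.
#' @return list with `reads` (named character vector of read sequences) and
#'   `segments` (ground-truth table: read, segment index, molecule, artifact
#'   label in `none`/`no_polya`/`missing_primer`).
#' @export
render_reads <- function(sim, config,
                         fwd_primer = LRISO_FWD_PRIMER,
                         rev_primer = LRISO_REV_PRIMER) {
  set.seed(config$seed + 3L)
  mol <- sim$molecules
  n <- nrow(mol)
  lambda <- trunc_pois_lambda(config$mean_segments_per_read)

  ord <- sample.int(n)
  ks <- rtrunc_pois(ceiling(n / max(1, config$mean_segments_per_read) * 1.3) + 20L,
                    lambda)
  while (sum(ks) < n) ks <- c(ks, rtrunc_pois(50L, lambda))
  cs <- cumsum(ks)
  n_reads <- which(cs >= n)[1L]
  ks <- ks[seq_len(n_reads)]
  ks[n_reads] <- n - if (n_reads > 1L) cs[n_reads - 1L] else 0L

  read_of <- rep(seq_len(n_reads), times = ks)
  segidx <- unlist(lapply(ks, seq_len), use.names = FALSE)

  artifact <- rep("none", n)
  if (config$artifact_fraction > 0) {
    hit <- runif(n) < config$artifact_fraction
    artifact[hit] <- sample(c("no_polya", "missing_primer"), sum(hit),
                            replace = TRUE)
  }

  mo <- mol[ord, ]
  tail <- strrep("A", POLYA_TAIL_LEN)
  insert <- ifelse(artifact == "no_polya",
                   revcomp(mo$cdna),
                   revcomp(paste0(mo$cdna, tail)))
  seg <- paste0(fwd_primer, mo$cell_barcode, mo$umi, insert,
                ifelse(artifact == "missing_primer", "", rev_primer))
  flip <- runif(n) < 0.5
  seg[flip] <- revcomp(seg[flip])

  reads <- vapply(split(seg, read_of), paste0, "", collapse = "")
  names(reads) <- sprintf("R%05d", seq_len(n_reads))

  if (config$error_rate > 0) {
    for (r in seq_along(reads)) {
      len <- nchar(reads[r])
      nerr <- rbinom(1L, len, config$error_rate)
      if (nerr == 0L) next
      pos <- sample.int(len, nerr)
      chars <- strsplit(reads[r], "", fixed = TRUE)[[1]]
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      reads[r] <- paste0(chars, collapse = "")
    }
  }

  segments <- data.frame(read_id = sprintf("R%05d", read_of),
                         segment_index = segidx,
                         molecule_id = mo$molecule_id,
                         cell_barcode = mo$cell_barcode,
                         umi = mo$umi,
                         artifact = artifact)
  list(reads = reads, segments = segments)
}
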