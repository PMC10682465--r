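# Spliced-alignment emission: the generator's molecules carry their true
# genomic exon blocks, so alignment records are exact. This stands in for the
# genome alignment step so all downstream stages are testable without an
# aligner.

#' Emit exact spliced-alignment records for simulated molecules
#'
#' One record per (deduplicated) molecule; fusion molecules produce one record
#' per locus sharing the same `read_id`. When a variant panel is supplied,
#' per-read base calls at panel positions covered by the molecule are attached
#' (`chrom:pos=BASE`, 1-based, `;`-separated), reflecting any implanted
#' variants.
#'
#' @param sim output of [simulate_molecules()].
#' @param reference the [simulate_reference()] output (for reference bases).
#' @param panel optional variant panel (defaults to `sim$panel`).
#' @return data.frame in the spliced-alignment dialect: `read_id`,
#'   `cell_barcode`, `umi`, `chrom`, `strand`, `block_starts`, `block_ends`
#'   (comma-separated 0-based half-open), `base_calls`.
#' @export
emit_alignments <- function(sim, reference, panel = sim$panel) {
  mol <- sim$molecules
  base_calls <- rep("", nrow(mol))
  if (!is.null(panel) && nrow(panel)) {
    for (i in seq_len(nrow(mol))) {
      calls <- character(0)
      for (v in seq_len(nrow(panel))) {
        if (mol$chrom[i] != panel$chrom[v]) next
        b <- string_to_blocks(mol$block_starts[i], mol$block_ends[i])
        pos0 <- panel$pos[v] - 1L
        if (is.na(genomic_to_tx(b, mol$strand[i], pos0))) next
        tag <- sprintf("%s:%d:%s:%s", panel$chrom[v], panel$pos[v],
                       panel$ref[v], panel$alt[v])
        carried <- grepl(tag, mol$variants[i], fixed = TRUE)
        calls <- c(calls, sprintf("%s:%d=%s", panel$chrom[v], panel$pos[v],
                                  if (carried) panel$alt[v] else panel$ref[v]))
      }
      base_calls[i] <- paste(calls, collapse = ";")
    }
  }
  aln <- data.frame(read_id = mol$molecule_id,
                    cell_barcode = mol$cell_barcode,
                    umi = mol$umi,
                    chrom = mol$chrom,
                    strand = mol$strand,
                    block_starts = mol$block_starts,
                    block_ends = mol$block_ends,
                    base_calls = base_calls)
  fus <- mol[mol$is_fusion, , drop = FALSE]
  if (nrow(fus)) {
    aln2 <- data.frame(read_id = fus$molecule_id,
                       cell_barcode = fus$cell_barcode,
                       umi = fus$umi,
                       chrom = fus$chrom2,
                       strand = fus$strand2,
                       block_starts = fus$block_starts2,
                       block_ends = fus$block_ends2,
                       base_calls = "")
    aln <- rbind(aln, aln2)
    aln <- aln[order(aln$read_id), ]
    rownames(aln) <- NULL
  }
  aln
}
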