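# File interfaces: genome FASTA, annotation GTF (1-based inclusive on disk,
# 0-based half-open in memory), CAGE/polyA BED (0-based half-open), reads
# FASTA, the spliced-alignment TSV dialect, and plain TSV tables.

#' Write a simulated reference to standard file formats
#'
#' @param reference a [simulate_reference()] object.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gtf"),
             cage = file.path(dir, "cage.bed"),
             polya = file.path(dir, "polya.bed"))
  Biostrings::writeXStringSet(reference$genome, paths["genome"])

  ex <- reference$exons
  tx_bio <- setNames(reference$transcripts$biotype,
                     reference$transcripts$transcript_id)
  feat <- rbind(
    data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
               strand = ex$strand, type = "exon", gene_id = ex$gene_id,
               transcript_id = ex$transcript_id),
    data.frame(chrom = reference$utr3$chrom, start = reference$utr3$start,
               end = reference$utr3$end, strand = reference$utr3$strand,
               type = "three_prime_utr", gene_id = reference$utr3$gene_id,
               transcript_id = reference$utr3$transcript_id))
  gr <- GenomicRanges::GRanges(feat$chrom,
                               IRanges::IRanges(feat$start + 1L, feat$end),
                               strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$gene_id <- feat$gene_id
  S4Vectors::mcols(gr)$transcript_id <- feat$transcript_id
  S4Vectors::mcols(gr)$gene_biotype <- "protein_coding"
  S4Vectors::mcols(gr)$transcript_biotype <- unname(tx_bio[feat$transcript_id])
  rtracklayer::export(gr, paths["annotation"], format = "gtf")

  cage_gr <- GenomicRanges::GRanges(reference$cage$chrom,
                                    IRanges::IRanges(reference$cage$start + 1L,
                                                     reference$cage$end),
                                    strand = reference$cage$strand)
  rtracklayer::export(cage_gr, paths["cage"], format = "bed")
  polya_gr <- GenomicRanges::GRanges(reference$polya$chrom,
                                     IRanges::IRanges(reference$polya$pos + 1L,
                                                      reference$polya$pos + 1L),
                                     strand = reference$polya$strand)
  rtracklayer::export(polya_gr, paths["polya"], format = "bed")
  invisible(paths)
}

#' Read a GTF annotation into exon / 3'UTR tables
#'
#' @param path GTF file (1-based inclusive).
#' @return list with `exons`, `utr3`, `transcripts` and `genes` data.frames
#'   (0-based half-open coordinates).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  base <- data.frame(chrom = as.character(df$seqnames),
                     start = df$start - 1L, end = df$end,
                     strand = as.character(df$strand),
                     gene_id = df$gene_id, transcript_id = df$transcript_id)
  exons <- base[df$type == "exon", ]
  rownames(exons) <- NULL
  utr3 <- base[df$type == "three_prime_utr", ]
  rownames(utr3) <- NULL
  tx <- unique(data.frame(transcript_id = df$transcript_id,
                          gene_id = df$gene_id,
                          biotype = if ("transcript_biotype" %in% names(df))
                            df$transcript_biotype else NA_character_))
  genes <- unique(data.frame(gene_id = df$gene_id,
                             gene_biotype = if ("gene_biotype" %in% names(df))
                               df$gene_biotype else NA_character_))
  list(exons = exons, utr3 = utr3, transcripts = tx, genes = genes)
}

#' Read CAGE or polyA BED evidence
#'
#' @param path BED file (0-based half-open).
#' @param as_sites if TRUE, return single positions (`pos` = interval start)
#'   as used for polyA sites; else intervals.
#' @return data.frame with `chrom`, `start`/`end` or `pos`, and `strand`.
#' @export
read_bed_evidence <- function(path, as_sites = FALSE) {
  gr <- rtracklayer::import(path, format = "bed")
  if (as_sites) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr) - 1L,
               strand = as.character(GenomicRanges::strand(gr)))
  } else {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
  }
}

#' Write reads as FASTA
#' @param reads named character vector.
#' @param path output file.
#' @export
write_reads_fasta <- function(reads, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path)
  invisible(path)
}

#' Read a FASTA read set as a named character vector
#' @param path FASTA file.
#' @export
read_fasta_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read/write the spliced-alignment TSV dialect
#'
#' Columns: read_id, cell_barcode, umi, chrom, strand, block_starts,
#' block_ends (comma-separated, 0-based half-open), base_calls.
#'
#' @param alignments alignment data.frame.
#' @param path TSV file.
#' @export
write_alignments_tsv <- function(alignments, path) {
  write.table(alignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  df <- read.delim(path, colClasses = "character")
  df$base_calls[is.na(df$base_calls)] <- ""
  df
}

#' Read a barcode whitelist (one barcode per line)
#' @param path text file.
#' @export
read_whitelist <- function(path) readLines(path)

#' Read a mutation panel TSV (chrom, pos, ref, alt, gene; 1-based positions)
#' @param path TSV file.
#' @export
read_panel <- function(path) {
  p <- read.delim(path)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(p)))
  p
}

#' Run the full generator and write every pipeline input to disk
#'
#' Writes the reference files ([write_reference()]), concatenated reads
#' (FASTA), barcode whitelist, spliced alignments (TSV dialect), cell
#' metadata, variant panel, and ground-truth tables.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return invisibly, a list with the in-memory objects and written paths.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  sim <- simulate_molecules(config, ref)
  rr <- render_reads(sim, config)
  aln <- emit_alignments(sim, ref)
  paths <- write_reference(ref, dir)
  paths["reads"] <- file.path(dir, "reads.fasta")
  write_reads_fasta(rr$reads, paths["reads"])
  paths["whitelist"] <- file.path(dir, "whitelist.txt")
  writeLines(sort(unique(sim$cells$cell_barcode)), paths["whitelist"])
  paths["alignments"] <- file.path(dir, "alignments.tsv")
  write_alignments_tsv(aln, paths["alignments"])
  paths["cells"] <- file.path(dir, "cells.tsv")
  write.table(sim$cells, paths["cells"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sim$panel)) {
    paths["panel"] <- file.path(dir, "panel.tsv")
    write.table(sim$panel, paths["panel"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (tt in c("usage", "apa")) {
    paths[paste0("truth_", tt)] <- file.path(dir, sprintf("truth_%s.tsv", tt))
    write.table(sim$truth[[tt]], paths[paste0("truth_", tt)], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  paths["truth_molecules"] <- file.path(dir, "truth_molecules.tsv")
  write.table(sim$molecules[, setdiff(names(sim$molecules), "cdna")],
              paths["truth_molecules"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(reference = ref, sim = sim, reads = rr, alignments = aln,
                 paths = paths))
}
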