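#' Simulate a toy reference: genome, annotation, CAGE peaks and polyA sites
#'
#' Lays out non-overlapping multi-exon genes on two chromosomes (alternating,
#' so fusion partners always lie on different sequences), builds 1-3 isoforms
#' per gene by skipping internal exons, appends a 3'UTR of `utr_length` nt to
#' the terminal exon, and plants canonical GT-AG motifs at every annotated
#' intron. Every transcript's TSS gets a CAGE interval and its TES a polyA
#' site; each gene additionally carries the proximal polyA site of the
#' two-site model, halfway into the UTR.
#'
#' All coordinates are 0-based half-open internally; [write_reference()]
#' emits 1-based GTF and 0-based BED.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `lriso_reference`: a list with `genome`
#'   (DNAStringSet), `genes`, `transcripts`, `exons`, `utr3`, `cage`, `polya`,
#'   `apa_sites` data.frames, `tx_blocks` (genomic exon block matrices per
#'   transcript), and the `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  utr <- config$utr_length

  n_iso <- config$n_isoforms
  if (is.null(n_iso)) {
    n_iso <- vapply(seq_len(n), function(g) {
      if (g %% 3L == 0L) 1L else sample(2:3, 1L)
    }, 1L)
  }

  chroms <- rep(c("chr1", "chr2"), length.out = n)
  cursor <- c(chr1 = 1000L, chr2 = 1000L)

  genes <- list(); txs <- list(); exons <- list(); utr3 <- list()
  cage <- list(); polya <- list(); apa <- list(); tx_blocks <- list()

  for (g in seq_len(n)) {
    gid <- sprintf("G%03d", g)
    chrom <- chroms[g]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(4:7, 1L)
    widths <- sample(120:250, n_ex, replace = TRUE)
    # the transcript-terminal exon carries the 3'UTR
    if (strand == "+") widths[n_ex] <- widths[n_ex] + utr else widths[1L] <- widths[1L] + utr
    introns <- sample(300:800, n_ex - 1L, replace = TRUE)
    starts <- cursor[chrom] + cumsum(c(0L, widths[-n_ex] + introns))
    ends <- starts + widths
    blocks <- cbind(start = starts, end = ends)
    cursor[chrom] <- ends[n_ex] + 10000L

    # isoform exon subsets: T1 full; others each skip one internal exon
    skippable <- if (n_ex > 2L) seq(2L, n_ex - 1L) else integer(0)
    k_iso <- min(n_iso[g], length(skippable) + 1L)
    skips <- if (k_iso > 1L) sample(skippable, k_iso - 1L) else integer(0)
    bios <- c("protein_coding",
              sample(c("protein_coding", "NMD", "retained_intron", "lncRNA"),
                     k_iso - 1L, replace = TRUE))
    for (k in seq_len(k_iso)) {
      tid <- sprintf("%s.T%d", gid, k)
      keep <- setdiff(seq_len(n_ex), if (k > 1L) skips[k - 1L] else integer(0))
      b <- blocks[keep, , drop = FALSE]
      tx_blocks[[tid]] <- b
      tss <- if (strand == "+") b[1L, "start"] else b[nrow(b), "end"] - 1L
      tes <- if (strand == "+") b[nrow(b), "end"] - 1L else b[1L, "start"]
      txs[[tid]] <- data.frame(transcript_id = tid, gene_id = gid,
                               chrom = chrom, strand = strand,
                               biotype = bios[k], tss_pos = tss, tes_pos = tes)
      exons[[tid]] <- data.frame(chrom = chrom, start = b[, "start"],
                                 end = b[, "end"], strand = strand,
                                 gene_id = gid, transcript_id = tid,
                                 feature = "exon")
      cage[[tid]] <- data.frame(chrom = chrom, start = max(0L, tss - 5L),
                                end = tss + 6L, strand = strand)
      polya[[tid]] <- data.frame(chrom = chrom, pos = tes, strand = strand)
    }

    # 3'UTR interval (shared terminal exon) and two-site polyA geometry
    if (strand == "+") {
      utr_start <- ends[n_ex] - utr; utr_end <- ends[n_ex]
    } else {
      utr_start <- starts[1L]; utr_end <- starts[1L] + utr
    }
    proximal_k <- utr %/% 2L  # UTR coordinate (1..L) of the proximal site
    prox_pos <- if (strand == "+") utr_start + proximal_k - 1L else utr_end - proximal_k
    polya[[paste0(gid, ".prox")]] <- data.frame(chrom = chrom, pos = prox_pos,
                                                strand = strand)
    coding <- vapply(seq_len(k_iso),
                     function(k) bios[k] == "protein_coding", TRUE)
    for (k in which(coding)) {
      utr3[[sprintf("%s.T%d", gid, k)]] <- data.frame(
        gene_id = gid, transcript_id = sprintf("%s.T%d", gid, k),
        chrom = chrom, strand = strand, start = utr_start, end = utr_end)
    }
    apa[[gid]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             utr_start = utr_start, utr_end = utr_end,
                             L = utr, proximal_k = proximal_k,
                             distal_pos = if (strand == "+") utr_end - 1L else utr_start,
                             proximal_pos = prox_pos)
    genes[[gid]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               start = starts[1L], end = ends[n_ex],
                               gene_biotype = "protein_coding")
  }

  genes <- do.call(rbind, genes); rownames(genes) <- NULL
  txs <- do.call(rbind, txs); rownames(txs) <- NULL
  exons <- do.call(rbind, exons); rownames(exons) <- NULL
  utr3 <- do.call(rbind, utr3); rownames(utr3) <- NULL
  cage <- unique(do.call(rbind, cage)); rownames(cage) <- NULL
  polya <- unique(do.call(rbind, polya)); rownames(polya) <- NULL
  apa <- do.call(rbind, apa); rownames(apa) <- NULL

  genome <- Biostrings::DNAStringSet(setNames(
    vapply(c("chr1", "chr2"), function(ch) random_dna(cursor[ch] + 1000L), ""),
    c("chr1", "chr2")))

  # plant canonical transcript-strand GT-AG motifs at all annotated introns
  junc <- unique(do.call(rbind, lapply(names(tx_blocks), function(tid) {
    b <- tx_blocks[[tid]]
    if (nrow(b) < 2L) return(NULL)
    data.frame(chrom = txs$chrom[txs$transcript_id == tid][1L],
               strand = txs$strand[txs$transcript_id == tid][1L],
               donor = b[-nrow(b), "end"], acceptor = b[-1L, "start"])
  })))
  for (i in seq_len(nrow(junc))) {
    ch <- junc$chrom[i]; s <- junc$donor[i]; e <- junc$acceptor[i]
    if (junc$strand[i] == "+") {
      Biostrings::subseq(genome[[ch]], s + 1L, s + 2L) <- Biostrings::DNAString("GT")
      Biostrings::subseq(genome[[ch]], e - 1L, e) <- Biostrings::DNAString("AG")
    } else {
      Biostrings::subseq(genome[[ch]], s + 1L, s + 2L) <- Biostrings::DNAString("CT")
      Biostrings::subseq(genome[[ch]], e - 1L, e) <- Biostrings::DNAString("AC")
    }
  }

  # resolve variant positions (mid first transcript exon of T1, shared by all
  # isoforms) into a mutation panel with genomic coordinates
  panel <- NULL
  vs <- config$variant_spec
  if (!is.null(vs)) {
    vs <- as.data.frame(vs)
    rows <- lapply(seq_len(nrow(vs)), function(i) {
      gid <- vs$gene[i]
      if (is.numeric(gid)) gid <- sprintf("G%03d", gid)
      if (!is.null(vs$position) && !is.na(vs$position[i])) {
        chrom <- vs$chrom[i]; pos1 <- as.integer(vs$position[i])
        ref <- vs$ref[i]; alt <- vs$alt[i]
      } else {
        tid <- sprintf("%s.T1", gid)
        b <- tx_blocks[[tid]]
        strand <- genes$strand[genes$gene_id == gid]
        first <- if (strand == "+") b[1L, ] else b[nrow(b), ]
        chrom <- genes$chrom[genes$gene_id == gid]
        pos0 <- as.integer(floor((first["start"] + first["end"]) / 2))
        pos1 <- pos0 + 1L
        ref <- seq_substr(genome, chrom, pos0, pos0 + 1L)
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
      }
      data.frame(chrom = chrom, pos = pos1, ref = ref, alt = alt, gene = gid,
                 carriers = vs$carriers[i],
                 allele_fraction = vs$allele_fraction[i])
    })
    panel <- do.call(rbind, rows)
  }

  structure(list(genome = genome, genes = genes, transcripts = txs,
                 exons = exons, utr3 = utr3, cage = cage, polya = polya,
                 apa_sites = apa, tx_blocks = tx_blocks, panel = panel,
                 config = config),
            class = "lriso_reference")
}

#' @export
print.lriso_reference <- function(x, ...) {
  cat(sprintf("Synthetic reference: %d genes, %d transcripts on %d sequences\n",
              nrow(x$genes), nrow(x$transcripts), length(x$genome)))
  invisible(x)
}
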