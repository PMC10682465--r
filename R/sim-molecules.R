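# Molecule-level simulation: draws cDNA molecules per cell from the
# configured isoform-usage mixtures and the two-site polyadenylation model,
# implants variants and fusion molecules, and records complete ground truth.

# transcript-coordinate offset (0-based) of a genomic position inside blocks
genomic_to_tx <- function(blocks, strand, pos0) {
  w <- blocks[, "end"] - blocks[, "start"]
  total <- sum(w)
  i <- which(pos0 >= blocks[, "start"] & pos0 < blocks[, "end"])
  if (length(i) != 1L) return(NA_integer_)
  plus_off <- sum(w[seq_len(i - 1L)]) + (pos0 - blocks[i, "start"])
  if (strand == "+") plus_off else total - 1L - plus_off
}

spliced_seq <- function(genome, chrom, strand, blocks) {
  s <- paste0(vapply(seq_len(nrow(blocks)), function(i) {
    seq_substr(genome, chrom, blocks[i, "start"], blocks[i, "end"])
  }, ""), collapse = "")
  if (strand == "-") revcomp(s) else s
}

truncate_blocks_proximal <- function(blocks, strand, utr_start, utr_end, p_k) {
  # molecule terminates at UTR position p_k instead of L
  k <- nrow(blocks)
  if (strand == "+") blocks[k, "end"] <- utr_start + p_k
  else blocks[1L, "start"] <- utr_end - p_k
  blocks
}

#' Simulate tagged cDNA molecules with ground truth
#'
#' Per gene and cell type, isoform identities are drawn from the configured
#' usage mixtures and each molecule's 3' end terminates at the distal polyA
#' site with the configured probability (else at the proximal site). Variants
#' are implanted at their allele fraction in carrier cell types; fusion
#' molecules join the 5' exons of one gene to the terminal exon of another.
#'
#' @param config a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @return list with `molecules` (one row per molecule: tags, exon blocks,
#'   cDNA sequence, carried variants), `cells` (barcode, cell type, biopsy
#'   sample), `panel` (implanted variant table, 1-based positions), and
#'   `truth` (`usage`, `apa`, `fusion`).
#' @export
simulate_molecules <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "lriso_reference"))
  set.seed(config$seed + 2L)
  ref <- reference
  cts <- config$cell_types
  n_cells <- length(cts) * config$cells_per_type

  cells <- data.frame(
    cell_barcode = random_tags(n_cells, 16L),
    cell_type = rep(cts, each = config$cells_per_type))
  cells$sample <- unname(config$cell_type_sample[cells$cell_type])

  # --- ground-truth usage (Pi) and distal fractions per gene x cell type ----
  usage <- list(); apa_truth <- list()
  for (gid in ref$genes$gene_id) {
    tids <- ref$transcripts$transcript_id[ref$transcripts$gene_id == gid]
    for (ct in cts) {
      if (!is.null(config$isoform_usage)) {
        rows <- config$isoform_usage[config$isoform_usage$gene_id == gid &
                                       config$isoform_usage$cell_type == ct, ]
        if (nrow(rows)) {
          p <- rows$prop[order(rows$isoform_index)]
          stopifnot(length(p) == length(tids))
        } else p <- NULL
      } else p <- NULL
      if (is.null(p)) {
        if (length(tids) == 1L) p <- 1
        else { g <- rgamma(length(tids), shape = 2); p <- g / sum(g) }
      }
      usage[[paste(gid, ct)]] <- data.frame(gene_id = gid, cell_type = ct,
                                            transcript_id = tids, prop = p)
      f <- config$apa_distal_fraction
      if (is.null(f)) f <- runif(1L, 0.2, 0.9)
      else if (is.data.frame(f)) {
        row <- f[f$gene_id == gid & f$cell_type == ct, ]
        f <- if (nrow(row)) row$fraction[1L] else runif(1L, 0.2, 0.9)
      }
      apa_truth[[paste(gid, ct)]] <- data.frame(gene_id = gid, cell_type = ct,
                                                distal_fraction = f)
    }
  }
  usage <- do.call(rbind, usage); rownames(usage) <- NULL
  apa_truth <- do.call(rbind, apa_truth); rownames(apa_truth) <- NULL

  # --- spliced sequences, full-length and proximally terminated -------------
  seq_full <- list(); seq_prox <- list(); blocks_prox <- list()
  for (tid in names(ref$tx_blocks)) {
    tx <- ref$transcripts[ref$transcripts$transcript_id == tid, ]
    ap <- ref$apa_sites[ref$apa_sites$gene_id == tx$gene_id, ]
    b <- ref$tx_blocks[[tid]]
    seq_full[[tid]] <- spliced_seq(ref$genome, tx$chrom, tx$strand, b)
    bp <- truncate_blocks_proximal(b, tx$strand, ap$utr_start, ap$utr_end,
                                   ap$proximal_k)
    blocks_prox[[tid]] <- bp
    seq_prox[[tid]] <- substr(seq_full[[tid]], 1L,
                              nchar(seq_full[[tid]]) - (ap$L - ap$proximal_k))
  }

  # --- draw molecules -------------------------------------------------------
  rows <- vector("list", 4096L); nr <- 0L
  for (gid in ref$genes$gene_id) {
    gstrand <- ref$genes$strand[ref$genes$gene_id == gid]
    gchrom <- ref$genes$chrom[ref$genes$gene_id == gid]
    for (ct in cts) {
      idx <- which(cells$cell_type == ct)
      n_mol_cell <- rpois(length(idx), config$umis_per_cell_gene)
      total <- sum(n_mol_cell)
      if (total == 0L) next
      u <- usage[usage$gene_id == gid & usage$cell_type == ct, ]
      f <- apa_truth$distal_fraction[apa_truth$gene_id == gid &
                                       apa_truth$cell_type == ct]
      tid <- sample(u$transcript_id, total, replace = TRUE, prob = u$prop)
      distal <- runif(total) < f
      nr <- nr + 1L
      rows[[nr]] <- data.frame(
        gene_id = gid, transcript_id = tid,
        cell_barcode = rep(cells$cell_barcode[idx], n_mol_cell),
        cell_type = ct, chrom = gchrom, strand = gstrand, distal = distal,
        is_fusion = FALSE)
    }
  }
  mol <- do.call(rbind, rows[seq_len(nr)])
  rownames(mol) <- NULL

  bs <- character(nrow(mol)); be <- character(nrow(mol)); cdna <- character(nrow(mol))
  for (i in seq_len(nrow(mol))) {
    tid <- mol$transcript_id[i]
    b <- if (mol$distal[i]) ref$tx_blocks[[tid]] else blocks_prox[[tid]]
    st <- blocks_to_string(b[, "start"], b[, "end"])
    bs[i] <- st$starts; be[i] <- st$ends
    cdna[i] <- if (mol$distal[i]) seq_full[[tid]] else seq_prox[[tid]]
  }
  mol$block_starts <- bs; mol$block_ends <- be; mol$cdna <- cdna
  mol$gene_id2 <- NA_character_; mol$chrom2 <- NA_character_
  mol$strand2 <- NA_character_
  mol$block_starts2 <- NA_character_; mol$block_ends2 <- NA_character_
  mol$variants <- ""

  # --- implant panel variants ----------------------------------------------
  panel <- ref$panel
  if (!is.null(panel)) {
    for (v in seq_len(nrow(panel))) {
      carriers <- strsplit(panel$carriers[v], ",", fixed = TRUE)[[1]]
      pos0 <- panel$pos[v] - 1L
      cand <- which(mol$cell_type %in% carriers & mol$chrom == panel$chrom[v])
      for (i in cand) {
        b <- string_to_blocks(mol$block_starts[i], mol$block_ends[i])
        off <- genomic_to_tx(b, mol$strand[i], pos0)
        if (is.na(off)) next
        if (runif(1L) < panel$allele_fraction[v]) {
          base <- if (mol$strand[i] == "+") panel$alt[v] else revcomp(panel$alt[v])
          substr(mol$cdna[i], off + 1L, off + 1L) <- base
          tag <- sprintf("%s:%d:%s:%s", panel$chrom[v], panel$pos[v],
                         panel$ref[v], panel$alt[v])
          mol$variants[i] <- if (mol$variants[i] == "") tag
                             else paste(mol$variants[i], tag, sep = ";")
        }
      }
    }
  }

  # --- fusion molecules: 5' exons of gene A joined to terminal exon of B ----
  fusion_truth <- NULL
  fs <- config$fusion_spec
  if (!is.null(fs)) {
    gid5 <- if (is.numeric(fs$gene_5p)) sprintf("G%03d", fs$gene_5p) else fs$gene_5p
    gid3 <- if (is.numeric(fs$gene_3p)) sprintf("G%03d", fs$gene_3p) else fs$gene_3p
    g5 <- ref$genes[ref$genes$gene_id == gid5, ]
    g3 <- ref$genes[ref$genes$gene_id == gid3, ]
    if (g5$chrom == g3$chrom) stop("fusion partners must lie on different chromosomes")
    b5 <- ref$tx_blocks[[sprintf("%s.T1", gid5)]]
    b3 <- ref$tx_blocks[[sprintf("%s.T1", gid3)]]
    # transcript-orientation exons 1-2 of gene A
    part5 <- if (g5$strand == "+") b5[1:2, , drop = FALSE]
             else b5[(nrow(b5) - 1L):nrow(b5), , drop = FALSE]
    part3 <- if (g3$strand == "+") b3[nrow(b3), , drop = FALSE]
             else b3[1L, , drop = FALSE]
    bp5 <- if (g5$strand == "+") part5[2L, "end"] - 1L else part5[1L, "start"]
    bp3 <- if (g3$strand == "+") part3[1L, "start"] else part3[1L, "end"] - 1L
    cdna_f <- paste0(spliced_seq(ref$genome, g5$chrom, g5$strand, part5),
                     spliced_seq(ref$genome, g3$chrom, g3$strand, part3))
    carrier_cells <- cells$cell_barcode[cells$cell_type == fs$cell_type]
    n_f <- as.integer(fs$n_umis)
    st5 <- blocks_to_string(part5[, "start"], part5[, "end"])
    st3 <- blocks_to_string(part3[, "start"], part3[, "end"])
    fus <- data.frame(
      gene_id = gid5, transcript_id = paste0(gid5, "::", gid3),
      cell_barcode = sample(carrier_cells, n_f, replace = TRUE),
      cell_type = fs$cell_type, chrom = g5$chrom, strand = g5$strand,
      distal = NA, is_fusion = TRUE,
      block_starts = st5$starts, block_ends = st5$ends, cdna = cdna_f,
      gene_id2 = gid3, chrom2 = g3$chrom, strand2 = g3$strand,
      block_starts2 = st3$starts, block_ends2 = st3$ends, variants = "")
    mol <- rbind(mol, fus)
    fusion_truth <- list(gene_5p = gid5, gene_3p = gid3,
                         breakpoint_5p = bp5, breakpoint_3p = bp3,
                         n_umis = n_f, cell_type = fs$cell_type)
  }

  mol$molecule_id <- sprintf("M%06d", seq_len(nrow(mol)))
  mol$umi <- random_tags(nrow(mol), 12L)
  mol <- mol[, c("molecule_id", "gene_id", "transcript_id", "cell_barcode",
                 "cell_type", "umi", "chrom", "strand", "block_starts",
                 "block_ends", "distal", "is_fusion", "gene_id2", "chrom2",
                 "strand2", "block_starts2", "block_ends2", "cdna", "variants")]

  list(molecules = mol, cells = cells, panel = panel,
       truth = list(usage = usage, apa = apa_truth, fusion = fusion_truth))
}

#' Simulate two-site 3'UTR coverage profiles
#'
#' Direct generator of the coverage matrix the APA model assumes: each of
#' `n_molecules` reads covers the UTR from position 1 to the distal end with
#' probability `distal_fraction`, otherwise to the proximal site; the exact
#' 3' end wobbles uniformly within `wobble` nt of the site.
#'
#' @param L UTR length (nt).
#' @param proximal_k proximal site position (UTR coordinates, 1-based).
#' @param n_molecules reads per condition (vector, one per condition).
#' @param distal_fraction true distal-usage fraction per condition.
#' @param wobble maximal uniform shift of each molecule's 3' end.
#' @return integer coverage matrix, conditions x positions.
#' @export
simulate_utr_coverage <- function(L, proximal_k, n_molecules, distal_fraction,
                                  wobble = 5L) {
  stopifnot(length(n_molecules) == length(distal_fraction),
            proximal_k > 50L, proximal_k <= L - 50L)
  m <- length(n_molecules)
  w <- matrix(0L, nrow = m, ncol = L)
  for (c in seq_len(m)) {
    n <- n_molecules[c]
    distal <- runif(n) < distal_fraction[c]
    site <- ifelse(distal, L, proximal_k)
    ends <- pmin(L, pmax(1L, site + sample(seq(-wobble, wobble), n, replace = TRUE)))
    cnt <- rev(cumsum(rev(tabulate(ends, nbins = L))))
    w[c, ] <- cnt  # molecules cover positions 1..end
  }
  w
}
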