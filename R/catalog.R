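# Isoform catalog: collapse aligned molecules into isoforms by junction
# chain, assign SQANTI-style structural categories against a reference
# annotation, apply artifact filters (intrapriming, noncanonical novel
# junctions, RT-switch repeats, minimal UMI support), validate 5'/3' ends
# against CAGE and polyA sites, and classify cell-type specificity.

CANONICAL_MOTIFS <- c("GT-AG", "GC-AG", "AT-AC")

# per-transcript chains plus per-gene splice-site sets from an exon table
annotation_index <- function(exons) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id",
                  "transcript_id") %in% names(exons)))
  txs <- split(exons, exons$transcript_id)
  tx <- do.call(rbind, lapply(txs, function(e) {
    e <- e[order(e$start), ]
    b <- cbind(start = e$start, end = e$end)
    data.frame(transcript_id = e$transcript_id[1L], gene_id = e$gene_id[1L],
               chrom = e$chrom[1L], strand = e$strand[1L],
               chain = blocks_to_chain(b),
               tss_pos = if (e$strand[1L] == "+") b[1L, "start"] else b[nrow(b), "end"] - 1L,
               tes_pos = if (e$strand[1L] == "+") b[nrow(b), "end"] - 1L else b[1L, "start"])
  }))
  rownames(tx) <- NULL
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], start = min(e$start), end = max(e$end))
  }))
  rownames(genes) <- NULL
  intron_sites <- lapply(split(tx, tx$gene_id), function(g) {
    j <- do.call(rbind, lapply(g$chain, chain_junctions))
    list(starts = unique(j[, "donor"]), ends = unique(j[, "acceptor"]))
  })
  junction_keys <- unique(unlist(lapply(seq_len(nrow(tx)), function(i) {
    j <- chain_junctions(tx$chain[i])
    if (nrow(j) == 0L) return(character(0))
    paste(tx$chrom[i], tx$strand[i], j[, "donor"], j[, "acceptor"], sep = "|")
  })))
  list(tx = tx, genes = genes, intron_sites = intron_sites,
       junction_keys = junction_keys)
}

#' Collapse aligned molecules into an isoform catalog
#'
#' Multi-exon molecules sharing an identical junction chain merge into one
#' isoform (TSS = 5'-most observed start, TES = modal end with ties resolved
#' 3'-most); mono-exon molecules merge when their intervals overlap at least
#' 95% reciprocally. Reads aligning to more than one locus (fusion
#' candidates) are left out of the catalog.
#'
#' @param alignments spliced-alignment records (see [emit_alignments()]).
#' @return list of class `lriso_catalog` with `isoforms` (one row per
#'   isoform: chain, ends, UMI total), `counts` (isoform x cell long table)
#'   and `assignment` (read -> isoform).
#' @export
collapse_molecules <- function(alignments) {
  empty <- structure(list(
    isoforms = data.frame(), counts = data.frame(), assignment = data.frame()),
    class = "lriso_catalog")
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty)
  multi <- names(which(table(alignments$read_id) > 1L))
  aln <- alignments[!(alignments$read_id %in% multi), , drop = FALSE]
  if (nrow(aln) == 0L) return(empty)

  bl <- lapply(seq_len(nrow(aln)), function(i) {
    string_to_blocks(aln$block_starts[i], aln$block_ends[i])
  })
  aln$n_exons <- vapply(bl, nrow, 1L)
  aln$chain <- vapply(bl, blocks_to_chain, "")
  aln$first_start <- vapply(bl, function(b) b[1L, "start"], 1L)
  aln$last_end <- vapply(bl, function(b) b[nrow(b), "end"], 1L)
  aln$tss_pos <- ifelse(aln$strand == "+", aln$first_start, aln$last_end - 1L)
  aln$tes_pos <- ifelse(aln$strand == "+", aln$last_end - 1L, aln$first_start)

  groups <- integer(nrow(aln))
  multiex <- aln$n_exons > 1L
  key <- paste(aln$chrom, aln$strand, aln$chain)
  groups[multiex] <- match(key[multiex], unique(key[multiex]))

  # mono-exon molecules: single-linkage clusters of >=95% reciprocal overlaps
  mono <- which(!multiex)
  if (length(mono)) {
    ir <- IRanges::IRanges(start = aln$first_start[mono] + 1L,
                           end = aln$last_end[mono])
    ov <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    samechr <- aln$chrom[mono][q] == aln$chrom[mono][s] &
      aln$strand[mono][q] == aln$strand[mono][s]
    wq <- IRanges::width(ir)[q]; ws <- IRanges::width(ir)[s]
    wo <- IRanges::width(IRanges::pintersect(ir[q], ir[s]))
    recip <- samechr & wo >= 0.95 * wq & wo >= 0.95 * ws
    parent <- seq_along(mono)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (p in which(recip)) {
      a <- find(q[p]); b <- find(s[p])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_along(mono), find, 1L)
    groups[mono] <- max(groups) + match(roots, unique(roots))
  }

  split_ix <- split(seq_len(nrow(aln)), groups)
  iso <- do.call(rbind, lapply(names(split_ix), function(g) {
    a <- aln[split_ix[[g]], ]
    plus <- a$strand[1L] == "+"
    tss <- if (plus) min(a$tss_pos) else max(a$tss_pos)
    tes_tab <- table(a$tes_pos)
    modal <- as.integer(names(tes_tab)[tes_tab == max(tes_tab)])
    tes <- if (plus) max(modal) else min(modal)
    data.frame(group = g, chrom = a$chrom[1L], strand = a$strand[1L],
               n_exons = a$n_exons[1L], chain = a$chain[1L],
               tss_pos = tss, tes_pos = tes, total_umis = nrow(a))
  }))
  ord <- order(iso$chrom, pmin(iso$tss_pos, iso$tes_pos))
  iso <- iso[ord, ]
  iso$isoform_id <- sprintf("I%05d", seq_len(nrow(iso)))
  rownames(iso) <- NULL
  id_of_group <- setNames(iso$isoform_id, iso$group)
  iso$group <- NULL
  assignment <- data.frame(read_id = aln$read_id,
                           isoform_id = unname(id_of_group[as.character(groups)]),
                           cell_barcode = aln$cell_barcode)
  counts <- as.data.frame(table(isoform_id = assignment$isoform_id,
                                cell_barcode = assignment$cell_barcode),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "count"
  counts <- counts[counts$count > 0L, ]
  rownames(counts) <- NULL
  structure(list(isoforms = iso, counts = counts, assignment = assignment),
            class = "lriso_catalog")
}

#' @export
print.lriso_catalog <- function(x, ...) {
  cat(sprintf("Isoform catalog: %d isoforms, %d assigned molecules\n",
              nrow(x$isoforms), nrow(x$assignment)))
  if ("category" %in% names(x$isoforms)) {
    print(table(x$isoforms$category))
  }
  invisible(x)
}

#' Assign SQANTI-style structural categories
#'
#' FSM: junction chain identical to a reference transcript. ISM: contiguous
#' sub-chain of a reference chain. NIC: all splice sites known at the locus
#' but the combination (or junction pairing) is new. NNC: at least one
#' unknown splice site (neojunction). Mono-exon and intergenic isoforms are
#' `other`.
#'
#' @param catalog output of [collapse_molecules()].
#' @param exons reference exon annotation (chrom, start, end, strand,
#'   gene_id, transcript_id).
#' @return the catalog with `category`, `gene_id` and `matched_transcript`
#'   columns added to `isoforms`.
#' @export
classify_catalog <- function(catalog, exons) {
  idx <- annotation_index(exons)
  iso <- catalog$isoforms
  if (nrow(iso) == 0L) return(catalog)

  giso <- GenomicRanges::GRanges(iso$chrom,
                                 IRanges::IRanges(pmin(iso$tss_pos, iso$tes_pos) + 1L,
                                                  pmax(iso$tss_pos, iso$tes_pos) + 1L),
                                 strand = iso$strand)
  gref <- GenomicRanges::GRanges(idx$genes$chrom,
                                 IRanges::IRanges(idx$genes$start + 1L,
                                                  idx$genes$end),
                                 strand = idx$genes$strand)
  ov <- GenomicRanges::findOverlaps(giso, gref)
  loci <- split(idx$genes$gene_id[S4Vectors::subjectHits(ov)],
                factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(iso))))

  category <- character(nrow(iso))
  gene_id <- rep(NA_character_, nrow(iso))
  matched <- rep(NA_character_, nrow(iso))
  for (i in seq_len(nrow(iso))) {
    genes_here <- loci[[i]]
    if (length(genes_here) == 0L || iso$n_exons[i] == 1L) {
      category[i] <- "other"
      gene_id[i] <- if (length(genes_here)) genes_here[1L] else NA_character_
      next
    }
    gene_id[i] <- genes_here[1L]
    ref <- idx$tx[idx$tx$gene_id %in% genes_here &
                    idx$tx$chrom == iso$chrom[i] &
                    idx$tx$strand == iso$strand[i], ]
    chain <- iso$chain[i]
    fsm <- ref$transcript_id[ref$chain == chain]
    if (length(fsm)) {
      category[i] <- "FSM"; matched[i] <- fsm[1L]
      gene_id[i] <- ref$gene_id[ref$transcript_id == fsm[1L]]
      next
    }
    needle <- paste0(",", chain, ",")
    ism <- ref$transcript_id[vapply(ref$chain, function(rc) {
      rc != "" && grepl(needle, paste0(",", rc, ","), fixed = TRUE)
    }, TRUE)]
    if (length(ism)) {
      category[i] <- "ISM"; matched[i] <- ism[1L]
      gene_id[i] <- ref$gene_id[ref$transcript_id == ism[1L]]
      next
    }
    j <- chain_junctions(chain)
    known_starts <- unique(unlist(lapply(genes_here, function(g)
      idx$intron_sites[[g]]$starts)))
    known_ends <- unique(unlist(lapply(genes_here, function(g)
      idx$intron_sites[[g]]$ends)))
    if (all(j[, "donor"] %in% known_starts) &&
        all(j[, "acceptor"] %in% known_ends)) {
      category[i] <- "NIC"
    } else {
      category[i] <- "NNC"
    }
  }
  catalog$isoforms$category <- category
  catalog$isoforms$gene_id <- gene_id
  catalog$isoforms$matched_transcript <- matched
  catalog
}

#' Flag intrapriming artifacts
#'
#' An isoform is flagged when the genomic window immediately downstream of
#' its TES (in transcript orientation) is A-rich: A-fraction at least
#' `a_fraction` over `window` nt. Windows truncated at contig ends are
#' evaluated as-is.
#'
#' @param isoforms data.frame with `chrom`, `strand`, `tes_pos`.
#' @param genome DNAStringSet.
#' @param window window length in nt (default 20).
#' @param a_fraction flagging threshold (default 0.6).
#' @return logical vector.
#' @export
detect_intrapriming <- function(isoforms, genome, window = 20L, a_fraction = 0.6) {
  vapply(seq_len(nrow(isoforms)), function(i) {
    ch <- isoforms$chrom[i]
    len <- length(genome[[ch]])
    if (isoforms$strand[i] == "+") {
      s <- isoforms$tes_pos[i] + 1L
      e <- min(len, s + window)
      if (s >= e) return(FALSE)
      seq <- seq_substr(genome, ch, s, e)
    } else {
      e <- isoforms$tes_pos[i]
      s <- max(0L, e - window)
      if (s >= e) return(FALSE)
      seq <- revcomp(seq_substr(genome, ch, s, e))
    }
    a_fraction_of(seq) >= a_fraction
  }, TRUE)
}

junction_motif <- function(genome, chrom, strand, donor, acceptor) {
  d2 <- seq_substr(genome, chrom, donor, donor + 2L)
  a2 <- seq_substr(genome, chrom, acceptor - 2L, acceptor)
  if (strand == "+") paste0(d2, "-", a2)
  else paste0(revcomp(a2), "-", revcomp(d2))
}

# r-mers of `w` as a character vector
kmers <- function(w, r) {
  n <- nchar(w)
  if (n < r) return(character(0))
  substring(w, seq_len(n - r + 1L), seq(r, n))
}

#' Flag reverse-transcriptase template-switching artifacts
#'
#' A novel junction is flagged when an exact direct repeat of at least
#' `repeat_len` nt occurs near both intron boundaries (within `repeat_len` nt
#' of the donor-side exon/intron boundary and of the intron end upstream of
#' the acceptor). Reference-supported junctions are never tested.
#'
#' @param isoforms data.frame with `chrom`, `strand`, `chain`.
#' @param genome DNAStringSet.
#' @param junction_keys reference junction keys (`chrom|strand|donor|acceptor`).
#' @param repeat_len minimal repeat length (default 8).
#' @return logical vector.
#' @export
detect_rt_switch <- function(isoforms, genome, junction_keys, repeat_len = 8L) {
  vapply(seq_len(nrow(isoforms)), function(i) {
    j <- chain_junctions(isoforms$chain[i])
    if (nrow(j) == 0L) return(FALSE)
    keys <- paste(isoforms$chrom[i], isoforms$strand[i],
                  j[, "donor"], j[, "acceptor"], sep = "|")
    novel <- which(!(keys %in% junction_keys))
    for (k in novel) {
      d <- j[k, "donor"]; a <- j[k, "acceptor"]
      len <- length(genome[[isoforms$chrom[i]]])
      w1 <- seq_substr(genome, isoforms$chrom[i],
                       max(0L, d - repeat_len), min(len, d + repeat_len))
      w2 <- seq_substr(genome, isoforms$chrom[i],
                       max(0L, a - repeat_len), min(len, a + repeat_len))
      if (length(intersect(kmers(w1, repeat_len), kmers(w2, repeat_len)))) {
        return(TRUE)
      }
    }
    FALSE
  }, TRUE)
}

#' Filter artifact isoforms from a catalog
#'
#' Removes isoforms that are (a) intrapriming-flagged, (b) carry a novel
#' junction with a noncanonical motif (outside GT-AG/GC-AG/AT-AC), (c) are
#' RT-switch-flagged, or (d) have fewer than `min_umis` UMIs; the removal
#' reason reported is the first matching one in that order.
#'
#' @param catalog classified catalog ([classify_catalog()]).
#' @param genome DNAStringSet.
#' @param exons reference exon annotation.
#' @param min_umis minimal UMI support (default 3).
#' @param window,a_fraction see [detect_intrapriming()].
#' @param repeat_len see [detect_rt_switch()].
#' @return list with the retained `catalog` and a `report` data.frame
#'   (isoform_id, reason).
#' @export
filter_catalog <- function(catalog, genome, exons, min_umis = 3L,
                           window = 20L, a_fraction = 0.6, repeat_len = 8L) {
  iso <- catalog$isoforms
  if (nrow(iso) == 0L) return(list(catalog = catalog, report = data.frame()))
  idx <- annotation_index(exons)
  flag_ip <- detect_intrapriming(iso, genome, window, a_fraction)
  flag_nc <- vapply(seq_len(nrow(iso)), function(i) {
    j <- chain_junctions(iso$chain[i])
    if (nrow(j) == 0L) return(FALSE)
    keys <- paste(iso$chrom[i], iso$strand[i], j[, "donor"], j[, "acceptor"],
                  sep = "|")
    novel <- which(!(keys %in% idx$junction_keys))
    any(vapply(novel, function(k) {
      !(junction_motif(genome, iso$chrom[i], iso$strand[i],
                       j[k, "donor"], j[k, "acceptor"]) %in% CANONICAL_MOTIFS)
    }, TRUE))
  }, TRUE)
  flag_rt <- detect_rt_switch(iso, genome, idx$junction_keys, repeat_len)
  flag_low <- iso$total_umis < min_umis

  reason <- rep(NA_character_, nrow(iso))
  reason[flag_low] <- "min_umis"
  reason[flag_rt] <- "rt_switch"
  reason[flag_nc] <- "noncanonical"
  reason[flag_ip] <- "intrapriming"

  iso$flag_intrapriming <- flag_ip
  iso$flag_noncanonical <- flag_nc
  iso$flag_rt_switch <- flag_rt
  report <- data.frame(isoform_id = iso$isoform_id, reason = reason)
  report <- report[!is.na(report$reason), ]
  rownames(report) <- NULL

  keep <- is.na(reason)
  catalog$isoforms <- iso[keep, ]
  rownames(catalog$isoforms) <- NULL
  catalog$counts <- catalog$counts[catalog$counts$isoform_id %in%
                                     catalog$isoforms$isoform_id, ]
  catalog$assignment <- catalog$assignment[catalog$assignment$isoform_id %in%
                                             catalog$isoforms$isoform_id, ]
  list(catalog = catalog, report = report)
}

#' Validate isoform 5' and 3' ends against CAGE and polyA evidence
#'
#' An isoform is end-validated when its TSS lies within `window` bp of a CAGE
#' interval and its TES within `window` bp of a polyA site. Non-FSM isoforms
#' failing either check are removed; FSM isoforms are always retained, with
#' the `end_unvalidated` flag recorded.
#'
#' @param catalog classified catalog.
#' @param cage data.frame (chrom, start, end, 0-based half-open; optional
#'   strand).
#' @param polya data.frame (chrom, pos, 0-based; optional strand).
#' @param window distance threshold in bp (default 50).
#' @return list with the retained `catalog` and `removed` isoform ids.
#' @export
validate_ends <- function(catalog, cage, polya, window = 50L) {
  iso <- catalog$isoforms
  if (nrow(iso) == 0L) return(list(catalog = catalog, removed = character(0)))
  if (is.null(cage) || nrow(cage) == 0L || is.null(polya) || nrow(polya) == 0L) {
    warning("empty CAGE or polyA evidence: all non-FSM isoforms removed")
  }
  tss_ok <- vapply(seq_len(nrow(iso)), function(i) {
    if (is.null(cage) || nrow(cage) == 0L) return(FALSE)
    cc <- cage[cage$chrom == iso$chrom[i], , drop = FALSE]
    if ("strand" %in% names(cc)) cc <- cc[cc$strand == iso$strand[i], , drop = FALSE]
    if (nrow(cc) == 0L) return(FALSE)
    p <- iso$tss_pos[i]
    any(p >= cc$start - window & p <= cc$end - 1L + window)
  }, TRUE)
  tes_ok <- vapply(seq_len(nrow(iso)), function(i) {
    if (is.null(polya) || nrow(polya) == 0L) return(FALSE)
    pp <- polya[polya$chrom == iso$chrom[i], , drop = FALSE]
    if ("strand" %in% names(pp)) pp <- pp[pp$strand == iso$strand[i], , drop = FALSE]
    if (nrow(pp) == 0L) return(FALSE)
    any(abs(iso$tes_pos[i] - pp$pos) <= window)
  }, TRUE)
  iso$end_unvalidated <- !(tss_ok & tes_ok)
  drop <- iso$end_unvalidated & iso$category != "FSM"
  removed <- iso$isoform_id[drop]
  catalog$isoforms <- iso[!drop, ]
  rownames(catalog$isoforms) <- NULL
  catalog$counts <- catalog$counts[catalog$counts$isoform_id %in%
                                     catalog$isoforms$isoform_id, ]
  catalog$assignment <- catalog$assignment[catalog$assignment$isoform_id %in%
                                             catalog$isoforms$isoform_id, ]
  list(catalog = catalog, removed = removed)
}

#' Classify cell-type specificity of isoforms
#'
#' Among FSM/NIC/NNC isoforms supported by at least three reads, an isoform
#' is `cell_specific` when present in exactly one cell and
#' `cell_type_specific` when present in at least three cells, all of one cell
#' type; otherwise `shared`. Other isoforms get `NA`.
#'
#' @param catalog classified catalog.
#' @param cell_types data.frame with `cell_barcode` and `cell_type`.
#' @return the catalog with a `specificity` column added.
#' @export
specificity_class <- function(catalog, cell_types) {
  iso <- catalog$isoforms
  cnt <- catalog$counts
  unlabeled <- setdiff(unique(cnt$cell_barcode), cell_types$cell_barcode)
  if (length(unlabeled)) {
    warning(sprintf("%d cells without cell-type label excluded", length(unlabeled)))
    cnt <- cnt[!(cnt$cell_barcode %in% unlabeled), ]
  }
  ctype <- setNames(cell_types$cell_type, cell_types$cell_barcode)
  spec <- rep(NA_character_, nrow(iso))
  for (i in seq_len(nrow(iso))) {
    if (!(iso$category[i] %in% c("FSM", "NIC", "NNC"))) next
    if (iso$total_umis[i] < 3L) next
    cells <- cnt$cell_barcode[cnt$isoform_id == iso$isoform_id[i] & cnt$count > 0L]
    if (length(cells) == 0L) next
    types <- unique(ctype[cells])
    spec[i] <- if (length(cells) == 1L) "cell_specific"
    else if (length(cells) >= 3L && length(types) == 1L) "cell_type_specific"
    else "shared"
  }
  catalog$isoforms$specificity <- spec
  catalog
}

#' Full isoform-catalog pipeline
#'
#' Collapse, classify, artifact-filter, end-validate and specificity-label in
#' one call.
#'
#' @param alignments spliced-alignment records.
#' @param exons reference exon annotation.
#' @param genome DNAStringSet.
#' @param cage,polya end evidence (see [validate_ends()]).
#' @param cell_types cell-barcode to cell-type map.
#' @param min_umis minimal UMI support (default 3).
#' @param end_window end-validation window (default 50).
#' @return list with the final `catalog`, the artifact `filter_report` and
#'   the end-validation `end_removed` ids.
#' @export
run_catalog <- function(alignments, exons, genome, cage, polya, cell_types,
                        min_umis = 3L, end_window = 50L) {
  cat0 <- collapse_molecules(alignments)
  cat1 <- classify_catalog(cat0, exons)
  f <- filter_catalog(cat1, genome, exons, min_umis = min_umis)
  v <- validate_ends(f$catalog, cage, polya, window = end_window)
  out <- specificity_class(v$catalog, cell_types)
  list(catalog = out, filter_report = f$report, end_removed = v$removed)
}
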