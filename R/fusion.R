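# Fusion transcript detection from split alignments: reads aligning to two
# distinct genes on different chromosomes (or far apart on one), aggregated
# into breakpoint-clustered events with UMI support thresholds; custom
# breakpoint-reference read assignment and group-specificity Fisher tests.

# assign each alignment row to the gene with maximal overlap (same strand)
assign_genes <- function(alignments, genes) {
  ga <- GenomicRanges::GRanges(alignments$chrom, IRanges::IRanges(
    vapply(seq_len(nrow(alignments)), function(i)
      string_to_blocks(alignments$block_starts[i], alignments$block_ends[i])[1L, "start"] + 1L, 1L),
    vapply(seq_len(nrow(alignments)), function(i) {
      b <- string_to_blocks(alignments$block_starts[i], alignments$block_ends[i])
      b[nrow(b), "end"]
    }, 1L)), strand = alignments$strand)
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  ov <- GenomicRanges::findOverlaps(ga, gg)
  gene_id <- rep(NA_character_, nrow(alignments))
  q <- S4Vectors::queryHits(ov)
  gene_id[q] <- genes$gene_id[S4Vectors::subjectHits(ov)]
  gene_id
}

#' Find reads split-aligned across two separate genes
#'
#' Retains reads with loci in at least two distinct genes, each locus with at
#' least `min_locus_bp` aligned bases, where the loci lie on different
#' chromosomes or more than `min_distance` bp apart.
#'
#' @param alignments spliced-alignment records (multiple rows per read for
#'   split alignments).
#' @param genes gene table (`gene_id`, `chrom`, `strand`, `start`, `end`).
#' @param min_distance minimal same-chromosome separation (default 100,000).
#' @param min_locus_bp minimal aligned bases per locus (default 200).
#' @return the retained alignment rows with `gene_id` and `aligned_bp`
#'   columns.
#' @export
find_fusion_reads <- function(alignments, genes, min_distance = 100000L,
                              min_locus_bp = 200L) {
  if (nrow(alignments) == 0L) return(alignments[0, ])
  aln <- alignments
  aln$gene_id <- assign_genes(aln, genes)
  aln$aligned_bp <- vapply(seq_len(nrow(aln)), function(i)
    block_width(aln$block_starts[i], aln$block_ends[i]), 1L)
  keep <- unlist(lapply(split(seq_len(nrow(aln)), aln$read_id), function(ix) {
    a <- aln[ix, ]
    if (length(unique(a$gene_id[!is.na(a$gene_id)])) < 2L) return(integer(0))
    if (any(a$aligned_bp < min_locus_bp)) return(integer(0))
    spans <- lapply(ix, function(i)
      string_to_blocks(aln$block_starts[i], aln$block_ends[i]))
    ok <- FALSE
    for (i in seq_along(ix)) for (j in seq_along(ix)) {
      if (i >= j || identical(a$gene_id[i], a$gene_id[j])) next
      if (a$chrom[i] != a$chrom[j]) { ok <- TRUE; next }
      gap <- max(spans[[j]][1L, "start"] - spans[[i]][nrow(spans[[i]]), "end"],
                 spans[[i]][1L, "start"] - spans[[j]][nrow(spans[[j]]), "end"])
      if (gap > min_distance) ok <- TRUE
    }
    if (ok) ix else integer(0)
  }), use.names = FALSE)
  out <- aln[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Aggregate fusion reads into events
#'
#' Reads are grouped by gene pair and by breakpoint pair (clustered with a
#' +/- `tolerance` bp window around the first-seen breakpoints); events with
#' fewer than `min_umis` supporting molecules are dropped.
#'
#' @param fusion_reads output of [find_fusion_reads()] (UMI-deduplicated).
#' @param cell_types cell-barcode to cell-type map.
#' @param min_umis minimal supporting UMIs (default 10).
#' @param tolerance breakpoint clustering tolerance in bp (default 10).
#' @return data.frame of events: gene pair, breakpoints, `n_umis`,
#'   `n_cells`, per-cell-type counts (`celltype_counts`, `;`-separated).
#' @export
aggregate_events <- function(fusion_reads, cell_types, min_umis = 10L,
                             tolerance = 10L) {
  if (nrow(fusion_reads) == 0L) return(data.frame())
  ctype <- setNames(cell_types$cell_type, cell_types$cell_barcode)
  per_read <- lapply(split(fusion_reads, fusion_reads$read_id), function(a) {
    a <- a[seq_len(2L), ]  # 5' locus first as emitted
    b1 <- string_to_blocks(a$block_starts[1L], a$block_ends[1L])
    b2 <- string_to_blocks(a$block_starts[2L], a$block_ends[2L])
    bp5 <- if (a$strand[1L] == "+") b1[nrow(b1), "end"] - 1L else b1[1L, "start"]
    bp3 <- if (a$strand[2L] == "+") b2[1L, "start"] else b2[nrow(b2), "end"] - 1L
    data.frame(read_id = a$read_id[1L], cell_barcode = a$cell_barcode[1L],
               gene_5p = a$gene_id[1L], gene_3p = a$gene_id[2L],
               bp5 = bp5, bp3 = bp3)
  })
  reads <- do.call(rbind, per_read)
  events <- list()
  for (pair in unique(paste(reads$gene_5p, reads$gene_3p))) {
    r <- reads[paste(reads$gene_5p, reads$gene_3p) == pair, ]
    r <- r[order(r$bp5, r$bp3), ]
    cl <- integer(nrow(r)); reps <- list()
    for (i in seq_len(nrow(r))) {
      hit <- 0L
      for (k in seq_along(reps)) {
        if (abs(r$bp5[i] - reps[[k]][1L]) <= tolerance &&
            abs(r$bp3[i] - reps[[k]][2L]) <= tolerance) { hit <- k; break }
      }
      if (hit == 0L) { reps[[length(reps) + 1L]] <- c(r$bp5[i], r$bp3[i]); hit <- length(reps) }
      cl[i] <- hit
    }
    for (k in seq_along(reps)) {
      rr <- r[cl == k, ]
      tc <- table(ctype[rr$cell_barcode])
      events[[paste(pair, k)]] <- data.frame(
        gene_5p = rr$gene_5p[1L], gene_3p = rr$gene_3p[1L],
        breakpoint_5p = round_half_away(stats::median(rr$bp5)),
        breakpoint_3p = round_half_away(stats::median(rr$bp3)),
        n_umis = nrow(rr), n_cells = length(unique(rr$cell_barcode)),
        celltype_counts = paste(sprintf("%s=%d", names(tc), as.integer(tc)),
                                collapse = ";"))
    }
  }
  out <- do.call(rbind, events)
  out <- out[out$n_umis >= min_umis, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign reads to a small custom breakpoint reference
#'
#' Each read is scored against every reference sequence by best local
#' alignment (match +1, mismatch -1, unit gaps). A read is assigned when
#' exactly one sequence attains the best score with a margin of at least two
#' edits (4 score units) over the runner-up and the best alignment has at
#' least 80% identity over its overlap; otherwise it is `ambiguous` or
#' `poor`.
#'
#' @param reads named character vector of read sequences.
#' @param reference named character vector of reference sequences.
#' @param margin_edits minimal winning margin, in edits (default 2).
#' @param min_identity minimal percent identity over the aligned overlap
#'   (default 80).
#' @return data.frame: `read_id`, `assigned` (reference name or NA),
#'   `reason` (NA, `ambiguous` or `poor`), `best_score`.
#' @export
assign_reads_to_references <- function(reads, reference, margin_edits = 2L,
                                       min_identity = 80) {
  if (length(reference) == 0L) stop("empty custom reference")
  stopifnot(!is.null(names(reference)), all(nzchar(reference)))
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  refset <- Biostrings::DNAStringSet(reference)
  rows <- lapply(seq_along(reads), function(i) {
    alns <- lapply(seq_along(refset), function(k) {
      Biostrings::pairwiseAlignment(Biostrings::DNAString(reads[[i]]),
                                    refset[[k]], type = "local",
                                    substitutionMatrix = mat,
                                    gapOpening = 0, gapExtension = 1)
    })
    scores <- vapply(alns, Biostrings::score, 1)
    o <- order(-scores)
    best <- o[1L]
    margin <- if (length(scores) > 1L) scores[best] - scores[o[2L]] else Inf
    pid <- Biostrings::pid(alns[[best]])
    if (pid < min_identity) {
      data.frame(read_id = names(reads)[i], assigned = NA_character_,
                 reason = "poor", best_score = scores[best])
    } else if (margin < 2 * margin_edits) {
      data.frame(read_id = names(reads)[i], assigned = NA_character_,
                 reason = "ambiguous", best_score = scores[best])
    } else {
      data.frame(read_id = names(reads)[i], assigned = names(reference)[best],
                 reason = NA_character_, best_score = scores[best])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-specificity Fisher test per reference sequence
#'
#' For each reference sequence, a two-sided Fisher's exact test on
#' `[[group1 hits, group1 non-hits], [group2 hits, group2 non-hits]]`, where
#' non-hits are that group's reads assigned to other sequences.
#'
#' @param assignments output of [assign_reads_to_references()].
#' @param groups data.frame mapping `read_id` to `group` (exactly two groups
#'   among assigned reads).
#' @return data.frame: reference sequence, per-group hit counts, `p_value`.
#' @export
contingency_test <- function(assignments, groups) {
  grp <- setNames(groups$group, groups$read_id)
  a <- assignments[!is.na(assignments$assigned), ]
  a$group <- grp[a$read_id]
  a <- a[!is.na(a$group), ]
  gl <- sort(unique(groups$group))
  stopifnot(length(gl) == 2L)
  totals <- c(sum(a$group == gl[1L]), sum(a$group == gl[2L]))
  rows <- lapply(sort(unique(a$assigned)), function(ref) {
    h1 <- sum(a$assigned == ref & a$group == gl[1L])
    h2 <- sum(a$assigned == ref & a$group == gl[2L])
    data.frame(reference = ref, group1 = gl[1L], group2 = gl[2L],
               hits_group1 = h1, hits_group2 = h2,
               p_value = fisher2x2(h1, totals[1L] - h1, h2, totals[2L] - h2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
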