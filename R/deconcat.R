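# Deconcatenation of concatenated full-length cDNA reads: approximate primer
# scanning, segmentation between successive primer hits, tag extraction
# (barcode, UMI, polyA) with whitelist rescue, and directional UMI
# deduplication.

# matrix-level worker: all non-overlapping primer occurrences in one read,
# columns start/end/edit/kind (1 forward, 2 reverse) / strand (1 +, 2 -),
# sorted by start; overlaps resolved lowest edit first, then leftmost
primer_patterns <- function(forward_primer, reverse_primer) {
  list(list(seq = forward_primer, kind = 1L, strand = 1L),
       list(seq = reverse_primer, kind = 2L, strand = 1L),
       list(seq = revcomp(forward_primer), kind = 1L, strand = 2L),
       list(seq = revcomp(reverse_primer), kind = 2L, strand = 2L))
}

hits_matrix <- function(read, pats, max_edit) {
  cand <- lapply(pats, function(p) {
    m <- cpp_scan_edit(read, p$seq, as.integer(max_edit))
    if (nrow(m) == 0L) return(NULL)
    cbind(m, kind = p$kind, strand = p$strand)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) {
    return(matrix(integer(0), ncol = 5,
                  dimnames = list(NULL, c("start", "end", "edit", "kind", "strand"))))
  }
  cand <- cand[order(cand[, "edit"], cand[, "start"]), , drop = FALSE]
  keep <- logical(nrow(cand))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand[i, "start"] < occ_e & cand[i, "end"] > occ_s)) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, cand[i, "start"]); occ_e <- c(occ_e, cand[i, "end"])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out[, "start"]), , drop = FALSE]
}

# matrix-level worker: gaps between successive hits with orientation codes
# (1 sense, 2 antisense, 0 invalid pair)
gaps_matrix <- function(hm) {
  n <- nrow(hm)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 7,
                  dimnames = list(NULL, c("start", "end", "lkind", "lstrand",
                                          "rkind", "rstrand", "orient"))))
  }
  i <- seq_len(n - 1L)
  orient <- integer(n - 1L)
  sense <- hm[i, "kind"] == 1L & hm[i, "strand"] == 1L &
    hm[i + 1L, "kind"] == 2L & hm[i + 1L, "strand"] == 1L
  anti <- hm[i, "kind"] == 2L & hm[i, "strand"] == 2L &
    hm[i + 1L, "kind"] == 1L & hm[i + 1L, "strand"] == 2L
  orient[sense] <- 1L; orient[anti] <- 2L
  cbind(start = hm[i, "end"], end = hm[i + 1L, "start"],
        lkind = hm[i, "kind"], lstrand = hm[i, "strand"],
        rkind = hm[i + 1L, "kind"], rstrand = hm[i + 1L, "strand"],
        orient = orient)
}

#' Locate approximate primer occurrences in a read
#'
#' Finds all non-overlapping occurrences of the forward or reverse primer, or
#' their reverse complements, within `max_edit` edits (substitutions and
#' indels). Overlapping candidates are resolved lowest edit distance first,
#' then leftmost.
#'
#' @param read a single read sequence (character).
#' @param forward_primer,reverse_primer primer sequences.
#' @param max_edit maximal edit distance (default 3).
#' @return data.frame with `primer_kind` (`forward`/`reverse`), `strand`
#'   (`+` for the primer as given, `-` for its reverse complement), `start`,
#'   `end` (0-based half-open offsets) and `edit_distance`, sorted by start.
#' @export
find_primer_hits <- function(read, forward_primer = LRISO_FWD_PRIMER,
                             reverse_primer = LRISO_REV_PRIMER, max_edit = 3L) {
  stopifnot(nchar(forward_primer) > 0L, nchar(reverse_primer) > 0L, max_edit >= 0L)
  if (is.na(read) || nchar(read) == 0L) {
    return(data.frame(primer_kind = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      edit_distance = integer(0)))
  }
  hm <- hits_matrix(read, primer_patterns(forward_primer, reverse_primer),
                    max_edit)
  data.frame(primer_kind = c("forward", "reverse")[hm[, "kind"]],
             strand = c("+", "-")[hm[, "strand"]],
             start = unname(hm[, "start"]), end = unname(hm[, "end"]),
             edit_distance = unname(hm[, "edit"]))
}

#' Split a read into candidate segments between successive primer hits
#'
#' One candidate per gap between successive hits; read flanks outside the
#' outermost primers are excluded. A segment is valid only when its bounding
#' primers form a correctly oriented pair: `forward(+) -> reverse(+)`
#' (segment in sense orientation) or `reverse(-) -> forward(-)` (segment
#' reverse-complemented).
#'
#' @param read read sequence.
#' @param hits primer hits from [find_primer_hits()], sorted by start.
#' @return data.frame with `start`, `end` (0-based gap coordinates),
#'   bounding `left_kind`/`left_strand`/`right_kind`/`right_strand`,
#'   `orientation` (`+`, `-`, or NA) and `valid`.
#' @export
split_segments <- function(read, hits) {
  if (is.null(hits) || nrow(hits) < 2L) {
    return(data.frame(start = integer(0), end = integer(0),
                      left_kind = character(0), left_strand = character(0),
                      right_kind = character(0), right_strand = character(0),
                      orientation = character(0), valid = logical(0),
                      sequence = character(0)))
  }
  stopifnot(!is.unsorted(hits$start))
  hm <- cbind(start = hits$start, end = hits$end, edit = hits$edit_distance,
              kind = match(hits$primer_kind, c("forward", "reverse")),
              strand = match(hits$strand, c("+", "-")))
  gm <- gaps_matrix(hm)
  out <- data.frame(start = unname(gm[, "start"]), end = unname(gm[, "end"]),
                    left_kind = c("forward", "reverse")[gm[, "lkind"]],
                    left_strand = c("+", "-")[gm[, "lstrand"]],
                    right_kind = c("forward", "reverse")[gm[, "rkind"]],
                    right_strand = c("+", "-")[gm[, "rstrand"]],
                    orientation = c(NA_character_, "+", "-")[gm[, "orient"] + 1L])
  out$valid <- !is.na(out$orientation) & out$end > out$start
  out$sequence <- substr(rep(read, nrow(out)), out$start + 1L, out$end)
  out
}

#' Extract barcode, UMI and polyA status from a valid segment
#'
#' After orientation normalization (barcode end at the 5' primer side) the
#' segment reads `barcode(16) + UMI(12) + polyT tract + reverse-complemented
#' cDNA`. The polyA tail is detected, in cDNA sense orientation, as a 3' run
#' of at least `polya_min_run` bases with at most 10% non-A, and trimmed.
#' Barcodes must match the whitelist exactly or have a unique Hamming-1
#' neighbour in it.
#'
#' @param segment segment sequence (between the primers).
#' @param orientation `"+"` or `"-"` as reported by [split_segments()].
#' @param whitelist character vector of valid 16 nt barcodes.
#' @param polya_min_run minimal qualifying polyA run (default 20).
#' @return list with `accepted` (logical), `reason` (`NA`,
#'   `"too_short"`, `"no_barcode_match"`, `"no_polya"`), and for accepted
#'   segments `cell_barcode`, `umi`, `cdna` (sense, polyA trimmed).
#' @export
extract_tags <- function(segment, orientation, whitelist, polya_min_run = 20L) {
  res <- extract_tags_batch(segment, orientation, whitelist, polya_min_run)
  out <- list(accepted = res$accepted[1L], reason = res$reason[1L])
  if (out$accepted) {
    out$cell_barcode <- res$cell_barcode[1L]
    out$umi <- res$umi[1L]
    out$cdna <- res$cdna[1L]
  }
  out
}

# vectorized worker shared by extract_tags() and deconcat_reads()
extract_tags_batch <- function(segments, orientations, whitelist,
                               polya_min_run = 20L) {
  n <- length(segments)
  seqs <- segments
  minus <- orientations == "-"
  if (any(minus)) seqs[minus] <- revcomp(segments[minus])
  reason <- rep(NA_character_, n)
  too_short <- nchar(seqs) < 28L + polya_min_run
  reason[too_short] <- "too_short"

  bc <- substr(seqs, 1L, 16L)
  umi <- substr(seqs, 17L, 28L)
  rest <- substr(seqs, 29L, nchar(seqs))

  idx <- cpp_match_hamming1(bc, whitelist)
  no_bc <- idx <= 0L
  reason[is.na(reason) & no_bc] <- "no_barcode_match"
  bc[idx > 0L] <- whitelist[idx[idx > 0L]]

  # the sense-orientation polyA tail is the leading polyT tract of `rest`
  run <- cpp_prefix_run(rest, "T", 0.10)
  no_pa <- run < polya_min_run
  reason[is.na(reason) & no_pa] <- "no_polya"

  cdna <- revcomp(substr(rest, run + 1L, nchar(rest)))
  accepted <- is.na(reason) & nchar(cdna) > 0L
  reason[is.na(reason) & !accepted] <- "too_short"
  data.frame(accepted = accepted, reason = reason, cell_barcode = bc,
             umi = umi, cdna = cdna)
}

#' Deconcatenate a read set into tagged cDNA molecules
#'
#' Runs primer scanning, segmentation and tag extraction over a read set and
#' returns accepted molecules plus a rejection report. Every candidate
#' segment is either accepted or rejected with exactly one primary reason
#' (`wrong_pair` for misoriented/missing primer pairs, then `too_short`,
#' `no_barcode_match`, `no_polya`).
#'
#' @param reads named character vector (or DNAStringSet) of reads.
#' @param whitelist character vector of valid barcodes.
#' @param forward_primer,reverse_primer,max_edit see [find_primer_hits()].
#' @param polya_min_run see [extract_tags()].
#' @return list with `molecules` (molecule_id, cell_barcode, umi, cdna,
#'   source_read_id, segment_index) and `rejections` (read, segment index,
#'   reason).
#' @export
deconcat_reads <- function(reads, whitelist,
                           forward_primer = LRISO_FWD_PRIMER,
                           reverse_primer = LRISO_REV_PRIMER,
                           max_edit = 3L, polya_min_run = 20L) {
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("R%05d", seq_along(reads))
  nr <- length(reads)
  pats <- primer_patterns(forward_primer, reverse_primer)
  seq_l <- vector("list", nr); ori_l <- vector("list", nr)
  rid_l <- vector("list", nr); sidx_l <- vector("list", nr)
  valid_l <- vector("list", nr)
  for (r in seq_len(nr)) {
    hm <- hits_matrix(reads[[r]], pats, max_edit)
    gm <- gaps_matrix(hm)
    ng <- nrow(gm)
    if (ng == 0L) next
    ok <- gm[, "orient"] > 0L & gm[, "end"] > gm[, "start"]
    seqs <- character(ng)
    seqs[ok] <- substr(rep(reads[[r]], sum(ok)), gm[ok, "start"] + 1L,
                       gm[ok, "end"])
    seq_l[[r]] <- seqs
    ori_l[[r]] <- c("wrong", "+", "-")[ifelse(ok, gm[, "orient"] + 1L, 1L)]
    rid_l[[r]] <- rep(names(reads)[r], ng)
    sidx_l[[r]] <- seq_len(ng)
    valid_l[[r]] <- ok
  }
  seqs <- unlist(seq_l); oris <- unlist(ori_l)
  rids <- unlist(rid_l); sidx <- unlist(sidx_l); valid <- unlist(valid_l)
  if (length(seqs) == 0L) {
    return(list(molecules = data.frame(), rejections = data.frame()))
  }
  reason <- rep(NA_character_, length(seqs))
  reason[!valid] <- "wrong_pair"
  ok <- which(valid)
  molecules <- data.frame()
  if (length(ok)) {
    tags <- extract_tags_batch(seqs[ok], oris[ok], whitelist, polya_min_run)
    reason[ok] <- tags$reason
    acc <- ok[tags$accepted]
    molecules <- data.frame(
      molecule_id = sprintf("D%06d", seq_along(acc)),
      cell_barcode = tags$cell_barcode[tags$accepted],
      umi = tags$umi[tags$accepted],
      has_polya = TRUE,
      cdna = tags$cdna[tags$accepted],
      source_read_id = rids[acc],
      segment_index = sidx[acc])
  }
  rej <- which(!is.na(reason))
  rejections <- data.frame(read_id = rids[rej], segment_index = sidx[rej],
                           reason = reason[rej])
  list(molecules = molecules, rejections = rejections)
}

#' Directional UMI deduplication within cells
#'
#' Within each cell barcode, molecules whose UMIs are identical or within
#' Hamming distance 1 are merged, lower-count UMIs into higher-count ones
#' (directional merge). The representative keeps the longest cDNA and reports
#' the number of merged members as its read count.
#'
#' @param molecules data.frame with `cell_barcode`, `umi`, `cdna` columns.
#' @return deduplicated data.frame with an added `read_count` column.
#' @export
dedup_umis <- function(molecules) {
  if (nrow(molecules) == 0L) {
    molecules$read_count <- integer(0)
    return(molecules)
  }
  out <- lapply(split(molecules, molecules$cell_barcode), function(cellm) {
    tab <- table(cellm$umi)
    umis <- names(tab)
    # deterministic order: count desc, then UMI
    ordu <- order(-as.integer(tab), umis)
    umis <- umis[ordu]; cnt <- as.integer(tab)[ordu]
    cluster <- integer(length(umis))
    for (i in seq_along(umis)) {
      if (cluster[i] != 0L) next
      cluster[i] <- i
      if (i < length(umis)) {
        rest <- which(cluster == 0L)
        rest <- rest[rest > i]
        if (length(rest)) {
          d <- cpp_hamming(rep(umis[i], length(rest)), umis[rest])
          cluster[rest[!is.na(d) & d <= 1L]] <- i
        }
      }
    }
    reps <- lapply(unique(cluster), function(cl) {
      members <- cellm[cellm$umi %in% umis[cluster == cl], , drop = FALSE]
      rep_row <- members[which.max(nchar(members$cdna)), , drop = FALSE]
      rep_row$umi <- umis[which(cluster == cl)[1L]]
      rep_row$read_count <- nrow(members)
      rep_row
    })
    do.call(rbind, reps)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
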