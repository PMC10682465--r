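# Panel-guided mutation calling per cell: count reference and alternative
# bases per cell at panel positions; a cell is mutated at a variant as soon
# as one alternative read is seen; variants mutated in any distal-biopsy cell
# are germline, the rest somatic.

parse_base_calls <- function(base_calls) {
  # "chrom:pos=B;chrom:pos=B" -> data.frame(chrom, pos, base)
  if (is.na(base_calls) || base_calls == "") {
    return(data.frame(chrom = character(0), pos = integer(0), base = character(0)))
  }
  parts <- strsplit(strsplit(base_calls, ";", fixed = TRUE)[[1]], "[:=]")
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             base = vapply(parts, `[`, "", 3L))
}

#' Call panel mutations per cell
#'
#' Counts alternative and reference reads per cell at each panel position
#' (1-based). A cell is mutated at a variant when it has at least `min_alt`
#' alternative reads. Cells without coverage at a position yield no call
#' (absence is not wild-type).
#'
#' @param alignments spliced-alignment records with a `base_calls` column.
#' @param panel data.frame: `chrom`, `pos` (1-based), `ref`, `alt`, `gene`.
#' @param min_alt minimal alternative reads to call a cell mutated
#'   (default 1).
#' @return data.frame: cell, variant, `n_alt`, `n_ref`, `mutated`.
#' @export
call_mutations <- function(alignments, panel, min_alt = 1L) {
  calls <- list()
  withbc <- which(!is.na(alignments$base_calls) & alignments$base_calls != "")
  obs <- do.call(rbind, lapply(withbc, function(i) {
    b <- parse_base_calls(alignments$base_calls[i])
    b$cell_barcode <- alignments$cell_barcode[i]
    b
  }))
  rows <- list()
  for (v in seq_len(nrow(panel))) {
    o <- obs[obs$chrom == panel$chrom[v] & obs$pos == panel$pos[v], , drop = FALSE]
    if (is.null(o) || nrow(o) == 0L) next
    for (cell in unique(o$cell_barcode)) {
      bases <- o$base[o$cell_barcode == cell]
      n_alt <- sum(bases == panel$alt[v])
      n_ref <- sum(bases == panel$ref[v])
      rows[[paste(v, cell)]] <- data.frame(
        cell_barcode = cell, chrom = panel$chrom[v], pos = panel$pos[v],
        ref = panel$ref[v], alt = panel$alt[v], gene = panel$gene[v],
        n_alt = n_alt, n_ref = n_ref, mutated = n_alt >= min_alt)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(cell_barcode = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      gene = character(0), n_alt = integer(0),
                      n_ref = integer(0), mutated = logical(0)))
  }
  rownames(out) <- NULL
  out
}

#' Classify variants as germline or somatic
#'
#' A variant mutated in at least one cell from a distal (tumor-free) biopsy
#' is germline; a variant mutated only in tumor-site cells is somatic;
#' variants with no mutated cell are unclassified.
#'
#' @param calls output of [call_mutations()].
#' @param samples data.frame mapping `cell_barcode` to `sample`
#'   (`tumor`/`distal`).
#' @return data.frame: variant, mutated-cell counts per sample class,
#'   `classification`.
#' @export
classify_variants <- function(calls, samples) {
  smp <- setNames(samples$sample, samples$cell_barcode)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  rows <- lapply(unique(key), function(k) {
    cc <- calls[key == k, ]
    mut <- cc[cc$mutated, , drop = FALSE]
    n_tumor <- sum(smp[mut$cell_barcode] == "tumor", na.rm = TRUE)
    n_distal <- sum(smp[mut$cell_barcode] == "distal", na.rm = TRUE)
    cls <- if (nrow(mut) == 0L) "unclassified"
           else if (n_distal >= 1L) "germline" else "somatic"
    data.frame(chrom = cc$chrom[1L], pos = cc$pos[1L], ref = cc$ref[1L],
               alt = cc$alt[1L], gene = cc$gene[1L],
               mutated_cells_tumor = n_tumor, mutated_cells_distal = n_distal,
               classification = cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
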