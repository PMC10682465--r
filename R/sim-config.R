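#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator: the
#' gene/isoform architecture, per-cell-type isoform usage mixtures, the
#' two-site 3'UTR polyadenylation model, the concatenated read structure
#' (primer + 16 nt barcode + 12 nt UMI + polyT + cDNA repeats), optional gene
#' fusions and implanted variants. One top-level seed determines every output;
#' generator stages use fixed seed offsets so each stage is reproducible on
#' its own.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_genes number of simulated genes (>= 1).
#' @param cell_types character vector of cell-type (condition) names.
#' @param cells_per_type number of cells per cell type.
#' @param cell_type_sample named character vector mapping each cell type to a
#'   biopsy label, `"tumor"` or `"distal"`; defaults to the first type tumor,
#'   the rest distal. Used by the mutation germline/somatic rule.
#' @param isoform_usage `NULL` (per gene x cell type usage drawn from a
#'   symmetric Dirichlet) or a data.frame with columns `gene_id`, `cell_type`,
#'   `isoform_index`, `prop`; proportions per gene and cell type must sum to 1.
#' @param apa_distal_fraction `NULL` (drawn uniformly in \[0.2, 0.9\]), a
#'   single value in \[0, 1\] applied everywhere, or a data.frame with columns
#'   `gene_id`, `cell_type`, `fraction`.
#' @param utr_length annotated 3'UTR length in nt; must exceed 101 so both
#'   50 nt windows of the two-site model fit.
#' @param mean_segments_per_read mean number of cDNA segments concatenated per
#'   sequencing read (truncated Poisson, minimum 1). Default 4, the
#'   concatenation factor the library design targets.
#' @param error_rate per-base substitution probability applied to rendered
#'   reads (HiFi-like, substitution-dominated).
#' @param umis_per_cell_gene mean number of molecules per cell per gene
#'   (Poisson).
#' @param artifact_fraction fraction of rendered segments turned into library
#'   artifacts (half lack the polyA tract, half lack one primer).
#' @param n_isoforms optional integer vector (length `n_genes`) of isoform
#'   counts per gene; by default every third gene is single-isoform and the
#'   rest carry 2-3 isoforms.
#' @param fusion_spec `NULL` or a list with elements `gene_5p`, `gene_3p`
#'   (gene ids or indices; must lie on different chromosomes), `n_umis`, and
#'   `cell_type` (the carrier cell type).
#' @param variant_spec `NULL` or a data.frame with columns `gene` (id or
#'   index), `carriers` (comma-separated carrier cell types),
#'   `allele_fraction`, and optionally `chrom`, `position` (1-based), `ref`,
#'   `alt`; unspecified positions are placed mid first exon by
#'   [simulate_reference()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       cell_types = c("tumor", "distal"),
                       cells_per_type = 100L,
                       cell_type_sample = NULL,
                       isoform_usage = NULL,
                       apa_distal_fraction = NULL,
                       utr_length = 300L,
                       mean_segments_per_read = 4,
                       error_rate = 0.002,
                       umis_per_cell_gene = 1,
                       artifact_fraction = 0,
                       n_isoforms = NULL,
                       fusion_spec = NULL,
                       variant_spec = NULL) {
  stopifnot(n_genes >= 1L, cells_per_type >= 1L, length(cell_types) >= 1L,
            utr_length > 101L, mean_segments_per_read > 0,
            error_rate >= 0, error_rate <= 1,
            artifact_fraction >= 0, artifact_fraction < 1,
            umis_per_cell_gene > 0)
  if (anyDuplicated(cell_types)) stop("cell_types must be unique")
  if (is.null(cell_type_sample)) {
    cell_type_sample <- setNames(
      c("tumor", rep("distal", length(cell_types) - 1L)), cell_types)
  }
  if (!all(cell_types %in% names(cell_type_sample)) ||
      !all(cell_type_sample %in% c("tumor", "distal"))) {
    stop("cell_type_sample must map every cell type to 'tumor' or 'distal'")
  }
  if (!is.null(isoform_usage)) {
    need <- c("gene_id", "cell_type", "isoform_index", "prop")
    if (!all(need %in% names(isoform_usage))) {
      stop("isoform_usage needs columns ", paste(need, collapse = ", "))
    }
    sums <- tapply(isoform_usage$prop,
                   paste(isoform_usage$gene_id, isoform_usage$cell_type), sum)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("isoform usage proportions must sum to 1 per gene and cell type")
    }
  }
  if (is.numeric(apa_distal_fraction) && length(apa_distal_fraction) == 1L) {
    stopifnot(apa_distal_fraction >= 0, apa_distal_fraction <= 1)
  }
  if (!is.null(n_isoforms)) {
    stopifnot(length(n_isoforms) == n_genes, all(n_isoforms >= 1L))
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              cell_types = cell_types,
              cells_per_type = as.integer(cells_per_type),
              cell_type_sample = cell_type_sample,
              isoform_usage = isoform_usage,
              apa_distal_fraction = apa_distal_fraction,
              utr_length = as.integer(utr_length),
              mean_segments_per_read = mean_segments_per_read,
              error_rate = error_rate,
              umis_per_cell_gene = umis_per_cell_gene,
              artifact_fraction = artifact_fraction,
              n_isoforms = n_isoforms,
              fusion_spec = fusion_spec,
              variant_spec = variant_spec)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic long-read scRNA-seq configuration\n")
  cat(sprintf("  %d genes, %d cell types (%s), %d cells/type, seed %d\n",
              x$n_genes, length(x$cell_types),
              paste(x$cell_types, collapse = ", "), x$cells_per_type, x$seed))
  cat(sprintf("  3'UTR %d nt, mean %.2g segments/read, error rate %.4g\n",
              x$utr_length, x$mean_segments_per_read, x$error_rate))
  if (!is.null(x$fusion_spec)) cat("  fusion implanted\n")
  if (!is.null(x$variant_spec)) {
    cat(sprintf("  %d variants implanted\n", nrow(as.data.frame(x$variant_spec))))
  }
  invisible(x)
}
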