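# Differential isoform usage between two conditions: Pearson chi-squared on
# the per-gene isoform x condition UMI table, isoform usage shares Pi (in
# percent), per-isoform DeltaPi, the top-two-by-direction DeltaPi sum, the
# (p_adj <= 0.05 AND top2 > 20 points) calling rule, rank-product gene
# ranking, and biotype/noncoding accounting.

#' Per-gene isoform x condition count tables
#'
#' @param counts long count table (`isoform_id`, `cell_barcode`, `count`).
#' @param groups cell-barcode to condition map (`cell_barcode`, `condition`).
#' @param c1,c2 the two condition names (table columns, in this order).
#' @param isoform_genes data.frame mapping `isoform_id` to `gene_id`.
#' @return named list (by gene) of integer matrices, isoforms x 2 conditions.
#' @export
isoform_count_tables <- function(counts, groups, c1, c2, isoform_genes) {
  cond_of <- setNames(groups$condition, groups$cell_barcode)
  gene_of <- setNames(isoform_genes$gene_id, isoform_genes$isoform_id)
  x <- counts
  x$condition <- cond_of[x$cell_barcode]
  x <- x[x$condition %in% c(c1, c2) & !is.na(gene_of[x$isoform_id]), ]
  x$gene_id <- gene_of[x$isoform_id]
  tabs <- lapply(split(x, x$gene_id), function(g) {
    m <- tapply(g$count, list(g$isoform_id, factor(g$condition, c(c1, c2))),
                sum, default = 0L)
    m <- matrix(as.integer(m), nrow = nrow(m),
                dimnames = list(rownames(m), c(c1, c2)))
    m
  })
  tabs
}

#' Select genes testable for differential isoform usage
#'
#' A gene is excluded when its name matches the mitochondrial/ribosomal
#' pattern, when any condition's total count is below `min_depth` (25 reads
#' per condition, inclusive), or when it has fewer than two isoforms.
#'
#' @param tables named list of isoform x condition count matrices.
#' @param min_depth minimal reads per condition (default 25).
#' @param exclude_pattern regular expression on gene names for
#'   mitochondrial/ribosomal exclusion.
#' @return list with `tables` (testable) and `exclusions` (gene, reason).
#' @export
filter_testable <- function(tables, min_depth = 25L,
                            exclude_pattern = "^(MT-|RPS|RPL|MRPS|MRPL)") {
  reason <- vapply(names(tables), function(g) {
    m <- tables[[g]]
    if (grepl(exclude_pattern, g)) return("mito_ribo")
    if (nrow(m) < 2L) return("single_isoform")
    if (any(colSums(m) < min_depth)) return("depth")
    NA_character_
  }, "")
  excl <- data.frame(gene_id = names(tables), reason = reason)
  excl <- excl[!is.na(excl$reason), ]
  rownames(excl) <- NULL
  list(tables = tables[is.na(reason)], exclusions = excl)
}

# summed two largest DeltaPi of common sign (single-signed entries sum alone)
top2_direction_sum <- function(delta) {
  pos <- sort(delta[delta > 0], decreasing = TRUE)
  neg <- sort(delta[delta < 0])
  up <- sum(pos[seq_len(min(2L, length(pos)))])
  down <- abs(sum(neg[seq_len(min(2L, length(neg)))]))
  max(up, down, 0)
}

#' Chi-squared test of differential isoform usage for one gene
#'
#' Pearson's chi-squared without continuity correction on the isoform x
#' condition table. Pi vectors are column-normalized percentages; DeltaPi is
#' their per-isoform difference (condition 1 minus condition 2) in percentage
#' points.
#'
#' @param table isoform x 2 condition count matrix.
#' @return list with `result` (one-row data.frame: p_value, top2_sum,
#'   statistic, df, low_expected) and `delta_pi` (per-isoform Pi and DeltaPi).
#' @export
test_gene <- function(table) {
  stopifnot(ncol(table) == 2L, nrow(table) >= 2L, all(colSums(table) > 0L))
  m <- table[rowSums(table) > 0L, , drop = FALSE]
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  pi1 <- 100 * table[, 1L] / sum(table[, 1L])
  pi2 <- 100 * table[, 2L] / sum(table[, 2L])
  delta <- pi1 - pi2
  list(result = data.frame(p_value = unname(ht$p.value),
                           statistic = unname(ht$statistic),
                           df = unname(ht$parameter),
                           top2_sum = top2_direction_sum(delta),
                           low_expected = any(ht$expected < 5)),
       delta_pi = data.frame(isoform_id = rownames(table),
                             pi_c1 = unname(pi1), pi_c2 = unname(pi2),
                             delta_pi = unname(delta)))
}

#' Differential calling rule
#'
#' A gene is called differentially spliced when its BH-adjusted p-value is at
#' most `alpha` (inclusive) and the top-two DeltaPi sum exceeds
#' `delta_threshold` percentage points (strict).
#'
#' @param results data.frame with `p_adjusted` and `top2_sum`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param delta_threshold DeltaPi threshold in percentage points (default 20).
#' @return the data.frame with a logical `called` column.
#' @export
call_differential <- function(results, alpha = 0.05, delta_threshold = 20) {
  results$called <- results$p_adjusted <= alpha &
    results$top2_sum > delta_threshold
  results
}

#' Rank called genes by combined effect-size and significance rank
#'
#' rank_score = sqrt(rank by descending top2_sum x rank by ascending
#' adjusted p); smaller is better. Output ascending by score, ties broken by
#' gene id.
#'
#' @param results data.frame of called genes with `gene_id`, `top2_sum`,
#'   `p_adjusted`.
#' @return the data.frame with `rank_score`, ordered.
#' @export
rank_genes <- function(results) {
  stopifnot(nrow(results) >= 1L)
  r_dpi <- rank(-results$top2_sum, ties.method = "average")
  r_p <- rank(results$p_adjusted, ties.method = "average")
  results$rank_score <- sqrt(r_dpi * r_p)
  results <- results[order(results$rank_score, results$gene_id), ]
  rownames(results) <- NULL
  results
}

#' Full differential isoform usage analysis
#'
#' Filters testable genes, tests each with the chi-squared statistic, adjusts
#' p-values with BH across all tested genes, applies the calling rule, and
#' ranks called genes.
#'
#' @param tables named list of isoform x 2 condition count matrices.
#' @param min_depth,exclude_pattern see [filter_testable()].
#' @param alpha,delta_threshold see [call_differential()].
#' @return list with `results` (per tested gene), `delta_pi` (long format),
#'   `called` (ranked called subset) and `exclusions`.
#' @export
run_diff_usage <- function(tables, min_depth = 25L,
                           exclude_pattern = "^(MT-|RPS|RPL|MRPS|MRPL)",
                           alpha = 0.05, delta_threshold = 20) {
  ft <- filter_testable(tables, min_depth, exclude_pattern)
  if (!length(ft$tables)) {
    return(list(results = data.frame(), delta_pi = data.frame(),
                called = data.frame(), exclusions = ft$exclusions))
  }
  tests <- lapply(names(ft$tables), function(g) {
    t <- test_gene(ft$tables[[g]])
    t$result$gene_id <- g
    t$delta_pi$gene_id <- g
    t
  })
  results <- do.call(rbind, lapply(tests, `[[`, "result"))
  delta_pi <- do.call(rbind, lapply(tests, `[[`, "delta_pi"))
  results$p_adjusted <- p.adjust(results$p_value, method = "BH")
  results <- call_differential(results, alpha, delta_threshold)
  called <- results[results$called, ]
  if (nrow(called)) called <- rank_genes(called)
  results <- results[, c("gene_id", "p_value", "p_adjusted", "statistic",
                         "df", "top2_sum", "low_expected", "called")]
  list(results = results, delta_pi = delta_pi, called = called,
       exclusions = ft$exclusions)
}

#' Biotype change of the top expressed isoform between conditions
#'
#' For each called gene, compares the biotype of the most expressed isoform
#' in each condition (ties: larger count in the other condition, then
#' lexicographic isoform id). The transition label classifies isoforms as
#' protein_coding vs non_coding.
#'
#' @param tables named list of count matrices.
#' @param biotypes data.frame mapping `isoform_id` to `biotype`.
#' @param genes gene ids to evaluate (default: all in `tables`).
#' @return data.frame: gene, top isoform and biotype per condition,
#'   `changed`, `transition`.
#' @export
biotype_change <- function(tables, biotypes, genes = names(tables)) {
  bio_of <- setNames(biotypes$biotype, biotypes$isoform_id)
  cls <- function(b) ifelse(b == "protein_coding", "protein_coding", "non_coding")
  rows <- lapply(genes, function(g) {
    m <- tables[[g]]
    top_of <- function(col, other) {
      o <- order(-m[, col], -m[, other], rownames(m))
      rownames(m)[o[1L]]
    }
    t1 <- top_of(1L, 2L); t2 <- top_of(2L, 1L)
    b1 <- unname(bio_of[t1]); b2 <- unname(bio_of[t2])
    changed <- !identical(b1, b2)
    data.frame(gene_id = g, top_c1 = t1, top_c2 = t2,
               biotype_c1 = b1, biotype_c2 = b2, changed = changed,
               transition = if (changed) paste0(cls(b1), "->", cls(b2))
                            else NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noncoding expression fraction of protein-coding genes
#'
#' For protein-coding genes with at least `min_umis` UMIs in a condition, the
#' ratio of UMIs on non-protein-coding isoforms (NMD, retained intron, ...)
#' to total gene expression in that condition.
#'
#' @param tables named list of count matrices.
#' @param biotypes isoform biotype map.
#' @param gene_biotypes data.frame mapping `gene_id` to `gene_biotype`.
#' @param min_umis minimal per-condition expression (default 20).
#' @return data.frame: gene, condition, total and noncoding UMIs, `fraction`.
#' @export
noncoding_fraction <- function(tables, biotypes, gene_biotypes, min_umis = 20L) {
  bio_of <- setNames(biotypes$biotype, biotypes$isoform_id)
  gbio <- setNames(gene_biotypes$gene_biotype, gene_biotypes$gene_id)
  rows <- list()
  for (g in names(tables)) {
    if (is.na(gbio[g]) || gbio[g] != "protein_coding") next
    m <- tables[[g]]
    nc <- bio_of[rownames(m)] != "protein_coding"
    for (cond in colnames(m)) {
      total <- sum(m[, cond])
      if (total < min_umis) next
      rows[[paste(g, cond)]] <- data.frame(
        gene_id = g, condition = cond, total_umis = total,
        noncoding_umis = sum(m[nc, cond]),
        fraction = sum(m[nc, cond]) / total)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}
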