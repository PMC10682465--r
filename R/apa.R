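# Alternative polyadenylation under the two-site 3'UTR model: distal site =
# the most 3' position with coverage above a threshold in any cell type;
# proximal site = the position maximizing the squared gap between the mean
# coverage of the 50 nt windows after and before it; per-condition distal
# usage F = W_d / (W_d + W_p); pairwise Fraction Change with a two-sided
# Fisher test on rounded window means and BH correction across genes.

#' Build testable 3'UTR regions from annotation
#'
#' Groups of overlapping 3'UTR exons sharing the same 5' start are merged to
#' their union; a gene with overlapping 3'UTR exons whose 5' starts differ is
#' dropped entirely (such configurations create false-positive APA calls).
#' Non-overlapping alternative last exons are retained as separate regions.
#'
#' @param utr3 data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open 3'UTR exon intervals, one row per transcript).
#' @return data.frame of regions: `gene_id`, `region_id`, `chrom`, `strand`,
#'   `start`, `end`, `L`.
#' @export
build_utr_regions <- function(utr3) {
  out <- list()
  for (gid in unique(utr3$gene_id)) {
    u <- utr3[utr3$gene_id == gid, , drop = FALSE]
    u <- u[order(u$start), ]
    ir <- IRanges::IRanges(u$start + 1L, u$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    dropped <- FALSE
    regions <- list()
    for (k in seq_along(red)) {
      members <- u[revmap[[k]], , drop = FALSE]
      fivep <- if (members$strand[1L] == "+") members$start else members$end
      if (length(unique(fivep)) > 1L) { dropped <- TRUE; break }
      regions[[k]] <- data.frame(gene_id = gid,
                                 region_id = sprintf("%s.U%d", gid, k),
                                 chrom = members$chrom[1L],
                                 strand = members$strand[1L],
                                 start = min(members$start),
                                 end = max(members$end))
    }
    if (!dropped) out <- c(out, regions)
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), region_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0), L = integer(0)))
  }
  res <- do.call(rbind, out)
  res$L <- res$end - res$start
  rownames(res) <- NULL
  res
}

#' Per-condition 3'UTR coverage matrix
#'
#' Exact per-base read coverage over one UTR region, summed per condition and
#' reported in transcript (5'->3') orientation: index 1 is the UTR 5' end
#' regardless of genomic strand.
#'
#' @param alignments spliced-alignment records.
#' @param region one row of [build_utr_regions()] output.
#' @param groups data.frame mapping `cell_barcode` to `condition`.
#' @param conditions condition order for the matrix rows (default: unique
#'   values of `groups$condition`).
#' @return integer matrix, conditions x L.
#' @export
utr_coverage <- function(alignments, region, groups,
                         conditions = unique(groups$condition)) {
  L <- region$end - region$start
  w <- matrix(0L, nrow = length(conditions), ncol = L,
              dimnames = list(conditions, NULL))
  cond_of <- setNames(groups$condition, groups$cell_barcode)
  aln <- alignments[alignments$chrom == region$chrom &
                      alignments$strand == region$strand, , drop = FALSE]
  if (nrow(aln) == 0L) return(w)
  for (i in seq_len(nrow(aln))) {
    cond <- cond_of[aln$cell_barcode[i]]
    if (is.na(cond) || !(cond %in% conditions)) next
    b <- string_to_blocks(aln$block_starts[i], aln$block_ends[i])
    diffv <- integer(L + 1L)
    hit <- FALSE
    for (k in seq_len(nrow(b))) {
      s <- max(b[k, "start"], region$start); e <- min(b[k, "end"], region$end)
      if (s >= e) next
      diffv[s - region$start + 1L] <- diffv[s - region$start + 1L] + 1L
      diffv[e - region$start + 1L] <- diffv[e - region$start + 1L] - 1L
      hit <- TRUE
    }
    if (hit) {
      ci <- match(cond, conditions)
      w[ci, ] <- w[ci, ] + cumsum(diffv[seq_len(L)])
    }
  }
  if (region$strand == "-") w <- w[, rev(seq_len(L)), drop = FALSE]
  w
}

#' Distal polyA site position
#'
#' The most 3' UTR position with coverage strictly above `threshold` in any
#' condition.
#'
#' @param w coverage matrix (conditions x L, transcript orientation).
#' @param threshold coverage threshold (default 10, strict `>`).
#' @return list with `testable` and, when testable, `L_star`.
#' @export
find_distal_site <- function(w, threshold = 10L) {
  covered <- which(apply(w, 2L, max) > threshold)
  if (!length(covered)) return(list(testable = FALSE, reason = "low_coverage"))
  list(testable = TRUE, L_star = max(covered))
}

#' Proximal polyA site by maximal squared coverage gap
#'
#' Over conditions c and positions P in `[51, L_star - 50]`, maximizes
#' `(mean(w[c, P+1..P+50]) - mean(w[c, P-50..P-1]))^2`; ties are broken by
#' smallest P, then smallest condition index. A flat profile (objective
#' identically zero) is flagged degenerate.
#'
#' @param w coverage matrix.
#' @param L_star distal site from [find_distal_site()].
#' @return list with `testable` and, when testable, `P_star`, `C_star`,
#'   `objective`, `degenerate`.
#' @export
find_proximal_site <- function(w, L_star) {
  if (L_star - 50L < 51L) return(list(testable = FALSE, reason = "short_utr"))
  P <- seq(51L, L_star - 50L)
  obj <- matrix(0, nrow = nrow(w), ncol = length(P))
  for (ci in seq_len(nrow(w))) {
    cs <- c(0, cumsum(as.numeric(w[ci, ])))
    after <- (cs[P + 51L] - cs[P + 1L]) / 50
    before <- (cs[P] - cs[P - 50L]) / 50
    obj[ci, ] <- (after - before)^2
  }
  mx <- max(obj)
  hits <- which(obj >= mx - 1e-12, arr.ind = TRUE)
  # argmax ties: smallest P, then smallest condition index
  hits <- hits[order(hits[, "col"], hits[, "row"]), , drop = FALSE]
  list(testable = TRUE, degenerate = mx <= 0,
       P_star = P[hits[1L, "col"]], C_star = unname(hits[1L, "row"]),
       objective = mx)
}

#' Distal and proximal usage of one condition
#'
#' `W_d` and `W_p` are the mean coverages of the 50 positions immediately
#' upstream of the distal and proximal sites; the distal-usage fraction is
#' `F = W_d / (W_d + W_p)`.
#'
#' @param w coverage matrix.
#' @param L_star,P_star site positions.
#' @param condition row index or row name of `w`.
#' @return list with `W_d`, `W_p`, `F` (`NA` with reason `zero_coverage`
#'   when `W_d + W_p = 0`).
#' @export
compute_usage <- function(w, L_star, P_star, condition) {
  ci <- if (is.character(condition)) match(condition, rownames(w)) else condition
  W_d <- mean(w[ci, seq(L_star - 50L, L_star - 1L)])
  W_p <- mean(w[ci, seq(P_star - 50L, P_star - 1L)])
  F <- if (W_d + W_p > 0) W_d / (W_d + W_p) else NA_real_
  list(condition = condition, W_d = W_d, W_p = W_p, F = F,
       excluded = is.na(F),
       reason = if (is.na(F)) "zero_coverage" else NA_character_)
}

#' Compare distal usage between two conditions
#'
#' Fraction Change = `F_C1 - F_C2` (positive = 3'UTR lengthening in C1); the
#' p-value is a two-sided Fisher's exact test on the 2x2 table of rounded
#' window means `[[W_d_C1, W_p_C1], [W_d_C2, W_p_C2]]` (nearest integer,
#' halves away from zero).
#'
#' @param usage_c1,usage_c2 outputs of [compute_usage()].
#' @return one-row data.frame with `fraction_change` and `p_value`.
#' @export
compare_conditions <- function(usage_c1, usage_c2) {
  stopifnot(!usage_c1$excluded, !usage_c2$excluded)
  tab <- round_half_away(c(usage_c1$W_d, usage_c1$W_p,
                           usage_c2$W_d, usage_c2$W_p))
  data.frame(fraction_change = usage_c1$F - usage_c2$F,
             p_value = fisher2x2(tab[1L], tab[2L], tab[3L], tab[4L]))
}

#' BH correction and direction calls over APA comparisons
#'
#' @param comparisons data.frame with one row per gene/region: `p_value`,
#'   `fraction_change` and identifier columns.
#' @param alpha FDR threshold for direction calls (default 0.05).
#' @return the table with `p_adjusted` and `direction`
#'   (`lengthened`/`shortened`/`none`), sorted by `p_adjusted`.
#' @export
apa_table <- function(comparisons, alpha = 0.05) {
  if (is.null(comparisons) || nrow(comparisons) == 0L) {
    return(data.frame())
  }
  comparisons$p_adjusted <- p.adjust(comparisons$p_value, method = "BH")
  comparisons$direction <- ifelse(
    comparisons$p_adjusted < alpha & comparisons$fraction_change > 0, "lengthened",
    ifelse(comparisons$p_adjusted < alpha & comparisons$fraction_change < 0,
           "shortened", "none"))
  comparisons <- comparisons[order(comparisons$p_adjusted), ]
  rownames(comparisons) <- NULL
  comparisons
}

#' Full APA pipeline between two conditions
#'
#' Site detection uses all conditions in `groups` jointly; the hypothesis
#' test compares the two named conditions. Untestable regions (coverage never
#' above threshold, UTR too short for both windows, flat profile, zero
#' coverage in a tested condition) are reported with their reason.
#'
#' @param alignments spliced-alignment records.
#' @param utr3 3'UTR exon annotation (see [build_utr_regions()]).
#' @param groups cell-barcode to condition map.
#' @param c1,c2 condition names to compare (Fraction Change = F_c1 - F_c2).
#' @param threshold distal-site coverage threshold (default 10).
#' @return list with `table` (per-gene results incl. L*/P*/C*, W_d/W_p/F per
#'   condition, fraction_change, p, p_adjusted, direction) and `skipped`.
#' @export
run_apa <- function(alignments, utr3, groups, c1, c2, threshold = 10L) {
  regions <- build_utr_regions(utr3)
  conditions <- unique(groups$condition)
  stopifnot(c1 %in% conditions, c2 %in% conditions)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    w <- utr_coverage(alignments, reg, groups, conditions)
    ds <- find_distal_site(w, threshold)
    if (!ds$testable) {
      skipped[[reg$region_id]] <- data.frame(region_id = reg$region_id,
                                             reason = ds$reason)
      next
    }
    ps <- find_proximal_site(w, ds$L_star)
    if (!ps$testable || ps$degenerate) {
      skipped[[reg$region_id]] <- data.frame(
        region_id = reg$region_id,
        reason = if (!ps$testable) ps$reason else "flat_profile")
      next
    }
    u1 <- compute_usage(w, ds$L_star, ps$P_star, match(c1, conditions))
    u2 <- compute_usage(w, ds$L_star, ps$P_star, match(c2, conditions))
    if (u1$excluded || u2$excluded) {
      skipped[[reg$region_id]] <- data.frame(region_id = reg$region_id,
                                             reason = "zero_coverage")
      next
    }
    cmp <- compare_conditions(u1, u2)
    rows[[reg$region_id]] <- data.frame(
      gene_id = reg$gene_id, region_id = reg$region_id, chrom = reg$chrom,
      L_star = ds$L_star, P_star = ps$P_star, C_star = ps$C_star,
      W_d_c1 = u1$W_d, W_p_c1 = u1$W_p, F_c1 = u1$F,
      W_d_c2 = u2$W_d, W_p_c2 = u2$W_p, F_c2 = u2$F,
      fraction_change = cmp$fraction_change, p_value = cmp$p_value)
  }
  tab <- apa_table(do.call(rbind, rows))
  skipped <- do.call(rbind, skipped)
  rownames(skipped) <- NULL
  list(table = tab, skipped = skipped)
}
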