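# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force, never through the code paths they check.

# best edit distance of `pattern` against any substring of `read`
# (exhaustive sliding-window Levenshtein via utils::adist)
oracle_best_edit <- function(read, pattern, slack = 3L) {
  m <- nchar(pattern)
  lens <- seq(max(1L, m - slack), m + slack)
  best <- Inf
  for (len in lens) {
    if (len > nchar(read)) next
    subs <- substring(read, seq_len(nchar(read) - len + 1L),
                      seq(len, nchar(read)))
    best <- min(best, min(adist(pattern, subs)))
  }
  best
}

# two-sided Fisher p by full hypergeometric enumeration on [[a,b],[c,d]]
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# brute-force SQANTI-style category: exhaustive chain / sub-chain search
oracle_classify <- function(chain, chrom, strand, n_exons, exons) {
  if (n_exons == 1L) return("other")
  jx <- lriso:::chain_junctions(chain)
  e_sel <- exons[exons$chrom == chrom & exons$strand == strand, ]
  tx <- split(e_sel, e_sel$transcript_id)
  ref_chains <- lapply(tx, function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2L) return(NULL)
    cbind(donor = e$end[-nrow(e)], acceptor = e$start[-1L])
  })
  ref_chains <- Filter(Negate(is.null), ref_chains)
  same <- function(a, b) nrow(a) == nrow(b) && all(a == b)
  if (any(vapply(ref_chains, function(rc) same(rc, jx), TRUE))) return("FSM")
  for (rc in ref_chains) {
    if (nrow(jx) >= nrow(rc)) next
    for (s in seq_len(nrow(rc) - nrow(jx) + 1L)) {
      if (same(rc[s:(s + nrow(jx) - 1L), , drop = FALSE], jx)) return("ISM")
    }
  }
  known_d <- unique(unlist(lapply(ref_chains, function(rc) rc[, "donor"])))
  known_a <- unique(unlist(lapply(ref_chains, function(rc) rc[, "acceptor"])))
  if (all(jx[, "donor"] %in% known_d) && all(jx[, "acceptor"] %in% known_a)) {
    return("NIC")
  }
  "NNC"
}

# small shared fixtures -------------------------------------------------------

tiny_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, n_genes = 6L, cells_per_type = 12L,
             umis_per_cell_gene = 1, error_rate = 0, ...)
}

tiny_world <- function(seed = 11L, ...) {
  cfg <- tiny_config(seed = seed, ...)
  ref <- simulate_reference(cfg)
  sim <- simulate_molecules(cfg, ref)
  list(config = cfg, ref = ref, sim = sim)
}

# a synthetic catalog object from bare isoform rows
as_catalog <- function(isoforms, counts = NULL) {
  structure(list(isoforms = isoforms,
                 counts = if (is.null(counts)) data.frame() else counts,
                 assignment = data.frame()),
            class = "lriso_catalog")
}
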