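# handcrafted single-gene annotation on a small genome for structural tests
make_toy_locus <- function(seed = 42L) {
  set.seed(seed)
  genome <- Biostrings::DNAStringSet(c(chrT = paste(
    sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")))
  ex <- data.frame(
    chrom = "chrT", strand = "+", gene_id = "GA",
    transcript_id = rep(c("TA1", "TA2"), c(4L, 3L)),
    start = c(1000L, 1500L, 2000L, 2500L, 1000L, 2000L, 2500L),
    end = c(1200L, 1700L, 2200L, 2700L, 1200L, 2200L, 2700L))
  list(genome = genome, exons = ex)
}

aln_row <- function(read_id, cell, starts, ends, chrom = "chrT", strand = "+",
                    umi = "AAAAAAAAAAAA") {
  data.frame(read_id = read_id, cell_barcode = cell, umi = umi,
             chrom = chrom, strand = strand,
             block_starts = paste(starts, collapse = ","),
             block_ends = paste(ends, collapse = ","), base_calls = "")
}

test_that("molecules with identical junction chains collapse to one isoform", {
  aln <- rbind(
    aln_row("m1", "cellA", c(1000, 1500), c(1200, 1700)),
    aln_row("m2", "cellA", c(1050, 1500), c(1200, 1700)),  # later TSS
    aln_row("m3", "cellB", c(1000, 1500), c(1200, 1700)),
    aln_row("m4", "cellA", c(1000, 1506), c(1200, 1700)))  # shifted acceptor
  cat0 <- collapse_molecules(aln)
  expect_equal(nrow(cat0$isoforms), 2L)
  main <- cat0$isoforms[cat0$isoforms$total_umis == 3L, ]
  expect_equal(main$tss_pos, 1000L)  # 5'-most observed start
  cnt <- cat0$counts[cat0$counts$isoform_id == main$isoform_id, ]
  expect_setequal(paste(cnt$cell_barcode, cnt$count),
                  c("cellA 2", "cellB 1"))
  expect_equal(sum(cat0$counts$count), nrow(cat0$assignment))
})

test_that("structural categories match the brute-force chain search oracle", {
  toy <- make_toy_locus()
  cases <- rbind(
    aln_row("fsm",  "c1", c(1000, 1500, 2000, 2500), c(1200, 1700, 2200, 2700)),
    aln_row("fsm2", "c1", c(1000, 2000, 2500), c(1200, 2200, 2700)),
    aln_row("ism",  "c1", c(2000, 2500), c(2200, 2700)),
    aln_row("nic",  "c1", c(1000, 1500, 2500), c(1200, 1700, 2700)),
    aln_row("nnc",  "c1", c(1000, 1506), c(1200, 1700)),
    aln_row("mono", "c1", 1000, 1200),
    aln_row("intergenic", "c1", c(4000, 4400), c(4100, 4500)))
  cat0 <- classify_catalog(collapse_molecules(cases), toy$exons)
  iso <- cat0$isoforms
  got <- setNames(iso$category, iso$isoform_id)
  for (i in seq_len(nrow(iso))) {
    locus_genes <- if (iso$tss_pos[i] < 3000) toy$exons else toy$exons[0, ]
    oracle <- if (iso$n_exons[i] == 1L || nrow(locus_genes) == 0L) "other"
              else oracle_classify(iso$chain[i], iso$chrom[i], iso$strand[i],
                                   iso$n_exons[i], toy$exons)
    expect_identical(iso$category[i], oracle)
  }
  expect_setequal(unique(iso$category), c("FSM", "ISM", "NIC", "NNC", "other"))
  fsm <- iso[iso$category == "FSM", ]
  expect_setequal(fsm$matched_transcript, c("TA1", "TA2"))
})

test_that("intrapriming detection is strand-symmetric", {
  richA <- strrep("A", 20)
  half <- paste0(strrep("A", 10), strrep("C", 10))
  genome <- Biostrings::DNAStringSet(c(
    chrP = paste0(strrep("C", 100), richA, strrep("C", 100), half, strrep("C", 100)),
    chrM = paste0(strrep("C", 100), as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(half))), strrep("C", 100),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(richA))),
      strrep("C", 100))))
  iso <- data.frame(
    chrom = c("chrP", "chrP", "chrM", "chrM"),
    strand = c("+", "+", "-", "-"),
    tes_pos = c(99L, 219L, 240L, 120L))
  flags <- detect_intrapriming(iso, genome)
  expect_identical(flags, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("RT-switch flags planted direct repeats at novel junctions only", {
  set.seed(99)
  base <- sample(c("A", "C", "G", "T"), 700, replace = TRUE)
  rep8 <- strsplit("GATTACAG", "")[[1]]
  # novel junction donor=200 acceptor=300; plant the repeat across both
  base[197:204] <- rep8
  base[297:304] <- rep8
  # second junction donor=500 acceptor=600 with only a 7-mer in common
  rep7 <- strsplit("TTGACAT", "")[[1]]
  base[497:503] <- rep7
  base[597:603] <- rep7
  genome <- Biostrings::DNAStringSet(c(chrR = paste(base, collapse = "")))
  iso <- data.frame(chrom = "chrR", strand = "+",
                    chain = c("200-300", "500-600"))
  expect_identical(detect_rt_switch(iso, genome, junction_keys = character(0),
                                    repeat_len = 8L), c(TRUE, FALSE))
  # the same junction is exempt when reference-supported
  expect_false(detect_rt_switch(iso[1L, ], genome,
                                junction_keys = "chrR|+|200|300")[1L])
})

test_that("catalog filter applies reasons in fixed precedence", {
  toy <- make_toy_locus()
  aln <- rbind(
    aln_row("a1", "c1", c(1000, 1500, 2000, 2500), c(1200, 1700, 2200, 2700)),
    aln_row("a2", "c2", c(1000, 1500, 2000, 2500), c(1200, 1700, 2200, 2700)),
    aln_row("b1", "c1", c(1000, 2000, 2500), c(1200, 2200, 2700)),
    aln_row("b2", "c2", c(1000, 2000, 2500), c(1200, 2200, 2700)),
    aln_row("b3", "c3", c(1000, 2000, 2500), c(1200, 2200, 2700)))
  cat0 <- classify_catalog(collapse_molecules(aln), toy$exons)
  f <- filter_catalog(cat0, toy$genome, toy$exons, min_umis = 3L)
  # the 2-UMI FSM falls below the UMI threshold, the 3-UMI one survives
  expect_equal(nrow(f$catalog$isoforms), 1L)
  expect_identical(f$report$reason, "min_umis")
  expect_equal(f$catalog$isoforms$total_umis, 3L)

  # FSM with noncanonical reference junctions is retained (novel-only rule)
  expect_false(f$catalog$isoforms$flag_noncanonical)
})

test_that("planted intrapriming artifacts are removed with that reason", {
  cfg <- sim_config(seed = 19, n_genes = 16, cells_per_type = 12,
                    umis_per_cell_gene = 1, error_rate = 0)
  w <- list(ref = simulate_reference(cfg))
  w$sim <- simulate_molecules(cfg, w$ref)
  aln <- emit_alignments(w$sim, w$ref)
  cat0 <- classify_catalog(collapse_molecules(aln), w$ref$exons)
  genome <- w$ref$genome
  iso <- cat0$isoforms
  # plant only at TES positions no other isoform shares or neighbours, so the
  # A-runs tag exactly the intended isoforms
  iso_end <- paste(iso$chrom, iso$strand, iso$tes_pos)
  lonely <- vapply(seq_len(nrow(iso)), function(i) {
    sum(iso$chrom == iso$chrom[i] &
          abs(iso$tes_pos - iso$tes_pos[i]) <= 42L) == 1L
  }, TRUE)
  planted <- head(iso$isoform_id[lonely], 10L)
  expect_length(planted, 10L)
  for (id in planted) {
    r <- iso[iso$isoform_id == id, ]
    if (r$strand == "+") {
      Biostrings::subseq(genome[[r$chrom]], r$tes_pos + 2L, r$tes_pos + 21L) <-
        Biostrings::DNAString(strrep("A", 20))
    } else {
      Biostrings::subseq(genome[[r$chrom]], r$tes_pos - 19L, r$tes_pos) <-
        Biostrings::DNAString(strrep("T", 20))
    }
  }
  f <- filter_catalog(cat0, genome, w$ref$exons, min_umis = 1L)
  expect_setequal(f$report$isoform_id[f$report$reason == "intrapriming"], planted)
})

test_that("end validation keeps FSM and applies the 50 bp windows", {
  iso <- data.frame(
    isoform_id = c("i1", "i2", "i3"),
    chrom = "chrT", strand = "+",
    category = c("NNC", "NNC", "FSM"),
    tss_pos = c(1010L, 1010L, 5000L),
    tes_pos = c(2049L, 2051L, 5500L))
  cat0 <- as_catalog(iso, counts = data.frame(isoform_id = iso$isoform_id,
                                              cell_barcode = "c1", count = 1L))
  cage <- data.frame(chrom = "chrT", start = 995L, end = 1005L, strand = "+")
  polya <- data.frame(chrom = "chrT", pos = 2000L, strand = "+")
  v <- validate_ends(cat0, cage, polya, window = 50L)
  # TSS 10 bp away and TES 49 bp away: retained; TES 51 bp away: removed
  expect_setequal(v$catalog$isoforms$isoform_id, c("i1", "i3"))
  expect_identical(v$removed, "i2")
  # FSM with no matching evidence is kept but flagged
  expect_true(v$catalog$isoforms$end_unvalidated[
    v$catalog$isoforms$isoform_id == "i3"])
  expect_warning(validate_ends(cat0, cage[0, ], polya, window = 50L), "empty")
})

test_that("specificity classes follow the 1-cell / 3-cells-one-type rules", {
  iso <- data.frame(isoform_id = c("i1", "i2", "i3", "i4"),
                    category = c("FSM", "NNC", "NIC", "ISM"),
                    total_umis = c(3L, 3L, 3L, 5L))
  counts <- rbind(
    data.frame(isoform_id = "i1", cell_barcode = "t1", count = 3L),
    data.frame(isoform_id = "i2", cell_barcode = c("t1", "t2", "t3"), count = 1L),
    data.frame(isoform_id = "i3", cell_barcode = c("t1", "d1"), count = c(2L, 1L)),
    data.frame(isoform_id = "i4", cell_barcode = "t1", count = 5L))
  cells <- data.frame(cell_barcode = c("t1", "t2", "t3", "d1"),
                      cell_type = c("tumor", "tumor", "tumor", "distal"))
  got <- specificity_class(as_catalog(iso, counts), cells)
  expect_identical(got$isoforms$specificity,
                   c("cell_specific", "cell_type_specific", "shared",
                     NA_character_))
})

test_that("error-free full pipeline yields a 100% FSM, fully validated catalog", {
  w <- tiny_world(seed = 23)
  aln <- emit_alignments(w$sim, w$ref)
  res <- run_catalog(aln, w$ref$exons, w$ref$genome, w$ref$cage, w$ref$polya,
                     w$sim$cells[, c("cell_barcode", "cell_type")],
                     min_umis = 1L)
  iso <- res$catalog$isoforms
  expect_true(all(iso$category == "FSM"))
  expect_false(any(iso$end_unvalidated))
  expect_length(res$end_removed, 0L)
  # count conservation: every single-locus molecule is assigned exactly once
  expect_equal(sum(res$catalog$counts$count), nrow(w$sim$molecules))
  # per-transcript counts equal the simulated truth
  truth <- table(w$sim$molecules$transcript_id)
  got <- setNames(iso$total_umis, iso$matched_transcript)
  expect_equal(unclass(truth)[names(got)], unclass(got)[names(got)],
               ignore_attr = TRUE)
})
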