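FWD <- LRISO_FWD_PRIMER
REV <- LRISO_REV_PRIMER

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("exact primer pair is found with correct kinds and strands", {
  set.seed(1)
  read <- paste0(FWD, rand_seq(80), REV)
  hits <- find_primer_hits(read, FWD, REV, max_edit = 0)
  expect_equal(nrow(hits), 2L)
  expect_identical(hits$primer_kind, c("forward", "reverse"))
  expect_identical(hits$strand, c("+", "+"))
  expect_equal(hits$start, c(0L, nchar(FWD) + 80L))
  expect_equal(hits$edit_distance, c(0L, 0L))
})

test_that("reverse-complemented occurrences are reported on the minus strand", {
  set.seed(2)
  seg <- paste0(FWD, rand_seq(60), REV)
  read <- paste0(rand_seq(30), revcomp(seg), rand_seq(30))
  hits <- find_primer_hits(read, FWD, REV, max_edit = 1)
  expect_equal(nrow(hits), 2L)
  expect_identical(hits$primer_kind, c("reverse", "forward"))
  expect_identical(hits$strand, c("-", "-"))
})

test_that("edit distances match the exhaustive sliding-window oracle", {
  set.seed(3)
  for (rep in 1:25) {
    primer <- rand_seq(20)
    core <- strsplit(primer, "")[[1]]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      pos <- sample(length(core), nmut)
      core[pos] <- vapply(core[pos],
                          function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    }
    read <- paste0(rand_seq(40), paste(core, collapse = ""), rand_seq(40))
    hits <- find_primer_hits(read, primer, "GGGGGGGGGGGGGGGGGGGG", max_edit = 2)
    hits <- hits[hits$primer_kind == "forward" & hits$strand == "+", ]
    oracle <- oracle_best_edit(read, primer, slack = 2L)
    if (oracle <= 2) {
      expect_gte(nrow(hits), 1L)
      expect_equal(min(hits$edit_distance), oracle)
    }
  }
})

test_that("a single indel in the primer is still located", {
  set.seed(4)
  primer <- rand_seq(22)
  mut <- paste0(substr(primer, 1, 10), substr(primer, 12, 22))  # one deletion
  read <- paste0(rand_seq(50), mut, rand_seq(50))
  hits <- find_primer_hits(read, primer, "GGGGGGGGGGGGGGGGGGGGGG", max_edit = 2)
  expect_gte(nrow(hits), 1L)
  expect_equal(min(hits$edit_distance), 1L)
  h <- hits[which.min(hits$edit_distance), ]
  expect_equal(h$start, 50L)
  expect_equal(h$end, 50L + 21L)
})

test_that("raising max_edit never decreases the number of hits", {
  set.seed(5)
  for (rep in 1:10) {
    read <- paste0(FWD, rand_seq(100), REV, rand_seq(50))
    n <- vapply(0:3, function(k) nrow(find_primer_hits(read, FWD, REV, k)), 1L)
    expect_true(all(diff(n) >= 0))
  }
})

test_that("segments between primer pairs are enumerated and validated", {
  set.seed(6)
  a <- rand_seq(60); b <- rand_seq(70)
  read <- paste0(FWD, a, REV, FWD, b, REV)
  hits <- find_primer_hits(read, FWD, REV, 1)
  segs <- split_segments(read, hits)
  expect_equal(nrow(segs), 3L)  # two valid segments plus the rev->fwd gap
  expect_identical(segs$valid, c(TRUE, FALSE, TRUE))
  expect_identical(segs$sequence[segs$valid], c(a, b))

  # wrong pair: fwd ... fwd
  read2 <- paste0(FWD, a, FWD)
  segs2 <- split_segments(read2, find_primer_hits(read2, FWD, REV, 1))
  expect_equal(nrow(segs2), 1L)
  expect_false(segs2$valid)

  expect_equal(nrow(split_segments(read, hits[0, ])), 0L)
})

test_that("tag extraction enforces whitelist, polyA and length rules", {
  set.seed(7)
  wl <- vapply(1:5, function(i) rand_seq(16), "")
  umi <- rand_seq(12)
  # an A/T-free 3' end keeps tail trimming exact (tail-adjacent A's are
  # indistinguishable from the polyA tail under the 10% tolerance)
  cdna <- paste0(rand_seq(190), "GCGCGCGCG")
  seg <- paste0(wl[2], umi, revcomp(paste0(cdna, strrep("A", 30))))
  got <- extract_tags(seg, "+", wl, polya_min_run = 20)
  expect_true(got$accepted)
  expect_identical(got$cell_barcode, wl[2])
  expect_identical(got$umi, umi)
  expect_identical(got$cdna, cdna)

  # reverse-complemented segment round-trips identically
  got_rc <- extract_tags(revcomp(seg), "-", wl, polya_min_run = 20)
  expect_identical(got_rc[c("cell_barcode", "umi", "cdna")],
                   got[c("cell_barcode", "umi", "cdna")])

  # Hamming-1 barcode rescue
  bc_mut <- wl[2]
  substr(bc_mut, 3, 3) <- setdiff(c("A","C","G","T"), substr(bc_mut, 3, 3))[1]
  seg_mut <- paste0(bc_mut, umi, revcomp(paste0(cdna, strrep("A", 30))))
  got_mut <- extract_tags(seg_mut, "+", wl, 20)
  expect_true(got_mut$accepted)
  expect_identical(got_mut$cell_barcode, wl[2])

  # barcode far from the whitelist
  bad <- extract_tags(paste0(strrep("N", 16), umi,
                             revcomp(paste0(cdna, strrep("A", 30)))), "+", wl, 20)
  expect_false(bad$accepted)
  expect_identical(bad$reason, "no_barcode_match")

  # short polyA run
  nop <- extract_tags(paste0(wl[1], umi, revcomp(paste0(cdna, "AAA"))), "+", wl, 20)
  expect_false(nop$accepted)
  expect_identical(nop$reason, "no_polya")

  # too short
  ts <- extract_tags(substr(seg, 1, 30), "+", wl, 20)
  expect_identical(ts$reason, "too_short")
})

test_that("every candidate segment is accepted or rejected with one reason", {
  cfg <- tiny_config(artifact_fraction = 0.15)
  ref <- simulate_reference(cfg)
  sim <- simulate_molecules(cfg, ref)
  rr <- render_reads(sim, cfg)
  dec <- deconcat_reads(rr$reads, unique(sim$cells$cell_barcode))
  n_candidates <- sum(vapply(rr$reads, function(r) {
    h <- find_primer_hits(r)
    max(0L, nrow(h) - 1L)
  }, 1L))
  expect_equal(nrow(dec$molecules) + nrow(dec$rejections), n_candidates)
  expect_true(all(dec$rejections$reason %in%
                    c("wrong_pair", "too_short", "no_barcode_match", "no_polya")))
})

test_that("directional UMI dedup merges within cells only", {
  m <- data.frame(cell_barcode = rep("B1", 2), umi = rep("AAAAAAAAAAAA", 2),
                  cdna = c("ACGT", "ACGTACGT"))
  d <- dedup_umis(m)
  expect_equal(nrow(d), 1L)
  expect_equal(d$read_count, 2L)
  expect_identical(d$cdna, "ACGTACGT")  # longest representative

  # directional merge of a count-1 neighbour into the count-5 UMI
  m2 <- data.frame(cell_barcode = "B1",
                   umi = c(rep("AAAAAAAAAAAA", 5), "AAAAAAAAAAAT"),
                   cdna = strrep("A", c(10, 10, 10, 10, 10, 9)))
  d2 <- dedup_umis(m2)
  expect_equal(nrow(d2), 1L)
  expect_identical(d2$umi, "AAAAAAAAAAAA")
  expect_equal(d2$read_count, 6L)

  # same UMI in different cells stays separate
  m3 <- data.frame(cell_barcode = c("B1", "B2"), umi = "AAAAAAAAAAAA",
                   cdna = "ACGT")
  expect_equal(nrow(dedup_umis(m3)), 2L)

  # distance-2 UMIs are not merged
  m4 <- data.frame(cell_barcode = "B1",
                   umi = c("AAAAAAAAAAAA", "AAAAAAAAAATT"), cdna = "ACGT")
  expect_equal(nrow(dedup_umis(m4)), 2L)
})
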