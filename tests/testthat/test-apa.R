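# exhaustive-scan oracle for the proximal-site objective
oracle_proximal <- function(w, L_star) {
  best <- list(obj = -Inf, P = NA, C = NA)
  for (P in 51:(L_star - 50L)) for (ci in seq_len(nrow(w))) {
    obj <- (mean(w[ci, (P + 1L):(P + 50L)]) - mean(w[ci, (P - 50L):(P - 1L)]))^2
    if (obj > best$obj + 1e-12) best <- list(obj = obj, P = P, C = ci)
  }
  best
}

step_profile <- function() {
  matrix(c(rep(20, 100), rep(12, 100)), nrow = 1)
}

test_that("the two-site worked example evaluates exactly", {
  w <- step_profile()
  ds <- find_distal_site(w, threshold = 10)
  expect_true(ds$testable)
  expect_equal(ds$L_star, 200L)
  ps <- find_proximal_site(w, ds$L_star)
  expect_equal(ps$P_star, 100L)
  expect_equal(ps$C_star, 1L)
  u <- compute_usage(w, ds$L_star, ps$P_star, 1L)
  expect_equal(u$W_d, 12)
  expect_equal(u$W_p, 20)
  expect_equal(u$F, 0.375)
})

test_that("proximal site matches the exhaustive scan oracle on random profiles", {
  set.seed(8)
  for (rep in 1:10) {
    w <- matrix(rpois(2 * 180, lambda = 15), nrow = 2)
    ds <- find_distal_site(w, threshold = 10)
    if (!ds$testable || ds$L_star < 101L) next
    ps <- find_proximal_site(w, ds$L_star)
    oc <- oracle_proximal(w, ds$L_star)
    expect_equal(ps$P_star, oc$P)
    expect_equal(ps$objective, oc$obj, tolerance = 1e-12)
  }
})

test_that("distal-site threshold is strict and spans any condition", {
  w10 <- matrix(10, nrow = 1, ncol = 200)
  expect_false(find_distal_site(w10, 10)$testable)  # 10 is not > 10
  w2 <- rbind(rep(0, 200), c(rep(20, 150), rep(0, 50)))
  ds <- find_distal_site(w2, 10)
  expect_true(ds$testable)
  expect_equal(ds$L_star, 150L)
  # a step present only in condition 2 sets C*
  w3 <- rbind(rep(30, 200), c(rep(30, 120), rep(12, 80)))
  ps <- find_proximal_site(w3, 200L)
  expect_equal(ps$C_star, 2L)
  expect_equal(ps$P_star, 120L)
})

test_that("flat profiles are degenerate with tie-broken P* = 51", {
  w <- matrix(20, nrow = 1, ncol = 300)
  ps <- find_proximal_site(w, 300L)
  expect_true(ps$degenerate)
  expect_equal(ps$P_star, 51L)
  u <- compute_usage(w, 300L, 150L, 1L)
  expect_equal(u$F, 0.5)  # all reads reach the distal site
  z <- compute_usage(matrix(0, 1, 300), 300L, 150L, 1L)
  expect_true(z$excluded)
  expect_identical(z$reason, "zero_coverage")
})

test_that("fraction change carries the lengthening sign convention", {
  u1 <- list(W_d = 9, W_p = 1, F = 0.9, excluded = FALSE)
  u2 <- list(W_d = 3, W_p = 7, F = 0.3, excluded = FALSE)
  cmp <- compare_conditions(u1, u2)
  expect_equal(cmp$fraction_change, 0.6)
  # identical usage: no change, p = 1
  same <- compare_conditions(u1, u1)
  expect_equal(same$fraction_change, 0)
  expect_equal(same$p_value, 1)
  # Fisher p equals the hypergeometric enumeration
  a <- list(W_d = 12, W_p = 20, F = 12 / 32, excluded = FALSE)
  b <- list(W_d = 20, W_p = 12, F = 20 / 32, excluded = FALSE)
  expect_equal(compare_conditions(a, b)$p_value, oracle_fisher(12, 20, 20, 12))
})

test_that("fraction change is antisymmetric and F is scale invariant", {
  set.seed(12)
  w <- simulate_utr_coverage(250L, 120L, c(300L, 300L), c(0.7, 0.35))
  ds <- find_distal_site(w); ps <- find_proximal_site(w, ds$L_star)
  u1 <- compute_usage(w, ds$L_star, ps$P_star, 1L)
  u2 <- compute_usage(w, ds$L_star, ps$P_star, 2L)
  fwd <- compare_conditions(u1, u2); swp <- compare_conditions(u2, u1)
  expect_equal(fwd$fraction_change, -swp$fraction_change)
  expect_equal(fwd$p_value, swp$p_value)
  u1s <- compute_usage(w * 3L, ds$L_star, ps$P_star, 1L)
  expect_equal(u1s$F, u1$F)
})

test_that("BH adjustment and direction calls follow the step-up rule", {
  one <- data.frame(gene_id = "g", p_value = 0.03, fraction_change = 0.2)
  expect_equal(apa_table(one)$p_adjusted, 0.03)
  four <- data.frame(gene_id = letters[1:4],
                     p_value = c(0.01, 0.02, 0.04, 0.8),
                     fraction_change = c(0.5, -0.5, 0.5, 0.5))
  got <- apa_table(four)
  expect_equal(got$p_adjusted[match(letters[1:4], got$gene_id)],
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_identical(got$direction[match(c("a", "b", "d"), got$gene_id)],
                   c("lengthened", "shortened", "none"))
  expect_equal(nrow(apa_table(data.frame())), 0L)
})

test_that("null two-site genes are rarely called at FDR 0.05", {
  set.seed(33)
  rows <- lapply(1:100, function(g) {
    w <- simulate_utr_coverage(250L, 120L, c(400L, 400L), c(0.5, 0.5))
    ds <- find_distal_site(w); ps <- find_proximal_site(w, ds$L_star)
    u1 <- compute_usage(w, ds$L_star, ps$P_star, 1L)
    u2 <- compute_usage(w, ds$L_star, ps$P_star, 2L)
    cbind(data.frame(gene_id = g), compare_conditions(u1, u2))
  })
  got <- apa_table(do.call(rbind, rows))
  expect_lte(mean(got$direction != "none"), 0.08)
})

test_that("estimated F increases monotonically with the true distal fraction", {
  set.seed(44)
  fs <- c(0.2, 0.4, 0.6, 0.8)
  F_hat <- vapply(fs, function(f) {
    w <- simulate_utr_coverage(300L, 150L, 2000L, f, wobble = 0L)
    ds <- find_distal_site(w); ps <- find_proximal_site(w, ds$L_star)
    compute_usage(w, ds$L_star, ps$P_star, 1L)$F
  }, 1)
  expect_true(all(diff(F_hat) > 0))
  expect_equal(F_hat, fs / (1 + fs), tolerance = 0.05)
})

test_that("3'UTR region building merges same-start and drops mixed-start overlaps", {
  same_start <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                           start = 100L, end = c(300L, 500L))
  r <- build_utr_regions(same_start)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 100L); expect_equal(r$end, 500L); expect_equal(r$L, 400L)

  mixed <- data.frame(gene_id = "g2", chrom = "chr1", strand = "+",
                      start = c(100L, 150L), end = c(400L, 500L))
  expect_equal(nrow(build_utr_regions(mixed)), 0L)

  apart <- data.frame(gene_id = "g3", chrom = "chr1", strand = "+",
                      start = c(100L, 1000L), end = c(400L, 1400L))
  expect_equal(nrow(build_utr_regions(apart)), 2L)

  # minus strand: the 5' start is the genomic end
  minus <- data.frame(gene_id = "g4", chrom = "chr1", strand = "-",
                      start = c(100L, 200L), end = 500L)
  expect_equal(nrow(build_utr_regions(minus)), 1L)
})

test_that("coverage arrays are reported 5'->3' regardless of strand", {
  aln <- data.frame(read_id = "m1", cell_barcode = "c1", umi = "U",
                    chrom = "chr1", strand = "-",
                    block_starts = "100", block_ends = "150", base_calls = "")
  region <- data.frame(gene_id = "g", region_id = "g.U1", chrom = "chr1",
                       strand = "-", start = 100L, end = 300L)
  groups <- data.frame(cell_barcode = "c1", condition = "a")
  w <- utr_coverage(aln, region, groups)
  # genomic [100,150) is the 3'-most UTR chunk of a minus-strand gene
  expect_true(all(w[1, 151:200] == 1L))
  expect_true(all(w[1, 1:150] == 0L))
})
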