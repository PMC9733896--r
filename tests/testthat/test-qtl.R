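test_that("Hill-Robertson r2 matches hand-computed haplotype tables", {
  # identical columns: perfect LD
  x <- rep(c(2, 0), each = 5)
  expect_equal(hill_robertson_r2(x, x), 1)
  # haplotype counts at exact independence: 2/2/2/2
  a <- c(2, 2, 2, 2, 0, 0, 0, 0)
  b <- c(2, 2, 0, 0, 2, 2, 0, 0)
  expect_equal(hill_robertson_r2(a, b), 0)
  # AB=4 Ab=1 aB=1 ab=4: D = 0.4 - 0.25 = 0.15, r2 = 0.15^2/0.0625 = 0.36
  x <- rep(c(2, 2, 0, 0), c(4, 1, 1, 4))
  y <- rep(c(2, 0, 2, 0), c(4, 1, 1, 4))
  expect_equal(hill_robertson_r2(x, y), 0.36)
  expect_equal(hill_robertson_r2(y, x), 0.36)  # symmetry
  # heterozygous lines are excluded pairwise
  x1 <- c(x, 1); y1 <- c(y, 2)
  expect_equal(hill_robertson_r2(x1, y1), 0.36)
  # monomorphic locus undefined
  expect_true(is.na(hill_robertson_r2(rep(2, 6), c(2, 2, 2, 0, 0, 0))))
})

test_that("critical r2 is small for independent markers and deterministic", {
  cfg <- sim_config(n_lines = 200, n_snps = 100, n_chromosomes = 4,
                    within_block_r = 0, maf_low = 0.3, maf_high = 0.7,
                    seed = 61)
  panel <- simulate_line_genotypes(cfg)
  r1 <- critical_r2(panel, n_pairs = 3000, seed = 8)
  r2 <- critical_r2(panel, n_pairs = 3000, seed = 8)
  expect_identical(r1$r2c, r2$r2c)
  expect_lt(r1$r2c, 0.3)
  # percentile 100 returns the sampled maximum
  rmax <- critical_r2(panel, n_pairs = 500, percentile = 100, seed = 9)
  expect_gte(rmax$r2c, r1$r2c)

  single <- tiny_panel(matrix(rep(c(0, 2), 10), ncol = 2))
  expect_error(critical_r2(single), "two chromosomes")
})

test_that("LD clustering produces the expected intervals on hand cases", {
  # single significant SNP: degenerate interval at its own position
  G <- cbind(rep(c(0, 2), each = 5), rep(c(0, 2), each = 5),
             rep(c(0, 2), times = 5))
  panel <- tiny_panel(G, pos = c(100L, 200L, 300L))
  sig1 <- tibble::tibble(snp_id = "S01", chrom = "chr1", pos_bp = 100,
                         minus_log10_p = 6, slope = -1)
  q1 <- cluster_significant_snps(sig1, panel, r2c = 0.5, trait = "Y")
  expect_equal(q1$lower_bp, 100)
  expect_equal(q1$upper_bp, 100)
  expect_equal(q1$slope_sign, -1)

  # SNPs 1,2 in perfect LD, SNP 3 unlinked: two QTLs at r2c = 0.5
  sig3 <- tibble::tibble(snp_id = c("S01", "S02", "S03"), chrom = "chr1",
                         pos_bp = c(100, 200, 300),
                         minus_log10_p = c(6, 8, 5), slope = c(1, 1, -2))
  q3 <- cluster_significant_snps(sig3, panel, r2c = 0.5, trait = "Y")
  expect_equal(nrow(q3), 2)
  pair <- q3[q3$n_members == 2, ]
  expect_equal(pair$lower_bp, 100)
  expect_equal(pair$upper_bp, 200)
  expect_equal(pair$peak_snp, "S02")   # most significant member
  expect_equal(q3[q3$n_members == 1, ]$peak_snp, "S03")
})

test_that("average-linkage clustering matches a brute-force oracle for small inputs", {
  for (seed in 1:8) {
    set.seed(700 + seed)
    n <- sample(3:6, 1)
    G <- matrix(sample(c(0, 2), 40 * n, replace = TRUE), nrow = 40)
    # ensure polymorphism
    G[1, ] <- 0; G[2, ] <- 2
    panel <- tiny_panel(G, pos = as.integer(seq_len(n) * 50))
    r2c <- runif(1, 0.05, 0.6)
    sig <- tibble::tibble(snp_id = sprintf("S%02d", seq_len(n)),
                          chrom = "chr1", pos_bp = seq_len(n) * 50,
                          minus_log10_p = runif(n, 5, 9), slope = rnorm(n))
    q <- cluster_significant_snps(sig, panel, r2c, trait = "Y")
    # oracle: explicit agglomeration on d = 1 - sqrt(r2), cut 1 - sqrt(r2c)
    R <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      if (i == j) 1 else hill_robertson_r2(G[, i], G[, j])
    }))
    R[is.na(R)] <- 0
    oracle <- brute_average_linkage(1 - sqrt(R), 1 - sqrt(r2c))
    got <- integer(n)
    for (ci in seq_len(nrow(q))) {
      got[match(q$members[[ci]], sig$snp_id)] <- ci
    }
    expect_identical(partition_key(got), partition_key(oracle))
    # partition property: every significant SNP in exactly one QTL
    expect_setequal(unlist(q$members), sig$snp_id)
    expect_equal(sum(q$n_members), n)
  }
})

test_that("sqrt and raw clustering scales agree on well-separated LD blocks", {
  # two tight blocks (within r2 = 1) far apart in LD: the partition must not
  # depend on whether distances and cutoff are both sqrt-transformed or raw
  col <- rep(c(0, 2), each = 10)
  other <- rep(c(0, 2), times = 10)
  G <- cbind(col, col, other, other)
  panel <- tiny_panel(G, pos = c(10L, 20L, 500L, 600L))
  sig <- tibble::tibble(snp_id = sprintf("S%02d", 1:4), chrom = "chr1",
                        pos_bp = c(10, 20, 500, 600),
                        minus_log10_p = 5:8, slope = 1)
  for (r2c in c(0.2, 0.5, 0.8)) {
    qs <- cluster_significant_snps(sig, panel, r2c, transform = "sqrt")
    qr <- cluster_significant_snps(sig, panel, r2c, transform = "raw")
    expect_identical(qs$members, qr$members)
    expect_equal(nrow(qs), 2)
  }
})

test_that("QTL overlap requires a shared marker and nearby peaks", {
  qa <- tibble::tibble(chrom = "chr1", peak_bp = 1e6,
                       members = list(c("S01", "S02")))
  qb_same <- tibble::tibble(chrom = "chr1", peak_bp = 1.2e6,
                            members = list(c("S02", "S03")))
  qb_far <- tibble::tibble(chrom = "chr1", peak_bp = 1e6 + 0.2 * 1e7,
                           members = list(c("S02", "S03")))
  qb_disjoint <- tibble::tibble(chrom = "chr1", peak_bp = 1.1e6,
                                members = list(c("S08", "S09")))
  qc <- tibble::tibble(chrom = "chr2", peak_bp = 1e6,
                       members = list(c("S01", "S02")))
  L <- 1e7
  expect_true(qtl_overlap(qa, qa, L))          # identical member sets
  expect_true(qtl_overlap(qa, qb_same, L))
  expect_false(qtl_overlap(qa, qb_far, L))     # peaks 0.2 L apart
  expect_false(qtl_overlap(qa, qb_disjoint, L))
  expect_false(qtl_overlap(qa, qc, L))         # different chromosomes
})
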