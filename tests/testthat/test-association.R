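test_that("sequential ANOVA reduces to classical one-way SS for one term", {
  y <- c(3.1, 2.9, 3.4, 5.0, 5.3, 4.8, 7.2, 6.9, 7.0)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  res <- sequential_anova(y, list(group = g))
  ref <- anova(lm(y ~ g))
  expect_equal(res$ss[1], ref[["Sum Sq"]][1], tolerance = 1e-12)
  expect_equal(res$df[1], ref$Df[1])
  expect_equal(res$p_value[1], ref[["Pr(>F)"]][1], tolerance = 1e-12)
})

test_that("orthogonal terms make sequential SS order-invariant", {
  set.seed(12)
  n <- 16
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)   # orthogonal to x1
  y <- 1 + 2 * x1 - 1.5 * x2 + rnorm(n, 0, 0.3)
  ab <- sequential_anova(y, list(first = x1, second = x2))
  ba <- sequential_anova(y, list(second = x2, first = x1))
  expect_equal(ab$ss[ab$term == "first"], ba$ss[ba$term == "first"],
               tolerance = 1e-10)
  expect_equal(ab$ss[ab$term == "second"], ba$ss[ba$term == "second"],
               tolerance = 1e-10)
})

test_that("sequential SS matches brute-force nested projections on a toy fit", {
  set.seed(13)
  n <- 8
  block <- factor(rep(1:2, each = 4))
  t <- rep(c(0, 1), 4)
  h <- runif(n)
  y <- 2 + 0.5 * t + 3 * h + rnorm(n, 0, 0.4)
  mats <- list(model.matrix(~block)[, -1, drop = FALSE],
               cbind(t), cbind(h), cbind(t * h))
  oracle <- brute_sequential_ss(y, mats)
  res <- sequential_anova(y, list(block = block, treatment = t,
                                  genetic = h, interaction = t * h))
  expect_equal(res$ss[1:4], oracle$ss, tolerance = 1e-8)
  expect_equal(res$ss[res$term == "residual"], oracle$rss, tolerance = 1e-8)
  # rank-deficient extra term gets 0 df
  res2 <- sequential_anova(y, list(block = block, again = block))
  expect_equal(res2$df[res2$term == "again"], 0)
})

test_that("the vectorised scan agrees with per-SNP lm type-I ANOVA", {
  ex <- make_experiment(41, n_snps = 150, n_mixtures = 48, k = 8,
                        n_lines = 96, traits = "Y")
  Fm <- mixture_allele_frequencies(ex$panel, ex$design)
  HEm <- nei_diversity(Fm)
  elig <- eligible_snps(Fm)
  ids <- elig$snp_id[elig$eligible][1:10]
  scan <- gwda_scan(ex$pheno, HEm[, ids], ex$design, "Y", map = ex$panel$map)
  plots <- design_plots(ex$design)
  d0 <- dplyr::inner_join(plots, ex$pheno[, c("plot_id", "Y")], by = "plot_id")
  for (sid in ids) {
    d <- dplyr::mutate(d0, h = HEm[mixture_id, sid],
                       t = as.numeric(treatment == "CWD"),
                       block = factor(block))
    ref <- anova(lm(Y ~ block + t + h + t:h, data = d))
    row <- scan[scan$snp_id == sid, ]
    expect_equal(row$minus_log10_p_genetic,
                 -log10(ref["h", "Pr(>F)"]), tolerance = 1e-8)
    expect_equal(row$minus_log10_p_interaction,
                 -log10(ref["t:h", "Pr(>F)"]), tolerance = 1e-8)
    expect_equal(row$minus_log10_p_treatment,
                 -log10(ref["t", "Pr(>F)"]), tolerance = 1e-8)
    expect_equal(row$ss_genetic, ref["h", "Sum Sq"], tolerance = 1e-8)
    fit <- lm(Y ~ block + t + h + t:h, data = d)
    expect_equal(row$slope_genetic, unname(coef(fit)["h"]), tolerance = 1e-8)
    expect_equal(row$slope_interaction, unname(coef(fit)["t:h"]),
                 tolerance = 1e-8)
  }
})

test_that("sequential SS plus residual SS conserves total SS on every scan row", {
  ex <- make_experiment(42, n_snps = 200, traits = "Y")
  Fm <- mixture_allele_frequencies(ex$panel, ex$design)
  HEm <- nei_diversity(Fm)
  elig <- eligible_snps(Fm)
  scan <- gwda_scan(ex$pheno, HEm[, elig$snp_id[elig$eligible]], ex$design, "Y")
  y <- dplyr::inner_join(design_plots(ex$design), ex$pheno,
                         by = c("plot_id", "mixture_id", "treatment", "block"))$Y
  ss_mean <- length(y) * mean(y)^2
  total <- sum(y^2) - ss_mean
  ok <- !scan$degenerate
  lhs <- scan$ss_block + scan$ss_treatment + scan$ss_genetic +
    dplyr::coalesce(scan$ss_interaction, 0) + scan$ss_residual
  expect_true(all(abs(lhs[ok] - total) <= 1e-8 * total))
})

test_that("a design-constant regressor is flagged degenerate and skipped", {
  ex <- make_experiment(43, n_lines = 24, n_snps = 40, n_mixtures = 12, k = 4,
                        traits = "Y")
  HEm <- nei_diversity(mixture_allele_frequencies(ex$panel, ex$design))
  HEm[, 3] <- 0.42  # constant across mixtures
  scan <- gwda_scan(ex$pheno, HEm, ex$design, "Y")
  expect_true(scan$degenerate[3])
  expect_true(is.na(scan$minus_log10_p_genetic[3]))
  expect_false(any(scan$degenerate[-3]))
})

test_that("a planted diversity effect is the genome-wide GWDA peak", {
  wins <- 0L
  for (seed in 1:10) {
    ex <- make_experiment(100 + seed, n_snps = 300,
                          effect_table = planted_effect(25, "diversity"),
                          traits = "Y")
    Fm <- mixture_allele_frequencies(ex$panel, ex$design)
    HEm <- nei_diversity(Fm)
    elig <- eligible_snps(Fm)
    ids <- elig$snp_id[elig$eligible]
    scan <- gwda_scan(ex$pheno, HEm[, ids], ex$design, "Y")
    peak <- scan$snp_id[which.max(scan$minus_log10_p_genetic)]
    if (peak %in% planted_block_ids(ex$panel, ex$cfg, 25)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("an interaction-only effect is detected on the interaction term", {
  hits <- 0L
  for (seed in 1:10) {
    ex <- make_experiment(200 + seed, n_snps = 300,
                          effect_table = planted_effect(25, "interaction"),
                          traits = "Y")
    Fm <- mixture_allele_frequencies(ex$panel, ex$design)
    HEm <- nei_diversity(Fm)
    ids <- eligible_snps(Fm)
    ids <- ids$snp_id[ids$eligible]
    scan <- gwda_scan(ex$pheno, HEm[, ids], ex$design, "Y")
    mult <- effective_tests_galwey(Fm[, ids], ex$panel$map)
    planted <- planted_block_ids(ex$panel, ex$cfg, 25)
    row <- scan[scan$snp_id %in% planted, ]
    if (any(row$minus_log10_p_interaction > mult$threshold_minus_log10,
            na.rm = TRUE)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 6L)
})

test_that("missing trait values beyond 10% abort the scan", {
  ex <- make_experiment(44, n_lines = 24, n_snps = 30, n_mixtures = 12, k = 4,
                        traits = "Y")
  ph <- ex$pheno
  ph$Y[1:3] <- NA  # 25% of 12 plots
  HEm <- nei_diversity(mixture_allele_frequencies(ex$panel, ex$design))
  expect_error(gwda_scan(ph, HEm, ex$design, "Y"), "missing")
})

test_that("HE-vs-F threshold arithmetic and collinearity guard", {
  ex <- make_experiment(45, n_snps = 60, traits = "Y")
  Fm <- mixture_allele_frequencies(ex$panel, ex$design)
  HEm <- nei_diversity(Fm)
  sid <- eligible_snps(Fm)
  sid <- sid$snp_id[sid$eligible][1]
  res <- he_vs_f_test(ex$pheno, ex$design, Fm[, sid], HEm[, sid], "Y",
                      n_detected = 30)
  expect_equal(round(res$threshold_minus_log10, 2), 2.78)
  expect_false(res$flagged_collinear)
  # fewer than 3 distinct frequencies: HE is affine in F, test undefined
  f2 <- ifelse(Fm[, sid] > 0.5, 0.75, 0.25)
  res2 <- he_vs_f_test(ex$pheno, ex$design, f2, nei_diversity(f2), "Y",
                       n_detected = 30)
  expect_true(res2$flagged_collinear)
})

test_that("the HE-vs-F test is calibrated under a pure-F trait and powered under HE", {
  ex <- make_experiment(46, n_snps = 60)
  Fm <- mixture_allele_frequencies(ex$panel, ex$design)
  HEm <- nei_diversity(Fm)
  el <- eligible_snps(Fm)
  sid <- el$snp_id[which.max(el$f_max - el$f_min)]  # widest frequency spread
  plots <- design_plots(ex$design)
  f_pl <- Fm[plots$mixture_id, sid]
  he_pl <- HEm[plots$mixture_id, sid]
  alpha_raw <- 0.001

  rej_null <- 0L
  for (seed in 1:100) {
    set.seed(3000 + seed)
    ph <- dplyr::mutate(plots, Y = 100 + 40 * f_pl + rnorm(nrow(plots), 0, 5))
    r <- he_vs_f_test(ph, ex$design, Fm[, sid], HEm[, sid], "Y",
                      n_detected = 50)
    if (r$minus_log10_p > -log10(alpha_raw)) rej_null <- rej_null + 1L
  }
  expect_lte(rej_null / 100, 0.05)

  rej_he <- 0L
  for (seed in 1:50) {
    set.seed(4000 + seed)
    ph <- dplyr::mutate(plots, Y = 100 + 80 * he_pl + rnorm(nrow(plots), 0, 2))
    r <- he_vs_f_test(ph, ex$design, Fm[, sid], HEm[, sid], "Y",
                      n_detected = 50)
    if (r$minus_log10_p > -log10(alpha_raw)) rej_he <- rej_he + 1L
  }
  expect_gte(rej_he / 50, 0.8)
})
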