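# Shared fixture builders: everything is generated in code at test time.

# A tiny hand-made panel: n lines x m SNPs from an explicit dosage matrix.
tiny_panel <- function(G, chrom = NULL, pos = NULL) {
  m <- ncol(G)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- as.integer(seq_len(m) * 1000)
  rownames(G) <- sprintf("L%03d", seq_len(nrow(G)))
  genotype_panel(G, tibble::tibble(snp_id = sprintf("S%02d", seq_len(m)),
                                   chrom = chrom, pos_bp = pos))
}

# A complete small experiment: panel + laid-out design + phenotypes.
make_experiment <- function(seed, n_lines = 96, n_snps = 600,
                            n_chromosomes = 3, n_mixtures = 96, k = 12,
                            maf_low = 0.35, maf_high = 0.65,
                            within_block_r = 0.8, ld_block_length = 10,
                            effect_table = NULL, block_sd = 3,
                            treatment_shift = -24, residual_sd = 5,
                            traits = NULL) {
  cfg <- sim_config(n_lines = n_lines, n_snps = n_snps,
                    n_chromosomes = n_chromosomes,
                    ld_block_length = ld_block_length,
                    within_block_r = within_block_r,
                    maf_low = maf_low, maf_high = maf_high,
                    effect_table = effect_table, block_sd = block_sd,
                    treatment_shift = treatment_shift,
                    residual_sd = residual_sd, seed = seed)
  panel <- simulate_line_genotypes(cfg)
  design <- build_mixture_design(rownames(panel$geno), n_mixtures, k,
                                 seed = seed)
  per_tr <- n_mixtures / 2
  n_blocks <- if (per_tr %% 4 == 0) 4 else if (per_tr %% 2 == 0) 2 else 1
  design <- assign_layout(design, n_blocks = n_blocks, seed = seed)
  pheno <- simulate_phenotypes(panel, design, cfg, traits = traits)
  list(cfg = cfg, panel = panel, design = design, pheno = pheno)
}

# Default planted-effect magnitudes used across recovery tests
# (trait units per unit F or HE, against residual_sd = 5).
default_slope <- c(freq = 40, diversity = 80, interaction = 120)

planted_effect <- function(snp, type, trait = "Y",
                           slope = default_slope[[type]]) {
  data.frame(snp = snp, type = type, trait = trait, slope = slope)
}

# LD-block membership of a SNP index: SNPs sharing a (chromosome, block)
# cell of the simulator's layout.
planted_block_ids <- function(panel, cfg, snp_index) {
  per_chr <- diff(floor(seq(0, cfg$n_snps, length.out = cfg$n_chromosomes + 1)))
  chrom_start <- cumsum(c(0, per_chr))
  ci <- findInterval(snp_index - 1, chrom_start, rightmost.closed = FALSE)
  within <- snp_index - chrom_start[ci]
  blk <- (within - 1) %/% cfg$ld_block_length
  idx_in_chr <- which((seq_len(per_chr[ci]) - 1) %/% cfg$ld_block_length == blk)
  panel$map$snp_id[chrom_start[ci] + idx_in_chr]
}

# Brute-force average-linkage clustering on a distance matrix, cut at
# height h: repeatedly merge the closest pair of clusters (average of
# pairwise member distances) while the minimum inter-cluster distance is
# <= h. Independent of stats::hclust.
brute_average_linkage <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- integer(n)
  for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
  membership
}

# Canonical form of a partition for comparison.
partition_key <- function(membership) {
  unname(split(seq_along(membership), membership)) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, min, integer(1)))])()
}

# Brute-force sequential type-I SS by explicit projection: for each nested
# design matrix, project y with P = X (X'X)^+ X' built from the SVD.
brute_sequential_ss <- function(y, mats) {
  proj_rss <- function(X) {
    s <- svd(X)
    keep <- s$d > max(dim(X)) * max(s$d) * 1e-12
    U <- s$u[, keep, drop = FALSE]
    sum((y - U %*% crossprod(U, y))^2)
  }
  X <- matrix(1, length(y), 1)
  rss_prev <- proj_rss(X)
  ss <- numeric(length(mats))
  for (i in seq_along(mats)) {
    X <- cbind(X, mats[[i]])
    rss <- proj_rss(X)
    ss[i] <- rss_prev - rss
    rss_prev <- rss
  }
  list(ss = ss, rss = rss_prev)
}
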