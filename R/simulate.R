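#' Simulation configuration for synthetic mixture experiments
#'
#' Bundles every knob of the synthetic-data generator: the genotype panel
#' (inbred lines with LD-block structure), and the phenotype model (block,
#' treatment, per-locus frequency/diversity effects, residual noise).
#'
#' The phenotype generative model mirrors the association model fitted
#' downstream: for each plot,
#' \deqn{y = \mu + block + shift \cdot 1[CWD] + \sum_e s_e \, x_e + \epsilon,}
#' where \eqn{x_e} is the mixture's allele frequency (type `"freq"`) or Nei
#' diversity (type `"diversity"`) at the planted SNP, interaction effects
#' (type `"interaction"`) contribute \eqn{s_e \cdot HE} in CWD plots only,
#' block effects are drawn once per (treatment, block) pair with standard
#' deviation `block_sd`, and \eqn{\epsilon \sim N(0, residual\_sd^2)}.
#'
#' @param n_lines Number of inbred lines in the panel.
#' @param n_snps Total number of SNPs.
#' @param n_chromosomes Number of chromosomes the SNPs are spread across.
#' @param ld_block_length Number of consecutive SNPs per correlated LD block.
#' @param within_block_r Target correlation between adjacent SNPs within a
#'   block, in `[0,1]` (0 = independent, 1 = identical columns).
#' @param maf_low,maf_high Bounds of the uniform distribution the per-block
#'   line-population allele frequency is drawn from.
#' @param het_rate Residual heterozygosity rate: probability that an inbred
#'   dosage is replaced by 1. Default 0 (fully inbred).
#' @param effect_table Planted genetic effects: a data frame with columns
#'   `snp` (column index into the panel), `type` (one of `"freq"`,
#'   `"diversity"`, `"interaction"`), `trait` (trait name) and `slope`
#'   (trait units per unit F or HE). `NULL` for a null genome.
#' @param grand_mean Trait grand mean (trait units).
#' @param block_sd Standard deviation of block effects (trait units).
#' @param treatment_shift Additive shift applied to CWD plots (trait units).
#' @param residual_sd Residual standard deviation (trait units).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 24, n_snps = 200, seed = 1)
sim_config <- function(n_lines = 96, n_snps = 5000, n_chromosomes = 14,
                       ld_block_length = 10, within_block_r = 0.8,
                       maf_low = 0.1, maf_high = 0.9, het_rate = 0,
                       effect_table = NULL, grand_mean = 100,
                       block_sd = 3, treatment_shift = -24,
                       residual_sd = 5, seed = NULL) {
  stopifnot(n_lines >= 2, n_snps >= 1, n_chromosomes >= 1,
            ld_block_length >= 1)
  if (n_snps < n_chromosomes) {
    abort("infeasible config: n_snps < n_chromosomes")
  }
  if (!(maf_low >= 0 && maf_low <= maf_high && maf_high <= 1)) {
    abort("need 0 <= maf_low <= maf_high <= 1")
  }
  if (within_block_r < 0 || within_block_r > 1) {
    abort("within_block_r must be in [0, 1]")
  }
  if (het_rate < 0 || het_rate > 1) abort("het_rate must be in [0, 1]")
  if (block_sd < 0 || residual_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  if (!is.null(effect_table)) {
    effect_table <- tibble::as_tibble(effect_table)
    stopifnot(all(c("snp", "type", "trait", "slope") %in% names(effect_table)))
    if (!all(effect_table$type %in% c("freq", "diversity", "interaction"))) {
      abort("effect types must be 'freq', 'diversity' or 'interaction'")
    }
    if (any(effect_table$snp < 1 | effect_table$snp > n_snps)) {
      abort("planted snp indices must lie in [1, n_snps]")
    }
  }
  structure(
    list(n_lines = n_lines, n_snps = n_snps, n_chromosomes = n_chromosomes,
         ld_block_length = ld_block_length, within_block_r = within_block_r,
         maf_low = maf_low, maf_high = maf_high, het_rate = het_rate,
         effect_table = effect_table, grand_mean = grand_mean,
         block_sd = block_sd, treatment_shift = treatment_shift,
         residual_sd = residual_sd, seed = seed),
    class = "sim_config")
}

#' Simulate an inbred-line genotype panel with LD-block structure
#'
#' Lines are simulated as haploid allele draws doubled to dosages `{0, 2}`
#' (an optional residual-heterozygosity rate produces 1s). SNPs are laid out
#' on chromosomes with strictly increasing physical positions and partitioned
#' into LD blocks of `ld_block_length` consecutive SNPs. Within a block each
#' SNP copies the previous SNP's allele per line with probability
#' `within_block_r` and redraws it from the block allele frequency otherwise,
#' so adjacent within-block correlation is approximately `within_block_r`
#' while blocks are mutually independent.
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel`: list with `geno` (lines x SNPs dosage matrix,
#'   dimnames set) and `map` (tibble `snp_id`, `chrom`, `pos_bp`).
#' @export
#' @examples
#' panel <- simulate_line_genotypes(sim_config(n_lines = 12, n_snps = 50, seed = 2))
#' dim(panel$geno)
simulate_line_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genotypes"), {
    n <- config$n_lines
    m <- config$n_snps
    per_chr <- diff(floor(seq(0, m, length.out = config$n_chromosomes + 1)))
    chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chr)
    geno <- matrix(0L, nrow = n, ncol = m)
    pos <- integer(m)
    col0 <- 0L
    for (nc in per_chr) {
      if (nc == 0) next
      pos[col0 + seq_len(nc)] <- cumsum(sample.int(5000L, nc, replace = TRUE))
      # blocks of consecutive SNPs within the chromosome
      block_id <- (seq_len(nc) - 1L) %/% config$ld_block_length
      for (b in unique(block_id)) {
        idx <- col0 + which(block_id == b)
        p <- runif(1, config$maf_low, config$maf_high)
        a <- matrix(0L, nrow = n, ncol = length(idx))
        a[, 1] <- rbinom(n, 1L, p)
        if (length(idx) > 1) {
          for (j in 2:length(idx)) {
            keep <- rbinom(n, 1L, config$within_block_r) == 1L
            fresh <- rbinom(n, 1L, p)
            a[, j] <- ifelse(keep, a[, j - 1L], fresh)
          }
        }
        geno[, idx] <- 2L * a
      }
      col0 <- col0 + nc
    }
    if (config$het_rate > 0) {
      het <- matrix(runif(n * m) < config$het_rate, n, m)
      geno[het] <- 1L
    }
    snp_id <- sprintf("SNP%06d", seq_len(m))
    line_id <- sprintf("L%03d", seq_len(n))
    dimnames(geno) <- list(line_id, snp_id)
    genotype_panel(geno,
                   tibble::tibble(snp_id = snp_id, chrom = chrom, pos_bp = pos))
  })
}

#' Construct and validate a genotype panel
#'
#' @param geno Lines x SNPs dosage matrix (values 0/1/2), with line ids as
#'   rownames and SNP ids as colnames.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos_bp`; one row per
#'   SNP, in the column order of `geno`; positions strictly increasing within
#'   chromosome.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(geno, map) {
  geno <- as.matrix(geno)
  map <- tibble::as_tibble(map)
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(map)),
            ncol(geno) == nrow(map))
  if (anyNA(geno)) abort("genotype matrix contains missing values")
  bad <- which(!(geno %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(geno))
    abort(sprintf("invalid dosage %s at line %s, SNP %s (must be 0/1/2)",
                  geno[bad[1]], rownames(geno)[rc[1]] %||% rc[1],
                  colnames(geno)[rc[2]] %||% rc[2]))
  }
  if (anyDuplicated(map$snp_id)) abort("duplicate snp_id in map")
  ok <- vapply(split(map$pos_bp, map$chrom),
               function(p) all(diff(p) > 0), logical(1))
  if (!all(ok)) {
    abort(sprintf("positions not strictly increasing on %s",
                  paste(names(ok)[!ok], collapse = ", ")))
  }
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("L%03d", seq_len(nrow(geno)))
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d lines x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

#' Simulate plot-level phenotypes for a mixture experiment
#'
#' Evaluates the generative model described in [sim_config()] on the actual
#' per-mixture allele frequencies and Nei diversities implied by `panel` and
#' `design` (the same quantities the association scan later regresses on).
#'
#' @param panel A `genotype_panel`.
#' @param design A `mixture_design` with a plot layout (see [assign_layout()]).
#' @param config A [sim_config()]; `config$effect_table` names the planted
#'   effects and traits.
#' @param traits Traits to simulate; defaults to the traits named in the
#'   effect table, or `"Y"` if there are none.
#' @return A tibble with one row per plot: `plot_id`, `mixture_id`,
#'   `treatment`, `block`, and one column per simulated trait.
#' @export
simulate_phenotypes <- function(panel, design, config, traits = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "sim_config"))
  plots <- design_plots(design)
  eff <- config$effect_table
  if (is.null(traits)) {
    traits <- if (!is.null(eff) && nrow(eff)) unique(eff$trait) else "Y"
  }
  planted_snps <- if (!is.null(eff) && nrow(eff)) unique(eff$snp) else integer(0)
  if (length(planted_snps)) {
    Fm <- mixture_allele_frequencies(panel, design,
                                     snps = panel$map$snp_id[planted_snps])
    HEm <- nei_diversity(Fm)
    mono <- apply(Fm, 2, function(f) diff(range(f)) == 0)
    if (any(mono)) {
      warn(sprintf("planted effect on SNP(s) monomorphic across mixtures: %s",
                   paste(colnames(Fm)[mono], collapse = ", ")))
    }
  }
  with_seed(derive_seed(config$seed, "phenotypes"), {
    n_plot <- nrow(plots)
    is_cwd <- plots$treatment == "CWD"
    bt <- interaction(plots$treatment, plots$block, drop = TRUE)
    block_eff <- setNames(rnorm(nlevels(bt), 0, config$block_sd), levels(bt))
    out <- plots
    for (tr in traits) {
      y <- rep(config$grand_mean, n_plot) +
        block_eff[as.character(bt)] +
        ifelse(is_cwd, config$treatment_shift, 0)
      if (!is.null(eff)) {
        for (r in which(eff$trait == tr)) {
          sid <- panel$map$snp_id[eff$snp[r]]
          x <- switch(eff$type[r],
            freq = Fm[plots$mixture_id, sid],
            diversity = HEm[plots$mixture_id, sid],
            interaction = ifelse(is_cwd, HEm[plots$mixture_id, sid], 0))
          y <- y + eff$slope[r] * x
        }
      }
      y <- y + rnorm(n_plot, 0, config$residual_sd)
      out[[tr]] <- unname(y)
    }
    tibble::as_tibble(out)
  })
}
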