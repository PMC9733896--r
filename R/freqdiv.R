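#' Per-mixture allele frequencies from component genotypes
#'
#' Imputes the allele frequency of each SNP in each mixture from its
#' component lines, assuming a balanced contribution of every component:
#' \deqn{F_{i,j} = \frac{1}{2k}\sum_{c=1}^{k} G_{i,c},}
#' the mean of the per-line allele frequencies \eqn{G/2} over the mixture's
#' `k` components. For fully inbred components (dosages 0/2) this is the
#' fraction of components carrying the allele coded as dosage 2. Frequencies
#' lie in `[0, 1]`.
#'
#' @param panel A `genotype_panel`.
#' @param design A `mixture_design`.
#' @param snps Optional character vector of SNP ids to restrict to.
#' @return Numeric matrix, mixtures x SNPs, with mixture ids as rownames and
#'   SNP ids as colnames.
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 12, n_snps = 30, seed = 3)
#' panel <- simulate_line_genotypes(cfg)
#' d <- build_mixture_design(rownames(panel$geno), n_mixtures = 6, k = 4, seed = 3)
#' Fm <- mixture_allele_frequencies(panel, d)
#' range(Fm)
mixture_allele_frequencies <- function(panel, design, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(design, "mixture_design"))
  missing_lines <- setdiff(design$line_ids, rownames(panel$geno))
  if (length(missing_lines)) {
    abort(sprintf("component line(s) missing from genotype panel: %s",
                  paste(missing_lines, collapse = ", ")))
  }
  G <- panel$geno
  if (!is.null(snps)) G <- G[, snps, drop = FALSE]
  M <- design_membership(design)
  Fm <- (M %*% G[colnames(M), , drop = FALSE]) / (2 * design$k)
  storage.mode(Fm) <- "double"
  Fm
}

#' Nei expected heterozygosity
#'
#' The expected heterozygosity of a biallelic locus at allele frequency F:
#' \eqn{H_E = 2F(1-F)}, elementwise. Maximal (0.5) at F = 0.5 and zero at
#' fixation.
#'
#' @param F Numeric vector or matrix of allele frequencies in `[0, 1]`.
#' @return Object of the same shape with HE values in `[0, 0.5]`.
#' @export
#' @examples
#' nei_diversity(c(0, 1/12, 0.5, 1))
nei_diversity <- function(F) {
  if (any(F < 0 | F > 1, na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  2 * F * (1 - F)
}

#' SNP eligibility for diversity scans
#'
#' A SNP is eligible when, across mixtures, its minimum frequency is strictly
#' below 0.5, its maximum strictly above 0.5, and the spread between them is
#' at least 0.5. This guards against reading a pure allele-frequency effect
#' as a diversity effect: HE is a deterministic (quadratic) function of F, so
#' only SNPs whose frequencies straddle 0.5 widely let the two be separated.
#'
#' @param F Mixtures x SNPs frequency matrix.
#' @return A tibble with one row per SNP: `snp_id`, `f_min`, `f_max`,
#'   `eligible`.
#' @export
eligible_snps <- function(F) {
  stopifnot(nrow(F) >= 1)
  f_min <- apply(F, 2, min)
  f_max <- apply(F, 2, max)
  tibble::tibble(
    snp_id = colnames(F) %||% as.character(seq_len(ncol(F))),
    f_min = unname(f_min),
    f_max = unname(f_max),
    eligible = unname(f_min < 0.5 & f_max > 0.5 & (f_max - f_min) >= 0.5))
}
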