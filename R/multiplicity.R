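#' Galwey effective number of independent tests
#'
#' Per-SNP tests across a genome are correlated through linkage
#' disequilibrium, so a raw Bonferroni correction over all SNPs is too
#' severe. The Galwey estimator summarises the correlation matrix of the
#' tested regressors into an effective test count
#' \deqn{M_{eff} = \frac{(\sum_i \sqrt{\lambda_i})^2}{\sum_i \lambda_i},}
#' where \eqn{\lambda_i} are the eigenvalues of the SNP x SNP Pearson
#' correlation matrix (negative eigenvalues truncated to 0). The estimator is
#' applied per chromosome to the correlation of mixture allele frequencies
#' (the unit entering the regressions) and summed over chromosomes; a
#' chromosome left with a single SNP contributes exactly 1.
#' Constant-frequency SNPs are excluded before computing correlations.
#'
#' @param F Mixtures x SNPs allele-frequency matrix.
#' @param map SNP map tibble (`snp_id`, `chrom`); only SNPs present in both
#'   `F` and `map` are used.
#' @param alpha Family-wise level for the derived threshold (default 0.05).
#' @return A `multiplicity_result`: list with `m_eff` (genome total, rounded
#'   half-up), `m_eff_raw`, `alpha`, `threshold_minus_log10`
#'   (`-log10(alpha / m_eff)`) and `per_chromosome` tibble.
#' @export
effective_tests_galwey <- function(F, map, alpha = 0.05) {
  map <- tibble::as_tibble(map)
  snps <- intersect(colnames(F), map$snp_id)
  if (!length(snps)) abort("no SNPs shared between F and map")
  F <- F[, snps, drop = FALSE]
  keep <- apply(F, 2, function(x) sd(x) > 0)
  if (!any(keep)) abort("no polymorphic SNPs left after excluding constants")
  F <- F[, keep, drop = FALSE]
  chrom <- map$chrom[match(colnames(F), map$snp_id)]
  per <- lapply(split(seq_len(ncol(F)), chrom), function(idx) {
    m <- length(idx)
    if (m == 1) return(tibble::tibble(n_snps = 1L, m_eff = 1))
    Z <- scale(F[, idx, drop = FALSE])
    n <- nrow(Z)
    # eigenvalues of the m x m correlation matrix via the smaller Gram side
    lam <- if (m <= n) {
      eigen(crossprod(Z) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
    } else {
      eigen(tcrossprod(Z) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
    }
    lam <- pmax(lam, 0)
    tot <- m  # trace of an m x m correlation matrix
    tibble::tibble(n_snps = m, m_eff = sum(sqrt(lam))^2 / tot)
  })
  per_chrom <- dplyr::bind_rows(per, .id = "chrom")
  raw <- sum(per_chrom$m_eff)
  m_eff <- floor(raw + 0.5)  # round half-up
  structure(list(m_eff = m_eff, m_eff_raw = raw, alpha = alpha,
                 threshold_minus_log10 = bonferroni_threshold(alpha, m_eff),
                 per_chromosome = per_chrom),
            class = "multiplicity_result")
}

#' @export
print.multiplicity_result <- function(x, ...) {
  cat(sprintf("<multiplicity_result> M_eff = %d (raw %.2f) over %d chromosome(s)\n",
              x$m_eff, x$m_eff_raw, nrow(x$per_chromosome)))
  cat(sprintf("  genome-wide threshold: -log10(%g / %d) = %.2f\n",
              x$alpha, x$m_eff, x$threshold_minus_log10))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.multiplicity_result <- function(x, ...) x$per_chromosome

#' @exportS3Method generics::glance
glance.multiplicity_result <- function(x, ...) {
  tibble::tibble(m_eff = x$m_eff, m_eff_raw = x$m_eff_raw, alpha = x$alpha,
                 threshold_minus_log10 = x$threshold_minus_log10)
}

#' Bonferroni-corrected genome-wide threshold on the -log10 scale
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m_eff Effective number of independent tests (>= 1).
#' @return `-log10(alpha / m_eff)`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 1774)  # 4.55
#' bonferroni_threshold(0.05, 30)    # 2.78
#' bonferroni_threshold(0.05, 1)     # 1.301
bonferroni_threshold <- function(alpha, m_eff) {
  stopifnot(alpha > 0, alpha < 1, m_eff >= 1)
  -log10(alpha / m_eff)
}
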