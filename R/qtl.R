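#' Hill-Robertson r-squared between two loci
#'
#' Squared haplotypic correlation \eqn{r^2 = D^2 / (p_A p_a q_B q_b)} with
#' \eqn{D = f_{AB} - p_A q_B}, estimated from haplotype counts. Inbred
#' dosages are mapped to haplotypes (0 -> allele a, 2 -> allele A); lines
#' heterozygous (dosage 1) at either locus carry ambiguous haplotypes and are
#' excluded pairwise.
#'
#' @param x,y Per-line dosage vectors (0/1/2) at the two loci.
#' @return r-squared in `[0, 1]`, or `NA` when either locus is monomorphic
#'   among the usable lines.
#' @export
#' @examples
#' # counts AB=4, Ab=1, aB=1, ab=4: D = 0.4 - 0.25 = 0.15, r2 = 0.36
#' x <- rep(c(2, 2, 0, 0), c(4, 1, 1, 4))
#' y <- rep(c(2, 0, 2, 0), c(4, 1, 1, 4))
#' hill_robertson_r2(x, y)
hill_robertson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  use <- x %in% c(0, 2) & y %in% c(0, 2)
  a <- x[use] / 2
  b <- y[use] / 2
  pA <- mean(a); qB <- mean(b)
  if (pA %in% c(0, 1) || qB %in% c(0, 1)) return(NA_real_)
  fAB <- mean(a == 1 & b == 1)
  D <- fAB - pA * qB
  D^2 / (pA * (1 - pA) * qB * (1 - qB))
}

# Internal: r2 matrix among a set of SNP columns of a dosage matrix.
r2_matrix <- function(geno) {
  m <- ncol(geno)
  R <- diag(1, m)
  dimnames(R) <- list(colnames(geno), colnames(geno))
  if (m < 2) return(R)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    R[i, j] <- R[j, i] <- hill_robertson_r2(geno[, i], geno[, j])
  }
  R
}

#' Empirical critical r-squared from unlinked marker pairs
#'
#' The null level of LD expected by chance: r-squared is computed for
#' `n_pairs` SNP pairs sampled uniformly with their two members on different
#' chromosomes, and the stated percentile of that distribution is returned.
#' The default 99.9th percentile corresponds to a 0.1% risk of declaring two
#' unlinked markers in LD.
#'
#' @param panel A `genotype_panel` with at least two chromosomes.
#' @param n_pairs Number of cross-chromosome pairs to sample.
#' @param percentile Percentile of the null r-squared distribution, in
#'   (0, 100].
#' @param seed Integer seed.
#' @return A `critical_r2` object: list with `r2c`, `percentile`, `n_pairs`,
#'   `seed`.
#' @export
critical_r2 <- function(panel, n_pairs = 10000, percentile = 99.9,
                        seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), percentile > 0,
            percentile <= 100)
  chrom <- panel$map$chrom
  if (length(unique(chrom)) < 2) {
    abort("critical r2 needs markers on at least two chromosomes")
  }
  with_seed(derive_seed(seed, "critical_r2"), {
    m <- ncol(panel$geno)
    i <- sample.int(m, n_pairs, replace = TRUE)
    j <- sample.int(m, n_pairs, replace = TRUE)
    redo <- which(chrom[i] == chrom[j])
    while (length(redo)) {
      j[redo] <- sample.int(m, length(redo), replace = TRUE)
      redo <- redo[chrom[i[redo]] == chrom[j[redo]]]
    }
    r2 <- vapply(seq_len(n_pairs), function(s) {
      hill_robertson_r2(panel$geno[, i[s]], panel$geno[, j[s]])
    }, numeric(1))
    r2 <- r2[!is.na(r2)]
    structure(list(r2c = unname(quantile(r2, percentile / 100)),
                   percentile = percentile, n_pairs = n_pairs, seed = seed),
              class = "critical_r2")
  })
}

#' @export
print.critical_r2 <- function(x, ...) {
  cat(sprintf("<critical_r2> r2c = %.4f (%.1fth percentile of %d unlinked pairs)\n",
              x$r2c, x$percentile, x$n_pairs))
  invisible(x)
}

#' Group significant SNPs into LD-block QTL intervals
#'
#' Significant SNPs on one chromosome are clustered into LD blocks by
#' average-linkage agglomerative clustering on the distance
#' \eqn{d = 1 - \sqrt{r^2}} (the square-root transform makes LD closer to
#' normally distributed), with the tree cut at \eqn{1 - \sqrt{r^2_c}} so the
#' cutoff lives on the same scale as the distances (`transform = "sqrt"`,
#' the default; `"raw"` clusters on \eqn{1 - r^2} cut at \eqn{1 - r^2_c}).
#' Each cluster becomes one QTL whose bounds are the min/max member
#' positions and whose peak is the most significant member (ties broken by
#' smaller position, then snp id).
#'
#' @param sig Tibble of significant SNPs for one trait: columns `snp_id`,
#'   `chrom`, `pos_bp`, `minus_log10_p`, `slope` and optionally `maf`.
#' @param panel The `genotype_panel` (line genotypes used for LD).
#' @param r2c Critical r-squared (a number or a [critical_r2()] object).
#' @param trait Trait label carried into the output.
#' @param transform `"sqrt"` (default) or `"raw"`.
#' @return A tibble of QTL intervals: `trait`, `chrom`, `lower_bp`,
#'   `peak_bp`, `upper_bp`, `peak_snp`, `minus_log10_p`, `slope`,
#'   `slope_sign`, `maf`, `n_members`, `members` (list column), ordered by
#'   (trait, chrom, lower_bp).
#' @export
cluster_significant_snps <- function(sig, panel, r2c, trait = "trait",
                                     transform = c("sqrt", "raw")) {
  transform <- match.arg(transform)
  if (inherits(r2c, "critical_r2")) r2c <- r2c$r2c
  sig <- tibble::as_tibble(sig)
  stopifnot(all(c("snp_id", "chrom", "pos_bp", "minus_log10_p") %in% names(sig)),
            nrow(sig) >= 1)
  cut_h <- if (transform == "sqrt") 1 - sqrt(r2c) else 1 - r2c
  out <- lapply(split(sig, sig$chrom), function(sc) {
    if (nrow(sc) == 1) {
      cl <- 1L
    } else {
      R <- r2_matrix(panel$geno[, sc$snp_id, drop = FALSE])
      R[is.na(R)] <- 0
      D <- if (transform == "sqrt") 1 - sqrt(R) else 1 - R
      hc <- hclust(as.dist(D), method = "average")
      cl <- cutree(hc, h = cut_h)
    }
    dplyr::bind_rows(lapply(split(seq_len(nrow(sc)), cl), function(idx) {
      mem <- sc[idx, ]
      peak <- dplyr::arrange(mem, dplyr::desc(.data$minus_log10_p),
                             .data$pos_bp, .data$snp_id)[1, ]
      tibble::tibble(
        trait = trait, chrom = mem$chrom[1],
        lower_bp = min(mem$pos_bp), peak_bp = peak$pos_bp,
        upper_bp = max(mem$pos_bp), peak_snp = peak$snp_id,
        minus_log10_p = peak$minus_log10_p,
        slope = if ("slope" %in% names(peak)) peak$slope else NA_real_,
        slope_sign = if ("slope" %in% names(peak)) sign(peak$slope) else NA_real_,
        maf = if ("maf" %in% names(peak)) peak$maf else NA_real_,
        n_members = nrow(mem), members = list(sort(mem$snp_id)))
    }))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$trait, .data$chrom,
                 .data$lower_bp)
}

#' Do two QTL intervals overlap?
#'
#' QTLs of different traits are called overlapping when they share at least
#' one significant member SNP and their peak positions are less than one
#' tenth of the chromosome's physical length apart. QTLs on different
#' chromosomes never overlap.
#'
#' @param a,b One-row QTL tibbles as returned by
#'   [cluster_significant_snps()].
#' @param chrom_length_bp Total physical length of the chromosome (bp).
#' @return `TRUE` or `FALSE`.
#' @export
qtl_overlap <- function(a, b, chrom_length_bp) {
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  shared <- length(intersect(a$members[[1]], b$members[[1]])) > 0
  shared && abs(a$peak_bp[1] - b$peak_bp[1]) < chrom_length_bp / 10
}
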