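#' Derive kernel-number yield components
#'
#' From plot yield Y (g/m2), thousand-kernel weight TKW (g) and spike density
#' NSM2 (spikes/m2): kernels per m2 `NKM2 = 1000 * Y / TKW` and kernels per
#' spike `NKS = 1000 * Y / (TKW * NSM2) = NKM2 / NSM2`. Formulas are applied
#' per plot, never to treatment means.
#'
#' @param pheno Data frame with columns `Y`, `TKW` and (for NKS) `NSM2`.
#' @return `pheno` as a tibble with `NKM2` and `NKS` columns added; plots
#'   with non-positive TKW or NSM2 get `NA` with a warning.
#' @export
#' @examples
#' derive_yield_components(tibble::tibble(Y = 300, TKW = 50, NSM2 = 200))
derive_yield_components <- function(pheno) {
  pheno <- tibble::as_tibble(pheno)
  stopifnot(all(c("Y", "TKW") %in% names(pheno)))
  bad_tkw <- !is.na(pheno$TKW) & pheno$TKW <= 0
  if (any(bad_tkw)) {
    warn(sprintf("%d plot(s) with non-positive TKW: NKM2/NKS set to NA",
                 sum(bad_tkw)))
  }
  pheno$NKM2 <- ifelse(bad_tkw, NA_real_, 1000 * pheno$Y / pheno$TKW)
  if ("NSM2" %in% names(pheno)) {
    bad_nsm <- !is.na(pheno$NSM2) & pheno$NSM2 <= 0
    if (any(bad_nsm)) {
      warn(sprintf("%d plot(s) with non-positive NSM2: NKS set to NA",
                   sum(bad_nsm)))
    }
    pheno$NKS <- ifelse(bad_nsm, NA_real_, pheno$NKM2 / pheno$NSM2)
  }
  pheno
}

#' Per-trait treatment ANOVA
#'
#' Least-squares ANOVA of one trait on treatment and block-within-treatment,
#' reporting the treatment test on the -log10 scale together with the
#' per-treatment means and the percent mean difference
#' `100 * (mean_CWD - mean_R) / mean_R`.
#'
#' @param pheno Plot-level phenotype tibble with `treatment`, `block` and the
#'   trait column.
#' @param trait Trait column name.
#' @param ref,alt Treatment labels used as reference (R) and alternative
#'   (CWD) when forming the percent difference.
#' @return One-row tibble: `trait`, `mean_R`, `mean_CWD`, `pct_diff`,
#'   `minus_log10_p`, `significant` (at -log10 p = 1.301, i.e. p = 0.05).
#' @export
treatment_anova <- function(pheno, trait, ref = "R", alt = "CWD") {
  pheno <- tibble::as_tibble(pheno)
  stopifnot(trait %in% names(pheno))
  trs <- unique(pheno$treatment)
  if (length(trs) < 2) abort("both treatments must be present")
  d <- data.frame(y = pheno[[trait]],
                  treatment = factor(pheno$treatment),
                  block = factor(pheno$block))
  d <- d[complete.cases(d), ]
  fit <- lm(y ~ treatment + treatment:block, data = d)
  an <- anova(fit)
  p <- an[["Pr(>F)"]][rownames(an) == "treatment"]
  m_ref <- mean(d$y[d$treatment == ref])
  m_alt <- mean(d$y[d$treatment == alt])
  mlp <- -log10(p)
  tibble::tibble(trait = trait, mean_R = m_ref, mean_CWD = m_alt,
                 pct_diff = 100 * (m_alt - m_ref) / m_ref,
                 minus_log10_p = mlp,
                 significant = mlp > -log10(0.05))
}

#' Pairwise Pearson trait correlations
#'
#' Correlation matrix with per-pair p-values, either within one treatment or
#' over all plots. For `subset = "all"` correlations are computed on
#' residuals after removing per-treatment means (a treatment covariate), so
#' a pure treatment shift does not masquerade as a trait correlation.
#'
#' @param pheno Plot-level phenotype tibble.
#' @param traits Character vector of trait columns.
#' @param subset `"all"`, or a treatment label to restrict to.
#' @return A `trait_cor` object holding matrices `r` and `p` plus `n`;
#'   constant traits yield `NA` entries. Use [tidy()] for a long tibble.
#' @export
trait_correlations <- function(pheno, traits, subset = "all") {
  pheno <- tibble::as_tibble(pheno)
  stopifnot(all(traits %in% names(pheno)))
  if (!identical(subset, "all")) {
    pheno <- dplyr::filter(pheno, .data$treatment == subset)
  }
  if (nrow(pheno) < 3) abort("need at least 3 plots in the subset")
  X <- as.matrix(pheno[traits])
  if (identical(subset, "all")) {
    tr <- factor(pheno$treatment)
    X <- apply(X, 2, function(col) col - ave(col, tr))
  }
  q <- length(traits)
  r <- diag(1, q); p <- matrix(NA_real_, q, q)
  dimnames(r) <- dimnames(p) <- list(traits, traits)
  for (i in seq_len(q - 1)) for (j in (i + 1):q) {
    xi <- X[, i]; xj <- X[, j]
    ok <- is.finite(xi) & is.finite(xj)
    if (sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- suppressWarnings(cor.test(xi[ok], xj[ok]))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = nrow(X), subset = subset),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  cat(sprintf("<trait_cor> Pearson correlations (%s, n = %d plots)\n",
              x$subset, x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trait_cor <- function(x, ...) {
  traits <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(trait1 = traits[idx[, 1]], trait2 = traits[idx[, 2]],
                 r = x$r[idx], p_value = x$p[idx])
}
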