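#' Per-treatment diversity slopes across the genome
#'
#' Within one treatment's plots, fits for every SNP the model
#' \deqn{P = \mu + \beta_k HE_k + Block + e}
#' by ordinary least squares (block dummies included) and returns the partial
#' slope \eqn{\beta_k} of the trait on Nei diversity at SNP k. SNPs whose
#' diversity is constant within the treatment are excluded (`NA`).
#'
#' @param pheno Plot-level phenotype tibble.
#' @param HE Mixtures x SNPs diversity matrix, restricted by the caller to
#'   SNPs eligible in both treatments.
#' @param design A `mixture_design` with plots.
#' @param trait Trait column.
#' @param treatment Treatment label to subset to.
#' @return A tibble `snp_id`, `slope` (NA for excluded SNPs).
#' @export
per_treatment_slopes <- function(pheno, HE, design, trait, treatment) {
  pheno <- tibble::as_tibble(pheno)
  plots <- design_plots(design)
  plots <- dplyr::filter(plots, .data$treatment == !!treatment)
  d <- dplyr::inner_join(plots, pheno[, c("plot_id", trait)], by = "plot_id")
  d <- d[!is.na(d[[trait]]), ]
  n_blocks <- length(unique(d$block))
  if (nrow(d) < n_blocks + 2) {
    abort(sprintf("too few plots (%d) in treatment %s", nrow(d), treatment))
  }
  y <- d[[trait]]
  X0 <- model.matrix(~f, data.frame(f = factor(d$block)))
  q0 <- qr(X0)
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  H <- HE[d$mixture_id, , drop = FALSE]
  Ht <- H - Q0 %*% crossprod(Q0, H)
  a <- colSums(Ht^2)
  const <- a <= 1e-10 * pmax(colSums(H^2), 1)
  beta <- drop(crossprod(Ht, y)) / a
  beta[const] <- NA_real_
  tibble::tibble(snp_id = colnames(H) %||% as.character(seq_len(ncol(H))),
                 slope = unname(beta))
}

# Internal: signed-rank -log10 p with standard tie handling (exact zeros
# dropped); degenerate when everything is zero.
signed_rank_mlp <- function(v, alternative = "two.sided") {
  v <- v[!is.na(v)]
  nz <- v[v != 0]
  if (!length(nz)) return(NA_real_)
  p <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = alternative, exact = FALSE)$p.value)
  -log10(p)
}

#' Census of diversity-slope signs in one treatment
#'
#' Counts strictly positive and strictly negative per-SNP diversity slopes
#' and tests, by a one-sample Wilcoxon signed-rank test of the slope vector
#' against zero, whether diversity has a predominantly positive or negative
#' genome-wide effect on the trait. Exact zero slopes are excluded from the
#' signed-rank statistic and reported separately. Significance is read
#' against `-log10 p = 1.301` (p = 0.05). Because SNPs are not pruned for
#' LD, slopes are correlated and the p-value is anti-conservative; treat it
#' as descriptive.
#'
#' @param slopes Tibble from [per_treatment_slopes()] (or any tibble with a
#'   `slope` column).
#' @param trait,treatment Labels carried into the output.
#' @param alternative Passed to [stats::wilcox.test()]; default two-sided.
#' @return One-row tibble: `trait`, `treatment`, `n_positive`, `n_negative`,
#'   `n_zero`, `minus_log10_p`, `significant`.
#' @export
sign_census <- function(slopes, trait = "trait", treatment = "",
                        alternative = "two.sided") {
  v <- slopes$slope
  v <- v[!is.na(v)]
  if (length(v) < 10) abort("need at least 10 slopes for a census")
  mlp <- signed_rank_mlp(v, alternative)
  tibble::tibble(trait = trait, treatment = treatment,
                 n_positive = sum(v > 0), n_negative = sum(v < 0),
                 n_zero = sum(v == 0), minus_log10_p = mlp,
                 significant = !is.na(mlp) & mlp > -log10(0.05))
}

#' Paired test of the stress-gradient hypothesis
#'
#' The stress-gradient hypothesis predicts that diversity's effect on
#' performance becomes more positive under stress. For each SNP the paired
#' slope difference \eqn{\Delta_k = \beta_{CWD,k} - \beta_{R,k}} is formed
#' and a Wilcoxon signed-rank test applied to the \eqn{\Delta} vector. The
#' direction summary says whether the median shift supports the prediction
#' (slopes higher under controlled water deficit) or runs against it.
#'
#' @param beta_cwd,beta_r Tibbles from [per_treatment_slopes()] for the CWD
#'   and R treatments (paired by `snp_id`).
#' @param trait Label carried into the output.
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   one-sided directional test of Delta > 0.
#' @return One-row tibble: `trait`, `n_delta_positive`, `n_delta_negative`,
#'   `n_delta_zero`, `minus_log10_p`, `significant`, `direction` (one of
#'   `"supports stress gradient"`, `"against stress gradient"`, `"none"`).
#' @export
stress_gradient_test <- function(beta_cwd, beta_r, trait = "trait",
                                 alternative = "two.sided") {
  d <- dplyr::inner_join(
    dplyr::rename(beta_cwd, b_cwd = "slope"),
    dplyr::rename(beta_r, b_r = "slope"), by = "snp_id")
  d <- d[!is.na(d$b_cwd) & !is.na(d$b_r), ]
  if (nrow(d) < 10) abort("need at least 10 paired slopes")
  delta <- d$b_cwd - d$b_r
  mlp <- signed_rank_mlp(delta, alternative)
  md <- median(delta)
  direction <- if (md > 0) "supports stress gradient" else if (md < 0) {
    "against stress gradient"
  } else "none"
  tibble::tibble(trait = trait,
                 n_delta_positive = sum(delta > 0),
                 n_delta_negative = sum(delta < 0),
                 n_delta_zero = sum(delta == 0),
                 minus_log10_p = mlp,
                 significant = !is.na(mlp) & mlp > -log10(0.05),
                 direction = direction)
}
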