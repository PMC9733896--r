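#' Sequential (type-I) ANOVA over an ordered list of model terms
#'
#' Fits nested least-squares models by adding the terms in the order given;
#' each term's sum of squares is the drop in residual SS when it enters after
#' all preceding terms. F statistics test every term against the residual
#' mean square of the full model. Terms adding no rank (collinear with what
#' precedes them) get 0 df and no test.
#'
#' @param y Numeric response vector.
#' @param terms Named list of term blocks, in fitting order. Each element is
#'   a numeric vector/matrix of covariates or a factor (expanded to treatment
#'   contrasts).
#' @param intercept Fit an intercept before all terms (default `TRUE`).
#' @return A tibble with one row per term plus a `"residual"` row: `term`,
#'   `df`, `ss`, `f_stat`, `p_value`.
#' @export
#' @examples
#' y <- c(1, 2, 3, 4, 6, 7)
#' g <- factor(rep(c("a", "b"), each = 3))
#' sequential_anova(y, list(group = g))
sequential_anova <- function(y, terms, intercept = TRUE) {
  stopifnot(is.list(terms), length(terms) >= 1, !is.null(names(terms)))
  n <- length(y)
  expand <- function(tm) {
    if (is.factor(tm) || is.character(tm)) {
      model.matrix(~f, data.frame(f = factor(tm)))[, -1, drop = FALSE]
    } else {
      as.matrix(tm)
    }
  }
  X <- if (intercept) matrix(1, n, 1) else matrix(numeric(0), n, 0)
  q <- if (ncol(X)) qr(X) else NULL
  rank_prev <- if (is.null(q)) 0L else q$rank
  rss_prev <- if (is.null(q)) sum(y^2) else sum(qr.resid(q, y)^2)
  out <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    X <- cbind(X, expand(terms[[i]]))
    q <- qr(X)
    if (q$rank >= n && i < length(terms)) {
      # saturated before the last term: remaining terms get 0 df
    }
    df_i <- q$rank - rank_prev
    rss_i <- if (q$rank < n) sum(qr.resid(q, y)^2) else 0
    out[[i]] <- list(term = names(terms)[i], df = df_i,
                     ss = rss_prev - rss_i)
    rank_prev <- q$rank
    rss_prev <- rss_i
  }
  df_res <- n - rank_prev
  ms_res <- if (df_res > 0) rss_prev / df_res else NA_real_
  res <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  res$f_stat <- ifelse(res$df > 0, (res$ss / res$df) / ms_res, NA_real_)
  res$p_value <- ifelse(res$df > 0, pf(res$f_stat, res$df, df_res,
                                       lower.tail = FALSE), NA_real_)
  dplyr::bind_rows(res, tibble::tibble(term = "residual", df = df_res,
                                       ss = rss_prev, f_stat = NA_real_,
                                       p_value = NA_real_))
}

# Internal: base design matrix for the scan and its pre-genetic sequential SS.
# shared coding fits the 4 block labels (reused across treatments) before
# treatment; nested coding fits treatment first then block-within-treatment,
# which is also the coding under which the interaction coefficient equals
# beta_CWD - beta_R from per-treatment fits.
scan_base <- function(block, tvec, coding = c("shared", "nested")) {
  coding <- match.arg(coding)
  block <- factor(block)
  n <- length(tvec)
  if (coding == "shared") {
    terms <- list(block = block, treatment = tvec)
  } else {
    bt <- interaction(factor(ifelse(tvec == 1, "CWD", "R")), block, drop = TRUE)
    terms <- list(treatment = tvec, block = bt)
  }
  Xb <- model.matrix(~f, data.frame(f = block))[, -1, drop = FALSE]
  X0 <- if (coding == "shared") {
    cbind(1, Xb, tvec)
  } else {
    Xbt <- model.matrix(~f, data.frame(
      f = interaction(factor(tvec), block, drop = TRUE)))[, -1, drop = FALSE]
    cbind(1, tvec, Xbt)
  }
  list(X0 = X0, terms = terms, coding = coding)
}

# Internal vectorised scan core: sequential type-I ANOVA across all SNP
# columns of H at once. Terms enter as (base terms, genetic, interaction);
# each F-test uses the full model's residual mean square.
scan_engine <- function(y, block, tvec, H, coding = "shared") {
  n <- length(y)
  base <- scan_base(block, tvec, coding)
  X0 <- base$X0
  q0 <- qr(X0)
  p0 <- q0$rank
  Q0 <- qr.Q(q0)[, seq_len(p0), drop = FALSE]
  y0 <- y - Q0 %*% crossprod(Q0, y)
  ss_after0 <- sum(y0^2)

  # pre-genetic terms are SNP-independent: sequential SS computed once
  pre <- sequential_anova(y, base$terms)
  ss_block <- pre$ss[pre$term == "block"]
  df_block <- pre$df[pre$term == "block"]
  ss_treat <- pre$ss[pre$term == "treatment"]
  df_treat <- pre$df[pre$term == "treatment"]

  Ht <- H - Q0 %*% crossprod(Q0, H)
  a <- colSums(Ht^2)
  scale_h <- pmax(colSums(H^2), 1)
  degenerate <- a <= 1e-10 * scale_h
  u <- drop(crossprod(Ht, y))

  G <- H * tvec
  Gt <- G - Q0 %*% crossprod(Q0, G)
  b <- colSums(Ht * Gt)
  cc <- colSums(Gt^2)
  r2n <- cc - ifelse(a > 0, b^2 / a, 0)
  v <- drop(crossprod(Gt, y))
  int_ok <- !degenerate & r2n > 1e-10 * pmax(colSums(G^2), 1)

  ss_gen <- ifelse(degenerate, NA_real_, u^2 / a)
  r2y <- v - ifelse(a > 0, (b / a) * u, 0)
  ss_int <- ifelse(int_ok, r2y^2 / r2n, ifelse(degenerate, NA_real_, 0))

  df_full <- p0 + ifelse(degenerate, 0L, 1L) + ifelse(int_ok, 1L, 0L)
  df_res <- n - df_full
  rss <- ss_after0 - ifelse(degenerate, 0, ss_gen) - ifelse(int_ok, ss_int, 0)
  ms_res <- rss / df_res

  f_gen <- ss_gen / ms_res
  p_gen <- pf(f_gen, 1, df_res, lower.tail = FALSE)
  f_int <- ifelse(int_ok, ss_int / ms_res, NA_real_)
  p_int <- ifelse(int_ok, pf(f_int, 1, df_res, lower.tail = FALSE), NA_real_)
  f_tr <- (ss_treat / df_treat) / ms_res
  p_tr <- pf(f_tr, df_treat, df_res, lower.tail = FALSE)

  det <- a * cc - b^2
  slope_gen <- ifelse(int_ok, (cc * u - b * v) / det,
                      ifelse(degenerate, NA_real_, u / a))
  slope_int <- ifelse(int_ok, (a * v - b * u) / det, NA_real_)

  tibble::tibble(
    snp_id = colnames(H) %||% as.character(seq_len(ncol(H))),
    minus_log10_p_treatment = as.numeric(-log10(p_tr)),
    minus_log10_p_genetic = as.numeric(-log10(p_gen)),
    minus_log10_p_interaction = as.numeric(-log10(p_int)),
    slope_genetic = as.numeric(slope_gen),
    slope_interaction = as.numeric(slope_int),
    ss_block = ss_block, ss_treatment = ss_treat,
    ss_genetic = as.numeric(ss_gen),
    ss_interaction = as.numeric(ifelse(int_ok, ss_int, NA_real_)),
    ss_residual = as.numeric(rss), df_residual = as.numeric(df_res),
    degenerate = unname(degenerate))
}

# Internal shared front end for both scans.
run_scan <- function(pheno, X, design, trait, kind, map = NULL,
                     block_coding = "shared") {
  pheno <- tibble::as_tibble(pheno)
  stopifnot(trait %in% names(pheno))
  plots <- design_plots(design)
  pheno <- dplyr::inner_join(plots, pheno[, c("plot_id", trait)], by = "plot_id")
  y <- pheno[[trait]]
  if (mean(is.na(y)) > 0.10) {
    abort(sprintf("trait %s missing for more than 10%% of plots", trait))
  }
  keep <- !is.na(y)
  pheno <- pheno[keep, ]
  y <- y[keep]
  miss <- setdiff(pheno$mixture_id, rownames(X))
  if (length(miss)) abort(sprintf("mixtures missing from genetic matrix: %s",
                                  paste(head(miss, 3), collapse = ", ")))
  H <- X[pheno$mixture_id, , drop = FALSE]
  tvec <- as.numeric(pheno$treatment == "CWD")
  res <- scan_engine(y, pheno$block, tvec, H, coding = block_coding)
  res$trait <- trait
  res$scan_kind <- kind
  if (!is.null(map)) {
    res <- dplyr::left_join(res, map[, c("snp_id", "chrom", "pos_bp")],
                            by = "snp_id")
  }
  res <- dplyr::relocate(res, "trait", "scan_kind", "snp_id")
  class(res) <- c("mixscan_scan", class(res))
  attr(res, "n_plots") <- length(y)
  res
}

#' Genome-wide diversity association scan (GWDA)
#'
#' For each SNP, fits the plot-level linear model
#' \deqn{y = \mu + Block + T + HE_k + T{\times}HE_k + e}
#' by least squares and tests each term with sequential type-I sums of
#' squares, in that order, against the full model's residual mean square.
#' \eqn{HE_k} is the mixture-level Nei diversity at SNP k mapped to plots.
#' SNPs whose regressor is constant across plots (given the design) are
#' flagged `degenerate` and not tested.
#'
#' @param pheno Plot-level phenotype tibble (`plot_id` + trait column).
#' @param HE Mixtures x SNPs Nei diversity matrix (from [nei_diversity()]),
#'   restricted to eligible SNPs by the caller (see [eligible_snps()]).
#' @param design A `mixture_design` with plots.
#' @param trait Trait column to scan.
#' @param map Optional SNP map (`snp_id`, `chrom`, `pos_bp`) to attach.
#' @param block_coding `"shared"` (default) fits the block labels, reused
#'   across treatments, before the treatment term -- the only coding under
#'   which the term order (Block, T, genetics, interaction) leaves the
#'   treatment term its df. `"nested"` fits treatment first and then
#'   block-within-treatment; under it the interaction slope equals the
#'   difference of per-treatment diversity slopes.
#' @return A `mixscan_scan` tibble, one row per SNP, with -log10 p-values for
#'   the treatment, genetic and interaction terms, slopes of the genetic term
#'   (reference treatment R) and of the interaction (CWD minus R), sequential
#'   SS per term and residual df.
#' @seealso [gwfa_scan()], [sequential_anova()], [effective_tests_galwey()]
#' @export
gwda_scan <- function(pheno, HE, design, trait, map = NULL,
                      block_coding = c("shared", "nested")) {
  run_scan(pheno, HE, design, trait, "GWDA", map, match.arg(block_coding))
}

#' Genome-wide frequency association scan (GWFA)
#'
#' Same model and sequential tests as [gwda_scan()], with the mixture allele
#' frequency \eqn{F_k} as the genetic regressor (classical allele-frequency
#' association extended to mixtures).
#'
#' @inheritParams gwda_scan
#' @param F Mixtures x SNPs allele-frequency matrix.
#' @return A `mixscan_scan` tibble (see [gwda_scan()]).
#' @export
gwfa_scan <- function(pheno, F, design, trait, map = NULL,
                      block_coding = c("shared", "nested")) {
  run_scan(pheno, F, design, trait, "GWFA", map, match.arg(block_coding))
}

#' @exportS3Method generics::glance
glance.mixscan_scan <- function(x, ...) {
  tibble::tibble(
    trait = x$trait[1], scan_kind = x$scan_kind[1],
    n_snps = nrow(x), n_degenerate = sum(x$degenerate),
    max_minus_log10_p = max(x$minus_log10_p_genetic, na.rm = TRUE),
    n_plots = attr(x, "n_plots") %||% NA_integer_)
}

#' Incremental test of diversity beyond frequency (HE vs. F)
#'
#' A diversity association at a SNP could be an allele-frequency effect in
#' disguise, because HE is a deterministic function of F. For a detected
#' HE-QTL peak this test asks whether HE explains the trait beyond F: the
#' reference model contains blocks, treatment, \eqn{F_k} and
#' \eqn{T{\times}F_k}; the augmented model adds \eqn{HE_k} (and
#' \eqn{T{\times}HE_k} when the QTL was detected on the interaction term),
#' and the added term(s) are tested by an incremental F-test against the
#' augmented model's residual. Since HE is quadratic in F, the augmented
#' model nests the reference one. The significance threshold is Bonferroni
#' over the number of detected HE-QTLs: `-log10(alpha / n_detected)`.
#'
#' @param pheno Plot-level phenotype tibble.
#' @param design A `mixture_design` with plots.
#' @param F_k,HE_k Named numeric vectors (mixture id -> frequency /
#'   diversity) for the peak SNP.
#' @param trait Trait column.
#' @param n_detected Number of detected HE-QTLs entering the Bonferroni
#'   correction.
#' @param interaction_qtl Was the QTL detected on the T x HE term? If so the
#'   interaction column joins the augmented model too.
#' @param alpha Family-wise level (default 0.05).
#' @return One-row tibble: `trait`, `minus_log10_p`, `df`, `f_stat`,
#'   `threshold_minus_log10`, `significant`, `flagged_collinear`.
#' @export
he_vs_f_test <- function(pheno, design, F_k, HE_k, trait, n_detected,
                         interaction_qtl = FALSE, alpha = 0.05) {
  stopifnot(n_detected >= 1)
  thr <- -log10(alpha / n_detected)
  plots <- design_plots(design)
  pheno <- dplyr::inner_join(plots, tibble::as_tibble(pheno)[, c("plot_id", trait)],
                             by = "plot_id")
  d <- data.frame(y = pheno[[trait]], block = factor(pheno$block),
                  t = as.numeric(pheno$treatment == "CWD"),
                  f = unname(F_k[pheno$mixture_id]),
                  he = unname(HE_k[pheno$mixture_id]))
  d <- d[complete.cases(d), ]
  if (length(unique(d$f)) < 3) {
    return(tibble::tibble(trait = trait, minus_log10_p = NA_real_,
                          df = NA_integer_, f_stat = NA_real_,
                          threshold_minus_log10 = thr, significant = NA,
                          flagged_collinear = TRUE))
  }
  ref <- lm(y ~ block + t + f + t:f, data = d)
  aug <- if (interaction_qtl) {
    lm(y ~ block + t + f + t:f + he + t:he, data = d)
  } else {
    lm(y ~ block + t + f + t:f + he, data = d)
  }
  cmp <- anova(ref, aug)
  p <- cmp[["Pr(>F)"]][2]
  mlp <- -log10(p)
  tibble::tibble(trait = trait, minus_log10_p = mlp,
                 df = as.integer(cmp$Df[2]), f_stat = cmp$F[2],
                 threshold_minus_log10 = thr,
                 significant = mlp > thr, flagged_collinear = FALSE)
}
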