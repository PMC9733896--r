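#' Run the full mixture-diversity association pipeline
#'
#' End-to-end orchestration: per-mixture allele frequencies and Nei
#' diversity, SNP eligibility, GWFA and GWDA scans for every trait, Galwey
#' multiplicity correction, LD-block QTL intervals (with the incremental
#' HE-vs-F test on every detected HE-QTL peak), and the genome-wide slope
#' census with the paired stress-gradient test. All randomness (the
#' critical-r2 pair sampling) derives from `seed`.
#'
#' @param panel A `genotype_panel`.
#' @param design A `mixture_design` with plot layout.
#' @param pheno Plot-level phenotype tibble (`plot_id` + trait columns).
#' @param traits Character vector of trait columns to analyse.
#' @param alpha Family-wise level (default 0.05).
#' @param r2_percentile,n_pairs Critical-r2 settings (see [critical_r2()]).
#' @param transform Clustering scale for QTL intervals (`"sqrt"` or
#'   `"raw"`).
#' @param seed Integer seed.
#' @param out_dir Optional directory: when given, result tables are written
#'   as TSV (`scans.tsv`, `qtl.tsv`, `census.tsv`, `manifest.tsv`).
#' @return A list bundle: `freq` (F matrix), `he` (HE matrix),
#'   `eligibility`, `multiplicity`, `scans` (one tibble, all traits and both
#'   scan kinds), `qtl` (intervals incl. HE-vs-F columns), `census`,
#'   `stress_gradient`, `manifest` (filtering counts).
#' @export
run_pipeline <- function(panel, design, pheno, traits, alpha = 0.05,
                         r2_percentile = 99.9, n_pairs = 10000,
                         transform = "sqrt", seed = NULL, out_dir = NULL) {
  validate_design(design)
  Fm <- mixture_allele_frequencies(panel, design)
  HEm <- nei_diversity(Fm)
  elig <- eligible_snps(Fm)
  elig_ids <- elig$snp_id[elig$eligible]
  poly_ids <- elig$snp_id[elig$f_max > elig$f_min]
  if (!length(elig_ids)) abort("no SNPs pass the eligibility filter")

  mult <- effective_tests_galwey(Fm[, poly_ids, drop = FALSE], panel$map,
                                 alpha = alpha)
  thr <- mult$threshold_minus_log10

  maf <- pmin(colMeans(Fm), 1 - colMeans(Fm))
  scans <- dplyr::bind_rows(lapply(traits, function(tr) {
    dplyr::bind_rows(
      gwfa_scan(pheno, Fm[, poly_ids, drop = FALSE], design, tr,
                map = panel$map),
      gwda_scan(pheno, HEm[, elig_ids, drop = FALSE], design, tr,
                map = panel$map))
  }))

  qtl <- dplyr::bind_rows(lapply(c("GWFA", "GWDA"), function(kind) {
    dplyr::bind_rows(lapply(traits, function(tr) {
      sc <- dplyr::filter(scans, .data$scan_kind == kind, .data$trait == tr,
                          !.data$degenerate)
      sig <- dplyr::filter(
        sc, .data$minus_log10_p_genetic > thr |
          (!is.na(.data$minus_log10_p_interaction) &
             .data$minus_log10_p_interaction > thr))
      if (!nrow(sig)) return(NULL)
      sig <- dplyr::transmute(
        sig, snp_id = .data$snp_id, chrom = .data$chrom,
        pos_bp = .data$pos_bp,
        minus_log10_p = pmax(.data$minus_log10_p_genetic,
                             .data$minus_log10_p_interaction, na.rm = TRUE),
        slope = .data$slope_genetic,
        interaction_hit = !is.na(.data$minus_log10_p_interaction) &
          .data$minus_log10_p_interaction > thr &
          .data$minus_log10_p_genetic <= thr,
        maf = unname(maf[.data$snp_id]))
      r2c <- critical_r2(panel, n_pairs = n_pairs,
                         percentile = r2_percentile, seed = seed)
      q <- cluster_significant_snps(sig, panel, r2c, trait = tr,
                                    transform = transform)
      q$scan_kind <- kind
      q$interaction_qtl <- vapply(q$members, function(m) {
        all(sig$interaction_hit[match(m, sig$snp_id)])
      }, logical(1))
      q
    }))
  }))

  # HE-vs-F incremental test on every detected HE-QTL peak
  if (!is.null(qtl) && nrow(qtl)) {
    he_qtl <- which(qtl$scan_kind == "GWDA")
    n_det <- length(he_qtl)
    qtl$he_vs_f_minus_log10_p <- NA_real_
    qtl$he_vs_f_significant <- NA
    for (i in he_qtl) {
      hv <- he_vs_f_test(pheno, design, Fm[, qtl$peak_snp[i]],
                         HEm[, qtl$peak_snp[i]], qtl$trait[i],
                         n_detected = n_det,
                         interaction_qtl = qtl$interaction_qtl[i],
                         alpha = alpha)
      qtl$he_vs_f_minus_log10_p[i] <- hv$minus_log10_p
      qtl$he_vs_f_significant[i] <- hv$significant
    }
  }

  # genome-wide slope census on SNPs eligible in the design (both
  # treatments see every mixture's HE, so the eligible set is shared)
  census <- NULL; sgh <- NULL
  for (tr in traits) {
    b_cwd <- per_treatment_slopes(pheno, HEm[, elig_ids, drop = FALSE],
                                  design, tr, "CWD")
    b_r <- per_treatment_slopes(pheno, HEm[, elig_ids, drop = FALSE],
                                design, tr, "R")
    census <- dplyr::bind_rows(
      census,
      sign_census(b_cwd, trait = tr, treatment = "CWD"),
      sign_census(b_r, trait = tr, treatment = "R"))
    sgh <- dplyr::bind_rows(sgh, stress_gradient_test(b_cwd, b_r, trait = tr))
  }

  manifest <- tibble::tibble(
    step = c("snps_total", "snps_polymorphic", "snps_eligible", "m_eff",
             "threshold_minus_log10", "n_plots", "n_qtl"),
    value = c(ncol(panel$geno), length(poly_ids), length(elig_ids),
              mult$m_eff, thr, nrow(design_plots(design)),
              if (is.null(qtl)) 0 else nrow(qtl)))

  out <- list(freq = Fm, he = HEm, eligibility = elig, multiplicity = mult,
              scans = scans, qtl = qtl, census = census,
              stress_gradient = sgh, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(scans, file.path(out_dir, "scans.tsv"))
    if (!is.null(qtl) && nrow(qtl)) {
      readr::write_tsv(
        dplyr::mutate(qtl, members = vapply(.data$members, paste,
                                            character(1), collapse = ";")),
        file.path(out_dir, "qtl.tsv"))
    }
    readr::write_tsv(dplyr::bind_rows(census), file.path(out_dir, "census.tsv"))
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }
  out
}
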