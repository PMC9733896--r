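#' Read and write genotype panels
#'
#' The text format is a delimited dosage matrix (lines x SNPs, with line ids
#' in the first column and SNP ids as header) plus a tab-separated SNP map
#' (`snp_id`, `chrom`, `pos_bp`). `read_genotypes()` validates dosages,
#' rejects duplicate SNP ids and missing calls, and sorts SNPs by position
#' within chromosome. Coordinates are 1-based inclusive bp throughout.
#'
#' @param path,map_path Paths to the matrix file and SNP map file.
#' @param panel A `genotype_panel` (for writing).
#' @return `read_genotypes()` a `genotype_panel`; the writers return the
#'   path(s) invisibly.
#' @export
read_genotypes <- function(path, map_path) {
  gm <- readr::read_tsv(path, show_col_types = FALSE)
  map <- readr::read_tsv(map_path, show_col_types = FALSE)
  line_id <- gm[[1]]
  G <- as.matrix(gm[, -1])
  rownames(G) <- line_id
  if (all(G == round(G), na.rm = TRUE)) storage.mode(G) <- "integer"
  if (anyNA(G)) {
    bad <- colnames(G)[colSums(is.na(G)) > 0]
    abort(sprintf("missing genotype calls at SNP(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  map <- dplyr::arrange(map, .data$chrom, .data$pos_bp)
  map$pos_bp <- as.integer(map$pos_bp)
  genotype_panel(G[, map$snp_id, drop = FALSE], map)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(panel, path, map_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  gm <- tibble::as_tibble(panel$geno, rownames = "line_id")
  readr::write_tsv(gm, path)
  readr::write_tsv(panel$map, map_path)
  invisible(c(path, map_path))
}

#' Read a genotype panel from a VCF file
#'
#' Biallelic SNP records are converted to dosages (count of ALT alleles per
#' GT call); multi-allelic records are skipped with a message. Requires the
#' `vcfR` package.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A `genotype_panel`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  n_skip <- sum(!biallelic)
  if (n_skip) inform(sprintf("skipped %d non-biallelic record(s)", n_skip))
  gt <- vcfR::extract.gt(v)[biallelic, , drop = FALSE]
  dos <- apply(gt, 2, function(col) {
    vapply(strsplit(gsub("\\|", "/", col), "/"), function(al) {
      if (anyNA(al) || any(al == ".")) NA_real_ else sum(al == "1")
    }, numeric(1))
  })
  if (anyNA(dos)) abort("missing genotype calls in VCF")
  snp_id <- fix[biallelic, "ID"]
  snp_id[is.na(snp_id) | snp_id == "."] <- paste0(
    fix[biallelic, "CHROM"], ":", fix[biallelic, "POS"])[is.na(snp_id) | snp_id == "."]
  map <- tibble::tibble(snp_id = snp_id, chrom = fix[biallelic, "CHROM"],
                        pos_bp = as.integer(fix[biallelic, "POS"]))
  genotype_panel(t(dos), map)
}

#' Read and write mixture designs
#'
#' The design CSV is wide (`mixture_id`, `component_1` .. `component_k`);
#' the layout CSV has columns `plot_id`, `mixture_id`, `treatment`, `block`.
#'
#' @param design A `mixture_design`.
#' @param path,layout_path File paths (`layout_path` optional).
#' @return `read_design()` a `mixture_design`; writers return paths
#'   invisibly.
#' @export
write_design <- function(design, path, layout_path = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  wide <- design$compositions |>
    dplyr::group_by(.data$mixture_id) |>
    dplyr::mutate(slot = paste0("component_", dplyr::row_number())) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "slot", values_from = "line_id")
  readr::write_csv(wide, path)
  if (!is.null(layout_path) && !is.null(design$plots)) {
    readr::write_csv(design$plots, layout_path)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, layout_path = NULL) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  comp_cols <- grep("^component_", names(wide), value = TRUE)
  long <- tidyr::pivot_longer(wide, dplyr::all_of(comp_cols),
                              values_to = "line_id") |>
    dplyr::select("mixture_id", "line_id")
  k <- length(comp_cols)
  line_ids <- sort(unique(long$line_id))
  r <- nrow(long) / length(line_ids)
  if (r != round(r)) abort("design is not replication-balanced")
  plots <- if (!is.null(layout_path)) {
    readr::read_csv(layout_path, show_col_types = FALSE,
                    col_types = readr::cols(block = readr::col_character()))
  } else NULL
  d <- new_mixture_design(long, k, as.integer(r), line_ids, plots = plots)
  validate_design(d)
  d
}
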