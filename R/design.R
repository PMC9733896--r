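#' Select homogeneous mixture components from a candidate panel
#'
#' Keeps candidates whose stem height lies inside `[height_min, height_max]`,
#' finds the flowering-date window of width `flowering_window` containing the
#' most in-height candidates, and returns the `n_select` of those closest to
#' the median height (ties broken by line id). This mirrors the agronomic
#' practice of minimising within-plot competition by restricting height and
#' phenology spread among mixture components.
#'
#' @param trait_table Data frame with columns `line_id`, `height_cm`,
#'   `flowering_day` (one row per candidate line).
#' @param height_min,height_max Acceptable stem height range (cm).
#' @param flowering_window Maximum allowed flowering-day spread (days) among
#'   the selected lines.
#' @param n_select Number of lines to return.
#' @return Character vector of `n_select` selected line ids, sorted.
#' @export
#' @examples
#' tt <- tibble::tibble(line_id = sprintf("L%02d", 1:20),
#'                      height_cm = seq(85, 115, length.out = 20),
#'                      flowering_day = rep(150:154, 4))
#' filter_components(tt, 90, 110, flowering_window = 5, n_select = 6)
filter_components <- function(trait_table, height_min, height_max,
                              flowering_window, n_select) {
  stopifnot(height_min < height_max, flowering_window > 0, n_select >= 1)
  tt <- tibble::as_tibble(trait_table)
  stopifnot(all(c("line_id", "height_cm", "flowering_day") %in% names(tt)))
  in_height <- dplyr::filter(tt, .data$height_cm >= height_min,
                             .data$height_cm <= height_max)
  if (nrow(in_height) < n_select) {
    abort(sprintf(
      "only %d candidates have height in [%g, %g] cm but n_select = %d (height constraint binding)",
      nrow(in_height), height_min, height_max, n_select))
  }
  # best flowering window: slide a window of the given width over sorted days
  days <- sort(unique(in_height$flowering_day))
  counts <- vapply(days, function(d0) {
    sum(in_height$flowering_day >= d0 &
          in_height$flowering_day <= d0 + flowering_window)
  }, numeric(1))
  best <- days[which.max(counts)]
  pool <- dplyr::filter(in_height, .data$flowering_day >= best,
                        .data$flowering_day <= best + flowering_window)
  if (nrow(pool) < n_select) {
    abort(sprintf(
      "no flowering window of %g days holds %d in-height candidates (best holds %d; flowering constraint binding)",
      flowering_window, n_select, nrow(pool)))
  }
  med <- median(pool$height_cm)
  pool <- dplyr::arrange(pool, abs(.data$height_cm - med), .data$line_id)
  sort(pool$line_id[seq_len(n_select)])
}

new_mixture_design <- function(compositions, k, r, line_ids, plots = NULL) {
  structure(list(compositions = compositions, plots = plots,
                 k = k, r = r, line_ids = line_ids),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %d mixtures of k = %d components from %d lines (r = %d)\n",
              length(unique(x$compositions$mixture_id)), x$k,
              length(x$line_ids), x$r))
  if (!is.null(x$plots)) {
    cat(sprintf("  layout: %d plots, treatments %s\n", nrow(x$plots),
                paste(unique(x$plots$treatment), collapse = "/")))
  }
  invisible(x)
}

#' Accessors for mixture designs
#'
#' `design_compositions()` returns the long composition table (one row per
#' mixture component); `design_plots()` the plot layout.
#' @param design A `mixture_design`.
#' @return A tibble.
#' @export
design_compositions <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  design$compositions
}

#' @rdname design_compositions
#' @export
design_plots <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  if (is.null(design$plots)) abort("design has no plot layout; call assign_layout()")
  design$plots
}

#' Build a balanced design of unique k-way mixtures
#'
#' Samples `n_mixtures` distinct `k`-component mixtures from `line_ids` such
#' that every line appears in exactly `r = n_mixtures * k / n_lines` mixtures
#' and no two mixtures share the same composition. The sampler keeps a
#' remaining-quota counter per line, draws each mixture's `k` distinct lines
#' with probability proportional to remaining quota, and rejects duplicated
#' compositions or dead-end states, restarting the whole design up to
#' `max_restarts` times.
#'
#' @param line_ids Character vector of component line ids.
#' @param n_mixtures Number of mixtures to build.
#' @param k Components per mixture.
#' @param seed Integer seed.
#' @param max_restarts Restart budget before giving up.
#' @return A `mixture_design` (compositions only; no plot layout yet).
#' @export
#' @examples
#' d <- build_mixture_design(sprintf("L%02d", 1:12), n_mixtures = 6, k = 4, seed = 1)
#' table(design_compositions(d)$line_id)  # every line in exactly 2 mixtures
build_mixture_design <- function(line_ids, n_mixtures, k, seed = NULL,
                                 max_restarts = 200) {
  line_ids <- as.character(line_ids)
  n_lines <- length(line_ids)
  stopifnot(k >= 1, k <= n_lines, n_mixtures >= 1)
  if ((n_mixtures * k) %% n_lines != 0) {
    abort(sprintf("n_mixtures * k = %d not divisible by %d lines",
                  n_mixtures * k, n_lines))
  }
  r <- (n_mixtures * k) %/% n_lines
  with_seed(derive_seed(seed, "design"), {
    for (attempt in seq_len(max_restarts)) {
      quota <- setNames(rep(r, n_lines), line_ids)
      comps <- vector("list", n_mixtures)
      keys <- character(n_mixtures)
      ok <- TRUE
      for (j in seq_len(n_mixtures)) {
        placed <- FALSE
        for (try in 1:100) {
          avail <- names(quota)[quota > 0]
          if (length(avail) < k) break
          sel <- if (length(avail) == k) avail else {
            sample(avail, k, prob = quota[avail])
          }
          key <- paste(sort(sel), collapse = "|")
          if (j > 1 && key %in% keys[seq_len(j - 1)]) next
          comps[[j]] <- sort(sel)
          keys[j] <- key
          quota[sel] <- quota[sel] - 1L
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok && all(quota == 0)) {
        compositions <- tibble::tibble(
          mixture_id = rep(sprintf("M%03d", seq_len(n_mixtures)), each = k),
          line_id = unlist(comps))
        return(new_mixture_design(compositions, k, r, sort(line_ids)))
      }
    }
    abort(sprintf(
      "could not build a valid design in %d restarts; try another seed",
      max_restarts))
  })
}

#' Assign mixtures to treatments and blocks
#'
#' Randomly splits the mixtures evenly across treatments and, within each
#' treatment, evenly across blocks, producing one plot per mixture.
#'
#' @param design A `mixture_design`.
#' @param treatments Treatment labels; default `c("R", "CWD")` (rainfed vs
#'   controlled water deficit).
#' @param n_blocks Blocks per treatment.
#' @param seed Integer seed.
#' @return The design with a `plots` tibble (`plot_id`, `mixture_id`,
#'   `treatment`, `block`).
#' @export
assign_layout <- function(design, treatments = c("R", "CWD"), n_blocks = 4,
                          seed = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  mids <- unique(design$compositions$mixture_id)
  n <- length(mids)
  if (n %% length(treatments) != 0) {
    abort(sprintf("%d mixtures not divisible by %d treatments", n,
                  length(treatments)))
  }
  per_tr <- n %/% length(treatments)
  if (per_tr %% n_blocks != 0) {
    abort(sprintf("%d mixtures per treatment not divisible by %d blocks",
                  per_tr, n_blocks))
  }
  with_seed(derive_seed(seed, "layout"), {
    shuffled <- sample(mids)
    plots <- tibble::tibble(
      plot_id = sprintf("P%03d", seq_len(n)),
      mixture_id = shuffled,
      treatment = rep(treatments, each = per_tr),
      block = as.character(rep(rep(seq_len(n_blocks), each = per_tr %/% n_blocks),
                               times = length(treatments))))
    new_mixture_design(design$compositions, design$k, design$r,
                       design$line_ids, plots = plots)
  })
}

#' Validate a mixture design against its structural invariants
#'
#' Independent set-based re-check of the generator's guarantees: distinct
#' components within each mixture, all compositions unique as sets, equal
#' per-line replication, and (if a layout is present) one plot per mixture
#' with an even treatment split.
#'
#' @param design A `mixture_design`.
#' @return Invisibly `TRUE`; aborts with the violated invariant otherwise.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  comp <- split(design$compositions$line_id, design$compositions$mixture_id)
  if (!all(lengths(comp) == design$k)) abort("a mixture does not have k components")
  if (any(vapply(comp, anyDuplicated, integer(1)) > 0)) {
    abort("a mixture contains a duplicated line")
  }
  keys <- vapply(comp, function(s) paste(sort(s), collapse = "|"), character(1))
  if (anyDuplicated(keys)) abort("two mixtures share the same composition")
  reps <- table(design$compositions$line_id)
  if (!setequal(names(reps), design$line_ids) ||
      !all(reps == design$r)) {
    abort("per-line replication is not uniform at r")
  }
  if (!is.null(design$plots)) {
    p <- design$plots
    if (anyDuplicated(p$mixture_id) || !setequal(p$mixture_id, names(comp))) {
      abort("layout does not place each mixture on exactly one plot")
    }
    tr <- table(p$treatment)
    if (length(unique(tr)) != 1) abort("plots not split evenly across treatments")
  }
  invisible(TRUE)
}

#' Pairwise line co-occurrence histogram
#'
#' Diagnostic: how often each pair of lines ends up in the same mixture.
#'
#' @param design A `mixture_design`.
#' @return A tibble `n_cooccurrences`, `n_pairs` counting line pairs by the
#'   number of mixtures they share.
#' @export
cooccurrence_histogram <- function(design) {
  M <- design_membership(design)
  cc <- t(M) %*% M
  counts <- cc[upper.tri(cc)]
  tibble::as_tibble(as.data.frame(table(n_cooccurrences = counts),
                                  stringsAsFactors = FALSE)) |>
    dplyr::mutate(n_cooccurrences = as.integer(as.character(.data$n_cooccurrences))) |>
    dplyr::rename(n_pairs = "Freq")
}

# Internal: mixtures x lines 0/1 membership matrix with dimnames.
design_membership <- function(design) {
  comp <- design$compositions
  mids <- unique(comp$mixture_id)
  M <- matrix(0L, nrow = length(mids), ncol = length(design$line_ids),
              dimnames = list(mids, design$line_ids))
  M[cbind(match(comp$mixture_id, mids), match(comp$line_id, design$line_ids))] <- 1L
  M
}
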