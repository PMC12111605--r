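#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' all hypotheses up to the largest `i` with `p_(i) <= q i / m` are
#' flagged.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q target false discovery rate.
#' @return Logical vector, `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(logical())
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  out <- rep(FALSE, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH") <= q
  out
}

#' Select significant SNPs from a score track
#'
#' Applies the method-specific significance rule: iHS uses a fixed
#' `-log10(p)` threshold (strictly greater than 4 by default); XP-EHH and
#' Rsb control the FDR at 0.05 over all scored SNPs genome-wide
#' (Benjamini-Hochberg on `p = 10^-neglog10_p`); ROH island tracks flag
#' the uppermost `top_fraction` of per-SNP coverage percentages (already
#' recorded by [island_track()]).
#'
#' @param track a `sweep_scan` or `roh_island` tibble.
#' @param method one of `"ihs"`, `"xpehh"`, `"rsb"`, `"roh"`; defaults to
#'   the track's own method tag.
#' @param ihs_threshold `-log10(p)` cutoff for iHS (strict inequality).
#' @param fdr_q FDR level for XP-EHH/Rsb.
#' @return The significant rows of `track`, with the selection rule in
#'   `attr(, "rule")`.
#' @export
significant_snps <- function(track, method = NULL, ihs_threshold = 4,
                             fdr_q = 0.05) {
  if (is.null(method)) method <- attr(track, "method")
  if (is.null(method) && inherits(track, "roh_island")) method <- "roh"
  if (is.null(method)) stop("significant_snps: supply a method")
  method <- match.arg(method, c("ihs", "xpehh", "rsb", "roh"))
  if (method == "ihs") {
    keep <- !is.na(track$neglog10_p) & track$neglog10_p > ihs_threshold
    rule <- sprintf("-log10(p) > %g", ihs_threshold)
  } else if (method %in% c("xpehh", "rsb")) {
    p <- 10^(-track$neglog10_p)
    keep <- bh_fdr(p, fdr_q) & !is.na(track$neglog10_p)
    rule <- sprintf("BH FDR <= %g", fdr_q)
  } else {
    keep <- track$significant
    rule <- sprintf("top %.3g%% of ROH coverage",
                    100 * attr(track, "top_fraction"))
  }
  out <- track[keep, , drop = FALSE]
  attr(out, "rule") <- rule
  attr(out, "method") <- method
  out
}

#' Merge significant SNPs into candidate regions
#'
#' Places a window around every significant SNP (half the window on each
#' side in `"center"` mode, the full window on each side in `"flank"`
#' mode) and unions overlapping or adjacent windows per chromosome. Each
#' merged region records its peak SNP: the one with the largest absolute
#' score (or coverage percent for ROH).
#'
#' @param snps tibble of significant SNPs (`chrom`, `pos`, and `score`,
#'   `percent` or another value column).
#' @param window_bp total window size around each SNP, bp.
#' @param mode `"center"` (window_bp/2 per side) or `"flank"`
#'   (window_bp per side).
#' @param value_col column used to pick the peak; defaults to `score`
#'   then `percent`.
#' @param method method tag stored on the regions.
#' @return A `regions` tibble: `chrom`, `start`, `end`, `peak_pos`,
#'   `peak_value`, `n_snps`, `method`.
#' @export
merge_regions <- function(snps, window_bp = 1e6, mode = c("center", "flank"),
                          value_col = NULL, method = NULL) {
  mode <- match.arg(mode)
  if (is.null(method)) method <- attr(snps, "method") %||% "unknown"
  if (is.null(value_col)) {
    value_col <- intersect(c("score", "percent", "neglog10_p"), names(snps))[1]
  }
  half <- if (mode == "center") window_bp / 2 else window_bp
  if (!nrow(snps)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), peak_pos = numeric(),
                          peak_value = numeric(), n_snps = integer(),
                          method = character()))
  }
  val <- if (!is.na(value_col)) snps[[value_col]] else rep(NA_real_, nrow(snps))
  df <- tibble::tibble(chrom = snps$chrom, pos = as.numeric(snps$pos),
                       value = val) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(w_start = pmax(.data$pos - half, 1),
                  w_end = .data$pos + half)
  out <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      new_reg <- c(TRUE, d$w_start[-1] > cummax(d$w_end)[-nrow(d)])
      d$reg <- cumsum(new_reg)
      d |>
        dplyr::group_by(.data$reg) |>
        dplyr::summarise(
          start = min(.data$w_start), end = max(.data$w_end),
          peak_pos = .data$pos[which.max(abs(.data$value))],
          peak_value = .data$value[which.max(abs(.data$value))],
          n_snps = dplyr::n(), .groups = "drop") |>
        dplyr::select(-"reg")
    }) |>
    dplyr::ungroup()
  out$method <- method
  tibble::new_tibble(out[, c("chrom", "start", "end", "peak_pos",
                             "peak_value", "n_snps", "method")],
                     class = "regions")
}

#' Map candidate regions to overlapping genes
#'
#' A gene is assigned to a region when their intervals intersect (any
#' overlap, half-open coordinates, so a gene starting exactly at a
#' region's end is excluded). Output is ordered by region then gene
#' start.
#'
#' @param regions a [merge_regions()] tibble (1-based inclusive bp).
#' @param genes a [read_gene_bed()] tibble (0-based half-open).
#' @return A tibble pairing regions with genes: region columns plus
#'   `gene_id`, `symbol`, `gene_start`, `gene_end`. Empty (with a
#'   warning) when no annotation is loaded.
#' @export
annotate_genes <- function(regions, genes) {
  if (is.null(genes) || !nrow(genes)) {
    warning("annotate_genes: no gene annotation loaded")
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), method = character(),
                          gene_id = character(), symbol = character(),
                          gene_start = numeric(), gene_end = numeric()))
  }
  purrr::pmap_dfr(regions, function(chrom, start, end, method, ...) {
    r0 <- start - 1  # region as 0-based half-open [start-1, end)
    hit <- genes$chrom == chrom & genes$start < end & genes$end > r0
    gg <- genes[hit, , drop = FALSE]
    gg <- gg[order(gg$start), , drop = FALSE]
    if (!nrow(gg)) return(NULL)
    tibble::tibble(chrom = chrom, start = start, end = end, method = method,
                   gene_id = gg$gene_id, symbol = gg$symbol,
                   gene_start = gg$start, gene_end = gg$end)
  })
}

#' Cross-method overlap of significant SNP sets
#'
#' Counts, for every non-empty combination of methods, the SNPs
#' (keyed by chromosome and position) significant in exactly that
#' combination (`n_exclusive`, Venn semantics) and in at least that
#' combination (`n_shared`, plain intersection).
#'
#' @param snp_sets named list (>= 2 entries) of tibbles with `chrom` and
#'   `pos` columns, one per method.
#' @return A tibble: `combo` (methods joined by `+`), `n_methods`,
#'   `n_exclusive`, `n_shared`.
#' @export
overlap_summary <- function(snp_sets) {
  stopifnot(length(snp_sets) >= 2, !is.null(names(snp_sets)))
  keys <- lapply(snp_sets, function(d) unique(paste(d$chrom, d$pos)))
  methods <- names(snp_sets)
  k <- length(methods)
  combos <- unlist(lapply(seq_len(k), function(r)
    utils::combn(methods, r, simplify = FALSE)), recursive = FALSE)
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(s) all_keys %in% s,
                   logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, methods))
  purrr::map_dfr(combos, function(cmb) {
    inside <- rowSums(member[, cmb, drop = FALSE]) == length(cmb)
    outside <- rowSums(member[, setdiff(methods, cmb), drop = FALSE]) > 0
    tibble::tibble(combo = paste(cmb, collapse = "+"),
                   n_methods = length(cmb),
                   n_exclusive = sum(inside & !outside),
                   n_shared = sum(inside))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
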