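#' Call runs of homozygosity (sliding-window method)
#'
#' PLINK-style ROH detection per individual and chromosome: every window
#' of `window_snps` consecutive SNPs is classified homozygous if it holds
#' at most `window_het` heterozygous and `window_missing` missing calls;
#' each SNP's hit proportion is the fraction of windows covering it that
#' are homozygous; maximal stretches of SNPs with hit proportion at least
#' `hit_threshold` are split at inter-SNP gaps above `max_gap_bp` and
#' retained as ROH if they hold at least `min_snps` SNPs, span at least
#' `min_length_bp`, and average at least one SNP per `density_bp`.
#'
#' @param g a [geno_matrix()].
#' @param window_snps sliding-window size in SNPs.
#' @param window_het maximum heterozygous calls per homozygous window.
#' @param window_missing maximum missing calls per homozygous window.
#' @param hit_threshold minimum homozygous-window proportion per SNP.
#' @param min_snps minimum SNPs per emitted segment.
#' @param min_length_bp minimum segment length, bp.
#' @param max_gap_bp maximum gap between consecutive SNPs in a segment.
#' @param density_bp required SNP density: at most this many bp per SNP.
#' @return A `roh_calls` tibble: `individual_id`, `chrom`, `start`,
#'   `end` (1-based, inclusive of the outermost SNPs), `n_snps`, `n_het`,
#'   `length`.
#' @export
call_roh <- function(g, window_snps = 50, window_het = 1, window_missing = 5,
                     hit_threshold = 0.05, min_snps = 50,
                     min_length_bp = 3e5, max_gap_bp = 1e6,
                     density_bp = 5e4) {
  stopifnot(inherits(g, "geno_matrix"))
  out <- list()
  for (cc in unique(g$variants$chrom)) {
    sel <- g$variants$chrom == cc
    pos <- g$variants$pos[sel]
    d <- g$dosages[, sel, drop = FALSE]
    if (sum(sel) < window_snps) next
    for (i in seq_len(nrow(d))) {
      seg <- roh_one(d[i, ], pos, window_snps, window_het, window_missing,
                     hit_threshold, min_snps, min_length_bp, max_gap_bp,
                     density_bp)
      if (!is.null(seg) && nrow(seg)) {
        seg$individual_id <- g$individual_ids[i]
        seg$chrom <- cc
        out[[length(out) + 1L]] <- seg
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(start = integer(), end = integer(), n_snps = integer(),
                   n_het = integer(), individual_id = character(),
                   chrom = character())
  res <- dplyr::mutate(res, length = .data$end - .data$start + 1)
  res <- res[, c("individual_id", "chrom", "start", "end", "n_snps",
                 "n_het", "length")]
  res <- dplyr::arrange(res, .data$individual_id, .data$chrom, .data$start)
  tibble::new_tibble(res, class = "roh_calls")
}

roh_one <- function(dos, pos, w, max_het, max_miss, hit_thr, min_snps,
                    min_len, max_gap, density_bp) {
  L <- length(dos)
  het <- as.integer(!is.na(dos) & dos == 1L)
  mis <- as.integer(is.na(dos))
  nwin <- L - w + 1L
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  whet <- ch[(w + 1):(L + 1)] - ch[1:nwin]
  wmis <- cm[(w + 1):(L + 1)] - cm[1:nwin]
  hom <- as.integer(whet <= max_het & wmis <= max_miss)
  chom <- c(0L, cumsum(hom))
  j <- seq_len(L)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nwin)
  hits <- chom[hi + 1L] - chom[lo]
  prop <- hits / (hi - lo + 1L)
  in_run <- prop >= hit_thr
  # split candidate stretches at large physical gaps
  brk <- c(FALSE, diff(pos) > max_gap)
  run_id <- cumsum(!in_run | brk)
  runs <- split(j[in_run], run_id[in_run])
  segs <- lapply(runs, function(idx) {
    n <- length(idx)
    len <- pos[idx[n]] - pos[idx[1]] + 1
    if (n < min_snps || len < min_len || len / n > density_bp) return(NULL)
    tibble::tibble(start = as.integer(pos[idx[1]]),
                   end = as.integer(pos[idx[n]]),
                   n_snps = n, n_het = sum(het[idx]))
  })
  dplyr::bind_rows(segs)
}

#' ROH length-class spectrum
#'
#' Classifies segments into the five half-open length classes (0-2],
#' (2-4], (4-8], (8-16] and >16 Mb and reports the count and mean length
#' per class (per population when a `pop` column or vector is supplied).
#'
#' @param segments a `roh_calls` tibble from [call_roh()].
#' @param pop optional population label per segment (or a column named
#'   `pop` in `segments`).
#' @return A tibble: `pop` (if given), `class`, `n`, `mean_length_bp`.
#' @export
classify_spectrum <- function(segments, pop = NULL) {
  classes <- c("0-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb", ">16 Mb")
  if (is.null(pop) && "pop" %in% names(segments)) pop <- segments$pop
  cls <- cut(segments$length / 1e6, breaks = c(0, 2, 4, 8, 16, Inf),
             labels = classes, right = TRUE)
  df <- tibble::tibble(pop = if (is.null(pop)) "all" else as.character(pop),
                       class = factor(cls, levels = classes),
                       length = segments$length)
  out <- df |>
    dplyr::group_by(.data$pop, .data$class, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_length_bp = mean(.data$length), .groups = "drop")
  out$mean_length_bp[is.nan(out$mean_length_bp)] <- NA_real_
  if (is.null(pop)) out$pop <- NULL
  out
}

#' ROH-based inbreeding coefficient (F_ROH)
#'
#' `F_ROH = sum(L_ROH) / L_auto`: the fraction of the autosomal genome an
#' individual carries inside runs of homozygosity.
#'
#' @param segments a `roh_calls` tibble.
#' @param l_auto autosomal genome length in bp. Defaults to the summed
#'   first-to-last SNP span per chromosome of `variants` if supplied.
#' @param individual_ids individuals to report (those without segments get
#'   `froh = 0`); defaults to the individuals present in `segments`.
#' @param variants optional [variant_table()] used to derive `l_auto`.
#' @return A tibble: `individual_id`, `froh`, `l_auto`.
#' @export
froh <- function(segments, l_auto = NULL, individual_ids = NULL,
                 variants = NULL) {
  if (is.null(l_auto)) {
    if (is.null(variants)) stop("froh: supply l_auto or variants")
    l_auto <- sum(tapply(variants$pos, variants$chrom,
                         function(p) max(p) - min(p) + 1))
  }
  stopifnot(l_auto > 0)
  if (is.null(individual_ids)) individual_ids <- unique(segments$individual_id)
  tot <- tapply(segments$length, segments$individual_id, sum)
  v <- as.vector(tot[match(individual_ids, names(tot))])
  v[is.na(v)] <- 0
  if (any(v > l_auto)) stop("froh: summed ROH length exceeds l_auto")
  tibble::tibble(individual_id = individual_ids, froh = v / l_auto,
                 l_auto = l_auto)
}

#' ROH island track
#'
#' For every SNP, the percentage of individuals whose called ROH covers
#' it; loci covered in an unusually high fraction of individuals (ROH
#' islands) mark putative selection. The significance threshold is the
#' empirical `1 - top_fraction` quantile of the per-SNP percentages; SNPs
#' at or above it are flagged.
#'
#' @param segments a `roh_calls` tibble for one population.
#' @param variants the [variant_table()] of scanned SNPs.
#' @param n_individuals number of individuals scanned (denominator).
#' @param top_fraction flagged upper fraction of the percent distribution.
#' @return A `roh_island` tibble: `chrom`, `pos`, `percent`,
#'   `significant`; the threshold is in `attr(, "threshold")`.
#' @export
island_track <- function(segments, variants, n_individuals,
                         top_fraction = 0.001) {
  stopifnot(n_individuals > 0)
  cov <- numeric(nrow(variants))
  for (cc in unique(variants$chrom)) {
    vi <- which(variants$chrom == cc)
    pos <- variants$pos[vi]
    seg <- segments[segments$chrom == cc, , drop = FALSE]
    if (!nrow(seg)) next
    # per-individual segments are disjoint, so covering segments = individuals
    a <- findInterval(seg$start - 1L, pos) + 1L   # first SNP >= start
    b <- findInterval(seg$end, pos)               # last SNP <= end
    delta <- numeric(length(vi) + 1L)
    ok <- a <= b
    for (k in which(ok)) {
      delta[a[k]] <- delta[a[k]] + 1
      delta[b[k] + 1L] <- delta[b[k] + 1L] - 1
    }
    cov[vi] <- cumsum(delta[seq_along(vi)])
  }
  percent <- 100 * cov / n_individuals
  thr <- stats::quantile(percent, 1 - top_fraction, names = FALSE, type = 7)
  out <- tibble::tibble(chrom = variants$chrom, pos = variants$pos,
                        percent = percent, significant = percent >= thr)
  tibble::new_tibble(out, threshold = thr, top_fraction = top_fraction,
                     class = "roh_island")
}
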