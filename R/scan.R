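#' Standardize scores within strata
#'
#' Subtracts the stratum mean and divides by the stratum standard
#' deviation (population form, i.e. denominator `n`), so each stratum has
#' mean 0 and sd 1 afterwards. Strata with fewer than `min_count` finite
#' values are merged with the nearest neighbouring stratum before
#' standardizing (strata are assumed ordered, as frequency bins are).
#' A zero-variance stratum yields zeros with a warning.
#'
#' @param values numeric vector (NAs pass through untouched).
#' @param strata integer/factor stratum per value; a single stratum by
#'   default.
#' @param min_count minimum finite values a stratum may hold.
#' @return Numeric vector of standardized values.
#' @export
standardize <- function(values, strata = NULL, min_count = 1) {
  if (is.null(strata)) strata <- rep(1L, length(values))
  stopifnot(length(strata) == length(values))
  strata <- merge_small_strata(strata, is.finite(values), min_count)
  out <- rep(NA_real_, length(values))
  warned <- FALSE
  for (s in unique(strata[!is.na(strata)])) {
    i <- which(strata == s & is.finite(values))
    if (!length(i)) next
    x <- values[i]
    m <- mean(x)
    sdev <- sqrt(mean((x - m)^2))
    if (sdev == 0) {
      out[i] <- 0
      warned <- TRUE
    } else {
      out[i] <- (x - m) / sdev
    }
  }
  if (warned) warning("zero-variance stratum: scores set to 0")
  out
}

# merge strata holding < min_count usable values into the nearest
# neighbour by stratum order; ties go to the neighbour with fewer values,
# then to the left
merge_small_strata <- function(strata, usable, min_count) {
  s <- as.integer(factor(strata))
  lev <- sort(unique(s[!is.na(s)]))
  counts <- vapply(lev, function(l) sum(usable & !is.na(s) & s == l), 0L)
  while (length(lev) > 1 && any(counts < min_count)) {
    i <- which(counts < min_count)[1]
    nb <- if (i == 1) 2L else if (i == length(lev)) i - 1L else {
      if (counts[i - 1] <= counts[i + 1]) i - 1L else i + 1L
    }
    s[s == lev[i]] <- lev[nb]
    counts[nb] <- counts[nb] + counts[i]
    lev <- lev[-i]; counts <- counts[-i]
  }
  s
}

#' Two-sided Gaussian p-value on the -log10 scale
#'
#' Maps a standardized score X to
#' \eqn{p_X = -\log_{10}(1 - 2|\Phi(X) - 0.5|)}, the two-sided standard
#' normal tail probability of |X| on the -log10 scale. Computed in log
#' space so very large scores do not underflow; values beyond `cap` are
#' clamped.
#'
#' @param x numeric vector of standardized scores.
#' @param cap upper clamp for the returned -log10 p.
#' @return Nonnegative numeric vector, `NA` where `x` is `NA`.
#' @export
pvalue_transform <- function(x, cap = 320) {
  out <- -(stats::pnorm(-abs(x), log.p = TRUE) + log(2)) / log(10)
  out[is.nan(out)] <- NA_real_
  pmin(pmax(out, 0), cap)
}

#' Integrated haplotype score (iHS) scan
#'
#' For every SNP, integrates the EHH decay of the ancestral and of the
#' derived allele (trapezoidal rule) to obtain iHH_A and iHH_D, forms the
#' unstandardized score `uniHS = ln(iHH_A / iHH_D)`, and standardizes it
#' to mean 0 / sd 1 within derived-allele-frequency bins, so that extreme
#' iHS marks unusually long haplotypes around an allele given its
#' frequency. Two-sided Gaussian p-values are attached via
#' [pvalue_transform()]. SNPs where either allele has fewer than
#' `min_carriers` carriers, or where an integral is zero, are flagged in
#' `note` and left unscored.
#'
#' @param h a [hap_matrix()] of one population (may span chromosomes;
#'   each is scanned separately).
#' @param stop_threshold EHH value at which the outward scan stops.
#' @param max_extension maximum extension per side, bp.
#' @param gap_cap_bp cap on per-interval trapezoid width (see
#'   [integrate_decay()]); `Inf` disables.
#' @param min_carriers minimum carrier haplotypes per allele.
#' @param bin_width derived-allele-frequency bin width for
#'   standardization.
#' @param min_bin_count bins with fewer scored SNPs merge with their
#'   nearest neighbour.
#' @return A `sweep_scan` tibble: `chrom`, `pos`, `vid`, `daf`, `raw`
#'   (uniHS), `score` (iHS), `neglog10_p`, `edge` (decay reached a
#'   chromosome end), `note`.
#' @export
scan_ihs <- function(h, stop_threshold = 0.05, max_extension = 1e6,
                     gap_cap_bp = 2e4, min_carriers = 2,
                     bin_width = 0.025, min_bin_count = 10) {
  stopifnot(inherits(h, "hap_matrix"))
  res <- purrr::map_dfr(split_chrom(h), function(hc) {
    A <- hc$alleles
    pos <- as.numeric(hc$variants$pos)
    m <- ncol(A)
    daf <- colMeans(A)
    poly <- daf > 0 & daf < 1
    raw <- rep(NA_real_, m); edge <- logical(m); note <- rep(NA_character_, m)
    for (j in seq_len(m)) {
      rows_d <- which(A[, j] == 1L); rows_a <- which(A[, j] == 0L)
      if (length(rows_a) < min_carriers || length(rows_d) < min_carriers) {
        note[j] <- "low_carriers"; next
      }
      ra <- ihh_site_cpp(A, j - 1L, rows_a - 1L, integer(length(rows_a)), 1,
                         stop_threshold, max_extension, gap_cap_bp, pos,
                         0L, m - 1L, poly)
      rd <- ihh_site_cpp(A, j - 1L, rows_d - 1L, integer(length(rows_d)), 1,
                         stop_threshold, max_extension, gap_cap_bp, pos,
                         0L, m - 1L, poly)
      if (ra[1] <= 0 || rd[1] <= 0) { note[j] <- "zero_ihh"; next }
      # difference of logs so relabelling ancestral/derived flips the
      # sign exactly
      raw[j] <- log(ra[1]) - log(rd[1])
      edge[j] <- ra[2] > 0 || rd[2] > 0
    }
    tibble::tibble(chrom = hc$variants$chrom, pos = hc$variants$pos,
                   vid = hc$variants$vid, daf = daf, raw = raw,
                   edge = edge, note = note)
  })
  bins <- pmin(findInterval(res$daf, seq(0, 1, by = bin_width),
                            rightmost.closed = TRUE), ceiling(1 / bin_width))
  res$score <- standardize(res$raw, bins, min_count = min_bin_count)
  res$neglog10_p <- pvalue_transform(res$score)
  new_sweep_scan(res, "ihs",
                 list(stop_threshold = stop_threshold,
                      max_extension = max_extension, gap_cap_bp = gap_cap_bp,
                      bin_width = bin_width, min_bin_count = min_bin_count))
}

#' Per-SNP integrated EHHS (iES) track
#'
#' Integrates the site-specific EHHS decay at every SNP of one
#' population; the building block of [scan_xpehh()] and [scan_rsb()],
#' exposed so a track computed once can feed both scans.
#'
#' @inheritParams scan_xpehh
#' @param h a [hap_matrix()].
#' @return A tibble: `chrom`, `pos`, `vid`, `ies`, `edge`.
#' @export
integrated_ehhs <- function(h, stop_threshold = 0.05, max_extension = 1e6,
                            gap_cap_bp = 2e4, min_carriers = 2,
                            include_focal = TRUE) {
  stopifnot(inherits(h, "hap_matrix"))
  purrr::map_dfr(split_chrom(h), function(hc) {
    A <- hc$alleles
    pos <- as.numeric(hc$variants$pos)
    m <- ncol(A); nh <- nrow(A)
    ies <- rep(NA_real_, m); edge <- logical(m)
    rows0 <- seq_len(nh) - 1L
    ones <- integer(nh)
    cm <- colMeans(A)
    poly <- cm > 0 & cm < 1
    for (j in seq_len(m)) {
      if (nh < min_carriers) break
      if (include_focal) {
        g0 <- A[, j]
        anchor <- group_homozygosity_cpp(A, j - 1L, rows0)
      } else {
        g0 <- ones
        anchor <- 1
      }
      r <- ihh_site_cpp(A, j - 1L, rows0, g0, anchor, stop_threshold,
                        max_extension, gap_cap_bp, pos, 0L, m - 1L, poly)
      ies[j] <- r[1]
      edge[j] <- r[2] > 0
    }
    tibble::tibble(chrom = hc$variants$chrom, pos = hc$variants$pos,
                   vid = hc$variants$vid, ies = ies, edge = edge)
  })
}

#' Cross-population EHH (XP-EHH) scan
#'
#' Per SNP, integrates the site-specific EHHS curve over all haplotypes
#' within each population (iES) and forms
#' `unXP-EHH = ln(iES_pop1 / iES_pop2)`; a completed or near-complete
#' sweep in one population shortens its haplotype homozygosity asymmetry,
#' pushing the score away from 0. Scores are standardized globally (mean
#' 0, sd 1) and mapped to two-sided Gaussian p-values.
#'
#' @param h1,h2 [hap_matrix()] objects for populations 1 and 2, on the
#'   same variant table (same chrom/pos).
#' @inheritParams scan_ihs
#' @param include_focal whether the focal SNP's alleles split the initial
#'   EHHS groups.
#' @param ies1,ies2 optional precomputed [integrated_ehhs()] tracks for
#'   the two populations (so one pair of tracks can serve both XP-EHH and
#'   Rsb).
#' @return A `sweep_scan` tibble (`raw` = unXP-EHH, `score` = XP-EHH).
#' @export
scan_xpehh <- function(h1, h2, stop_threshold = 0.05, max_extension = 1e6,
                       gap_cap_bp = 2e4, min_carriers = 2,
                       include_focal = TRUE, ies1 = NULL, ies2 = NULL) {
  check_same_variants(h1, h2)
  t1 <- ies1 %||% integrated_ehhs(h1, stop_threshold, max_extension,
                                  gap_cap_bp, min_carriers, include_focal)
  t2 <- ies2 %||% integrated_ehhs(h2, stop_threshold, max_extension,
                                  gap_cap_bp, min_carriers, include_focal)
  raw <- ifelse(t1$ies > 0 & t2$ies > 0, log(t1$ies) - log(t2$ies),
                NA_real_)
  note <- ifelse(is.na(raw), "zero_ies", NA_character_)
  res <- tibble::tibble(chrom = t1$chrom, pos = t1$pos, vid = t1$vid,
                        daf = (colMeans(h1$alleles) + colMeans(h2$alleles)) / 2,
                        raw = raw, edge = t1$edge | t2$edge, note = note)
  res$score <- standardize(res$raw)
  res$neglog10_p <- pvalue_transform(res$score)
  new_sweep_scan(res, "xpehh",
                 list(stop_threshold = stop_threshold,
                      max_extension = max_extension, gap_cap_bp = gap_cap_bp,
                      include_focal = include_focal))
}

#' Rsb scan (within-population normalized iES ratio)
#'
#' Like [scan_xpehh()] but each population's log iES is first centred on
#' its own population-wide median (Tang et al.'s inES), which absorbs any
#' population-wide multiplicative difference in haplotype homozygosity;
#' `unRsb = inES_pop1 - inES_pop2`, then global standardization and
#' two-sided Gaussian p-values.
#'
#' @inheritParams scan_xpehh
#' @param center one of `"median"` (default) or `"mean"`: the statistic
#'   used to centre each population's log iES.
#' @return A `sweep_scan` tibble (`raw` = unRsb, `score` = Rsb).
#' @export
scan_rsb <- function(h1, h2, stop_threshold = 0.05, max_extension = 1e6,
                     gap_cap_bp = 2e4, min_carriers = 2,
                     include_focal = TRUE, center = c("median", "mean"),
                     ies1 = NULL, ies2 = NULL) {
  center <- match.arg(center)
  check_same_variants(h1, h2)
  t1 <- ies1 %||% integrated_ehhs(h1, stop_threshold, max_extension,
                                  gap_cap_bp, min_carriers, include_focal)
  t2 <- ies2 %||% integrated_ehhs(h2, stop_threshold, max_extension,
                                  gap_cap_bp, min_carriers, include_focal)
  ok <- t1$ies > 0 & t2$ies > 0 & !is.na(t1$ies) & !is.na(t2$ies)
  cfun <- if (center == "median") stats::median else mean
  l1 <- ifelse(ok, log(t1$ies), NA_real_)
  l2 <- ifelse(ok, log(t2$ies), NA_real_)
  raw <- (l1 - cfun(l1[ok])) - (l2 - cfun(l2[ok]))
  note <- ifelse(ok, NA_character_, "zero_ies")
  res <- tibble::tibble(chrom = t1$chrom, pos = t1$pos, vid = t1$vid,
                        daf = (colMeans(h1$alleles) + colMeans(h2$alleles)) / 2,
                        raw = raw, edge = t1$edge | t2$edge, note = note)
  res$score <- standardize(res$raw)
  res$neglog10_p <- pvalue_transform(res$score)
  new_sweep_scan(res, "rsb",
                 list(stop_threshold = stop_threshold,
                      max_extension = max_extension, gap_cap_bp = gap_cap_bp,
                      include_focal = include_focal, center = center))
}

new_sweep_scan <- function(df, method, params) {
  df <- df[, c("chrom", "pos", "vid", "daf", "raw", "score", "neglog10_p",
               "edge", "note")]
  tibble::new_tibble(df, method = method, params = params,
                     class = "sweep_scan")
}

#' Method tag of a scan result
#' @param x a `sweep_scan` tibble.
#' @return `"ihs"`, `"xpehh"` or `"rsb"`.
#' @export
scan_method <- function(x) attr(x, "method")

split_chrom <- function(h) {
  ch <- h$variants$chrom
  if (length(unique(ch)) == 1) return(list(h))
  lapply(unique(ch), function(cc) subset_sites(h, ch == cc))
}

check_same_variants <- function(h1, h2) {
  v1 <- h1$variants; v2 <- h2$variants
  if (nrow(v1) != nrow(v2) || !all(v1$chrom == v2$chrom) ||
      !all(v1$pos == v2$pos)) {
    stop("both populations must share the same variant table (chrom, pos)")
  }
  invisible(TRUE)
}
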