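#' Extended haplotype homozygosity decay around a focal SNP
#'
#' Computes the EHH curve of Sabeti et al. for one core allele: among the
#' `n_a` haplotypes carrying the allele at the focal SNP, the probability
#' that two randomly drawn haplotypes are identical over the interval from
#' the focal SNP out to each flanking marker,
#' \deqn{EHH_{s,t} = \sum_k n_k (n_k - 1) / (n_a (n_a - 1)),}
#' where the groups `k` partition the carriers by identity over `[s..t]`.
#' Both sides are scanned outward until the curve falls below
#' `stop_threshold`, reaches zero, extends `max_extension` bp, or hits the
#' chromosome end.
#'
#' @param h a [hap_matrix()] (single chromosome at the focal SNP).
#' @param focal column index of the focal SNP.
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @param stop_threshold EHH value below which the outward scan stops.
#' @param max_extension maximum extension per side, bp.
#' @param min_carriers minimum number of carrier haplotypes; fewer gives
#'   `NULL` (the SNP is not computable, not an error).
#' @return An object of class `ehh_decay`: a list with a `points` tibble
#'   (`side`, `pos`, `value`), the focal position/value, and per-side
#'   `truncated` / `hit_end` flags. `NULL` if there are too few carriers.
#' @export
ehh_at <- function(h, focal, core_allele, stop_threshold = 0.05,
                   max_extension = 1e6, min_carriers = 2) {
  stopifnot(inherits(h, "hap_matrix"), core_allele %in% c(0L, 1L))
  rows <- which(h$alleles[, focal] == core_allele)
  if (length(rows) < min_carriers) return(NULL)
  groups0 <- integer(length(rows))  # all carriers identical at the focal
  decay_build(h, focal, rows, groups0, anchor = 1,
              stop_threshold, max_extension)
}

#' Site-specific EHH (EHHS) decay over all haplotypes
#'
#' Same group-refinement homozygosity as [ehh_at()] but over all `n_s`
#' haplotypes regardless of core allele; the basis of the iES integrals
#' used by XP-EHH and Rsb. By default the focal SNP's own alleles take
#' part in the haplotype spanning `[s..t]`, so the curve starts at the
#' focal-site homozygosity rather than at 1; set `include_focal = FALSE`
#' to start all haplotypes in one group.
#'
#' @inheritParams ehh_at
#' @param include_focal should the focal SNP's alleles partition the
#'   initial groups?
#' @return An `ehh_decay` object, or `NULL` when fewer than `min_carriers`
#'   haplotypes are present.
#' @export
ehhs_at <- function(h, focal, stop_threshold = 0.05, max_extension = 1e6,
                    min_carriers = 2, include_focal = TRUE) {
  stopifnot(inherits(h, "hap_matrix"))
  rows <- seq_len(nrow(h$alleles))
  if (length(rows) < min_carriers) return(NULL)
  if (include_focal) {
    al <- h$alleles[, focal]
    groups0 <- if (any(al == 1L) && any(al == 0L)) al else integer(length(rows))
    anchor <- group_homozygosity_cpp(h$alleles, focal - 1L, rows - 1L)
  } else {
    groups0 <- integer(length(rows))
    anchor <- 1
  }
  decay_build(h, focal, rows, groups0, anchor, stop_threshold, max_extension)
}

decay_build <- function(h, focal, rows, groups0, anchor, stop_threshold,
                        max_extension) {
  pos <- as.numeric(h$variants$pos)
  ch <- h$variants$chrom
  same <- ch == ch[focal]
  # restrict the reachable range to the focal chromosome
  lo <- min(which(same)); hi <- max(which(same))
  sides <- lapply(c(-1L, 1L), function(sd) {
    r <- ehh_side_cpp(h$alleles, focal - 1L, rows - 1L, as.integer(groups0),
                      sd, stop_threshold, max_extension, pos)
    idx <- r$idx + 1L
    keep <- idx >= lo & idx <= hi
    # off-chromosome markers (multi-chrom container) count as hitting the end
    if (any(!keep)) r$hit_end <- TRUE
    list(idx = idx[keep], ehh = r$ehh[keep],
         truncated = r$truncated && all(keep), hit_end = r$hit_end)
  })
  pts <- tibble::tibble(
    side = c(rep("left", length(sides[[1]]$idx)), "focal",
             rep("right", length(sides[[2]]$idx))),
    pos = c(rev(pos[sides[[1]]$idx]), pos[focal], pos[sides[[2]]$idx]),
    value = c(rev(sides[[1]]$ehh), anchor, sides[[2]]$ehh)
  )
  structure(
    list(points = pts, focal_index = focal, focal_pos = pos[focal],
         anchor = anchor, stop_threshold = stop_threshold,
         truncated = c(left = sides[[1]]$truncated, right = sides[[2]]$truncated),
         hit_end = c(left = sides[[1]]$hit_end, right = sides[[2]]$hit_end)),
    class = "ehh_decay"
  )
}

#' @export
print.ehh_decay <- function(x, ...) {
  cat(sprintf("<ehh_decay> focal %s bp, anchor %.4f, %d left / %d right points\n",
              format(x$focal_pos, big.mark = ","), x$anchor,
              sum(x$points$side == "left"), sum(x$points$side == "right")))
  invisible(x)
}

#' Integrate an EHH/EHHS decay curve (trapezoidal rule)
#'
#' Area under the decay curve in bp x EHH units, summed over both sides.
#' The curve is linearly interpolated between markers and anchored at the
#' focal value; when a side was truncated by the stop threshold, the last
#' segment is interpolated down to the threshold crossing rather than to
#' the sub-threshold point. Inter-marker gaps wider than `gap_cap_bp`
#' contribute at most `gap_cap_bp` to the trapezoid width, so sparse
#' regions cannot dominate the integral (`Inf` disables the cap).
#'
#' @param decay an `ehh_decay` from [ehh_at()]/[ehhs_at()].
#' @param gap_cap_bp maximum trapezoid width per marker interval, bp.
#' @return Nonnegative area (numeric scalar); 0 for a focal-only curve.
#' @export
integrate_decay <- function(decay, gap_cap_bp = 2e4) {
  stopifnot(inherits(decay, "ehh_decay"))
  pts <- decay$points
  thr <- decay$stop_threshold
  a_left <- side_area(rev(pts$value[pts$side != "right"]),
                      rev(pts$pos[pts$side != "right"]),
                      thr, decay$truncated[["left"]], gap_cap_bp)
  a_right <- side_area(pts$value[pts$side != "left"],
                       pts$pos[pts$side != "left"],
                       thr, decay$truncated[["right"]], gap_cap_bp)
  a_left + a_right
}

# values/positions ordered outward from the focal anchor (first element)
side_area <- function(v, p, thr, truncated, gap_cap) {
  k <- length(v)
  if (k < 2) return(0)
  w <- pmin(abs(diff(p)), gap_cap)
  seg <- (v[-k] + v[-1]) / 2 * w
  if (truncated && v[k] < thr) {
    drop <- v[k - 1] - v[k]
    f <- if (drop > 0) (v[k - 1] - thr) / drop else 0
    seg[k - 1] <- (v[k - 1] + thr) / 2 * (w[k - 1] * f)
  }
  sum(seg)
}
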