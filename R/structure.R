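#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centres the dosage matrix by twice the allele frequency and scales by
#' `sum(2 p (1 - p))`: `G = Z Z' / sum(2 p_j (1 - p_j))`. Missing
#' genotypes are mean-imputed per site; monomorphic sites are excluded.
#'
#' @param g a [geno_matrix()].
#' @return An `n x n` symmetric matrix of class `grm` with individual ids
#'   as dimnames.
#' @export
grm <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(d)) stop("grm: no polymorphic sites")
  Z <- sweep(d, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centring
  G <- tcrossprod(Z) / sum(2 * p * (1 - p))
  dimnames(G) <- list(g$individual_ids, g$individual_ids)
  class(G) <- c("grm", "matrix", "array")
  G
}

#' Principal components from a relationship matrix
#'
#' Eigen-decomposes the GRM; component `i` scores are the eigenvector
#' scaled by the square root of its eigenvalue, and the percent variance
#' explained is the eigenvalue over the trace.
#'
#' @param G a [grm()] (any symmetric relationship matrix).
#' @param k number of components to keep.
#' @return An object of class `sweep_pca` with `scores` (tibble:
#'   `individual_id`, `PC1..PCk`), `pct_var`, and `eigenvalues`.
#'   [tidy()] returns the scores, [glance()] a one-row summary.
#' @export
grm_pca <- function(G, k = 2) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), k < nrow(G))
  if (any(!is.finite(G))) stop("grm_pca: non-finite relationship values")
  ee <- eigen(unclass(G), symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  scores <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(G)))
  structure(
    list(scores = dplyr::bind_cols(tibble::tibble(individual_id = ids),
                                   tibble::as_tibble(scores)),
         pct_var = 100 * ee$values / sum(ee$values),
         eigenvalues = ee$values, k = k),
    class = "sweep_pca"
  )
}

#' @export
print.sweep_pca <- function(x, ...) {
  cat(sprintf("<sweep_pca> %d individuals, %d components; PC1 %.2f%%, PC2 %.2f%%\n",
              nrow(x$scores), x$k, x$pct_var[1],
              if (length(x$pct_var) > 1) x$pct_var[2] else NA))
  invisible(x)
}

#' @rdname grm_pca
#' @param x a `sweep_pca`.
#' @param ... unused.
#' @export
tidy.sweep_pca <- function(x, ...) x$scores

#' @rdname grm_pca
#' @export
glance.sweep_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), k = x$k,
                 pct_var_pc1 = x$pct_var[1],
                 pct_var_pc2 = if (length(x$pct_var) > 1) x$pct_var[2] else NA_real_)
}

#' Pairwise linkage disequilibrium (r-squared) by distance
#'
#' Squared Pearson correlation of dosage vectors for all SNP pairs within
#' `max_dist_bp` on the same chromosome, with the physical distance
#' converted to Morgan at `mb_per_morgan` (100 Mb/Morgan by default,
#' i.e. 1 cM/Mb). Monomorphic (zero-variance) sites are skipped; missing
#' dosages are mean-imputed per site.
#'
#' @param g a [geno_matrix()].
#' @param max_dist_bp maximum pair distance, bp.
#' @param mb_per_morgan physical-to-genetic map scaling.
#' @return A tibble: `chrom`, `pos1`, `pos2`, `dist_bp`, `c_morgan`, `r2`.
#' @export
pairwise_r2 <- function(g, max_dist_bp = 5e6, mb_per_morgan = 100) {
  stopifnot(inherits(g, "geno_matrix"))
  out <- list()
  for (cc in unique(g$variants$chrom)) {
    sel <- which(g$variants$chrom == cc)
    pos <- as.numeric(g$variants$pos[sel])
    d <- g$dosages[, sel, drop = FALSE]
    storage.mode(d) <- "double"
    mu <- colMeans(d, na.rm = TRUE)
    X <- sweep(d, 2, mu)
    X[is.na(X)] <- 0
    ss <- sqrt(colSums(X^2))
    ok <- ss > 0
    X <- sweep(X[, ok, drop = FALSE], 2, ss[ok], "/")
    pos <- pos[ok]
    m <- ncol(X)
    if (m < 2) next
    R <- crossprod(X)            # correlation matrix of retained sites
    ij <- which(upper.tri(R), arr.ind = TRUE)
    dist <- pos[ij[, 2]] - pos[ij[, 1]]
    keep <- dist <= max_dist_bp
    out[[cc]] <- tibble::tibble(
      chrom = cc, pos1 = pos[ij[keep, 1]], pos2 = pos[ij[keep, 2]],
      dist_bp = dist[keep],
      c_morgan = dist[keep] / (mb_per_morgan * 1e6),
      r2 = R[ij[keep, , drop = FALSE]]^2)
  }
  if (!length(out)) return(tibble::tibble(chrom = character(), pos1 = numeric(),
                                          pos2 = numeric(), dist_bp = numeric(),
                                          c_morgan = numeric(), r2 = numeric()))
  dplyr::bind_rows(out)
}

#' LD-based effective population size trajectory
#'
#' Bins SNP pairs by genetic distance and converts each bin's mean
#' r-squared into an effective population size via
#' \deqn{N_{e,t} = \frac{1}{4c}\left(\frac{1}{r^2} - 1\right),}
#' with `c` the bin-midpoint distance in Morgan and the corresponding
#' time depth `t = 1/(2c)` generations ago (distant pairs reflect recent
#' Ne, close pairs ancient Ne).
#'
#' @param r2_pairs output of [pairwise_r2()].
#' @param bins number of equal-width distance bins, or a vector of bin
#'   breaks in Morgan.
#' @param min_pairs bins with fewer pairs are dropped.
#' @param adjust_n optional sample size: subtracts `1/n` from the mean
#'   r-squared to remove finite-sample inflation before inverting.
#' @return A tibble of `NePoint`s: `c` (Morgan, bin midpoint), `t`
#'   (generations ago), `mean_r2`, `n_pairs`, `ne`.
#' @export
ne_trajectory <- function(r2_pairs, bins = 20, min_pairs = 10,
                          adjust_n = NULL) {
  cm <- r2_pairs$c_morgan
  if (length(bins) == 1) {
    bins <- seq(min(cm), max(cm), length.out = bins + 1)
  }
  idx <- cut(cm, breaks = bins, include.lowest = TRUE, labels = FALSE)
  mid <- (bins[-1] + bins[-length(bins)]) / 2
  out <- tibble::tibble(bin = seq_along(mid), c = mid) |>
    dplyr::left_join(
      tibble::tibble(bin = idx, r2 = r2_pairs$r2) |>
        dplyr::filter(!is.na(.data$bin)) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n()),
      by = "bin")
  out <- dplyr::filter(out, !is.na(.data$mean_r2), .data$n_pairs >= min_pairs,
                       .data$c > 0)
  r2 <- out$mean_r2
  if (!is.null(adjust_n)) r2 <- pmax(r2 - 1 / adjust_n, 1e-12)
  out$ne <- pmax((1 / (4 * out$c)) * (1 / r2 - 1), 0)
  out$t <- 1 / (2 * out$c)
  out[, c("c", "t", "mean_r2", "n_pairs", "ne")]
}
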