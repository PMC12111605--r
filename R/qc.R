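#' Per-site genotype call rate
#'
#' @param g a [geno_matrix()].
#' @param sites optional site index; all sites by default.
#' @return Fraction of non-missing genotype calls per site, in `[0, 1]`.
#' @export
call_rate <- function(g, sites = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  if (!is.null(sites)) d <- d[, sites, drop = FALSE]
  if (nrow(d) == 0) stop("call_rate: no individuals")
  colMeans(!is.na(d))
}

#' Per-site minor allele frequency
#'
#' MAF is `min(p, 1 - p)` with `p` the alternate/derived-allele frequency
#' among non-missing alleles.
#'
#' @inheritParams call_rate
#' @return Numeric vector in `[0, 0.5]`; an all-missing site errors.
#' @export
maf <- function(g, sites = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  if (!is.null(sites)) d <- d[, sites, drop = FALSE]
  nn <- colSums(!is.na(d))
  if (any(nn == 0)) stop("maf: site with no genotype calls")
  p <- colSums(d, na.rm = TRUE) / (2 * nn)
  pmin(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the sample size and minor
#' allele count, the heterozygote count follows
#' \eqn{P(n_{Aa}) \propto n! / (n_{AA}! n_{Aa}! n_{aa}!) \, 2^{n_{Aa}}};
#' the p-value sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed count (the default
#' behaviour of the usual genotype-QC tools).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors recycle together).
#' @return p-value(s) in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- cbind(n_AA, n_Aa, n_aa)
  if (any(n < 0) || any(n != floor(n))) stop("hwe_exact_p: counts must be nonnegative integers")
  apply(n, 1, function(x) hwe_exact_one(x[1], x[2], x[3]))
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("hwe_exact_p: empty table")
  n1 <- 2 * n_AA + n_Aa            # allele-1 count
  nm <- min(n1, 2 * n - n1)        # minor allele count
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2) # feasible heterozygote counts
  logp <- vapply(hets, function(h) {
    aa <- (nm - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) + h * log(2)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Apply variant quality control
#'
#' Removes sites failing any of the three standard pre-scan filters:
#' genotype call rate below `min_callrate`, minor allele frequency below
#' `min_maf`, or exact Hardy-Weinberg p-value below `min_hwe_p`. When a
#' population factor is supplied the HWE test runs within each population
#' and a site fails if it fails in any of them (`joint = TRUE` pools all
#' individuals instead). For the report each removed site is counted once
#' under the first rule it fails, in the order call rate, MAF, HWE.
#'
#' @param g a [geno_matrix()].
#' @param h optional matching [hap_matrix()] filtered alongside.
#' @param min_callrate,min_maf,min_hwe_p filter thresholds; sites with
#'   values `>=` the threshold pass.
#' @param pop optional population factor (one value per individual) for
#'   the HWE test.
#' @param joint pool populations for the HWE test.
#' @return A list with `genotypes`, `haplotypes` (or `NULL`), and
#'   `report`, a one-row `qc_report` tibble of counts.
#' @export
apply_qc <- function(g, h = NULL, min_callrate = 0.95, min_maf = 0.01,
                     min_hwe_p = 1e-5, pop = NULL, joint = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  m <- ncol(d)
  nn <- colSums(!is.na(d))
  cr <- colMeans(!is.na(d))
  p <- ifelse(nn > 0, colSums(d, na.rm = TRUE) / (2 * nn), NA_real_)
  mafv <- pmin(p, 1 - p)
  fail_cr <- cr < min_callrate
  fail_maf <- (!is.na(mafv) & mafv < min_maf) | (is.na(mafv) & min_maf > 0)
  hwe_p <- site_hwe_p(d, pop, joint)
  fail_hwe <- !is.na(hwe_p) & hwe_p < min_hwe_p
  fail_any <- fail_cr | fail_maf | fail_hwe
  first <- rep(NA_character_, m)
  first[fail_hwe] <- "hwe"
  first[fail_maf] <- "maf"
  first[fail_cr] <- "callrate"
  report <- tibble::new_tibble(
    tibble::tibble(n_input = m,
                   n_fail_callrate = sum(first == "callrate", na.rm = TRUE),
                   n_fail_maf = sum(first == "maf", na.rm = TRUE),
                   n_fail_hwe = sum(first == "hwe", na.rm = TRUE),
                   n_pass = sum(!fail_any)),
    class = "qc_report")
  list(genotypes = subset_sites(g, !fail_any),
       haplotypes = if (!is.null(h)) subset_sites(h, !fail_any) else NULL,
       report = report)
}

site_hwe_p <- function(d, pop, joint) {
  groups <- if (is.null(pop) || joint) list(seq_len(nrow(d))) else
    split(seq_len(nrow(d)), pop)
  pmat <- vapply(groups, function(idx) {
    dd <- d[idx, , drop = FALSE]
    nAA <- colSums(dd == 0, na.rm = TRUE)
    nAa <- colSums(dd == 1, na.rm = TRUE)
    naa <- colSums(dd == 2, na.rm = TRUE)
    ifelse(nAA + nAa + naa > 0, hwe_exact_p(nAA, nAa, naa), NA_real_)
  }, numeric(ncol(d)))
  if (ncol(d) == 1) pmat <- matrix(pmat, nrow = 1)
  apply(pmat, 1, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d sites in: %d removed (call rate %d, MAF %d, HWE %d), %d pass\n",
    x$n_input, x$n_input - x$n_pass, x$n_fail_callrate, x$n_fail_maf,
    x$n_fail_hwe, x$n_pass))
  invisible(x)
}

#' @rdname apply_qc
#' @param x a `qc_report`.
#' @param ... unused.
#' @export
tidy.qc_report <- function(x, ...) {
  tibble::tibble(rule = c("callrate", "maf", "hwe"),
                 n_fail = c(x$n_fail_callrate, x$n_fail_maf, x$n_fail_hwe))
}

#' @rdname apply_qc
#' @export
glance.qc_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
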