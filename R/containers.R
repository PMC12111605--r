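#' Phased haplotype container
#'
#' Wraps a `2n x m` integer matrix of phased alleles (0 = ancestral,
#' 1 = derived) together with the variant table describing its columns.
#' Rows `2i - 1` and `2i` are the two haplotypes of individual `i`; no
#' missing entries are allowed (EHH-type statistics assume complete
#' phased data).
#'
#' @param alleles integer matrix, rows = haplotypes, columns = variants,
#'   entries in `{0, 1}`.
#' @param variants a variant table as built by [variant_table()]: one row
#'   per column of `alleles`, positions strictly increasing within each
#'   chromosome.
#' @param individual_ids character vector of length `nrow(alleles) / 2`.
#'
#' @return An object of class `hap_matrix`.
#' @seealso [geno_matrix()], [hap_to_geno()], [read_phased_vcf()]
#' @export
hap_matrix <- function(alleles, variants, individual_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L) {
    stop("hap_matrix: row count must be even (two haplotypes per individual)")
  }
  if (anyNA(alleles)) stop("hap_matrix: missing alleles are not allowed")
  if (length(alleles) && !all(alleles %in% c(0L, 1L))) {
    stop("hap_matrix: alleles must be coded 0 (ancestral) / 1 (derived)")
  }
  variants <- validate_variant_table(variants)
  if (nrow(variants) != ncol(alleles)) {
    stop("hap_matrix: variants table must have one row per column")
  }
  n <- nrow(alleles) %/% 2L
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (length(individual_ids) != n) {
    stop("hap_matrix: need one individual id per pair of rows")
  }
  structure(
    list(alleles = alleles, variants = variants,
         individual_ids = as.character(individual_ids)),
    class = "hap_matrix"
  )
}

#' Genotype dosage container
#'
#' Wraps an `n x m` matrix of alternate/derived-allele dosages (0, 1, 2 or
#' `NA` for missing) plus the variant table. Used by QC, ROH calling,
#' LD/Ne estimation and the GRM.
#'
#' @param dosages numeric/integer matrix, rows = individuals.
#' @param variants a [variant_table()].
#' @param individual_ids character vector of row labels.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants, individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop("geno_matrix: dosages must be 0/1/2 or NA")
  variants <- validate_variant_table(variants)
  if (nrow(variants) != ncol(dosages)) {
    stop("geno_matrix: variants table must have one row per column")
  }
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (length(individual_ids) != nrow(dosages)) {
    stop("geno_matrix: need one individual id per row")
  }
  structure(
    list(dosages = dosages, variants = variants,
         individual_ids = as.character(individual_ids)),
    class = "geno_matrix"
  )
}

#' Build a variant table
#'
#' One row per biallelic SNP. Positions are 1-based physical coordinates
#' and must be strictly increasing within each chromosome. `anc_is_ref`
#' records which allele was treated as ancestral when the haplotypes were
#' recoded (0 = ancestral).
#'
#' @param chrom chromosome labels.
#' @param pos 1-based bp positions.
#' @param vid variant identifiers (defaults to `chrom_pos`).
#' @param ref_allele,alt_allele single-character alleles.
#' @param anc_is_ref logical, `TRUE` where the reference allele is coded 0.
#' @return A tibble of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, vid = NULL, ref_allele = "A",
                          alt_allele = "T", anc_is_ref = TRUE) {
  m <- length(pos)
  chrom <- as.character(rep_len(chrom, m))
  if (is.null(vid)) vid <- paste0(chrom, "_", pos)
  out <- tibble::tibble(
    chrom = chrom,
    pos = as.integer(pos),
    vid = as.character(vid),
    ref_allele = rep_len(as.character(ref_allele), m),
    alt_allele = rep_len(as.character(alt_allele), m),
    anc_is_ref = rep_len(as.logical(anc_is_ref), m)
  )
  validate_variant_table(out)
}

validate_variant_table <- function(v) {
  stopifnot(is.data.frame(v))
  needed <- c("chrom", "pos")
  if (!all(needed %in% names(v))) {
    stop("variant table needs at least columns chrom, pos")
  }
  if (!"vid" %in% names(v)) v$vid <- paste0(v$chrom, "_", v$pos)
  if (!"anc_is_ref" %in% names(v)) v$anc_is_ref <- TRUE
  inc <- tapply(v$pos, v$chrom, function(p) all(diff(p) > 0))
  if (length(inc) && !all(unlist(inc))) {
    stop("variant positions must be strictly increasing within a chromosome")
  }
  class(v) <- unique(c("variant_table", class(tibble::as_tibble(v))))
  tibble::new_tibble(v, class = "variant_table")
}

#' Collapse phased haplotypes to genotype dosages
#'
#' @param h a [hap_matrix()].
#' @return A [geno_matrix()] whose dosages are the per-individual row-pair
#'   sums of the haplotype alleles.
#' @export
hap_to_geno <- function(h) {
  stopifnot(inherits(h, "hap_matrix"))
  a <- h$alleles
  idx1 <- seq(1L, nrow(a), by = 2L)
  d <- a[idx1, , drop = FALSE] + a[idx1 + 1L, , drop = FALSE]
  geno_matrix(d, h$variants, h$individual_ids)
}

#' Subset container columns (sites)
#'
#' @param x a `hap_matrix` or `geno_matrix`.
#' @param keep logical or integer index over sites.
#' @return The same class of object restricted to the kept sites.
#' @export
subset_sites <- function(x, keep) {
  if (inherits(x, "hap_matrix")) {
    hap_matrix(x$alleles[, keep, drop = FALSE], x$variants[keep, , drop = FALSE],
               x$individual_ids)
  } else if (inherits(x, "geno_matrix")) {
    geno_matrix(x$dosages[, keep, drop = FALSE], x$variants[keep, , drop = FALSE],
                x$individual_ids)
  } else {
    stop("subset_sites: unsupported class")
  }
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d haplotypes (%d individuals) x %d sites, %d chromosome(s)\n",
              nrow(x$alleles), length(x$individual_ids), ncol(x$alleles),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d sites, %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Number of individuals / sites
#' @param x a container object.
#' @return integer count.
#' @export
n_individuals <- function(x) length(x$individual_ids)

#' @rdname n_individuals
#' @export
n_sites <- function(x) nrow(x$variants)
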