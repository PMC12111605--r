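#' Read a phased VCF into haplotype and genotype matrices
#'
#' Keeps biallelic SNPs with fully phased, non-missing genotypes and
#' recodes alleles so that 0 is ancestral according to `ancestral`:
#' `"ref"` treats the reference allele as ancestral, `"aa"` uses the
#' `AA` INFO tag (sites whose tag matches neither allele are dropped),
#' and `"major"` treats the sample-wise major allele as ancestral (ties
#' keep REF). Multi-allelic or non-SNP records, and sites with unphased
#' or missing genotypes, are dropped and counted in the returned
#' `skipped` element.
#'
#' @param path VCF file (plain or gzipped).
#' @param ancestral ancestral-allele policy: `"ref"`, `"aa"` or
#'   `"major"`.
#' @return A list with `haplotypes` ([hap_matrix()]), `genotypes`
#'   ([geno_matrix()]) and `skipped` (named counts of dropped records).
#' @export
read_phased_vcf <- function(path, ancestral = c("ref", "aa", "major")) {
  ancestral <- match.arg(ancestral)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  n_in <- nrow(fix)
  biallelic <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  phased <- apply(gt, 1, function(x) all(grepl("^[01]\\|[01]$", x)))
  keep <- biallelic & phased
  skipped <- c(non_biallelic = sum(!biallelic),
               unphased_or_missing = sum(biallelic & !phased))
  aa <- NULL
  if (ancestral == "aa") {
    aa <- toupper(vcfR::extract.info(v, element = "AA"))
    aa_ok <- !is.na(aa) & (aa == fix[, "REF"] | aa == fix[, "ALT"])
    skipped <- c(skipped, no_ancestral_tag = sum(keep & !aa_ok))
    keep <- keep & aa_ok
  }
  if (!any(keep)) stop("read_phased_vcf: no phased biallelic SNPs retained")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  n_ind <- ncol(gt)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  # alleles as sites x haplotypes, then transpose to haplotypes x sites
  A <- matrix(0L, nrow = 2 * n_ind, ncol = nrow(gt))
  A[seq(1, 2 * n_ind, 2), ] <- t(a1)
  A[seq(2, 2 * n_ind, 2), ] <- t(a2)
  anc_is_ref <- rep(TRUE, nrow(fix))
  if (ancestral == "aa") {
    anc_is_ref <- aa[keep] == fix[, "REF"]
  } else if (ancestral == "major") {
    anc_is_ref <- colMeans(A) <= 0.5  # ALT frequency; ties keep REF
  }
  flip <- which(!anc_is_ref)
  if (length(flip)) A[, flip] <- 1L - A[, flip]
  variants <- variant_table(chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            vid = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                         paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                         fix[, "ID"]),
                            ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
                            anc_is_ref = anc_is_ref)
  h <- hap_matrix(A, variants, colnames(gt))
  out <- list(haplotypes = h, genotypes = hap_to_geno(h), skipped = skipped)
  out
}

#' Write a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased `GT` entries from a
#' [hap_matrix()]; alleles coded 0 are written as REF. Used mainly to
#' export simulated panels.
#'
#' @param h a [hap_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(h, path) {
  stopifnot(inherits(h, "hap_matrix"))
  v <- h$variants
  n <- length(h$individual_ids)
  a1 <- h$alleles[seq(1, 2 * n, 2), , drop = FALSE]
  a2 <- h$alleles[seq(2, 2 * n, 2), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow = n)
  header <- c("##fileformat=VCFv4.2",
              "##source=sweepscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", h$individual_ids), collapse = "\t"))
  body <- cbind(v$chrom, v$pos, v$vid,
                if ("ref_allele" %in% names(v)) v$ref_allele else "A",
                if ("alt_allele" %in% names(v)) v$alt_allele else "T",
                ".", "PASS", ".", "GT", t(gt))
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read gene annotation (BED4+ or GFF3)
#'
#' BED input is taken as 0-based half-open; GFF3 `gene` features are
#' converted from 1-based closed coordinates. Records with
#' `start >= end` (after conversion) are rejected and counted in
#' `attr(, "rejected")`.
#'
#' @param path a `.bed`, `.gff`/`.gff3` file.
#' @return A tibble of gene annotations: `gene_id`, `symbol`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @export
read_gene_bed <- function(path) {
  is_gff <- grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)
  if (!is_gff && file.exists(path)) {
    first <- readLines(path, n = 1)
    if (length(first) && grepl("^##gff-version", first)) is_gff <- TRUE
  }
  if (is_gff) {
    g <- rtracklayer::readGFF(path)
    g <- g[g$type == "gene", , drop = FALSE]
    ids <- if ("ID" %in% names(g)) as.character(g$ID) else NA_character_
    sym <- if ("Name" %in% names(g)) as.character(g$Name) else ids
    out <- tibble::tibble(gene_id = ids, symbol = sym,
                          chrom = as.character(g$seqid),
                          start = as.numeric(g$start) - 1,  # to 0-based half-open
                          end = as.numeric(g$end))
  } else {
    if (file.size(path) == 0) {
      out <- tibble::tibble(gene_id = character(), symbol = character(),
                            chrom = character(), start = numeric(),
                            end = numeric())
      attr(out, "rejected") <- 0L
      return(out)
    }
    b <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:min(6, count_bed_cols(path))],
                           fill = TRUE)
    nm <- if ("name" %in% names(b)) as.character(b$name) else
      paste0(b$chrom, ":", b$start, "-", b$end)
    out <- tibble::tibble(gene_id = nm, symbol = nm,
                          chrom = as.character(b$chrom),
                          start = as.numeric(b$start), end = as.numeric(b$end))
  }
  bad <- !(out$start < out$end)
  out <- out[!bad, , drop = FALSE]
  attr(out, "rejected") <- sum(bad)
  out
}

count_bed_cols <- function(path) {
  length(strsplit(readLines(path, n = 1), "\t")[[1]])
}

#' Write a result track as TSV
#'
#' Any result tibble (score track, ROH calls, island track, Ne
#' trajectory, regions) is written with a header, fixed float precision
#' and deterministic row order (`chrom`, `pos`/`start` when present).
#'
#' @param track a tibble.
#' @param path output file.
#' @param digits significant digits for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, digits = 6) {
  df <- as.data.frame(track)
  ord <- intersect(c("chrom", "pos", "start", "individual_id"), names(df))
  if (length(ord)) df <- df[do.call(order, df[ord]), , drop = FALSE]
  isnum <- vapply(df, is.double, TRUE)
  df[isnum] <- lapply(df[isnum], function(x) {
    ifelse(is.na(x), NA, sprintf(paste0("%.", digits, "g"), x))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a track written by [write_track()]
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_track <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
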