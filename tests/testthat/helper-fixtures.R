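# Small programmatic fixtures shared across tests.

# random phased panel with positions on a 5 kb grid-ish spacing
random_panel <- function(n_hap, m, seed) {
  set.seed(seed)
  A <- matrix(rbinom(n_hap * m, 1, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                          each = n_hap)]),
              nrow = n_hap)
  pos <- sort(sample.int(m * 5000L, m))
  hap_matrix(A, variant_table("1", pos))
}

# write a small phased VCF by hand (text fixture built at test time)
write_test_vcf <- function(path, records, samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts, id = ".", info = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")
}
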