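# In-code fixtures: small genotype matrices and VCF text built on the fly.

toy_genotypes <- function(dosage, pops, allele_labels = NULL) {
  dosage <- as.matrix(dosage)
  genotype_matrix(dosage,
                  sample_ids = paste0("s", seq_len(nrow(dosage))),
                  pop_labels = pops,
                  locus_ids = paste0("L", seq_len(ncol(dosage))),
                  allele_labels = allele_labels)
}

# random genotype matrix with missingness, for property-style tests
random_genotypes <- function(n_samp, n_loci, n_pops = 2, miss = 0.1) {
  p <- runif(n_loci, 0.05, 0.95)
  X <- matrix(rbinom(n_samp * n_loci, 2, rep(p, each = n_samp)),
              nrow = n_samp)
  X[matrix(runif(length(X)) < miss, nrow = n_samp)] <- NA_integer_
  toy_genotypes(X, rep_len(paste0("pop", seq_len(n_pops)), n_samp))
}

# minimal VCF text: gts is a loci x samples character matrix of GT strings
write_vcf_text <- function(path, samples, gts, ref = "A", alt = "T") {
  n_loci <- nrow(gts)
  ref <- rep_len(ref, n_loci)
  alt <- rep_len(alt, n_loci)
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  recs <- vapply(seq_len(n_loci), function(j)
    paste(c("1", j, paste0("snp", j), ref[j], alt[j], ".", "PASS", ".", "GT",
            gts[j, ]), collapse = "\t"), character(1))
  writeLines(c(header, recs), path)
  path
}

write_popmap_text <- function(path, samples, pops) {
  writeLines(paste(samples, pops, sep = "\t"), path)
  path
}
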