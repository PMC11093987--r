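# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

make_aln <- function(seqs, alphabet = "protein", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  new_alignment(ids, seqs, alphabet)
}

# entropy profile with prescribed per-position entropies, for classifier tests
fake_profile <- function(entropy, gene_id = "geneX", focal_id = "acc_01") {
  out <- data.frame(position = seq_along(entropy), entropy = entropy,
                    n_effective = 10L, low_support = FALSE)
  attr(out, "gene_id") <- gene_id
  attr(out, "focal_id") <- focal_id
  class(out) <- c("entropy_profile", "data.frame")
  out
}

write_toy_vcf <- function(path, rows, samples = c("S1", "S2")) {
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

# VCF text from a haplotype matrix (pairs of rows become diploid samples),
# used as the independent second path for VCF-derived statistics
write_vcf_from_haplotypes <- function(h, path, chrom = "Chr1") {
  n_dip <- nrow(h$mat) %/% 2L
  samples <- sprintf("S%02d", seq_len(n_dip))
  rows <- vapply(seq_along(h$positions), function(j) {
    gts <- vapply(seq_len(n_dip), function(s) {
      paste(h$mat[2 * s - 1, j], h$mat[2 * s, j], sep = "|")
    }, character(1))
    vcf_row(chrom, h$positions[j], "A", "T", gts)
  }, character(1))
  write_toy_vcf(path, rows, samples)
}

random_protein_records <- function(n, len_range = c(20L, 40L)) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c(aas, "-"), sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("rec%03d", seq_len(n))
  seqs
}
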