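# Shared fixtures, all generated in code.

toy_reference <- function(seq = "ACGTACGT", name = "1") {
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- name
  dna
}

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(contig = "1", len = 1000L, samples = NULL) {
  h <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, len)
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  c(h, paste(cols, collapse = "\t"))
}

# A well-separated planted trio: the signature-17-like profile plus two
# sparse random profiles (real signatures are peaked, not flat).
planted_signature_trio <- function(seed = 3L) {
  set.seed(seed)
  r1 <- stats::rgamma(96, 0.3); r1 <- r1 / sum(r1)
  r2 <- stats::rgamma(96, 0.3); r2 <- r2 / sum(r2)
  sigs <- cbind(
    sig17like = make_signature_set(0)[, "sig17like"],
    random1 = r1, random2 = r2
  )
  rownames(sigs) <- mut_types_96()
  sigs
}

random_stochastic_matrix <- function(n_row, n_col, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_row * n_col), n_row, n_col)
  sweep(m, 2L, colSums(m), "/")
}
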