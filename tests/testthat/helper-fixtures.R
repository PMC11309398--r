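# Shared fixtures built in code.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a transcript with given exon lengths laid on a synthetic contig
make_tx <- function(id, exon_lens, gene = paste0("g_", id), strand = "+",
                    intron = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- head(c(0L, cumsum(exon_lens + intron)), length(exon_lens))
  exons <- cbind(start = starts, end = starts + exon_lens)
  contig <- random_dna(max(exons[, 2]))
  seqs <- substring(contig, exons[, 1] + 1L, exons[, 2])
  if (strand == "-") {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
    seqs <- rc(seqs)
  }
  tx <- transcript_model(id, gene, toupper(gene), strand, exons, seqs)
  attr(tx, "contig") <- paste0("chr_", id)
  attr(tx, "contig_seq") <- contig
  tx
}

random_count_dataset <- function(n_feat, n_samp, max_count = 100,
                                 seed = 1) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1L, n_feat * n_samp,
                         replace = TRUE) - 1L, n_feat, n_samp,
              dimnames = list(sprintf("f%04d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  count_dataset(m,
                rep_len(c("homogenate", "synaptosome"), n_samp),
                rep_len(c("control", "control", "case", "case"), n_samp))
}

# The nine printed isoform-switch rows used as a worked example
# (gene, donor, acceptor, log2 fold change, raw p).
switch_example_table <- function() {
  data.frame(
    gene = c("ATF6", "ATF6", "ATF6", "ANKS1B", "ANKS1B",
             "GSK3B", "GSK3B", "UBA2", "UBA2"),
    donor = c(9L, 15L, 14L, 4L, 8L, 9L, 10L, 16L, 16L),
    acceptor = c(2L, 10L, 10L, 2L, 2L, 7L, 9L, 9L, 10L),
    log2fc = c(-2.81, 1.94, -1.25, 1.21, -1.01, 1.58, -1.68, -1.84, 1.49),
    p = c(0.00740, 0.00860, 0.0363, 0.000585, 0.0170,
          0.00370, 0.00666, 0.00755, 0.0473),
    stringsAsFactors = FALSE)
}

# brute-force Benjamini-Hochberg, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
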