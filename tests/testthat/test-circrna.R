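test_that("junction enumeration yields E(E+1)/2 pairings per transcript", {
  for (E in c(1, 2, 3, 5)) {
    tx <- make_tx(paste0("t", E), rep(120, E), seed = E)
    ref <- build_backsplice_reference(list(tx))
    expect_equal(nrow(ref), E * (E + 1) / 2)
    expect_true(all(ref$donor >= ref$acceptor))
  }
  tx3 <- make_tx("t3", c(120, 150, 130), seed = 3)
  ref3 <- build_backsplice_reference(list(tx3))
  expect_setequal(paste(ref3$donor, ref3$acceptor),
                  c("1 1", "2 1", "2 2", "3 1", "3 2", "3 3"))
  expect_error(build_backsplice_reference(list(tx3), flank_len = 0),
               "flank_len")
})

test_that("junction sequences are donor-end + acceptor-start flanks", {
  tx <- make_tx("tx", c(200, 300), seed = 7)
  ref <- build_backsplice_reference(list(tx), flank_len = 150)
  j21 <- ref[ref$donor == 2 & ref$acceptor == 1, ]
  e1 <- tx$exon_seqs[1]; e2 <- tx$exon_seqs[2]
  expect_equal(j21$junction_seq,
               paste0(substr(e2, 151, 300), substr(e1, 1, 150)))
  expect_equal(j21$breakpoint_offset, 150)
  expect_equal(j21$donor_flank_len, 150)

  # single-exon circle shorter than the flank: clamped, no wrap
  j11 <- ref[ref$donor == 1 & ref$acceptor == 1, ]
  expect_equal(j11$donor_flank_len, 150)
  expect_equal(j11$junction_seq, paste0(substr(e1, 51, 200), substr(e1, 1, 150)))

  short <- make_tx("s", c(60), seed = 8)
  refs <- build_backsplice_reference(list(short), flank_len = 150)
  expect_equal(refs$donor_flank_len, 60)
  expect_equal(nchar(refs$junction_seq), 120)
  expect_equal(refs$junction_seq,
               paste0(short$exon_seqs[1], short$exon_seqs[1]))
})

test_that("every junction sequence sits in the doubled circle across the breakpoint", {
  txs <- simulate_transcriptome(n_transcripts = 5, seed = 9)
  ref <- build_backsplice_reference(txs)
  expect_equal(nrow(ref), sum(vapply(txs, function(t)
    nrow(t$exons) * (nrow(t$exons) + 1) / 2, 0)))
  for (i in seq_len(nrow(ref))) {
    tx <- txs[[ref$transcript_id[i]]]
    circ <- paste(tx$exon_seqs[ref$acceptor[i]:ref$donor[i]], collapse = "")
    dbl <- paste0(circ, circ)
    pos <- regexpr(ref$junction_seq[i], dbl, fixed = TRUE)[1]
    expect_gt(pos, 0)
    # placement crosses the circularization point of the doubled sequence
    expect_lte(pos, nchar(circ))
    expect_gt(pos + nchar(ref$junction_seq[i]) - 1, nchar(circ))
  }
})

test_that("identical circles from redundant transcripts collapse", {
  tx1 <- make_tx("txA", c(150, 200), gene = "gX", seed = 10)
  tx2 <- tx1
  tx2$transcript_id <- "txB"       # same gene, same exon spans
  ref <- build_backsplice_reference(list(tx1, tx2))
  expect_equal(nrow(ref), 3)
  expect_true(all(ref$transcript_id == "txA"))
})

test_that("read partition agrees with a sliding-window Hamming oracle", {
  set.seed(15)
  txs <- lapply(1:3, function(i) make_tx(paste0("t", i), c(150, 150)))
  seqs <- vapply(txs, transcript_sequence, "")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  L <- 40
  reads <- character(300)
  for (i in seq_len(300)) {
    r <- sample(3, 1)
    if (r == 1) {                  # verbatim copy
      s <- sample(nchar(seqs[1]) - L + 1, 1)
      reads[i] <- substr(seqs[1], s, s + L - 1)
    } else if (r == 2) {           # mutated copy of a random transcript
      j <- sample(3, 1)
      s <- sample(nchar(seqs[j]) - L + 1, 1)
      v <- strsplit(substr(seqs[j], s, s + L - 1), "")[[1]]
      k <- sample(0:4, 1)
      if (k > 0) {
        at <- sample(L, k)
        v[at] <- vapply(v[at], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      }
      reads[i] <- paste(v, collapse = "")
    } else {
      reads[i] <- random_dna(L)
    }
    if (runif(1) < 0.3) reads[i] <- rc(reads[i])
  }
  names(reads) <- sprintf("r%03d", seq_along(reads))
  for (mm in c(0, 2)) {
    got <- partition_reads_by_linear_alignment(reads, txs, mm)
    oracle_mapped <- vapply(reads, function(rd) {
      any(vapply(seqs, function(sq) {
        n <- nchar(sq)
        for (cand in c(rd, rc(rd))) {
          for (s in seq_len(n - L + 1)) {
            d <- sum(strsplit(substr(sq, s, s + L - 1), "")[[1]] !=
                       strsplit(cand, "")[[1]])
            if (d <= mm) return(TRUE)
          }
        }
        FALSE
      }, TRUE))
    }, TRUE)
    expect_setequal(got$mapped_ids, names(reads)[oracle_mapped])
    expect_identical(names(got$unmapped), names(reads)[!oracle_mapped])
  }
})

test_that("junction counting enforces the anchor rule and ambiguity discard", {
  tx <- make_tx("tx", c(200, 300), seed = 17)
  ref <- build_backsplice_reference(list(tx), flank_len = 150)
  j21 <- which(ref$donor == 2 & ref$acceptor == 1)
  js <- ref$junction_seq[j21]; bp <- ref$breakpoint_offset[j21]

  centered <- substr(js, bp - 49, bp + 50)       # 50 nt on each side
  lop <- substr(js, bp - 94, bp + 5)             # only 5 nt past breakpoint
  jc <- count_junction_reads(c(a = centered, b = lop), ref,
                             min_anchor = 10, max_mismatch = 0)
  expect_equal(unname(jc$counts[j21, 1]), 1L)
  expect_equal(sum(jc$counts), 1L)

  # same read sequence planted in two distinct junction references -> discard
  ref2 <- ref[c(j21, j21), ]
  ref2$junction_id <- c("gA|t|2|1", "gB|t|2|1")
  jc2 <- count_junction_reads(c(a = centered), ref2,
                              min_anchor = 10, max_mismatch = 0)
  expect_equal(sum(jc2$counts), 0L)
  expect_equal(unname(jc2$ambiguous_discarded), 1L)

  # reverse-complement orientation still counts
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(centered)))
  jc3 <- count_junction_reads(c(a = rc), ref, min_anchor = 10,
                              max_mismatch = 0)
  expect_equal(unname(jc3$counts[j21, 1]), 1L)
})

test_that("error-free pipeline counts equal the substring-search oracle", {
  sim <- simulate_transcriptome_and_reads(n_transcripts = 8, n_circles = 5,
                                          n_reads = 8000, seed = 19)
  ref <- build_backsplice_reference(sim$transcripts)
  part <- partition_reads_by_linear_alignment(sim$reads, sim$transcripts, 0)
  jc <- count_junction_reads(part$unmapped, ref, min_anchor = 10,
                             max_mismatch = 0)
  tot <- rowSums(jc$counts)
  # oracle: exact substring placement crossing the breakpoint with anchors
  oracle <- setNames(integer(nrow(ref)), ref$junction_id)
  L <- sim$read_length
  for (rd in part$unmapped) {
    hits <- integer(0)
    for (i in seq_len(nrow(ref))) {
      p <- regexpr(rd, ref$junction_seq[i], fixed = TRUE)[1]
      if (p > 0 && p + L - 1 >= ref$breakpoint_offset[i] + 10 &&
          p <= ref$breakpoint_offset[i] - 10 + 1)
        hits <- c(hits, i)
    }
    if (length(hits) == 1) oracle[hits] <- oracle[hits] + 1L
  }
  expect_identical(as.integer(unname(tot)), unname(oracle))
  # junctions of zero planted abundance stay at zero
  planted <- sim$truth$circles$junction_id
  expect_true(all(tot[setdiff(ref$junction_id, planted)] == 0))
})

test_that("combined normalization and filter boundaries behave as specified", {
  set.seed(21)
  ns <- 10
  lin <- matrix(rpois(200 * ns, 60), 200, ns,
                dimnames = list(sprintf("lin%03d", 1:200),
                                sprintf("s%02d", 1:ns)))
  linear <- count_dataset(lin, rep(c("synaptosome", "homogenate"),
                                   each = ns / 2),
                          rep("control", ns))
  circ <- rbind(keep = c(4L, 4L, 4L, 4L, 4L, 0L, 0L, 0L, 0L, 0L),
                drop = c(4L, 4L, 4L, 4L, 3L, 0L, 0L, 0L, 0L, 0L))
  colnames(circ) <- colnames(lin)
  de <- combined_circ_de(linear, circ, "fraction",
                         c("synaptosome", "homogenate"))
  expect_identical(de$feature_id, "keep")

  empty <- matrix(0L, 2, ns, dimnames = dimnames(circ))
  de0 <- combined_circ_de(linear, empty, "fraction",
                          c("synaptosome", "homogenate"))
  expect_equal(nrow(de0), 0)

  bad <- circ; colnames(bad)[1] <- "zz"
  expect_error(combined_circ_de(linear, bad, "fraction",
                                c("synaptosome", "homogenate")), "zz")
})

test_that("isoform switches require opposite-sign significant pairs", {
  tab <- switch_example_table()
  tab$feature_id <- sprintf("%s|tx|%d|%d", tab$gene, tab$donor,
                            tab$acceptor)
  sw <- detect_isoform_switches(tab, p_cutoff = 0.05)
  expect_setequal(sw$genes, c("ATF6", "ANKS1B", "GSK3B", "UBA2"))

  one <- data.frame(gene = "G1", donor = 3, acceptor = 1,
                    log2fc = 2, p = 0.001)
  expect_length(detect_isoform_switches(one)$genes, 0)

  same_sign <- data.frame(gene = "G1", donor = c(3, 4), acceptor = c(1, 2),
                          log2fc = c(2, 1.5), p = c(0.001, 0.002))
  expect_length(detect_isoform_switches(same_sign)$genes, 0)
})

test_that("exon span histogram tallies detected junctions only", {
  ref <- data.frame(junction_id = c("g|t|1|1", "g|t|9|7", "g|t|5|1"),
                    donor = c(1, 9, 5), acceptor = c(1, 7, 1),
                    stringsAsFactors = FALSE)
  cnt <- matrix(c(3, 1, 0), 3, 1,
                dimnames = list(ref$junction_id, "s1"))
  h <- exon_span_summary(ref, cnt)
  expect_equal(as.integer(h[c("0", "2")]), c(1L, 1L))
  expect_false("4" %in% names(h))

  set.seed(23)
  txs <- simulate_transcriptome(n_transcripts = 4, seed = 23)
  refr <- build_backsplice_reference(txs)
  rnd <- matrix(rpois(nrow(refr) * 2, 0.5), nrow(refr), 2,
                dimnames = list(refr$junction_id, c("a", "b")))
  h2 <- exon_span_summary(refr, rnd)
  det <- refr[rowSums(rnd)[refr$junction_id] > 0, ]
  expect_equal(as.vector(h2), as.vector(table(det$donor - det$acceptor)))
})

test_that("junction reference FASTA and manifest round-trip", {
  dir <- withr::local_tempdir()
  txs <- simulate_transcriptome(n_transcripts = 3, seed = 73)
  ref <- build_backsplice_reference(txs)
  fa <- file.path(dir, "junc.fa"); mf <- file.path(dir, "junc.tsv")
  write_junction_reference(ref, fa, mf)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(seqs), setNames(ref$junction_seq,
                                                ref$junction_id))
  man <- read_results(mf)
  expect_identical(man$junction_id, ref$junction_id)
  expect_identical(man$breakpoint_offset, ref$breakpoint_offset)
})
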