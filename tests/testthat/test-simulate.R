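test_that("count simulator is deterministic and matches its stated means", {
  a <- simulate_count_dataset(n_genes = 100, n_per_cell = 3, seed = 5)
  b <- simulate_count_dataset(n_genes = 100, n_per_cell = 3, seed = 5)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth$interaction_effect, b$truth$interaction_effect)

  # Poisson limit: flat baseline log2(100), no effects, 50 reps/cell ->
  # per-gene mean ~= 100 * mean(multiplier) within Monte-Carlo error
  sim <- simulate_count_dataset(
    n_genes = 60, n_per_cell = 50,
    baseline_log2 = rep(log2(100), 60),
    fraction_effect = 0, condition_effect = 0, dispersion = 0,
    libsize_multipliers = rep(1, 200), seed = 9)
  gm <- rowMeans(sim$dataset$counts)
  se <- sqrt(100 / 200)                       # Poisson se of a mean of 200
  expect_true(all(abs(gm - 100) < 4 * se))
})

test_that("a planted interaction shows up as the expected ratio of ratios", {
  sim <- simulate_count_dataset(
    n_genes = 40, n_per_cell = 60,
    baseline_log2 = rep(8, 40), fraction_effect = 0, condition_effect = 0,
    interaction_effect = rep(2, 40), dispersion = 0.05,
    libsize_multipliers = rep(1, 240), seed = 21)
  ds <- sim$dataset
  cellmean <- function(fr, co)
    rowMeans(ds$counts[, ds$fraction == fr & ds$condition == co])
  ratio <- (cellmean("synaptosome", "case") /
              cellmean("synaptosome", "control")) /
           (cellmean("homogenate", "case") /
              cellmean("homogenate", "control"))
  expect_equal(mean(ratio), 4, tolerance = 0.1)
  expect_identical(sim$truth$misloc_genes$feature_id,
                   rownames(ds$counts))
})

test_that("read simulator hits the binomial junction-spanning expectation", {
  # one circle gets every read: expected spanning fraction (L-2a+1)/C
  txs <- list(make_tx("tx1", c(600, 400), seed = 31))
  circles <- data.frame(transcript_id = "tx1", donor = 2, acceptor = 1,
                        weight = 1)
  sim <- simulate_reads(txs, circles,
                        linear_weights = c(tx1 = 0), n_reads = 4000,
                        read_length = 100, seed = 32)
  tr <- sim$truth$circles
  expect_equal(tr$circ_len, 1000)
  expect_equal(tr$expected_spanning, 4000 * 81 / 1000)
  # count spanning reads by substring search on the wrapped junction
  circ <- paste0(txs[[1]]$exon_seqs[1], txs[[1]]$exon_seqs[2])
  junc <- paste0(substr(circ, 1000 - 89, 1000), substr(circ, 1, 90))
  hits <- sum(vapply(sim$reads, function(r) {
    p <- regexpr(r, junc, fixed = TRUE)[1]
    p > 0 && p <= 90 - 9 && p + 100 - 1 >= 90 + 10
  }, TRUE))
  sdv <- sqrt(4000 * 0.081 * (1 - 0.081))
  expect_lt(abs(hits - tr$expected_spanning), 3 * sdv)
})

test_that("zero circle weight yields reads free of back-splice sequence", {
  txs <- list(make_tx("tx1", c(300, 300), seed = 41))
  circles <- data.frame(transcript_id = "tx1", donor = 2, acceptor = 1,
                        weight = 0)
  sim <- simulate_reads(txs, circles, linear_weights = c(tx1 = 1),
                        n_reads = 500, read_length = 80, seed = 42)
  # junction-crossing 40+40 nt probe around the back-splice point
  probe <- paste0(substr(txs[[1]]$exon_seqs[2], 261, 300),
                  substr(txs[[1]]$exon_seqs[1], 1, 40))
  expect_false(any(grepl(probe, sim$reads, fixed = TRUE)))
  # and every read is a substring of the linear transcript
  lin <- transcript_sequence(txs[[1]])
  expect_true(all(vapply(sim$reads, function(r)
    grepl(r, lin, fixed = TRUE), TRUE)))
})

test_that("multi-circle simulation keeps per-junction counts near expectation", {
  sim <- simulate_transcriptome_and_reads(n_transcripts = 10, n_circles = 3,
                                          n_reads = 20000, seed = 51)
  ref <- build_backsplice_reference(sim$transcripts)
  part <- partition_reads_by_linear_alignment(sim$reads, sim$transcripts, 0)
  jc <- count_junction_reads(part$unmapped, ref, min_anchor = 10,
                             max_mismatch = 0)
  tot <- rowSums(jc$counts)
  tr <- sim$truth$circles[!sim$truth$circles$short_circle, ]
  for (i in seq_len(nrow(tr))) {
    expc <- tr$expected_spanning[i]
    p <- expc / tr$n_reads[i]
    sdv <- sqrt(max(tr$n_reads[i] * p * (1 - p), 1))
    expect_lt(abs(tot[tr$junction_id[i]] - expc), 3 * sdv)
  }
})

test_that("mirna site simulator is deterministic and null when folds are 1", {
  a <- simulate_mirna_sites(seed = 61)
  b <- simulate_mirna_sites(seed = 61)
  expect_identical(a$shortlist, b$shortlist)
  expect_identical(a$background, b$background)
  # null: shortlist fractions track background fractions
  et <- site_enrichment_test(a$shortlist, a$background)
  expect_gt(min(et$p), 0.001)      # no planted signal to find
  expect_true(all(et$call == "ns"))
})

test_that("planted miRNA fold enrichment appears at the stated magnitude", {
  # many miRNAs and a large background keep the totals nearly unchanged,
  # so observed/expected per-miRNA fraction ratio ~ the planted fold
  sim <- simulate_mirna_sites(n_mirnas = 400, n_genes_background = 20000,
                              shortlist_size = 200,
                              enriched = c(mir007 = 8), mean_lambda = 1,
                              seed = 62)
  s <- sim$shortlist$sites; b <- sim$background$sites
  i <- which(sim$shortlist$mirna_id == "mir007")
  ratio <- (s[i] / sum(s)) / (b[i] / sum(b))
  expect_equal(ratio, 8, tolerance = 0.2 * 8)
  et <- site_enrichment_test(sim$shortlist, sim$background)
  expect_equal(et$mirna_id[which.max(et$chi2)], "mir007")
})

test_that("FASTQ write/read round-trips simulated reads exactly", {
  dir <- withr::local_tempdir()
  txs <- list(make_tx("tx1", c(200, 200), seed = 71))
  sim <- simulate_reads(txs, NULL, c(tx1 = 1), n_reads = 50,
                        read_length = 60, seed = 72)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_identical(back, sim$reads)
})
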