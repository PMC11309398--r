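#' Simulate a 2x2 factorial negative-binomial count dataset
#'
#' Counts for gene g in sample s are drawn
#' `NB(mean = m_s * 2^(b0_g + bF_g*[syn] + bC_g*[case] + bI_g*[syn & case]),
#' variance = mu + alpha_g * mu^2)`, with `m_s` a per-sample library-size
#' multiplier. The interaction coefficient `bI_g` is the mislocalization
#' ground truth: nonzero for a chosen subset of genes, with alternating sign
#' when given as a scalar size. `alpha = 0` degenerates to Poisson.
#'
#' Defaults emulate a desk-scale version of a fractionated brain RNA-seq
#' study: 2000 genes, 6 replicates per fraction-by-condition cell, wide log2
#' baselines, gene-level fraction effects of sd 1 (strong synaptic
#' enrichment signal), condition effects of sd 0.3, dispersion 0.1 and
#' log-normal library sizes of sd 0.2.
#'
#' @param n_genes number of genes G.
#' @param n_per_cell replicates per fraction-by-condition cell.
#' @param baseline_log2 length-2 `(mean, sd)` of the per-gene log2 baseline,
#'   or a length-`n_genes` vector of baselines.
#' @param fraction_effect,condition_effect per-gene coefficients; a scalar is
#'   interpreted as a normal sd from which coefficients are drawn.
#' @param n_interaction number of genes given a nonzero interaction.
#' @param interaction_size |bI| planted in those genes (signs alternate), or
#'   a full per-gene vector via `interaction_effect`.
#' @param interaction_effect optional explicit per-gene interaction vector;
#'   overrides `n_interaction`/`interaction_size`.
#' @param dispersion per-gene NB dispersion alpha (scalar recycled).
#' @param libsize_sd sd of the log-normal library-size multipliers.
#' @param libsize_multipliers optional explicit per-sample multipliers.
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return A list with `dataset` (a [count_dataset()]) and `truth` (list
#'   recording the planted coefficients, the mislocalized gene set and the
#'   simulation parameters).
#' @export
simulate_count_dataset <- function(n_genes = 2000, n_per_cell = 6,
                                   baseline_log2 = c(5, 2),
                                   fraction_effect = 1,
                                   condition_effect = 0.3,
                                   n_interaction = 0, interaction_size = 1.5,
                                   interaction_effect = NULL,
                                   dispersion = 0.1,
                                   libsize_sd = 0.2,
                                   libsize_multipliers = NULL,
                                   seed = 1) {
  set.seed(seed)
  G <- n_genes
  b0 <- if (length(baseline_log2) == G && G != 2) baseline_log2
        else rnorm(G, baseline_log2[1], baseline_log2[2])
  expand <- function(x, what) {
    if (length(x) == 1) rnorm(G, 0, x)
    else if (length(x) == G) x
    else stop(what, " must be a scalar sd or one value per gene")
  }
  bF <- expand(fraction_effect, "fraction_effect")
  bC <- expand(condition_effect, "condition_effect")
  if (is.null(interaction_effect)) {
    bI <- numeric(G)
    if (n_interaction > 0) {
      idx <- sample.int(G, n_interaction)
      bI[idx] <- rep(c(1, -1), length.out = n_interaction) * interaction_size
    }
  } else {
    if (length(interaction_effect) != G)
      stop("interaction_effect must have one value per gene")
    bI <- interaction_effect
  }
  alpha <- rep_len(dispersion, G)
  if (any(alpha < 0)) stop("dispersion must be >= 0")

  cells <- expand.grid(rep = seq_len(n_per_cell),
                       fraction = c("homogenate", "synaptosome"),
                       condition = c("control", "case"),
                       stringsAsFactors = FALSE)
  S <- nrow(cells)
  m <- if (is.null(libsize_multipliers)) exp(rnorm(S, 0, libsize_sd))
       else rep_len(libsize_multipliers, S)
  if (any(m <= 0)) stop("library multipliers must be positive")

  counts <- matrix(0L, G, S)
  for (s in seq_len(S)) {
    syn <- cells$fraction[s] == "synaptosome"
    case <- cells$condition[s] == "case"
    mu <- m[s] * 2^(b0 + bF * syn + bC * case + bI * (syn & case))
    if (any(!is.finite(mu))) stop("non-finite NB mean; check effect sizes")
    counts[, s] <- ifelse(alpha > 0,
                          rnbinom(G, mu = mu, size = 1 / alpha),
                          rpois(G, mu))
  }
  gene_ids <- sprintf("gene%04d", seq_len(G))
  dimnames(counts) <- list(gene_ids,
                           sprintf("s%02d_%s_%s", seq_len(S),
                                   substr(cells$fraction, 1, 3),
                                   substr(cells$condition, 1, 4)))
  ds <- count_dataset(counts, cells$fraction, cells$condition)
  truth <- list(
    misloc_genes = data.frame(feature_id = gene_ids[bI != 0],
                              beta_interaction = bI[bI != 0],
                              stringsAsFactors = FALSE),
    baseline_log2 = setNames(b0, gene_ids),
    fraction_effect = setNames(bF, gene_ids),
    condition_effect = setNames(bC, gene_ids),
    interaction_effect = setNames(bI, gene_ids),
    dispersion = setNames(alpha, gene_ids),
    libsize_multipliers = setNames(m, colnames(counts)),
    seed = seed)
  list(dataset = ds, truth = truth)
}

#' Simulate a toy multi-exon transcriptome
#'
#' Random transcripts, each on its own synthetic contig with fixed-length
#' introns, exon counts and lengths drawn uniformly from the given ranges,
#' and uniformly random A/C/G/T exon sequences. The contig sequence is kept
#' as an attribute so the set can be written with
#' [write_transcript_annotation()] and re-read with [parse_annotation()].
#'
#' @param n_transcripts number of transcripts (one gene each).
#' @param exon_count_range,exon_length_range inclusive integer ranges.
#' @param intron_length fixed intron length on the synthetic contigs.
#' @param seed integer RNG seed.
#' @return Named list of [transcript_model()] objects.
#' @export
simulate_transcriptome <- function(n_transcripts = 20,
                                   exon_count_range = c(2, 8),
                                   exon_length_range = c(100, 400),
                                   intron_length = 50, seed = 1) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_transcripts)) {
    tid <- sprintf("tx%03d", i)
    gid <- sprintf("g%03d", i)
    # sample() would treat a scalar range as 1:n, so index the range vector
    counts_range <- exon_count_range[1]:exon_count_range[2]
    E <- counts_range[sample.int(length(counts_range), 1)]
    lens_range <- exon_length_range[1]:exon_length_range[2]
    lens <- lens_range[sample.int(length(lens_range), E, replace = TRUE)]
    starts <- head(c(0L, cumsum(lens + intron_length)), E)
    exons <- cbind(start = starts, end = starts + lens)
    contig_len <- max(exons[, 2])
    contig_seq <- paste(sample(c("A", "C", "G", "T"), contig_len,
                               replace = TRUE), collapse = "")
    exon_seqs <- substring(contig_seq, exons[, 1] + 1L, exons[, 2])
    tx <- transcript_model(tid, gid, toupper(gid), "+", exons, exon_seqs)
    attr(tx, "contig") <- paste0("chr_", tid)
    attr(tx, "contig_seq") <- contig_seq
    out[[tid]] <- tx
  }
  out
}

#' Simulate reads from linear and circularized transcripts
#'
#' Linear reads are substrings of the spliced transcript sequence with start
#' positions uniform over the valid range; circular reads are substrings of
#' the circularized exon block (start uniform over the circle, wrapping
#' across the back-splice point). Reads are allocated multinomially to
#' sources in proportion to their weights; bases are flipped i.i.d. at rate
#' `error_rate`. Qualities are constant ('I'); nothing downstream reads them.
#'
#' The truth records, per circle, the number of reads emitted, the circle
#' length, and the expected number of reads spanning the back-splice point
#' with at least `truth_anchor` nt on each side:
#' `n_reads * (L - 2a + 1) / C_len` for circles not shorter than the read.
#' Circles shorter than the read are generated with wrap-around and flagged
#' `short_circle` (full-length junction alignment is then impossible).
#'
#' @param transcripts list from [simulate_transcriptome()] (or any
#'   transcript models with exon sequences).
#' @param circles data frame `(transcript_id, donor, acceptor, weight)` with
#'   `donor >= acceptor` (1-based exon indices in transcript order); `NULL`
#'   for none.
#' @param linear_weights named per-transcript weights (default: equal).
#' @param n_reads total reads to emit.
#' @param read_length read length L in nt.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param truth_anchor anchor length a used for the expected spanning count.
#' @param seed integer RNG seed.
#' @return A list with `reads` (named character vector), `truth` (list with
#'   per-circle table `circles` and per-transcript linear read counts), and
#'   `read_length`.
#' @export
simulate_reads <- function(transcripts, circles = NULL,
                           linear_weights = NULL, n_reads = 50000,
                           read_length = 100, error_rate = 0,
                           truth_anchor = 10, seed = 1) {
  set.seed(seed)
  stopifnot(error_rate >= 0, error_rate < 1)
  tx_ids <- vapply(transcripts, `[[`, "", "transcript_id")
  names(transcripts) <- tx_ids
  tx_seq <- vapply(transcripts, transcript_sequence, "")
  if (is.null(linear_weights))
    linear_weights <- setNames(rep(1, length(tx_ids)), tx_ids)
  lw <- linear_weights[tx_ids]
  lw[is.na(lw)] <- 0
  lw[nchar(tx_seq) < read_length] <- 0   # too short to emit a full read

  circ_seq <- character(0)
  if (!is.null(circles) && nrow(circles) > 0) {
    stopifnot(all(circles$donor >= circles$acceptor))
    circ_seq <- vapply(seq_len(nrow(circles)), function(i) {
      tx <- transcripts[[circles$transcript_id[i]]]
      if (is.null(tx)) stop("circle references unknown transcript ",
                            circles$transcript_id[i])
      if (circles$donor[i] > nrow(tx$exons))
        stop("circle exon index out of range for ", tx$transcript_id)
      paste(tx$exon_seqs[circles$acceptor[i]:circles$donor[i]],
            collapse = "")
    }, "")
  }
  w <- c(lw, if (length(circ_seq)) circles$weight else NULL)
  if (all(w <= 0)) stop("all source weights are zero")
  n_src <- length(w)
  alloc <- as.vector(rmultinom(1, n_reads, w / sum(w)))

  n_lin <- length(tx_ids)
  reads <- character(n_reads)
  origin <- integer(n_reads)
  pos <- 1L
  for (j in seq_len(n_src)) {
    k <- alloc[j]
    if (k == 0) next
    if (j <= n_lin) {
      s <- tx_seq[j]
      starts <- sample.int(nchar(s) - read_length + 1L, k, replace = TRUE)
      reads[pos:(pos + k - 1L)] <- substring(s, starts,
                                             starts + read_length - 1L)
    } else {
      cs <- circ_seq[j - n_lin]
      clen <- nchar(cs)
      dbl <- paste(rep(cs, ceiling((clen + read_length) / clen)),
                   collapse = "")
      starts <- sample.int(clen, k, replace = TRUE)    # uniform on circle
      reads[pos:(pos + k - 1L)] <- substring(dbl, starts,
                                             starts + read_length - 1L)
    }
    origin[pos:(pos + k - 1L)] <- j
    pos <- pos + k
  }
  # shuffle so read order carries no source information
  ord <- sample.int(n_reads)
  reads <- reads[ord]; origin <- origin[ord]
  if (error_rate > 0) reads <- mutate_reads(reads, error_rate)
  names(reads) <- sprintf("read%06d", seq_len(n_reads))

  circle_truth <- NULL
  if (length(circ_seq)) {
    clen <- nchar(circ_seq)
    nr <- alloc[(n_lin + 1):n_src]
    a <- truth_anchor
    frac <- ifelse(clen >= read_length,
                   pmax(read_length - 2 * a + 1, 0) / clen, NA_real_)
    tx_of <- circles$transcript_id
    gene_of <- vapply(transcripts[tx_of], `[[`, "", "gene_id")
    circle_truth <- data.frame(
      junction_id = paste(gene_of, tx_of, circles$donor, circles$acceptor,
                          sep = "|"),
      transcript_id = tx_of, donor = circles$donor,
      acceptor = circles$acceptor, weight = circles$weight,
      circ_len = clen, n_reads = nr,
      expected_spanning = nr * frac,
      short_circle = clen < read_length,
      stringsAsFactors = FALSE)
  }
  linear_truth <- setNames(alloc[seq_len(n_lin)], tx_ids)
  list(reads = reads,
       truth = list(circles = circle_truth, linear_reads = linear_truth,
                    error_rate = error_rate, truth_anchor = truth_anchor,
                    seed = seed),
       read_length = read_length)
}

mutate_reads <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    v <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(v)) < rate)
    if (length(hit)) {
      for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1)
      r <- paste(v, collapse = "")
    }
    r
  }, "", USE.NAMES = FALSE)
}

#' Simulate a transcriptome together with linear and back-spliced reads
#'
#' Convenience wrapper around [simulate_transcriptome()] and
#' [simulate_reads()] that also picks random circles: one call yields the
#' transcript models, a read set and the ground truth. For multi-sample
#' designs call [simulate_reads()] repeatedly on one transcriptome with
#' different seeds/weights.
#'
#' @inheritParams simulate_transcriptome
#' @inheritParams simulate_reads
#' @param n_circles number of distinct back-splice circles to plant.
#' @param circ_read_share share of reads allocated (in expectation) to the
#'   circular sources collectively.
#' @return A list with `transcripts`, `circles`, `reads`, `truth`,
#'   `read_length`.
#' @export
simulate_transcriptome_and_reads <- function(n_transcripts = 20,
                                             exon_count_range = c(2, 8),
                                             exon_length_range = c(100, 400),
                                             n_circles = 15,
                                             circ_read_share = 0.1,
                                             n_reads = 50000,
                                             read_length = 100,
                                             error_rate = 0, seed = 1) {
  txs <- simulate_transcriptome(n_transcripts, exon_count_range,
                                exon_length_range, seed = seed)
  set.seed(seed + 1L)
  tx_ids <- names(txs)
  picks <- sample(tx_ids, n_circles, replace = n_circles > length(tx_ids))
  circles <- do.call(rbind, lapply(unique(picks), function(tid) {
    E <- nrow(txs[[tid]]$exons)
    k <- sum(picks == tid)
    pairs <- unique(t(replicate(k, sort(sample.int(E, 2, replace = TRUE)))))
    data.frame(transcript_id = tid, donor = pairs[, 2],
               acceptor = pairs[, 1], stringsAsFactors = FALSE)
  }))
  circles <- circles[!duplicated(circles), , drop = FALSE]
  circles$weight <- exp(rnorm(nrow(circles), 0, 0.5))
  # scale so circles get circ_read_share of the total weight mass
  lin_w <- setNames(exp(rnorm(length(tx_ids), 0, 0.5)), tx_ids)
  circles$weight <- circles$weight / sum(circles$weight) *
    sum(lin_w) * circ_read_share / (1 - circ_read_share)
  sim <- simulate_reads(txs, circles, lin_w, n_reads, read_length,
                        error_rate, seed = seed + 2L)
  list(transcripts = txs, circles = circles, reads = sim$reads,
       truth = sim$truth, read_length = read_length)
}

#' Write reads as FASTQ
#'
#' @param reads named character vector of read sequences.
#' @param file output path.
#' @return `file`, invisibly. Qualities are constant `'I'`.
#' @export
write_fastq <- function(reads, file) {
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), ""))
  names(qual) <- names(dna)
  Biostrings::writeXStringSet(dna, file, format = "fastq", qualities = qual)
  invisible(file)
}

#' Read a FASTQ file as a named character vector
#'
#' @param file FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(file) {
  dna <- Biostrings::readDNAStringSet(file, format = "fastq")
  out <- as.character(dna)
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

#' Simulate miRNA binding-site tables with planted enrichment
#'
#' Background per-gene site counts for miRNA m are Poisson with rate
#' `lambda_m` (log-normal across miRNAs); shortlist genes draw their counts
#' with `lambda_m` multiplied by the planted fold factor for enriched
#' miRNAs. Totals per miRNA are returned as site tables; the background is
#' transcriptome-wide and includes the shortlist genes.
#'
#' @param n_mirnas number of miRNAs.
#' @param n_genes_background number of genes in the background set.
#' @param shortlist_size number of genes in the shortlist
#'   (<= `n_genes_background`).
#' @param enriched named numeric vector of fold factors, names in
#'   `mir001 ...`; unnamed scalar count `k` plants `k` miRNAs at
#'   `enriched_fold`.
#' @param enriched_fold fold used when `enriched` is a count.
#' @param mean_lambda mean per-gene site rate.
#' @param seed integer RNG seed.
#' @return A list with `shortlist` and `background` site tables (data frames
#'   `mirna_id`, `sites`) and `truth` (named fold factors).
#' @export
simulate_mirna_sites <- function(n_mirnas = 50, n_genes_background = 5000,
                                 shortlist_size = 200, enriched = NULL,
                                 enriched_fold = 8, mean_lambda = 0.5,
                                 seed = 1) {
  set.seed(seed)
  stopifnot(shortlist_size <= n_genes_background)
  ids <- sprintf("mir%03d", seq_len(n_mirnas))
  folds <- setNames(rep(1, n_mirnas), ids)
  if (!is.null(enriched)) {
    if (is.null(names(enriched))) {
      picked <- sample(ids, as.integer(enriched[1]))
      folds[picked] <- enriched_fold
    } else {
      if (!all(names(enriched) %in% ids))
        stop("enriched names must be among the simulated miRNA ids")
      folds[names(enriched)] <- enriched
    }
  }
  lambda <- mean_lambda * exp(rnorm(n_mirnas, 0, 0.5))
  # shortlist genes are part of the background (transcriptome-wide index)
  n_rest <- n_genes_background - shortlist_size
  short_counts <- vapply(seq_len(n_mirnas), function(m)
    sum(rpois(shortlist_size, lambda[m] * folds[m])), 0)
  rest_counts <- vapply(seq_len(n_mirnas), function(m)
    sum(rpois(n_rest, lambda[m])), 0)
  background <- data.frame(mirna_id = ids,
                           sites = as.integer(short_counts + rest_counts),
                           stringsAsFactors = FALSE)
  shortlist <- data.frame(mirna_id = ids,
                          sites = as.integer(short_counts),
                          stringsAsFactors = FALSE)
  list(shortlist = shortlist, background = background,
       truth = list(folds = folds, lambda = setNames(lambda, ids),
                    seed = seed))
}
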