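#' Build the exhaustive back-splice junction reference
#'
#' For every transcript with E exons, emits all donor/acceptor pairings with
#' `donor >= acceptor` -- E(E+1)/2 junctions per transcript, including each
#' single exon spliced back on itself. The junction sequence is the last
#' `flank_len` nt of the circularized exon block (ending at the donor exon
#' 3' end) followed by its first `flank_len` nt (starting at the acceptor
#' exon 5' end); flanks are clamped to the circle and never wrap, so short
#' circles get shorter flanks and no duplicated sequence. Junctions that are
#' identical at the (gene, donor exon genomic span, acceptor exon genomic
#' span) level across redundant transcripts are collapsed, keeping the first
#' transcript in id order.
#'
#' @param transcripts list of [transcript_model()] objects with exon
#'   sequences.
#' @param flank_len maximum flank length on each side of the breakpoint
#'   (150 by default).
#' @return A data frame of class `BackspliceReference` with columns
#'   `junction_id` (`gene|transcript|donor|acceptor`), `gene_id`,
#'   `transcript_id`, `donor`, `acceptor`, `donor_flank_len`,
#'   `acceptor_flank_len`, `breakpoint_offset`, `junction_seq`.
#' @export
build_backsplice_reference <- function(transcripts, flank_len = 150) {
  if (flank_len < 1) stop("flank_len must be >= 1")
  transcripts <- transcripts[order(vapply(transcripts, `[[`, "",
                                          "transcript_id"))]
  rows <- lapply(transcripts, function(tx) {
    if (is.null(tx$exon_seqs))
      stop("transcript ", tx$transcript_id, " has no exon sequences")
    E <- nrow(tx$exons)
    pairs <- which(upper.tri(matrix(0, E, E), diag = TRUE), arr.ind = TRUE)
    # row = acceptor a, col = donor d, a <= d
    a <- pairs[, 1]; d <- pairs[, 2]
    circ <- vapply(seq_along(a), function(i)
      paste(tx$exon_seqs[a[i]:d[i]], collapse = ""), "")
    clen <- nchar(circ)
    dfl <- as.integer(pmin(flank_len, clen))
    afl <- as.integer(pmin(flank_len, clen))
    seq <- paste0(substring(circ, clen - dfl + 1L, clen),
                  substring(circ, 1L, afl))
    span <- function(idx) paste(tx$exons[idx, 1], tx$exons[idx, 2],
                                sep = "-")
    data.frame(
      junction_id = paste(tx$gene_id, tx$transcript_id, d, a, sep = "|"),
      gene_id = tx$gene_id, transcript_id = tx$transcript_id,
      donor = as.integer(d), acceptor = as.integer(a),
      donor_flank_len = dfl, acceptor_flank_len = afl,
      breakpoint_offset = dfl, junction_seq = seq,
      dedup_key = paste(tx$gene_id, span(d), span(a), sep = "|"),
      stringsAsFactors = FALSE)
  })
  ref <- do.call(rbind, rows)
  rownames(ref) <- NULL
  ref <- ref[!duplicated(ref$dedup_key), , drop = FALSE]
  ref$dedup_key <- NULL
  class(ref) <- c("BackspliceReference", "data.frame")
  ref
}

#' Write a back-splice junction reference as FASTA plus TSV manifest
#'
#' @param ref a [build_backsplice_reference()] result.
#' @param fasta_file,manifest_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_junction_reference <- function(ref, fasta_file, manifest_file) {
  dna <- Biostrings::DNAStringSet(setNames(ref$junction_seq,
                                           ref$junction_id))
  Biostrings::writeXStringSet(dna, fasta_file)
  write.table(ref[, c("junction_id", "gene_id", "transcript_id", "donor",
                      "acceptor", "donor_flank_len", "acceptor_flank_len",
                      "breakpoint_offset")],
              manifest_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_file, manifest_file))
}

#' Partition reads by ungapped full-length linear alignment
#'
#' A read is mapped iff it has an ungapped full-length placement within any
#' spliced transcript sequence, in either orientation, with at most
#' `max_mismatch` mismatches; everything else is returned as unmapped, in
#' input order. The per-read best transcript assignment is also returned so
#' linear per-transcript counts can be derived from simulated reads.
#'
#' @param reads named character vector of read sequences.
#' @param transcripts list of [transcript_model()] objects with sequences.
#' @param max_mismatch maximum Hamming mismatches.
#' @return A list with `mapped_ids`, `unmapped` (named character vector),
#'   and `assignment` (per-read transcript id, `NA` when unmapped).
#' @export
partition_reads_by_linear_alignment <- function(reads, transcripts,
                                                max_mismatch = 2) {
  if (length(reads) == 0L) {
    warning("empty read set")
    return(list(mapped_ids = character(0),
                unmapped = setNames(character(0), character(0)),
                assignment = character(0)))
  }
  tx_ids <- vapply(transcripts, `[[`, "", "transcript_id")
  refs <- vapply(transcripts, transcript_sequence, "")
  idx <- cpp_assign_reads(unname(reads), unname(refs),
                          as.integer(max_mismatch))
  assignment <- setNames(tx_ids[idx], names(reads))
  mapped <- !is.na(idx)
  list(mapped_ids = names(reads)[mapped],
       unmapped = reads[!mapped],
       assignment = assignment)
}

#' Per-transcript linear counts from read assignments
#'
#' @param assignment per-read transcript assignment from
#'   [partition_reads_by_linear_alignment()].
#' @param transcripts the transcript models (fixes row order).
#' @return Named integer vector of read counts per transcript.
#' @export
tabulate_linear_counts <- function(assignment, transcripts) {
  tx_ids <- vapply(transcripts, `[[`, "", "transcript_id")
  tab <- table(factor(assignment, levels = tx_ids))
  setNames(as.integer(tab), tx_ids)
}

#' Count junction-spanning reads
#'
#' A read counts toward a junction iff it aligns ungapped and full-length to
#' the junction sequence (either orientation) with at most `max_mismatch`
#' mismatches and the placement covers at least `min_anchor` nt on each side
#' of the breakpoint. Among multiple qualifying junctions the unique
#' mismatch-minimum wins; mismatch ties across distinct junctions discard
#' the read, tallied per sample in `ambiguous_discarded`.
#'
#' @param unmapped a named character vector of reads (one sample), or a
#'   named list of such vectors (one element per sample).
#' @param ref a [build_backsplice_reference()] result.
#' @param min_anchor minimum aligned nt on each side of the breakpoint.
#' @param max_mismatch maximum Hamming mismatches.
#' @return A list with `counts` (junction x sample integer matrix) and
#'   `ambiguous_discarded` (named integer per sample).
#' @export
count_junction_reads <- function(unmapped, ref, min_anchor = 10,
                                 max_mismatch = 2) {
  stopifnot(min_anchor >= 1)
  if (!is.list(unmapped)) unmapped <- list(sample1 = unmapped)
  if (is.null(names(unmapped)))
    names(unmapped) <- sprintf("sample%d", seq_along(unmapped))
  counts <- matrix(0L, nrow(ref), length(unmapped),
                   dimnames = list(ref$junction_id, names(unmapped)))
  ambiguous <- setNames(integer(length(unmapped)), names(unmapped))
  for (s in seq_along(unmapped)) {
    rd <- unmapped[[s]]
    if (length(rd) == 0L) next
    if (any(2L * min_anchor > nchar(rd)))
      stop("min_anchor too large for the read length")
    hit <- cpp_assign_junction_reads(unname(rd), ref$junction_seq,
                                     as.integer(ref$breakpoint_offset),
                                     as.integer(min_anchor),
                                     as.integer(max_mismatch))
    ambiguous[s] <- sum(hit == -1L)
    tab <- tabulate(hit[hit > 0L], nbins = nrow(ref))
    counts[, s] <- as.integer(tab)
  }
  list(counts = counts, ambiguous_discarded = ambiguous)
}

#' Joint circular + linear differential expression
#'
#' Appends the junction count matrix to the linear count matrix, estimates
#' median-of-ratios size factors on the combined table (normalizing the
#' circles in the context of the rest of the transcriptome), filters
#' circular features by `(circ_min_count, circ_min_samples)`, runs the
#' two-group Wald test for the requested contrast, and reports circular
#' features only.
#'
#' @param linear a [count_dataset()] of linear transcript counts.
#' @param circ_counts junction x sample integer matrix (same samples), as
#'   `counts` from [count_junction_reads()].
#' @param contrast_factor `"fraction"` or `"condition"`.
#' @param contrast `c(B, A)` levels of that factor.
#' @param within optional named filter, e.g. `c(condition = "control")`, to
#'   restrict samples before testing.
#' @param circ_min_count,circ_min_samples circular feature filter (4 counts
#'   in at least 5 samples by default).
#' @param dispersion_prior_df passed to [two_group_de()].
#' @return Data frame of DE results restricted to circular features.
#' @export
combined_circ_de <- function(linear, circ_counts,
                             contrast_factor = c("fraction", "condition"),
                             contrast, within = NULL,
                             circ_min_count = 4, circ_min_samples = 5,
                             dispersion_prior_df = 8) {
  contrast_factor <- match.arg(contrast_factor)
  circ_counts <- as.matrix(circ_counts)
  if (!identical(colnames(linear$counts), colnames(circ_counts))) {
    diffs <- c(setdiff(colnames(linear$counts), colnames(circ_counts)),
               setdiff(colnames(circ_counts), colnames(linear$counts)))
    if (length(diffs) > 0L)
      stop("sample sets differ: ", paste(diffs, collapse = ", "))
    circ_counts <- circ_counts[, colnames(linear$counts), drop = FALSE]
  }
  if (any(rownames(circ_counts) %in% rownames(linear$counts)))
    stop("junction ids collide with linear feature ids")
  combined <- count_dataset(rbind(linear$counts, circ_counts),
                            as.character(linear$fraction),
                            as.character(linear$condition))
  if (!is.null(within)) {
    keep <- as.character(combined[[names(within)]]) == within[[1]]
    combined <- subset_samples(combined, keep)
  }
  sf <- estimate_size_factors(combined)
  is_circ <- rownames(combined$counts) %in% rownames(circ_counts)
  circ_keep <- rowSums(combined$counts >= circ_min_count) >=
    circ_min_samples & is_circ
  groups <- as.character(combined[[contrast_factor]])
  if (!all(contrast %in% groups))
    stop("contrast level(s) absent after subsetting")
  use <- !is_circ | circ_keep
  de <- two_group_de(combined$counts[use, , drop = FALSE], groups, contrast,
                     size_factors = sf,
                     dispersion_prior_df = dispersion_prior_df)
  de[de$feature_id %in% rownames(circ_counts), , drop = FALSE]
}

parse_junction_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  ok <- lengths(parts) == 4L
  if (!all(ok)) stop("junction id not parseable: ", ids[!ok][1])
  data.frame(gene = vapply(parts, `[[`, "", 1),
             transcript = vapply(parts, `[[`, "", 2),
             donor = as.integer(vapply(parts, `[[`, "", 3)),
             acceptor = as.integer(vapply(parts, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Detect circRNA isoform switches
#'
#' A gene switches isoforms when it carries at least two significantly
#' changed back-splice junctions (`p < p_cutoff`) with opposite log2
#' fold-change signs. All opposite-sign significant pairs are listed with
#' both isoforms' statistics.
#'
#' @param circ_de data frame with per-junction `log2fc` and `p`; junction
#'   identity is taken from `gene`/`donor`/`acceptor` columns if present,
#'   otherwise parsed from `feature_id` as `gene|transcript|donor|acceptor`.
#' @param p_cutoff raw p-value cutoff (0.05 by default).
#' @return A list with `genes` (character vector of switching genes) and
#'   `pairs` (data frame: gene, donor/acceptor/log2fc/p of both isoforms).
#' @export
detect_isoform_switches <- function(circ_de, p_cutoff = 0.05) {
  d <- circ_de
  if (!all(c("gene", "donor", "acceptor") %in% names(d)))
    d <- cbind(d, parse_junction_ids(d$feature_id))
  sig <- d[d$p < p_cutoff, , drop = FALSE]
  pairs <- list()
  for (g in unique(sig$gene)) {
    gi <- sig[sig$gene == g, , drop = FALSE]
    if (nrow(gi) < 2) next
    up <- which(gi$log2fc > 0); dn <- which(gi$log2fc < 0)
    for (i in up) for (j in dn) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene = g,
        donor_1 = gi$donor[i], acceptor_1 = gi$acceptor[i],
        log2fc_1 = gi$log2fc[i], p_1 = gi$p[i],
        donor_2 = gi$donor[j], acceptor_2 = gi$acceptor[j],
        log2fc_2 = gi$log2fc[j], p_2 = gi$p[j],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene = character(0), donor_1 = integer(0),
               acceptor_1 = integer(0), log2fc_1 = numeric(0),
               p_1 = numeric(0), donor_2 = integer(0),
               acceptor_2 = integer(0), log2fc_2 = numeric(0),
               p_2 = numeric(0), stringsAsFactors = FALSE)
  list(genes = unique(pairs$gene), pairs = pairs)
}

#' Exon-span histogram of detected junctions
#'
#' Span is `donor - acceptor` (0 = a single exon spliced back on itself);
#' the histogram covers junctions with a total count above zero.
#'
#' @param ref a [build_backsplice_reference()] result (or any data frame
#'   with `junction_id`, `donor`, `acceptor`).
#' @param counts junction x sample count matrix; rownames must match
#'   `junction_id`.
#' @return A table of span -> number of detected junctions.
#' @export
exon_span_summary <- function(ref, counts) {
  total <- rowSums(as.matrix(counts))[ref$junction_id]
  total[is.na(total)] <- 0
  detected <- ref[total > 0, , drop = FALSE]
  table(span = detected$donor - detected$acceptor)
}
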