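#' Transcript model
#'
#' A transcript as an ordered set of exons with optional exon sequences.
#' Exons are kept in transcript (5'->3') order -- exon 1 is the 5'-most exon
#' regardless of genomic strand -- with coordinates stored internally as
#' 0-based half-open intervals. Exon numbering used in back-splice junction
#' names is 1-based in this order.
#'
#' @param transcript_id,gene_id,gene_name identifier strings.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open genomic intervals,
#'   one row per exon, in transcript order.
#' @param exon_seqs optional character vector of exon sequences (one per
#'   exon, alphabet A/C/G/T/N), already oriented 5'->3' in transcript order.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name = gene_id,
                             strand = "+", exons, exon_seqs = NULL) {
  exons <- as.matrix(exons)
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, ": empty exon list")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exons[, 2] <= exons[, 1]) || any(exons[, 1] < 0))
    stop("transcript ", transcript_id, ": invalid exon interval")
  if (!is.null(exon_seqs)) {
    if (length(exon_seqs) != nrow(exons))
      stop("transcript ", transcript_id,
           ": exon_seqs length does not match exon count")
    if (any(nchar(exon_seqs) != exons[, 2] - exons[, 1]))
      stop("transcript ", transcript_id,
           ": exon sequence length disagrees with interval width")
    if (any(grepl("[^ACGTN]", exon_seqs)))
      stop("transcript ", transcript_id, ": exon sequence outside {A,C,G,T,N}")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_name = gene_name, strand = strand,
                 exons = unname(exons), exon_seqs = exon_seqs),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s, %s strand, %d exon%s%s)\n",
              x$transcript_id, x$gene_id, x$strand, nrow(x$exons),
              if (nrow(x$exons) == 1L) "" else "s",
              if (is.null(x$exon_seqs)) "" else ", sequences attached"))
  invisible(x)
}

#' Parse a transcript annotation with sequences
#'
#' Reads exon records from a GTF/GFF file and attaches exon sequences from a
#' FASTA file. The FASTA may contain genomic contigs (exon sequences are
#' extracted by coordinate and reverse-complemented on the minus strand so
#' exon 1 is the transcript 5' end) or spliced transcript sequences named by
#' `transcript_id` (exon sequences are cut at cumulative exon offsets).
#'
#' @param annotation_file path to a GTF/GFF file with exon features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @param fasta_file path to a FASTA file covering every referenced contig
#'   (genomic mode) or every transcript (transcript mode).
#' @return A list of [transcript_model()] objects, ordered by transcript id.
#' @export
parse_annotation <- function(annotation_file, fasta_file) {
  gr <- rtracklayer::import(annotation_file)
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon records")
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("exon records lack transcript_id attributes")
  # transcripts announced by transcript/mRNA features but owning no exons
  tx_feats <- gr[tolower(as.character(gr$type)) %in% c("transcript", "mrna")]
  missing_tx <- setdiff(unique(tx_feats$transcript_id),
                        unique(ex$transcript_id))
  if (length(missing_tx) > 0L)
    stop("transcript(s) without exon records: ",
         paste(sort(missing_tx), collapse = ", "))

  by_contig <- all(unique(as.character(GenomicRanges::seqnames(ex))) %in%
                     names(seqs))
  tx_ids <- sort(unique(ex$transcript_id))
  if (!by_contig) {
    absent <- setdiff(unique(as.character(GenomicRanges::seqnames(ex))),
                      names(seqs))
    if (!all(tx_ids %in% names(seqs)))
      stop("sequence missing for contig(s): ", paste(absent, collapse = ", "))
  }

  lapply(setNames(tx_ids, tx_ids), function(tid) {
    e <- ex[ex$transcript_id == tid]
    strand <- as.character(GenomicRanges::strand(e))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    # transcript order: exon_number attribute when present, else coordinate
    if (!is.null(e$exon_number) && !anyNA(e$exon_number)) {
      e <- e[order(as.integer(as.character(e$exon_number)))]
    } else {
      e <- e[order(GenomicRanges::start(e),
                   decreasing = (strand == "-"))]
    }
    exons <- to_zero_based(GenomicRanges::start(e), GenomicRanges::end(e))
    gene_id <- if (is.null(e$gene_id)) tid else e$gene_id[1]
    gene_name <- if (is.null(e$gene_name) || is.na(e$gene_name[1]))
      gene_id else e$gene_name[1]
    if (by_contig) {
      contig <- as.character(GenomicRanges::seqnames(e))[1]
      cs <- as.character(seqs[[contig]])
      if (max(exons[, 2]) > nchar(cs))
        stop("exon of ", tid, " extends beyond contig ", contig)
      raw <- substring(cs, exons[, 1] + 1L, exons[, 2])
      exon_seqs <- if (strand == "-") reverse_complement(raw) else raw
    } else {
      ts <- as.character(seqs[[tid]])
      w <- exons[, 2] - exons[, 1]
      ends <- cumsum(w)
      if (ends[length(ends)] > nchar(ts))
        stop("exons of ", tid, " exceed transcript sequence length")
      exon_seqs <- substring(ts, ends - w + 1L, ends)
    }
    transcript_model(tid, gene_id, gene_name, strand, exons, exon_seqs)
  })
}

#' Spliced transcript sequence
#'
#' Concatenated exon sequences of a transcript in transcript order.
#'
#' @param tx a [transcript_model()] with `exon_seqs` attached.
#' @return A single character string.
#' @export
transcript_sequence <- function(tx) {
  if (is.null(tx$exon_seqs)) stop("transcript has no exon sequences attached")
  paste(tx$exon_seqs, collapse = "")
}

#' Write a transcript set as GTF and genome FASTA
#'
#' Counterpart of [parse_annotation()] used mainly by the simulators: each
#' transcript's exons are laid out on its recorded (synthetic) contig.
#'
#' @param transcripts list of [transcript_model()] objects; each must carry
#'   a `contig` and `contig_seq` attribute (as produced by
#'   [simulate_transcriptome()]).
#' @param gtf_file,fasta_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcript_annotation <- function(transcripts, gtf_file, fasta_file) {
  rows <- lapply(transcripts, function(tx) {
    contig <- attr(tx, "contig")
    if (is.null(contig)) stop("transcript ", tx$transcript_id,
                              " carries no contig attribute")
    one <- to_one_based(tx$exons)
    data.frame(
      seqname = contig, source = "synloc", feature = "exon",
      start = one[, 1], end = one[, 2], score = ".", strand = tx$strand,
      frame = ".",
      attr = sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; exon_number "%d";',
        tx$gene_id, tx$transcript_id, tx$gene_name, seq_len(nrow(tx$exons))),
      stringsAsFactors = FALSE)
  })
  gtf <- do.call(rbind, rows)
  write.table(gtf, gtf_file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  contigs <- vapply(transcripts, function(tx) attr(tx, "contig"), "")
  seqs <- vapply(transcripts, function(tx) attr(tx, "contig_seq"), "")
  keep <- !duplicated(contigs)
  dna <- Biostrings::DNAStringSet(setNames(seqs[keep], contigs[keep]))
  Biostrings::writeXStringSet(dna, fasta_file)
  invisible(c(gtf_file, fasta_file))
}
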