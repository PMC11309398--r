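#' Analysis configuration
#'
#' Central container for every tunable the pipeline exposes, with the
#' defaults used throughout: the mRNA count filter (ten counts in at least
#' nine samples), the circular RNA filter (four counts in at least five
#' samples), the primary mislocalization FDR cutoff 0.001 (0.01 preset for
#' smaller designs), 150 nt junction flanks, a 10 nt anchor and up to 2
#' mismatches for junction alignment.
#'
#' `n_samples = "auto"` resolves to 1 with the normal reference --- the
#' empirically standardized, calibrated form of the mislocalization
#' statistic --- and to the total number of samples contributing to both
#' contrasts when `null_dist = "student_t"` (the literal N-sample
#' construction; see the vignette for why it is not the default).
#'
#' @param min_count,min_samples mRNA feature filter.
#' @param circ_min_count,circ_min_samples circular RNA feature filter.
#' @param misloc_fdr_cutoff FDR cutoff for mislocalization direction calls.
#' @param de_alpha raw p cutoff used in overlap/concordance summaries.
#' @param flank_len junction flank length (nt).
#' @param min_anchor minimum aligned nt each side of a breakpoint.
#' @param max_mismatch maximum Hamming mismatches in read alignment.
#' @param n_samples `"auto"` or an integer N for the mislocalization test.
#' @param null_dist `"normal"` or `"student_t"`.
#' @param dispersion_prior_df moderation prior df for the DE engine.
#' @param mirna_fdr_cutoff FDR cutoff for miRNA enrichment calls.
#' @param seed integer seed for any stochastic step.
#' @return A list of class `AnalysisConfig`.
#' @export
analysis_config <- function(min_count = 10, min_samples = 9,
                            circ_min_count = 4, circ_min_samples = 5,
                            misloc_fdr_cutoff = 0.001, de_alpha = 0.05,
                            flank_len = 150, min_anchor = 10,
                            max_mismatch = 2, n_samples = "auto",
                            null_dist = c("normal", "student_t"),
                            dispersion_prior_df = 8,
                            mirna_fdr_cutoff = 0.05, seed = 1) {
  null_dist <- match.arg(null_dist)
  stopifnot(min_count >= 1, min_samples >= 1, circ_min_count >= 1,
            circ_min_samples >= 1, flank_len >= 1, min_anchor >= 1,
            max_mismatch >= 0,
            misloc_fdr_cutoff > 0, misloc_fdr_cutoff < 1,
            de_alpha > 0, de_alpha < 1,
            mirna_fdr_cutoff > 0, mirna_fdr_cutoff < 1)
  if (!identical(n_samples, "auto")) stopifnot(n_samples >= 1)
  structure(list(min_count = min_count, min_samples = min_samples,
                 circ_min_count = circ_min_count,
                 circ_min_samples = circ_min_samples,
                 misloc_fdr_cutoff = misloc_fdr_cutoff,
                 de_alpha = de_alpha, flank_len = flank_len,
                 min_anchor = min_anchor, max_mismatch = max_mismatch,
                 n_samples = n_samples, null_dist = null_dist,
                 dispersion_prior_df = dispersion_prior_df,
                 mirna_fdr_cutoff = mirna_fdr_cutoff,
                 seed = as.integer(seed)),
            class = "AnalysisConfig")
}

resolve_n_samples <- function(config, total_samples) {
  if (!identical(config$n_samples, "auto")) return(config$n_samples)
  if (config$null_dist == "student_t") total_samples else 1
}

#' Run the mRNA, circular RNA and miRNA analyses end to end
#'
#' Stages run in order as their inputs allow: feature filtering, size
#' factors, the four subset two-group contrasts (synaptosome vs homogenate
#' within each condition; case vs control within each fraction), the
#' mislocalization test, circular RNA detection/quantification/DE, and
#' miRNA site enrichment. A stage whose inputs are missing is skipped with
#' a logged warning. Every output table is written as TSV under `out_dir`;
#' given identical inputs, config and seed the outputs are byte-identical
#' across runs.
#'
#' @param config an [analysis_config()].
#' @param counts a [count_dataset()] (mRNA stage input), or `NULL`.
#' @param reads named list of per-sample read vectors, or a single named
#'   character vector (circ stage input), or `NULL`.
#' @param transcripts transcript models with sequences (circ stage), or
#'   `NULL`.
#' @param circ_sample_info optional data frame (`sample_id`, `fraction`,
#'   `condition`) describing the read samples; required for circular DE.
#' @param mirna_shortlist,mirna_background site tables (miRNA stage), or
#'   `NULL`.
#' @param out_dir output directory, created if needed.
#' @return A list bundle with elements `de` (list of the four contrast
#'   tables), `misloc`, `circ` (reference, counts, DE, switches, span),
#'   `mirna`, and `log` (character vector, also written to `run_log.txt`).
#' @export
run_full_analysis <- function(config = analysis_config(), counts = NULL,
                              reads = NULL, transcripts = NULL,
                              circ_sample_info = NULL,
                              mirna_shortlist = NULL,
                              mirna_background = NULL,
                              out_dir = "synloc_results") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c("synloc run",
           sprintf("config: %s", paste(names(unclass(config)),
                                       unlist(config), sep = "=",
                                       collapse = " ")))
  note <- function(...) log <<- c(log, sprintf(...))
  out <- list(de = NULL, misloc = NULL, circ = NULL, mirna = NULL)
  set.seed(config$seed)

  if (!is.null(counts)) {
    note("mRNA stage: %d features x %d samples", nrow(counts$counts),
         ncol(counts$counts))
    filtered <- filter_features(counts, config$min_count,
                                config$min_samples)
    note("filter (%d in >=%d samples): %d of %d features kept",
         config$min_count, config$min_samples, nrow(filtered$counts),
         nrow(counts$counts))
    de <- list()
    for (cond in c("control", "case")) {
      sub <- subset_samples(filtered, filtered$condition == cond)
      de[[paste0("syn_vs_hom_", cond)]] <-
        two_group_de(sub, as.character(sub$fraction),
                     c("synaptosome", "homogenate"),
                     dispersion_prior_df = config$dispersion_prior_df)
    }
    for (frac in c("homogenate", "synaptosome")) {
      sub <- subset_samples(filtered, filtered$fraction == frac)
      de[[paste0("case_vs_control_", frac)]] <-
        two_group_de(sub, as.character(sub$condition),
                     c("case", "control"),
                     dispersion_prior_df = config$dispersion_prior_df)
    }
    for (nm in names(de))
      write_results(de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))
    out$de <- de

    misin <- build_misloc_input(de$case_vs_control_synaptosome,
                                de$case_vs_control_homogenate)
    N <- resolve_n_samples(config, ncol(filtered$counts))
    out$misloc <- misloc_test(misin, n_samples = N,
                              null_dist = config$null_dist,
                              fdr_cutoff = config$misloc_fdr_cutoff)
    note("mislocalization: N=%s, %s reference; %d up, %d down of %d",
         format(N), config$null_dist,
         sum(out$misloc$direction == "up"),
         sum(out$misloc$direction == "down"), nrow(out$misloc))
    write_results(out$misloc, file.path(out_dir, "mislocalization.tsv"))
  } else {
    warning("mRNA stage skipped: no counts supplied")
    note("mRNA stage skipped: no counts supplied")
  }

  if (!is.null(reads) && !is.null(transcripts)) {
    ref <- build_backsplice_reference(transcripts, config$flank_len)
    note("circ stage: %d junctions from %d transcripts", nrow(ref),
         length(transcripts))
    write_junction_reference(ref, file.path(out_dir, "junctions.fa"),
                             file.path(out_dir, "junctions.tsv"))
    if (!is.list(reads)) reads <- list(sample1 = reads)
    unmapped <- lapply(reads, function(rd)
      partition_reads_by_linear_alignment(rd, transcripts,
                                          config$max_mismatch)$unmapped)
    note("unmapped reads per sample: %s",
         paste(vapply(unmapped, length, 0L), collapse = ","))
    jc <- count_junction_reads(unmapped, ref, config$min_anchor,
                               config$max_mismatch)
    write_results(data.frame(junction_id = rownames(jc$counts), jc$counts,
                             check.names = FALSE),
                  file.path(out_dir, "circ_counts.tsv"))
    out$circ <- list(reference = ref, counts = jc$counts,
                     ambiguous_discarded = jc$ambiguous_discarded)
    if (!is.null(circ_sample_info)) {
      linear <- lapply(reads, function(rd)
        tabulate_linear_counts(
          partition_reads_by_linear_alignment(rd, transcripts,
                                              config$max_mismatch)$assignment,
          transcripts))
      lin_mat <- do.call(cbind, linear)
      colnames(lin_mat) <- names(reads)
      info <- circ_sample_info[match(names(reads),
                                     circ_sample_info$sample_id), ]
      lin_ds <- count_dataset(lin_mat, info$fraction, info$condition)
      cde <- try(combined_circ_de(
        lin_ds, jc$counts, "fraction", c("synaptosome", "homogenate"),
        within = c(condition = "control"),
        circ_min_count = config$circ_min_count,
        circ_min_samples = config$circ_min_samples,
        dispersion_prior_df = config$dispersion_prior_df), silent = TRUE)
      if (inherits(cde, "try-error")) {
        note("circ DE skipped: %s", attr(cde, "condition")$message)
      } else {
        out$circ$de <- cde
        out$circ$switches <- detect_isoform_switches(cde, config$de_alpha)
        out$circ$span <- exon_span_summary(ref, jc$counts)
        note("circ DE: %d junctions pass (%d in >=%d samples)",
             nrow(cde), config$circ_min_count, config$circ_min_samples)
        write_results(cde, file.path(out_dir, "circ_de.tsv"))
      }
    }
  } else {
    warning("circ stage skipped: needs reads and transcripts")
    note("circ stage skipped: needs reads and transcripts")
  }

  if (!is.null(mirna_shortlist) && !is.null(mirna_background)) {
    out$mirna <- site_enrichment_test(mirna_shortlist, mirna_background,
                                      config$mirna_fdr_cutoff)
    note("miRNA stage: %d enriched of %d",
         sum(out$mirna$call == "enriched"), nrow(out$mirna))
    write_results(out$mirna, file.path(out_dir, "mirna_enrichment.tsv"))
  } else {
    warning("miRNA stage skipped: needs shortlist and background tables")
    note("miRNA stage skipped: needs shortlist and background tables")
  }

  writeLines(log, file.path(out_dir, "run_log.txt"))
  out$log <- log
  out
}
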