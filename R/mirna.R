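#' miRNA binding-site enrichment test
#'
#' For each miRNA, compares the fraction of all shortlist binding sites it
#' accounts for (`s_m / S`) with the same fraction in the transcriptome-wide
#' background (`b_m / B`). The log2 fold change is
#' `log2((s_m/S) / (b_m/B))`; significance is a chi-squared test on the
#' 2x2 table `[[s_m, S - s_m], [b_m, B - b_m]]` with 1 df (upper tail), and
#' Benjamini-Hochberg q-values. Zero cells get a +0.5 continuity offset for
#' the fold change only (flagged); the chi-squared statistic uses the raw
#' counts.
#'
#' The background is the full transcriptome-wide site index and by
#' convention includes the shortlist genes; set
#' `subtract_shortlist = TRUE` to test against the disjoint complement
#' instead.
#'
#' @param shortlist,background site tables: data frames with columns
#'   `mirna_id` and `sites` (non-negative integer totals per miRNA).
#' @param fdr_cutoff q-value threshold for the enrichment call.
#' @param yates apply the Yates continuity correction (off by default).
#' @param subtract_shortlist subtract shortlist counts from the background
#'   before testing.
#' @return Data frame with columns `mirna_id`, `sites_shortlist`,
#'   `total_shortlist`, `sites_background`, `total_background`, `log2fc`,
#'   `zero_offset` (logical), `chi2`, `p`, `q`, `call`
#'   (`enriched`/`deenriched`/`ns`).
#' @export
site_enrichment_test <- function(shortlist, background, fdr_cutoff = 0.05,
                                 yates = FALSE,
                                 subtract_shortlist = FALSE) {
  absent <- setdiff(shortlist$mirna_id, background$mirna_id)
  if (length(absent) > 0L)
    stop("shortlist miRNA(s) absent from background: ",
         paste(absent, collapse = ", "))
  s <- shortlist$sites
  b <- background$sites[match(shortlist$mirna_id, background$mirna_id)]
  if (subtract_shortlist) {
    if (any(b < s)) stop("background counts smaller than shortlist counts")
    b <- b - s
  }
  S <- sum(s); B <- sum(b)
  if (S <= 0 || B <= 0) stop("site totals must be positive")
  zero <- s == 0 | b == 0
  s_adj <- ifelse(zero, s + 0.5, s)
  b_adj <- ifelse(zero, b + 0.5, b)
  log2fc <- log2((s_adj / S) / (b_adj / B))
  chi2 <- chisq_2x2(s, S - s, b, B - b, yates = yates)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  call <- rep("ns", length(s))
  call[q < fdr_cutoff & log2fc > 0] <- "enriched"
  call[q < fdr_cutoff & log2fc < 0] <- "deenriched"
  data.frame(mirna_id = shortlist$mirna_id,
             sites_shortlist = s, total_shortlist = S,
             sites_background = b, total_background = B,
             log2fc = log2fc, zero_offset = zero,
             chi2 = chi2, p = p, q = q,
             call = factor(call, levels = c("enriched", "deenriched", "ns")),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Vectorized 2x2 chi-squared from expected counts; equals
# stats::chisq.test(matrix, correct = yates)$statistic cell for cell.
chisq_2x2 <- function(a, c, b, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  obs <- cbind(a, c, b, d)
  row1 <- a + c; row2 <- b + d
  col1 <- a + b; col2 <- c + d
  exp <- cbind(row1 * col1, row1 * col2, row2 * col1, row2 * col2) / n
  dev <- abs(obs - exp)
  if (yates) dev <- pmax(dev - 0.5, 0)
  out <- rowSums(dev^2 / exp)
  out[!is.finite(out)] <- 0       # degenerate margins carry no evidence
  unname(out)
}
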