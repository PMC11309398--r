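#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed exactly as the classical
#' median-of-ratios procedure: a pseudo-reference is the geometric mean of
#' each feature's counts across samples (features with any zero excluded),
#' and a sample's size factor is the median of its count-to-reference ratios.
#'
#' @param x a [count_dataset()] or a counts matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "CountDataset")) x$counts else as.matrix(x)
  lg <- log(counts)
  ref <- rowMeans(lg)               # -Inf for any feature containing a zero
  use <- is.finite(ref)
  if (!any(use))
    stop("no feature has nonzero counts in every sample; ",
         "supply size factors computed with a pseudo-reference fallback")
  ratios <- exp(lg[use, , drop = FALSE] - ref[use])
  sf <- apply(ratios, 2, median)
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factor")
  sf
}

#' Filter features by a minimum count in a minimum number of samples
#'
#' Keeps a feature iff at least `min_samples` samples have a count of at
#' least `min_count`; feature order is preserved. Defaults follow the mRNA
#' filter (ten counts in at least nine samples); circular RNA features use
#' (4, 5).
#'
#' @param ds a [count_dataset()].
#' @param min_count,min_samples integer thresholds (>= 1).
#' @return The filtered `CountDataset`.
#' @export
filter_features <- function(ds, min_count = 10, min_samples = 9) {
  stopifnot(min_count >= 1, min_samples >= 1)
  keep <- rowSums(ds$counts >= min_count) >= min_samples
  count_dataset(ds$counts[keep, , drop = FALSE],
                as.character(ds$fraction), as.character(ds$condition),
                ds$size_factors)
}

# Pooled within-group method-of-moments NB dispersion, moderated toward the
# across-gene median with prior df `prior_df`. The moderation keeps the Wald
# null near-normal at small replication, where raw per-gene moments are too
# noisy; prior_df = 0 gives the raw pooled estimate.
moment_dispersion <- function(yA, yB, prior_df = 8, floor = 1e-8) {
  nA <- ncol(yA); nB <- ncol(yB)
  mA <- rowMeans(yA); mB <- rowMeans(yB)
  vA <- apply(yA, 1, var); vB <- apply(yB, 1, var)
  aA <- (vA - mA) / mA^2
  aB <- (vB - mB) / mB^2
  aA[!is.finite(aA)] <- 0
  aB[!is.finite(aB)] <- 0
  a <- ((nA - 1) * aA + (nB - 1) * aB) / (nA + nB - 2)
  a <- pmax(a, floor)
  if (prior_df > 0 && length(a) > 1) {
    d <- nA + nB - 2
    a0 <- median(a)
    a <- pmax((d * a + prior_df * a0) / (d + prior_df), floor)
  }
  a
}

#' Two-group negative-binomial Wald test
#'
#' A deliberately small differential-expression engine: normalized counts
#' (count / size factor), group means, a moderated method-of-moments
#' negative-binomial dispersion, a delta-method standard error for the log2
#' fold change, a Wald statistic with two-sided normal p-values and
#' Benjamini-Hochberg q-values. The contrast is reported as log2(B over A).
#' Downstream mislocalization analysis only consumes (log2fc, se), so tables
#' from a full-featured DE tool can be substituted interchangeably.
#'
#' @param ds a [count_dataset()] or counts matrix.
#' @param groups character/factor of group labels, one per sample.
#' @param contrast length-2 character vector `c(B, A)`: fold changes are
#'   B over A.
#' @param size_factors optional; computed by [estimate_size_factors()] on
#'   `ds` when absent (dataset-supplied factors are used if present).
#' @param dispersion_prior_df prior df moderating the per-feature dispersion
#'   toward the across-feature median (0 disables moderation).
#' @return A data frame with columns `feature_id`, `base_mean`, `log2fc`,
#'   `se`, `wald`, `p`, `q`.
#' @export
two_group_de <- function(ds, groups, contrast, size_factors = NULL,
                         dispersion_prior_df = 8) {
  counts <- if (inherits(ds, "CountDataset")) ds$counts else as.matrix(ds)
  if (is.null(size_factors))
    size_factors <- if (inherits(ds, "CountDataset") &&
                        !is.null(ds$size_factors)) ds$size_factors
                    else estimate_size_factors(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups length must equal the sample count")
  B <- which(groups == contrast[1]); A <- which(groups == contrast[2])
  if (length(A) < 2 || length(B) < 2)
    stop("each contrast group needs at least 2 samples")
  y <- sweep(counts, 2, size_factors, "/")
  yA <- y[, A, drop = FALSE]; yB <- y[, B, drop = FALSE]
  muA <- rowMeans(yA); muB <- rowMeans(yB)
  alpha <- moment_dispersion(yA, yB, prior_df = dispersion_prior_df)
  cpseudo <- 0.5 / exp(mean(log(size_factors)))
  # difference of logs, not log of ratio: keeps contrast swap an exact
  # negation so p-values are bit-identical under (B,A) -> (A,B)
  log2fc <- log2(muB + cpseudo) - log2(muA + cpseudo)
  nA <- length(A); nB <- length(B)
  # Var of a group mean of normalized counts under NB(mu*sf, alpha)
  vA <- muA / nA^2 * sum(1 / size_factors[A]) + alpha * muA^2 / nA
  vB <- muB / nB^2 * sum(1 / size_factors[B]) + alpha * muB^2 / nB
  se <- sqrt(vB / ((muB + cpseudo) * log(2))^2 +
             vA / ((muA + cpseudo) * log(2))^2)
  se <- pmax(se, 1e-8)
  wald <- log2fc / se
  p <- 2 * pnorm(-abs(wald))
  zero <- muA == 0 & muB == 0      # degenerate guard: nothing observed
  log2fc[zero] <- 0; wald[zero] <- 0; p[zero] <- 1
  data.frame(feature_id = rownames(counts),
             base_mean = rowMeans(y),
             log2fc = log2fc, se = se, wald = wald, p = p,
             q = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap and sign concordance of two DE tables
#'
#' Counts features significant (`p < alpha`) in each table, their
#' intersection, and the percentage of the intersection with the same
#' log2 fold-change sign.
#'
#' @param deA,deB data frames as returned by [two_group_de()], sharing a
#'   feature-id namespace.
#' @param alpha raw p-value significance cutoff.
#' @return A list with `n_sig_a`, `n_sig_b`, `n_overlap`,
#'   `pct_concordant` (`NA` when the overlap is empty).
#' @export
overlap_concordance <- function(deA, deB, alpha = 0.05) {
  sigA <- deA$feature_id[deA$p < alpha]
  sigB <- deB$feature_id[deB$p < alpha]
  ov <- intersect(sigA, sigB)
  pct <- if (length(ov) == 0L) NA_real_ else {
    sA <- sign(deA$log2fc[match(ov, deA$feature_id)])
    sB <- sign(deB$log2fc[match(ov, deB$feature_id)])
    100 * mean(sA == sB)
  }
  list(n_sig_a = length(sigA), n_sig_b = length(sigB),
       n_overlap = length(ov), pct_concordant = pct)
}
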