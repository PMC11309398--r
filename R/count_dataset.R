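#' Count dataset with fraction and condition factors
#'
#' Container for a feature-by-sample table of non-negative integer counts
#' together with the two per-sample factors the fractionation design needs:
#' `fraction` (synaptosome or homogenate) and `condition` (case or control).
#'
#' @param counts integer matrix, features x samples, with unique row and
#'   column names.
#' @param fraction character/factor per sample, levels
#'   `c("homogenate", "synaptosome")`.
#' @param condition character/factor per sample, levels
#'   `c("control", "case")`.
#' @param size_factors optional positive per-sample normalization factors.
#' @return An object of class `CountDataset`: a list with elements `counts`,
#'   `fraction`, `condition`, `size_factors`.
#' @export
count_dataset <- function(counts, fraction, condition, size_factors = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("counts must carry feature and sample names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts))) stop("duplicate sample id")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  n <- ncol(counts)
  if (length(fraction) != n || length(condition) != n)
    stop("fraction/condition length must equal the sample count")
  fraction <- factor(as.character(fraction),
                     levels = c("homogenate", "synaptosome"))
  condition <- factor(as.character(condition), levels = c("control", "case"))
  if (anyNA(fraction))
    stop("sample ", colnames(counts)[which(is.na(fraction))[1]],
         ": fraction must be 'homogenate' or 'synaptosome'")
  if (anyNA(condition))
    stop("sample ", colnames(counts)[which(is.na(condition))[1]],
         ": condition must be 'control' or 'case'")
  if (!is.null(size_factors)) {
    if (length(size_factors) != n || any(!is.finite(size_factors)) ||
        any(size_factors <= 0))
      stop("size_factors must be positive and one per sample")
  }
  structure(list(counts = counts, fraction = fraction, condition = condition,
                 size_factors = size_factors),
            class = "CountDataset")
}

#' @export
print.CountDataset <- function(x, ...) {
  cat(sprintf("CountDataset: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(fraction = x$fraction, condition = x$condition))
  invisible(x)
}

#' @export
dim.CountDataset <- function(x) dim(x$counts)

#' Subset a CountDataset by samples
#'
#' @param ds a [count_dataset()].
#' @param samples logical/integer/character sample index.
#' @return A `CountDataset` restricted to the chosen samples.
#' @export
subset_samples <- function(ds, samples) {
  count_dataset(ds$counts[, samples, drop = FALSE],
                as.character(ds$fraction)[samples],
                as.character(ds$condition)[samples],
                ds$size_factors[samples])
}

#' Read and write count datasets as TSV
#'
#' Counts are stored as a TSV with a `feature_id` column followed by one
#' column per sample; sample metadata is a 3-column TSV
#' (`sample_id`, `fraction`, `condition`). A write-then-read round trip
#' reproduces the dataset exactly.
#'
#' @param ds a [count_dataset()].
#' @param counts_file,metadata_file file paths.
#' @return `write_count_dataset()` returns the paths invisibly;
#'   `read_count_dataset()` returns a `CountDataset`.
#' @export
write_count_dataset <- function(ds, counts_file, metadata_file) {
  df <- data.frame(feature_id = rownames(ds$counts), ds$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = colnames(ds$counts),
                   fraction = as.character(ds$fraction),
                   condition = as.character(ds$condition),
                   stringsAsFactors = FALSE)
  write.table(md, metadata_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_file, metadata_file))
}

#' @rdname write_count_dataset
#' @export
read_count_dataset <- function(counts_file, metadata_file) {
  df <- read.delim(counts_file, check.names = FALSE,
                   colClasses = "character")
  if (names(df)[1] != "feature_id") stop("first column must be feature_id")
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature id: ", df$feature_id[duplicated(df$feature_id)][1])
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer count at feature '%s', sample '%s'",
                 df$feature_id[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  rownames(num) <- df$feature_id
  md <- read.delim(metadata_file, stringsAsFactors = FALSE)
  need <- c("sample_id", "fraction", "condition")
  if (!all(need %in% names(md)))
    stop("metadata must have columns sample_id, fraction, condition")
  if (!setequal(md$sample_id, colnames(num)))
    stop("metadata samples do not match count table samples")
  md <- md[match(colnames(num), md$sample_id), ]
  miss <- md$sample_id[is.na(md$condition) | md$condition == "" |
                         is.na(md$fraction) | md$fraction == ""]
  if (length(miss) > 0L)
    stop("sample missing fraction/condition: ", paste(miss, collapse = ", "))
  count_dataset(num, md$fraction, md$condition)
}

#' Read and write result tables as TSV
#'
#' Floating-point columns are written with 15 significant digits so that a
#' round trip is numerically faithful.
#'
#' @param x a data frame.
#' @param file file path.
#' @return `write_results()` returns `file` invisibly; `read_results()` the
#'   data frame.
#' @export
write_results <- function(x, file) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- formatC(y[[j]], digits = 15,
                                             format = "g")
  }
  write.table(y, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_results
#' @export
read_results <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}
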