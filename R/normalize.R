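# Count normalization: median-of-ratios size factors and a log2 transform
# for gene/peak counts, plus the bespoke per-kilobase / per-million
# normalization used for retrotransposon family counts.

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference features of
#' `count / geometric mean across samples`, using only features with
#' strictly positive counts in every sample (so the geometric mean is
#' finite). Two identical samples get identical factors.
#'
#' @param counts non-negative count matrix, features x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stopf(paste("no feature has positive counts in every sample;",
                "add a pseudo-count or filter samples"))
  logc <- log(counts[ref, , drop = FALSE])
  logmeans <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(median(col - logmeans)))
  names(sf) <- colnames(counts)
  sf
}

#' Log2 normalization with size factors
#'
#' `value = log2(count / factor + pseudo)`. With the default pseudo-count
#' of 1 the values are non-negative and a zero count maps to 0. This is
#' the pipeline's normalized scale; downstream rules (expressed > 0,
#' fold-change > 2) are expressed on it.
#'
#' @param counts count matrix, features x samples.
#' @param size_factors named factors covering all samples; computed with
#'   [medianRatioSizeFactors()] when NULL.
#' @param pseudo positive pseudo-count (default 1).
#' @return numeric matrix of log2-scale values with attributes `method`,
#'   `sizeFactors` and `pseudo`.
#' @export
normalizeLog <- function(counts, size_factors = NULL, pseudo = 1) {
  if (pseudo <= 0) stopf("'pseudo' must be > 0")
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- medianRatioSizeFactors(counts)
  if (is.null(names(size_factors)) && length(size_factors) == ncol(counts))
    names(size_factors) <- colnames(counts)
  if (!all(colnames(counts) %in% names(size_factors)))
    stopf("size factors must cover every sample")
  sf <- size_factors[colnames(counts)]
  if (any(sf <= 0)) stopf("size factors must be positive")
  out <- log2(sweep(counts, 2, sf, "/") + pseudo)
  attr(out, "method") <- "log2-median-of-ratios"
  attr(out, "sizeFactors") <- sf
  attr(out, "pseudo") <- pseudo
  out
}

#' Repeat-family normalization (per merged kb, per million repeat reads)
#'
#' `value = log2( count / (length_kb * total_repeat_reads_millions) + 1 )`,
#' where `length_kb` is the merged length of the family's instance union in
#' kilobases and the totals are per-sample sums over all families. Note the
#' formula is a rate: doubling a family's count together with the sample
#' total changes the value.
#'
#' @param family_counts family x sample count matrix.
#' @param merged_length_bp named vector of merged union lengths in bp, one
#'   per family (row).
#' @return numeric matrix on the log2 scale with attribute `method`.
#' @export
normalizeRepeats <- function(family_counts, merged_length_bp) {
  m <- as.matrix(family_counts)
  if (is.null(rownames(m))) stopf("family_counts needs family rownames")
  if (!all(rownames(m) %in% names(merged_length_bp)))
    stopf("merged_length_bp missing families: %s",
          paste(setdiff(rownames(m), names(merged_length_bp)), collapse = ", "))
  len_kb <- merged_length_bp[rownames(m)] / 1000
  if (any(len_kb <= 0)) stopf("merged lengths must be > 0")
  totals_m <- colSums(m) / 1e6
  if (any(totals_m <= 0))
    stopf("every sample needs > 0 total repeat reads")
  rate <- sweep(sweep(m, 1, len_kb, "/"), 2, totals_m, "/")
  out <- log2(rate + 1)
  attr(out, "method") <- "log2-per-kb-per-million"
  out
}
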