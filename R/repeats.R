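# Family-level retrotransposon quantification and Shannon-entropy stage
# specificity. Low entropy of a family's stage-probability profile marks
# restriction to few stages; Q_s = H - log2(p_s) localizes the stage.

#' Count fragments per repeat family
#'
#' Instances are merged into a per-family union first (consistent with the
#' merged-length normalization); a fragment counts once per family when it
#' overlaps the union, even if it spans two merged-adjacent instances.
#'
#' @param fragments named list of GRanges, one per sample.
#' @param instances repeat GRanges with `family` and `repclass` metadata
#'   columns (see [readRepeatTable()]).
#' @return list: `counts` (family x sample integer matrix), `summary`
#'   (DataFrame: family, repclass, n_instances, merged_length_bp) and
#'   `unions` (named list of merged GRanges per family).
#' @export
countRepeatFragments <- function(fragments, instances) {
  assert_granges(instances)
  if (is.null(mcols(instances)$family))
    stopf("instances need a 'family' metadata column")
  fams <- sort(unique(mcols(instances)$family))
  unions <- lapply(fams, function(f)
    mergeIntervals(instances[mcols(instances)$family == f]))
  names(unions) <- fams
  counts <- vapply(fragments, function(fr)
    vapply(unions, function(u)
      sum(overlapsAny(fr, u, ignore.strand = TRUE)), integer(1)),
    integer(length(fams)))
  counts <- matrix(counts, nrow = length(fams),
                   dimnames = list(fams, names(fragments)))
  repclass <- vapply(fams, function(f)
    mcols(instances)$repclass[match(f, mcols(instances)$family)], "")
  summary <- DataFrame(
    family = fams,
    repclass = unname(repclass),
    n_instances = unname(vapply(fams, function(f)
      sum(mcols(instances)$family == f), integer(1))),
    merged_length_bp = unname(vapply(unions, function(u)
      sum(width(u)), numeric(1))))
  list(counts = counts, summary = summary, unions = unions)
}

#' Shannon entropy of a probability vector (bits)
#'
#' `H = -sum(p * log2(p))` with the convention `0 * log(0) = 0`.
#'
#' @param p non-negative vector summing to 1 (tolerance 1e-9).
#' @return entropy in bits.
#' @export
shannonEntropy <- function(p) {
  if (any(p < 0)) stopf("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stopf("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz])) + 0   # + 0 normalizes IEEE negative zero
}

#' Stage-specificity scores from normalized stage profiles
#'
#' Each family's stage means are converted to a probability vector
#' `p_s = mean_s / sum(means)`; the Shannon entropy `H` measures how
#' restricted the family is (0 = one stage only, log2(T) = uniform), the
#' per-stage score `Q_s = H - log2(p_s)` is minimal at the family's
#' characteristic stage, and families are ranked by ascending entropy
#' (most stage-specific first, deterministic tie-break by family name).
#' All-zero profiles are excluded with a warning.
#'
#' @param values normalized matrix (e.g. from [normalizeRepeats()]),
#'   families x samples; must be non-negative.
#' @param design a [StageDesign-class].
#' @return DataFrame ordered by rank with `family`, `entropy` (bits),
#'   `assigned_stage` (argmin Q), `rank`, and matrix columns `p` and `Q`.
#' @export
stageSpecificity <- function(values, design) {
  if (any(values < 0)) stopf("normalized values must be non-negative")
  sm <- stageMeans(values, design)
  zero <- rowSums(sm) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero profile(s) excluded from specificity")
    sm <- sm[!zero, , drop = FALSE]
  }
  if (nrow(sm) == 0L) stopf("no usable profiles")
  p <- sm / rowSums(sm)
  H <- apply(p, 1, shannonEntropy)
  Q <- H - log2(p)                       # Inf where p_s = 0; argmin unaffected
  assigned <- colnames(p)[apply(Q, 1, which.min)]
  ord <- order(H, rownames(p))
  out <- DataFrame(family = rownames(p)[ord], entropy = unname(H[ord]),
                   assigned_stage = assigned[ord],
                   rank = seq_along(ord))
  out$p <- p[ord, , drop = FALSE]
  out$Q <- Q[ord, , drop = FALSE]
  out
}

#' Top stage-specific families per stage
#'
#' For every stage, the `top_n` lowest-entropy families assigned to it,
#' with their stage-mean profiles for heat-map export.
#'
#' @param values normalized matrix, families x samples.
#' @param design a [StageDesign-class].
#' @param top_n families to keep per stage (>= 1).
#' @return DataFrame with `stage`, `family`, `entropy`, `rank_in_stage`
#'   and a matrix column `profile` of stage means.
#' @export
rankStageSpecific <- function(values, design, top_n = 5L) {
  if (top_n < 1L) stopf("'top_n' must be >= 1")
  if (nrow(values) < 2L) stopf("need >= 2 families")
  spec <- stageSpecificity(values, design)
  sm <- stageMeans(values, design)
  pieces <- lapply(stages(design), function(s) {
    sub <- spec[spec$assigned_stage == s, ]
    sub <- head(sub, top_n)              # spec is already entropy-ordered
    if (nrow(sub) == 0L) return(NULL)
    DataFrame(stage = s, family = sub$family, entropy = sub$entropy,
              rank_in_stage = seq_len(nrow(sub)))
  })
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  out$profile <- sm[out$family, , drop = FALSE]
  out
}
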