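# Stage-level peak processing: replicate consensus with sex-chromosome
# exclusion, the unified peak list across stages, fragment quantification,
# TSS-distance location classes, stage-gained regions, TSS enrichment
# profiles, promoter CpG classes and the 2-Mb gene-density correlation.

#' Replicate-consensus peaks for one stage
#'
#' Only chromatin regions supported by every biological replicate are kept:
#' the union of all replicate peaks is merged, and a merged region survives
#' iff it contains at least one position covered by a peak in every
#' replicate (>= 1 bp mutual overlap); the surviving region spans the full
#' union of the overlapping group. Peaks on excluded chromosomes (sex
#' chromosomes by default) are dropped first.
#'
#' @param rep_sets list (length >= 2) of GRanges, one per replicate.
#' @param excluded_chroms chromosome names to drop (default chrX/chrY).
#' @param stage optional stage label stored in `metadata`-style mcols.
#' @return GRanges of consensus regions.
#' @export
consensusPeaks <- function(rep_sets, excluded_chroms = c("chrX", "chrY"),
                           stage = NULL) {
  if (!is.list(rep_sets) || length(rep_sets) < 2L)
    stopf("need >= 2 replicate peak sets")
  reps <- lapply(rep_sets, function(gr) {
    assert_granges(gr)
    granges(gr[!as.character(seqnames(gr)) %in% excluded_chroms])
  })
  union_merged <- mergeIntervals(do.call(c, unname(reps)))
  core <- Reduce(function(a, b) GenomicRanges::intersect(a, b,
                                                         ignore.strand = TRUE),
                 lapply(reps, reduce))
  out <- union_merged[overlapsAny(union_merged, core, ignore.strand = TRUE)]
  if (!is.null(stage)) mcols(out)$stage <- stage
  out
}

#' Unified peak list across stages
#'
#' Merges all stages' consensus peaks into disjoint unified peaks and flags,
#' for each unified peak and each stage, whether the stage's consensus
#' overlaps it.
#'
#' @param per_stage named list of consensus GRanges, one per stage.
#' @return GRanges named `peak_00001`, ... with one logical presence
#'   metadata column per stage.
#' @export
unifyPeaks <- function(per_stage) {
  if (length(per_stage) < 1L) stopf("need >= 1 stage")
  if (is.null(names(per_stage))) stopf("per_stage must be a named list")
  unified <- mergeIntervals(do.call(c, unname(lapply(per_stage, granges))))
  pres <- vapply(per_stage, function(gr)
    overlapsAny(unified, gr, ignore.strand = TRUE),
    logical(length(unified)))
  pres <- matrix(pres, nrow = length(unified),
                 dimnames = list(NULL, names(per_stage)))
  mcols(unified) <- DataFrame(pres, check.names = FALSE)
  names(unified) <- sprintf("peak_%05d", seq_along(unified))
  unified
}

#' Count fragments per unified peak
#'
#' A fragment is counted for a peak when they share >= 1 bp; a fragment
#' straddling two adjacent peaks is counted in both.
#'
#' @param fragments named list of GRanges, one per sample.
#' @param peaks unified peak GRanges (names become feature ids).
#' @return integer matrix, peaks x samples.
#' @export
quantifyPeaks <- function(fragments, peaks) {
  assert_granges(peaks)
  if (is.null(names(fragments))) stopf("fragments must be a named list")
  m <- vapply(fragments, function(fr)
    countOverlaps(peaks, fr, ignore.strand = TRUE),
    integer(length(peaks)))
  m <- matrix(m, nrow = length(peaks),
              dimnames = list(names(peaks), names(fragments)))
  m
}

#' Classify peaks by distance to the nearest TSS
#'
#' Distance is the minimum over all TSSs of the gap between the peak's
#' closest edge and the TSS (0 when a TSS lies inside the peak). Classes:
#' `promoter_proximal` (< 1 kb), `intermediate` (1-5 kb), `distal`
#' (> 5 kb). The signed distance is positive when the peak lies downstream
#' of the nearest TSS in gene orientation, negative upstream.
#'
#' @param peaks GRanges.
#' @param genes stranded gene GRanges (>= 1 gene).
#' @return DataFrame with `peak_id`, `distance` (bp, unsigned),
#'   `signed_distance`, `nearest_gene` and `class`.
#' @export
classifyPeakLocation <- function(peaks, genes) {
  assert_granges(peaks); assert_granges(genes)
  if (length(genes) == 0L) stopf("need >= 1 gene")
  tss <- tssOf(genes)
  h <- GenomicRanges::distanceToNearest(peaks, tss, ignore.strand = TRUE)
  if (length(h) < length(peaks))
    stopf("some peaks lie on chromosomes without genes")
  d <- mcols(h)$distance
  ti <- subjectHits(h)
  tpos <- start(tss)[ti]
  pk <- peaks[queryHits(h)]
  right_of <- start(pk) > tpos        # peak entirely right of the TSS
  inside <- d == 0
  minus <- as.character(strand(tss))[ti] == "-"
  sgn <- ifelse(inside, 0, ifelse(xor(right_of, minus), 1, -1))
  cls <- ifelse(d < 1000, "promoter_proximal",
                ifelse(d <= 5000, "intermediate", "distal"))
  DataFrame(peak_id = if (is.null(names(pk))) as.character(queryHits(h))
                      else names(pk),
            distance = d, signed_distance = as.integer(sgn * d),
            nearest_gene = if (is.null(names(tss))) as.character(ti)
                           else names(tss)[ti],
            class = cls)
}

#' Stage-gained accessible regions
#'
#' Assigns each unified peak to the FIRST stage of `stage_order` at which
#' it is present, requiring absence at all earlier stages of that order;
#' each peak lands in at most one stage, so the per-stage sets are disjoint
#' and together cover every peak present somewhere in the order.
#'
#' @param unified unified peak GRanges from [unifyPeaks()] with logical
#'   presence columns.
#' @param stage_order ordered character vector of stages to analyze (must
#'   be presence columns of `unified`).
#' @return named list, stage -> GRanges of regions gained at that stage.
#' @export
gainedRegions <- function(unified, stage_order) {
  assert_granges(unified)
  pres <- as.matrix(mcols(unified)[, stage_order, drop = FALSE])
  if (!is.logical(pres)) stopf("presence columns must be logical")
  first <- apply(pres, 1, function(p) {
    w <- which(p)
    if (length(w)) w[1] else NA_integer_
  })
  out <- lapply(seq_along(stage_order), function(i) unified[!is.na(first) & first == i])
  names(out) <- stage_order
  out
}

#' TSS enrichment profile
#'
#' Mean fragment coverage in fixed-width bins across TSS-centred windows,
#' oriented so upstream is always on the left (minus-strand windows are
#' reversed), and normalized by the mean of the outermost 10% of bins so a
#' flat background sits at 1.
#'
#' @param fragments GRanges of fragments for one sample.
#' @param genes stranded gene GRanges.
#' @param flank half-window size in bp (default 2000).
#' @param bin bin width in bp (default 50); `2 * flank` must be a multiple.
#' @param groups optional named factor/character (gene_id -> group, e.g. a
#'   promoter CpG class); profiles are then computed per group.
#' @return list with `position` (bin centre offsets from the TSS) and
#'   `enrichment` (numeric vector, or a bins x groups matrix).
#' @export
tssProfile <- function(fragments, genes, flank = 2000L, bin = 50L,
                       groups = NULL) {
  assert_granges(fragments); assert_granges(genes)
  if (length(genes) == 0L || length(fragments) == 0L)
    stopf("need >= 1 gene and >= 1 fragment")
  if ((2L * flank) %% bin != 0L) stopf("2*flank must be a multiple of bin")
  nbins <- as.integer(2L * flank / bin)
  tss <- tssOf(genes)
  win_start <- start(tss) - flank            # window = [tss-flank, tss+flank)
  windows <- GRanges(seqnames(tss), IRanges(pmax(win_start, 1L),
                                            win_start + 2L * flank - 1L))
  profile_for <- function(idx) {
    counts <- numeric(nbins)
    h <- findOverlaps(fragments, windows[idx], ignore.strand = TRUE)
    if (length(h)) {
      wi <- idx[subjectHits(h)]
      fs <- start(fragments)[queryHits(h)] - win_start[wi]
      fe <- end(fragments)[queryHits(h)] - win_start[wi]
      fs <- pmax(fs, 0L); fe <- pmin(fe, 2L * flank - 1L)
      minus <- as.character(strand(tss))[wi] == "-"
      b1 <- ifelse(minus, (2L * flank - 1L - fe), fs) %/% bin
      b2 <- ifelse(minus, (2L * flank - 1L - fs), fe) %/% bin
      for (k in seq_along(b1)) {
        rng <- (b1[k]:b2[k]) + 1L
        counts[rng] <- counts[rng] + 1
      }
    }
    counts / length(idx)
  }
  k <- max(1L, floor(nbins * 0.05))          # outer 10% of bins, split
  normalize <- function(cov) {
    base <- mean(cov[c(seq_len(k), nbins - seq_len(k) + 1L)])
    if (base <= 0)
      stopf("flank baseline is zero; enlarge 'flank' or add fragments")
    cov / base
  }
  position <- (seq_len(nbins) - 0.5) * bin - flank
  if (is.null(groups)) {
    return(list(position = position,
                enrichment = normalize(profile_for(seq_along(tss)))))
  }
  gid <- names(genes)
  if (is.null(gid)) stopf("grouped profiles need named genes")
  grp <- groups[gid]
  lev <- sort(unique(as.character(grp[!is.na(grp)])))
  prof <- vapply(lev, function(g) normalize(profile_for(which(grp == g))),
                 numeric(nbins))
  list(position = position, enrichment = prof)
}

#' Promoter CpG classes (HCP / ICP / LCP)
#'
#' Computes, per promoter sequence (+/- 500 bp of the TSS), either the CpG
#' observed/expected ratio `(#CG * L) / (#C * #G)` (default) or the raw G+C
#' fraction, and classes promoters with the conventional cutoffs:
#' HCP ratio >= 0.75, ICP 0.25 <= ratio < 0.75, LCP ratio < 0.25.
#' N bases are excluded from all counts and from L.
#'
#' @param promoter_seqs named [Biostrings::DNAStringSet] keyed by gene id,
#'   ACGTN alphabet, length >= 200 bp.
#' @param mode `"cpg_oe"` (default) or `"gc_fraction"`.
#' @return DataFrame with `gene_id`, `ratio` and `class`.
#' @export
classifyPromoters <- function(promoter_seqs, mode = c("cpg_oe", "gc_fraction")) {
  mode <- match.arg(mode)
  if (!is(promoter_seqs, "DNAStringSet"))
    promoter_seqs <- DNAStringSet(promoter_seqs)
  widths <- width(promoter_seqs)
  if (any(widths < 200L)) stopf("promoter sequences must be >= 200 bp")
  lf <- letterFrequency(promoter_seqs, c("A", "C", "G", "T", "N"))
  if (any(rowSums(lf) != widths))
    stopf("promoter sequences must use the ACGTN alphabet only")
  L <- widths - lf[, "N"]
  if (any(L == 0L)) stopf("promoter sequence of only N bases")
  ratio <- if (mode == "gc_fraction") {
    (lf[, "C"] + lf[, "G"]) / L
  } else {
    cg <- dinucleotideFrequency(promoter_seqs)[, "CG"]
    cxg <- lf[, "C"] * lf[, "G"]
    ifelse(cxg == 0, 0, cg * L / cxg)
  }
  cls <- ifelse(ratio >= 0.75, "HCP", ifelse(ratio >= 0.25, "ICP", "LCP"))
  DataFrame(gene_id = names(promoter_seqs), ratio = unname(ratio),
            class = unname(cls))
}

#' Gene-density correlation over genome windows
#'
#' Bins the genome into fixed windows (2 Mb by default; the last partial
#' window of each chromosome is kept and its density uses the actual
#' width), counts genes per window by TSS, computes per-sample fragment
#' density (fragments per Mb per million mapped), and reports Pearson and
#' Spearman correlations of density against gene count across windows.
#'
#' @param fragments named list of GRanges, one per sample.
#' @param genes gene GRanges.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param window window size in bp (default 2e6).
#' @return list with `windows` (DataFrame: chrom, start, end, gene_count,
#'   one density column per sample) and `correlations` (DataFrame: sample,
#'   pearson, spearman).
#' @export
geneDensityCorrelation <- function(fragments, genes, genome, window = 2e6) {
  assert_granges(genes)
  if (is.null(names(genome))) stopf("'genome' must be named chrom lengths")
  starts <- lapply(names(genome), function(chr)
    seq(1, genome[[chr]], by = window))
  chr <- rep(names(genome), lengths(starts))
  s <- unlist(starts)
  windows <- GRanges(factor(chr, levels = names(genome)),
                     IRanges(s, pmin(s + window - 1, genome[chr])))
  if (length(windows) < 3L) stopf("need >= 3 windows; shrink 'window'")
  gene_count <- countOverlaps(windows, tssOf(genes), ignore.strand = TRUE)
  wbp <- width(windows)
  dens <- vapply(fragments, function(fr) {
    n <- countOverlaps(windows, fr, ignore.strand = TRUE)
    (n / (wbp / 1e6)) / (length(fr) / 1e6)
  }, numeric(length(windows)))
  dens <- matrix(dens, nrow = length(windows),
                 dimnames = list(NULL, names(fragments)))
  corr <- DataFrame(
    sample = colnames(dens),
    pearson = apply(dens, 2, cor, y = gene_count, method = "pearson"),
    spearman = apply(dens, 2, cor, y = gene_count, method = "spearman"))
  wdf <- DataFrame(chrom = as.character(seqnames(windows)),
                   start = start(windows) - 1L, end = end(windows),
                   gene_count = gene_count)
  for (s in colnames(dens)) wdf[[paste0("density_", s)]] <- dens[, s]
  list(windows = wdf, correlations = corr)
}
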