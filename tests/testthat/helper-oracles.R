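# Independent brute-force oracles and fixture builders. The oracles are
# deliberately naive (all-pairs scans, per-base unions) so they share no
# code path with the package's interval engine.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

gr <- function(chrom, start1, end1 = NULL, width = NULL, ...) {
  if (is.null(end1)) GRanges(chrom, IRanges(start1, width = width), ...)
  else GRanges(chrom, IRanges(start1, end1), ...)
}

# All-pairs overlap oracle: every (i, j) with >= 1 shared bp, with the
# shared width, computed by direct interval arithmetic.
brute_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
    ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
    if (ov >= 1L) out <- rbind(out, c(i, j, ov))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 3)
  colnames(out) <- c("a", "b", "overlap")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Per-base boolean union oracle: total covered bp on a small chromosome.
brute_union_bp <- function(a, chrom_len) {
  covered <- rep(FALSE, chrom_len)
  for (i in seq_along(a)) covered[start(a)[i]:end(a)[i]] <- TRUE
  sum(covered)
}

# All-pairs fragment-in-peak counting oracle.
brute_counts <- function(peaks, fragments) {
  vapply(seq_along(peaks), function(i)
    sum(as.character(seqnames(fragments)) ==
          as.character(seqnames(peaks))[i] &
        start(fragments) <= end(peaks)[i] &
        end(fragments) >= start(peaks)[i]), integer(1))
}

random_granges <- function(n, chroms = c("chr1", "chr2", "chr3"),
                           max_pos = 1e5, max_width = 500) {
  s <- sample.int(max_pos, n, replace = TRUE)
  gr(sample(chroms, n, replace = TRUE), s,
     s + sample.int(max_width, n, replace = TRUE))
}

# All permutations of 1..n (n small), for confusion-matrix label matching.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# Best achievable agreement between predicted and true labels over all
# label permutations (exhaustive Hungarian-style matching for small k).
best_label_agreement <- function(pred, truth, k) {
  conf <- table(factor(pred, levels = seq_len(k)),
                factor(truth, levels = seq_len(k)))
  best <- 0
  for (p in all_perms(k)) {
    hit <- sum(conf[cbind(p, seq_len(k))])
    if (hit > best) best <- hit
  }
  best / length(truth)
}

# Promoter sequence with an exact CpG observed/expected ratio: k "CGA"
# blocks then isolated C and G blocks, padded with A to `L`. With
# C = G = 200 and L = 1000, ratio = k * L / (C * G) = k / 40.
seq_with_cpg_ratio <- function(k, L = 1000L, cg_each = 200L) {
  body <- paste0(strrep("CGA", k), strrep("CA", cg_each - k),
                 strrep("GA", cg_each - k))
  paste0(body, strrep("A", L - nchar(body)))
}

# A small StageDesign reused by expression-level tests.
tiny_design <- function(stages = c("oocyte", "2cell", "4cell", "8cell",
                                   "morula")) {
  StageDesign(stages = stages, replicates = 2L)
}

# One shared default-scale simulation per test run (built lazily: several
# acceptance checks reuse it rather than regenerate).
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    d <- StageDesign()
    g <- simulateGenome(d, seed = seed)
    s <- simulateStageData(g, d, seed = seed)
    .sim_cache[[key]] <- list(design = d, genome = g, data = s)
  }
  .sim_cache[[key]]
}

# Stage-level peak processing of the shared simulation, computed once.
default_peaks <- function(seed = 101L) {
  key <- paste0("p", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- default_sim(seed)
    cons <- lapply(stages(sim$design), function(s)
      consensusPeaks(sim$data$peak_reps[[s]], stage = s))
    names(cons) <- stages(sim$design)
    unified <- unifyPeaks(cons)
    gained <- gainedRegions(unified, c("zygote", "2cell", "4cell", "8cell",
                                       "morula", "ICM", "TE"))
    .sim_cache[[key]] <- list(consensus = cons, unified = unified,
                              gained = gained)
  }
  .sim_cache[[key]]
}

# Scaled-down simulation config for fast structural tests.
small_config <- function() {
  list(genome = c(chr1 = 20e6, chr2 = 20e6, chrX = 8e6),
       n_genes = 300L, n_ega = 80L, n_maternal = 80L,
       n_constitutive = 40L, n_repeat_families = 10L,
       instances_per_family = 30L, n_gained_per_stage = 40L,
       n_sperm_peaks = 80L, n_oocyte_peaks = 20L, n_chrx_peaks = 10L,
       n_constitutive_peaks = 60L, n_background_fragments = 4000L)
}
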