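# EGA gene calling, peak-to-gene assignment with promoter/distal roles,
# per-cluster accessibility decomposition, and ChIP binding-site
# integration statistics.

CLEAVAGE_STAGES <- c("2cell", "4cell", "8cell", "morula")

#' Call embryonic genome activation (EGA) genes
#'
#' A gene is an EGA gene when BOTH hold on replicate-averaged normalized
#' expression: (1) expressed (stage mean > `expressed_threshold`) in at
#' least one of the 2-cell to morula stages; (2) more than 2-fold above
#' the oocyte — by default a strict log2 difference > 1 between the
#' maximal cleavage-stage mean and the oocyte mean (`log_diff`), or on
#' de-logged counts with `linear_ratio`
#' (`2^max - 1 > 2 * (2^oocyte - 1)`).
#'
#' @param values normalized matrix (log2 scale), genes x samples.
#' @param design a [StageDesign-class] containing `oocyte` and the
#'   cleavage stages.
#' @param fc_mode `"log_diff"` (default) or `"linear_ratio"`.
#' @param expressed_threshold expressed cutoff on the normalized scale
#'   (default 0).
#' @param cleavage_stages stages forming the EGA window.
#' @return DataFrame per gene: `gene_id`, `oocyte`, `max_cleavage`,
#'   `log2_fc`, `expressed`, `fc_pass`, `ega`; the called gene ids are in
#'   attribute `ega_genes`.
#' @export
callEgaGenes <- function(values, design,
                         fc_mode = c("log_diff", "linear_ratio"),
                         expressed_threshold = 0,
                         cleavage_stages = CLEAVAGE_STAGES) {
  fc_mode <- match.arg(fc_mode)
  need <- c("oocyte", cleavage_stages)
  miss <- setdiff(need, stages(design))
  if (length(miss)) stopf("design is missing stage(s): %s",
                          paste(miss, collapse = ", "))
  sm <- stageMeans(values, design)
  ooc <- sm[, "oocyte"]
  clv <- sm[, cleavage_stages, drop = FALSE]
  mx <- apply(clv, 1, max)
  expressed <- apply(clv, 1, function(p) any(p > expressed_threshold))
  fc_pass <- if (fc_mode == "log_diff") {
    (mx - ooc) > 1
  } else {
    (2^mx - 1) > 2 * (2^ooc - 1)
  }
  ega <- expressed & fc_pass
  out <- DataFrame(gene_id = rownames(sm), oocyte = unname(ooc),
                   max_cleavage = unname(mx), log2_fc = unname(mx - ooc),
                   expressed = unname(expressed), fc_pass = unname(fc_pass),
                   ega = unname(ega))
  attr(out, "ega_genes") <- rownames(sm)[ega]
  out
}

#' Assign peaks to genes within a flanking window
#'
#' A peak links to a gene when it overlaps the gene body extended by
#' `flank` bp on both sides (default 10 kb); with `anchor = "tss"` the
#' window is TSS +/- `flank` instead. One peak may link to several genes.
#' Each link carries the peak's distance to THAT gene's TSS and a role:
#' `promoter` (< 1 kb), `distal` (> 5 kb) or `other` (1-5 kb).
#'
#' @param peaks GRanges (named).
#' @param genes stranded gene GRanges (named).
#' @param flank window extension in bp (default 10000).
#' @param anchor `"body"` (default) or `"tss"`.
#' @return DataFrame with `peak_id`, `gene_id`, `tss_distance`, `side`
#'   (upstream/inside/downstream in gene orientation) and `role`.
#' @export
assignPeaksToGenes <- function(peaks, genes, flank = 10000L,
                               anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  assert_granges(peaks); assert_granges(genes)
  if (flank < 0) stopf("'flank' must be >= 0")
  base <- if (anchor == "body") granges(genes) else granges(tssOf(genes))
  win <- suppressWarnings(GenomicRanges::trim(
    resize(base, width(base) + 2L * flank, fix = "center")))
  h <- findOverlaps(peaks, win, ignore.strand = TRUE)
  pi <- queryHits(h); gi <- subjectHits(h)
  tss <- tssOf(genes)
  tpos <- start(tss)[gi]
  ps <- start(peaks)[pi]; pe <- end(peaks)[pi]
  inside <- tpos >= ps & tpos <= pe
  d <- ifelse(inside, 0L, pmin(abs(ps - tpos), abs(pe - tpos)))
  right_of <- ps > tpos
  minus <- as.character(strand(genes))[gi] == "-"
  side <- ifelse(inside, "inside",
                 ifelse(xor(right_of, minus), "downstream", "upstream"))
  role <- ifelse(d < 1000, "promoter", ifelse(d > 5000, "distal", "other"))
  DataFrame(peak_id = if (is.null(names(peaks))) as.character(pi)
                      else names(peaks)[pi],
            gene_id = if (is.null(names(genes))) as.character(gi)
                      else names(genes)[gi],
            tss_distance = d, side = side, role = role)
}

#' Mean promoter and distal accessibility per expression cluster
#'
#' For each expression cluster and each stage, the mean standardized
#' accessibility over all promoter-role peak links of the cluster's member
#' genes, and separately over all distal-role links. Clusters with no
#' linked peaks of a role yield NA (missing), never zero.
#'
#' @param assignments named integer vector, gene_id -> cluster (NA =
#'   unassigned), e.g. from [clusterAssignments()].
#' @param map peak-gene link DataFrame from [assignPeaksToGenes()].
#' @param peak_profiles standardized peak matrix (peaks x stages) from
#'   [standardizeProfiles()].
#' @return list of two clusters x stages matrices: `promoter` and `distal`.
#' @export
clusterAccessibility <- function(assignments, map, peak_profiles) {
  cl <- sort(unique(assignments[!is.na(assignments)]))
  stages <- colnames(peak_profiles)
  one_role <- function(role) {
    sub <- map[map$role == role & map$peak_id %in% rownames(peak_profiles), ]
    out <- t(vapply(cl, function(k) {
      genes_k <- names(assignments)[!is.na(assignments) & assignments == k]
      pk <- sub$peak_id[sub$gene_id %in% genes_k]
      if (length(pk) == 0L) return(rep(NA_real_, length(stages)))
      colMeans(peak_profiles[pk, , drop = FALSE])
    }, numeric(length(stages))))
    dimnames(out) <- list(paste0("C", cl), stages)
    out
  }
  list(promoter = one_role("promoter"), distal = one_role("distal"))
}

#' ChIP binding-site overlap with stage-gained accessible regions
#'
#' Counts ChIP sites overlapping (>= 1 bp) the union of the gained regions
#' of the stages of interest, with a per-stage breakdown. Splitting gained
#' regions into abutting pieces does not change the count (overlap is
#' positional).
#'
#' @param chip GRanges of binding sites (non-empty).
#' @param gained named list stage -> GRanges from [gainedRegions()].
#' @param stages_of_interest stages whose gained regions define "open"
#'   (default the 2- and 4-cell stages).
#' @return list: `n_sites`, `n_open`, `fraction`, `per_stage` (named
#'   integer vector).
#' @export
chipOverlap <- function(chip, gained, stages_of_interest = c("2cell", "4cell")) {
  assert_granges(chip)
  if (length(chip) == 0L) stopf("empty ChIP site set")
  miss <- setdiff(stages_of_interest, names(gained))
  if (length(miss)) stopf("no gained regions for stage(s): %s",
                          paste(miss, collapse = ", "))
  open_set <- mergeIntervals(do.call(c, unname(lapply(
    gained[stages_of_interest], granges))))
  n_open <- sum(overlapsAny(chip, open_set, ignore.strand = TRUE))
  per_stage <- vapply(gained[stages_of_interest], function(g)
    sum(overlapsAny(chip, g, ignore.strand = TRUE)), integer(1))
  list(n_sites = length(chip), n_open = n_open,
       fraction = n_open / length(chip), per_stage = per_stage)
}

#' Genes targeted by ChIP binding sites
#'
#' Genes whose body extended by `flank` bp (10 kb default) overlaps at
#' least one binding site.
#'
#' @param chip GRanges of binding sites.
#' @param genes named gene GRanges.
#' @param flank window extension in bp.
#' @return character vector of target gene ids.
#' @export
chipTargets <- function(chip, genes, flank = 10000L) {
  assert_granges(chip); assert_granges(genes)
  win <- suppressWarnings(GenomicRanges::trim(
    resize(granges(genes), width(genes) + 2L * flank, fix = "center")))
  hit <- overlapsAny(win, chip, ignore.strand = TRUE)
  names(genes)[hit]
}

#' Fraction of accessible repeat elements bound by a factor
#'
#' The denominator is ELEMENTS (e.g. the MLT2A1 instances accessible at the
#' 4-cell stage), unlike [chipOverlap()] whose denominator is sites.
#'
#' @param chip GRanges of binding sites.
#' @param accessible GRanges of accessible repeat instances (non-empty).
#' @return fraction in `[0, 1]` of instances overlapping >= 1 site.
#' @export
repeatOverlapFraction <- function(chip, accessible) {
  assert_granges(chip); assert_granges(accessible)
  if (length(accessible) == 0L) stopf("empty accessible element set")
  mean(suppressWarnings(overlapsAny(accessible, chip, ignore.strand = TRUE)))
}
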