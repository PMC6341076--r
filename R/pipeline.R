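# One-call orchestration of the whole pipeline on simulated data:
# simulate -> consensus -> unify -> quantify -> normalize -> cluster ->
# EGA -> ChIP overlap -> repeat specificity -> density correlation, with
# all tables and a JSON report written to a run directory. Deterministic
# under (config, seed).

#' Run the full synthetic-data pipeline
#'
#' Generates a complete staged dataset with planted ground truth, runs
#' every analysis stage with the standard parameters (6 fuzzy centers,
#' membership threshold 0.3, 10-kb gene flank, 2-Mb windows, CpG cutoffs
#' 0.75/0.25, pseudo-count 1, fold-change > 2 over oocyte), and writes
#' per-stage consensus BED files, the unified peak list, count and
#' normalized tables, the EGA call table, cluster assignments, the
#' specificity table and a `report.json` summary. Byte-identical output
#' under the same `(config, seed)`.
#'
#' @param outdir run directory (created if missing).
#' @param seed master integer seed; module substreams are derived from it.
#' @param design a [StageDesign-class].
#' @param config simulation overrides passed to [simulateGenome()].
#' @param centers,m,membership_threshold fuzzy clustering parameters.
#' @param flank peak-to-gene window (bp).
#' @param chip_n_sites,chip_fraction planted ChIP site number and overlap
#'   fraction (defaults reproduce a 697/2782 design).
#' @param fc_mode EGA fold-change mode, see [callEgaGenes()].
#' @return the report, invisibly (a named list; also in
#'   `<outdir>/report.json`).
#' @export
runPipeline <- function(outdir, seed = 1L, design = StageDesign(),
                        config = list(), centers = 6L, m = 1.25,
                        membership_threshold = 0.3, flank = 10000L,
                        chip_n_sites = 2782L, chip_fraction = 0.2505,
                        fc_mode = "log_diff") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome_obj <- simulateGenome(design, seed = seed, config = config)
  sim <- simulateStageData(genome_obj, design, seed = seed)
  cfg <- genome_obj$config
  embryo_order <- intersect(c("zygote", "2cell", "4cell", "8cell",
                              "morula", "ICM", "TE"), stages(design))

  consensus <- lapply(stages(design), function(s)
    consensusPeaks(sim$peak_reps[[s]], cfg$excluded_chroms, stage = s))
  names(consensus) <- stages(design)
  for (s in stages(design))
    writeBed(consensus[[s]], file.path(outdir, paste0("consensus_", s, ".bed")))
  unified <- unifyPeaks(consensus)
  writeBed(unified, file.path(outdir, "unified_peaks.bed"))

  peak_counts <- quantifyPeaks(sim$fragments, unified)
  writeCounts(peak_counts, file.path(outdir, "peak_counts.tsv"))
  norm_peaks <- normalizeLog(peak_counts)
  kept <- prefilterFeatures(norm_peaks, design)
  Z <- standardizeProfiles(kept, design)
  fc <- fuzzyCMeans(Z, c = centers, m = m,
                    seed = sub_seed(seed, "cluster"))
  fc <- assignClusters(fc, membership_threshold)
  cl_tab <- data.frame(feature_id = rownames(membership(fc)),
                       cluster = clusterAssignments(fc),
                       max_membership = apply(membership(fc), 1, max))
  write.table(cl_tab, file.path(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  norm_genes <- normalizeLog(sim$gene_counts)
  ega <- callEgaGenes(norm_genes, design, fc_mode = fc_mode)
  write.table(as.data.frame(ega), file.path(outdir, "ega_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  called <- attr(ega, "ega_genes")
  planted_ega <- genome_obj$manifest$genes$gene_id[
    genome_obj$manifest$genes$class == "ega"]

  gained <- gainedRegions(unified, embryo_order)
  chip <- simulateChipSites(
    open_regions = mergeIntervals(c(granges(gained[["2cell"]]),
                                    granges(gained[["4cell"]]))),
    genome = genome_obj$genome, n_sites = chip_n_sites,
    fraction = chip_fraction, avoid = sim$planted_peaks,
    seed = sub_seed(seed, "chipsites"))
  overlap <- chipOverlap(chip, gained, c("2cell", "4cell"))

  rep_q <- countRepeatFragments(sim$fragments, genome_obj$repeats)
  lens <- setNames(rep_q$summary$merged_length_bp, rep_q$summary$family)
  rep_norm <- normalizeRepeats(rep_q$counts, lens)
  spec <- stageSpecificity(rep_norm, design)
  write.table(as.data.frame(spec[, c("family", "entropy", "assigned_stage",
                                     "rank")]),
              file.path(outdir, "repeat_specificity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fam_tab <- genome_obj$manifest$repeat_families
  spec_match <- mean(spec$assigned_stage[match(fam_tab$family, spec$family)] ==
                       fam_tab$stage, na.rm = TRUE)

  dens <- geneDensityCorrelation(sim$fragments, genome_obj$genes,
                                 genome_obj$genome, window = cfg$window_bp)
  corr <- setNames(dens$correlations$pearson, dens$correlations$sample)

  pcls <- classifyPromoters(genome_obj$promoter_seqs)
  prom_agree <- mean(pcls$class ==
                       genome_obj$manifest$genes$promoter_class[
                         match(pcls$gene_id,
                               genome_obj$manifest$genes$gene_id)])

  report <- list(
    seed = seed,
    n_unified_peaks = length(unified),
    consensus_peaks_per_stage = vapply(consensus, length, integer(1)),
    cluster_sizes = as.list(table(factor(cl_tab$cluster,
                                         levels = seq_len(centers)))),
    n_unassigned = sum(is.na(cl_tab$cluster)),
    n_ega_called = length(called),
    ega_precision = if (length(called))
      mean(called %in% planted_ega) else NA,
    ega_recall = mean(planted_ega %in% called),
    chip_overlap = overlap[c("n_sites", "n_open", "fraction")],
    repeat_stage_recovery = spec_match,
    density_pearson = as.list(corr),
    promoter_class_agreement = prom_agree)
  write_json(report, file.path(outdir, "report.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  invisible(report)
}
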