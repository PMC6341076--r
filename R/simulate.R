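# Deterministic synthetic-data generator: a multi-stage accessibility +
# expression dataset with planted ground truth (EGA activation waves,
# maternal decay, stage-gained peaks, replicate-private decoys,
# stage-specific repeat families, promoter CpG classes, sperm-like
# placement in gene-poor windows), so every downstream module is testable
# without external data.

sim_defaults <- function() {
  list(
    genome = c(chr1 = 60e6, chr2 = 60e6, chr3 = 40e6, chrX = 20e6),
    excluded_chroms = c("chrX", "chrY"),
    window_bp = 2e6,
    n_genes = 1200L,
    gene_slot_bp = 25000L,
    gene_len_range = c(2000L, 15000L),
    n_ega = 300L,                 # planted EGA genes, split over the waves
    ega_waves = c("2cell", "4cell", "8cell", "morula"),
    n_maternal = 300L,
    n_constitutive = 150L,        # remainder of n_genes is silent
    promoter_class_fractions = c(HCP = 0.5, ICP = 0.3, LCP = 0.2),
    n_repeat_families = 40L,
    instances_per_family = 60L,
    repeat_len_range = c(300L, 800L),
    peak_width = 400L,
    peak_slot_bp = 4000L,
    n_constitutive_peaks = 200L,
    n_gained_per_stage = 120L,    # zygote..TE gained accessible regions
    n_sperm_peaks = 300L,
    n_oocyte_peaks = 54L,         # the oocyte's near-inaccessible chromatin
    n_chrx_peaks = 40L,
    decoy_fraction = 0.15,        # replicate-private peaks per stage
    rep_jitter_bp = 50L,
    n_background_fragments = 15000L,
    peak_fragment_mu = 20,
    repeat_fragment_mu = 4,
    repeat_offstage_mu = 0.05,
    fragment_len = 50L,           # single-end 50 bp reads
    nb_dispersion = 0.1,
    noiseless = FALSE,
    mean_silent = 0.1,
    mean_constitutive = 150,
    mean_maternal = 300,
    mean_ega = 250,
    maternal_decay = 0.4,
    peak_mu_present = 50,
    peak_mu_absent = 1
  )
}

merge_config <- function(config) {
  cfg <- sim_defaults()
  if (length(config)) {
    bad <- setdiff(names(config), names(cfg))
    if (length(bad)) stopf("unknown config key(s): %s",
                           paste(bad, collapse = ", "))
    cfg[names(config)] <- config
  }
  cfg
}

# 2-Mb windows over the genome with a per-window placement weight; gene
# placement and fragment background both key off the gene richness of the
# window so that "gene-poor" and "gene-rich" are real, plantable features.
make_windows <- function(genome, window_bp) {
  starts <- lapply(names(genome), function(chr)
    seq(1, genome[[chr]], by = window_bp))
  chr <- rep(names(genome), lengths(starts))
  s <- unlist(starts)
  GRanges(factor(chr, levels = names(genome)),
          IRanges(s, pmin(s + window_bp - 1, genome[chr])))
}

# A regular grid of candidate positions over the whole genome, carrying
# the full set of seqlevels so later concatenations stay warning-free.
genome_grid <- function(genome, by, width) {
  starts <- lapply(names(genome), function(chr)
    seq(1, genome[[chr]] - by, by = by))
  chr <- rep(names(genome), lengths(starts))
  GRanges(factor(chr, levels = names(genome)),
          IRanges(unlist(starts), width = width))
}

# Construct a promoter sequence of length L with an exact CpG dinucleotide
# count k at ~50% GC: shuffle letter tokens, then break surplus accidental
# CG adjacencies by swapping the G with a safe A/T position. Letter counts
# are preserved, so the final CpG observed/expected ratio is k*L/(C*G).
make_promoter_seq <- function(L, k) {
  nC <- nG <- round(L / 4)
  nAT <- L - nC - nG
  tokens <- c(rep("CG", k), rep("C", nC - k), rep("G", nG - k),
              sample(c(rep("A", ceiling(nAT / 2)), rep("T", floor(nAT / 2)))))
  x <- strsplit(paste(sample(tokens), collapse = ""), "")[[1]]
  repeat {
    cg <- which(x[-length(x)] == "C" & x[-1] == "G")
    if (length(cg) <= k) break
    drop <- sample(cg, length(cg) - k)
    for (pos in drop) {
      at <- which(x %in% c("A", "T"))
      ok <- at[at > 1 & x[pmax(at - 1, 1)] != "C" & at != pos + 1]
      j <- ok[sample.int(length(ok), 1)]
      tmp <- x[j]; x[j] <- "G"; x[pos + 1] <- tmp
    }
  }
  paste(x, collapse = "")
}

cpg_count_for_ratio <- function(ratio, L) {
  nC <- round(L / 4)
  max(0L, round(ratio * nC * nC / L))
}

#' Simulate a genome annotation with planted ground truth
#'
#' Generates non-overlapping gene bodies on a weighted window layout (so
#' windows differ genuinely in gene density), repeat-family instances with
#' one planted characteristic stage per family, and 1001-bp promoter
#' sequences (+/- 500 bp of each TSS) whose CpG observed/expected ratio is
#' constructed to hit the requested HCP/ICP/LCP class. Deterministic under
#' `seed`. The genome always contains a sex chromosome so the exclusion
#' rule has coverage.
#'
#' @param design a [StageDesign-class]; repeat families are assigned
#'   characteristic stages cycling over its stages.
#' @param seed integer seed.
#' @param config named list overriding entries of the default
#'   configuration (chromosome lengths, gene/repeat numbers, class
#'   fractions, ...).
#' @return list with `genes` (GRanges), `repeats` (GRanges),
#'   `promoter_seqs` (DNAStringSet), `genome` (named lengths), `windows`
#'   (GRanges with `gene_count`), `config` and `manifest` (planted truth:
#'   per-gene class and activation stage, promoter classes, per-family
#'   stage).
#' @export
simulateGenome <- function(design = StageDesign(), seed = 1L, config = list()) {
  cfg <- merge_config(config)
  genome <- cfg$genome
  with_seed(sub_seed(seed, "genome"), {
    windows <- make_windows(genome, cfg$window_bp)
    wweight <- stats::rgamma(length(windows), shape = 0.5, rate = 1) + 0.01
    # gene slots: disjoint by construction, sampled by window weight
    slot_starts <- genome_grid(genome, cfg$gene_slot_bp, 1L)
    slot_win <- findOverlaps(slot_starts, windows, select = "first")
    if (cfg$n_genes > length(slot_starts))
      stopf("genome too small for %d genes", cfg$n_genes)
    pick <- sample.int(length(slot_starts), cfg$n_genes,
                       prob = wweight[slot_win])
    glen <- sample(cfg$gene_len_range[1]:cfg$gene_len_range[2], cfg$n_genes,
                   replace = TRUE)
    gstart <- start(slot_starts)[pick] +
      sample.int(cfg$gene_slot_bp - max(glen) - 1L, cfg$n_genes, replace = TRUE)
    genes <- GRanges(seqnames(slot_starts)[pick],
                     IRanges(gstart, width = glen),
                     strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE))
    gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
    names(genes) <- gene_id
    mcols(genes)$gene_id <- gene_id
    genes <- genes[order(as.character(seqnames(genes)), start(genes))]
    gene_id <- names(genes)

    # planted gene classes; EGA waves cycle over the activation stages
    auto <- !as.character(seqnames(genes)) %in% cfg$excluded_chroms
    cls <- rep("silent", cfg$n_genes)
    idx_pool <- sample(which(auto))  # EGA/maternal genes stay on autosomes
    n_ega <- min(cfg$n_ega, length(idx_pool))
    ega_idx <- idx_pool[seq_len(n_ega)]
    mat_idx <- idx_pool[n_ega + seq_len(min(cfg$n_maternal,
                                            length(idx_pool) - n_ega))]
    rest <- setdiff(seq_len(cfg$n_genes), c(ega_idx, mat_idx))
    const_idx <- sample(rest, min(cfg$n_constitutive, length(rest)))
    cls[ega_idx] <- "ega"; cls[mat_idx] <- "maternal"
    cls[const_idx] <- "constitutive"
    activation <- rep(NA_character_, cfg$n_genes)
    activation[ega_idx] <- rep(cfg$ega_waves,
                               length.out = length(ega_idx))

    # promoter sequences with constructed CpG classes
    frac <- cfg$promoter_class_fractions / sum(cfg$promoter_class_fractions)
    pcls <- sample(rep(names(frac), round(frac * cfg$n_genes))[
      seq_len(cfg$n_genes)])
    target <- c(HCP = 0.95, ICP = 0.5, LCP = 0.05)
    L <- 1001L
    seqs <- vapply(pcls, function(p)
      make_promoter_seq(L, cpg_count_for_ratio(target[[p]], L)), "")
    promoter_seqs <- DNAStringSet(seqs)
    names(promoter_seqs) <- gene_id

    # repeat families, each with a planted characteristic stage
    fam <- sprintf("fam%02d_%s", seq_len(cfg$n_repeat_families),
                   rep(c("ERVL", "ERV1", "L1", "Alu"),
                       length.out = cfg$n_repeat_families))
    fam[1] <- "MLT2A1"; if (cfg$n_repeat_families >= 2) fam[2] <- "LTR12C"
    repclass <- rep(c("LTR/ERVL", "LTR/ERV1", "LINE/L1", "SINE/Alu"),
                    length.out = cfg$n_repeat_families)
    fam_stage <- rep(stages(design), length.out = cfg$n_repeat_families)
    if (cfg$n_repeat_families >= 2) {
      fam_stage[1] <- "4cell"; fam_stage[2] <- "8cell"
    }
    n_inst <- cfg$instances_per_family
    rlen <- sample(cfg$repeat_len_range[1]:cfg$repeat_len_range[2],
                   cfg$n_repeat_families * n_inst, replace = TRUE)
    rchr <- sample(names(genome), cfg$n_repeat_families * n_inst,
                   replace = TRUE, prob = genome / sum(genome))
    rstart <- floor(runif(length(rchr), 1, genome[rchr] - max(rlen))) + 1
    repeats <- GRanges(factor(rchr, levels = names(genome)),
                       IRanges(rstart, width = rlen),
                       family = rep(fam, each = n_inst),
                       repclass = rep(repclass, each = n_inst))

    mcols(windows)$gene_count <- countOverlaps(windows, tssOf(genes),
                                               ignore.strand = TRUE)
    manifest <- list(
      seed = seed,
      genes = data.frame(gene_id = gene_id, class = cls,
                         activation_stage = activation,
                         promoter_class = unname(pcls),
                         stringsAsFactors = FALSE),
      repeat_families = data.frame(family = fam, repclass = repclass,
                                   stage = fam_stage,
                                   stringsAsFactors = FALSE))
    list(genes = genes, repeats = repeats, promoter_seqs = promoter_seqs,
         genome = genome, windows = windows, config = cfg,
         manifest = manifest)
  })
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(as.integer(round(mu)))
  as.integer(rnbinom(n, mu = mu, size = 1 / dispersion))
}

# Place n width-1 anchors by window weight, then expand to fragments.
place_by_window <- function(n, windows, weight, len) {
  if (n == 0L) return(GRanges())
  wi <- sample.int(length(windows), n, replace = TRUE, prob = weight)
  pos <- start(windows)[wi] +
    floor(runif(n, 0, width(windows)[wi] - len))
  GRanges(seqnames(windows)[wi], IRanges(pos, width = len))
}

#' Simulate per-stage accessibility and expression data
#'
#' Emits, per sample, fragment intervals and, per stage and replicate,
#' called peak sets, plus gene and peak count matrices. Planted structure:
#' stage-gained peaks appear in BOTH replicates from their gain stage
#' onwards and never before; a configurable fraction of decoy peaks appear
#' in only one replicate; chrX peaks exercise the exclusion rule; sperm
#' background fragments preferentially hit gene-poor 2-Mb windows while
#' all other stages prefer gene-rich windows; each repeat family's
#' fragments are concentrated at its planted stage; gene counts follow a
#' negative-binomial model with planted EGA activation waves (promoter
#' accessibility leading expression by one stage) and maternal decay.
#'
#' @param genome_obj result of [simulateGenome()].
#' @param design the [StageDesign-class] used throughout.
#' @param seed integer seed (independent of the genome seed).
#' @return list with `fragments` (named list per sample), `peak_reps`
#'   (list stage -> list of replicate GRanges), `gene_counts`,
#'   `peak_counts` (integer matrices), `planted_peaks` (GRanges with
#'   `peak_class`, `gain_stage` and per-stage presence columns) and
#'   `manifest` (adds decoy ids and per-stage planted peak ids).
#' @export
simulateStageData <- function(genome_obj, design = StageDesign(), seed = 1L) {
  cfg <- genome_obj$config
  genome <- genome_obj$genome
  genes <- genome_obj$genes
  gm <- genome_obj$manifest$genes
  stage_list <- stages(design)
  embryo_order <- intersect(c("zygote", "2cell", "4cell", "8cell",
                              "morula", "ICM", "TE"), stage_list)
  with_seed(sub_seed(seed, "stagedata"), {
    windows <- genome_obj$windows
    gcount <- mcols(windows)$gene_count
    auto_win <- !as.character(seqnames(windows)) %in% cfg$excluded_chroms
    w_rich <- (gcount + 0.5) * auto_win
    w_poor <- (1 / (gcount + 1)) * auto_win
    w_x <- as.numeric(!auto_win)

    # --- planted peak layout -------------------------------------------
    # promoter peaks for EGA genes: gained one stage before activation
    ega <- gm$gene_id[gm$class == "ega"]
    tss <- tssOf(genes[ega])
    prom_peaks <- GRanges(seqnames(tss),
                          IRanges(pmax(start(tss) - cfg$peak_width %/% 2, 1),
                                  width = cfg$peak_width))
    act <- gm$activation_stage[match(ega, gm$gene_id)]
    lead <- embryo_order[pmax(match(act, embryo_order) - 1L, 1L)]
    # non-promoter peak slots: disjoint grid, away from gene bodies
    slots <- genome_grid(genome, cfg$peak_slot_bp, cfg$peak_width)
    slots <- IRanges::shift(slots, 1000L)
    slots <- slots[!overlapsAny(slots, genes + 1000L, ignore.strand = TRUE)]
    slot_win <- findOverlaps(slots, windows, select = "first")
    take_slots <- function(n, weight) {
      avail <- which(!mcols(slots)$used)
      if (length(avail) < n) stopf("not enough peak slots; enlarge genome")
      pick <- sample(avail, n, prob = weight[slot_win[avail]] + 1e-9)
      mcols(slots)$used[pick] <<- TRUE
      granges(slots)[pick]
    }
    mcols(slots)$used <- FALSE
    n_g <- cfg$n_gained_per_stage
    gained_extra <- do.call(c, lapply(embryo_order, function(s)
      take_slots(n_g, w_rich)))
    const_peaks <- take_slots(cfg$n_constitutive_peaks, w_rich)
    sperm_peaks <- take_slots(cfg$n_sperm_peaks, w_poor)
    oocyte_peaks <- take_slots(cfg$n_oocyte_peaks, w_rich)
    chrx_peaks <- take_slots(cfg$n_chrx_peaks, w_x)

    planted <- c(prom_peaks, gained_extra, const_peaks, sperm_peaks,
                 oocyte_peaks, chrx_peaks)
    peak_class <- c(rep("ega_promoter", length(prom_peaks)),
                    rep("gained", length(gained_extra)),
                    rep("constitutive", length(const_peaks)),
                    rep("sperm", length(sperm_peaks)),
                    rep("oocyte", length(oocyte_peaks)),
                    rep("chrX", length(chrx_peaks)))
    gain_stage <- c(lead, rep(embryo_order, each = n_g),
                    rep(NA_character_, length(const_peaks) +
                          length(sperm_peaks) + length(oocyte_peaks)),
                    sample(embryo_order, length(chrx_peaks), replace = TRUE))
    pres <- matrix(FALSE, length(planted), length(stage_list),
                   dimnames = list(NULL, stage_list))
    emb_pos <- match(gain_stage, embryo_order)
    for (i in seq_along(planted)) {
      pres[i, ] <- switch(peak_class[i],
        constitutive = TRUE,
        sperm = stage_list == "sperm",
        oocyte = stage_list == "oocyte",
        stage_list %in% embryo_order[seq(emb_pos[i], length(embryo_order))])
    }
    mcols(planted) <- DataFrame(peak_class = peak_class,
                                gain_stage = gain_stage, pres,
                                check.names = FALSE)
    names(planted) <- sprintf("planted_%04d", seq_along(planted))

    # --- replicate peak calls (with jitter and one-replicate decoys) ----
    jitter_peaks <- function(gr) {
      j1 <- sample(-cfg$rep_jitter_bp:cfg$rep_jitter_bp, length(gr), TRUE)
      j2 <- sample(-cfg$rep_jitter_bp:cfg$rep_jitter_bp, length(gr), TRUE)
      GRanges(seqnames(gr), IRanges(pmax(start(gr) + j1, 1), end(gr) + j2))
    }
    decoy_ids <- list()
    peak_reps <- lapply(stage_list, function(s) {
      present <- planted[pres[, s]]
      reps <- lapply(samples(design, s), function(sm) jitter_peaks(present))
      names(reps) <- samples(design, s)
      n_decoy <- round(cfg$decoy_fraction * length(present))
      if (n_decoy > 0) {
        dec <- take_slots(n_decoy, w_rich)
        reps[[1]] <- sort(c(reps[[1]], dec))
        decoy_ids[[s]] <<- dec
      }
      reps
    })
    names(peak_reps) <- stage_list

    # --- fragments per sample ------------------------------------------
    reps_info <- genome_obj$repeats
    fam_tab <- genome_obj$manifest$repeat_families
    fam_union <- lapply(fam_tab$family, function(f)
      mergeIntervals(reps_info[mcols(reps_info)$family == f]))
    names(fam_union) <- fam_tab$family
    frag_len <- cfg$fragment_len
    fragments <- lapply(samples(design), function(sm) {
      s <- stageOf(design, sm)
      bg_w <- if (s == "sperm") w_poor else w_rich
      bg <- place_by_window(cfg$n_background_fragments, windows, bg_w,
                            frag_len)
      present <- planted[pres[, s]]
      npk <- nb_draw(length(present), cfg$peak_fragment_mu,
                     cfg$nb_dispersion)
      pk_idx <- rep(seq_along(present), npk)
      pk <- GRanges(seqnames(present)[pk_idx],
                    IRanges(start(present)[pk_idx] +
                              floor(runif(length(pk_idx), 0,
                                          pmax(width(present)[pk_idx] -
                                                 frag_len, 1))),
                            width = frag_len))
      rp <- lapply(seq_len(nrow(fam_tab)), function(k) {
        u <- fam_union[[k]]
        mu <- if (fam_tab$stage[k] == s) cfg$repeat_fragment_mu
              else cfg$repeat_offstage_mu
        nn <- nb_draw(length(u), mu, cfg$nb_dispersion)
        ui <- rep(seq_along(u), nn)
        if (length(ui) == 0L) return(GRanges())
        GRanges(seqnames(u)[ui],
                IRanges(start(u)[ui] +
                          floor(runif(length(ui), 0,
                                      pmax(width(u)[ui] - frag_len, 1))),
                        width = frag_len))
      })
      sort(c(bg, pk, do.call(c, rp)), ignore.strand = TRUE)
    })
    names(fragments) <- samples(design)

    # --- gene expression counts ----------------------------------------
    n_genes <- nrow(gm)
    base <- numeric(n_genes)
    base[gm$class == "silent"] <- cfg$mean_silent
    base[gm$class == "constitutive"] <-
      stats::rlnorm(sum(gm$class == "constitutive"),
                    log(cfg$mean_constitutive), 0.5)
    base[gm$class == "maternal"] <-
      stats::rlnorm(sum(gm$class == "maternal"), log(cfg$mean_maternal), 0.4)
    base[gm$class == "ega"] <-
      stats::rlnorm(sum(gm$class == "ega"), log(cfg$mean_ega), 0.4)
    absent <- if (cfg$noiseless) 0 else cfg$mean_silent
    gene_mu <- vapply(stage_list, function(s) {
      mu <- rep(absent, n_genes)
      k <- match(s, embryo_order)       # NA for oocyte / sperm
      ci <- gm$class == "constitutive"
      mu[ci] <- base[ci]
      mi <- gm$class == "maternal"
      mu[mi] <- if (s == "oocyte") base[mi]
        else if (s == "sperm") absent
        else base[mi] * cfg$maternal_decay^k
      ei <- gm$class == "ega"
      if (!is.na(k)) {
        on <- ei & match(gm$activation_stage, embryo_order) <= k
        mu[on] <- base[on]
      }
      mu
    }, numeric(n_genes))
    gene_counts <- vapply(samples(design), function(sm)
      nb_draw(n_genes, gene_mu[, stageOf(design, sm)], cfg$nb_dispersion),
      integer(n_genes))
    dimnames(gene_counts) <- list(gm$gene_id, samples(design))

    # --- peak accessibility counts (over planted peaks) ----------------
    peak_mu <- ifelse(pres, cfg$peak_mu_present,
                      if (cfg$noiseless) 0 else cfg$peak_mu_absent)
    peak_counts <- vapply(samples(design), function(sm)
      nb_draw(nrow(pres), peak_mu[, stageOf(design, sm)], cfg$nb_dispersion),
      integer(nrow(pres)))
    dimnames(peak_counts) <- list(names(planted), samples(design))

    manifest <- genome_obj$manifest
    manifest$planted_peaks <- data.frame(
      peak_id = names(planted), chrom = as.character(seqnames(planted)),
      start = start(planted) - 1L, end = end(planted),
      peak_class = peak_class, gain_stage = gain_stage,
      stringsAsFactors = FALSE)
    list(fragments = fragments, peak_reps = peak_reps,
         gene_counts = gene_counts, peak_counts = peak_counts,
         planted_peaks = planted, decoys = decoy_ids, manifest = manifest)
  })
}

#' Simulate ChIP binding sites with a planted overlap fraction
#'
#' Places exactly `round(fraction * n_sites)` sites overlapping the given
#' open regions (one site centred inside a sampled region) and the rest in
#' space overlapping neither the open regions nor `avoid`.
#'
#' @param open_regions GRanges the overlapping sites must hit (e.g. the
#'   union of 2-/4-cell gained regions, or accessible repeat instances).
#' @param genome named chromosome lengths.
#' @param n_sites total number of sites.
#' @param fraction planted overlap fraction in `[0, 1]`.
#' @param avoid GRanges that non-overlapping sites must also miss
#'   (default: the open regions only).
#' @param width site width in bp (default 200).
#' @param seed integer seed.
#' @return GRanges of `n_sites` binding sites.
#' @export
simulateChipSites <- function(open_regions, genome, n_sites, fraction,
                              avoid = NULL, width = 200L, seed = 1L) {
  assert_granges(open_regions)
  if (fraction < 0 || fraction > 1) stopf("'fraction' must be in [0, 1]")
  n_in <- round(fraction * n_sites)
  if (n_in > 0 && length(open_regions) == 0L)
    stopf("no open regions to place overlapping sites in")
  forbidden <- mergeIntervals(c(granges(open_regions),
                                if (is.null(avoid)) GRanges()
                                else granges(avoid)))
  with_seed(sub_seed(seed, "chip"), {
    inside <- GRanges()
    if (n_in > 0) {
      ri <- sample.int(length(open_regions), n_in, replace = TRUE)
      center <- start(open_regions)[ri] +
        floor(runif(n_in, 0, width(open_regions)[ri]))
      inside <- GRanges(factor(as.character(seqnames(open_regions))[ri],
                               levels = names(genome)),
                        IRanges(pmax(center - width %/% 2, 1),
                                width = width))
    }
    n_out <- n_sites - n_in
    outside <- GRanges()
    tries <- 0L
    while (length(outside) < n_out) {
      tries <- tries + 1L
      if (tries > 200L)
        stopf("not enough never-accessible space for %d sites", n_out)
      need <- n_out - length(outside)
      chr <- sample(names(genome), need * 2L, replace = TRUE,
                    prob = genome / sum(genome))
      pos <- floor(runif(length(chr), 1, genome[chr] - width)) + 1
      cand <- GRanges(factor(chr, levels = names(genome)),
                      IRanges(pos, width = width))
      cand <- cand[!overlapsAny(cand, forbidden, ignore.strand = TRUE)]
      outside <- c(outside, head(cand, need))
    }
    out <- sort(c(inside, outside), ignore.strand = TRUE)
    names(out) <- sprintf("site_%04d", seq_along(out))
    out
  })
}

#' Simulate standardized time-course wave profiles
#'
#' `n_waves` Gaussian-bump temporal shapes with peaks spread evenly over
#' the stages, replicated `n_per_wave` times with additive Gaussian noise
#' and z-scored per feature — the planted-structure benchmark for the
#' fuzzy clustering engine.
#'
#' @param n_per_wave features per wave.
#' @param n_waves number of distinct waves (default 6).
#' @param n_stages number of time points (default 9).
#' @param noise_sd additive noise SD before standardization (default 0.15).
#' @param seed integer seed.
#' @return list with `X` (matrix, features x stages, row-standardized)
#'   and `labels` (integer wave of each feature).
#' @export
simulateWaveProfiles <- function(n_per_wave = 50L, n_waves = 6L,
                                 n_stages = 9L, noise_sd = 0.15, seed = 1L) {
  with_seed(sub_seed(seed, "waves"), {
    t <- seq_len(n_stages)
    centers <- seq(1, n_stages, length.out = n_waves)
    shapes <- t(vapply(centers, function(mu) exp(-(t - mu)^2 / 2),
                       numeric(n_stages)))
    labels <- rep(seq_len(n_waves), each = n_per_wave)
    X <- shapes[labels, ] + matrix(rnorm(length(labels) * n_stages,
                                         sd = noise_sd),
                                   nrow = length(labels))
    X <- (X - rowMeans(X)) / apply(X, 1, sd_pop)
    rownames(X) <- sprintf("f%04d", seq_len(nrow(X)))
    list(X = X, labels = labels)
  })
}
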