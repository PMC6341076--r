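# Consensus / unified peak logic, quantification, location classes,
# gained regions, TSS profiles, promoter CpG classes and window density.

test_that("consensusPeaks keeps only replicate-supported regions", {
  # overlapping replicate peaks extend to the union span
  r1 <- gr("chr1", 101, 300)
  r2 <- gr("chr1", 251, 400)
  cons <- consensusPeaks(list(r1, r2))
  expect_identical(start(cons), 101L)
  expect_identical(end(cons), 400L)
  # replicate-private peak is dropped
  r1b <- gr("chr1", c(101, 1001), c(300, 1100))
  cons <- consensusPeaks(list(r1b, r2))
  expect_length(cons, 1)
  expect_identical(end(cons), 400L)
  # abutting but non-overlapping replicate peaks do not form consensus
  cons <- consensusPeaks(list(gr("chr1", 101, 200), gr("chr1", 201, 300)))
  expect_length(cons, 0)
  # sex-chromosome peaks are excluded before anything else
  rx1 <- gr(c("chr1", "chrX"), c(101, 501), c(300, 700))
  rx2 <- gr(c("chr1", "chrX"), c(101, 501), c(300, 700))
  cons <- consensusPeaks(list(rx1, rx2))
  expect_identical(as.character(seqnames(cons)), "chr1")
  expect_error(consensusPeaks(list(r1)), ">= 2 replicate")
})

test_that("unifyPeaks merges stages and records presence", {
  a <- gr("chr1", 101, 200)
  u <- unifyPeaks(list(s1 = a, s2 = a))
  expect_length(u, 1)
  expect_true(all(unlist(mcols(u)[, c("s1", "s2")])))
  u <- unifyPeaks(list(s1 = gr("chr1", 101, 200), s2 = gr("chr1", 501, 600)))
  expect_length(u, 2)
  expect_identical(sum(mcols(u)$s1), 1L)
  expect_identical(sum(mcols(u)$s2), 1L)
  # overlapping chain across three stages collapses to one peak in all
  u <- unifyPeaks(list(s1 = gr("chr1", 101, 200),
                       s2 = gr("chr1", 151, 260),
                       s3 = gr("chr1", 241, 350)))
  expect_length(u, 1)
  expect_true(all(unlist(mcols(u)[, c("s1", "s2", "s3")])))
})

test_that("quantifyPeaks counts >=1 bp overlaps, incl. straddlers", {
  peaks <- gr("chr1", c(101, 201), c(200, 300))
  names(peaks) <- c("p1", "p2")
  frags <- list(s1 = gr("chr1", c(110, 120, 130, 200, 951), c(150, 160, 170, 210, 1000)))
  m <- quantifyPeaks(frags, peaks)
  expect_identical(m["p1", "s1"], 4L)  # 1-bp overlap counts; straddler too
  expect_identical(m["p2", "s1"], 1L)
  withr::with_seed(17, {
    peaks <- mergeIntervals(random_granges(60))
    names(peaks) <- paste0("p", seq_along(peaks))
    fr <- random_granges(1000, max_width = 60)
    expect_identical(unname(quantifyPeaks(list(s = fr), peaks)[, 1]),
                     brute_counts(peaks, fr))
  })
})

test_that("peak location classes follow the TSS-distance thresholds", {
  genes <- gr("chr1", 50001, 60000, strand = "+")
  names(genes) <- "G1"
  mcols(genes)$gene_id <- "G1"
  peaks <- gr("chr1", c(49501, 46001, 37001, 49901),
              c(49900, 46500, 37500, 50200))
  cl <- classifyPeakLocation(peaks, genes)
  expect_identical(cl$distance, c(100L, 3500L, 12500L, 0L))
  expect_identical(cl$class, c("promoter_proximal", "intermediate",
                               "distal", "promoter_proximal"))
  expect_identical(cl$signed_distance[1], -100L)  # upstream of + TSS
  expect_error(classifyPeakLocation(peaks, GRanges()), "gene")
})

test_that("peak-TSS distance agrees with a brute-force min-over-TSS scan", {
  withr::with_seed(23, {
    genes <- random_granges(30, max_pos = 5e4, max_width = 2000)
    strand(genes) <- sample(c("+", "-"), 30, replace = TRUE)
    names(genes) <- paste0("G", 1:30)
    peaks <- random_granges(80, max_pos = 5e4, max_width = 300)
  })
  got <- classifyPeakLocation(peaks, genes)$distance
  tpos <- start(tssOf(genes))
  tchr <- as.character(seqnames(genes))
  brute <- vapply(seq_along(peaks), function(i) {
    same <- tchr == as.character(seqnames(peaks))[i]
    if (!any(same)) return(NA_integer_)
    d <- pmax(pmax(start(peaks)[i] - tpos[same] - 1L,
                   tpos[same] - end(peaks)[i] - 1L), 0L)
    min(d)
  }, integer(1))
  expect_identical(got, brute[!is.na(brute)])
})

test_that("gainedRegions implements first-presence over the given order", {
  u <- gr("chr1", c(101, 501, 901), c(200, 600, 1000))
  names(u) <- c("p1", "p2", "p3")
  pres <- DataFrame(zygote = c(TRUE, FALSE, FALSE),
                    `2cell` = c(FALSE, TRUE, FALSE),
                    morula = c(TRUE, TRUE, TRUE), check.names = FALSE)
  mcols(u) <- pres
  g <- gainedRegions(u, c("zygote", "2cell", "morula"))
  expect_identical(names(g$zygote), "p1")
  expect_identical(names(g$`2cell`), "p2")
  expect_identical(names(g$morula), "p3")
  # order starting later re-assigns: p1 (zygote+morula) now gains at morula
  g2 <- gainedRegions(u, c("2cell", "morula"))
  expect_identical(sort(names(g2$morula)), c("p1", "p3"))
  # disjoint and exhaustive over peaks present somewhere in the order
  all_ids <- unlist(lapply(g, names))
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_setequal(all_ids, c("p1", "p2", "p3"))
})

test_that("tssProfile is flat on uniform fragments, peaked at the TSS", {
  withr::with_seed(31, {
    genes <- gr("chr1", seq(10000, 190000, by = 10000), width = 1)
    genes <- GenomicRanges::resize(genes, 5000)
    strand(genes) <- "+"
    names(genes) <- paste0("G", seq_along(genes))
    pos <- sample.int(2e5, 20000, replace = TRUE)
    uni <- gr("chr1", pos, pos + 49)
    prof <- tssProfile(uni, genes)
    expect_true(all(abs(prof$enrichment - 1) < 0.35))
    expect_lt(sd(prof$enrichment), 0.12)
  })
  tss_frag <- rep(gr("chr1", start(genes) - 24, start(genes) + 25), 50)
  prof <- tssProfile(c(tss_frag, uni[1:2000]), genes)
  center <- which.min(abs(prof$position))
  expect_gt(prof$enrichment[center], 10)
  expect_lt(max(prof$enrichment[c(1:4, 77:80)]), 3)
})

test_that("tssProfile orients minus-strand windows upstream-left", {
  gene <- gr("chr1", 5001, 8000, strand = "-")
  names(gene) <- "G1"
  # a stack of fragments 500 bp upstream of the minus-strand TSS (end 8000)
  frags <- gr("chr1", rep(8501, 30), rep(8550, 30))
  # uniform background to keep the flank baseline positive
  withr::with_seed(37, {
    pos <- sample(6001:9900, 400, replace = TRUE)
  })
  bg <- gr("chr1", pos, pos + 49)
  prof <- tssProfile(c(frags, bg), gene)
  peak_pos <- prof$position[which.max(prof$enrichment)]
  expect_lt(peak_pos, -400)
  expect_gt(peak_pos, -650)
})

test_that("promoter CpG classes honor the 0.75 / 0.25 cutoffs", {
  # ratio = k/40 for these constructions (C = G = 200, L = 1000)
  seqs <- Biostrings::DNAStringSet(c(
    hcp = seq_with_cpg_ratio(32),    # 0.80
    icp = seq_with_cpg_ratio(20),    # 0.50
    lcp = seq_with_cpg_ratio(4),     # 0.10
    at75 = seq_with_cpg_ratio(30),   # exactly 0.75 -> HCP (inclusive)
    at25 = seq_with_cpg_ratio(10)))  # exactly 0.25 -> ICP (inclusive)
  cl <- classifyPromoters(seqs)
  expect_equal(cl$ratio, c(0.80, 0.50, 0.10, 0.75, 0.25), tolerance = 1e-12)
  expect_identical(cl$class, c("HCP", "ICP", "LCP", "HCP", "ICP"))
  allA <- Biostrings::DNAStringSet(c(g = strrep("A", 1000)))
  cl <- classifyPromoters(allA)
  expect_identical(cl$ratio, 0)
  expect_identical(cl$class, "LCP")
  # gc_fraction mode measures raw G+C
  gc <- classifyPromoters(seqs, mode = "gc_fraction")
  expect_equal(gc$ratio[1], 0.4, tolerance = 1e-12)
  expect_error(classifyPromoters(Biostrings::DNAStringSet(c(x = strrep("A", 100)))),
               ">= 200")
})

test_that("N bases are excluded from CpG counts and length", {
  s <- paste0(seq_with_cpg_ratio(20, L = 900), strrep("N", 100))
  cl <- classifyPromoters(Biostrings::DNAStringSet(c(g = s)))
  # effective L = 900; C = G = 200 unchanged; k = 20
  expect_equal(cl$ratio, 20 * 900 / (200 * 200), tolerance = 1e-12)
})

test_that("geneDensityCorrelation ties density to gene content", {
  genome <- c(chr1 = 2e7, chr2 = 2e7)
  withr::with_seed(41, {
    # genes concentrated on chr1
    g1 <- sample.int(genome[1] - 5000, 180)
    g2 <- sample.int(genome[2] - 5000, 20)
    genes <- gr(rep(c("chr1", "chr2"), c(180, 20)),
                c(g1, g2), c(g1, g2) + 2000)
    strand(genes) <- "+"
    names(genes) <- paste0("G", seq_along(genes))
    rich_pos <- sample.int(genome[1] - 50, 5000)
    poor_pos <- sample.int(genome[2] - 50, 5000)
  })
  rich <- gr("chr1", rich_pos, rich_pos + 49)   # follows the genes
  poor <- gr("chr2", poor_pos, poor_pos + 49)   # avoids them
  res <- geneDensityCorrelation(list(rich = rich, poor = poor),
                                genes, genome, window = 2e6)
  expect_identical(sum(res$windows$gene_count), 200L)
  expect_gt(res$correlations$pearson[res$correlations$sample == "rich"], 0.3)
  expect_lt(res$correlations$pearson[res$correlations$sample == "poor"], -0.3)
  expect_true(all(abs(res$correlations$pearson) <= 1))
  expect_error(geneDensityCorrelation(list(s = rich), genes, genome,
                                      window = 5e7), ">= 3 windows")
})
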