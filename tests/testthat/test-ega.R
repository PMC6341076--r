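# EGA gene calling, peak-gene assignment, cluster decomposition and
# ChIP-site statistics.

ega_design <- tiny_design()

expr_matrix <- function(stage_profiles) {
  # stage_profiles: named list gene -> c(oocyte, 2cell, 4cell, 8cell, morula)
  m <- do.call(rbind, stage_profiles)[, rep(1:5, each = 2)]
  colnames(m) <- samples(ega_design)
  m
}

test_that("EGA rule: expressed in cleavage AND strictly > 2-fold of oocyte", {
  m <- expr_matrix(list(
    up = c(0, 0, 0, 5, 5),        # classic activation: called
    flat = c(6, 6.2, 6.5, 6.4, 6.3),  # FC fails
    boundary = c(2, 3, 2, 2, 2),  # log2 difference exactly 1: not called
    silent = c(0, 0, 0, 0, 0)))   # expressed fails
  res <- callEgaGenes(m, ega_design)
  expect_identical(attr(res, "ega_genes"), "up")
  expect_identical(res$ega, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(res$expressed[3] && !res$fc_pass[3])
  # linear-ratio mode de-logs before comparing
  res2 <- callEgaGenes(m, ega_design, fc_mode = "linear_ratio")
  expect_true("up" %in% attr(res2, "ega_genes"))
  expect_false("flat" %in% attr(res2, "ega_genes"))
  d_bad <- StageDesign(stages = c("2cell", "4cell"), replicates = 2L)
  expect_error(callEgaGenes(m[, 3:6], d_bad), "oocyte")
})

test_that("peak-gene links use gene body +/- 10 kb with TSS-distance roles", {
  genes <- gr("chr1", 50001, 60000, strand = "+")
  names(genes) <- "G1"
  peaks <- gr("chr1", c(41001, 75001, 52001, 49801),
              c(42000, 76000, 52500, 50300))
  names(peaks) <- c("up10k", "far", "body", "attss")
  map <- assignPeaksToGenes(peaks, genes)
  expect_setequal(map$peak_id, c("up10k", "body", "attss"))
  expect_identical(map$side[map$peak_id == "up10k"], "upstream")
  expect_identical(map$role[map$peak_id == "up10k"], "distal")
  expect_identical(map$role[map$peak_id == "attss"], "promoter")
  expect_identical(map$role[map$peak_id == "body"], "other")  # 2 kb from TSS
  expect_error(assignPeaksToGenes(peaks, genes, flank = -1), "flank")
  # TSS anchor mode narrows the window to TSS +/- flank
  map_tss <- assignPeaksToGenes(peaks, genes, flank = 3000, anchor = "tss")
  expect_setequal(map_tss$peak_id, c("body", "attss"))
})

test_that("peak-gene links match a brute-force window scan", {
  withr::with_seed(71, {
    genes <- random_granges(25, max_pos = 2e5, max_width = 8000)
    strand(genes) <- sample(c("+", "-"), 25, TRUE)
    names(genes) <- paste0("G", 1:25)
    peaks <- random_granges(120, max_pos = 2e5, max_width = 400)
    names(peaks) <- paste0("p", 1:120)
  })
  map <- assignPeaksToGenes(peaks, genes, flank = 10000)
  got <- sort(paste(map$peak_id, map$gene_id))
  want <- character(0)
  for (i in seq_along(peaks)) for (j in seq_along(genes)) {
    if (as.character(seqnames(peaks))[i] != as.character(seqnames(genes))[j])
      next
    ws <- max(start(genes)[j] - 10000, 1); we <- end(genes)[j] + 10000
    if (start(peaks)[i] <= we && end(peaks)[i] >= ws)
      want <- c(want, paste(names(peaks)[i], names(genes)[j]))
  }
  expect_identical(got, sort(want))
})

test_that("cluster accessibility decomposition averages linked profiles", {
  prof <- rbind(p1 = c(-1, 0, 1), p2 = c(1, 0, -1), p3 = c(0, 1, -1))
  colnames(prof) <- c("s1", "s2", "s3")
  map <- DataFrame(peak_id = c("p1", "p2", "p3"),
                   gene_id = c("gA", "gA", "gB"),
                   tss_distance = c(0L, 100L, 9000L),
                   side = "inside",
                   role = c("promoter", "promoter", "distal"))
  assignments <- c(gA = 1L, gB = 2L)
  dec <- clusterAccessibility(assignments, map, prof)
  # gA has two promoter peaks: the cluster-1 curve is their mean
  expect_equal(unname(dec$promoter["C1", ]), c(0, 0, 0))
  expect_equal(unname(dec$distal["C2", ]), c(0, 1, -1))
  # a cluster without links of a role is missing, not zero
  expect_true(all(is.na(dec$distal["C1", ])))
  expect_true(all(is.na(dec$promoter["C2", ])))
})

test_that("chipOverlap counts sites positionally over gained unions", {
  gained <- list(`2cell` = gr("chr1", c(1001, 5001), c(2000, 6000)),
                 `4cell` = gr("chr1", 9001, 10000))
  chip <- gr("chr1", c(1500, 5900, 9500, 20001), c(1700, 6100, 9600, 20200))
  ov <- chipOverlap(chip, gained, c("2cell", "4cell"))
  expect_identical(ov$n_sites, 4L)
  expect_identical(ov$n_open, 3L)
  expect_equal(ov$fraction, 0.75)
  expect_identical(unname(ov$per_stage), c(2L, 1L))
  # splitting a gained region into abutting halves changes nothing
  gained2 <- list(`2cell` = gr("chr1", c(1001, 1501, 5001), c(1500, 2000, 6000)),
                  `4cell` = gained$`4cell`)
  expect_identical(chipOverlap(chip, gained2, c("2cell", "4cell"))$n_open,
                   ov$n_open)
  # chip entirely inside gained space -> fraction 1
  inside <- gr("chr1", c(1100, 5500), c(1200, 5600))
  expect_equal(chipOverlap(inside, gained, "2cell")$fraction, 1)
  expect_error(chipOverlap(GRanges(), gained, "2cell"), "empty")
})

test_that("chipTargets applies the 10-kb gene window", {
  genes <- gr("chr1", c(50001, 63001), c(60000, 70000), strand = "+")
  names(genes) <- c("G1", "G2")
  expect_identical(chipTargets(gr("chr1", 47001, 47200), genes), "G1")
  expect_identical(chipTargets(gr("chr1", 30001, 30200), genes), character(0))
  # a site between two genes' windows targets both
  expect_setequal(chipTargets(gr("chr1", 61001, 61200), genes),
                  c("G1", "G2"))
})

test_that("repeatOverlapFraction has elements in the denominator", {
  withr::with_seed(73, {
    acc <- gr("chr1", seq(1000, 100000, by = 1000),
              seq(1000, 100000, by = 1000) + 300)
  })
  bound <- acc[1:30]
  chip <- GenomicRanges::resize(bound, 50, fix = "center")
  expect_equal(repeatOverlapFraction(chip, acc), 0.30)
  expect_equal(repeatOverlapFraction(gr("chr2", 1, 100), acc), 0)
  expect_equal(repeatOverlapFraction(chip, bound), 1)
  expect_error(repeatOverlapFraction(chip, GRanges()), "empty")
})
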