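# Readers/writers for the plain-text formats the pipeline touches and the
# interval algebra every other module calls. All text formats use BED
# conventions (0-based half-open, tab-separated); in memory intervals live
# in GRanges (1-based closed) and the shift happens exactly once, here.

bed0_to_granges <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' Track, browser and `#` comment lines are skipped. Columns 4-6 are mapped
#' to `name`, `score` and strand when present. Coordinates are 0-based
#' half-open on disk and 1-based closed in the returned GRanges.
#'
#' @param path path to a tab-separated BED file.
#' @return GRanges sorted by (chromosome, start), with `name`/`score`
#'   metadata columns when the file provides them.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L)
    return(sort(GRanges()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("line %d: fewer than 3 tab-separated columns", line_no[nf < 3L][1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stopf("line %d: non-integer coordinate", line_no[bad][1])
  bad <- end0 <= start0 | start0 < 0L
  if (any(bad))
    stopf("line %d: invalid interval (need 0 <= start < end)",
          line_no[bad][1])
  gr <- bed0_to_granges(chrom, start0, end0)
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    mcols(gr)$score <- sc
  }
  if (all(nf >= 6L)) {
    st <- vapply(fields, `[[`, "", 6L)
    st[!st %in% c("+", "-")] <- "*"
    strand(gr) <- st
  }
  seqlevels(gr) <- sort(seqlevels(gr))   # lexicographic chromosome order
  sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as sorted BED
#'
#' Emits BED3, or BED6 when `name`/`score`/strand information is present.
#' `readBed(writeBed(x))` preserves coordinates exactly.
#'
#' @param gr a GRanges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  assert_granges(gr)
  seqlevels(gr) <- sort(seqlevels(gr))
  gr <- sort(gr, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  has_strand <- any(as.character(strand(gr)) != "*")
  if (!is.null(mcols(gr)$name) || !is.null(mcols(gr)$score) || has_strand) {
    nm <- mcols(gr)$name
    df$name <- if (is.null(nm)) "." else nm
    sc <- mcols(gr)$score
    df$score <- if (is.null(sc)) 0 else sc
    df$strand <- as.character(strand(gr))
    df$strand[df$strand == "*"] <- "."
  }
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stopf("cannot write BED to '%s': %s", path,
                               conditionMessage(e)))
  invisible(path)
}

#' All overlapping interval pairs with their overlap width
#'
#' The interval-intersection primitive behind the ChIP-site statistics:
#' every pair of intervals from `a` and `b` on the same chromosome sharing
#' at least `min_overlap` bp.
#'
#' @param a,b GRanges.
#' @param min_overlap minimum shared bp for a pair to be reported (>= 1).
#' @return DataFrame with columns `a` (index into `a`), `b` (index into
#'   `b`) and `overlap` (shared bp).
#' @export
intersectIntervals <- function(a, b, min_overlap = 1L) {
  assert_granges(a); assert_granges(b)
  if (min_overlap < 1L) stopf("'min_overlap' must be >= 1")
  # sets may legitimately share no chromosome (empty result); the Seqinfo
  # merge note for that case is suppressed
  h <- suppressWarnings(
    findOverlaps(a, b, minoverlap = min_overlap, ignore.strand = TRUE))
  ov <- suppressWarnings(
    width(pintersect(granges(a)[queryHits(h)],
                     granges(b)[subjectHits(h)], ignore.strand = TRUE)))
  DataFrame(a = queryHits(h), b = subjectHits(h), overlap = ov)
}

#' Merge intervals within a gap
#'
#' Minimal disjoint set covering the input, joining intervals whose
#' separation (in 0-based half-open terms) is at most `gap` bp; `gap = 0`
#' joins overlapping and abutting intervals. Idempotent.
#'
#' @param gr a GRanges.
#' @param gap non-negative bp.
#' @return merged, sorted GRanges (strand ignored).
#' @export
mergeIntervals <- function(gr, gap = 0L) {
  assert_granges(gr)
  if (gap < 0) stopf("'gap' must be >= 0")
  reduce(granges(gr), min.gapwidth = gap + 1L, ignore.strand = TRUE)
}

#' Read a gene annotation table
#'
#' Tab-separated with header `gene_id, chrom, start, end, strand`;
#' coordinates 0-based half-open gene bodies. The TSS is `start` for `+`
#' genes and `end - 1` for `-` genes (0-based), preserved exactly through
#' the coordinate shift.
#'
#' @param path path to the TSV.
#' @return GRanges named by `gene_id` with a `gene_id` metadata column.
#' @export
readGeneTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene_id: %s", df$gene_id[duplicated(df$gene_id)][1])
  bad <- which(df$end <= df$start)
  if (length(bad)) stopf("gene row %d: end <= start", bad[1])
  gr <- bed0_to_granges(df$chrom, df$start, df$end,
                        strand = df$strand, gene_id = df$gene_id)
  names(gr) <- df$gene_id
  gr
}

#' Transcription start sites of a gene annotation
#'
#' @param genes stranded GRanges from [readGeneTable()].
#' @return width-1 GRanges at each TSS (gene start on `+`, gene end on `-`).
#' @export
tssOf <- function(genes) {
  assert_granges(genes)
  resize(genes, width = 1L, fix = "start")
}

#' Read a RepeatMasker-style repeat instance table
#'
#' Tab-separated with header `family, repclass, chrom, start, end`
#' (0-based half-open).
#'
#' @param path path to the TSV.
#' @return GRanges with `family` and `repclass` metadata columns.
#' @export
readRepeatTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "repclass", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("repeat table missing column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad)) stopf("repeat row %d: end <= start", bad[1])
  bed0_to_granges(df$chrom, df$start, df$end,
                  family = df$family, repclass = df$repclass)
}

#' Read / write a count matrix
#'
#' TSV with a `feature_id` first column and one column per sample.
#' Counts must be non-negative integers; duplicate feature ids are an
#' error. `readCounts(writeCounts(m))` is the identity.
#'
#' @param path path to the TSV.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
readCounts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stopf("count matrix must have a 'feature_id' first column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stopf("duplicate feature_id: %s", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0))
    stopf("counts must be non-negative numbers (offending feature: %s)",
          ids[which(rowSums(is.na(m) | m < 0) > 0)[1]])
  if (any(m != round(m)))
    stopf("counts must be integers (offending feature: %s)",
          ids[which(rowSums(m != round(m)) > 0)[1]])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname readCounts
#' @param counts integer matrix with rownames (features) and colnames
#'   (samples).
#' @export
writeCounts <- function(counts, path) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs feature rownames and sample colnames")
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
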