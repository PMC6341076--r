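#' StageDesign: an ordered developmental stage series with replicates
#'
#' Fixes the "earlier/later" semantics used by gained-region calling and
#' EGA gene calling: stages are ordered, every sample belongs to exactly
#' one stage, and the index of each stage is queryable.
#'
#' @slot stages character vector of unique, ordered stage names.
#' @slot samples character vector of unique sample ids.
#' @slot stage factor (levels = stages) giving each sample's stage,
#'   parallel to `samples`.
#' @export
setClass("StageDesign",
  representation(stages = "character", samples = "character",
                 stage = "factor"))

setValidity("StageDesign", function(object) {
  msg <- NULL
  if (anyDuplicated(object@stages)) msg <- c(msg, "stage names must be unique")
  if (anyDuplicated(object@samples)) msg <- c(msg, "sample ids must be unique")
  if (length(object@stage) != length(object@samples))
    msg <- c(msg, "one stage per sample required")
  if (!identical(levels(object@stage), object@stages))
    msg <- c(msg, "stage factor levels must equal the ordered stage list")
  if (anyNA(object@stage)) msg <- c(msg, "every sample needs a known stage")
  if (is.null(msg)) TRUE else msg
})

#' Construct a StageDesign
#'
#' @param stages ordered character vector of stage names. The default is the
#'   nine-point pre-implantation series profiled with two biological
#'   replicates per stage.
#' @param replicates integer (>= 2) replicates per stage; sample ids become
#'   `<stage>_rep<k>`.
#' @param samples,sample_stage alternatively, explicit sample ids and their
#'   stages (overrides `replicates`).
#' @return A [StageDesign-class] object.
#' @examples
#' d <- StageDesign()
#' stages(d)
#' samples(d, stage = "2cell")
#' @export
StageDesign <- function(stages = c("oocyte", "sperm", "zygote", "2cell",
                                   "4cell", "8cell", "morula", "ICM", "TE"),
                        replicates = 2L,
                        samples = NULL, sample_stage = NULL) {
  if (is.null(samples)) {
    if (replicates < 2L) stopf("at least 2 replicates per stage are required")
    samples <- as.vector(t(outer(stages, seq_len(replicates),
                                 function(s, k) paste0(s, "_rep", k))))
    sample_stage <- rep(stages, each = replicates)
  }
  new("StageDesign", stages = stages, samples = samples,
      stage = factor(sample_stage, levels = stages))
}

#' @describeIn StageDesign ordered stage names.
#' @param x a StageDesign.
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @export
setMethod("stages", "StageDesign", function(x) x@stages)

#' @describeIn StageDesign sample ids, optionally restricted to one stage.
#' @param stage optional stage name.
#' @export
setGeneric("samples", function(x, stage = NULL) standardGeneric("samples"))
#' @export
setMethod("samples", "StageDesign", function(x, stage = NULL) {
  if (is.null(stage)) return(x@samples)
  if (!stage %in% x@stages) stopf("unknown stage '%s'", stage)
  x@samples[x@stage == stage]
})

#' @describeIn StageDesign the stage of each sample id.
#' @param ids sample ids.
#' @export
setGeneric("stageOf", function(x, ids) standardGeneric("stageOf"))
#' @export
setMethod("stageOf", "StageDesign", function(x, ids) {
  i <- match(ids, x@samples)
  if (anyNA(i)) stopf("unknown sample id(s): %s",
                      paste(ids[is.na(i)], collapse = ", "))
  as.character(x@stage[i])
})

#' @describeIn StageDesign 1-based index of stage names in the series order.
#' @param stage_names stage names to index.
#' @export
setGeneric("stageIndex", function(x, stage_names) standardGeneric("stageIndex"))
#' @export
setMethod("stageIndex", "StageDesign", function(x, stage_names) {
  i <- match(stage_names, x@stages)
  if (anyNA(i)) stopf("unknown stage(s): %s",
                      paste(stage_names[is.na(i)], collapse = ", "))
  i
})

setMethod("show", "StageDesign", function(object) {
  cat("StageDesign with", length(object@stages), "stages,",
      length(object@samples), "samples\n")
  cat("  stages: ", paste(object@stages, collapse = " -> "), "\n")
  tab <- table(object@stage)
  cat("  replicates per stage:",
      paste(range(tab), collapse = "-"), "\n")
})

#' FuzzyClustering: soft time-course clustering result
#'
#' Result of [fuzzyCMeans()]: a membership matrix over `c` centers, the
#' center profiles over stages, the fuzzifier, the per-iteration objective
#' trace and (after [assignClusters()]) thresholded hard assignments where
#' features whose maximum membership falls below the threshold stay
#' unassigned (NA).
#'
#' @slot centers c x T numeric matrix of center profiles (columns = stages).
#' @slot membership n x c numeric matrix; rows sum to 1.
#' @slot m fuzzifier (> 1).
#' @slot threshold membership threshold used for assignment (NA before
#'   [assignClusters()] is called).
#' @slot assignments named integer vector, NA = unassigned.
#' @slot objective numeric per-iteration objective values (non-increasing).
#' @export
setClass("FuzzyClustering",
  representation(centers = "matrix", membership = "matrix", m = "numeric",
                 threshold = "numeric", assignments = "integer",
                 objective = "numeric"))

setValidity("FuzzyClustering", function(object) {
  msg <- NULL
  u <- object@membership
  if (ncol(u) != nrow(object@centers))
    msg <- c(msg, "membership columns must match number of centers")
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    msg <- c(msg, "membership entries must lie in [0, 1]")
  if (nrow(u) > 0 && max(abs(rowSums(u) - 1)) > 1e-9)
    msg <- c(msg, "membership rows must sum to 1 (tol 1e-9)")
  if (object@m <= 1) msg <- c(msg, "fuzzifier m must be > 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn FuzzyClustering the n x c membership matrix.
#' @param x a FuzzyClustering.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @export
setMethod("membership", "FuzzyClustering", function(x) x@membership)

#' @describeIn FuzzyClustering the c x T center matrix.
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @export
setMethod("clusterCenters", "FuzzyClustering", function(x) x@centers)

#' @describeIn FuzzyClustering named integer assignments (NA = unassigned).
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))
#' @export
setMethod("clusterAssignments", "FuzzyClustering", function(x) x@assignments)

#' @describeIn FuzzyClustering per-iteration objective values.
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @export
setMethod("objectiveTrace", "FuzzyClustering", function(x) x@objective)

setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering:", nrow(object@membership), "features,",
      nrow(object@centers), "centers, m =", object@m, "\n")
  if (!is.na(object@threshold)) {
    a <- object@assignments
    cat("  assigned (threshold ", object@threshold, "): ",
        sum(!is.na(a)), "/", length(a), "\n", sep = "")
  }
  cat("  iterations:", length(object@objective),
      " final objective:", signif(tail(object@objective, 1), 6), "\n")
})
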