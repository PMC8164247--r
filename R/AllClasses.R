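#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Sentinel gene symbol for non-targeting control guides
#'
#' Guides whose `gene` equals this string are treated as non-targeting
#' controls: they pass through normalization and QC but are never scored
#' at the gene level.
#'
#' @export
NONTARGETING <- "NONTARGETING"

# ---------------------------------------------------------------------------
# ScreenExperiment
# ---------------------------------------------------------------------------

#' ScreenExperiment: guide-level counts from a pooled CRISPR screen
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a guide x sample
#' matrix of raw sgRNA counts. `rowData` carries the guide library
#' (`guide_id`, `gene`), `colData` the sample sheet (`sample_id`,
#' `cell_line`, `screen_type`, `condition`, `drug`, `replicate`).
#'
#' Validity requires: non-negative integer counts; unique guide and sample
#' ids; `condition` in `control`/`treated`; `screen_type` in
#' `knockout`/`activation`; and, for every treated sample, a matching
#' control sample with the same cell line, screen type and replicate.
#'
#' @aliases ScreenExperiment-class
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

.valid_screen_experiment <- function(object) {
  msg <- character()
  cts <- assay(object, "counts")
  if (any(is.na(cts))) msg <- c(msg, "counts contain NA")
  else {
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be whole numbers")
  }
  rd <- rowData(object)
  cd <- colData(object)
  need_rd <- c("guide_id", "gene")
  need_cd <- c("sample_id", "cell_line", "screen_type", "condition",
               "drug", "replicate")
  if (!all(need_rd %in% colnames(rd))) {
    msg <- c(msg, paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  } else {
    if (anyDuplicated(rd$guide_id))
      msg <- c(msg, "duplicate guide_id in library")
  }
  if (!all(need_cd %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need_cd, collapse = ", ")))
  } else {
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "duplicate sample_id in sample sheet")
    if (!all(cd$condition %in% c("control", "treated")))
      msg <- c(msg, "condition must be 'control' or 'treated'")
    if (!all(cd$screen_type %in% c("knockout", "activation")))
      msg <- c(msg, "screen_type must be 'knockout' or 'activation'")
    if (!all(cd$replicate == round(cd$replicate)) || any(cd$replicate < 1))
      msg <- c(msg, "replicate must be a positive integer")
    trt <- cd[cd$condition == "treated", , drop = FALSE]
    ctl <- cd[cd$condition == "control", , drop = FALSE]
    if (nrow(trt)) {
      key_t <- paste(trt$cell_line, trt$screen_type, trt$replicate)
      key_c <- paste(ctl$cell_line, ctl$screen_type, ctl$replicate)
      miss <- !(key_t %in% key_c)
      if (any(miss))
        msg <- c(msg, paste0("treated sample(s) without matching control: ",
                             paste(trt$sample_id[miss], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("ScreenExperiment", .valid_screen_experiment)

#' Construct a ScreenExperiment
#'
#' @param counts guide x sample matrix of raw sgRNA counts (non-negative
#'   integers). Row order must match `guideInfo`, column order `sampleInfo`.
#' @param guideInfo data.frame with columns `guide_id` and `gene`
#'   (non-targeting controls use gene [NONTARGETING]).
#' @param sampleInfo data.frame sample sheet with columns `sample_id`,
#'   `cell_line`, `screen_type` (`knockout`/`activation`), `condition`
#'   (`control`/`treated`), `drug` (empty string for controls) and
#'   `replicate`.
#' @return A validated [ScreenExperiment-class] object.
#' @examples
#' se <- ScreenExperiment(
#'   counts = matrix(1:4, 2, 2,
#'                   dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   guideInfo = data.frame(guide_id = c("g1", "g2"), gene = c("A", "A")),
#'   sampleInfo = data.frame(
#'     sample_id = c("s1", "s2"), cell_line = "L1",
#'     screen_type = "activation",
#'     condition = c("control", "treated"),
#'     drug = c("", "gemcitabine"), replicate = 1L))
#' @export
ScreenExperiment <- function(counts, guideInfo, sampleInfo) {
  counts <- as.matrix(counts)
  guideInfo <- as.data.frame(guideInfo)
  sampleInfo <- as.data.frame(sampleInfo)
  if (nrow(counts) != nrow(guideInfo))
    stop("counts has ", nrow(counts), " rows but guideInfo has ",
         nrow(guideInfo))
  if (ncol(counts) != nrow(sampleInfo))
    stop("counts has ", ncol(counts), " columns but sampleInfo has ",
         nrow(sampleInfo), " samples")
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), as.character(sampleInfo$sample_id)))
    stop("count matrix column names do not match sample sheet sample_id order")
  rownames(counts) <- as.character(guideInfo$guide_id)
  colnames(counts) <- as.character(sampleInfo$sample_id)
  if (is.numeric(counts) && !anyNA(counts) && all(counts == round(counts)) &&
      all(counts < .Machine$integer.max))
    storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(guideInfo),
    colData = DataFrame(sampleInfo, row.names = sampleInfo$sample_id))
  new("ScreenExperiment", se)
}

#' @describeIn ScreenExperiment guide library annotation as a data.frame
#' @param se,object a `ScreenExperiment`
#' @export
guideInfo <- function(se) as.data.frame(rowData(se))

#' @describeIn ScreenExperiment sample sheet as a data.frame
#' @export
sampleInfo <- function(se) as.data.frame(colData(se))

#' @importFrom BiocGenerics counts
#' @describeIn ScreenExperiment raw count matrix
#' @exportMethod counts
setMethod("counts", "ScreenExperiment", function(object) {
  assay(object, "counts")
})

setMethod("show", "ScreenExperiment", function(object) {
  cd <- colData(object)
  gi <- rowData(object)
  n_nt <- sum(gi$gene == NONTARGETING)
  cat("ScreenExperiment:", nrow(object), "guides (",
      length(unique(gi$gene[gi$gene != NONTARGETING])), "genes,",
      n_nt, "non-targeting ) x", ncol(object), "samples\n")
  cat("  cell lines:", paste(unique(cd$cell_line), collapse = ", "), "\n")
  cat("  screen types:", paste(unique(cd$screen_type), collapse = ", "), "\n")
  drugs <- setdiff(unique(cd$drug), "")
  cat("  drugs:", paste(drugs, collapse = ", "), "\n")
  cat("  replicates:", paste(sort(unique(cd$replicate)), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# GeneSetList
# ---------------------------------------------------------------------------

#' GeneSetList: a collection of named gene sets
#'
#' Lightweight container for GMT-style gene-set collections: unique set
#' ids, one free-text description per set, and non-empty character vectors
#' of member gene symbols.
#'
#' @aliases GeneSetList-class
#' @export
setClass("GeneSetList",
         representation(setIds = "character",
                        descriptions = "character",
                        genes = "list"))

setValidity("GeneSetList", function(object) {
  msg <- character()
  if (anyDuplicated(object@setIds)) msg <- c(msg, "duplicate set ids")
  if (length(object@descriptions) != length(object@setIds))
    msg <- c(msg, "descriptions length mismatch")
  if (length(object@genes) != length(object@setIds))
    msg <- c(msg, "genes list length mismatch")
  if (any(lengths(object@genes) == 0))
    msg <- c(msg, "gene sets must have at least one member")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetList
#'
#' @param genes named list of character vectors (member gene symbols);
#'   names are the set ids. Duplicate members within a set are removed
#'   with a warning.
#' @param descriptions optional character vector of descriptions, recycled
#'   from `""`.
#' @return A `GeneSetList`.
#' @examples
#' gs <- GeneSetList(list(S1 = c("A", "B"), S2 = c("B", "C", "D")))
#' lengths(geneSets(gs))
#' @export
GeneSetList <- function(genes, descriptions = NULL) {
  if (is.null(names(genes)) || any(names(genes) == ""))
    stop("gene set list must be fully named")
  ndup <- sum(vapply(genes, anyDuplicated, 0L) > 0)
  if (ndup > 0) {
    warning(ndup, " set(s) contained duplicate members; deduplicated")
    genes <- lapply(genes, unique)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(genes))
  new("GeneSetList", setIds = names(genes),
      descriptions = as.character(descriptions),
      genes = unname(lapply(genes, as.character)))
}

#' @describeIn GeneSetList member genes as a named list
#' @param x,object a `GeneSetList`
#' @export
geneSets <- function(x) {
  stats::setNames(x@genes, x@setIds)
}

#' @describeIn GeneSetList set descriptions, named by set id
#' @export
setDescriptions <- function(x) stats::setNames(x@descriptions, x@setIds)

setMethod("length", "GeneSetList", function(x) length(x@setIds))

setMethod("names", "GeneSetList", function(x) x@setIds)

setMethod("show", "GeneSetList", function(object) {
  sz <- lengths(object@genes)
  cat("GeneSetList with", length(object), "sets; sizes",
      if (length(sz)) paste0("[", min(sz), ", ", max(sz), "]") else "[]", "\n")
})

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

.EXPR_STATES <- c("raw_counts", "normalized", "zscored")

#' ExpressionMatrix: gene x sample expression values with a processing state
#'
#' Wraps a numeric gene x sample matrix together with its processing state
#' (`raw_counts` -> `normalized` -> `zscored`). Raw counts must be
#' non-negative; normalized and z-scored matrices must be finite
#' everywhere.
#'
#' @aliases ExpressionMatrix-class
#' @export
setClass("ExpressionMatrix",
         representation(values = "matrix", state = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have gene rownames and sample colnames")
  if (length(object@state) != 1 || !object@state %in% .EXPR_STATES)
    msg <- c(msg, paste("state must be one of:",
                        paste(.EXPR_STATES, collapse = ", ")))
  else if (object@state == "raw_counts") {
    if (any(is.na(v)) || any(v < 0))
      msg <- c(msg, "raw counts must be non-negative and non-missing")
  } else if (any(!is.finite(v))) {
    msg <- c(msg, paste("non-finite values in", object@state, "matrix"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric gene x sample matrix with dimnames.
#' @param state processing state: `"raw_counts"` (default), `"normalized"`
#'   or `"zscored"`.
#' @return An `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, state = "raw_counts") {
  new("ExpressionMatrix", values = as.matrix(values), state = state)
}

#' @describeIn ExpressionMatrix the underlying matrix
#' @param x,object an `ExpressionMatrix`
#' @export
exprValues <- function(x) x@values

#' @describeIn ExpressionMatrix the processing state
#' @export
exprState <- function(x) x@state

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "samples; state:", object@state, "\n")
})
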