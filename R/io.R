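.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    quote = "", stringsAsFactors = FALSE)
}

#' Read a screen sample sheet
#'
#' TSV with columns sample_id, cell_line, screen_type, condition, drug,
#' replicate. Controls carry an empty drug field.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
  d <- .read_tsv(path)
  need <- c("sample_id", "cell_line", "screen_type", "condition", "drug",
            "replicate")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop(path, ": sample sheet missing column(s): ",
         paste(miss, collapse = ", "))
  d$drug[is.na(d$drug)] <- ""
  if (anyDuplicated(d$sample_id))
    stop(path, ": duplicate sample_id: ",
         d$sample_id[duplicated(d$sample_id)][1])
  bad <- which(!d$condition %in% c("control", "treated"))
  if (length(bad))
    stop(path, ": line ", bad[1] + 1, ": field 'condition' must be ",
         "control/treated, got '", d$condition[bad[1]], "'")
  d
}

#' Read a MAGeCK-style sgRNA count table
#'
#' TSV whose first two columns are `sgRNA` and `gene`, followed by one
#' column per sample in the sample sheet. Counts must be non-negative
#' integers and guide ids unique.
#'
#' @param path count TSV path.
#' @param sampleSheet a sample sheet data.frame
#'   (from [readSampleSheet()]) or a path to one.
#' @return a [ScreenExperiment-class].
#' @export
readCountTable <- function(path, sampleSheet) {
  if (is.character(sampleSheet)) sampleSheet <- readSampleSheet(sampleSheet)
  d <- .read_tsv(path)
  if (ncol(d) < 3 || !identical(colnames(d)[1:2], c("sgRNA", "gene")))
    stop(path, ": first two columns must be 'sgRNA' and 'gene'")
  sample_cols <- colnames(d)[-(1:2)]
  miss <- setdiff(sampleSheet$sample_id, sample_cols)
  if (length(miss))
    stop(path, ": sample sheet sample(s) absent from count table: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(sample_cols, sampleSheet$sample_id)
  if (length(extra))
    stop(path, ": count column(s) absent from sample sheet: ",
         paste(extra, collapse = ", "))
  if (anyDuplicated(d$sgRNA))
    stop(path, ": duplicate guide_id: ", d$sgRNA[duplicated(d$sgRNA)][1])
  cts <- as.matrix(d[, sampleSheet$sample_id, drop = FALSE])
  if (!is.numeric(cts) || any(is.na(cts)) || any(cts != round(cts)) ||
      any(cts < 0)) {
    bad <- which(is.na(cts) | cts != round(cts) | cts < 0,
                 arr.ind = TRUE)[1, ]
    stop(path, ": line ", bad[1] + 1, ", field '",
         colnames(cts)[bad[2]], "': counts must be non-negative integers")
  }
  rownames(cts) <- d$sgRNA
  ScreenExperiment(cts, data.frame(guide_id = d$sgRNA, gene = d$gene),
                   sampleSheet)
}

#' @describeIn readCountTable write a ScreenExperiment back to the
#'   canonical tab-separated dialect (columns sgRNA, gene, samples).
#' @param se a [ScreenExperiment-class]
#' @export
writeCountTable <- function(se, path) {
  d <- data.frame(sgRNA = guideInfo(se)$guide_id, gene = guideInfo(se)$gene,
                  counts(se), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn readCountTable write the sample sheet TSV.
#' @param sheet sample sheet data.frame
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `set_id TAB description TAB gene...`.
#' Lines with fewer than 3 fields and duplicate set ids are errors;
#' duplicate genes within a set are deduplicated with a warning.
#'
#' @param path GMT path.
#' @return a [GeneSetList-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop(path, ": line ", short[1], ": expected at least 3 tab-separated ",
         "fields (set_id, description, genes...)")
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop(path, ": duplicate set_id: ", ids[duplicated(ids)][1])
  genes <- lapply(fields, function(f) f[-(1:2)])
  GeneSetList(stats::setNames(genes, ids),
              descriptions = vapply(fields, `[[`, "", 2))
}

#' @describeIn readGmt write a GeneSetList to GMT.
#' @param gsl a [GeneSetList-class]
#' @export
writeGmt <- function(gsl, path) {
  gs <- geneSets(gsl)
  desc <- setDescriptions(gsl)
  lines <- vapply(names(gs), function(id)
    paste(c(id, desc[[id]], gs[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample expression matrix
#'
#' TSV with a `gene` first column and one column per sample.
#'
#' @param path TSV path.
#' @param state processing state of the stored values (`"raw_counts"`,
#'   `"normalized"` or `"zscored"`).
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path, state = "raw_counts") {
  d <- .read_tsv(path)
  if (colnames(d)[1] != "gene")
    stop(path, ": first column must be 'gene'")
  if (anyDuplicated(d$gene))
    stop(path, ": duplicate gene symbol: ", d$gene[duplicated(d$gene)][1])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  ExpressionMatrix(m, state = state)
}

#' @describeIn readExpression write an ExpressionMatrix to TSV.
#' @param expr an [ExpressionMatrix-class]
#' @export
writeExpression <- function(expr, path) {
  d <- data.frame(gene = rownames(exprValues(expr)), exprValues(expr),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns sample_id, time (days, > 0), event (0/1) and an
#' optional treatment label.
#'
#' @param path TSV path.
#' @return data.frame with columns sample_id, time, event and optionally
#'   treatment.
#' @export
readSurvival <- function(path) {
  d <- .read_tsv(path)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop(path, ": survival table missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$time) | d$time <= 0)
  if (length(bad))
    stop(path, ": line ", bad[1] + 1,
         ": field 'time' must be positive, got '", d$time[bad[1]], "'")
  bad <- which(!d$event %in% c(0, 1))
  if (length(bad))
    stop(path, ": line ", bad[1] + 1,
         ": field 'event' must be 0 or 1, got '", d$event[bad[1]], "'")
  if (anyDuplicated(d$sample_id))
    stop(path, ": duplicate sample_id: ",
         d$sample_id[duplicated(d$sample_id)][1])
  d
}

#' @describeIn readSurvival write a survival table to TSV.
#' @param surv survival data.frame
#' @export
writeSurvival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
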