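#' Rank genes into a hit table
#'
#' Descending sort by score with deterministic gene-symbol tie-breaking.
#' Competition ranking ("1224") by default; dense ranking ("1223")
#' optionally.
#'
#' @param scores data.frame with a `gene` column and the score column.
#' @param scoreCol name of the score column (default `mean_l2fc_sum`).
#' @param topK keep only the top `topK` rows (NULL = all). NA scores
#'   always sort last and are dropped when `topK` is given.
#' @param ties `"competition"` (default) or `"dense"`.
#' @return `scores` sorted, with a `rank` column prepended.
#' @export
rankHits <- function(scores, scoreCol = "mean_l2fc_sum", topK = NULL,
                     ties = c("competition", "dense")) {
  ties <- match.arg(ties)
  if (!scoreCol %in% colnames(scores)) stop("no column '", scoreCol, "'")
  x <- scores[[scoreCol]]
  ord <- order(-x, scores$gene, na.last = TRUE, method = "radix")
  out <- scores[ord, , drop = FALSE]
  xs <- out[[scoreCol]]
  rk <- switch(ties,
    competition = rank(-xs, ties.method = "min", na.last = "keep"),
    dense = match(xs, sort(unique(xs), decreasing = TRUE)))
  out <- cbind(rank = rk, out)
  if (!is.null(topK)) {
    out <- out[!is.na(out[[scoreCol]]), , drop = FALSE]
    out <- utils::head(out, topK)
  }
  rownames(out) <- NULL
  out
}

#' Top-k hits per drug and cell line
#'
#' Mirrors per-drug top-hit tables: for each (cell line, screen type,
#' drug), the `topK` genes by L2FC sum.
#'
#' @param geneScoreTable output of [geneScores()].
#' @param topK hits per table (default 10).
#' @param ties ranking rule, see [rankHits()].
#' @return data.frame of stacked per-drug hit tables.
#' @export
rankHitsPerDrug <- function(geneScoreTable, topK = 10,
                            ties = "competition") {
  key <- paste(geneScoreTable$cell_line, geneScoreTable$screen_type,
               geneScoreTable$drug, sep = "\r")
  parts <- lapply(split(geneScoreTable, key), rankHits,
                  scoreCol = "l2fc_sum", topK = topK, ties = ties)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$cell_line, out$screen_type, out$drug, out$rank), ,
      drop = FALSE]
}

#' Join screen hits with per-gene survival associations
#'
#' One row per hit-table gene with the Cox p-value attached
#' (`-log10` transformed alongside); genes missing a survival result
#' keep NA columns.
#'
#' @param hits a hit table with a `gene` column (e.g. from [rankHits()]).
#' @param coxResults output of [coxPerGene()].
#' @return `hits` with survival_p, minus_log10_survival_p and
#'   survival_reason columns appended; row count equals `nrow(hits)`.
#' @export
integrateScreenSurvival <- function(hits, coxResults) {
  m <- match(hits$gene, coxResults$gene)
  hits$survival_p <- coxResults$p[m]
  hits$minus_log10_survival_p <- -log10(coxResults$p[m])
  hits$survival_reason <- ifelse(is.na(m), "gene absent from survival input",
                                 coxResults$reason[m])
  hits
}
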