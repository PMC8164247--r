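#' Counts-per-million normalization
#'
#' Per sample: `1e6 * (count + pseudocount) / sum(count + pseudocount)`.
#' The pseudocount (default 0.5) keeps downstream log2 fold changes
#' finite for zero counts.
#'
#' @param counts a [ScreenExperiment-class] or a numeric count matrix.
#' @param pseudocount non-negative value added to every count.
#' @return numeric matrix of the same shape; every column sums to 1e6.
#' @examples
#' cpmNormalize(matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "s")))
#' @export
cpmNormalize <- function(counts, pseudocount = 0.5) {
  if (is(counts, "ScreenExperiment")) counts <- counts(counts)
  stopifnot(pseudocount >= 0)
  x <- counts + pseudocount
  tot <- colSums(x)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    stop("all-zero sample column(s) with pseudocount 0: ",
         paste(bad, collapse = ", "))
  }
  sweep(x, 2, tot, "/") * 1e6
}

#' Treated/control comparison pairs of a screen
#'
#' One row per (cell line, screen type, drug, replicate): the treated
#' sample and its matched same-replicate control.
#'
#' @param se a [ScreenExperiment-class] or its sample sheet data.frame.
#' @return data.frame(cell_line, screen_type, drug, replicate, treated,
#'   control)
#' @export
screenComparisons <- function(se) {
  cd <- if (is(se, "ScreenExperiment")) sampleInfo(se) else as.data.frame(se)
  trt <- cd[cd$condition == "treated", , drop = FALSE]
  ctl <- cd[cd$condition == "control", , drop = FALSE]
  key <- function(d) paste(d$cell_line, d$screen_type, d$replicate, sep = "\r")
  m <- match(key(trt), key(ctl))
  if (anyNA(m)) stop("treated sample(s) without matching control")
  out <- data.frame(cell_line = trt$cell_line, screen_type = trt$screen_type,
                    drug = trt$drug, replicate = trt$replicate,
                    treated = trt$sample_id, control = ctl$sample_id[m],
                    stringsAsFactors = FALSE)
  out[order(out$cell_line, out$screen_type, out$drug, out$replicate), ,
      drop = FALSE]
}

#' Guide-level quality filter
#'
#' A guide is excluded from a given treated/control comparison when its
#' raw control count is below `controlMin` AND its raw treated count is
#' below `treatedMin` (default 10 / 50). With `logic = "or"` either
#' condition alone excludes. The default AND rule removes only guides
#' that are unmeasurable in both arms, which keeps strongly enriched
#' guides that start from a low baseline.
#'
#' @param se a [ScreenExperiment-class].
#' @param controlMin,treatedMin non-negative integer thresholds.
#' @param logic `"and"` (default) or `"or"`.
#' @param comparisons optional precomputed [screenComparisons()] table.
#' @param verbose log per-comparison exclusion counts.
#' @return list(keep = guides x comparisons logical matrix,
#'   comparisons = the comparison table,
#'   report = data.frame per comparison with n_excluded and
#'   excluded_fraction)
#' @export
filterGuides <- function(se, controlMin = 10, treatedMin = 50,
                         logic = c("and", "or"), comparisons = NULL,
                         verbose = TRUE) {
  logic <- match.arg(logic)
  stopifnot(controlMin >= 0, treatedMin >= 0)
  if (is.null(comparisons)) comparisons <- screenComparisons(se)
  cts <- counts(se)
  ctl <- cts[, comparisons$control, drop = FALSE]
  trt <- cts[, comparisons$treated, drop = FALSE]
  low_ctl <- ctl < controlMin
  low_trt <- trt < treatedMin
  drop <- if (logic == "and") low_ctl & low_trt else low_ctl | low_trt
  keep <- !drop
  dimnames(keep) <- list(rownames(cts), comparisons$treated)
  report <- cbind(comparisons[, c("cell_line", "screen_type", "drug",
                                  "replicate")],
                  n_excluded = colSums(drop),
                  n_retained = colSums(keep),
                  excluded_fraction = colMeans(drop))
  rownames(report) <- NULL
  if (verbose)
    message("filterGuides(", logic, " ", controlMin, "/", treatedMin, "): ",
            "mean exclusion ", sprintf("%.2f%%", 100 * mean(drop)),
            " across ", ncol(keep), " comparisons")
  list(keep = keep, comparisons = comparisons, report = report)
}

#' GuideFoldChange: per-comparison guide log2 fold changes
#'
#' Produced by [guideLog2FC()]. Slots hold the guide x comparison L2FC
#' matrix, the quality-filter keep mask, the comparison table, the
#' replicate-minimum matrix over guide x (cell line, screen type, drug)
#' groups, and the guide annotation.
#'
#' @aliases GuideFoldChange-class
#' @export
setClass("GuideFoldChange",
         representation(l2fc = "matrix", keep = "matrix",
                        comparisons = "data.frame",
                        replicateMin = "matrix", groups = "data.frame",
                        guides = "data.frame"))

setMethod("show", "GuideFoldChange", function(object) {
  cat("GuideFoldChange:", nrow(object@l2fc), "guides x",
      ncol(object@l2fc), "comparisons;",
      nrow(object@groups), "(cell line, screen type, drug) groups\n")
  cat("  filtered entries:",
      sprintf("%.2f%%", 100 * mean(!object@keep)), "\n")
})

#' Per-replicate guide log2 fold changes and replicate minima
#'
#' For every treated/control comparison, computes
#' `log2(CPM_treated / CPM_control)` per guide, masks comparisons that
#' fail the [filterGuides()] rule, and takes the minimum across the
#' surviving replicates of each (cell line, screen type, drug) group.
#' The replicate minimum is the guide statistic that feeds the gene-level
#' L2FC sum: a guide must be enriched in every replicate to score.
#'
#' @param se a [ScreenExperiment-class].
#' @param pseudocount CPM pseudocount (see [cpmNormalize()]).
#' @param controlMin,treatedMin,logic guide filter settings
#'   (see [filterGuides()]).
#' @param dropSamples sample ids excluded before any computation
#'   (e.g. a replicate flagged by [qcReplicateCorrelation()]).
#' @param verbose log filtering summary.
#' @return a [GuideFoldChange-class]
#' @export
guideLog2FC <- function(se, pseudocount = 0.5, controlMin = 10,
                        treatedMin = 50, logic = c("and", "or"),
                        dropSamples = character(), verbose = TRUE) {
  logic <- match.arg(logic)
  if (length(dropSamples)) {
    keep_samp <- !(colnames(se) %in% dropSamples)
    if (verbose)
      message("guideLog2FC: dropping ", sum(!keep_samp), " sample(s): ",
              paste(dropSamples, collapse = ", "))
    se <- se[, keep_samp]
  }
  comparisons <- screenComparisons(se)
  if (!nrow(comparisons)) stop("no treated/control comparisons available")
  cpm <- cpmNormalize(se, pseudocount)
  flt <- filterGuides(se, controlMin, treatedMin, logic,
                      comparisons = comparisons, verbose = verbose)
  l2fc <- log2(cpm[, comparisons$treated, drop = FALSE] /
               cpm[, comparisons$control, drop = FALSE])
  colnames(l2fc) <- comparisons$treated
  masked <- l2fc
  masked[!flt$keep] <- NA_real_

  grp_key <- paste(comparisons$cell_line, comparisons$screen_type,
                   comparisons$drug, sep = "\r")
  groups <- unique(comparisons[, c("cell_line", "screen_type", "drug")])
  rownames(groups) <- NULL
  ugrp <- paste(groups$cell_line, groups$screen_type, groups$drug, sep = "\r")
  repmin <- vapply(ugrp, function(g) {
    cols <- which(grp_key == g)
    do.call(pmin, c(lapply(cols, function(j) masked[, j]),
                    list(na.rm = TRUE)))
  }, numeric(nrow(l2fc)))
  colnames(repmin) <- paste(groups$cell_line, groups$screen_type,
                            groups$drug, sep = ".")
  new("GuideFoldChange", l2fc = l2fc, keep = flt$keep,
      comparisons = comparisons, replicateMin = repmin, groups = groups,
      guides = guideInfo(se))
}

#' @describeIn guideLog2FC long-format table of per-replicate L2FCs and
#'   replicate minima (one row per guide x comparison; `kept` marks
#'   comparisons surviving the filter).
#' @param gfc a [GuideFoldChange-class]
#' @export
guideL2FCTable <- function(gfc) {
  cmp <- gfc@comparisons
  n_g <- nrow(gfc@l2fc)
  out <- data.frame(
    guide_id = rep(rownames(gfc@l2fc), ncol(gfc@l2fc)),
    gene = rep(gfc@guides$gene, ncol(gfc@l2fc)),
    cell_line = rep(cmp$cell_line, each = n_g),
    screen_type = rep(cmp$screen_type, each = n_g),
    drug = rep(cmp$drug, each = n_g),
    replicate = rep(cmp$replicate, each = n_g),
    l2fc = as.vector(gfc@l2fc),
    kept = as.vector(gfc@keep))
  grp_key <- paste(out$cell_line, out$screen_type, out$drug, sep = "\r")
  ugrp <- paste(gfc@groups$cell_line, gfc@groups$screen_type,
                gfc@groups$drug, sep = "\r")
  out$replicate_min_l2fc <-
    gfc@replicateMin[cbind(rep(seq_len(n_g), ncol(gfc@l2fc)),
                           match(grp_key, ugrp))]
  out
}

#' Gene-level L2FC sum
#'
#' For each (cell line, screen type, drug) group, surviving guides of a
#' gene are ranked by their replicate-minimum L2FC (descending; ties
#' broken by guide id). The gene score is the sum of the top `topN`
#' (default 2) values — the "L2FC sum". Rank-1..3 values are retained for
#' pathway analysis. Non-targeting guides are never scored; genes with
#' fewer than `topN` surviving guides get `NA`.
#'
#' @param gfc a [GuideFoldChange-class] from [guideLog2FC()].
#' @param topN number of top guides summed (default 2).
#' @return data.frame(gene, cell_line, screen_type, drug, n_guides,
#'   rank1, rank2, rank3, guide1, guide2, l2fc_sum)
#' @export
geneScores <- function(gfc, topN = 2) {
  stopifnot(topN >= 1)
  guides <- gfc@guides
  targeting <- guides$gene != NONTARGETING
  universe <- sort(unique(guides$gene[targeting]))
  res <- vector("list", nrow(gfc@groups))
  for (g in seq_len(nrow(gfc@groups))) {
    v <- gfc@replicateMin[, g]
    ok <- targeting & !is.na(v)
    gene <- guides$gene[ok]
    gid <- guides$guide_id[ok]
    val <- v[ok]
    ord <- order(gene, -val, gid, method = "radix")
    gene <- gene[ord]; gid <- gid[ord]; val <- val[ord]
    rl <- rle(gene)
    pos <- sequence(rl$lengths)
    first <- match(rl$values, gene)        # index of rank-1 row per gene
    pick <- function(k) {
      idx <- first + (k - 1)
      ifelse(rl$lengths >= k, val[idx], NA_real_)
    }
    r1 <- pick(1); r2 <- pick(2); r3 <- pick(3)
    topsum <- rep(0, length(rl$values))
    for (k in seq_len(topN)) {
      idx <- first + (k - 1)
      kv <- ifelse(rl$lengths >= k, val[idx], NA_real_)
      topsum <- topsum + kv
    }
    m <- match(universe, rl$values)
    res[[g]] <- data.frame(
      gene = universe,
      cell_line = gfc@groups$cell_line[g],
      screen_type = gfc@groups$screen_type[g],
      drug = gfc@groups$drug[g],
      n_guides = ifelse(is.na(m), 0L, rl$lengths[m]),
      rank1 = r1[m], rank2 = r2[m], rank3 = r3[m],
      guide1 = gid[first][m],
      guide2 = ifelse(rl$lengths >= 2, gid[first + 1], NA_character_)[m],
      l2fc_sum = topsum[m])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Multi-drug mean of the L2FC sum
#'
#' Averages the gene L2FC sum (and the rank-1..3 guide values) across the
#' drug panel within each cell line and screen type. By default every
#' configured drug must be present and scored; with
#' `allowMissing = TRUE` the mean is taken over the available values with
#' a warning.
#'
#' @param scores output of [geneScores()].
#' @param drugs drug panel to average over (default: all drugs present).
#' @param allowMissing tolerate missing drugs / NA gene scores.
#' @return data.frame(gene, cell_line, screen_type, n_drugs,
#'   mean_l2fc_sum, mean_rank1, mean_rank2, mean_rank3)
#' @export
multiDrugScores <- function(scores, drugs = NULL, allowMissing = FALSE) {
  if (is.null(drugs)) drugs <- sort(unique(scores$drug))
  missing_drugs <- setdiff(drugs, unique(scores$drug))
  if (length(missing_drugs)) {
    if (!allowMissing)
      stop("drug(s) absent from gene scores: ",
           paste(missing_drugs, collapse = ", "),
           " (set allowMissing = TRUE to average over the present drugs)")
    warning("averaging over present drugs only; missing: ",
            paste(missing_drugs, collapse = ", "))
    drugs <- setdiff(drugs, missing_drugs)
  }
  sub <- scores[scores$drug %in% drugs, , drop = FALSE]
  key <- paste(sub$gene, sub$cell_line, sub$screen_type, sep = "\r")
  uk <- !duplicated(key)
  agg <- function(x) {
    s <- rowsum(ifelse(is.na(x), 0, x), key, reorder = FALSE)
    n <- rowsum(as.numeric(!is.na(x)), key, reorder = FALSE)
    if (allowMissing) ifelse(n > 0, s / n, NA_real_)
    else {
      full <- rowsum(rep(1, length(x)), key, reorder = FALSE)
      miss <- rowsum(as.numeric(is.na(x)), key, reorder = FALSE)
      ifelse(miss > 0 | full < length(drugs), NA_real_, s / n)
    }
  }
  out <- data.frame(gene = sub$gene[uk], cell_line = sub$cell_line[uk],
                    screen_type = sub$screen_type[uk],
                    n_drugs = as.vector(rowsum(as.numeric(!is.na(sub$l2fc_sum)),
                                               key, reorder = FALSE)),
                    mean_l2fc_sum = as.vector(agg(sub$l2fc_sum)),
                    mean_rank1 = as.vector(agg(sub$rank1)),
                    mean_rank2 = as.vector(agg(sub$rank2)),
                    mean_rank3 = as.vector(agg(sub$rank3)))
  out <- out[order(out$cell_line, out$screen_type, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-cell-line summaries of multi-drug scores
#'
#' Per gene and screen type: the mean of the per-cell-line multi-drug
#' means (hit prioritization) and their minimum (the conservative weight
#' used by the PancDS sensitivity score — a gene must score in both cell
#' lines to carry weight).
#'
#' @param multidrug output of [multiDrugScores()].
#' @return data.frame(gene, screen_type, n_cell_lines, mean_across_lines,
#'   min_across_lines)
#' @export
crossCellLineScores <- function(multidrug) {
  key <- paste(multidrug$gene, multidrug$screen_type, sep = "\r")
  uk <- !duplicated(key)
  x <- multidrug$mean_l2fc_sum
  n <- rowsum(as.numeric(!is.na(x)), key, reorder = FALSE)
  s <- rowsum(ifelse(is.na(x), 0, x), key, reorder = FALSE)
  total <- rowsum(rep(1, length(x)), key, reorder = FALSE)
  mn <- tapply(x, factor(key, levels = key[uk]),
               function(v) if (anyNA(v)) NA_real_ else min(v))
  out <- data.frame(gene = multidrug$gene[uk],
                    screen_type = multidrug$screen_type[uk],
                    n_cell_lines = as.vector(total),
                    mean_across_lines = ifelse(as.vector(n) == as.vector(total),
                                               as.vector(s / n), NA_real_),
                    min_across_lines = as.vector(mn))
  out <- out[order(out$screen_type, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine knockout and activation pathway-style gene summaries
#'
#' Optional gene-level combination across screen types: the sum of the
#' per-screen-type cross-cell-line means.
#'
#' @param cross output of [crossCellLineScores()].
#' @return data.frame(gene, n_screen_types, combined_score)
#' @export
combineScreenTypes <- function(cross) {
  key <- cross$gene
  uk <- !duplicated(key)
  x <- cross$mean_across_lines
  s <- rowsum(ifelse(is.na(x), 0, x), key, reorder = FALSE)
  n <- rowsum(as.numeric(!is.na(x)), key, reorder = FALSE)
  data.frame(gene = key[uk],
             n_screen_types = as.vector(n),
             combined_score = ifelse(as.vector(n) > 0, as.vector(s),
                                     NA_real_),
             row.names = NULL)
}

#' PancDS weight vector from screen scores
#'
#' The expression weight of a gene for a given drug is its minimum L2FC
#' sum across cell lines. With `drug = NULL` the multi-drug mean feeds
#' the minimum instead.
#'
#' @param scores output of [geneScores()].
#' @param drug drug to extract weights for, or NULL for multi-drug mean.
#' @param screenType restrict to one screen type (required when the
#'   table holds several).
#' @return named numeric vector of finite weights (NA-scored genes are
#'   dropped).
#' @export
pancdsWeights <- function(scores, drug = NULL, screenType = NULL) {
  if (!is.null(screenType))
    scores <- scores[scores$screen_type == screenType, , drop = FALSE]
  if (length(unique(scores$screen_type)) > 1)
    stop("multiple screen types present; pass screenType")
  if (!is.null(drug)) {
    scores <- scores[scores$drug == drug, , drop = FALSE]
    if (!nrow(scores)) stop("no scores for drug: ", drug)
    val <- scores$l2fc_sum
  } else {
    md <- multiDrugScores(scores)
    scores <- md
    val <- md$mean_l2fc_sum
  }
  mn <- tapply(val, scores$gene, function(v) if (anyNA(v)) NA_real_ else min(v))
  w <- mn[is.finite(mn)]
  stats::setNames(as.numeric(w), names(w))
}

#' Run the full screen-scoring chain
#'
#' Convenience wrapper: [guideLog2FC()] -> [geneScores()] ->
#' [multiDrugScores()] -> [crossCellLineScores()].
#'
#' @param se a [ScreenExperiment-class].
#' @param ... passed to [guideLog2FC()].
#' @param topN,drugs,allowMissing passed to the downstream steps.
#' @return list(guide_fc, gene_scores, multidrug, cross_cell_line)
#' @export
scoreScreen <- function(se, ..., topN = 2, drugs = NULL,
                        allowMissing = FALSE) {
  gfc <- guideLog2FC(se, ...)
  gs <- geneScores(gfc, topN = topN)
  md <- multiDrugScores(gs, drugs = drugs, allowMissing = allowMissing)
  list(guide_fc = gfc, gene_scores = gs, multidrug = md,
       cross_cell_line = crossCellLineScores(md))
}
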