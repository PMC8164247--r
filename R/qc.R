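#' Replicate-correlation QC of a screen
#'
#' Computes guide-level L2FC Spearman correlations within each
#' (cell line, screen type): between replicate pairs (same drug,
#' different replicate), non-replicate pairs (different drugs), and a
#' scrambled null in which one member of a pair has its guide labels
#' permuted. A replicate is flagged when its mean replicate correlation
#' falls below the 75th percentile of the non-replicate distribution of
#' its cell line and screen type; flagged replicates are reported, never
#' dropped automatically (pass them to `dropSamples` of [guideLog2FC()]
#' after inspection).
#'
#' @param se a [ScreenExperiment-class].
#' @param nPermutations number of scrambled-pair null draws per
#'   (cell line, screen type).
#' @param pseudocount CPM pseudocount for the underlying L2FCs.
#' @param seed RNG seed for the permutations.
#' @return list(pairs = data.frame(cell_line, screen_type, type, sample1,
#'   sample2, rho) with type in replicate/non_replicate/null,
#'   flags = data.frame per (cell_line, screen_type, replicate) with
#'   mean_replicate_rho, threshold and flagged)
#' @export
qcReplicateCorrelation <- function(se, nPermutations = 100,
                                   pseudocount = 0.5, seed = 1L) {
  set.seed(seed)
  cd <- sampleInfo(se)
  if (max(table(paste(cd$cell_line, cd$screen_type, cd$drug))) < 2 ||
      length(unique(cd$replicate)) < 2)
    stop("replicate QC needs at least 2 replicates")
  cmp <- screenComparisons(se)
  cpm <- cpmNormalize(se, pseudocount)
  l2fc <- log2(cpm[, cmp$treated, drop = FALSE] /
               cpm[, cmp$control, drop = FALSE])
  colnames(l2fc) <- cmp$treated

  pairs <- list(); nulls <- list()
  for (cl in unique(cmp$cell_line)) for (st in unique(cmp$screen_type)) {
    sub <- cmp[cmp$cell_line == cl & cmp$screen_type == st, , drop = FALSE]
    if (nrow(sub) < 2) next
    idx <- utils::combn(nrow(sub), 2)
    rho <- apply(idx, 2, function(ij)
      stats::cor(l2fc[, sub$treated[ij[1]]], l2fc[, sub$treated[ij[2]]],
                 method = "spearman"))
    type <- ifelse(sub$drug[idx[1, ]] == sub$drug[idx[2, ]],
                   "replicate", "non_replicate")
    pairs[[length(pairs) + 1]] <- data.frame(
      cell_line = cl, screen_type = st, type = type,
      sample1 = sub$treated[idx[1, ]], sample2 = sub$treated[idx[2, ]],
      rho = rho)
    # scrambled null: random pair, one side guide-permuted
    null_rho <- replicate(nPermutations, {
      ij <- sample(nrow(sub), 2)
      stats::cor(l2fc[, sub$treated[ij[1]]],
                 sample(l2fc[, sub$treated[ij[2]]]),
                 method = "spearman")
    })
    nulls[[length(nulls) + 1]] <- data.frame(
      cell_line = cl, screen_type = st, type = "null",
      sample1 = NA_character_, sample2 = NA_character_, rho = null_rho)
  }
  pairs <- do.call(rbind, c(pairs, nulls))
  rownames(pairs) <- NULL

  rep_pairs <- pairs[pairs$type == "replicate", , drop = FALSE]
  nonrep <- pairs[pairs$type == "non_replicate", , drop = FALSE]
  rep_of <- function(s) cd$replicate[match(s, cd$sample_id)]
  flags <- list()
  for (cl in unique(cmp$cell_line)) for (st in unique(cmp$screen_type)) {
    rp <- rep_pairs[rep_pairs$cell_line == cl & rep_pairs$screen_type == st, ]
    nr <- nonrep[nonrep$cell_line == cl & nonrep$screen_type == st, ]
    if (!nrow(rp)) next
    thr <- if (nrow(nr)) stats::quantile(nr$rho, 0.75, names = FALSE) else -Inf
    for (r in sort(unique(c(rep_of(rp$sample1), rep_of(rp$sample2))))) {
      involved <- rep_of(rp$sample1) == r | rep_of(rp$sample2) == r
      mrho <- mean(rp$rho[involved])
      flags[[length(flags) + 1]] <- data.frame(
        cell_line = cl, screen_type = st, replicate = r,
        mean_replicate_rho = mrho, threshold = thr,
        flagged = mrho < thr)
    }
  }
  flags <- do.call(rbind, flags)
  rownames(flags) <- NULL
  if (any(flags$flagged))
    message("qcReplicateCorrelation: flagged ", sum(flags$flagged),
            " replicate(s) for manual review")
  list(pairs = pairs, flags = flags)
}

#' Most variable guides, z-scored by row
#'
#' Selects the `n` guides with the highest CPM variance across samples
#' (the heatmap input of typical screen QC) and z-scores each row.
#' Constant rows are dropped with a warning before selection; if fewer
#' than `n` guides remain, all are returned with a warning.
#'
#' @param cpm CPM matrix (e.g. from [cpmNormalize()]) or a
#'   [ScreenExperiment-class].
#' @param n number of guides to keep.
#' @return numeric matrix of row z-scores, `min(n, usable guides)` rows,
#'   ordered by decreasing variance.
#' @export
topVariableGuides <- function(cpm, n = 500) {
  if (is(cpm, "ScreenExperiment")) cpm <- cpmNormalize(cpm)
  v <- apply(cpm, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant guide row(s) dropped")
    cpm <- cpm[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  if (n > nrow(cpm)) {
    warning("n = ", n, " exceeds ", nrow(cpm), " usable guides; returning all")
    n <- nrow(cpm)
  }
  keep <- order(v, decreasing = TRUE)[seq_len(n)]
  sub <- cpm[keep, , drop = FALSE]
  t(scale(t(sub)))
}
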