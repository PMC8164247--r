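#' Wilcoxon rank-sum enrichment of one gene-value vector over gene sets
#'
#' For each set, compares the values of member genes against all other
#' scored genes with a two-sample Wilcoxon rank-sum (Mann-Whitney) test.
#' Sets with fewer than `minSize` targeted (scored) genes are excluded
#' with a reason instead of a p-value. The exact null distribution is
#' used for small untied samples (m + n <= 50); otherwise the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param values named numeric vector, one value per scored gene
#'   (NA entries are dropped).
#' @param sets a [GeneSetList-class].
#' @param minSize minimum number of targeted genes per set (default 10).
#' @param alternative `"greater"` (member values exceed background;
#'   resistance direction, the default), `"less"` or `"two.sided"`.
#' @return data.frame(set_id, n_targeted, p, excluded, reason)
#' @export
pathwayWilcoxon <- function(values, sets, minSize = 10,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no scored genes")
  gs <- geneSets(sets)
  out <- data.frame(set_id = names(gs), n_targeted = NA_integer_,
                    p = NA_real_, excluded = FALSE, reason = "")
  for (i in seq_along(gs)) {
    member <- intersect(gs[[i]], names(values))
    out$n_targeted[i] <- length(member)
    if (length(member) < minSize) {
      out$excluded[i] <- TRUE
      out$reason[i] <- sprintf("fewer than %d genes targeted", minSize)
      next
    }
    bg <- values[setdiff(names(values), member)]
    if (!length(bg)) stop("empty background for set ", names(gs)[i])
    out$p[i] <- .wilcoxonP(values[member], bg, alternative)
  }
  out
}

.wilcoxonP <- function(x, y, alternative) {
  use_exact <- (length(x) + length(y) <= 50) &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = FALSE)$p.value)
}

#' Rank-stratified pathway enrichment with consolidated scores
#'
#' Runs [pathwayWilcoxon()] on the rank-1, rank-2 and rank-3 guide
#' values of each gene (the replicate-minimum L2FC of its top, second
#' and third guide) and sums the -log10 p-values into a consolidated
#' enrichment score. Input is one row per gene: either the per-drug
#' table from [geneScores()] filtered to a single (cell line, screen
#' type, drug), or the multi-drug means from [multiDrugScores()]
#' filtered to a single (cell line is already averaged, screen type).
#'
#' @param rankTable data.frame with a `gene` column and either
#'   `rank1`/`rank2`/`rank3` or `mean_rank1`..`mean_rank3` columns, one
#'   row per gene.
#' @param sets a [GeneSetList-class].
#' @param minSize,alternative see [pathwayWilcoxon()].
#' @param adjust also append Benjamini-Hochberg adjusted p-values per rank.
#' @return data.frame(set_id, n_targeted, p_rank1, p_rank2, p_rank3,
#'   consolidated_score, excluded, reason) plus, when `adjust = TRUE`,
#'   padj_rank1..3.
#' @export
pathwayEnrichment <- function(rankTable, sets, minSize = 10,
                              alternative = "greater", adjust = TRUE) {
  cols <- if (all(c("rank1", "rank2", "rank3") %in% colnames(rankTable)))
    c("rank1", "rank2", "rank3")
  else if (all(paste0("mean_rank", 1:3) %in% colnames(rankTable)))
    paste0("mean_rank", 1:3)
  else stop("rankTable needs rank1..3 or mean_rank1..3 columns")
  if (anyDuplicated(rankTable$gene))
    stop("rankTable must have one row per gene; filter to a single ",
         "cell line / screen type / drug first")
  res <- NULL
  for (k in 1:3) {
    v <- stats::setNames(rankTable[[cols[k]]], rankTable$gene)
    pk <- pathwayWilcoxon(v, sets, minSize = minSize,
                          alternative = alternative)
    if (is.null(res)) {
      res <- pk[, c("set_id", "n_targeted", "excluded", "reason")]
    }
    res[[paste0("p_rank", k)]] <- pk$p
  }
  res$consolidated_score <- consolidatedScore(
    res[, paste0("p_rank", 1:3), drop = FALSE])
  if (adjust) {
    for (k in 1:3)
      res[[paste0("padj_rank", k)]] <-
        stats::p.adjust(res[[paste0("p_rank", k)]], method = "BH")
  }
  res[, c("set_id", "n_targeted", paste0("p_rank", 1:3),
          "consolidated_score", "excluded", "reason",
          if (adjust) paste0("padj_rank", 1:3))]
}

#' Consolidated pathway score
#'
#' The sum of -log10 p over the available rank (and, when rows from
#' several screen types are combined upstream, screen-type) p-values.
#' All-NA rows give NA; p = 1 contributes 0.
#'
#' @param pvals numeric vector, matrix or data.frame of p-values in (0, 1].
#' @return numeric consolidated score(s), >= 0.
#' @export
consolidatedScore <- function(pvals) {
  m <- as.matrix(pvals)
  if (any(m <= 0 | m > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  s <- rowSums(-log10(m), na.rm = TRUE)
  s[rowSums(!is.na(m)) == 0] <- NA_real_
  as.numeric(s)
}

#' Combine pathway enrichment across screen types
#'
#' Sums the consolidated scores of knockout and activation runs per set
#' (missing screen types are flagged, not an error).
#'
#' @param ... named pathway enrichment tables from [pathwayEnrichment()]
#'   (e.g. `knockout = ..., activation = ...`).
#' @return data.frame(set_id, n_screen_types, consolidated_score)
#' @export
combinePathwayScreens <- function(...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    stop("pass named tables, e.g. knockout = , activation = ")
  ids <- sort(unique(unlist(lapply(tabs, `[[`, "set_id"))))
  sc <- sapply(tabs, function(t) t$consolidated_score[match(ids, t$set_id)])
  sc <- matrix(sc, nrow = length(ids))
  n <- rowSums(!is.na(sc))
  if (any(n < length(tabs)))
    message("combinePathwayScreens: ", sum(n < length(tabs)),
            " set(s) missing from some screen type")
  data.frame(set_id = ids, n_screen_types = n,
             consolidated_score = ifelse(n > 0, rowSums(sc, na.rm = TRUE),
                                         NA_real_))
}

#' Attach member-gene survival aggregates to pathway results
#'
#' For each set, aggregates the Cox p-values of its member genes by
#' Fisher's method (-2 sum ln p ~ chi-square with 2m df under the null)
#' and reports the median member p alongside. Sets with no member gene
#' in the Cox table get NA with a reason.
#'
#' @param pathwayResults output of [pathwayEnrichment()].
#' @param coxResults output of [coxPerGene()].
#' @param sets the [GeneSetList-class] used for enrichment.
#' @return `pathwayResults` with columns n_survival_genes,
#'   fisher_chisq, fisher_df, survival_p, median_member_p,
#'   survival_reason appended.
#' @export
pathwaySurvivalTable <- function(pathwayResults, coxResults, sets) {
  gs <- geneSets(sets)
  cox_p <- stats::setNames(coxResults$p, coxResults$gene)
  cox_p <- cox_p[!is.na(cox_p)]
  out <- pathwayResults
  out$n_survival_genes <- NA_integer_
  out$fisher_chisq <- NA_real_
  out$fisher_df <- NA_integer_
  out$survival_p <- NA_real_
  out$median_member_p <- NA_real_
  out$survival_reason <- ""
  for (i in seq_len(nrow(out))) {
    members <- gs[[out$set_id[i]]]
    p <- cox_p[intersect(members, names(cox_p))]
    out$n_survival_genes[i] <- length(p)
    if (!length(p)) {
      out$survival_reason[i] <- "no member gene with survival result"
      next
    }
    stat <- -2 * sum(log(p))
    df <- 2L * length(p)
    out$fisher_chisq[i] <- stat
    out$fisher_df[i] <- df
    out$survival_p[i] <- stats::pchisq(stat, df, lower.tail = FALSE)
    out$median_member_p[i] <- stats::median(p)
  }
  out
}
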