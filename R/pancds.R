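#' Variance-stabilizing-style normalization of raw expression counts
#'
#' Shifted-log counts-per-million:
#' `log2(1e6 * (count + 0.5) / sum(count + 0.5) + 1)` per sample. This is
#' a monotone, variance-damping stand-in for a dispersion-based VST; the
#' downstream per-gene z-scoring makes the sensitivity score insensitive
#' to the exact monotone transform used. Matrices already in state
#' `normalized` or `zscored` are rejected (pass pre-normalized data by
#' constructing the [ExpressionMatrix-class] with the right state).
#'
#' @param expr an [ExpressionMatrix-class] in state `raw_counts`.
#' @param pseudocount added to every count (default 0.5).
#' @return an [ExpressionMatrix-class] in state `normalized`.
#' @export
vstNormalize <- function(expr, pseudocount = 0.5) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (exprState(expr) != "raw_counts")
    stop("vstNormalize expects state 'raw_counts', got '", exprState(expr), "'")
  v <- exprValues(expr)
  if (any(v < 0)) stop("negative values in raw counts")
  x <- v + pseudocount
  norm <- log2(sweep(x, 2, colSums(x), "/") * 1e6 + 1)
  ExpressionMatrix(norm, state = "normalized")
}

#' Per-gene z-scores across samples
#'
#' `(x - mean) / sd` per gene row, with the sample (n - 1) standard
#' deviation. Genes with zero variance are set to 0 with a warning.
#'
#' @param expr an [ExpressionMatrix-class] in state `normalized`.
#' @return an [ExpressionMatrix-class] in state `zscored`.
#' @export
zscoreGenes <- function(expr) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (exprState(expr) != "normalized")
    stop("zscoreGenes expects state 'normalized', got '", exprState(expr), "'")
  v <- exprValues(expr)
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) z-scored to 0")
    sd[flat] <- 1
  }
  z <- (v - mu) / sd
  z[flat, ] <- 0
  ExpressionMatrix(z, state = "zscored")
}

#' PancDS drug-sensitivity score
#'
#' The resistance score of a sample is the sum over genes of the
#' screen-derived weight times the z-scored expression:
#' `sum_g w_g * z_gs` over the genes shared between the weight vector
#' and the matrix. Predicted sensitivity is its negation (high weighted
#' expression of resistance genes = resistant = low sensitivity).
#'
#' @param expr an [ExpressionMatrix-class] in state `zscored`.
#' @param weights named numeric weight vector (gene -> minimum L2FC sum
#'   across cell lines; see [pancdsWeights()]).
#' @param drug drug label carried into the output (informational).
#' @param topK optionally restrict to the `topK` genes by |weight|.
#' @param verbose log the gene-intersection size.
#' @return data.frame(sample_id, drug, resistance_score,
#'   predicted_sensitivity)
#' @export
sensitivityScore <- function(expr, weights, drug = NA_character_,
                             topK = NULL, verbose = TRUE) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (exprState(expr) != "zscored")
    stop("sensitivityScore expects state 'zscored', got '",
         exprState(expr), "'")
  weights <- weights[is.finite(weights)]
  if (!is.null(topK))
    weights <- weights[order(abs(weights),
                             decreasing = TRUE)][seq_len(min(topK,
                                                             length(weights)))]
  z <- exprValues(expr)
  shared <- intersect(names(weights), rownames(z))
  if (!length(shared))
    stop("no genes shared between weight vector and expression matrix")
  if (verbose)
    message("sensitivityScore: ", length(shared), " of ", length(weights),
            " weighted genes present in expression matrix")
  score <- as.numeric(weights[shared] %*% z[shared, , drop = FALSE])
  data.frame(sample_id = colnames(z), drug = drug,
             resistance_score = score,
             predicted_sensitivity = -score)
}

#' Group samples by predicted sensitivity
#'
#' `rule = "median"` splits on the median of `predicted_sensitivity`
#' (ties go to "low"); `rule = "tertile"` cuts at the 1/3 and 2/3
#' quantiles into resistant / intermediate / sensitive;
#' `rule = "fixed"` uses the supplied increasing `thresholds`
#' (k cutpoints -> k + 1 groups, labelled group1..group(k+1) from low to
#' high sensitivity).
#'
#' @param scores output of [sensitivityScore()] (or any data.frame with
#'   a `predicted_sensitivity` column).
#' @param rule `"median"`, `"tertile"` or `"fixed"`.
#' @param thresholds increasing numeric cutpoints for `rule = "fixed"`.
#' @return `scores` with a `group` character column appended.
#' @export
classifyScores <- function(scores, rule = c("median", "tertile", "fixed"),
                           thresholds = NULL) {
  rule <- match.arg(rule)
  x <- scores$predicted_sensitivity
  if (length(unique(x)) == 1) {
    warning("all scores equal; single group")
    scores$group <- "low"
    return(scores)
  }
  scores$group <- switch(rule,
    median = ifelse(x <= stats::median(x), "low", "high"),
    tertile = {
      q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
      ifelse(x <= q[1], "resistant",
             ifelse(x <= q[2], "intermediate", "sensitive"))
    },
    fixed = {
      if (is.null(thresholds) || is.unsorted(thresholds, strictly = TRUE))
        stop("rule 'fixed' needs strictly increasing thresholds")
      paste0("group", findInterval(x, thresholds) + 1L)
    })
  scores
}

#' Normalized area under a dose-response curve
#'
#' Trapezoidal integration of viability over log10(dose), divided by the
#' log-dose range, so a flat viability of 1 gives AUC 1 and complete
#' kill gives 0. Lower AUC = more sensitive.
#'
#' @param dr data.frame(dose, viability) as from
#'   [simulateDoseResponse()], or a numeric dose vector.
#' @param viability viability fractions when `dr` is a dose vector.
#' @return scalar AUC.
#' @export
doseResponseAUC <- function(dr, viability = NULL) {
  if (is.data.frame(dr)) {
    doses <- dr$dose; viability <- dr$viability
  } else doses <- dr
  stopifnot(length(doses) == length(viability), length(doses) >= 2,
            all(doses > 0), !is.unsorted(doses, strictly = TRUE))
  x <- log10(doses)
  auc <- sum(diff(x) * (utils::head(viability, -1) +
                        utils::tail(viability, -1)) / 2)
  auc / diff(range(x))
}
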