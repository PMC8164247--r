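#' Univariate Cox proportional-hazards association per gene
#'
#' Fits, for every gene, a univariate Cox model of overall survival on
#' the gene's normalized expression (Breslow tie handling, Wald
#' p-value). Samples are intersected by id between the expression matrix
#' and the survival table. Constant genes, non-converging fits and
#' apparent separation (|beta| beyond `betaBound`) are reported with a
#' reason instead of an estimate.
#'
#' @param expr an [ExpressionMatrix-class] in state `normalized` or
#'   `zscored` (or a plain numeric gene x sample matrix).
#' @param surv data.frame(sample_id, time, event) as from
#'   [readSurvival()] / [simulateSurvival()].
#' @param ties tie handling passed to [survival::coxph()]
#'   (default `"breslow"`).
#' @param betaBound |beta| above which the fit is flagged as separated.
#' @return data.frame(gene, beta, hr, se, p, n_used, reason)
#' @export
coxPerGene <- function(expr, surv, ties = "breslow", betaBound = 15) {
  v <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  shared <- intersect(colnames(v), surv$sample_id)
  if (length(shared) < 2)
    stop("fewer than 2 samples shared between expression and survival")
  v <- v[, shared, drop = FALSE]
  s <- surv[match(shared, surv$sample_id), , drop = FALSE]
  if (sum(s$event) < 2) stop("need at least 2 events")
  y <- survival::Surv(s$time, s$event)
  out <- data.frame(gene = rownames(v), beta = NA_real_, hr = NA_real_,
                    se = NA_real_, p = NA_real_,
                    n_used = length(shared), reason = "")
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    if (stats::var(x) == 0) {
      out$reason[i] <- "zero variance"
      next
    }
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(y ~ x, ties = ties,
                        control = survival::coxph.control(iter.max = 50)),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit))) {
      out$reason[i] <- "fit failed"
      next
    }
    b <- unname(stats::coef(fit))
    if (abs(b) > betaBound) {
      out$reason[i] <- "separation"
      next
    }
    sm <- summary(fit)$coefficients
    out$beta[i] <- b
    out$hr[i] <- exp(b)
    out$se[i] <- sm[1, "se(coef)"]
    out$p[i] <- sm[1, "Pr(>|z|)"]
  }
  out
}

#' Log-rank test of survival between groups
#'
#' Standard log-rank chi-square over the risk sets, df = k - 1 for k
#' groups, via [survival::survdiff()].
#'
#' @param groups named character/factor vector of group labels (names =
#'   sample ids) or a data.frame with `sample_id` and `group` columns.
#' @param surv data.frame(sample_id, time, event).
#' @return list(chisq, df, p, table = per-group n, observed and expected
#'   events)
#' @export
logrankTest <- function(groups, surv) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$sample_id)
  shared <- intersect(names(groups), surv$sample_id)
  if (length(shared) < 2) stop("fewer than 2 samples shared")
  g <- factor(groups[shared])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  s <- surv[match(shared, surv$sample_id), , drop = FALSE]
  sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
  df <- nlevels(g) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       table = data.frame(group = levels(g), n = as.vector(sd$n),
                          observed = as.vector(sd$obs),
                          expected = as.vector(sd$exp)))
}
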