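# Independent straight-line re-implementations used as oracles.
# Deliberately loop-based and structured differently from the package code.

oracle_cpm <- function(counts, pseudocount = 0.5) {
  out <- counts * 0
  for (j in seq_len(ncol(counts))) {
    col <- counts[, j] + pseudocount
    out[, j] <- col / sum(col) * 1e6
  }
  out
}

# Full scoring chain: guide L2FC per comparison, replicate minimum,
# per-gene top-n sum. Returns list(l2fc, repmin, gene) where gene is a
# long data.frame over (gene, cell_line, screen_type, drug).
oracle_score_screen <- function(counts, guide_df, sample_df,
                                pseudocount = 0.5, control_min = 10,
                                treated_min = 50, logic = "and", top_n = 2) {
  cpm <- oracle_cpm(counts, pseudocount)
  trt_all <- sample_df[sample_df$condition == "treated", , drop = FALSE]
  groups <- unique(trt_all[, c("cell_line", "screen_type", "drug")])
  genes <- sort(unique(guide_df$gene[guide_df$gene != "NONTARGETING"]))
  l2fc <- list()
  gene_rows <- list()
  repmin_all <- list()
  for (gi in seq_len(nrow(groups))) {
    cl <- groups$cell_line[gi]
    st <- groups$screen_type[gi]
    dr <- groups$drug[gi]
    trt <- trt_all[trt_all$cell_line == cl & trt_all$screen_type == st &
                   trt_all$drug == dr, , drop = FALSE]
    repmin <- rep(NA_real_, nrow(counts))
    for (g in seq_len(nrow(counts))) {
      vals <- numeric()
      for (k in seq_len(nrow(trt))) {
        ts <- trt$sample_id[k]
        cs <- sample_df$sample_id[
          sample_df$cell_line == cl & sample_df$screen_type == st &
          sample_df$condition == "control" &
          sample_df$replicate == trt$replicate[k]]
        fc <- log2(cpm[g, ts] / cpm[g, cs])
        l2fc[[paste(g, ts)]] <- fc
        dropped <- if (logic == "and")
          counts[g, cs] < control_min && counts[g, ts] < treated_min
        else counts[g, cs] < control_min || counts[g, ts] < treated_min
        if (!dropped) vals <- c(vals, fc)
      }
      if (length(vals)) repmin[g] <- min(vals)
    }
    repmin_all[[paste(cl, st, dr)]] <- repmin
    for (gene in genes) {
      idx <- which(guide_df$gene == gene & !is.na(repmin))
      v <- repmin[idx]
      ids <- guide_df$guide_id[idx]
      ord <- order(-v, ids)
      v <- v[ord]
      s <- if (length(v) >= top_n) sum(v[seq_len(top_n)]) else NA_real_
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene = gene, cell_line = cl, screen_type = st, drug = dr,
        rank1 = if (length(v) >= 1) v[1] else NA_real_,
        rank2 = if (length(v) >= 2) v[2] else NA_real_,
        rank3 = if (length(v) >= 3) v[3] else NA_real_,
        l2fc_sum = s)
    }
  }
  list(l2fc = l2fc, repmin = repmin_all, gene = do.call(rbind, gene_rows))
}

# Exact one-sided ("greater") Mann-Whitney p by full enumeration of group
# assignments (valid for small m + n).
oracle_wilcoxon_greater <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(pooled), m)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mean(u_all >= u_obs - 1e-9)
}

# Tie-corrected large-sample normal approximation (no continuity correction).
oracle_wilcoxon_normal <- function(x, y, alternative = "greater") {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (u - m * n / 2) / sqrt(sigma2)
  switch(alternative,
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z),
         two.sided = 2 * stats::pnorm(-abs(z)))
}

# Two-group log-rank statistic by direct risk-set bookkeeping.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(max(group) == 2)
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Normalized AUC of a noiseless Hill curve by adaptive quadrature.
oracle_hill_auc <- function(ic50, hill, dose_range) {
  f <- function(lx) 1 / (1 + (10^lx / ic50)^hill)
  lr <- log10(dose_range)
  stats::integrate(f, lr[1], lr[2], rel.tol = 1e-10)$value / diff(lr)
}
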