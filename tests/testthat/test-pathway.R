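make_values <- function(n, seed = 1, shift_genes = character(), shift = 0) {
  set.seed(seed)
  v <- stats::setNames(stats::rnorm(n), sprintf("G%03d", seq_len(n)))
  v[shift_genes] <- v[shift_genes] + shift
  v
}

test_that("Wilcoxon p-values match exact enumeration at small sizes", {
  set.seed(3)
  for (i in 1:20) {
    m <- sample(3:5, 1)
    n <- sample(4:7, 1)
    x <- rnorm(m)
    y <- rnorm(n)
    vals <- stats::setNames(c(x, y), sprintf("G%03d", seq_len(m + n)))
    sets <- GeneSetList(list(S = names(vals)[seq_len(m)]))
    p <- pathwayWilcoxon(vals, sets, minSize = 2)$p
    expect_equal(p, oracle_wilcoxon_greater(x, y), tolerance = 1e-10)
  }
})

test_that("complete separation gives the closed-form minimum p", {
  # 10 member values all above 40 background values: U = 400,
  # p = 1 / choose(50, 10)
  vals <- stats::setNames(c(10 + 1:10, 1:40 / 100), sprintf("G%03d", 1:50))
  sets <- GeneSetList(list(S = sprintf("G%03d", 1:10)))
  p <- pathwayWilcoxon(vals, sets)$p
  expect_equal(p, 1 / choose(50, 10), tolerance = 1e-12)
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(4)
  vals <- make_values(300)
  member <- names(vals)[1:30]
  sets <- GeneSetList(list(S = member))
  p <- pathwayWilcoxon(vals, sets)$p
  ref <- oracle_wilcoxon_normal(vals[member], vals[setdiff(names(vals),
                                                           member)])
  expect_equal(p, ref, tolerance = 1e-6)
  # with ties
  vals_t <- round(vals, 1)
  p_t <- pathwayWilcoxon(vals_t, sets)$p
  ref_t <- oracle_wilcoxon_normal(vals_t[member],
                                  vals_t[setdiff(names(vals_t), member)])
  expect_equal(p_t, ref_t, tolerance = 1e-6)
})

test_that("sets below the 10-targeted-gene cutoff are excluded with a reason", {
  vals <- make_values(100)
  sets <- GeneSetList(list(small = names(vals)[1:9],
                           ok = names(vals)[10:29]))
  res <- pathwayWilcoxon(vals, sets)
  expect_true(res$excluded[res$set_id == "small"])
  expect_match(res$reason[res$set_id == "small"], "fewer than 10")
  expect_true(is.na(res$p[res$set_id == "small"]))
  expect_false(res$excluded[res$set_id == "ok"])
  # membership counts only targeted (scored) genes
  sets2 <- GeneSetList(list(S = c(names(vals)[1:9], "NOT_A_GENE")))
  expect_true(pathwayWilcoxon(vals, sets2)$excluded)
})

test_that("rank-1 p-values are uniform under the null", {
  set.seed(6)
  ps <- replicate(400, {
    vals <- stats::setNames(rnorm(120), sprintf("G%03d", 1:120))
    members <- sample(names(vals), 15)
    .subset2(pathwayWilcoxon(vals, GeneSetList(list(S = members))), "p")
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # empirical type-I error close to nominal
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("consolidated score sums -log10 p across ranks", {
  expect_equal(consolidatedScore(matrix(c(0.1, 0.01, 0.001), 1)), 6)
  expect_equal(consolidatedScore(matrix(c(1, 1, 1), 1)), 0)
  expect_true(is.na(consolidatedScore(matrix(NA_real_, 1, 3))))
  expect_equal(consolidatedScore(matrix(c(0.1, NA, 0.01), 1)), 3)
  expect_error(consolidatedScore(matrix(c(0, 0.5), 1)), "0, 1")
})

test_that("pathwayEnrichment scores a planted pathway above background sets", {
  set.seed(11)
  n_genes <- 400
  gsim <- simulateGeneSets(sprintf("G%03d", 1:n_genes), nSets = 30,
                           plantedSize = 25, seed = 11)
  rank_tbl <- data.frame(gene = sprintf("G%03d", 1:n_genes))
  base <- stats::setNames(stats::rnorm(n_genes), rank_tbl$gene)
  base[gsim$plantedGenes] <- base[gsim$plantedGenes] + 1.5
  for (k in 1:3)
    rank_tbl[[paste0("rank", k)]] <- base - (k - 1) * 0.3 +
      stats::rnorm(n_genes, sd = 0.2)
  res <- pathwayEnrichment(rank_tbl, gsim$sets)
  scored <- res[!res$excluded, ]
  expect_identical(scored$set_id[which.max(scored$consolidated_score)],
                   "PATHWAY_PLANTED")
  expect_true(all(res$excluded[grepl("SMALL", res$set_id)]))
  expect_true(all(scored$consolidated_score >= 0))
  # BH columns present and within [0, 1]
  expect_true(all(scored$padj_rank1 >= scored$p_rank1 - 1e-12))
})

test_that("screen-type combination sums consolidated scores and flags gaps", {
  ko <- data.frame(set_id = c("S1", "S2"), consolidated_score = c(2, 3))
  act <- data.frame(set_id = c("S1", "S3"), consolidated_score = c(1, 5))
  expect_message(cmb <- combinePathwayScreens(knockout = ko,
                                              activation = act),
                 "missing from some")
  expect_equal(cmb$consolidated_score[cmb$set_id == "S1"], 3)
  expect_equal(cmb$n_screen_types[cmb$set_id == "S2"], 1)
  expect_error(combinePathwayScreens(ko, act), "named")
})

test_that("pathway survival aggregation uses Fisher's method", {
  sets <- GeneSetList(list(one = "G001", several = c("G002", "G003"),
                           absent = "NOPE"))
  pr <- data.frame(set_id = c("one", "several", "absent"))
  cox <- data.frame(gene = c("G001", "G002", "G003"),
                    p = c(0.02, 0.5, 0.1))
  out <- pathwaySurvivalTable(pr, cox, sets)
  # single-gene aggregate equals that gene's p
  expect_equal(out$survival_p[out$set_id == "one"], 0.02, tolerance = 1e-12)
  stat <- -2 * (log(0.5) + log(0.1))
  expect_equal(out$fisher_chisq[out$set_id == "several"], stat)
  expect_equal(out$survival_p[out$set_id == "several"],
               pchisq(stat, 4, lower.tail = FALSE))
  expect_true(is.na(out$survival_p[out$set_id == "absent"]))
  expect_match(out$survival_reason[out$set_id == "absent"], "no member")

  # uniform member p-values: Fisher statistic calibrated as chi-square(2m)
  set.seed(13)
  stats_null <- replicate(500, -2 * sum(log(runif(5))))
  expect_gt(stats::ks.test(stats_null, "pchisq", df = 10)$p.value, 0.01)
})
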