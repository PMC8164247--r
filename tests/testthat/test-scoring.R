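test_that("CPM normalization matches closed forms and a brute-force oracle", {
  one <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(cpmNormalize(one, pseudocount = 0)[1, 1], 1e6)
  two <- matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(as.vector(cpmNormalize(two, pseudocount = 0)), c(5e5, 5e5))
  expect_error(cpmNormalize(matrix(0, 2, 1,
                                   dimnames = list(c("a", "b"), "s")),
                            pseudocount = 0), "all-zero")

  set.seed(11)
  m <- matrix(rpois(600, 40), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  expect_equal(cpmNormalize(m, 0.5), oracle_cpm(m, 0.5), tolerance = 1e-9)
  expect_equal(colSums(cpmNormalize(m, 0.5)), rep(1e6, 6),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("guide filter implements the 10/50 rule in all four count cells", {
  # four guides covering (control >=/< 10) x (treated >=/< 50)
  ctrl <- matrix(c(9, 9, 10, 200), 4, 1)
  trt <- matrix(c(49, 1000, 49, 60), 4, 1)
  se <- fixture_screen(ctrl, trt, genes = rep("A", 4))
  flt <- filterGuides(se, verbose = FALSE)
  # AND rule: only control < 10 AND treated < 50 is excluded; a strongly
  # enriched guide from a low baseline (9 -> 1000) is retained
  expect_identical(as.vector(flt$keep), c(FALSE, TRUE, TRUE, TRUE))
  flt_or <- filterGuides(se, logic = "or", verbose = FALSE)
  expect_identical(as.vector(flt_or$keep), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(flt$report$n_excluded, 1)
  expect_equal(flt$report$excluded_fraction, 0.25)
})

test_that("guide L2FC matches closed forms and is antisymmetric", {
  # equal library sizes in both arms so CPM leaves ratios untouched
  ctrl <- matrix(rep(c(100, 200, 100), 2), 3, 2)
  trt <- matrix(rep(c(400, 0, 0), 2), 3, 2)
  se <- fixture_screen(ctrl, trt, genes = c("A", "B", "B"))
  gfc <- guideLog2FC(se, pseudocount = 0, verbose = FALSE)
  # treated = 4x control in all replicates
  expect_equal(gfc@replicateMin["sg01", 1], 2)
  # identical treated and control columns give exactly 0
  se0 <- fixture_screen(ctrl, ctrl, genes = c("A", "B", "B"))
  gfc0 <- guideLog2FC(se0, verbose = FALSE)
  expect_true(all(gfc0@l2fc == 0))

  # swapping treated/control labels negates every per-replicate L2FC
  inst <- random_screen_instance(3, n_genes = 10, drugs = 1)
  sw <- sampleInfo(inst$se)
  sw$condition <- ifelse(sw$condition == "control", "treated", "control")
  sw$drug <- ifelse(sw$condition == "treated", "drug1", "")
  se_sw <- ScreenExperiment(counts(inst$se), guideInfo(inst$se), sw)
  a <- guideLog2FC(inst$se, controlMin = 0, treatedMin = 0, verbose = FALSE)
  b <- guideLog2FC(se_sw, controlMin = 0, treatedMin = 0, verbose = FALSE)
  expect_equal(unname(a@l2fc[, order(colnames(a@l2fc))]),
               unname(-b@l2fc[, order(colnames(b@l2fc))]),
               tolerance = 1e-12)
  # replicate-min becomes -(replicate-max)
  expect_equal(unname(a@replicateMin[, 1]),
               unname(-apply(b@l2fc, 1, max)),
               tolerance = 1e-12)
})

test_that("gene L2FC sum follows the top-two rule with deterministic ties", {
  # one gene, guide minima (3, 2, -1, -5) -> sum of top two = 5
  ctrl <- matrix(rep(100, 4), 4, 1)
  trt <- matrix(100 * 2^c(3, 2, -1, -5), 4, 1)
  se <- fixture_screen(ctrl, round(trt), genes = rep("A", 4))
  gs <- geneScores(guideLog2FC(se, pseudocount = 0, controlMin = 0,
                               treatedMin = 0, verbose = FALSE))
  # CPM renormalization shifts all guides by the same library-size factor
  shift <- 2 * log2(sum(ctrl) / sum(round(trt)))
  expect_equal(gs$l2fc_sum, 5 + shift, tolerance = 1e-6)
  expect_equal(gs$rank1 - gs$rank2, 1, tolerance = 1e-6)
  expect_identical(gs$guide1, "sg01")
  expect_identical(gs$guide2, "sg02")

  # all guides identical: ties broken lexicographically by guide id
  se_tie <- fixture_screen(matrix(rep(100, 3), 3, 1),
                           matrix(rep(200, 3), 3, 1), genes = rep("B", 3))
  gst <- geneScores(guideLog2FC(se_tie, pseudocount = 0, verbose = FALSE))
  expect_equal(gst$l2fc_sum, 2 * gst$rank1)
  expect_identical(gst$guide1, "sg01")
  expect_identical(gst$guide2, "sg02")

  # genes with < 2 surviving guides are NA-flagged, not scored
  se_na <- fixture_screen(matrix(c(100, 0, 0), 3, 1),
                          matrix(c(200, 0, 0), 3, 1),
                          genes = c("A", "A", "B"))
  gsn <- geneScores(guideLog2FC(se_na, verbose = FALSE))
  expect_true(is.na(gsn$l2fc_sum[gsn$gene == "A"]))  # 1 surviving guide
  expect_true(is.na(gsn$l2fc_sum[gsn$gene == "B"]))  # 0 surviving guides
  expect_identical(gsn$n_guides[gsn$gene == "B"], 0L)
})

test_that("top-2 sum equals brute-force maximum over guide pairs", {
  inst <- random_screen_instance(7, n_genes = 50, guides_per_gene = 5,
                                 drugs = 1, reps = 2)
  gfc <- guideLog2FC(inst$se, verbose = FALSE)
  gs <- geneScores(gfc)
  rm <- gfc@replicateMin[, 1]
  gd <- guideInfo(inst$se)
  for (gene in unique(gs$gene)) {
    v <- rm[gd$gene == gene]
    v <- v[!is.na(v)]
    expected <- if (length(v) >= 2)
      max(apply(utils::combn(length(v), 2), 2, function(ij) sum(v[ij])))
    else NA_real_
    expect_equal(gs$l2fc_sum[gs$gene == gene], expected, tolerance = 1e-12)
  }
})

test_that("full scoring chain equals the straight-line oracle exactly", {
  for (seed in 1:5) {
    inst <- random_screen_instance(seed, n_genes = 15, guides_per_gene = 3,
                                   cell_lines = 2, drugs = 2, reps = 2)
    res <- scoreScreen(inst$se, verbose = FALSE)
    orc <- oracle_score_screen(inst$counts, inst$guide_df, inst$sample_df)
    key <- function(d) paste(d$gene, d$cell_line, d$screen_type, d$drug)
    m <- match(key(orc$gene), key(res$gene_scores))
    expect_false(anyNA(m))
    expect_equal(res$gene_scores$l2fc_sum[m], orc$gene$l2fc_sum)
    expect_equal(res$gene_scores$rank1[m], orc$gene$rank1)
    expect_equal(res$gene_scores$rank3[m], orc$gene$rank3)
  }
})

test_that("multi-drug and cross-cell-line aggregation follow the stated rules", {
  gs <- expand.grid(gene = c("A", "B"), cell_line = c("L1", "L2"),
                    screen_type = "activation",
                    drug = paste0("d", 1:4), stringsAsFactors = FALSE)
  gs$l2fc_sum <- 4
  gs$rank1 <- gs$rank2 <- gs$rank3 <- 2
  gs$l2fc_sum[gs$gene == "B" & gs$cell_line == "L2"] <- c(1, 2, 3, 4)
  md <- multiDrugScores(gs)
  expect_equal(md$mean_l2fc_sum[md$gene == "A"], c(4, 4))
  expect_equal(md$mean_l2fc_sum[md$gene == "B" & md$cell_line == "L2"], 2.5)

  cc <- crossCellLineScores(md)
  expect_equal(cc$mean_across_lines[cc$gene == "B"], (4 + 2.5) / 2)
  expect_equal(cc$min_across_lines[cc$gene == "B"], 2.5)
  expect_equal(cc$min_across_lines[cc$gene == "A"], 4)

  # missing drug errors unless explicitly allowed
  gs3 <- gs[gs$drug != "d4", ]
  expect_error(multiDrugScores(gs3, drugs = paste0("d", 1:4)), "d4")
  expect_warning(md3 <- multiDrugScores(gs3, drugs = paste0("d", 1:4),
                                        allowMissing = TRUE), "missing")
  expect_equal(md3$mean_l2fc_sum[md3$gene == "A"], c(4, 4))

  # NA gene scores propagate unless allowMissing
  gs_na <- gs
  gs_na$l2fc_sum[gs_na$gene == "A" & gs_na$drug == "d1"] <- NA
  md_na <- multiDrugScores(gs_na)
  expect_true(all(is.na(md_na$mean_l2fc_sum[md_na$gene == "A"])))
})

test_that("increasing a contributing guide's treated counts never lowers the gene score", {
  set.seed(21)
  for (i in 1:10) {
    ctrl <- matrix(rpois(8, 150), 4, 2)
    trt <- matrix(rpois(8, 150), 4, 2)
    se <- fixture_screen(ctrl, trt, genes = rep("A", 4))
    gs <- geneScores(guideLog2FC(se, verbose = FALSE))
    g1 <- gs$guide1[1]
    trt2 <- trt
    trt2[match(g1, sprintf("sg%02d", 1:4)), ] <-
      trt2[match(g1, sprintf("sg%02d", 1:4)), ] + sample(1:200, 1)
    se2 <- fixture_screen(ctrl, trt2, genes = rep("A", 4))
    gs2 <- geneScores(guideLog2FC(se2, verbose = FALSE))
    expect_gte(gs2$l2fc_sum[1], gs$l2fc_sum[1] - 1e-12)
  }
})

test_that("pancdsWeights is the minimum across cell lines", {
  gs <- expand.grid(gene = c("A", "B"), cell_line = c("L1", "L2"),
                    screen_type = "activation", drug = "d1",
                    stringsAsFactors = FALSE)
  gs$l2fc_sum <- c(3, -1, 5, 2)   # A/L1, B/L1, A/L2, B/L2
  gs$rank1 <- gs$rank2 <- gs$rank3 <- 0
  w <- pancdsWeights(gs, drug = "d1")
  expect_equal(w, c(A = 3, B = -1))
  expect_error(pancdsWeights(gs, drug = "nope"), "no scores")
})
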