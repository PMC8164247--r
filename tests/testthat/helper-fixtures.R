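# In-code fixtures shared across test files.

# A screen with explicit counts: one cell line, one screen type, one
# drug, nReps replicates. `ctrl` and `trt` are guide x replicate count
# matrices (same rows).
fixture_screen <- function(ctrl, trt, genes,
                           guide_ids = sprintf("sg%02d", seq_len(nrow(ctrl))),
                           cell_line = "L1", screen_type = "activation",
                           drug = "drugA") {
  nrep <- ncol(ctrl)
  stopifnot(ncol(trt) == nrep, nrow(trt) == nrow(ctrl))
  sheet <- data.frame(
    sample_id = c(sprintf("ctrl_r%d", seq_len(nrep)),
                  sprintf("trt_r%d", seq_len(nrep))),
    cell_line = cell_line, screen_type = screen_type,
    condition = rep(c("control", "treated"), each = nrep),
    drug = rep(c("", drug), each = nrep),
    replicate = rep(seq_len(nrep), 2))
  counts <- cbind(ctrl, trt)
  colnames(counts) <- sheet$sample_id
  rownames(counts) <- guide_ids
  ScreenExperiment(counts, data.frame(guide_id = guide_ids, gene = genes),
                   sheet)
}

# Random multi-group screen instance built without the package simulator
# (independent input for oracle-equivalence checks).
random_screen_instance <- function(seed, n_genes = 30, guides_per_gene = 4,
                                   n_nt = 5, cell_lines = 1, drugs = 2,
                                   reps = 2) {
  set.seed(seed)
  genes <- c(rep(sprintf("G%03d", seq_len(n_genes)), each = guides_per_gene),
             rep(NONTARGETING, n_nt))
  n_guides <- length(genes)
  guide_ids <- sprintf("sg%04d", seq_len(n_guides))
  cls <- sprintf("CL%d", seq_len(cell_lines))
  drg <- sprintf("drug%d", seq_len(drugs))
  sheet <- expand.grid(replicate = seq_len(reps), drug = c("", drg),
                       cell_line = cls, stringsAsFactors = FALSE)
  sheet$screen_type <- "knockout"
  sheet$condition <- ifelse(sheet$drug == "", "control", "treated")
  sheet$sample_id <- sprintf("%s_%s_r%d", sheet$cell_line,
                             ifelse(sheet$drug == "", "ctrl", sheet$drug),
                             sheet$replicate)
  sheet <- sheet[, c("sample_id", "cell_line", "screen_type", "condition",
                     "drug", "replicate")]
  mu <- stats::rlnorm(n_guides, meanlog = log(200), sdlog = 1)
  counts <- matrix(stats::rnbinom(n_guides * nrow(sheet),
                                  mu = rep(mu, nrow(sheet)), size = 5),
                   n_guides, nrow(sheet),
                   dimnames = list(guide_ids, sheet$sample_id))
  se <- ScreenExperiment(counts,
                         data.frame(guide_id = guide_ids, gene = genes),
                         sheet)
  list(se = se, counts = counts,
       guide_df = data.frame(guide_id = guide_ids, gene = genes),
       sample_df = sheet)
}

# z-scored ExpressionMatrix built directly from a matrix of z values.
fixture_zscored <- function(z) ExpressionMatrix(z, state = "zscored")
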