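#' Simulation configuration for a synthetic pooled CRISPR screen
#'
#' Holds every knob of the synthetic screen generator. The defaults
#' reproduce the benchmark design used throughout the package: a
#' 2-cell-line x 4-drug x 3-replicate activation screen over 500 genes
#' with 6 guides per gene and 100 non-targeting controls, negative
#' binomial counts (variance mu + alpha mu^2) around log-normally skewed
#' guide abundances at 5e5 reads per sample, a global kill factor of 0.2
#' in treated samples (~80% cell death), and 10 planted resistance genes
#' carrying a +3 log2 enrichment in 2 of their 6 guides.
#'
#' @aliases SimConfig-class
#' @export
setClass("SimConfig",
         representation(seed = "numeric",
                        nGenes = "numeric",
                        guidesPerGene = "numeric",
                        nNontargeting = "numeric",
                        cellLines = "character",
                        screenTypes = "character",
                        drugs = "character",
                        replicates = "numeric",
                        librarySize = "numeric",
                        nbDispersion = "numeric",
                        baselineSigma = "numeric",
                        killFactor = "numeric",
                        plantedGenes = "data.frame",
                        plantedPathwayGenes = "character",
                        plantedPathwayEffect = "numeric",
                        plantedPathwayGuides = "numeric",
                        survivalBeta = "numeric",
                        censoringRate = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (object@guidesPerGene < 1) msg <- c(msg, "guidesPerGene must be >= 1")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (!length(object@cellLines)) msg <- c(msg, "need at least one cell line")
  if (!length(object@drugs)) msg <- c(msg, "need at least one drug")
  if (!all(object@screenTypes %in% c("knockout", "activation")))
    msg <- c(msg, "screenTypes must be knockout/activation")
  if (object@librarySize <= 0) msg <- c(msg, "librarySize must be positive")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be positive")
  if (object@baselineSigma < 0) msg <- c(msg, "baselineSigma must be >= 0")
  if (object@killFactor <= 0 || object@killFactor > 1)
    msg <- c(msg, "killFactor must be in (0, 1]")
  pg <- object@plantedGenes
  if (nrow(pg)) {
    if (!all(c("gene", "n_guides", "effect_log2") %in% colnames(pg)))
      msg <- c(msg, "plantedGenes needs columns gene, n_guides, effect_log2")
    else {
      if (any(!is.finite(pg$effect_log2)))
        msg <- c(msg, "planted effect sizes must be finite")
      if (any(pg$n_guides > object@guidesPerGene))
        msg <- c(msg, "planted n_guides cannot exceed guidesPerGene")
      if (anyDuplicated(pg$gene)) msg <- c(msg, "duplicate planted genes")
    }
  }
  if (!is.finite(object@plantedPathwayEffect))
    msg <- c(msg, "plantedPathwayEffect must be finite")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate must be in [0, 1)")
  if (abs(object@survivalBeta) >= 5)
    msg <- c(msg, "survivalBeta must satisfy |beta| < 5")
  if (length(msg)) msg else TRUE
})

#' Gene identifiers of the simulated library
#' @param config a [SimConfig-class]
#' @return character vector `gene0001`, `gene0002`, ...
#' @export
simGeneIds <- function(config) {
  sprintf("gene%04d", seq_len(config@nGenes))
}

#' Build a simulation configuration
#'
#' See [SimConfig-class] for the meaning of each parameter. By default 10
#' planted resistance genes (the first 10 gene ids) carry a +3 log2
#' enrichment effect in 2 of their guides in every drug and cell line;
#' pass `plantedGenes = NULL` for a null screen.
#'
#' @param seed integer seed used by the generators.
#' @param nGenes,guidesPerGene,nNontargeting library dimensions.
#' @param cellLines,screenTypes,drugs,replicates screen design.
#' @param librarySize expected reads per sample.
#' @param nbDispersion negative binomial dispersion alpha (Var = mu + alpha mu^2).
#' @param baselineSigma sdlog of the log-normal guide-abundance skew.
#' @param killFactor global scalar on treated-sample means (drug kill).
#' @param plantedGenes data.frame(gene, n_guides, effect_log2) or NULL.
#' @param plantedPathwayGenes,plantedPathwayEffect,plantedPathwayGuides
#'   optional planted pathway: member genes receive `plantedPathwayEffect`
#'   log2 enrichment in `plantedPathwayGuides` guides.
#' @param survivalBeta log hazard ratio per unit latent resistance.
#' @param censoringRate expected fraction of censored survival records.
#' @return a validated [SimConfig-class]
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 50, drugs = "gemcitabine",
#'                  cellLines = "line1", plantedGenes = NULL)
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 500,
                      guidesPerGene = 6,
                      nNontargeting = 100,
                      cellLines = c("line1", "line2"),
                      screenTypes = "activation",
                      drugs = c("gemcitabine", "fluorouracil",
                                "irinotecan", "oxaliplatin"),
                      replicates = 3,
                      librarySize = 5e5,
                      nbDispersion = 0.05,
                      baselineSigma = 0.8,
                      killFactor = 0.2,
                      plantedGenes = "default",
                      plantedPathwayGenes = character(),
                      plantedPathwayEffect = 0,
                      plantedPathwayGuides = 3,
                      survivalBeta = 1,
                      censoringRate = 0.3) {
  if (identical(plantedGenes, "default")) {
    k <- max(0, min(10, nGenes))
    plantedGenes <- data.frame(
      gene = sprintf("gene%04d", seq_len(k)),
      n_guides = rep(2, k), effect_log2 = rep(3, k))
  }
  if (is.null(plantedGenes))
    plantedGenes <- data.frame(gene = character(), n_guides = numeric(),
                               effect_log2 = numeric())
  new("SimConfig", seed = as.numeric(seed), nGenes = nGenes,
      guidesPerGene = guidesPerGene, nNontargeting = nNontargeting,
      cellLines = cellLines, screenTypes = screenTypes, drugs = drugs,
      replicates = replicates, librarySize = librarySize,
      nbDispersion = nbDispersion, baselineSigma = baselineSigma,
      killFactor = killFactor, plantedGenes = plantedGenes,
      plantedPathwayGenes = plantedPathwayGenes,
      plantedPathwayEffect = plantedPathwayEffect,
      plantedPathwayGuides = plantedPathwayGuides,
      survivalBeta = survivalBeta, censoringRate = censoringRate)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes x", object@guidesPerGene,
      "guides +", object@nNontargeting, "non-targeting;",
      length(object@cellLines), "cell line(s) x", length(object@drugs),
      "drug(s) x", object@replicates, "replicate(s);",
      nrow(object@plantedGenes), "planted gene(s)\n")
})

.sim_library <- function(config) {
  genes <- rep(simGeneIds(config), each = config@guidesPerGene)
  gnum <- rep(seq_len(config@guidesPerGene), config@nGenes)
  guide_id <- sprintf("%s_g%d", genes, gnum)
  if (config@nNontargeting > 0) {
    nt_id <- sprintf("NTC_%04d", seq_len(config@nNontargeting))
    guide_id <- c(guide_id, nt_id)
    genes <- c(genes, rep(NONTARGETING, config@nNontargeting))
  }
  data.frame(guide_id = guide_id, gene = genes)
}

#' Simulate a pooled CRISPR drug-resistance screen
#'
#' Control counts are negative binomial around `librarySize` x guide
#' abundance (log-normal skew, sdlog `baselineSigma`); treated counts use
#' the same abundances scaled by the global `killFactor` and, for planted
#' (gene, guide) pairs, by `2^effect_log2`. Because counts-per-million
#' normalization removes any per-sample scalar, the kill factor cancels
#' and the expected guide-level log2 fold change equals the planted
#' effect (0 for unplanted guides).
#'
#' @param config a [SimConfig-class].
#' @param seed overrides `config@seed` when given.
#' @return list with elements `se` (a [ScreenExperiment-class]) and
#'   `truth` (planted genes/guides, planted pathway, config echo).
#' @examples
#' sim <- simulateScreen(simConfig(seed = 7, nGenes = 40, nNontargeting = 10,
#'                                 cellLines = "line1", drugs = "gemcitabine"))
#' sim$se
#' head(sim$truth$planted_guides)
#' @export
simulateScreen <- function(config, seed = NULL) {
  set.seed(if (is.null(seed)) config@seed else seed)
  lib <- .sim_library(config)
  n_guides <- nrow(lib)
  abundance <- stats::rlnorm(n_guides, meanlog = 0, sdlog = config@baselineSigma)
  abundance <- abundance / sum(abundance)

  # per-guide multiplicative treatment effect (same in every drug/cell line)
  effect <- rep(0, n_guides)
  planted_guides <- data.frame(guide_id = character(), gene = character(),
                               effect_log2 = numeric())
  plant <- function(gene, n_eff, eff) {
    idx <- which(lib$gene == gene)
    if (!length(idx)) stop("planted gene not in library: ", gene)
    idx <- idx[seq_len(min(n_eff, length(idx)))]
    effect[idx] <<- effect[idx] + eff
    planted_guides <<- rbind(planted_guides,
                             data.frame(guide_id = lib$guide_id[idx],
                                        gene = gene, effect_log2 = eff))
  }
  pg <- config@plantedGenes
  for (i in seq_len(nrow(pg)))
    plant(pg$gene[i], pg$n_guides[i], pg$effect_log2[i])
  for (g in config@plantedPathwayGenes)
    plant(g, config@plantedPathwayGuides, config@plantedPathwayEffect)

  cd <- expand.grid(replicate = seq_len(config@replicates),
                    drug = c("", config@drugs),
                    screen_type = config@screenTypes,
                    cell_line = config@cellLines,
                    stringsAsFactors = FALSE)
  cd$condition <- ifelse(cd$drug == "", "control", "treated")
  cd$sample_id <- ifelse(
    cd$condition == "control",
    sprintf("%s_%s_ctrl_r%d", cd$cell_line, cd$screen_type, cd$replicate),
    sprintf("%s_%s_%s_r%d", cd$cell_line, cd$screen_type, cd$drug,
            cd$replicate))
  cd <- cd[, c("sample_id", "cell_line", "screen_type", "condition",
               "drug", "replicate")]

  base_mu <- config@librarySize * abundance
  mu <- matrix(base_mu, n_guides, nrow(cd))
  treated <- cd$condition == "treated"
  mu[, treated] <- mu[, treated] * config@killFactor * 2^effect
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / config@nbDispersion),
    n_guides, nrow(cd), dimnames = list(lib$guide_id, cd$sample_id))

  se <- ScreenExperiment(counts, lib, cd)
  truth <- list(planted_genes = pg,
                planted_guides = planted_guides,
                planted_pathway_genes = config@plantedPathwayGenes,
                planted_pathway_effect = config@plantedPathwayEffect,
                config = config)
  list(se = se, truth = truth)
}

#' Simulate an expression cohort tied to a latent resistance phenotype
#'
#' Each sample carries a latent resistance phenotype r ~ N(0, 1). On the
#' log2 scale, gene g in sample s has value
#' `b_g + signal * r_s * sign(w_g) + noise` where `w_g` is the supplied
#' weight (only its sign and non-zeroness matter here); values are
#' exponentiated to a non-negative expression scale. Genes with zero
#' weight carry no phenotype signal.
#'
#' @param genes character vector of gene symbols for the matrix rows.
#' @param weights named numeric vector; names are a subset of `genes`.
#'   Genes absent from `weights` get weight 0.
#' @param nSamples number of cohort samples.
#' @param signal coupling strength c between phenotype and weighted genes.
#' @param noiseSd per-gene log2 noise standard deviation.
#' @param baselineMean,baselineSd distribution of per-gene log2 baselines.
#' @param seed RNG seed.
#' @return list(expr = [ExpressionMatrix-class] (state `raw_counts`),
#'   phenotype = named numeric latent resistance per sample)
#' @export
simulateExpression <- function(genes, weights, nSamples = 50, signal = 1,
                               noiseSd = 1, baselineMean = 6, baselineSd = 1.5,
                               seed = 1L) {
  set.seed(seed)
  w <- stats::setNames(rep(0, length(genes)), genes)
  if (length(weights)) {
    unknown <- setdiff(names(weights), genes)
    if (length(unknown))
      stop("weights for genes not in 'genes': ",
           paste(utils::head(unknown, 3), collapse = ", "))
    w[names(weights)] <- weights
  }
  r <- stats::rnorm(nSamples)
  names(r) <- sprintf("sample%03d", seq_len(nSamples))
  b <- stats::rnorm(length(genes), baselineMean, baselineSd)
  sig <- signal * sign(w)            # 0 for unweighted genes
  x <- outer(b, rep(1, nSamples)) + outer(sig, r) +
    matrix(stats::rnorm(length(genes) * nSamples, sd = noiseSd),
           length(genes), nSamples)
  values <- 2^x
  dimnames(values) <- list(genes, names(r))
  list(expr = ExpressionMatrix(values, state = "raw_counts"), phenotype = r)
}

#' Simulate survival times driven by a phenotype
#'
#' Event times are exponential with hazard
#' `baselineRate * exp(beta * phenotype)`. Censoring is independent
#' uniform on (0, tau), with tau solved numerically so that the expected
#' fraction of censored records equals `censoringRate`.
#'
#' @param phenotype numeric vector (one value per subject; names kept).
#' @param beta log hazard ratio per unit phenotype.
#' @param censoringRate expected censored fraction in `[0, 1)`.
#' @param baselineRate baseline hazard (events per day; default 1/365).
#' @param seed RNG seed.
#' @return data.frame(sample_id, time, event) with time in days > 0 and
#'   event 1 = death, 0 = censored.
#' @export
simulateSurvival <- function(phenotype, beta, censoringRate = 0,
                             baselineRate = 1 / 365, seed = 1L) {
  stopifnot(abs(beta) < 5, censoringRate >= 0, censoringRate < 1)
  set.seed(seed)
  n <- length(phenotype)
  lambda <- baselineRate * exp(beta * phenotype)
  t_event <- stats::rexp(n, rate = lambda)
  ids <- if (!is.null(names(phenotype))) names(phenotype)
         else sprintf("sample%03d", seq_len(n))
  if (censoringRate == 0) {
    return(data.frame(sample_id = ids, time = t_event, event = 1L))
  }
  # P(censored | lambda, tau) for C ~ U(0, tau): (1 - exp(-lambda tau)) / (lambda tau)
  pcens <- function(log_tau) {
    lt <- lambda * exp(log_tau)
    mean((1 - exp(-lt)) / lt) - censoringRate
  }
  log_tau <- stats::uniroot(pcens, interval = c(-20, 20) - log(baselineRate),
                            extendInt = "yes")$root
  cens <- stats::runif(n, 0, exp(log_tau))
  data.frame(sample_id = ids,
             time = pmin(t_event, cens),
             event = as.integer(t_event <= cens))
}

#' Simulate a gene-set collection with one planted set
#'
#' Draws `nSets` random sets with sizes uniform on `sizeRange`, plus
#' `nSmall` deliberately undersized sets (below the 10-gene scoring
#' cutoff, so the exclusion rule is exercised), plus one designated
#' planted set of size `plantedSize` whose id is returned in the
#' `planted` attribute-free element.
#'
#' @param genes gene universe to draw members from.
#' @param nSets number of random background sets.
#' @param sizeRange integer range of background set sizes.
#' @param nSmall number of undersized (size 5-9) sets to include.
#' @param plantedSize size of the planted set (0 to omit it).
#' @param seed RNG seed.
#' @return list(sets = [GeneSetList-class], planted = planted set id or
#'   NA, plantedGenes = its members)
#' @export
simulateGeneSets <- function(genes, nSets = 50, sizeRange = c(10, 50),
                             nSmall = 2, plantedSize = 30, seed = 1L) {
  set.seed(seed)
  sets <- list()
  planted_genes <- character()
  planted_id <- NA_character_
  if (plantedSize > 0) {
    planted_id <- "PATHWAY_PLANTED"
    planted_genes <- sample(genes, min(plantedSize, length(genes)))
    sets[[planted_id]] <- planted_genes
  }
  for (i in seq_len(nSets)) {
    sz <- sample(seq(sizeRange[1], min(sizeRange[2], length(genes))), 1)
    sets[[sprintf("PATHWAY_%03d", i)]] <- sample(genes, sz)
  }
  for (i in seq_len(nSmall)) {
    sz <- sample(5:9, 1)
    sets[[sprintf("PATHWAY_SMALL_%02d", i)]] <- sample(genes, sz)
  }
  list(sets = GeneSetList(sets), planted = planted_id,
       plantedGenes = planted_genes)
}

#' Simulate a dose-response curve
#'
#' Hill-type viability `1 / (1 + (dose / ic50)^hill)` relative to vehicle
#' (= 1), with optional Gaussian noise, floored at 0.
#'
#' @param ic50 half-maximal inhibitory concentration.
#' @param hill Hill slope (> 0).
#' @param doses ordered positive dose grid (default six-point serial
#'   dilution around `ic50`).
#' @param noiseSd viability noise standard deviation.
#' @param seed RNG seed.
#' @return data.frame(dose, viability)
#' @export
simulateDoseResponse <- function(ic50, hill, doses = ic50 * 4^(-3:2),
                                 noiseSd = 0, seed = 1L) {
  stopifnot(ic50 > 0, hill > 0, all(doses > 0), !is.unsorted(doses))
  set.seed(seed)
  v <- 1 / (1 + (doses / ic50)^hill)
  if (noiseSd > 0) v <- pmax(0, v + stats::rnorm(length(doses), sd = noiseSd))
  data.frame(dose = doses, viability = v)
}
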