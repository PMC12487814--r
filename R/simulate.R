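# Synthetic single-cell time series with known ground truth.
#
# Each (gene, cell type) is assigned a smooth temporal pattern on the
# log scale (flat, linear, sigmoid, pulse or sinusoid). A cell of type
# k with pseudotime tau gets per-gene logits
#   base_{g,k} + pattern_{g,k}(tau) + N(0, noiseSd)
# which are softmaxed into proportions; counts are Poisson with a
# log-normal library size. Within each (type, nominal time) block of
# n cells, pseudotimes are tau_c = t + rank(c) * pseudotimeStep, so
# neighboring cells differ by the configured step (0.002 day by
# default, i.e. a 0.198-day spread across 100 cells).

.PATTERNS <- c("flat", "linear", "sigmoid", "pulse", "sinusoid")

.pattern_table <- function(nGenes, nTypes, patterns = .PATTERNS) {
  df <- expand.grid(gene = seq_len(nGenes), type = seq_len(nTypes))
  m <- nrow(df)
  df$pattern <- sample(patterns, m, replace = TRUE)
  df$base <- rnorm(m, 0, 1)
  df$amp <- runif(m, 1.5, 2.5) * sample(c(-1, 1), m, replace = TRUE)
  df$center <- runif(m, 0.25, 0.75)
  df$freq <- sample(c(1, 1.5), m, replace = TRUE)
  df$phase <- runif(m, 0, 1)
  df
}

# pattern value at normalized time u in [0, 1] (vectorized over u)
.pattern_value <- function(row, u) {
  switch(as.character(row$pattern),
    flat = rep(0, length(u)),
    linear = row$amp * (u - 0.5),
    sigmoid = row$amp * (plogis((u - row$center) / 0.08) - 0.5),
    pulse = row$amp * exp(-(u - row$center)^2 / (2 * 0.12^2)),
    sinusoid = row$amp * sin(2 * pi * (row$freq * u + row$phase)),
    stop("unknown pattern"))
}

#' Evaluate a simulated gene's latent signal
#'
#' Returns the noise-free log-scale signal (base + pattern) of one
#' (gene, cell type) at the given pseudotimes, using a truth object
#' returned by the generators.
#'
#' @param truth the `truth` element of a [simulateRNA()] /
#'   [simulateMultimodal()] result.
#' @param gene,type gene and cell-type indices (1-based).
#' @param tau pseudotimes (days).
#' @return numeric vector of log-scale signals.
#' @export
simulatedSignal <- function(truth, gene, type, tau) {
  row <- truth$params[truth$params$gene == gene & truth$params$type == type, ]
  if (nrow(row) != 1) stop("unknown (gene, type)")
  row$base + .pattern_value(row, .norm_time(tau, truth$timeRange))
}

# normalized time in [0, 1]; a single-time-point design sits mid-range
.norm_time <- function(tau, timeRange) {
  span <- diff(timeRange)
  if (span == 0) rep(0.5, length(tau))
  else (tau - timeRange[1]) / span
}

.sim_logits <- function(ptab, nGenes, type, tau, timeRange, noiseSd) {
  u <- .norm_time(tau, timeRange)
  rows <- ptab[ptab$type == type, ]
  rows <- rows[order(rows$gene), ]
  sig <- vapply(seq_len(nGenes),
                function(g) rows$base[g] + .pattern_value(rows[g, ], u),
                numeric(length(u)))
  sig <- matrix(sig, nrow = length(u))      # cells x genes
  if (noiseSd > 0) sig <- sig + matrix(rnorm(length(sig), 0, noiseSd),
                                       nrow(sig), ncol(sig))
  sig
}

.sim_counts <- function(logits, lib) {
  p <- .softmax(logits)
  n <- nrow(p)
  cnt <- matrix(rpois(length(p), lambda = lib * p), n, ncol(p))
  Matrix::Matrix(t(cnt), sparse = TRUE)    # genes x cells
}

#' Simulate an scRNA-seq time series with known temporal patterns
#'
#' @param nCellTypes number of cell types (default 3).
#' @param nGenes number of genes (default 60).
#' @param timePoints nominal collection times, days
#'   (default 6.5 to 8.5 every 0.25).
#' @param cellsPerTypePerTime cells per (type, time) block (default 100).
#' @param noiseSd SD of the per-gene, per-cell Gaussian noise on the
#'   log-signal scale (the two study regimes use 3 with no pseudotime
#'   spread, and 1 with 0.002-day steps).
#' @param pseudotimeStep pseudotime gap between neighboring cells
#'   within a block, days (default 0.002).
#' @param libMeanLog,libSdLog log-normal library-size parameters.
#' @param patterns pattern families to draw from (default all five:
#'   flat, linear, sigmoid, pulse, sinusoid).
#' @param seed integer seed; output is bit-identical given the seed.
#' @return list with `data` (a [TemporalProfiles-class] carrying
#'   cell-type labels) and `truth` (pattern table, per-cell
#'   pseudotimes, time range, config).
#' @export
simulateRNA <- function(nCellTypes = 3, nGenes = 60,
                        timePoints = seq(6.5, 8.5, by = 0.25),
                        cellsPerTypePerTime = 100, noiseSd = 1,
                        pseudotimeStep = 0.002,
                        libMeanLog = log(1500), libSdLog = 0.3,
                        patterns = .PATTERNS, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ptab <- .pattern_table(nGenes, nCellTypes, patterns)
  timeRange <- range(timePoints)
  blocks <- list(); meta <- list(); tau_all <- list()
  for (k in seq_len(nCellTypes)) for (t in timePoints) {
    n <- cellsPerTypePerTime
    tau <- t + (seq_len(n) - 1) * pseudotimeStep
    logits <- .sim_logits(ptab, nGenes, k, tau, timeRange, noiseSd)
    lib <- rlnorm(n, libMeanLog, libSdLog)
    blocks[[length(blocks) + 1]] <- .sim_counts(logits, lib)
    meta[[length(meta) + 1]] <- data.frame(time = t, type = k, n = n)
    tau_all[[length(tau_all) + 1]] <- tau
  }
  counts <- do.call(cbind, blocks)
  md <- do.call(rbind, meta)
  rownames(counts) <- sprintf("gene%d", seq_len(nGenes))
  colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
  tau <- unlist(tau_all)
  names(tau) <- colnames(counts)
  data <- TemporalProfiles(counts,
    time = rep(md$time, md$n),
    condition = "none", batch = "batch1",
    cellType = sprintf("type%d", rep(md$type, md$n)),
    modality = "rna")
  list(data = data,
       truth = list(params = ptab, pseudotime = tau, timeRange = timeRange,
                    config = list(nCellTypes = nCellTypes, nGenes = nGenes,
                                  timePoints = timePoints,
                                  cellsPerTypePerTime = cellsPerTypePerTime,
                                  noiseSd = noiseSd,
                                  pseudotimeStep = pseudotimeStep,
                                  seed = seed)))
}

#' Simulate a sex-structured scRNA-seq time series
#'
#' Time points are sampled in alternating single sexes (mimicking
#' whole-embryo collections where each embryo has one sex), except at
#' `sharedTimes` where both sexes are sampled. A multiplicative
#' fold-change effect on `nEffectGenes` genes is applied to the
#' designated sex.
#'
#' @inheritParams simulateRNA
#' @param nEffectGenes number of sex-effect genes (default 10% of
#'   genes, at least 1).
#' @param logFC log fold change added to effect-gene logits in
#'   `effectSex` (default log(2)).
#' @param effectSex which sex carries the effect (default "f").
#' @param effectGeneBias `"random"` (default) samples effect genes
#'   uniformly; `"low"` samples them from the half of genes with
#'   below-median baseline expression, keeping the compositional
#'   footprint of the effect on the remaining genes' fractions small
#'   (relevant for small gene panels; with genome-scale panels the
#'   footprint is negligible either way).
#' @param sharedTimes time points sampled in both sexes (default: the
#'   middle time point).
#' @return list with `data` (condition = "f"/"m") and `truth`
#'   (including `effectGenes`).
#' @export
simulateSex <- function(nCellTypes = 2, nGenes = 60,
                        timePoints = seq(6.5, 8.5, by = 0.25),
                        cellsPerTypePerTime = 100, noiseSd = 1,
                        pseudotimeStep = 0.002, nEffectGenes = NULL,
                        logFC = log(2), effectSex = "f",
                        effectGeneBias = c("random", "low"),
                        sharedTimes = NULL,
                        libMeanLog = log(1500), libSdLog = 0.3, seed = 1) {
  effectGeneBias <- match.arg(effectGeneBias)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(nEffectGenes)) nEffectGenes <- max(1L, round(0.1 * nGenes))
  if (is.null(sharedTimes))
    sharedTimes <- timePoints[ceiling(length(timePoints) / 2)]
  ptab <- .pattern_table(nGenes, nCellTypes)
  pool <- if (effectGeneBias == "low") {
    base_mean <- tapply(ptab$base, ptab$gene, mean)
    as.integer(names(base_mean)[base_mean <= median(base_mean)])
  } else seq_len(nGenes)
  effectGenes <- sort(sample(pool, nEffectGenes))
  timeRange <- range(timePoints)
  sex_at <- rep(c("f", "m"), length.out = length(timePoints))
  blocks <- list(); time_v <- c(); sex_v <- c(); type_v <- c()
  for (k in seq_len(nCellTypes)) for (ti in seq_along(timePoints)) {
    t <- timePoints[ti]
    sexes <- if (t %in% sharedTimes) c("f", "m") else sex_at[ti]
    for (sx in sexes) {
      n <- cellsPerTypePerTime
      tau <- t + (seq_len(n) - 1) * pseudotimeStep
      logits <- .sim_logits(ptab, nGenes, k, tau, timeRange, noiseSd)
      if (sx == effectSex)
        logits[, effectGenes] <- logits[, effectGenes] + logFC
      lib <- rlnorm(n, libMeanLog, libSdLog)
      blocks[[length(blocks) + 1]] <- .sim_counts(logits, lib)
      time_v <- c(time_v, rep(t, n)); sex_v <- c(sex_v, rep(sx, n))
      type_v <- c(type_v, rep(k, n))
    }
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- sprintf("gene%d", seq_len(nGenes))
  colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
  data <- TemporalProfiles(counts, time = time_v, condition = sex_v,
                           batch = "batch1",
                           cellType = sprintf("type%d", type_v),
                           modality = "rna")
  list(data = data,
       truth = list(params = ptab, effectGenes = effectGenes,
                    logFC = logFC, effectSex = effectSex,
                    timeRange = timeRange,
                    config = list(nCellTypes = nCellTypes, nGenes = nGenes,
                                  timePoints = timePoints,
                                  sharedTimes = sharedTimes,
                                  cellsPerTypePerTime = cellsPerTypePerTime,
                                  noiseSd = noiseSd,
                                  pseudotimeStep = pseudotimeStep,
                                  seed = seed)))
}

#' Simulate paired RNA + ATAC trajectories with programmed time lags
#'
#' RNA is simulated as in [simulateRNA()] over `rnaTimePoints`. Each of
#' the first `nLinkedPeaks` genes gets a linked peak whose accessibility
#' probability is a sigmoid of the gene's latent signal evaluated at
#' `tau - lag`: a negative lag means accessibility changes ahead of
#' expression ("before"), positive behind ("after"); the time-lagged
#' cross-correlation of (expression, accessibility) peaks at the lag.
#' ATAC cells are coassays drawn at `atacTimePoints` (a subset of the
#' RNA time points) from the same simulated cells, yielding a
#' one-to-one pairing. Unlinked noise peaks have constant baseline
#' accessibility. Synthetic TSS/peak coordinates placing each linked
#' peak 50 kb upstream of its gene are included for proximity mapping.
#'
#' @inheritParams simulateRNA
#' @param rnaTimePoints RNA collection times (default 6.5 to 8.75 every
#'   0.25: 10 time points).
#' @param atacTimePoints ATAC/coassay collection times (default 7.5, 8,
#'   8.5, 8.75).
#' @param nLinkedPeaks number of genes with linked peaks (default
#'   half the genes).
#' @param peaksPerGene linked peaks per gene (default 1); all peaks of
#'   a gene share its lag and read the same shifted signal through
#'   independent Bernoulli draws.
#' @param lags programmed lags in days, recycled across linked peaks
#'   (positive = accessibility follows expression); must lie within
#'   +/- 0.4 day so the default shift grid can recover them.
#' @param nNoisePeaks unlinked peaks with constant baseline
#'   accessibility.
#' @param accGain,accBase slope and intercept mapping the latent signal
#'   to accessibility logits.
#' @param identitySd,identityDim per-cell identity component: each
#'   cell draws a latent identity vector of dimension `identityDim`
#'   (default 3) with SD `identitySd` (default 0.5), mapped onto gene
#'   logits through a fixed random loading matrix. The same per-gene
#'   offset shifts the cell's linked peaks' accessibility logits, so
#'   coassay partners share a low-dimensional cell identity -- the
#'   heterogeneity cross-modality alignment exploits. Constant in
#'   time, so programmed lags are unaffected.
#' @return list with `rna`, `atac` ([TemporalProfiles-class]),
#'   `pairing` (data.frame), and `truth` (pattern table, per-peak lag
#'   table, synthetic `tss` and `peaks` coordinate tables, config).
#' @export
simulateMultimodal <- function(nCellTypes = 2, nGenes = 40,
                               rnaTimePoints = seq(6.5, 8.75, by = 0.25),
                               atacTimePoints = c(7.5, 8, 8.5, 8.75),
                               cellsPerTypePerTime = 100, noiseSd = 1,
                               pseudotimeStep = 0.002,
                               nLinkedPeaks = NULL, peaksPerGene = 1,
                               lags = c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3),
                               nNoisePeaks = 10, accGain = 1.5, accBase = 0,
                               identitySd = 0.5, identityDim = 3,
                               libMeanLog = log(1500), libSdLog = 0.3,
                               patterns = .PATTERNS, seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (any(abs(lags) > 0.4))
    stop("programmed lags must lie within +/- 0.4 day")
  if (!all(atacTimePoints %in% rnaTimePoints))
    stop("atacTimePoints must be a subset of rnaTimePoints")
  if (is.null(nLinkedPeaks)) nLinkedPeaks <- floor(nGenes / 2)
  ptab <- .pattern_table(nGenes, nCellTypes, patterns)
  # lag identification needs time-varying signals: linked genes get
  # non-flat patterns
  linked <- seq_len(nLinkedPeaks)
  idx <- ptab$gene %in% linked & ptab$pattern == "flat"
  ptab$pattern[idx] <- if ("sinusoid" %in% patterns) "sinusoid" else "sigmoid"
  nLP <- nLinkedPeaks * peaksPerGene
  lagTable <- data.frame(peak = seq_len(nLP),
                         gene = rep(linked, each = peaksPerGene),
                         lag = rep(rep_len(lags, nLinkedPeaks),
                                   each = peaksPerGene))
  timeRange <- range(rnaTimePoints)
  nPeaks <- nLP + nNoisePeaks
  identityLoadings <- matrix(rnorm(nGenes * identityDim), identityDim,
                             nGenes) / sqrt(identityDim)
  rblocks <- list(); ablocks <- list()
  rmeta <- list(); ameta <- list()
  pair_r <- c(); pair_a <- c()
  cellno <- 0
  for (k in seq_len(nCellTypes)) for (t in rnaTimePoints) {
    n <- cellsPerTypePerTime
    tau <- t + (seq_len(n) - 1) * pseudotimeStep
    logits <- .sim_logits(ptab, nGenes, k, tau, timeRange, noiseSd)
    u <- matrix(rnorm(n * identityDim, 0, identitySd), n, identityDim)
    ident <- u %*% identityLoadings
    logits <- logits + ident
    lib <- rlnorm(n, libMeanLog, libSdLog)
    rblocks[[length(rblocks) + 1]] <- .sim_counts(logits, lib)
    ids <- sprintf("rna_c%d", cellno + seq_len(n))
    rmeta[[length(rmeta) + 1]] <- data.frame(id = ids, time = t, type = k)
    if (t %in% atacTimePoints) {
      # coassay: same cells, accessibility from the lag-shifted signal
      u_shift <- function(lag) .norm_time(tau - lag, timeRange)
      probs <- matrix(0, n, nPeaks)
      rows_k <- ptab[ptab$type == k, ]
      rows_k <- rows_k[order(rows_k$gene), ]
      for (p in seq_len(nLP)) {
        row <- rows_k[lagTable$gene[p], ]
        patt <- .pattern_value(row, u_shift(lagTable$lag[p]))
        probs[, p] <- plogis(accBase +
                               accGain * (patt + ident[, lagTable$gene[p]]))
      }
      if (nNoisePeaks > 0)
        probs[, nLP + seq_len(nNoisePeaks)] <- 0.1
      acc <- matrix(rbinom(length(probs), 1, probs), n, nPeaks)
      ablocks[[length(ablocks) + 1]] <- Matrix::Matrix(t(acc), sparse = TRUE)
      aids <- sub("^rna_", "atac_", ids)
      ameta[[length(ameta) + 1]] <- data.frame(id = aids, time = t, type = k)
      pair_r <- c(pair_r, ids); pair_a <- c(pair_a, aids)
    }
    cellno <- cellno + n
  }
  rmd <- do.call(rbind, rmeta); amd <- do.call(rbind, ameta)
  rcounts <- do.call(cbind, rblocks)
  rownames(rcounts) <- sprintf("gene%d", seq_len(nGenes))
  colnames(rcounts) <- rmd$id
  acounts <- do.call(cbind, ablocks)
  rownames(acounts) <- sprintf("peak%d", seq_len(nPeaks))
  colnames(acounts) <- amd$id
  rna <- TemporalProfiles(rcounts, time = rmd$time, condition = "none",
                          batch = "batch1",
                          cellType = sprintf("type%d", rmd$type),
                          modality = "rna")
  atac <- TemporalProfiles(acounts, time = amd$time, condition = "none",
                           batch = "atac_batch1",
                           cellType = sprintf("type%d", amd$type),
                           modality = "atac")
  keep <- pair_r %in% colnames(rna) & pair_a %in% colnames(atac)
  pairing <- data.frame(rna_cell_id = pair_r[keep],
                        atac_cell_id = pair_a[keep],
                        stringsAsFactors = FALSE)
  # synthetic coordinates: genes 1 Mb apart on chr1, + strand, linked
  # peak 50 kb upstream of its gene's TSS
  tss <- data.frame(chrom = "chr1",
                    position = 1e6 * seq_len(nGenes), strand = "+",
                    gene_id = sprintf("gene%d", seq_len(nGenes)))
  peaks <- data.frame(chrom = "chr1",
                      start = 1e6 * lagTable$gene - 50500 -
                        1500 * (seq_len(nLP) %% peaksPerGene),
                      end = 1e6 * lagTable$gene - 49500 -
                        1500 * (seq_len(nLP) %% peaksPerGene),
                      peak_id = sprintf("peak%d", seq_len(nLP)))
  if (nNoisePeaks > 0) {
    # noise peaks far from any gene's upstream window
    peaks <- rbind(peaks, data.frame(
      chrom = "chr2", start = 1e6 * seq_len(nNoisePeaks),
      end = 1e6 * seq_len(nNoisePeaks) + 1000,
      peak_id = sprintf("peak%d", nLP + seq_len(nNoisePeaks))))
  }
  list(rna = rna, atac = atac, pairing = pairing,
       truth = list(params = ptab, lagTable = lagTable, tss = tss,
                    peaks = peaks, timeRange = timeRange,
                    config = list(nCellTypes = nCellTypes, nGenes = nGenes,
                                  rnaTimePoints = rnaTimePoints,
                                  atacTimePoints = atacTimePoints,
                                  cellsPerTypePerTime = cellsPerTypePerTime,
                                  noiseSd = noiseSd,
                                  pseudotimeStep = pseudotimeStep,
                                  nLinkedPeaks = nLinkedPeaks,
                                  nNoisePeaks = nNoisePeaks,
                                  peaksPerGene = peaksPerGene,
                                  accGain = accGain, accBase = accBase,
                                  identitySd = identitySd,
                                  identityDim = identityDim,
                                  seed = seed)))
}

#' Named simulation presets
#'
#' The two single-modality study regimes, plus the sex and multimodal
#' fixtures: `"sim-noise3"` (noise SD 3, no pseudotime spread),
#' `"sim-pseudotime"` (noise SD 1, 0.002-day neighbor steps),
#' `"sex"` (alternating-sex design with 2-fold effect genes) and
#' `"multimodal"` (paired RNA/ATAC with programmed lags). The held-out
#' evaluation time points for the single-modality regimes are 6.75,
#' 7.25, 7.75 and 8.25.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return list with `generator` (function), `args`, and
#'   `holdoutTimes` where applicable. Run with
#'   `do.call(p$generator, c(p$args, seed = seed))`.
#' @export
simulationPreset <- function(name = c("sim-noise3", "sim-pseudotime",
                                      "sex", "multimodal"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    "sim-noise3" = list(generator = simulateRNA,
                        args = list(noiseSd = 3, pseudotimeStep = 0),
                        holdoutTimes = c(6.75, 7.25, 7.75, 8.25),
                        seed = seed),
    "sim-pseudotime" = list(generator = simulateRNA,
                            args = list(noiseSd = 1, pseudotimeStep = 0.002),
                            holdoutTimes = c(6.75, 7.25, 7.75, 8.25),
                            seed = seed),
    "sex" = list(generator = simulateSex, args = list(), seed = seed),
    "multimodal" = list(generator = simulateMultimodal, args = list(),
                        seed = seed))
}
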