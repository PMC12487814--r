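# Shared fixtures and trained models, built once per test run and
# cached across test files (training is the expensive part; every
# consumer reuses the same object).

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small, fast simulation + model for interface-level tests
tiny_sim <- function() cache_get("tiny_sim", function() {
  simulateRNA(nCellTypes = 2, nGenes = 20, timePoints = c(7, 7.5, 8),
              cellsPerTypePerTime = 30, noiseSd = 0.5, seed = 3)
})

tiny_model <- function() cache_get("tiny_model", function() {
  trainTemporalVAE(tiny_sim()$data, latentDim = 8, timeDim = 10,
                   maxEpochs = 30, patience = 30, seed = 2)
})

# main single-modality fixture: the pseudotime regime (noise SD 1,
# 0.002-day neighbor steps, 100 cells per block)
rna_fixture <- function() cache_get("rna_fixture", function() {
  simulateRNA(nCellTypes = 3, nGenes = 60,
              timePoints = seq(6.5, 8.5, by = 0.25),
              cellsPerTypePerTime = 100, noiseSd = 1,
              pseudotimeStep = 0.002, seed = 11)
})

rna_model_holdout <- function(h) {
  cache_get(paste0("rna_model_", h), function() {
    trainTemporalVAE(rna_fixture()$data, holdoutTimes = h,
                     maxEpochs = 120, patience = 12, seed = 5)
  })
}

# sex fixture: 120-gene panel, 2-fold effect on 5 low-expressed genes
sex_fixture <- function() cache_get("sex_fixture", function() {
  simulateSex(nCellTypes = 2, nGenes = 120,
              timePoints = seq(6.5, 8.5, by = 0.25),
              cellsPerTypePerTime = 100, noiseSd = 1,
              pseudotimeStep = 0.002, nEffectGenes = 5, logFC = log(2),
              effectGeneBias = "low", seed = 41)
})

sex_model <- function() cache_get("sex_model", function() {
  trainTemporalVAE(sex_fixture()$data, maxEpochs = 120, patience = 12,
                   seed = 9)
})

sex_scores <- function() cache_get("sex_scores", function() {
  sexBiasedScores(sex_model(), sex_fixture()$data, female = "f", male = "m")
})

# multimodal fixture with programmed lags (TLCC / direction checks)
mm_fixture <- function() cache_get("mm_fixture", function() {
  simulateMultimodal(nCellTypes = 2, nGenes = 40, cellsPerTypePerTime = 100,
                     rnaTimePoints = seq(6.5, 8.75, by = 0.25),
                     atacTimePoints = c(7.5, 8, 8.5, 8.75),
                     noiseSd = 0.2, identitySd = 0.5, identityDim = 3,
                     peaksPerGene = 3, accGain = 2.5, nNoisePeaks = 5,
                     lags = c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3), seed = 31)
})

mm_ensemble <- function() cache_get("mm_ensemble", function() {
  sim <- mm_fixture()
  lapply(1:5, function(i)
    trainMultimodal(sim$rna, sim$atac, sim$pairing, mseWeight = 100,
                    latentDim = 16, timeDim = 50, maxEpochs = 250,
                    patience = 25, seed = 10 + i,
                    rnaArgs = list(maxEpochs = 200, patience = 20)))
})

# direction-recovery fixture: monotone patterns so each peak has a
# well-defined temporal direction over the evaluation window, with one
# ATAC time point held out of training
mm_dir_case <- function() cache_get("mm_dir_case", function() {
  sim <- simulateMultimodal(nCellTypes = 2, nGenes = 40,
                            cellsPerTypePerTime = 100,
                            rnaTimePoints = seq(6.5, 8.75, by = 0.25),
                            atacTimePoints = c(7.5, 8, 8.5, 8.75),
                            noiseSd = 0.2, identitySd = 0.5,
                            identityDim = 3, peaksPerGene = 3,
                            accGain = 2.5, nNoisePeaks = 5,
                            lags = c(-0.2, -0.1, 0.1, 0.2),
                            patterns = c("linear", "sigmoid"), seed = 32)
  mm <- trainMultimodal(sim$rna, sim$atac, sim$pairing, mseWeight = 100,
                        holdoutTimes = 8, latentDim = 16, timeDim = 50,
                        maxEpochs = 250, patience = 25, seed = 13,
                        rnaArgs = list(maxEpochs = 200, patience = 20))
  list(sim = sim, mm = mm)
})

# small high-information coassay fixture for the mutual-NN alignment check
mnn_case <- function() cache_get("mnn_case", function() {
  sim <- simulateMultimodal(nCellTypes = 2, nGenes = 30,
                            cellsPerTypePerTime = 12,
                            rnaTimePoints = seq(7, 8.25, by = 0.25),
                            atacTimePoints = c(7.5, 8), noiseSd = 0.2,
                            identitySd = 2, identityDim = 8,
                            peaksPerGene = 16, accGain = 3, nNoisePeaks = 5,
                            libMeanLog = log(6000), seed = 21)
  mm <- trainMultimodal(sim$rna, sim$atac, sim$pairing, mseWeight = 1000,
                        latentDim = 16, timeDim = 50, maxEpochs = 1200,
                        patience = 1200, seed = 3,
                        rnaArgs = list(maxEpochs = 400, patience = 40,
                                       advWeight = 10))
  list(sim = sim, mm = mm)
})

# TLCC matrix + categorization from the ensemble around one query cell
tlcc_result <- function() cache_get("tlcc_result", function() {
  sim <- mm_fixture()
  pairs <- suppressWarnings(
    assignProximalPeaks(sim$truth$tss, sim$truth$peaks))
  q <- colnames(sim$rna)[timePoint(sim$rna) == 8.25][1]
  tl <- buildTLCCMatrix(mm_ensemble(), sim$rna, q, pairs)
  res <- filterAndCategorize(tl)
  lagmap <- setNames(sim$truth$lagTable$lag,
                     sprintf("peak%d", sim$truth$lagTable$peak))
  res$true_lag <- lagmap[res$peak_id]
  list(tlcc = tl, res = res, pairs = pairs, query = q)
})

# probe classifier accuracy (multinomial logistic via nnet)
probe_accuracy <- function(emb, labels, train_idx, test_idx) {
  df <- data.frame(y = factor(labels), emb)
  fit <- nnet::multinom(y ~ ., data = df[train_idx, ], trace = FALSE,
                        MaxNWts = 10000)
  mean(predict(fit, newdata = df[test_idx, ]) == df$y[test_idx])
}
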