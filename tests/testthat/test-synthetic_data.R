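test_that("generators are bit-identical under a fixed seed", {
  a <- simulateRNA(nCellTypes = 2, nGenes = 15, timePoints = c(7, 8),
                   cellsPerTypePerTime = 20, seed = 5)
  b <- simulateRNA(nCellTypes = 2, nGenes = 15, timePoints = c(7, 8),
                   cellsPerTypePerTime = 20, seed = 5)
  expect_identical(as.matrix(SummarizedExperiment::assay(a$data, "counts")),
                   as.matrix(SummarizedExperiment::assay(b$data, "counts")))
  expect_identical(a$truth$params, b$truth$params)
  c2 <- simulateRNA(nCellTypes = 2, nGenes = 15, timePoints = c(7, 8),
                    cellsPerTypePerTime = 20, seed = 6)
  expect_false(identical(
    as.matrix(SummarizedExperiment::assay(a$data, "counts")),
    as.matrix(SummarizedExperiment::assay(c2$data, "counts"))))
  # (suppress the zero-count-cell warning this tiny draw can produce)
  mm1 <- suppressWarnings(
    simulateMultimodal(nGenes = 10, cellsPerTypePerTime = 10, seed = 3))
  mm2 <- suppressWarnings(
    simulateMultimodal(nGenes = 10, cellsPerTypePerTime = 10, seed = 3))
  expect_identical(as.matrix(SummarizedExperiment::assay(mm1$atac, "counts")),
                   as.matrix(SummarizedExperiment::assay(mm2$atac, "counts")))
})

test_that("pseudotime spread matches the per-neighbor step", {
  sim <- simulateRNA(nCellTypes = 1, nGenes = 10, timePoints = 7,
                     cellsPerTypePerTime = 100, pseudotimeStep = 0.002,
                     seed = 2)
  tau <- sim$truth$pseudotime
  expect_equal(diff(range(tau)), 0.198)       # 99 x 0.002
  expect_equal(unique(round(diff(sort(tau)), 10)), 0.002)
  sim0 <- simulateRNA(nCellTypes = 1, nGenes = 10, timePoints = 7,
                      cellsPerTypePerTime = 50, pseudotimeStep = 0,
                      seed = 2)
  expect_equal(diff(range(sim0$truth$pseudotime)), 0)
})

test_that("empirical count proportions converge to the configured signal", {
  sim <- simulateRNA(nCellTypes = 1, nGenes = 12, timePoints = 7,
                     cellsPerTypePerTime = 10000, noiseSd = 0,
                     pseudotimeStep = 0, seed = 9)
  cts <- SummarizedExperiment::assay(sim$data, "counts")
  emp <- as.numeric(pseudobulk(cts))
  sig <- vapply(1:12, function(g) simulatedSignal(sim$truth, g, 1, 7),
                numeric(1))
  expected <- exp(sig) / sum(exp(sig))
  expect_lt(max(abs(emp - expected) / expected), 0.05)
})

test_that("flat patterns have time-constant signal", {
  sim <- simulateRNA(nCellTypes = 1, nGenes = 8, timePoints = c(7, 8),
                     cellsPerTypePerTime = 10, noiseSd = 0,
                     pseudotimeStep = 0, patterns = "flat", seed = 4)
  for (g in 1:8) {
    s <- simulatedSignal(sim$truth, g, 1, seq(7, 8, by = 0.1))
    expect_equal(diff(range(s)), 0)
  }
})

test_that("sex generator alternates sexes with shared time points and scales effects", {
  sim <- simulateSex(nCellTypes = 1, nGenes = 40, cellsPerTypePerTime = 400,
                     timePoints = seq(6.5, 8.5, 0.25), noiseSd = 0,
                     pseudotimeStep = 0, nEffectGenes = 3, logFC = log(2),
                     seed = 7)
  x <- sim$data
  tab <- table(timePoint(x), conditionLabel(x))
  both <- rownames(tab)[tab[, "f"] > 0 & tab[, "m"] > 0]
  expect_gte(length(both), 1)
  single <- rownames(tab)[xor(tab[, "f"] > 0, tab[, "m"] > 0)]
  expect_gt(length(single), 4)
  # at a shared time point, effect genes show about a 2-fold ratio
  t0 <- as.numeric(both[1])
  cts <- SummarizedExperiment::assay(x, "counts")
  f <- pseudobulk(cts[, timePoint(x) == t0 & conditionLabel(x) == "f"])
  m <- pseudobulk(cts[, timePoint(x) == t0 & conditionLabel(x) == "m"])
  eff <- sim$truth$effectGenes
  ratio <- (f / m)[eff]
  expect_equal(unname(ratio), rep(2, 3), tolerance = 0.15)
  # zero fold change leaves the sexes exchangeable
  sim0 <- simulateSex(nCellTypes = 1, nGenes = 40,
                      cellsPerTypePerTime = 400, noiseSd = 0,
                      pseudotimeStep = 0, nEffectGenes = 3, logFC = 0,
                      sharedTimes = 7, timePoints = c(7, 8), seed = 7)
  cts0 <- SummarizedExperiment::assay(sim0$data, "counts")
  sel <- timePoint(sim0$data) == 7
  f0 <- pseudobulk(cts0[, sel & conditionLabel(sim0$data) == "f"])
  m0 <- pseudobulk(cts0[, sel & conditionLabel(sim0$data) == "m"])
  expect_equal(unname(f0), unname(m0), tolerance = 0.1)
})

test_that("multimodal generator programs recoverable lags and binary peaks", {
  sim <- mm_fixture()
  acc <- SummarizedExperiment::assay(sim$atac, "counts")
  expect_true(all(acc@x %in% c(0, 1)))
  expect_true(all(sim$pairing$rna_cell_id %in% colnames(sim$rna)))
  expect_true(all(sim$pairing$atac_cell_id %in% colnames(sim$atac)))
  expect_true(all(timePoint(sim$atac) %in% timePoint(sim$rna)))
  expect_error(simulateMultimodal(nGenes = 10, lags = 0.45, seed = 1),
               "0.4")
  # the accessibility probability is a monotone transform of the
  # lag-shifted gene signal
  tr <- sim$truth
  gain <- tr$config$accGain
  grid <- seq(7.5, 9, by = 0.01)
  g <- tr$lagTable$gene[1]; lag <- tr$lagTable$lag[1]
  base <- tr$params$base[tr$params$gene == g & tr$params$type == 1]
  shifted <- simulatedSignal(tr, g, 1, grid - lag) - base
  prob <- plogis(gain * shifted)
  expect_equal(cor(prob, shifted, method = "spearman"), 1)
  # TLCC on the lag-shifted latent signal recovers each programmed lag
  # to grid precision
  for (p in seq_len(nrow(tr$lagTable))[1:6]) {
    g <- tr$lagTable$gene[p]; lag <- tr$lagTable$lag[p]
    e <- simulatedSignal(tr, g, 1, grid)
    a <- simulatedSignal(tr, g, 1, grid - lag)
    v <- tlccVector(e, a, grid)
    got <- seq(-0.5, 0.5, 0.01)[which.max(v)]
    expect_equal(got, lag, tolerance = 0.011)
  }
})

test_that("presets encode the two study regimes", {
  p3 <- simulationPreset("sim-noise3")
  expect_equal(p3$args$noiseSd, 3)
  expect_equal(p3$args$pseudotimeStep, 0)
  pp <- simulationPreset("sim-pseudotime")
  expect_equal(pp$args$noiseSd, 1)
  expect_equal(pp$args$pseudotimeStep, 0.002)
  expect_equal(pp$holdoutTimes, c(6.75, 7.25, 7.75, 8.25))
  out <- do.call(pp$generator, c(pp$args, list(nGenes = 8,
                                               cellsPerTypePerTime = 5,
                                               seed = 1)))
  expect_s4_class(out$data, "TemporalProfiles")
  expect_true(all(c("sex", "multimodal") %in%
                    eval(formals(simulationPreset)$name)))
})
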