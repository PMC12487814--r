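test_that("alignment loss identities hold", {
  z1 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("r", 1:8), NULL))
  expect_equal(alignmentLoss(z1, z1), 0)
  shift <- c(1, -2, 0.5, 0, 3)
  z2 <- sweep(z1, 2, shift, "+")
  expect_equal(alignmentLoss(z1, z2), sum(shift^2))
  pr <- data.frame(rna_cell_id = paste0("r", 1:8),
                   atac_cell_id = paste0("r", 8:1))
  rownames(z2) <- rownames(z1)
  expect_equal(alignmentLoss(z1, z2, pr),
               mean(rowSums((z1 - z2[8:1, ])^2)))
  expect_error(alignmentLoss(z1, z2[1:3, ]), "matching dimensions")
  expect_error(alignmentLoss(z1, z2, data.frame(rna_cell_id = "zz",
                                                atac_cell_id = "r1")),
               "unknown cell id")
})

test_that("multimodal training couples the models as specified", {
  case <- mnn_case()
  sim <- case$sim; mm <- case$mm
  # shared temporal interaction layer: bit-identical parameters
  expect_identical(mm@atac@params$inter, mm@rna@params$inter)
  # stepwise freezing: RNA parameters untouched by step 2
  rna_alone <- trainTemporalVAE(sim$rna, latentDim = 16, timeDim = 50,
                                maxEpochs = 400, patience = 40,
                                advWeight = 10, seed = 3)
  expect_identical(rna_alone@params$enc, mm@rna@params$enc)
  expect_identical(rna_alone@params$dec, mm@rna@params$dec)
  # losses on the fixture are finite and the training history decreased
  expect_lt(min(mm@atac@history$val_loss),
            mm@atac@history$val_loss[1])
  expect_error(trainMultimodal(sim$rna, sim$atac, sim$pairing[0, ]),
               "coassay")
})

test_that("coassay partners end up mutual nearest neighbors", {
  case <- mnn_case()
  zr <- encodeCells(case$mm@rna, case$sim$rna)$mean
  za <- encodeCells(case$mm@atac, case$sim$atac)$mean
  pr <- case$mm@pairing; np <- nrow(pr)
  d <- as.matrix(dist(rbind(zr[pr$rna_cell_id, ],
                            za[pr$atac_cell_id, ])))[1:np, np + (1:np)]
  mnn <- mean(vapply(seq_len(np), function(i)
    which.min(d[i, ]) == i && which.min(d[, i]) == i, logical(1)))
  expect_gte(mnn, 0.8)
})

test_that("atac loss rejects non-ATAC input and composes into the multimodal loss", {
  case <- mnn_case()
  sim <- case$sim; mm <- case$mm
  expect_error(atacLoss(mm@atac, sim$rna), "binarized ATAC")
  al <- atacLoss(mm@atac, sim$atac)
  zr <- encodeCells(mm@rna, sim$rna)$mean
  za <- encodeCells(mm@atac, sim$atac)$mean
  ml <- multimodalLoss(mm, sim$rna, sim$atac)
  expect_equal(ml,
               al + mm@mseWeight * alignmentLoss(zr, za, mm@pairing) +
                 translationLoss(mm, sim$rna, sim$atac,
                                 direction = "rna2atac") +
                 translationLoss(mm, sim$rna, sim$atac,
                                 direction = "atac2rna"))
  # the lambda = 0 limit removes the alignment term
  expect_equal(multimodalLoss(mm, sim$rna, sim$atac, mseWeight = 0),
               al + translationLoss(mm, sim$rna, sim$atac,
                                    direction = "rna2atac") +
                 translationLoss(mm, sim$rna, sim$atac,
                                 direction = "atac2rna"))
  # both translation directions are computable and above entropy floors
  expect_true(is.finite(translationLoss(mm, sim$rna, sim$atac,
                                        direction = "rna2atac")))
  expect_gte(translationLoss(mm, sim$rna, sim$atac,
                             direction = "rna2atac"), 0)
})

test_that("cross-modality predictions are probabilities, continuous in time", {
  case <- mnn_case()
  p1 <- predictCrossModality(case$mm, case$sim$rna, cells = 1:6,
                             tTarget = 7.8)
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- predictCrossModality(case$mm, case$sim$rna, cells = 1:6,
                             tTarget = 7.8 + 1e-4)
  expect_lt(max(abs(p1 - p2)), 1e-2)
})

test_that("held-out ATAC time: predicted direction statistic recovers truth", {
  case <- mm_dir_case()
  sim <- case$sim; mm <- case$mm
  ct <- cellType(sim$rna); tmr <- timePoint(sim$rna)
  tr <- sim$truth
  # ground truth from the generator: true accessibility probability
  # change of each linked peak between the held-out (8) and query (7.5)
  # time points, per cell type (identity offsets are zero-mean)
  true_change <- function(p, type) {
    g <- tr$lagTable$gene[p]; lag <- tr$lagTable$lag[p]
    base <- tr$params$base[tr$params$gene == g & tr$params$type == type]
    pr <- function(t) plogis(tr$config$accGain *
                               (simulatedSignal(tr, g, type, t - lag) - base))
    pr(8) - pr(7.5)
  }
  stats <- c(); labs <- c()
  for (k in seq_len(tr$config$nCellTypes)) {
    type <- sprintf("type%d", k)
    q <- colnames(sim$rna)[ct == type & tmr == 7.5]
    p8 <- predictCrossModality(mm, sim$rna, q, tTarget = 8)
    p75 <- predictCrossModality(mm, sim$rna, q, tTarget = 7.5)
    chg <- vapply(seq_len(nrow(tr$lagTable)), true_change, numeric(1),
                  type = k)
    keep <- which(abs(chg) > 0.05)
    st <- vapply(keep, function(j)
      as.numeric(pairedRankStatistic(p8[, j], p75[, j])), numeric(1))
    stats <- c(stats, st); labs <- c(labs, as.integer(chg[keep] > 0))
  }
  expect_gt(auroc(stats, labs), 0.7)
  expect_gte(mean((stats > 0.5) == (labs == 1)), 0.8)
})
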