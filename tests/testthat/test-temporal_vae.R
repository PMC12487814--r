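test_that("encoding is deterministic and identical cells coincide", {
  sim <- tiny_sim(); m <- tiny_model()
  x <- sim$data
  enc1 <- encodeCells(m, x, cells = 1:5)
  enc2 <- encodeCells(m, x, cells = 1:5)
  expect_identical(enc1, enc2)
  # duplicate a cell (same counts + metadata) -> same posterior
  cts <- SummarizedExperiment::assay(x, "counts")
  dup <- TemporalProfiles(cbind(cts[, c(1, 1)]), time = timePoint(x)[c(1, 1)],
                          condition = conditionLabel(x)[c(1, 1)],
                          batch = batchLabel(x)[c(1, 1)],
                          featureIds = rownames(x),
                          cellIds = c("a", "b"))
  e <- encodeCells(m, dup)
  expect_equal(e$mean[1, ], e$mean[2, ], ignore_attr = TRUE)
  expect_error(encodeCells(m, x[1:5, ]), "feature")
})

test_that("zero-count cells yield finite posteriors after depth guards", {
  m <- tiny_model(); sim <- tiny_sim()
  x <- sim$data
  cts <- SummarizedExperiment::assay(x, "counts")
  cts[, 1] <- 0
  expect_warning(
    x0 <- TemporalProfiles(cts, time = timePoint(x),
                           condition = conditionLabel(x),
                           batch = batchLabel(x), featureIds = rownames(x)),
    "zero total")
  expect_true(all(is.finite(encodeCells(m, x0)$mean)))
})

test_that("decoded profiles are simplex-valued and continuous in time", {
  m <- tiny_model(); x <- tiny_sim()$data
  p1 <- predictProfile(m, x, cells = 1:10, tTarget = 7.4)
  expect_true(all(p1 >= 0))
  expect_equal(unname(rowSums(p1)), rep(1, 10))
  p2 <- predictProfile(m, x, cells = 1:10, tTarget = 7.4 + 1e-4)
  expect_lt(max(rowSums(abs(p1 - p2))), 1e-2)
  # own time and condition equals the reconstruction path
  own <- predictProfile(m, x, cells = 1:10)
  own2 <- predictProfile(m, x, cells = 1:10,
                         tTarget = timePoint(x)[1:10],
                         conditionTarget = conditionLabel(x)[1:10])
  expect_equal(own, own2)
  expect_error(predictProfile(m, x, cells = 1:2, conditionTarget = "zz"),
               "not in level set")
})

test_that("loss identities: chance-level discriminator and generator arithmetic", {
  m <- tiny_model(); x <- tiny_sim()$data
  # zero the discriminator output layer -> uniform logits -> CE = log T
  m0 <- m
  nl <- length(m0@params$disc)
  m0@params$disc[[nl]]$W[] <- 0
  m0@params$disc[[nl]]$b[] <- 0
  expect_equal(discriminatorLoss(m0, x), log(length(m0@timeClasses)))
  # generator loss is exactly the difference of its two parts
  expect_equal(generatorLoss(m, x, cells = 1:50),
               rnaLoss(m, x, cells = 1:50) -
                 discriminatorLoss(m, x, cells = 1:50))
  # near-perfect logits drive CE toward zero
  tcl <- match(timePoint(x), m@timeClasses)
  ns <- asNamespace("chronocell")
  logits <- matrix(-50, ncol(x), length(m@timeClasses))
  logits[cbind(seq_len(ncol(x)), tcl)] <- 50
  P <- ns$.softmax(logits)
  expect_lt(-mean(log(P[cbind(seq_len(ncol(x)), tcl)])), 1e-6)
})

test_that("unseen time points have no discriminator class", {
  m <- tiny_model(); x <- tiny_sim()$data
  cts <- SummarizedExperiment::assay(x, "counts")[, 1:3]
  odd <- TemporalProfiles(cts, time = c(7, 7.5, 9.25),
                          condition = conditionLabel(x)[1:3],
                          batch = batchLabel(x)[1:3],
                          featureIds = rownames(x))
  expect_error(discriminatorLoss(m, odd), "unseen")
})

test_that("training reduces the objective and is seed-reproducible", {
  sim <- tiny_sim()
  m1 <- trainTemporalVAE(sim$data, latentDim = 8, timeDim = 10,
                         maxEpochs = 15, patience = 15, seed = 77)
  expect_lt(tail(m1@history$train_loss, 1), m1@history$train_loss[1])
  expect_true(all(is.finite(m1@history$train_loss)))
  expect_true(all(is.finite(m1@history$disc_loss)))
  m2 <- trainTemporalVAE(sim$data, latentDim = 8, timeDim = 10,
                         maxEpochs = 15, patience = 15, seed = 77)
  expect_equal(m1@history, m2@history, tolerance = 1e-12)
  expect_equal(m1@params, m2@params, tolerance = 1e-12)
  m3 <- trainTemporalVAE(sim$data, latentDim = 8, timeDim = 10,
                         maxEpochs = 15, patience = 15, seed = 78)
  expect_false(isTRUE(all.equal(m1@history$train_loss,
                                m3@history$train_loss)))
})

test_that("interpolation at a held-out midpoint respects monotone trends", {
  # noiseless linear-trend genes: the predicted fraction at the held-out
  # midpoint should lie between the fractions predicted at the flanks
  sim <- simulateRNA(nCellTypes = 1, nGenes = 30,
                     timePoints = seq(6.5, 8.5, by = 0.25),
                     cellsPerTypePerTime = 60, noiseSd = 0,
                     pseudotimeStep = 0, patterns = "linear", seed = 19)
  m <- trainTemporalVAE(sim$data, holdoutTimes = 7.25, latentDim = 16,
                        timeDim = 50, maxEpochs = 120, patience = 12,
                        seed = 6)
  x <- sim$data
  tm <- timePoint(x)
  frac_at <- function(t) {
    q <- which(tm == 7)[1:50]
    colMeans(predictProfile(m, x, cells = q, tTarget = t))
  }
  lo <- frac_at(7); mid <- frac_at(7.25); hi <- frac_at(7.5)
  between <- vapply(seq_len(30), function(g)
    (mid[g] >= pmin(lo[g], hi[g]) - 1e-4) &&
    (mid[g] <= pmax(lo[g], hi[g]) + 1e-4), logical(1))
  expect_gte(mean(between), 0.9)
})
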