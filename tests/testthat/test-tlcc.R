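test_that("neighbor selection reduces to top-k for one model and honors summed ranks", {
  set.seed(6)
  emb <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(sprintf("c%d", 1:60), NULL))
  got <- selectNeighbors(emb, "c1", kTop = 25, nKeep = 4)
  d <- sqrt(rowSums((emb - rep(emb["c1", ], each = 60))^2))
  plain <- names(sort(d[-1]))[1:4]
  expect_equal(got, c("c1", plain))
  # exact duplicates of the query come first
  emb2 <- rbind(emb, dup = emb["c1", ])
  expect_equal(selectNeighbors(emb2, "c1")[2], "dup")
  # consistent rankings across models reproduce the single-model answer
  perm_models <- lapply(1:10, function(i) emb[sample(nrow(emb)), ])
  expect_setequal(selectNeighbors(perm_models, "c1"), got)
  expect_error(selectNeighbors(emb, "zz"), "absent")
  expect_warning(selectNeighbors(emb[1:3, ], "c1", nKeep = 4), "eligible")
})

test_that("upstream peak-gene assignment is strand-aware and windowed", {
  tss <- data.frame(chrom = c("chr1", "chr1"), position = c(1e6, 2e6),
                    strand = c("+", "-"), gene_id = c("gp", "gm"))
  peaks <- data.frame(chrom = "chr1",
                      start = c(1e6 - 100000,   # 100 kb upstream of gp (+)
                                1e6 - 300000,   # 300 kb upstream: outside
                                2e6 + 100000,   # 100 kb upstream of gm (-)
                                2e6 - 100000),  # downstream of gm
                      end = NA, peak_id = c("p1", "p2", "p3", "p4"))
  peaks$end <- peaks$start + 500
  got <- assignProximalPeaks(tss, peaks, window = 200000)
  expect_setequal(paste(got$peak_id, got$gene_id),
                  c("p1 gp", "p3 gm"))
  expect_warning(
    assignProximalPeaks(tss, data.frame(chrom = "chrX", start = 1,
                                        end = 100, peak_id = "px")),
    "chrX")
})

test_that("TLCC vector matches a brute-force slice-and-correlate oracle", {
  grid <- seq(7.5, 9, by = 0.01)
  shifts <- seq(-0.5, 0.5, by = 0.01)
  core <- c(8, 8.5)
  oracle <- function(e, a) {
    vapply(shifts, function(s) {
      ti <- grid[grid >= core[1] & grid <= core[2]]
      ei <- e[match(round(ti, 10), round(grid, 10))]
      ai <- a[match(round(ti + s, 10), round(grid, 10))]
      if (sd(ei) == 0 || sd(ai) == 0) NA_real_ else cor(ei, ai)
    }, numeric(1))
  }
  set.seed(2)
  for (i in 1:5) {
    e <- cumsum(rnorm(length(grid)))
    a <- cumsum(rnorm(length(grid)))
    expect_equal(tlccVector(e, a, grid, shifts, core), oracle(e, a),
                 tolerance = 1e-12)
  }
  expect_length(tlccVector(sin(grid), cos(grid), grid), 101)
  # identical trajectories peak at zero shift with correlation one
  e <- sin(2 * pi * grid)
  v <- tlccVector(e, e, grid, shifts, core)
  expect_equal(v[shifts == 0], 1)
  expect_equal(which.max(v), which(shifts == 0))
  # acc(t) = expr(t + 0.1): accessibility leads, argmax at -0.1
  a2 <- sin(2 * pi * (grid + 0.1))
  v2 <- tlccVector(e, a2, grid, shifts, core)
  expect_equal(shifts[which.max(v2)], -0.1, tolerance = 1e-9)
  # constant window is recorded as missing
  expect_true(all(is.na(tlccVector(rep(1, length(grid)), e, grid,
                                   shifts, core))))
  expect_error(tlccVector(e, a2, grid, shifts = 0.005), "multiples")
  expect_error(tlccVector(e, a2, grid, coreWindow = c(7.4, 8)), "pad")
})

test_that("time reversal of both trajectories reverses the TLCC vector", {
  grid <- seq(7.5, 9, by = 0.01)
  shifts <- seq(-0.5, 0.5, by = 0.01)
  set.seed(14)
  e <- cumsum(rnorm(length(grid))); a <- cumsum(rnorm(length(grid)))
  fwd <- tlccVector(e, a, grid, shifts, c(8, 8.5))
  # reversed trajectories on the same grid; core maps to [8, 8.5] again
  rev_core <- c(7.5 + 9 - 8.5, 7.5 + 9 - 8)
  bwd <- tlccVector(rev(e), rev(a), grid, shifts, rev_core)
  expect_equal(bwd, rev(fwd), tolerance = 1e-12)
})

test_that("TLCC matrix has the prescribed shape and deterministic content", {
  sim <- mm_fixture()
  pairs3 <- suppressWarnings(
    assignProximalPeaks(sim$truth$tss, sim$truth$peaks))[1:3, ]
  q <- colnames(sim$rna)[timePoint(sim$rna) == 8.25][1]
  tl <- buildTLCCMatrix(mm_ensemble(), sim$rna, q, pairs3)
  expect_s4_class(tl, "TLCCMatrix")
  expect_equal(length(tl@shifts), 101)
  expect_equal(dim(tl@correlations), c(101, 15))  # 3 pairs x 5 cells
  expect_equal(nrow(tl@pairIndex), 15)
  tl2 <- buildTLCCMatrix(mm_ensemble(), sim$rna, q, pairs3)
  expect_identical(tl@correlations, tl2@correlations)
  expect_warning(empty <- buildTLCCMatrix(mm_ensemble(), sim$rna, q,
                                          pairs3[0, ]), "no .peak, gene.")
  expect_equal(ncol(empty@correlations), 0)
})

test_that("filtering drops weak or single-cell pairs and categorizes by sign", {
  shifts <- seq(-0.5, 0.5, by = 0.01)
  mk_col <- function(peak_at, height) height * cos(pi * (shifts - peak_at))
  cols <- cbind(mk_col(-0.2, 0.9), mk_col(-0.22, 0.8),  # pair A, 2 cells
                mk_col(0.3, 0.7),  mk_col(0.28, 0.9),   # pair B, 2 cells
                mk_col(0.1, 0.4),  mk_col(0.1, 0.45),   # pair C: too weak
                mk_col(-0.1, 0.9))                      # pair D: 1 cell
  idx <- data.frame(
    peak_id = c("pA", "pA", "pB", "pB", "pC", "pC", "pD"),
    gene_id = "g",
    cell_id = c("c1", "c2", "c1", "c2", "c1", "c2", "c1"))
  tl <- new("TLCCMatrix", shifts = shifts, correlations = cols,
            pairIndex = idx)
  res <- filterAndCategorize(tl, minMaxCorr = 0.5, minCells = 2)
  expect_setequal(res$peak_id, c("pA", "pB"))
  expect_equal(res$category[res$peak_id == "pA"], "before")
  expect_equal(res$category[res$peak_id == "pB"], "after")
  # discordant signs across cells are uncategorized
  cols2 <- cbind(mk_col(-0.2, 0.9), mk_col(0.2, 0.9))
  idx2 <- data.frame(peak_id = "pX", gene_id = "g",
                     cell_id = c("c1", "c2"))
  res2 <- filterAndCategorize(new("TLCCMatrix", shifts = shifts,
                                  correlations = cols2, pairIndex = idx2))
  expect_equal(res2$category, "uncategorized")
  # a best shift of exactly zero cannot be assigned a direction
  cols3 <- cbind(mk_col(0, 0.9), mk_col(0, 0.9))
  res3 <- filterAndCategorize(new("TLCCMatrix", shifts = shifts,
                                  correlations = cols3, pairIndex = idx2))
  expect_equal(res3$category, "uncategorized")
})

test_that("programmed lags are recovered end to end for most retained pairs", {
  out <- tlcc_result()
  res <- out$res
  expect_gt(nrow(res), 20)
  agree <- mean(sign(res$median_shift) == sign(res$true_lag))
  expect_gte(agree, 0.8)
  # categorized pairs agree with the programmed before/after class
  catd <- res[res$category != "uncategorized", ]
  expect_gte(mean((catd$category == "before") == (catd$true_lag < 0)), 0.75)
})
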