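test_that("sex-bias scores recover programmed effects and stay null elsewhere", {
  sim <- sex_fixture()
  tb <- sex_scores()
  agg <- tapply(tb$score, tb$gene, median)
  eff <- sprintf("gene%d", sim$truth$effectGenes)
  lab <- as.integer(names(agg) %in% eff)
  expect_gte(auroc(agg, lab), 0.9)
  expect_gt(min(agg[lab == 1]), 0.9)
  expect_lt(abs(mean(agg[lab == 0]) - 0.5), 0.05)
})

test_that("swapping the sex roles maps every score to its complement", {
  m <- sex_model(); x <- sex_fixture()$data
  sub <- x[, cellType(x) == "type1"]
  a <- sexBiasedScores(m, sub, female = "f", male = "m", window = FALSE)
  b <- sexBiasedScores(m, sub, female = "m", male = "f", window = FALSE)
  key <- paste(a$gene, a$cell_type, a$time)
  expect_identical(key, paste(b$gene, b$cell_type, b$time))
  expect_equal(a$score, 1 - b$score, tolerance = 1e-12)
})

test_that("scores are invariant to cell order and respect the cell floor", {
  m <- sex_model(); x <- sex_fixture()$data
  sub <- x[, which(cellType(x) == "type1" & timePoint(x) <= 7)]
  perm <- sample(ncol(sub))
  a <- sexBiasedScores(m, sub, window = FALSE)
  b <- sexBiasedScores(m, sub[, perm], window = FALSE)
  b <- b[order(match(paste(b$gene, b$time), paste(a$gene, a$time))), ]
  expect_equal(a$score, b$score, tolerance = 1e-12)
  # groups at or below the floor are skipped
  small <- x[, which(cellType(x) == "type1" & timePoint(x) == 6.5)[1:40]]
  expect_message(out <- sexBiasedScores(m, small, window = FALSE),
                 "skipping")
  expect_equal(nrow(out), 0)
  expect_error(sexBiasedScores(m, x, female = "nope"), "unseen")
})

test_that("consistent-bias calling applies the score and expression filters", {
  tb <- data.frame(gene = rep(c("g1", "g2", "g3", "g4"), 2),
                   cell_type = "ct", time = rep(c(1, 2), each = 4),
                   score = c(0.8, 0.6, 0.2, 0.9, 0.7, 0.4, 0.3, 0.8),
                   n_cells = 100,
                   log_fold_change = 0,
                   mean_expr = c(10, 1, 9, 0.1, 10, 1, 9, 0.1))
  out <- consistentSexBiasedGenes(tb)
  # top-half expression keeps g1 and g3; g1 stays above 0.5, g3 below
  expect_equal(out$female, "g1")
  expect_equal(out$male, "g3")
  # g2 flips across 0.5; g4 is female-consistent but fails the
  # expression filter
  expect_false(any(c("g2", "g4") %in% c(out$female, out$male)))
  expect_warning(res <- consistentSexBiasedGenes(tb[tb$n_cells > 1e6, ],
                                                 cellTypeName = "ct"),
                 "no retained")
  expect_length(res$female, 0)
})

test_that("gene-set shift test matches exact rank-sum enumeration", {
  exact_p <- function(down, up) {
    # P(rank-sum of 'down' >= observed) over all assignments
    pooled <- c(down, up)
    n <- length(pooled); k <- length(down)
    r <- rank(pooled)
    obs <- sum(r[seq_len(k)])
    combs <- combn(n, k)
    null <- colSums(matrix(r[combs], nrow = k))
    mean(null >= obs)
  }
  set.seed(8)
  for (i in 1:8) {
    scores <- rnorm(12)
    names(scores) <- sprintf("g%d", 1:12)
    down <- sprintf("g%d", 1:5); up <- sprintf("g%d", 6:12)
    expect_equal(genesetShiftTest(scores, setUp = up, setDown = down),
                 exact_p(scores[down], scores[up]), tolerance = 1e-10)
  }
  sc <- setNames(c(10, 9, 8, 1, 2, 3), sprintf("g%d", 1:6))
  p_sep <- genesetShiftTest(sc, setUp = c("g4", "g5", "g6"),
                            setDown = c("g1", "g2", "g3"))
  expect_equal(p_sep, 1 / choose(6, 3), tolerance = 1e-10)
  expect_error(genesetShiftTest(sc, "absent", "g1"), "intersect")
})

test_that("PPI odds-ratio permutation test behaves at the null and extremes", {
  set.seed(13)
  aut <- sprintf("a%d", 1:60); xg <- sprintf("x%d", 1:10)
  femA <- aut[1:12]
  # random edges: OR near 1, non-extreme p
  edges <- data.frame(gene1 = sample(aut, 400, replace = TRUE),
                      gene2 = sample(xg, 400, replace = TRUE))
  res <- ppiOddsRatio(edges, femA, xg, aut, nPerm = 100, seed = 2)
  expect_equal(res$status, "ok")
  expect_lt(abs(log(res$oddsRatio)), log(2.5))
  expect_gt(res$p, 0.05)
  # all edges concentrated on the female set: maximal OR, minimal p
  edges2 <- data.frame(gene1 = sample(femA, 120, replace = TRUE),
                       gene2 = sample(xg, 120, replace = TRUE))
  res2 <- ppiOddsRatio(edges2, femA, xg, aut, nPerm = 100, seed = 2)
  expect_equal(res2$p, 1 / 101)
  expect_gt(res2$oddsRatio, 10)
  # refusal below the interaction floor
  res3 <- ppiOddsRatio(edges[1:20, ], femA, xg, aut, nPerm = 100, seed = 2)
  expect_equal(res3$status, "refused")
  expect_true(is.na(res3$oddsRatio))
  expect_error(ppiOddsRatio(edges, c("zz"), xg, aut), "subset")
})

test_that("hypergeometric enrichment reduces to phyper", {
  uni <- sprintf("g%d", 1:100)
  expect_equal(hypergeometricTest(uni[1:10], uni[1:20], uni),
               phyper(9, 20, 80, 10, lower.tail = FALSE))
})
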