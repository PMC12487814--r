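#' Depth-normalized pseudobulk profile
#'
#' Every cell is scaled to unit total counts first, then the
#' proportion vectors are averaged, so the result is invariant to
#' per-cell sequencing depth and sums to 1. Zero-depth cells are
#' excluded with a warning.
#'
#' @param cells features x cells matrix (dense or sparse), or a
#'   [TemporalProfiles-class].
#' @return named numeric vector of feature proportions (sums to 1).
#' @examples
#' pseudobulk(cbind(c(2, 0), c(0, 2)))  # 0.5 0.5
#' @export
pseudobulk <- function(cells) {
  m <- if (methods::is(cells, "TemporalProfiles"))
    SummarizedExperiment::assay(cells, "counts") else cells
  m <- methods::as(m, "CsparseMatrix")
  depth <- Matrix::colSums(m)
  if (any(depth == 0)) {
    warning(sprintf("excluding %d zero-depth cell(s) from pseudobulk",
                    sum(depth == 0)))
    m <- m[, depth > 0, drop = FALSE]
    depth <- depth[depth > 0]
  }
  if (!ncol(m)) stop("no cells with positive depth")
  out <- as.numeric(Matrix::rowSums(Matrix::t(Matrix::t(m) / depth))) / ncol(m)
  names(out) <- rownames(m)
  out
}

#' Normalized paired-rank (signed-rank) statistic
#'
#' The Wilcoxon signed-rank sum of positive ranks of `a - b`, divided
#' by the total rank sum `n(n+1)/2` after removing zero differences
#' (midranks for ties). 1 means every `a` exceeds its `b`, 0 the
#' reverse, and 0.5 means no paired shift. When all differences are
#' zero the statistic is 0.5 with attribute `degenerate = TRUE`.
#'
#' This is the statistic behind both the sex-bias score (female vs male
#' predicted expression across cells; 1 = extremely female-biased) and
#' the differential-accessibility direction prediction.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return numeric in `[0, 1]`.
#' @examples
#' pairedRankStatistic(c(2, 3, 0), c(1, 1, 3))  # ranks 1,2,3; W+ = 3; 0.5
#' @export
pairedRankStatistic <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    out <- 0.5
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- rank(abs(d))
  sum(r[d > 0]) / (n * (n + 1) / 2)
}

#' Local inverse Simpson's index (LISI)
#'
#' Per-cell effective number of label categories in a
#' perplexity-calibrated Gaussian neighborhood: distances to neighbors
#' are converted to weights whose entropy matches `log(perplexity)`
#' (bandwidth found by bisection), label probabilities are the weighted
#' label frequencies, and the score is the inverse Simpson index
#' `1 / sum(p^2)`. Scores lie in `[1, #labels]`; means near the number
#' of labels indicate full mixing, means near 1 complete separation.
#'
#' @param embeddings cells x dims numeric matrix.
#' @param labels per-cell labels.
#' @param perplexity neighborhood size parameter (default 30).
#' @return numeric vector of per-cell scores, with the mean in
#'   attribute `"mean"`.
#' @export
lisiScore <- function(embeddings, labels, perplexity = 30) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 2) stop("LISI needs at least two cells")
  labels <- as.character(labels)
  k <- min(n - 1, max(5, ceiling(3 * perplexity)))
  perplexity <- min(perplexity, (n - 1) / 3 + 1e-9)
  lab_levels <- unique(labels)
  d2 <- as.matrix(stats::dist(embeddings))^2
  target <- log(perplexity)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[-1][seq_len(k)]
    di <- d2[i, nb]
    lo <- 1e-10; hi <- 1e10
    for (iter in 1:64) {
      betam <- sqrt(lo * hi)
      w <- exp(-di * betam)
      sw <- sum(w)
      if (sw <= 0) { hi <- betam; next }
      p <- w / sw
      h <- -sum(ifelse(p > 0, p * log(p), 0))
      if (h > target) lo <- betam else hi <- betam
    }
    w <- exp(-di * sqrt(lo * hi)); p <- w / sum(w)
    pl <- vapply(lab_levels, function(l) sum(p[labels[nb] == l]), numeric(1))
    scores[i] <- 1 / sum(pl^2)
  }
  attr(scores, "mean") <- mean(scores)
  scores
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling, invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric predictions.
#' @param labels binary labels (logical, 0/1, or a two-level factor
#'   whose larger level is the positive class).
#' @return numeric in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- .as_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  u <- sort(unique(labels))
  if (all(u %in% c(0, 1))) return(as.integer(labels == 1))
  if (length(u) != 2) stop("labels must be binary")
  as.integer(labels == u[2])
}

#' Normalized area under the precision-recall curve
#'
#' `(AUPR - PP) / (1 - PP)` where `PP` is the positive proportion, so 0
#' is the expected behavior of a random predictor and 1 a perfect one
#' (worse-than-random predictors can dip below 0). AUPR is computed by
#' the step-interpolation (average-precision) rule.
#'
#' @inheritParams auroc
#' @return numeric, at most 1.
#' @export
auprNorm <- function(scores, labels) {
  y <- .as_binary(labels)
  pp <- mean(y)
  if (pp == 1) stop("all labels positive: AUPRnorm undefined (PP = 1)")
  if (pp == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  # average precision with ties: evaluate at the last index of each
  # distinct score, weighting by positives gained in the tie group
  grp_end <- cumsum(rle(s)$lengths)
  tp_end <- tp[grp_end]
  prec_end <- prec[grp_end]
  dtp <- diff(c(0, tp_end))
  aupr <- sum(prec_end * dtp) / sum(y)
  (aupr - pp) / (1 - pp)
}

#' One-sided paired Wilcoxon signed-rank comparison
#'
#' Tests whether paired metric values in `a` exceed those in `b`
#' (alternative "greater"), via [stats::wilcox.test()] on the paired
#' differences. For fewer than 5 informative pairs a warning is issued
#' and the exact distribution is used. Identical vectors give p = 1 by
#' the one-sided convention.
#'
#' @param a,b paired numeric metric vectors (e.g. per cell type x time
#'   point).
#' @param alternative passed to [stats::wilcox.test()]
#'   (default "greater").
#' @return one-sided p-value.
#' @export
comparePaired <- function(a, b, alternative = "greater") {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  n <- sum(d != 0)
  if (n == 0) return(1)
  if (n < 5) warning("fewer than 5 informative pairs; exact p-value")
  suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = alternative,
                       exact = n < 50)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] kept for a stable interface.
#'
#' @param p numeric p-values.
#' @return adjusted p-values (FDR).
#' @export
adjustFDR <- function(p) stats::p.adjust(p, method = "BH")
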