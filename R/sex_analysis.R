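# Cross-condition (sex) differential prediction from trained models.

#' Per-gene sex-bias scores over time
#'
#' For each (cell type, time point) with more than `minCells` cells,
#' every cell's depth-normalized profile is predicted twice from the
#' same identity embedding and time -- once under the female and once
#' under the male condition factor -- and each gene's score is the
#' normalized paired-rank statistic of (female, male) predictions
#' across cells: 1 = extremely female-biased, 0 = extremely
#' male-biased, 0.5 = no difference. With an ensemble, per-model scores
#' are aggregated by the median. With `window = TRUE` (default) cells
#' from the previous and subsequent observed time points are pooled
#' with the current one, which makes the score robust to individual
#' samples when each time point contains a single sex.
#'
#' @param models a [TemporalVAE-class] or list of them (ensemble).
#' @param x a [TemporalProfiles-class] with cell-type labels.
#' @param female,male condition levels to contrast (defaults "f", "m").
#' @param minCells minimum cells per (cell type, time) row (default 50;
#'   smaller groups are skipped with a message).
#' @param window pool cells from the flanking time points (default TRUE).
#' @return data.frame with columns `gene`, `cell_type`, `time`,
#'   `score`, `n_cells`, `log_fold_change` (median per-cell log2 FC of
#'   pseudocount-1, depth-scaled predictions), `mean_expr` (mean
#'   predicted fraction across sexes, used by the expression filter of
#'   [consistentSexBiasedGenes()]).
#' @export
sexBiasedScores <- function(models, x, female = "f", male = "m",
                            minCells = 50, window = TRUE) {
  if (methods::is(models, "TemporalVAE")) models <- list(models)
  for (m in models) {
    if (!all(c(female, male) %in% m@conditionLevels))
      stop(sprintf("condition level '%s'/'%s' unseen in training", female, male))
  }
  ct <- cellType(x)
  if (is.null(ct)) stop("sex-bias scoring needs cell-type labels")
  tm <- timePoint(x)
  times <- sort(unique(tm))
  rows <- list()
  for (k in unique(ct)) {
    for (ti in seq_along(times)) {
      t <- times[ti]
      use_t <- if (window) times[max(1, ti - 1):min(length(times), ti + 1)]
               else t
      idx <- which(ct == k & tm %in% use_t)
      if (length(idx) <= minCells) {
        message(sprintf("skipping (%s, t=%g): %d cells <= %d",
                        k, t, length(idx), minCells))
        next
      }
      ids <- colnames(x)[idx]
      per_model <- lapply(models, function(m) {
        pf <- predictProfile(m, x, cells = ids, conditionTarget = female)
        pm <- predictProfile(m, x, cells = ids, conditionTarget = male)
        S <- m@config$depthScale
        list(score = vapply(seq_len(ncol(pf)), function(g)
               as.numeric(pairedRankStatistic(pf[, g], pm[, g])), numeric(1)),
             lfc = vapply(seq_len(ncol(pf)), function(g)
               median(log2((pf[, g] * S + 1) / (pm[, g] * S + 1))), numeric(1)),
             expr = colMeans((pf + pm) / 2))
      })
      med <- function(field) ensembleMedian(lapply(per_model, `[[`, field))
      rows[[length(rows) + 1]] <- data.frame(
        gene = models[[1]]@featureIds, cell_type = k, time = t,
        score = med("score"), n_cells = length(idx),
        log_fold_change = med("lfc"), mean_expr = med("expr"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(gene = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes with consistent sex bias across time
#'
#' Per cell type, restricts to time points present in the score table
#' with more than `minCellsPerTime` cells, keeps the top half of genes
#' by mean predicted expression at every retained time point
#' (consistently expressed genes), and calls a gene female-biased when
#' its score exceeds 0.5 at every retained time point (male-biased
#' symmetrically below 0.5).
#'
#' @param table output of [sexBiasedScores()].
#' @param cellTypeName which cell type to analyse (default: the only
#'   one present).
#' @param minCellsPerTime time points with fewer cells are dropped
#'   (default 25).
#' @return list with character vectors `female` and `male`.
#' @export
consistentSexBiasedGenes <- function(table, cellTypeName = NULL,
                                     minCellsPerTime = 25) {
  if (is.null(cellTypeName)) {
    u <- unique(table$cell_type)
    if (length(u) != 1) stop("specify cellTypeName (several present)")
    cellTypeName <- u
  }
  tb <- table[table$cell_type == cellTypeName &
                table$n_cells > minCellsPerTime, ]
  if (!nrow(tb)) {
    warning("no retained time points")
    return(list(female = character(0), male = character(0)))
  }
  times <- unique(tb$time)
  expressed <- NULL
  for (t in times) {
    tt <- tb[tb$time == t, ]
    top <- tt$gene[rank(-tt$mean_expr, ties.method = "first") <=
                     ceiling(nrow(tt) / 2)]
    expressed <- if (is.null(expressed)) top else intersect(expressed, top)
  }
  scores <- split(tb$score, tb$gene)
  genes <- intersect(names(scores), expressed)
  female <- genes[vapply(scores[genes], function(s) all(s > 0.5), logical(1))]
  male <- genes[vapply(scores[genes], function(s) all(s < 0.5), logical(1))]
  list(female = sort(female), male = sort(male))
}

#' One-sided rank-sum comparison of scores between two gene sets
#'
#' Tests whether sex-bias scores of genes in `setDown` (e.g. genes
#' downregulated in a knockout of a candidate regulator, hence
#' candidate activated targets) exceed those of genes in `setUp`, via a
#' one-sided Wilcoxon rank-sum test.
#'
#' @param scores named numeric vector of per-gene scores.
#' @param setUp,setDown character vectors of gene ids; both must
#'   intersect the scored genes.
#' @return one-sided p-value.
#' @export
genesetShiftTest <- function(scores, setUp, setDown) {
  up <- scores[intersect(names(scores), setUp)]
  down <- scores[intersect(names(scores), setDown)]
  if (!length(up) || !length(down))
    stop("both gene sets must intersect the scored genes")
  suppressWarnings(
    stats::wilcox.test(down, up, alternative = "greater")$p.value)
}

#' PPI odds ratio between female-biased autosomal and X-linked genes
#'
#' Computes the odds of a protein-protein interaction between
#' female-biased autosomal genes and female-biased X-linked genes,
#' relative to the odds between non-female-biased autosomal genes and
#' the same X-linked set, and a permutation p-value from `nPerm`
#' random autosomal sets of the same size. The test is refused (status
#' flag) when fewer than `minEdges` interactions link the autosomal
#' universe to the X-linked set.
#'
#' @param edges data.frame with columns `gene1`, `gene2` (undirected).
#' @param femaleAutosomal,femaleX,allAutosomal character gene sets;
#'   `femaleAutosomal` must be a subset of `allAutosomal`.
#' @param nPerm permutations (default 100).
#' @param minEdges minimum relevant interactions (default 50).
#' @param seed integer seed for the resampling.
#' @return list with `status` ("ok" or "refused"), `oddsRatio`,
#'   `p` (add-one-corrected permutation p), `nEdges`.
#' @export
ppiOddsRatio <- function(edges, femaleAutosomal, femaleX, allAutosomal,
                         nPerm = 100, minEdges = 50, seed = 1) {
  stopifnot(all(c("gene1", "gene2") %in% names(edges)))
  if (!all(femaleAutosomal %in% allAutosomal))
    stop("femaleAutosomal must be a subset of allAutosomal")
  count_between <- function(A, B) {
    sum((edges$gene1 %in% A & edges$gene2 %in% B) |
        (edges$gene1 %in% B & edges$gene2 %in% A))
  }
  nRel <- count_between(allAutosomal, femaleX)
  if (nRel < minEdges)
    return(list(status = "refused", oddsRatio = NA_real_, p = NA_real_,
                nEdges = nRel))
  or_for <- function(A) {
    other <- setdiff(allAutosomal, A)
    e11 <- count_between(A, femaleX)
    e01 <- count_between(other, femaleX)
    n11 <- length(A) * length(femaleX)
    n01 <- length(other) * length(femaleX)
    (e11 / pmax(n11 - e11, 1)) / (e01 / pmax(n01 - e01, 1))
  }
  obs <- or_for(femaleAutosomal)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  null <- replicate(nPerm,
    or_for(sample(allAutosomal, length(femaleAutosomal))))
  p <- (1 + sum(null >= obs)) / (nPerm + 1)
  list(status = "ok", oddsRatio = obs, p = p, nEdges = nRel)
}

#' Hypergeometric gene-set enrichment
#'
#' Plain hypergeometric (one-sided) test of over-representation of a
#' gene set among selected genes, the building block for ontology
#' enrichment reporting.
#'
#' @param selected,set,universe character gene vectors.
#' @return p-value.
#' @export
hypergeometricTest <- function(selected, set, universe) {
  selected <- intersect(selected, universe)
  set <- intersect(set, universe)
  q <- length(intersect(selected, set))
  stats::phyper(q - 1, length(set), length(universe) - length(set),
                length(selected), lower.tail = FALSE)
}
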