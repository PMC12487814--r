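# Time-lagged cross-correlation between predicted expression and
# accessibility trajectories, with ensemble neighbor selection and
# before/after categorization.
#
# Sign convention: TLCC(shift) = cor(expr(t), acc(t + shift)) over the
# core window. Accessibility leading expression (chromatin priming)
# puts the argmax at a negative shift -> category "before".

#' Ensemble nearest-neighbor selection around a query cell
#'
#' Per ensemble member, cells are ranked by Euclidean distance to the
#' query on the cell-identity embeddings and the `kTop` nearest are
#' retained. Cells absent from every member's top list are excluded;
#' the rest are ordered by summed rank (a member in which the cell is
#' absent contributes rank `kTop + 1`), and the query plus the `nKeep`
#' best neighbors are returned (five cells with the defaults).
#'
#' @param embeddings a cells x dims matrix with rownames, or a list of
#'   them (one per ensemble member).
#' @param query query cell id (present in all members).
#' @param kTop per-member neighborhood size (default 25).
#' @param nKeep neighbors kept after rank summation (default 4).
#' @return character vector: the query followed by up to `nKeep`
#'   neighbor ids (fewer, with a warning, when not enough cells are
#'   eligible).
#' @export
selectNeighbors <- function(embeddings, query, kTop = 25, nKeep = 4) {
  if (is.matrix(embeddings)) embeddings <- list(embeddings)
  rank_tabs <- lapply(embeddings, function(emb) {
    if (!query %in% rownames(emb)) stop("query cell absent from embeddings")
    d <- sqrt(rowSums((emb - rep(emb[query, ], each = nrow(emb)))^2))
    d <- d[names(d) != query]
    r <- rank(d, ties.method = "average")
    r[r <= kTop]
  })
  eligible <- unique(unlist(lapply(rank_tabs, names)))
  if (!length(eligible)) {
    warning("no eligible neighbors")
    return(query)
  }
  summed <- vapply(eligible, function(cell) {
    sum(vapply(rank_tabs, function(r)
      if (cell %in% names(r)) r[[cell]] else kTop + 1, numeric(1)))
  }, numeric(1))
  ord <- eligible[order(summed, eligible)]
  if (length(ord) < nKeep)
    warning(sprintf("only %d eligible neighbor(s) (requested %d)",
                    length(ord), nKeep))
  c(query, head(ord, nKeep))
}

#' Map peaks to genes by upstream proximity
#'
#' Pairs each peak with every gene whose upstream flank it overlaps:
#' the `window`-bp region immediately upstream of the transcription
#' start site, strand-aware (for a minus-strand gene the flank lies at
#' coordinates greater than the TSS). Coordinates are BED-style
#' 0-based half-open; the TSS table gives the 0-based TSS position.
#'
#' @param tss data.frame with columns `chrom`, `position` (0-based),
#'   `strand`, `gene_id`, or a path to such a TSV.
#' @param peaks data.frame with columns `chrom`, `start`, `end` and
#'   optionally `peak_id`, or a path to a BED file.
#' @param window upstream flank size in bp (default 200000).
#' @return data.frame with columns `peak_id`, `gene_id`.
#' @export
assignProximalPeaks <- function(tss, peaks, window = 200000) {
  if (is.character(tss))
    tss <- read.delim(tss, header = TRUE, stringsAsFactors = FALSE)
  if (is.character(peaks)) {
    peaks <- read.delim(peaks, header = FALSE, stringsAsFactors = FALSE)
    names(peaks)[1:3] <- c("chrom", "start", "end")
    if (ncol(peaks) >= 4) names(peaks)[4] <- "peak_id"
  }
  if (!"peak_id" %in% names(peaks))
    peaks$peak_id <- sprintf("peak%d", seq_len(nrow(peaks)))
  unknown <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(unknown))
    warning(sprintf("peak chromosome(s) absent from the TSS table: %s",
                    paste(unknown, collapse = ", ")))
  tss_gr <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$position + 1, width = 1),
    strand = tss$strand)
  up <- GenomicRanges::flank(tss_gr, width = window, start = TRUE)
  up <- GenomicRanges::trim(up)
  peak_gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(peak_gr, up))
  data.frame(
    peak_id = peaks$peak_id[S4Vectors::queryHits(hits)],
    gene_id = tss$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
}

#' Time-lagged cross-correlation vector for one trajectory pair
#'
#' For each shift, the accessibility trajectory is moved along the
#' (uniform) time grid and the Pearson correlation with the expression
#' trajectory is computed over the core window. Trajectories must be
#' given on a grid covering the core window padded by the largest
#' absolute shift on each side; shifts must be multiples of the grid
#' step. A constant window yields `NA` for that entry.
#'
#' @param expr,acc numeric trajectories on `timeGrid`.
#' @param timeGrid ascending, uniformly spaced times (days).
#' @param shifts shift grid in days (default -0.5 to 0.5 by 0.01: a
#'   101-entry vector).
#' @param coreWindow length-2 numeric, the correlation window (default
#'   `c(8, 8.5)`).
#' @return numeric vector, one correlation per shift.
#' @export
tlccVector <- function(expr, acc, timeGrid,
                       shifts = seq(-0.5, 0.5, by = 0.01),
                       coreWindow = c(8, 8.5)) {
  stopifnot(length(expr) == length(timeGrid),
            length(acc) == length(timeGrid))
  step <- diff(timeGrid)
  if (any(abs(step - step[1]) > 1e-9)) stop("time grid must be uniform")
  step <- step[1]
  k <- shifts / step
  if (any(abs(k - round(k)) > 1e-6))
    stop("shifts must be multiples of the grid step")
  k <- as.integer(round(k))
  core <- which(timeGrid >= coreWindow[1] - 1e-9 &
                  timeGrid <= coreWindow[2] + 1e-9)
  if (!length(core)) stop("core window outside the time grid")
  if (min(core) + min(k) < 1 || max(core) + max(k) > length(timeGrid))
    stop("time grid must pad the core window by the largest |shift|")
  e <- expr[core]
  vapply(k, function(ki) {
    a <- acc[core + ki]
    if (sd(e) == 0 || sd(a) == 0) NA_real_ else cor(e, a)
  }, numeric(1))
}

#' Predicted feature trajectory of one cell on a dense time grid
#'
#' Encodes the cell once and decodes it at every grid time, returning
#' depth-normalized expression fractions (RNA model) or accessibility
#' probabilities (via the ATAC decoder for [MultimodalVAE-class]
#' input with `modality = "atac"`).
#'
#' @param model a [TemporalVAE-class] or [MultimodalVAE-class].
#' @param x the [TemporalProfiles-class] holding the query cell
#'   (RNA data when `model` is multimodal).
#' @param cell query cell id.
#' @param timeGrid prediction times (days).
#' @param modality for multimodal models: which decoder to use.
#' @return features x times matrix.
#' @export
predictTrajectory <- function(model, x, cell, timeGrid,
                              modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  if (methods::is(model, "MultimodalVAE")) {
    rmod <- model@rna
  } else {
    rmod <- model
    if (modality == "atac") stop("ATAC trajectories need a MultimodalVAE")
  }
  dat <- .model_dat(rmod, x)
  idx <- .cell_idx(x, cell)
  bi <- .batch_input(dat, idx)
  enc <- .encode_batch(rmod@params, bi, rmod@latentDim)
  nT <- length(timeGrid)
  z <- enc$mu[rep(1, nT), , drop = FALSE]
  con_level <- conditionLabel(x)[idx]
  tenc <- sinusoidalEncode(timeGrid, rmod@timeSpec)
  if (modality == "rna") {
    e <- .interact(rmod@params, z, tenc,
                   oneHot(rep(con_level, nT), rmod@conditionLevels))$e
    bat <- oneHot(rep(batchLabel(x)[idx], nT), rmod@batchLevels)
    out <- t(.decode_rna(rmod@params, e, bat)$frac)
  } else {
    amod <- model@atac
    e <- .interact(amod@params, z, tenc,
                   oneHot(rep(con_level, nT), amod@conditionLevels))$e
    bat <- oneHot(rep(amod@batchLevels[1], nT), amod@batchLevels)
    out <- t(.decode_atac(amod@params, e, bat, matrix(0, nT, 1))$prob)
  }
  dimnames(out) <- list(if (modality == "rna") rmod@featureIds
                        else model@atac@featureIds, NULL)
  out
}

#' Build a TLCC matrix around a query cell
#'
#' Selects the query's neighbors on the ensemble RNA embeddings
#' ([selectNeighbors()]; five cells with the defaults), predicts each
#' cell's ensemble-median expression and accessibility trajectories on
#' the dense grid, and computes one TLCC vector per (peak, gene) pair
#' and cell, concatenated along the pair axis.
#'
#' @param models a [MultimodalVAE-class] or list of them (ensemble).
#' @param rna the RNA [TemporalProfiles-class].
#' @param queryCell query cell id.
#' @param pairs data.frame with columns `peak_id`, `gene_id` (e.g.
#'   from [assignProximalPeaks()]).
#' @param timeGrid prediction grid (default 7.5 to 9 by 0.01 days,
#'   padding the core window by the largest shift on each side).
#' @param shifts,coreWindow see [tlccVector()].
#' @param kTop,nKeep see [selectNeighbors()].
#' @return A [TLCCMatrix-class].
#' @export
buildTLCCMatrix <- function(models, rna, queryCell, pairs,
                            timeGrid = seq(7.5, 9, by = 0.01),
                            shifts = seq(-0.5, 0.5, by = 0.01),
                            coreWindow = c(8, 8.5), kTop = 25, nKeep = 4) {
  if (methods::is(models, "MultimodalVAE")) models <- list(models)
  if (!nrow(pairs)) {
    warning("no (peak, gene) pairs")
    return(methods::new("TLCCMatrix", shifts = shifts,
                        correlations = matrix(NA_real_, length(shifts), 0),
                        pairIndex = data.frame(peak_id = character(0),
                                               gene_id = character(0),
                                               cell_id = character(0))))
  }
  embs <- lapply(models, function(mm) encodeCells(mm@rna, rna)$mean)
  cells <- selectNeighbors(embs, queryCell, kTop = kTop, nKeep = nKeep)
  cols <- list(); index <- list()
  for (cell in cells) {
    expr <- ensembleMedian(lapply(models, function(mm)
      predictTrajectory(mm, rna, cell, timeGrid, "rna")))
    acc <- ensembleMedian(lapply(models, function(mm)
      predictTrajectory(mm, rna, cell, timeGrid, "atac")))
    for (i in seq_len(nrow(pairs))) {
      g <- pairs$gene_id[i]; p <- pairs$peak_id[i]
      cols[[length(cols) + 1]] <-
        tlccVector(expr[g, ], acc[p, ], timeGrid, shifts, coreWindow)
      index[[length(index) + 1]] <-
        data.frame(peak_id = p, gene_id = g, cell_id = cell,
                   stringsAsFactors = FALSE)
    }
  }
  methods::new("TLCCMatrix", shifts = shifts,
               correlations = do.call(cbind, cols),
               pairIndex = do.call(rbind, index))
}

# argmax shift of one TLCC column; ties resolved toward the smallest
# |shift|, an exact +/- tie is uncategorizable (NA)
.peak_shift <- function(v, shifts) {
  if (all(is.na(v))) return(NA_real_)
  mx <- max(v, na.rm = TRUE)
  cand <- shifts[which(!is.na(v) & v >= mx - 1e-12)]
  cand <- cand[abs(cand) == min(abs(cand))]
  if (length(cand) > 1) return(NA_real_)
  cand
}

#' Filter TLCC pairs and categorize before/after
#'
#' Drops (peak, gene, cell) columns whose maximum correlation is below
#' `minMaxCorr`, keeps (peak, gene) pairs surviving in at least
#' `minCells` cells, and categorizes each retained pair by the sign of
#' its argmax shift: negative (accessibility changes ahead of
#' expression) = `"before"`, positive = `"after"`. Pairs whose
#' retained cells disagree in sign, or whose best shift is 0 or tied
#' across signs, are `"uncategorized"`.
#'
#' @param tlcc a [TLCCMatrix-class].
#' @param minMaxCorr minimum per-column maximum correlation
#'   (default 0.5).
#' @param minCells minimum surviving cells per pair (default 2).
#' @return data.frame with columns `peak_id`, `gene_id`, `n_cells`,
#'   `median_shift`, `category`.
#' @export
filterAndCategorize <- function(tlcc, minMaxCorr = 0.5, minCells = 2) {
  stopifnot(methods::is(tlcc, "TLCCMatrix"))
  if (!ncol(tlcc@correlations))
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      n_cells = integer(0), median_shift = numeric(0),
                      category = character(0)))
  mx <- apply(tlcc@correlations, 2, function(v)
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  keep <- which(mx >= minMaxCorr)
  if (!length(keep))
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      n_cells = integer(0), median_shift = numeric(0),
                      category = character(0)))
  idx <- tlcc@pairIndex[keep, , drop = FALSE]
  best <- vapply(keep, function(j)
    .peak_shift(tlcc@correlations[, j], tlcc@shifts), numeric(1))
  key <- paste(idx$peak_id, idx$gene_id, sep = "\r")
  out <- lapply(split(seq_along(key), key), function(rows) {
    sh <- best[rows]
    n <- length(unique(idx$cell_id[rows]))
    if (n < minCells) return(NULL)
    cat <- if (anyNA(sh) || any(sh == 0)) "uncategorized"
           else if (all(sh < 0)) "before"
           else if (all(sh > 0)) "after"
           else "uncategorized"
    data.frame(peak_id = idx$peak_id[rows[1]],
               gene_id = idx$gene_id[rows[1]],
               n_cells = n, median_shift = median(sh),
               category = cat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      n_cells = integer(0), median_shift = numeric(0),
                      category = character(0)))
  rownames(out) <- NULL
  out
}
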