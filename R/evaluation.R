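#' Held-out time-point evaluation against the nearest-time baseline
#'
#' For each cell type with at least `minCells` cells at the held-out
#' time point, predicts the held-out pseudobulk from the query cells of
#' the same type at a neighboring time point (their profiles predicted
#' at the held-out time, averaged) and compares against the baseline:
#' the depth-normalized pseudobulk of the query cells themselves (the
#' nearest existing measurement). Both are scored by Pearson
#' correlation with the observed held-out pseudobulk. The model never
#' sees cell-type labels; they are used here only to form evaluation
#' groups.
#'
#' @param model a trained [TemporalVAE-class] whose training excluded
#'   `holdoutTime`.
#' @param x the full [TemporalProfiles-class] including held-out cells
#'   and cell-type labels.
#' @param holdoutTime the held-out time point (days).
#' @param queryTime neighboring time point supplying query cells
#'   (default: the nearest training time point).
#' @param minCells minimum held-out cells per cell type (default 25).
#' @return data.frame with one row per cell type: `cell_type`,
#'   `holdout_time`, `query_time`, `n_cells`, `pearson_model`,
#'   `pearson_baseline`.
#' @export
crossTimeEvaluation <- function(model, x, holdoutTime, queryTime = NULL,
                                minCells = 25) {
  ct <- cellType(x)
  if (is.null(ct)) stop("evaluation needs cell-type labels")
  tm <- timePoint(x)
  if (is.null(queryTime)) {
    cand <- model@timeClasses
    queryTime <- cand[which.min(abs(cand - holdoutTime))]
  }
  rows <- list()
  for (k in unique(ct)) {
    held <- which(ct == k & tm == holdoutTime)
    qry <- which(ct == k & tm == queryTime)
    if (length(held) < minCells || !length(qry)) next
    obs <- pseudobulk(x[, held])
    pred <- colMeans(predictProfile(model, x, cells = qry,
                                    tTarget = holdoutTime))
    base <- pseudobulk(x[, qry])
    rows[[length(rows) + 1]] <- data.frame(
      cell_type = k, holdout_time = holdoutTime, query_time = queryTime,
      n_cells = length(held),
      pearson_model = cor(pred, obs),
      pearson_baseline = cor(base, obs), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cell_type = character(0), holdout_time = numeric(0),
                      query_time = numeric(0), n_cells = integer(0),
                      pearson_model = numeric(0),
                      pearson_baseline = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
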