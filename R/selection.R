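# Hyperparameter grid, rank-based model selection, and ensembles.

#' Hyperparameter grid candidates
#'
#' Single-modality models vary the latent dimension over
#' `{25, 50, 100}` (3 candidates, minimum wavelength fixed at 1 day);
#' multimodal models additionally vary the embedding-alignment weight
#' lambda over `{1, 100, 10000}` (3 x 3 = 9 candidates). The number of
#' hidden layers (2) and the time-encoding dimension (50) are fixed in
#' all candidates.
#'
#' @param modality `"rna"` or `"multi"`.
#' @return data.frame of candidate configurations with a `model_id`.
#' @export
gridCandidates <- function(modality = c("rna", "multi")) {
  modality <- match.arg(modality)
  latent <- c(25, 50, 100)
  g <- if (modality == "rna") {
    expand.grid(latent_dim = latent, min_wavelength = 1)
  } else {
    expand.grid(latent_dim = latent, mse_weight = c(1, 100, 10000),
                min_wavelength = 1)
  }
  g$hidden_layers <- 2
  g$time_dim <- 50
  g$model_id <- sprintf("%s_%d", modality, seq_len(nrow(g)))
  g[, c("model_id", setdiff(names(g), "model_id"))]
}

#' Rank-based model selection over validation metrics
#'
#' Candidates are ranked per metric (correlation and LISI metrics:
#' higher is better; loss metrics: lower is better), ranks are summed
#' and rescaled so the best model has a summed rank of exactly 1, and
#' the minimum is returned. Ties are broken by smaller latent
#' dimension, then smaller lambda.
#'
#' @param scorecards data.frame with `model_id`, optional `latent_dim`
#'   and `mse_weight` columns, and one column per metric. Recognized
#'   lower-is-better metrics match `"loss"` in their name; all others
#'   are treated as higher-is-better.
#' @return the selected `model_id`; the rescaled summed ranks are
#'   attached as attribute `"ranks"`.
#' @export
selectBest <- function(scorecards) {
  stopifnot(is.data.frame(scorecards), nrow(scorecards) >= 2)
  meta <- intersect(c("model_id", "latent_dim", "mse_weight",
                      "min_wavelength", "hidden_layers", "time_dim"),
                    names(scorecards))
  metrics <- setdiff(names(scorecards), meta)
  if (!length(metrics)) stop("no metric columns in scorecards")
  for (m in metrics) {
    if (anyNA(scorecards[[m]]))
      stop(sprintf("metric '%s' is missing for some candidate", m))
  }
  rank_one <- function(m) {
    v <- scorecards[[m]]
    if (grepl("loss", m)) rank(v) else rank(-v)
  }
  summed <- Reduce(`+`, lapply(metrics, rank_one))
  rescaled <- summed / min(summed)
  best <- which(rescaled == min(rescaled))
  if (length(best) > 1) {
    o <- order(
      if ("latent_dim" %in% names(scorecards))
        scorecards$latent_dim[best] else best,
      if ("mse_weight" %in% names(scorecards))
        scorecards$mse_weight[best] else best)
    best <- best[o[1]]
  }
  out <- scorecards$model_id[best]
  attr(out, "ranks") <- setNames(rescaled, scorecards$model_id)
  out
}

#' Validation metrics for one trained model
#'
#' Computes the metrics entering rank-based selection on the validation
#' cells: `cross_time_pseudobulk_pearson` (each validation time point
#' predicted from its nearest other time point, Pearson correlation of
#' depth-normalized pseudobulks, averaged), `lisi_time_neighbors`
#' (mean LISI between each pair of neighboring time points on the
#' cell-identity embeddings), `lisi_heldout_neighbors` (LISI between
#' the two time points flanking each held-out time, when a hold-out
#' exists), and `lisi_batch` when more than one batch is present.
#'
#' @param model a [TemporalVAE-class].
#' @param x the training [TemporalProfiles-class].
#' @param split the [SplitPlan-class] used in training.
#' @param perplexity LISI perplexity (default 30).
#' @return named list of metrics (NULL entries omitted).
#' @export
modelScoreCard <- function(model, x, split, perplexity = 30) {
  va <- valIds(split)
  if (!length(va)) stop("score card needs a validation set")
  xv <- x[, va]
  tv <- timePoint(xv)
  times <- sort(unique(tv))
  # cross-time pseudobulk Pearson
  ct <- c()
  for (t in times) {
    others <- times[times != t]
    if (!length(others)) next
    q <- others[which.min(abs(others - t))]
    qc <- colnames(xv)[tv == q]
    pred <- predictProfile(model, xv, cells = qc, tTarget = t)
    obs <- pseudobulk(xv[, tv == t])
    ct <- c(ct, cor(colMeans(pred), obs))
  }
  emb <- encodeCells(model, xv)$mean
  lisi_pair <- function(t1, t2) {
    sel <- tv %in% c(t1, t2)
    if (length(unique(tv[sel])) < 2) return(NA_real_)
    attr(lisiScore(emb[sel, , drop = FALSE], tv[sel], perplexity), "mean")
  }
  ln <- mapply(lisi_pair, head(times, -1), times[-1])
  out <- list(cross_time_pseudobulk_pearson = mean(ct),
              lisi_time_neighbors = mean(ln, na.rm = TRUE))
  ho <- split@holdoutTimes
  if (length(ho)) {
    lh <- vapply(ho, function(h) {
      lo <- times[times < h]; hi <- times[times > h]
      if (!length(lo) || !length(hi)) return(NA_real_)
      lisi_pair(max(lo), min(hi))
    }, numeric(1))
    out$lisi_heldout_neighbors <- mean(lh, na.rm = TRUE)
  }
  bl <- batchLabel(xv)
  if (length(unique(bl)) > 1)
    out$lisi_batch <- attr(lisiScore(emb, bl, perplexity), "mean")
  out
}

#' Train an ensemble of models
#'
#' Trains `nModels` models with distinct seeds. With
#' `holdoutStrategy = "random-time"` each model additionally holds one
#' randomly chosen time point out of training (the robustness strategy
#' used for sex-bias scoring); with `"none"` only the seed varies.
#' Downstream consumers aggregate member outputs by the median (see
#' [ensembleMedian()]).
#'
#' @param x a [TemporalProfiles-class].
#' @param nModels ensemble size (default 10).
#' @param holdoutStrategy `"random-time"` or `"none"`.
#' @param seed base seed; model i uses `seed + i - 1`.
#' @param trainFun training function (default [trainTemporalVAE()]).
#' @param ... further arguments for `trainFun`.
#' @return list of models, with attributes `seeds` and `holdouts`.
#' @export
trainEnsemble <- function(x, nModels = 10,
                          holdoutStrategy = c("random-time", "none"),
                          seed = 1, trainFun = trainTemporalVAE, ...) {
  holdoutStrategy <- match.arg(holdoutStrategy)
  stopifnot(nModels >= 1)
  times <- sort(unique(timePoint(x)))
  seeds <- as.integer(seed) + seq_len(nModels) - 1L
  holdouts <- vector("list", nModels)
  if (holdoutStrategy == "random-time") {
    set.seed(seeds[1])
    if (length(times) < nModels) {
      message("fewer time points than models: sampling hold-outs with replacement")
      ho <- sample(times, nModels, replace = TRUE)
    } else ho <- sample(times, nModels)
    holdouts <- as.list(ho)
  }
  models <- vector("list", nModels)
  for (i in seq_len(nModels)) {
    args <- list(x = x, seed = seeds[i], ...)
    if (holdoutStrategy == "random-time") args$holdoutTimes <- holdouts[[i]]
    models[[i]] <- do.call(trainFun, args)
  }
  attr(models, "seeds") <- seeds
  attr(models, "holdouts") <- holdouts
  models
}

#' Median aggregation across ensemble members
#'
#' Element-wise median of a list of equal-shaped matrices or vectors.
#' With a single member this is the identity.
#'
#' @param outputs list of numeric matrices/vectors of identical shape.
#' @return the element-wise median, same shape as the inputs.
#' @export
ensembleMedian <- function(outputs) {
  stopifnot(length(outputs) >= 1)
  if (length(outputs) == 1) return(outputs[[1]])
  a <- array(unlist(outputs), dim = c(length(outputs[[1]]), length(outputs)))
  med <- apply(a, 1, median)
  out <- outputs[[1]]
  out[] <- med
  out
}
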