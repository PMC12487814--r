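#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom stats rnorm runif rpois rbinom plogis qlogis median sd cor
#'   quantile setNames complete.cases
#' @importFrom utils head read.delim write.table modifyList
NULL

#' TemporalProfiles: single-cell counts with temporal metadata
#'
#' `TemporalProfiles` extends
#' [SingleCellExperiment::SingleCellExperiment] and holds a sparse count
#' matrix (features x cells) together with the per-cell metadata the
#' temporal models require: collection time in days (`time`), a
#' categorical condition (e.g. sex), a batch label, and an optional
#' cell-type annotation used only for evaluation. The `modality` is
#' either `"rna"` (raw counts) or `"atac"` (binarized accessibility;
#' entries are coerced to 0/1 at construction).
#'
#' @slot modality character, `"rna"` or `"atac"`.
#'
#' @seealso [TemporalProfiles()] for the constructor, [timePoint()],
#'   [conditionLabel()], [batchLabel()], [cellType()], [modality()].
#' @export
setClass("TemporalProfiles",
  contains = "SingleCellExperiment",
  slots = c(modality = "character")
)

setValidity("TemporalProfiles", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (length(object@modality) != 1L ||
      !object@modality %in% c("rna", "atac"))
    msg <- c(msg, "modality must be one of 'rna', 'atac'")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("time", "condition", "batch")) {
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
  }
  if ("time" %in% colnames(cd)) {
    tm <- cd$time
    if (!is.numeric(tm) || any(!is.finite(tm)))
      msg <- c(msg, "time values must be finite numbers (days)")
  }
  if ("counts" %in% SummarizedExperiment::assayNames(object) && ncol(object) > 0) {
    cts <- SummarizedExperiment::assay(object, "counts")
    mn <- if (methods::is(cts, "sparseMatrix")) min(cts@x, 0) else min(cts)
    if (is.finite(mn) && mn < 0) msg <- c(msg, "counts must be non-negative")
    if (identical(object@modality, "atac")) {
      vals <- if (methods::is(cts, "sparseMatrix")) cts@x else as.vector(cts)
      if (length(vals) && !all(vals %in% c(0, 1)))
        msg <- c(msg, "atac counts must be binary (0/1)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TemporalProfiles object
#'
#' Cells are columns. ATAC counts are binarized (`x > 0 -> 1`) on entry.
#' Cells with zero total counts are dropped with a warning, because
#' library-size scaling is undefined for them.
#'
#' @param counts features x cells matrix (dense or `Matrix` sparse) of
#'   non-negative counts.
#' @param time numeric vector of per-cell collection times, in days.
#' @param condition per-cell condition labels (coerced to character).
#' @param batch per-cell batch labels (coerced to character).
#' @param cellType optional per-cell cell-type labels (evaluation only;
#'   never seen by the models during training).
#' @param modality `"rna"` or `"atac"`.
#' @param featureIds,cellIds optional dimnames; defaults taken from
#'   `counts` or generated.
#' @return A [TemporalProfiles-class] object.
#' @examples
#' m <- Matrix::rsparsematrix(20, 30, density = 0.3,
#'                            rand.x = function(n) rpois(n, 2) + 1)
#' tp <- TemporalProfiles(m, time = rep(c(1, 2, 3), each = 10),
#'                        condition = "f", batch = "b1")
#' tp
#' @export
TemporalProfiles <- function(counts, time, condition = "none",
                             batch = "batch1", cellType = NULL,
                             modality = c("rna", "atac"),
                             featureIds = NULL, cellIds = NULL) {
  modality <- match.arg(modality)
  counts <- methods::as(counts, "CsparseMatrix")
  n <- ncol(counts)
  if (!is.null(featureIds)) rownames(counts) <- featureIds
  if (!is.null(cellIds)) colnames(counts) <- cellIds
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("feature%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%d", seq_len(n))
  time <- rep_len(as.numeric(time), n)
  condition <- rep_len(as.character(condition), n)
  batch <- rep_len(as.character(batch), n)
  if (modality == "atac" && length(counts@x)) counts@x <- as.numeric(counts@x > 0)
  cd <- S4Vectors::DataFrame(time = time, condition = condition, batch = batch,
                             row.names = colnames(counts))
  if (!is.null(cellType)) cd$cell_type <- rep_len(as.character(cellType), n)
  depth <- Matrix::colSums(counts)
  keep <- depth > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d cell(s) with zero total counts", sum(!keep)))
    counts <- counts[, keep, drop = FALSE]
    cd <- cd[keep, , drop = FALSE]
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  methods::new("TemporalProfiles", sce, modality = modality)
}

#' @describeIn TemporalProfiles-class compact display
#' @param object a `TemporalProfiles` object
#' @export
setMethod("show", "TemporalProfiles", function(object) {
  tm <- timePoint(object)
  cat(sprintf("TemporalProfiles [%s]: %d features x %d cells\n",
              object@modality, nrow(object), ncol(object)))
  if (length(tm))
    cat(sprintf("  time points (days): %s\n",
                paste(sort(unique(tm)), collapse = ", ")))
  cat(sprintf("  conditions: %s | batches: %s\n",
              paste(unique(conditionLabel(object)), collapse = ", "),
              paste(unique(batchLabel(object)), collapse = ", ")))
  invisible(NULL)
})

#' Split plan for temporal hold-out evaluation
#'
#' Cells at the hold-out time points form the test set; remaining cells
#' are split per time point into validation and training at
#' `valRatio`, with at most `valCap` validation cells per time point.
#'
#' @slot trainIds,valIds,testIds character vectors of cell ids.
#' @slot holdoutTimes numeric, days.
#' @slot valRatio numeric fraction.
#' @slot valCap integer cap per time point.
#' @slot seed integer seed that generated the plan.
#' @export
setClass("SplitPlan", slots = c(
  trainIds = "character", valIds = "character", testIds = "character",
  holdoutTimes = "numeric", valRatio = "numeric", valCap = "numeric",
  seed = "numeric"))

setValidity("SplitPlan", function(object) {
  ids <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(ids)) return("train/val/test sets must be disjoint")
  TRUE
})

#' @describeIn SplitPlan-class compact display
#' @param object a `SplitPlan`
#' @export
setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d val / %d test cells (holdout: %s)\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds),
              if (length(object@holdoutTimes))
                paste(object@holdoutTimes, collapse = ", ") else "none"))
  invisible(NULL)
})

#' Sinusoidal time-encoding specification
#'
#' A `TimeEncoding` holds an even embedding dimension `d`, the minimum
#' wavelength (days) of the frequency ladder, and the ladder itself:
#' `d/2` angular frequencies `w_i = 2*pi / 10000^(2*i/d)`,
#' `i = 0 .. d/2 - 1` (radians per rescaled day). Time is rescaled as
#' `t' = t / minWavelength` before encoding, so the fastest component
#' has period exactly `minWavelength` days and the slowest has period
#' `minWavelength * 10000^((d-2)/d)` days.
#'
#' @slot d even integer dimension.
#' @slot minWavelength numeric, days.
#' @slot frequencies numeric vector of length `d/2`, strictly decreasing.
#' @seealso [timeEncoding()], [sinusoidalEncode()]
#' @export
setClass("TimeEncoding", slots = c(
  d = "numeric", minWavelength = "numeric", frequencies = "numeric"))

setValidity("TimeEncoding", function(object) {
  msg <- character(0)
  if (object@d < 2 || object@d %% 2 != 0) msg <- c(msg, "d must be a positive even integer")
  if (object@minWavelength <= 0) msg <- c(msg, "minWavelength must be positive")
  if (length(object@frequencies) != object@d / 2)
    msg <- c(msg, "frequencies must have length d/2")
  if (length(object@frequencies) > 1 && any(diff(object@frequencies) >= 0))
    msg <- c(msg, "frequencies must be strictly decreasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn TimeEncoding-class compact display
#' @param object a `TimeEncoding`
#' @export
setMethod("show", "TimeEncoding", function(object) {
  cat(sprintf("TimeEncoding: d = %d, min wavelength = %g day(s)\n",
              as.integer(object@d), object@minWavelength))
  cat(sprintf("  period range: %g .. %g day(s)\n",
              object@minWavelength,
              object@minWavelength * 10000^((object@d - 2) / object@d)))
  invisible(NULL)
})

#' Temporal conditional VAE model (one modality)
#'
#' Parameters of the conditional VAE for one data modality: encoder,
#' temporal interaction layer, decoder, adversarial time discriminator,
#' plus the factor level orders and the time-encoding spec needed to
#' reproduce inputs. Created by [trainTemporalVAE()] or as the
#' per-modality halves of [trainMultimodal()].
#'
#' @slot modality `"rna"` or `"atac"`.
#' @slot featureIds character, feature order the model was trained on.
#' @slot latentDim integer L, dimension of the cell-identity embedding
#'   (and of the time-aware embedding).
#' @slot timeSpec a [TimeEncoding-class].
#' @slot conditionLevels,batchLevels character, one-hot level orders.
#' @slot timeClasses numeric, distinct training time points (the
#'   discriminator's classes).
#' @slot params list of weight matrices/vectors (encoder, interaction,
#'   decoder, discriminator, dispersion, normalization constants).
#' @slot config list of training hyperparameters.
#' @slot history data.frame of per-epoch losses.
#' @slot seed integer training seed.
#' @export
setClass("TemporalVAE", slots = c(
  modality = "character", featureIds = "character", latentDim = "numeric",
  timeSpec = "TimeEncoding", conditionLevels = "character",
  batchLevels = "character", timeClasses = "numeric", params = "list",
  config = "list", history = "data.frame", seed = "numeric"))

#' @describeIn TemporalVAE-class compact display
#' @param object a `TemporalVAE`
#' @export
setMethod("show", "TemporalVAE", function(object) {
  cat(sprintf("TemporalVAE [%s]: %d features, latent dim %d, time dim %d\n",
              object@modality, length(object@featureIds),
              as.integer(object@latentDim), as.integer(object@timeSpec@d)))
  cat(sprintf("  trained on %d time points; conditions: %s\n",
              length(object@timeClasses),
              paste(object@conditionLevels, collapse = ", ")))
  if (nrow(object@history))
    cat(sprintf("  %d epochs (best val loss %.4g)\n",
                nrow(object@history), min(object@history$val_loss, na.rm = TRUE)))
  invisible(NULL)
})

#' Coupled RNA + ATAC temporal VAE
#'
#' Holds the reference (RNA) and secondary (ATAC) [TemporalVAE-class]
#' models trained by [trainMultimodal()]. The temporal interaction
#' layer of the ATAC model is tied to the RNA model's, so a cell encoded
#' from either modality can be decoded in the other at any target time.
#'
#' @slot rna,atac [TemporalVAE-class] models.
#' @slot mseWeight numeric, embedding-alignment weight lambda.
#' @slot pairing data.frame with columns `rna_cell_id`, `atac_cell_id`.
#' @export
setClass("MultimodalVAE", slots = c(
  rna = "TemporalVAE", atac = "TemporalVAE", mseWeight = "numeric",
  pairing = "data.frame"))

#' @describeIn MultimodalVAE-class compact display
#' @param object a `MultimodalVAE`
#' @export
setMethod("show", "MultimodalVAE", function(object) {
  cat(sprintf("MultimodalVAE: RNA (%d genes) + ATAC (%d peaks), lambda = %g\n",
              length(object@rna@featureIds), length(object@atac@featureIds),
              object@mseWeight))
  cat(sprintf("  %d coassay pairs\n", nrow(object@pairing)))
  invisible(NULL)
})

#' Time-lagged cross-correlation matrix
#'
#' A shift-by-pair matrix of Pearson correlations between a predicted
#' gene-expression trajectory and the peak-accessibility trajectory
#' shifted along time. With the default shift grid (-0.5 to 0.5 days in
#' 0.01-day steps) each column is a 101-dimensional TLCC vector for one
#' (peak, gene, cell) triple.
#'
#' @slot shifts numeric vector of time shifts (days).
#' @slot correlations matrix, `length(shifts)` x number of triples.
#' @slot pairIndex data.frame with columns `peak_id`, `gene_id`, `cell_id`.
#' @export
setClass("TLCCMatrix", slots = c(
  shifts = "numeric", correlations = "matrix", pairIndex = "data.frame"))

setValidity("TLCCMatrix", function(object) {
  msg <- character(0)
  if (nrow(object@correlations) != length(object@shifts))
    msg <- c(msg, "correlations must have one row per shift")
  if (ncol(object@correlations) != nrow(object@pairIndex))
    msg <- c(msg, "pairIndex must have one row per column of correlations")
  vals <- object@correlations[is.finite(object@correlations)]
  if (length(vals) && (min(vals) < -1 - 1e-8 || max(vals) > 1 + 1e-8))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn TLCCMatrix-class compact display
#' @param object a `TLCCMatrix`
#' @export
setMethod("show", "TLCCMatrix", function(object) {
  cat(sprintf("TLCCMatrix: %d shifts x %d (peak, gene, cell) triples\n",
              length(object@shifts), ncol(object@correlations)))
  invisible(NULL)
})
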