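#' Read a TemporalProfiles object from Matrix Market + TSV files
#'
#' Loads a sparse cell-by-feature (or feature-by-cell) count matrix in
#' Matrix Market format together with a feature list and a cell metadata
#' table, and validates them into a [TemporalProfiles-class].
#'
#' The metadata TSV must have columns `cell_id`, `time`, `condition`,
#' `batch`, and optionally `cell_type`. The matrix is oriented
#' automatically: whichever dimension matches the number of metadata
#' rows is taken as cells (features x cells is the stored orientation).
#'
#' @param matrixPath path to the `.mtx` file.
#' @param featuresPath path to a headerless one-column TSV of feature ids.
#' @param cellsMetaPath path to the cell metadata TSV (with header).
#' @param modality `"rna"` or `"atac"`; ATAC entries are binarized.
#' @return A [TemporalProfiles-class].
#' @seealso [writeTemporalProfiles()]
#' @export
readTemporalProfiles <- function(matrixPath, featuresPath, cellsMetaPath,
                                 modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  m <- Matrix::readMM(matrixPath)
  feats <- read.delim(featuresPath, header = FALSE,
                      stringsAsFactors = FALSE)[, 1]
  meta <- read.delim(cellsMetaPath, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_id", "time", "condition", "batch")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop(sprintf("metadata file '%s' lacks column(s): %s",
                 cellsMetaPath, paste(miss, collapse = ", ")))
  nc <- nrow(meta)
  if (ncol(m) == nc && nrow(m) == length(feats)) {
    # features x cells already
  } else if (nrow(m) == nc && ncol(m) == length(feats)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(paste0("dimension mismatch: matrix '%s' is %d x %d but '%s' ",
                        "has %d features and '%s' has %d cells"),
                 matrixPath, nrow(m), ncol(m), featuresPath, length(feats),
                 cellsMetaPath, nc))
  }
  if (length(m@x) && min(m@x) < 0)
    stop(sprintf("matrix '%s' contains negative counts", matrixPath))
  TemporalProfiles(m, time = meta$time, condition = meta$condition,
                   batch = meta$batch,
                   cellType = if ("cell_type" %in% colnames(meta)) meta$cell_type,
                   modality = modality, featureIds = as.character(feats),
                   cellIds = as.character(meta$cell_id))
}

#' Write a TemporalProfiles object to Matrix Market + TSV files
#'
#' Writes `counts.mtx`, `features.tsv` and `cells.tsv` under `dir`,
#' in the layout [readTemporalProfiles()] reads back.
#'
#' @param x a [TemporalProfiles-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeTemporalProfiles <- function(x, dir) {
  stopifnot(methods::is(x, "TemporalProfiles"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.mtx", "features.tsv", "cells.tsv"))
  Matrix::writeMM(SummarizedExperiment::assay(x, "counts"), paths[1])
  write.table(data.frame(rownames(x)), paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- data.frame(cell_id = colnames(x), time = timePoint(x),
                     condition = conditionLabel(x), batch = batchLabel(x),
                     stringsAsFactors = FALSE)
  if (!is.null(cellType(x))) meta$cell_type <- cellType(x)
  write.table(meta, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Convert somite counts to embryonic days
#'
#' Early embryos are staged by somite count; each somite stage adds
#' 2/34 day. `base_day` anchors somite 0 and is an explicit argument
#' because the count-to-day anchor is an assumption, not a measurement.
#'
#' @param somite non-negative somite count(s).
#' @param baseDay day assigned to somite 0 (default 8.0).
#' @return `baseDay + somite * 2/34`, in days.
#' @examples
#' somiteToDay(1, 8)   # 8.0588...
#' somiteToDay(34, 8)  # 10
#' @export
somiteToDay <- function(somite, baseDay = 8.0) {
  if (any(!is.finite(somite)) || any(somite < 0))
    stop("somite counts must be finite and non-negative")
  baseDay + somite * (2 / 34)
}

#' Hold-out / validation / training split over time points
#'
#' All cells at `holdoutTimes` become the test set. Remaining cells are
#' split per time point into validation and training at
#' `valRatio` (default 1:4 validation:training), with at most `valCap`
#' validation cells per time point. Deterministic given `seed`; the
#' test set depends only on the hold-out times.
#'
#' @param x a [TemporalProfiles-class].
#' @param holdoutTimes numeric days; must all be observed in `x`.
#' @param valRatio validation fraction of non-held-out cells (default 0.2).
#' @param valCap maximum validation cells per time point (default 2000).
#' @param seed integer seed.
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(x, holdoutTimes = numeric(0), valRatio = 0.2,
                      valCap = 2000, seed = 1) {
  tm <- timePoint(x)
  obs <- sort(unique(tm))
  bad <- setdiff(holdoutTimes, obs)
  if (length(bad))
    stop(sprintf("holdout time(s) %s not observed; observed times: %s",
                 paste(bad, collapse = ", "), paste(obs, collapse = ", ")))
  ids <- colnames(x)
  test <- ids[tm %in% holdoutTimes]
  rest_times <- setdiff(obs, holdoutTimes)
  if (!length(rest_times))
    stop("all cells fall at hold-out times; nothing left to train on")
  train <- character(0); val <- character(0)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (t in rest_times) {
    at <- ids[tm == t]
    nv <- min(floor(length(at) * valRatio), valCap)
    pick <- if (nv > 0) sample(at, nv) else character(0)
    val <- c(val, pick)
    train <- c(train, setdiff(at, pick))
  }
  methods::new("SplitPlan", trainIds = train, valIds = val, testIds = test,
               holdoutTimes = as.numeric(holdoutTimes), valRatio = valRatio,
               valCap = valCap, seed = as.numeric(seed))
}

#' Read and validate a coassay pairing table
#'
#' A coassay pairing is a one-to-one correspondence between RNA and ATAC
#' cells measured jointly. The TSV must have columns `rna_cell_id` and
#' `atac_cell_id`; no id may appear twice, and all ids must exist in the
#' corresponding objects when they are supplied.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @param rna,atac optional [TemporalProfiles-class] objects to validate
#'   the ids against.
#' @return data.frame with columns `rna_cell_id`, `atac_cell_id`.
#' @export
readCoassayPairing <- function(path, rna = NULL, atac = NULL) {
  pairs <- if (is.data.frame(path)) path else
    read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("rna_cell_id", "atac_cell_id")
  miss <- setdiff(need, colnames(pairs))
  if (length(miss))
    stop(sprintf("pairing lacks column(s): %s", paste(miss, collapse = ", ")))
  pairs <- pairs[, need]
  pairs[] <- lapply(pairs, as.character)
  if (anyDuplicated(pairs$rna_cell_id) || anyDuplicated(pairs$atac_cell_id))
    stop("pairing is not one-to-one: duplicated cell id")
  if (!is.null(rna)) {
    bad <- setdiff(pairs$rna_cell_id, colnames(rna))
    if (length(bad))
      stop(sprintf("%d paired RNA cell id(s) missing from the RNA object (e.g. %s)",
                   length(bad), bad[1]))
  }
  if (!is.null(atac)) {
    bad <- setdiff(pairs$atac_cell_id, colnames(atac))
    if (length(bad))
      stop(sprintf("%d paired ATAC cell id(s) missing from the ATAC object (e.g. %s)",
                   length(bad), bad[1]))
  }
  pairs
}
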