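#' Accessors for TemporalProfiles metadata
#'
#' Per-cell metadata accessors: collection time in days, condition and
#' batch labels, the optional cell-type annotation, and the modality.
#'
#' @param x a [TemporalProfiles-class] object.
#' @return `timePoint` returns a numeric vector (days); `conditionLabel`,
#'   `batchLabel` character vectors; `cellType` a character vector or
#'   `NULL` when no annotation is present; `modality` a length-1
#'   character.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
setGeneric("timePoint", function(x) standardGeneric("timePoint"))

#' @rdname profile-accessors
#' @export
setMethod("timePoint", "TemporalProfiles",
          function(x) SummarizedExperiment::colData(x)$time)

#' @rdname profile-accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname profile-accessors
#' @export
setMethod("conditionLabel", "TemporalProfiles",
          function(x) SummarizedExperiment::colData(x)$condition)

#' @rdname profile-accessors
#' @export
setGeneric("batchLabel", function(x) standardGeneric("batchLabel"))

#' @rdname profile-accessors
#' @export
setMethod("batchLabel", "TemporalProfiles",
          function(x) SummarizedExperiment::colData(x)$batch)

#' @rdname profile-accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname profile-accessors
#' @export
setMethod("cellType", "TemporalProfiles", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cell_type" %in% colnames(cd)) cd$cell_type else NULL
})

#' @rdname profile-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname profile-accessors
#' @export
setMethod("modality", "TemporalProfiles", function(x) x@modality)

#' @rdname profile-accessors
#' @export
setMethod("modality", "TemporalVAE", function(x) x@modality)

#' Accessors for SplitPlan cell-id sets
#'
#' @param x a [SplitPlan-class].
#' @return character vector of cell ids.
#' @name split-accessors
NULL

#' @rdname split-accessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname split-accessors
#' @export
setMethod("trainIds", "SplitPlan", function(x) x@trainIds)

#' @rdname split-accessors
#' @export
setGeneric("valIds", function(x) standardGeneric("valIds"))

#' @rdname split-accessors
#' @export
setMethod("valIds", "SplitPlan", function(x) x@valIds)

#' @rdname split-accessors
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @rdname split-accessors
#' @export
setMethod("testIds", "SplitPlan", function(x) x@testIds)
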