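#' Accessors for crossExpress classes
#'
#' Small read-only accessors for the package's S4 containers.
#'
#' @param x an object of the documented class.
#' @return `targetRanges` the underlying `GRanges`; `targetName` /
#'   `platformId` / `featureName` a string; `superIDs` the distinct
#'   superIDs; `summaryValues` the numeric matrix; `summaryKind`
#'   `"closed"` or `"open"`; `annotationTable` the `DataFrame`;
#'   `featureNames` the registered exclusion-feature names;
#'   `featureTags` the member tag ids of a derived feature.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("targetRanges", function(x) standardGeneric("targetRanges"))

#' @rdname accessors
#' @export
setMethod("targetRanges", "TargetReference", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("targetName", function(x) standardGeneric("targetName"))

#' @rdname accessors
#' @export
setMethod("targetName", "TargetReference", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("superIDs", function(x) standardGeneric("superIDs"))

#' @rdname accessors
#' @export
setMethod("superIDs", "TargetReference", function(x)
  unique(S4Vectors::mcols(x@ranges)$superID))

#' @rdname accessors
#' @export
setMethod("superIDs", "PlatformSummary", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setGeneric("platformId", function(x) standardGeneric("platformId"))

#' @rdname accessors
#' @export
setMethod("platformId", "PlatformSummary", function(x) x@platformId)

#' @rdname accessors
#' @export
setGeneric("summaryKind", function(x) standardGeneric("summaryKind"))

#' @rdname accessors
#' @export
setMethod("summaryKind", "PlatformSummary", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("summaryValues", function(x) standardGeneric("summaryValues"))

#' @rdname accessors
#' @export
setMethod("summaryValues", "PlatformSummary", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' @rdname accessors
#' @export
setMethod("annotationTable", "TagAnnotation", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setMethod("featureNames", "TagAnnotation", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))

#' @rdname accessors
#' @export
setMethod("featureName", "ExclusionFeature", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("featureTags", function(x) standardGeneric("featureTags"))

#' @rdname accessors
#' @export
setMethod("featureTags", "ExclusionFeature", function(x) x@tags)

setMethod("show", "TargetReference", function(object) {
  cat("TargetReference '", object@name, "': ", length(object@ranges),
      " intervals, ", length(unique(names(object@ranges))),
      " full target ids, ", length(superIDs(object)), " superIDs\n",
      sep = "")
})

setMethod("show", "ExclusionFeature", function(object) {
  if (object@derived) {
    cat("ExclusionFeature '", object@name, "' (derived): ",
        length(object@tags), " tags\n", sep = "")
  } else {
    cat("ExclusionFeature '", object@name, "': ",
        length(object@ranges), " intervals\n", sep = "")
  }
})

setMethod("show", "TagAnnotation", function(object) {
  tab <- object@table
  cat("TagAnnotation: ", nrow(tab), " tags (",
      sum(lengths(tab$matchedFull) > 0L), " matched), features: ",
      paste(object@features, collapse = ", "), "\n", sep = "")
})

setMethod("show", "PlatformSummary", function(object) {
  cat("PlatformSummary '", object@platformId, "' (", object@kind, "): ",
      nrow(object@values), " superIDs x ", ncol(object@values),
      " column(s)\n", sep = "")
})

setMethod("show", "MedianPolishFit", function(object) {
  cat("MedianPolishFit: ", length(object@rowEffects), " x ",
      length(object@colEffects), ", overall = ",
      format(object@overall, digits = 6), ", ", object@iterations,
      " iteration(s), converged = ", object@converged, "\n", sep = "")
})

setMethod("show", "FixtureSpec", function(object) {
  cat("FixtureSpec: ", object@nGenes, " genes on ", object@chromCount,
      " chromosome(s); ", 2L * object@nClosedSamplesPerGroup,
      " closed samples, ", 2L * object@nOpenSamplesPerGroup,
      " open platforms; seed ", object@seed, "\n", sep = "")
})

setMethod("show", "CombineConfig", function(object) {
  cat("CombineConfig: ", length(object@closedPlatforms), " closed + ",
      length(object@openPlatforms), " open platform(s), target '",
      object@targetName, "', exclusions [",
      paste(object@exclusionNames, collapse = ", "), "], join = ",
      object@joinMode, "\n", sep = "")
})
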