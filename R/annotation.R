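#' Construct an exclusion feature
#'
#' Interval-based features (e.g. SNP positions) carry a `GRanges`;
#' derived features (e.g. the multiTarget set) carry tag ids directly.
#' SNP-style features with attribute sub-filters (variant class,
#' functional category, validation status) are supported by pre-filtering
#' the feature BED before constructing the feature; no attribute parsing
#' happens here.
#'
#' @param name feature name, unique within a run.
#' @param ranges `GRanges` of feature intervals (interval features).
#' @param tags character vector of member tag ids (derived features).
#' @param derived logical.
#' @return an [ExclusionFeature].
#' @export
exclusionFeature <- function(name, ranges = GenomicRanges::GRanges(),
                             tags = character(), derived = length(tags) > 0L) {
  if (length(ranges) && is.null(names(ranges)))
    names(ranges) <- paste0(name, "_", seq_along(ranges))
  new("ExclusionFeature", name = name, ranges = ranges,
      derived = derived, tags = as.character(tags))
}

#' Annotate tags with matched targets and exclusion-feature hits
#'
#' For each distinct tag id, records which full target ids and superIDs
#' any of its alignments overlap (a tag with multiple genomic alignments
#' contributes all of them — cross-hybridization is a property of the
#' tag, not of one alignment), plus one presence/absence flag per
#' exclusion feature. Interval features are matched ignoring strand,
#' since features like SNPs annotate both strands. The derived
#' `multiTarget` feature — tags whose alignments hit two or more
#' distinct superIDs — is computed automatically and appears as the
#' `hit.multiTarget` column.
#'
#' Tags with no target match are retained with empty matched sets so
#' run statistics can report them as unmatched.
#'
#' @param tags named `GRanges` of tag alignments (names = tag ids; a tag
#'   id may appear on several rows).
#' @param target a [TargetReference].
#' @param features list of interval-based [ExclusionFeature]s.
#' @param strandPolicy,minOverlap passed to [matchIntervals()] for
#'   tag-to-target matching.
#' @return a [TagAnnotation].
#' @export
annotateTags <- function(tags, target, features = list(),
                         strandPolicy = c("require", "ignore"),
                         minOverlap = 1L) {
  strandPolicy <- match.arg(strandPolicy)
  stopifnot(is(target, "TargetReference"))
  fnames <- vapply(features, featureName, "")
  if (anyDuplicated(fnames))
    stop("duplicate exclusion feature name: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "))
  if ("multiTarget" %in% fnames)
    stop("'multiTarget' is derived automatically and cannot be supplied")
  tag_ids <- unique(names(tags))
  pairs <- matchIntervals(tags, targetRanges(target),
                          strandPolicy = strandPolicy,
                          minOverlap = minOverlap)
  sup_of <- S4Vectors::mcols(targetRanges(target))$superID
  names(sup_of) <- names(targetRanges(target))
  sup_of <- sup_of[!duplicated(names(sup_of))]
  full_by_tag <- split(pairs$subject_id, factor(pairs$query_id, tag_ids))
  matchedFull <- IRanges::CharacterList(lapply(full_by_tag, unique))
  matchedSuper <- IRanges::CharacterList(
    lapply(full_by_tag, function(f) unique(unname(sup_of[unique(f)]))))
  tab <- S4Vectors::DataFrame(tag_id = tag_ids,
                              matchedFull = matchedFull,
                              matchedSuper = matchedSuper)
  for (f in features) {
    if (f@derived) {
      hit <- tag_ids %in% f@tags
    } else {
      fp <- matchIntervals(tags, f@ranges, strandPolicy = "ignore",
                           minOverlap = 1L)
      hit <- tag_ids %in% fp$query_id
    }
    tab[[paste0("hit.", featureName(f))]] <- hit
  }
  tab$hit.multiTarget <- lengths(matchedSuper) >= 2L
  new("TagAnnotation", table = tab,
      features = c(fnames, "multiTarget"))
}

#' Derive the multiTarget exclusion feature
#'
#' Returns the derived feature whose members are the tags matched to two
#' or more distinct superIDs — candidates for cross-hybridization. The
#' definition is at the superID level: a tag hitting two exons (or
#' isoforms) of one gene is not multiTarget. Idempotent and dependent
#' only on the matched superID sets.
#'
#' @param annotation a [TagAnnotation].
#' @param level `"super"` (default, distinct superIDs) or `"full"`
#'   (distinct full target ids).
#' @return an [ExclusionFeature] with `derived = TRUE`.
#' @export
deriveMultiTarget <- function(annotation, level = c("super", "full")) {
  level <- match.arg(level)
  tab <- annotationTable(annotation)
  m <- if (level == "super") tab$matchedSuper else tab$matchedFull
  exclusionFeature("multiTarget", tags = tab$tag_id[lengths(m) >= 2L],
                   derived = TRUE)
}

#' Apply selected exclusion features
#'
#' Surviving tags are those matched to at least one target and flagged
#' by none of the selected features. Selecting no feature excludes
#' nothing beyond unmatched tags. Adding a feature can only shrink the
#' surviving set.
#'
#' @param annotation a [TagAnnotation].
#' @param selected character vector of feature names (may be empty; may
#'   include `"multiTarget"`).
#' @return character vector of surviving tag ids.
#' @export
applyExclusions <- function(annotation, selected = character()) {
  tab <- annotationTable(annotation)
  avail <- featureNames(annotation)
  unknown <- setdiff(selected, avail)
  if (length(unknown))
    stop("unknown exclusion feature(s) ",
         paste(unknown, collapse = ", "), "; available: ",
         paste(avail, collapse = ", "))
  keep <- lengths(tab$matchedFull) > 0L
  for (f in selected) keep <- keep & !tab[[paste0("hit.", f)]]
  tab$tag_id[keep]
}

#' Write a tag annotation table as TSV
#'
#' Columns: `tag_id`, comma-joined matched full target ids, then one
#' TRUE/FALSE column per feature.
#'
#' @param annotation a [TagAnnotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTagAnnotation <- function(annotation, path) {
  tab <- annotationTable(annotation)
  df <- data.frame(
    tag_id = tab$tag_id,
    matched_targets = vapply(tab$matchedFull, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  for (f in featureNames(annotation))
    df[[f]] <- tab[[paste0("hit.", f)]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write derived-feature membership as a one-column text file
#'
#' @param feature a derived [ExclusionFeature].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTags <- function(feature, path) {
  writeLines(featureTags(feature), path)
  invisible(path)
}
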