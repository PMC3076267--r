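#' TargetReference: a user-defined expression-unit reference
#'
#' A set of genomic intervals whose identifiers follow the
#' `superID@subID` convention (for example `BRCA1@Exon2`): the superID
#' names the expression unit (typically a gene) and the subID names a
#' sub-feature (typically an exon). Tags are matched against these
#' intervals and summarized per superID.
#'
#' Intervals are held as a [GenomicRanges::GRanges] whose names are the
#' full `superID@subID` identifiers, with `superID` and `subID` metadata
#' columns. All intervals sharing a full identifier must lie on one
#' chromosome and strand.
#'
#' @slot name single string naming the reference (e.g. a database tag).
#' @slot ranges `GRanges` of target sub-intervals.
#'
#' @aliases TargetReference
#' @exportClass TargetReference
setClass("TargetReference",
  representation(name = "character", ranges = "GRanges"))

setValidity("TargetReference", function(object) {
  gr <- object@ranges
  ids <- names(gr)
  if (length(gr) == 0L) return("target reference has no intervals")
  if (is.null(ids) || any(!nzchar(ids)))
    return("all target intervals must be named")
  n_at <- lengths(regmatches(ids, gregexpr("@", ids, fixed = TRUE)))
  bad <- ids[n_at != 1L]
  if (length(bad))
    return(paste0("target ids must contain exactly one '@': ",
                  paste(unique(bad), collapse = ", ")))
  parts <- strsplit(ids, "@", fixed = TRUE)
  sup <- vapply(parts, `[`, "", 1L)
  sub <- vapply(parts, `[`, "", 2L)
  if (any(!nzchar(sup)) || any(!nzchar(sub)))
    return("superID and subID must both be non-empty")
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- as.character(GenomicRanges::strand(gr))
  key <- paste(ch, st, sep = "\r")
  if (any(vapply(split(key, ids), function(k) length(unique(k)) > 1L, NA)))
    return("intervals of one full target id must share chromosome and strand")
  TRUE
})

#' ExclusionFeature: a filter for undesirable tags
#'
#' Either an interval-based feature (for example SNP positions: a tag is
#' hit when any of its alignments overlaps a feature interval) or a
#' derived feature defined directly as a set of tag identifiers (the
#' automatically generated `multiTarget` cross-hybridization set).
#'
#' @slot name single string, unique within a run.
#' @slot ranges `GRanges` of feature intervals (empty for derived
#'   features).
#' @slot derived logical flag; derived features carry tag ids instead of
#'   intervals.
#' @slot tags character vector of member tag ids (derived features only).
#'
#' @aliases ExclusionFeature
#' @exportClass ExclusionFeature
setClass("ExclusionFeature",
  representation(name = "character", ranges = "GRanges",
                 derived = "logical", tags = "character"),
  prototype(derived = FALSE, tags = character()))

setValidity("ExclusionFeature", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("feature name must be a single non-empty string")
  if (!object@derived && length(object@ranges) == 0L)
    return("interval-based exclusion feature must have at least one interval")
  TRUE
})

#' TagAnnotation: per-tag match and exclusion-hit table
#'
#' One row per distinct tag id, recording the full target ids and
#' superIDs the tag's alignments overlap, plus one logical column per
#' exclusion feature. Tags with no target match are retained with empty
#' matched sets so they can be reported as unmatched.
#'
#' @slot table an [S4Vectors::DataFrame] with columns `tag_id`
#'   (character), `matchedFull` and `matchedSuper`
#'   ([IRanges::CharacterList]), and one logical `hit.<feature>` column
#'   per registered feature.
#' @slot features character vector of registered feature names.
#'
#' @aliases TagAnnotation
#' @exportClass TagAnnotation
setClass("TagAnnotation",
  representation(table = "DataFrame", features = "character"))

setValidity("TagAnnotation", function(object) {
  tab <- object@table
  need <- c("tag_id", "matchedFull", "matchedSuper")
  if (!all(need %in% colnames(tab)))
    return("annotation table must have tag_id, matchedFull, matchedSuper")
  if (anyDuplicated(tab$tag_id))
    return("tag ids must be unique in an annotation table")
  hitcols <- paste0("hit.", object@features)
  if (!all(hitcols %in% colnames(tab)))
    return("every registered feature needs a hit.<name> column")
  TRUE
})

#' PlatformSummary: target-level values for one platform
#'
#' The result of summarization: one row per superID. Closed platforms
#' carry one log2-scale column per sample; open platforms carry a single
#' nonnegative RPKM column.
#'
#' @slot platformId single string.
#' @slot kind `"closed"` or `"open"`.
#' @slot values numeric matrix, rownames = superIDs, colnames = samples.
#'
#' @aliases PlatformSummary
#' @exportClass PlatformSummary
setClass("PlatformSummary",
  representation(platformId = "character", kind = "character",
                 values = "matrix"))

setValidity("PlatformSummary", function(object) {
  if (!object@kind %in% c("closed", "open"))
    return("kind must be 'closed' or 'open'")
  if (is.null(rownames(object@values)))
    return("summary matrix needs superID rownames")
  if (anyDuplicated(rownames(object@values)))
    return("superIDs must be unique")
  if (object@kind == "open") {
    if (ncol(object@values) != 1L)
      return("an open platform summarizes to a single RPKM column")
    if (any(object@values < 0, na.rm = TRUE))
      return("RPKM values must be nonnegative")
  }
  TRUE
})

#' MedianPolishFit: additive decomposition from Tukey median polish
#'
#' Holds the decomposition `x[i, j] = overall + row[i] + col[j] +
#' residual[i, j]`, which is exact by construction at every iteration.
#'
#' @slot overall numeric scalar.
#' @slot rowEffects,colEffects numeric vectors.
#' @slot residuals numeric matrix.
#' @slot iterations number of full row+column sweeps performed.
#' @slot converged logical.
#'
#' @aliases MedianPolishFit
#' @exportClass MedianPolishFit
setClass("MedianPolishFit",
  representation(overall = "numeric", rowEffects = "numeric",
                 colEffects = "numeric", residuals = "matrix",
                 iterations = "integer", converged = "logical"))

#' FixtureSpec: parameters of the synthetic data generator
#'
#' Defines the study conditions emulated by [generateFixture()]: a toy
#' genome of non-overlapping multi-exon genes, a closed platform whose
#' probes tile each gene's 3'-most exon, open platforms (one per sample)
#' whose reads spread across all exons, planted cross-hybridizing
#' (multiTarget) tags, planted SNP overlaps, and planted two-group
#' differential expression.
#'
#' @slot seed integer; fixes every random draw.
#' @slot nGenes number of genes.
#' @slot exonsPerGene integer range (min, max) of exons per gene.
#' @slot chromCount number of chromosomes genes are spread over.
#' @slot nClosedSamplesPerGroup closed-platform samples per group.
#' @slot nOpenSamplesPerGroup open platforms (= samples) per group.
#' @slot probesPerGene probes tiling each gene's last exon.
#' @slot readsPerSample expected aligned reads per open sample.
#' @slot fractionMultitargetTags fraction of tags planted to also align
#'   inside a second gene.
#' @slot fractionSnpTags fraction of tags planted to overlap a 1-bp SNP.
#' @slot nDeGenes number of genes with planted differential expression.
#' @slot deLog2Effect log2 group effect added to DE genes in group A.
#' @slot closedNoiseSd sd of log2-scale probe noise.
#' @slot readDispersion negative-binomial dispersion of per-gene counts
#'   (0 gives Poisson).
#' @slot platformEffectSd sd (log2 units) of the per-gene closed-platform
#'   tag effect: a hybridization-efficiency bias shared by a gene's
#'   probes and constant across samples. It leaves within-platform
#'   agreement untouched but decouples the two technologies, the reason
#'   cross-platform correlations are moderate while within-platform
#'   correlations are very high.
#' @slot tissueEffectSd sd (log2 units) of the continuous per-gene group
#'   effect shared by both technologies. Tissue contrasts show
#'   widespread differential expression, not a handful of changed genes
#'   on a null background; this makes fold-change rankings meaningful at
#'   every list depth. Draws are truncated at half `deLog2Effect` so the
#'   `nDeGenes` spiked genes remain the extreme tail by construction.
#'
#' @aliases FixtureSpec
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(seed = "integer", nGenes = "integer",
                 exonsPerGene = "integer", chromCount = "integer",
                 nClosedSamplesPerGroup = "integer",
                 nOpenSamplesPerGroup = "integer",
                 probesPerGene = "integer", readsPerSample = "integer",
                 fractionMultitargetTags = "numeric",
                 fractionSnpTags = "numeric", nDeGenes = "integer",
                 deLog2Effect = "numeric", closedNoiseSd = "numeric",
                 readDispersion = "numeric",
                 platformEffectSd = "numeric",
                 tissueEffectSd = "numeric"))

setValidity("FixtureSpec", function(object) {
  frs <- c(object@fractionMultitargetTags, object@fractionSnpTags)
  if (any(frs < 0) || any(frs > 1)) return("fractions must lie in [0, 1]")
  cnt <- c(object@nGenes, object@chromCount, object@probesPerGene,
           object@nClosedSamplesPerGroup, object@nOpenSamplesPerGroup,
           object@readsPerSample)
  if (any(cnt < 1L)) return("counts must be positive")
  if (length(object@exonsPerGene) != 2L ||
      object@exonsPerGene[1] < 1L ||
      object@exonsPerGene[2] < object@exonsPerGene[1])
    return("exonsPerGene must be an increasing positive (min, max) pair")
  if (object@nDeGenes > object@nGenes)
    return("more DE genes than genes")
  if (object@readDispersion < 0 || object@closedNoiseSd < 0 ||
      object@platformEffectSd < 0 || object@tissueEffectSd < 0)
    return("dispersion and effect sds must be nonnegative")
  TRUE
})

#' CombineConfig: configuration of an end-to-end combine run
#'
#' @slot closedPlatforms list of lists with elements `id`, `bed`
#'   (tag/probe BED path) and `measurements` (probe-by-sample table
#'   path).
#' @slot openPlatforms named character vector of BED paths (one platform
#'   per sample).
#' @slot targetName name of a built target reference.
#' @slot exclusionNames exclusion features to apply (may include
#'   `"multiTarget"`).
#' @slot joinMode `"intersection"` or `"union"`.
#' @slot projectDir output directory.
#' @slot strandPolicy `"require"` or `"ignore"`.
#' @slot minOverlap minimum overlap in bases for tag-to-target matching.
#' @slot dialect BED coordinate dialect, `"standard"` or `"closed_end"`.
#'
#' @aliases CombineConfig
#' @exportClass CombineConfig
setClass("CombineConfig",
  representation(closedPlatforms = "list", openPlatforms = "character",
                 targetName = "character", exclusionNames = "character",
                 joinMode = "character", projectDir = "character",
                 strandPolicy = "character", minOverlap = "integer",
                 dialect = "character"))

setValidity("CombineConfig", function(object) {
  if (length(object@closedPlatforms) + length(object@openPlatforms) < 1L)
    return("at least one platform is required")
  if (!object@joinMode %in% c("intersection", "union"))
    return("joinMode must be 'intersection' or 'union'")
  if (!object@strandPolicy %in% c("require", "ignore"))
    return("strandPolicy must be 'require' or 'ignore'")
  if (!object@dialect %in% c("standard", "closed_end"))
    return("dialect must be 'standard' or 'closed_end'")
  if (object@minOverlap < 1L) return("minOverlap must be >= 1")
  TRUE
})
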