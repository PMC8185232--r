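#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.OMICS_LEVELS <- c("peptide", "protein", "transcript", "metabolite", "kego")

#' OmicsMatrix: an entities-by-samples abundance table
#'
#' Thin extension of \linkS4class{SummarizedExperiment} carrying a single
#' \code{"abundance"} assay plus two pieces of pipeline state: the omics
#' \code{level} of the entities (peptide, protein, transcript, metabolite or
#' kego) and whether the values are on the log2 scale. Missing measurements
#' are stored as \code{NA}; linear-scale values must be non-negative.
#'
#' @slot level character(1), one of \code{"peptide"}, \code{"protein"},
#'   \code{"transcript"}, \code{"metabolite"}, \code{"kego"}.
#' @slot isLog2 logical(1), \code{TRUE} when values are log2-transformed.
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  slots = c(level = "character", isLog2 = "logical")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@level) != 1L || !object@level %in% .OMICS_LEVELS)
    msg <- c(msg, sprintf("level must be one of: %s",
                          paste(.OMICS_LEVELS, collapse = ", ")))
  if (length(object@isLog2) != 1L || is.na(object@isLog2))
    msg <- c(msg, "isLog2 must be TRUE or FALSE")
  v <- assay(object, withDimnames = FALSE)
  if (is.null(rownames(object)))
    msg <- c(msg, "entity ids (rownames) are required")
  else if (anyDuplicated(rownames(object)))
    msg <- c(msg, "entity ids must be unique")
  if (is.null(colnames(object)))
    msg <- c(msg, "sample ids (colnames) are required")
  if (ncol(v) > 0L && nrow(v) > 0L) {
    allNA <- colSums(!is.na(v)) == 0L
    if (any(allNA))
      msg <- c(msg, sprintf("sample column(s) entirely missing: %s",
                            paste(colnames(object)[allNA], collapse = ", ")))
  }
  if (isFALSE(object@isLog2) && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "linear-scale values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, entities in rows (rownames = ids), samples in
#'   columns (colnames = sample ids). \code{NA} marks missing cells.
#' @param level omics level tag; see \linkS4class{OmicsMatrix}.
#' @param isLog2 logical(1); are the values log2-transformed?
#' @param colData optional \code{DataFrame}/data.frame of per-sample metadata.
#' @return an \linkS4class{OmicsMatrix}.
#' @examples
#' m <- OmicsMatrix(matrix(1:6, 3, 2,
#'        dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
#'        level = "transcript")
#' omicsLevel(m)
#' @export
OmicsMatrix <- function(values, level, isLog2 = FALSE, colData = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(abundance = values),
                             colData = colData)
  new("OmicsMatrix", se, level = level, isLog2 = isLog2)
}

#' StudyDesign: lines, tissues, replicates and iTRAQ plex layout
#'
#' Describes a knock-out versus wild-type study: the ordered genotype labels
#' (first label is the wild-type reference), the tissues, the replicate count
#' per line-by-tissue cell, a per-sample table, and the assignment of
#' proteomics samples to 8-plex iTRAQ channels. Each plex carries exactly one
#' pooled-reference channel so that plexes can be placed on a common scale.
#'
#' @slot lines character; genotype labels, first = wild type.
#' @slot tissues character; tissue labels.
#' @slot replicates integer(1); replicates per line x tissue.
#' @slot samples data.frame with columns sample, line, tissue, replicate.
#' @slot plexAssignments data.frame with columns plex, channel (1-8), sample
#'   (NA for unused channels), reference (logical).
#' @export
setClass("StudyDesign",
  slots = c(lines = "character", tissues = "character",
            replicates = "integer", samples = "data.frame",
            plexAssignments = "data.frame")
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@lines) < 2L)
    msg <- c(msg, "need a wild-type line plus at least one knock-out line")
  if (anyDuplicated(object@lines))
    msg <- c(msg, "duplicated line labels")
  pa <- object@plexAssignments
  need <- c("plex", "channel", "sample", "reference")
  if (!all(need %in% names(pa))) {
    msg <- c(msg, "plexAssignments must have columns plex, channel, sample, reference")
  } else {
    nref <- tapply(pa$reference, pa$plex, sum)
    if (any(nref != 1L))
      msg <- c(msg, "each plex must carry exactly one reference channel")
    sampleCh <- pa$sample[!pa$reference & !is.na(pa$sample)]
    if (anyDuplicated(sampleCh))
      msg <- c(msg, "a sample id appears in more than one plex channel")
    if (!all(object@samples$sample %in% sampleCh))
      msg <- c(msg, "every sample must be assigned to exactly one plex channel")
  }
  if (!all(c("sample", "line", "tissue", "replicate") %in% names(object@samples)))
    msg <- c(msg, "samples must have columns sample, line, tissue, replicate")
  if (length(msg)) msg else TRUE
})

#' PhenotypeNetwork: filtered protein interaction network
#'
#' Candidate proteins that passed the phenotype-correlation filters, connected
#' by interaction-table edges at or above the configured score, with per-node
#' z-score annotations (one per knock-out contrast) and a functional-category
#' label. Every node has degree >= 1.
#'
#' @slot nodes data.frame: column \code{node}, optional \code{category}, and
#'   one \code{z.<contrast>} column per contrast.
#' @slot edges data.frame with columns a, b, score.
#' @slot minScore numeric(1); the score threshold the edges satisfy.
#' @export
setClass("PhenotypeNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame", minScore = "numeric")
)

setValidity("PhenotypeNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("a", "b", "score") %in% names(e)))
    msg <- c(msg, "edges must have columns a, b, score")
  else {
    if (any(e$a == e$b)) msg <- c(msg, "self-edges are not allowed")
    key <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate unordered edge pairs")
    if (length(object@minScore) == 1L && any(e$score < object@minScore))
      msg <- c(msg, "edge below the declared minimum score")
    deg <- table(c(e$a, e$b))
    if (!all(object@nodes$node %in% names(deg)))
      msg <- c(msg, "isolated node (degree 0) present")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: a seeded synthetic multi-omics study with ground truth
#'
#' Bundle returned by \code{\link{generateStudy}}: spectrum-level iTRAQ
#' reports, transcript counts, metabolite abundances with internal-standard
#' and tissue-weight vectors, peptide-to-protein and KEGO maps, a reaction
#' table, the per-line lignin (G+S monomer) phenotype vector, a STRING-style
#' interaction table, and a \code{truth} list sufficient to recompute every
#' planted quantity independently of the pipeline.
#'
#' @export
setClass("SyntheticStudy",
  slots = c(design = "StudyDesign", spectra = "data.frame",
            transcripts = "OmicsMatrix", metabolites = "OmicsMatrix",
            metaboliteStandard = "numeric", tissueWeight = "numeric",
            pepMap = "data.frame", kegoMap = "data.frame",
            reactions = "data.frame", lignin = "numeric",
            interactions = "data.frame", truth = "list")
)
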