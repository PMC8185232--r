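#' @rdname OmicsMatrix-class
#' @param x an \linkS4class{OmicsMatrix}.
#' @export
setGeneric("omicsLevel", function(x) standardGeneric("omicsLevel"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("isLog2", function(x) standardGeneric("isLog2"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname OmicsMatrix-class
setMethod("omicsLevel", "OmicsMatrix", function(x) x@level)

#' @rdname OmicsMatrix-class
setMethod("isLog2", "OmicsMatrix", function(x) x@isLog2)

#' @rdname OmicsMatrix-class
setMethod("abundances", "OmicsMatrix", function(x)
  assay(x, "abundance"))

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s, %s scale]: %d entities x %d samples (%.1f%% missing)\n",
              object@level, if (object@isLog2) "log2" else "linear",
              nrow(object), ncol(object),
              100 * mean(is.na(assay(object)))))
})

#' @rdname StudyDesign-class
#' @param x a \linkS4class{StudyDesign}.
#' @export
setGeneric("studyLines", function(x) standardGeneric("studyLines"))

#' @rdname StudyDesign-class
#' @export
setGeneric("wildType", function(x) standardGeneric("wildType"))

#' @rdname StudyDesign-class
#' @export
setGeneric("studyTissues", function(x) standardGeneric("studyTissues"))

#' @rdname StudyDesign-class
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @rdname StudyDesign-class
#' @export
setGeneric("plexTable", function(x) standardGeneric("plexTable"))

#' @rdname StudyDesign-class
setMethod("studyLines", "StudyDesign", function(x) x@lines)
#' @rdname StudyDesign-class
setMethod("wildType", "StudyDesign", function(x) x@lines[1L])
#' @rdname StudyDesign-class
setMethod("studyTissues", "StudyDesign", function(x) x@tissues)
#' @rdname StudyDesign-class
setMethod("sampleTable", "StudyDesign", function(x) x@samples)
#' @rdname StudyDesign-class
setMethod("plexTable", "StudyDesign", function(x) x@plexAssignments)

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d lines (WT = %s), %d tissue(s), %d replicate(s)\n",
              length(object@lines), object@lines[1L],
              length(object@tissues), object@replicates))
  cat(sprintf("  %d samples over %d iTRAQ plex(es), one reference channel each\n",
              nrow(object@samples), length(unique(object@plexAssignments$plex))))
})

#' @rdname PhenotypeNetwork-class
#' @param x a \linkS4class{PhenotypeNetwork}.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname PhenotypeNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname PhenotypeNetwork-class
setMethod("networkNodes", "PhenotypeNetwork", function(x) x@nodes)
#' @rdname PhenotypeNetwork-class
setMethod("networkEdges", "PhenotypeNetwork", function(x) x@edges)

setMethod("show", "PhenotypeNetwork", function(object) {
  cat(sprintf("PhenotypeNetwork: %d nodes, %d edges (score >= %.2f)\n",
              nrow(object@nodes), nrow(object@edges), object@minScore))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy\n")
  show(object@design)
  cat(sprintf("  %d spectra | %d transcripts | %d metabolites | %d planted lignin-tracking proteins\n",
              nrow(object@spectra), nrow(object@transcripts),
              nrow(object@metabolites),
              length(object@truth$plantedProteins)))
})
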