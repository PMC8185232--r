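#' Build a StudyDesign
#'
#' Lays out every line-by-tissue-by-replicate sample and assigns the
#' proteomics samples to 8-plex iTRAQ channels, reserving one pooled-reference
#' channel per plex (channel 1 by convention) so plexes can later be aligned
#' on a common scale.
#'
#' @param lines character; genotype labels, first = wild-type reference.
#' @param tissues character; tissue labels.
#' @param replicates integer(1); replicates per line x tissue.
#' @param channelsPerPlex integer(1); iTRAQ plex width (default 8).
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' studyDesign(c("WT", "ko1"), "leaf", 2L)
#' @export
studyDesign <- function(lines, tissues, replicates, channelsPerPlex = 8L) {
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L, channelsPerPlex >= 2L)
  samples <- expand.grid(replicate = seq_len(replicates), line = lines,
                         tissue = tissues, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[, c("line", "tissue", "replicate")]
  samples$sample <- sprintf("%s.%s.r%d", samples$line, samples$tissue,
                            samples$replicate)
  samples <- samples[, c("sample", "line", "tissue", "replicate")]
  perPlex <- channelsPerPlex - 1L          # one channel is the reference pool
  nPlex <- ceiling(nrow(samples) / perPlex)
  pa <- expand.grid(channel = seq_len(channelsPerPlex),
                    plex = sprintf("plex%02d", seq_len(nPlex)),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  pa <- pa[, c("plex", "channel")]
  pa$reference <- pa$channel == 1L
  pa$sample <- NA_character_
  slots <- which(!pa$reference)
  pa$sample[slots[seq_len(nrow(samples))]] <- samples$sample
  new("StudyDesign", lines = lines, tissues = tissues,
      replicates = replicates, samples = samples, plexAssignments = pa)
}

#' Default knock-out study design
#'
#' Nine Arabidopsis lines -- wild type plus eight arogenate dehydratase (ADT)
#' knock-out genotypes of increasing order -- in leaf and stem tissue.
#'
#' @param replicates integer(1); replicates per line x tissue (default 3).
#' @param tissues tissue labels (default leaf and stem).
#' @return a \linkS4class{StudyDesign}.
#' @export
defaultStudyDesign <- function(replicates = 3L, tissues = c("leaf", "stem")) {
  studyDesign(
    lines = c("WT", "adt1", "adt3", "adt4", "adt5",
              "adt4/5", "adt1/4/5", "adt3/4/5", "adt3/4/5/6"),
    tissues = tissues, replicates = replicates)
}

#' Default lignin phenotype vector
#'
#' Per-line stem lignin G+S monomer levels in relative units. Wild type is
#' highest; the single adt1 knock-out is near wild type (the basis for the
#' adt1 z-score band filter), and higher-order knock-outs lose progressively
#' more lignin, down to roughly 30% of wild type in the triple and quadruple
#' mutants.
#'
#' @return named numeric vector of G+S levels, one per line.
#' @export
defaultLigninLevels <- function() {
  c(WT = 100, adt1 = 99, adt3 = 85, adt4 = 80, adt5 = 76,
    `adt4/5` = 60, `adt1/4/5` = 45, `adt3/4/5` = 32, `adt3/4/5/6` = 30)
}
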