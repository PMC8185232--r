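#' @importFrom SummarizedExperiment rowData rowData<-
#' @importFrom stats median sd setNames
NULL

#' Distribute a spectrum's base-peak intensity over its reporter channels
#'
#' Each identified MS/MS spectrum carries one base-peak intensity and eight
#' reporter-ion intensities. The per-channel peptide intensity is the
#' base-peak intensity distributed proportionally to each channel's share of
#' the total reporter signal, so the eight channel intensities sum to the
#' base-peak intensity and reproduce the reporter ratios exactly. Channels
#' with zero reporter signal get zero.
#'
#' @param basePeak positive numeric(1), base-peak intensity.
#' @param reporters numeric(8), non-negative reporter-ion intensities
#'   (channel order 113-121).
#' @return numeric(8) of per-channel intensities, or all-\code{NA} with a
#'   warning when every reporter is zero (spectrum skipped).
#' @examples
#' channelIntensities(1000, rep(1, 8))    # 125 per channel
#' @export
channelIntensities <- function(basePeak, reporters) {
  stopifnot(length(reporters) == 8L, basePeak > 0, all(reporters >= 0))
  tot <- sum(reporters)
  if (tot == 0) {
    warning("all reporter intensities zero; spectrum skipped")
    return(rep(NA_real_, 8L))
  }
  basePeak * reporters / tot
}

#' Aggregate spectrum reports into a peptide-by-sample matrix
#'
#' Converts every spectrum to channel intensities, sums multiple spectra of
#' the same peptide within a plex channel-wise on the linear scale, maps
#' (plex, channel) to sample ids through the study design -- the pooled
#' reference channel of plex P becomes pseudo-sample \code{ref.P} -- and
#' log2-transforms. Peptides absent from the peptide-to-protein map are
#' excluded and reported in the \code{rejects} metadata entry.
#'
#' @param spectra spectrum-report data.frame
#'   (see \code{\link{readSpectrumReports}}).
#' @param pepMap data.frame with columns peptide, protein.
#' @param design a \linkS4class{StudyDesign}.
#' @return peptide-level log2 \linkS4class{OmicsMatrix}; \code{rowData()$shared}
#'   flags peptides mapping to more than one protein; column metadata records
#'   plex and reference status.
#' @export
aggregatePeptides <- function(spectra, pepMap, design) {
  mapped <- unique(pepMap$peptide)
  rejects <- sort(setdiff(unique(spectra$peptide), mapped))
  if (length(rejects)) {
    message(sprintf("excluding %d unmapped peptide(s)", length(rejects)))
    spectra <- spectra[spectra$peptide %in% mapped, , drop = FALSE]
  }
  ri <- as.matrix(spectra[, paste0("ri", 1:8)])
  tot <- rowSums(ri)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d spectra with all-zero reporters skipped", sum(zero)))
    spectra <- spectra[!zero, , drop = FALSE]
    ri <- ri[!zero, , drop = FALSE]; tot <- tot[!zero]
  }
  inten <- spectra$base_peak * ri / tot

  pa <- plexTable(design)
  pa$column <- ifelse(pa$reference, paste0("ref.", pa$plex), pa$sample)
  pa <- pa[!is.na(pa$column), , drop = FALSE]
  peptides <- sort(unique(spectra$peptide))
  m <- matrix(0, length(peptides), nrow(pa),
              dimnames = list(peptides, pa$column))
  seen <- matrix(FALSE, length(peptides), nrow(pa))
  pidx <- match(spectra$peptide, peptides)
  for (j in seq_len(nrow(pa))) {
    rows <- which(spectra$plex == pa$plex[j])
    if (!length(rows)) next
    contrib <- rowsum(inten[rows, pa$channel[j]], pidx[rows])
    ii <- as.integer(rownames(contrib))
    m[ii, j] <- m[ii, j] + contrib[, 1L]
    seen[ii, j] <- TRUE
  }
  m[!seen | m == 0] <- NA_real_
  lg <- log2(m)
  nProt <- table(pepMap$peptide[!duplicated(pepMap[, c("peptide", "protein")])])
  om <- OmicsMatrix(lg, level = "peptide", isLog2 = TRUE,
                    colData = S4Vectors::DataFrame(
                      plex = pa$plex, reference = pa$reference,
                      row.names = pa$column))
  rowData(om)$shared <- as.integer(nProt[peptides]) > 1L
  S4Vectors::metadata(om)$rejects <- rejects
  om
}

#' Align the pooled-reference channel across plexes
#'
#' Every plex carries one pooled-reference channel. For each peptide row and
#' each plex in which it was observed, an additive log2 shift is applied so
#' that the peptide's reference value in that plex equals its mean reference
#' value across plexes; afterwards reference values for any peptide are
#' identical in every plex, placing all plexes on one scale. A peptide seen
#' in only one plex is left unshifted. Plex rows whose reference value is
#' missing cannot be anchored and are dropped (set missing) with a warning.
#'
#' @param pm peptide-level log2 \linkS4class{OmicsMatrix} from
#'   \code{\link{aggregatePeptides}}.
#' @return the aligned \linkS4class{OmicsMatrix}.
#' @export
alignReferencePool <- function(pm) {
  stopifnot(isLog2(pm))
  cd <- colData(pm)
  v <- abundances(pm)
  plexes <- unique(cd$plex)
  refCol <- vapply(plexes, function(p)
    which(cd$plex == p & cd$reference), integer(1))
  refVals <- v[, refCol, drop = FALSE]          # peptides x plex
  nDropped <- 0L
  for (k in seq_along(plexes)) {
    cols <- which(cd$plex == plexes[k])
    dat <- v[, cols, drop = FALSE]
    observed <- rowSums(!is.na(dat)) > 0L
    orphan <- observed & is.na(refVals[, k])
    if (any(orphan)) {
      v[orphan, cols] <- NA_real_
      refVals[orphan, k] <- NA_real_
      nDropped <- nDropped + sum(orphan)
    }
  }
  if (nDropped > 0L)
    warning(sprintf("%d peptide-plex row(s) lacked a reference value and were dropped",
                    nDropped))
  target <- rowMeans(refVals, na.rm = TRUE)
  for (k in seq_along(plexes)) {
    cols <- which(cd$plex == plexes[k])
    shift <- target - refVals[, k]
    shift[is.na(shift)] <- 0
    v[, cols] <- v[, cols, drop = FALSE] + shift
  }
  out <- OmicsMatrix(v, level = "peptide", isLog2 = TRUE, colData = cd)
  rowData(out) <- rowData(pm)
  S4Vectors::metadata(out) <- S4Vectors::metadata(pm)
  out
}

#' Mean-center every sample column
#'
#' Subtracts the per-column mean over observed (non-missing) cells, so each
#' iTRAQ channel column has mean zero on the log2 scale. Idempotent.
#'
#' @param pm a log2 \linkS4class{OmicsMatrix}.
#' @return the centered matrix.
#' @export
centerColumns <- function(pm) {
  stopifnot(isLog2(pm))
  v <- abundances(pm)
  v <- sweep(v, 2L, colMeans(v, na.rm = TRUE), "-")
  out <- OmicsMatrix(v, level = omicsLevel(pm), isLog2 = TRUE,
                     colData = colData(pm))
  rowData(out) <- rowData(pm)
  S4Vectors::metadata(out) <- S4Vectors::metadata(pm)
  out
}

# Group accessions whose peptide sets are identical (indistinguishable
# proteins); the group id joins the member accessions with ";".
.proteinGroups <- function(pepMap) {
  pepMap <- unique(pepMap[, c("peptide", "protein")])
  sets <- vapply(split(pepMap$peptide, pepMap$protein),
                 function(p) paste(sort(p), collapse = "\r"), character(1))
  grp <- vapply(split(names(sets), sets),
                function(acc) paste(sort(acc), collapse = ";"), character(1))
  groupOf <- setNames(rep(grp, lengths(split(names(sets), sets))),
                      unlist(split(names(sets), sets)))
  unique(data.frame(peptide = pepMap$peptide,
                    group = unname(groupOf[pepMap$protein]),
                    stringsAsFactors = FALSE))
}

#' Roll peptides up to protein values
#'
#' Working on the reference-aligned, column-centered peptide matrix: values
#' are un-logged (2^x), peptides are split into those unique to a single
#' protein group and those shared between groups, each set is summed per
#' group per sample, and one value per group is kept -- the unique-peptide
#' rollup when it is identified in every channel, otherwise the shared
#' rollup -- before re-logging. Proteins whose peptide sets are identical are
#' indistinguishable and reported as one group id joining the accessions
#' with ";".
#'
#' @param pm aligned, centered peptide-level log2 \linkS4class{OmicsMatrix}.
#' @param pepMap data.frame with columns peptide, protein.
#' @param keepReference keep the pooled-reference pseudo-sample columns
#'   (default FALSE).
#' @return protein-level log2 \linkS4class{OmicsMatrix};
#'   \code{rowData()$provenance} records \code{"unique-rollup"} or
#'   \code{"shared-rollup"} per protein group.
#' @export
rollupProteins <- function(pm, pepMap, keepReference = FALSE) {
  stopifnot(isLog2(pm))
  gm <- .proteinGroups(pepMap)
  lin <- 2^abundances(pm)
  gm <- gm[gm$peptide %in% rownames(lin), , drop = FALSE]
  nGrp <- tapply(gm$group, gm$peptide, function(g) length(unique(g)))
  uniqPep <- names(nGrp)[nGrp == 1L]

  sumSet <- function(peps) {
    sub <- gm[gm$peptide %in% peps, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    idx <- lin[sub$peptide, , drop = FALSE]
    obs <- rowsum((!is.na(idx)) + 0, sub$group)
    s <- rowsum(ifelse(is.na(idx), 0, idx), sub$group)
    s[obs == 0] <- NA_real_
    s
  }
  uniqRoll <- sumSet(intersect(gm$peptide, uniqPep))
  sharedRoll <- sumSet(setdiff(gm$peptide, uniqPep))

  groups <- sort(unique(gm$group))
  out <- matrix(NA_real_, length(groups), ncol(lin),
                dimnames = list(groups, colnames(lin)))
  prov <- rep(NA_character_, length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    u <- if (!is.null(uniqRoll) && g %in% rownames(uniqRoll)) uniqRoll[g, ] else NULL
    s <- if (!is.null(sharedRoll) && g %in% rownames(sharedRoll)) sharedRoll[g, ] else NULL
    if (!is.null(u) && !anyNA(u)) {
      out[i, ] <- u; prov[i] <- "unique-rollup"
    } else if (!is.null(s) && any(!is.na(s))) {
      out[i, ] <- s; prov[i] <- "shared-rollup"
    } else if (!is.null(u) && any(!is.na(u))) {
      out[i, ] <- u; prov[i] <- "unique-rollup"
    }
  }
  keep <- rowSums(!is.na(out)) > 0L
  out <- out[keep, , drop = FALSE]; prov <- prov[keep]
  if (!keepReference) {
    cd <- colData(pm)
    out <- out[, !cd$reference, drop = FALSE]
  }
  om <- OmicsMatrix(log2(out), level = "protein", isLog2 = TRUE)
  rowData(om)$provenance <- prov
  om
}

#' Roll unique peptides up to KEGO-ready protein linear values
#'
#' The KEGO collapse consumes the unique-peptide linear table (not the
#' preference-rule mixed table): per protein group per sample, the sum of its
#' unique peptides' linear values.
#'
#' @inheritParams rollupProteins
#' @return protein-level linear-scale \linkS4class{OmicsMatrix}.
#' @export
uniquePeptideLinear <- function(pm, pepMap, keepReference = FALSE) {
  stopifnot(isLog2(pm))
  gm <- .proteinGroups(pepMap)
  lin <- 2^abundances(pm)
  gm <- gm[gm$peptide %in% rownames(lin), , drop = FALSE]
  nGrp <- tapply(gm$group, gm$peptide, function(g) length(unique(g)))
  sub <- gm[gm$peptide %in% names(nGrp)[nGrp == 1L], , drop = FALSE]
  if (!nrow(sub)) stop("no unique peptides available")
  idx <- lin[sub$peptide, , drop = FALSE]
  obs <- rowsum((!is.na(idx)) + 0, sub$group)
  s <- rowsum(ifelse(is.na(idx), 0, idx), sub$group)
  s[obs == 0] <- NA_real_
  if (!keepReference) s <- s[, !colData(pm)$reference, drop = FALSE]
  s <- s[rowSums(!is.na(s)) > 0L, , drop = FALSE]
  OmicsMatrix(s, level = "protein", isLog2 = FALSE)
}

#' Remove low-abundance noise signals
#'
#' Log2 protein values below the noise floor primarily represent noise that
#' interferes with z-score calculation; cells strictly below the floor are
#' set missing (cells exactly at the floor are retained) and entities left
#' with no observed cell are removed.
#'
#' @param x a log2 \linkS4class{OmicsMatrix}.
#' @param floor numeric(1); default 2.0 log2 units.
#' @return the filtered matrix.
#' @export
dropNoiseFloor <- function(x, floor = 2.0) {
  stopifnot(isLog2(x))
  v <- abundances(x)
  v[v < floor] <- NA_real_
  keep <- rowSums(!is.na(v)) > 0L
  OmicsMatrix(v[keep, , drop = FALSE], level = omicsLevel(x), isLog2 = TRUE,
              colData = colData(x))
}
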