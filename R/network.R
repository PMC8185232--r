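#' Spearman correlation of protein fold-change profiles to lignin levels
#'
#' Correlates each protein's log2-ratio profile across the knock-out lines
#' with the per-line lignin G+S monomer vector, using rank correlation with
#' average ranks for ties over pairwise-complete lines. Constant profiles
#' give missing rho with a warning.
#'
#' @param profiles protein x line matrix of log2 ratios (stem contrasts), or
#'   a \linkS4class{OmicsMatrix}.
#' @param lignin named numeric; per-line G+S lignin level.
#' @return data.frame with columns protein, rho, n_lines.
#' @export
spearmanToLignin <- function(profiles, lignin) {
  if (is(profiles, "OmicsMatrix")) profiles <- abundances(profiles)
  lines <- intersect(colnames(profiles), names(lignin))
  if (length(lines) < 4L)
    stop("need at least 4 lines shared between profiles and lignin levels")
  lv <- lignin[lines]
  rho <- rep(NA_real_, nrow(profiles))
  nl <- integer(nrow(profiles))
  nConst <- 0L
  for (i in seq_len(nrow(profiles))) {
    x <- profiles[i, lines]
    ok <- is.finite(x)
    nl[i] <- sum(ok)
    if (nl[i] < 4L) next
    if (sd(x[ok]) == 0) { nConst <- nConst + 1L; next }
    rho[i] <- cor(x[ok], lv[ok], method = "spearman")
  }
  if (nConst > 0L)
    warning(sprintf("%d constant profile(s): rho set missing", nConst))
  data.frame(protein = rownames(profiles), rho = rho, n_lines = nl,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select lignin-tracking candidate proteins
#'
#' A protein passes when its rank correlation to the lignin vector is strong
#' in either direction (|rho| at or above the cutoff; both signs retained)
#' and its z-score in the adt1-versus-WT contrast sits inside the band --
#' adt1 retains near-wild-type lignin, so a genuinely lignin-tracking
#' protein should be essentially unchanged there.
#'
#' @param records data.frame from \code{\link{spearmanToLignin}}.
#' @param adt1Z named numeric; per-protein z in the adt1 stem contrast.
#' @param rhoCut Spearman threshold in (0, 1]; default 0.85.
#' @param adt1Band z band half-width; default 0.5.
#' @param inclusive use |rho| >= cutoff (default) rather than strictly
#'   greater.
#' @return the records with columns adt1_z and passes added.
#' @export
selectCandidates <- function(records, adt1Z, rhoCut = 0.85, adt1Band = 0.5,
                             inclusive = TRUE) {
  stopifnot(rhoCut > 0, rhoCut <= 1, adt1Band >= 0)
  records$adt1_z <- adt1Z[match(records$protein, names(adt1Z))]
  rhoPass <- if (inclusive) abs(records$rho) >= rhoCut else
    abs(records$rho) > rhoCut
  records$passes <- !is.na(records$rho) & rhoPass &
    !is.na(records$adt1_z) & abs(records$adt1_z) <= adt1Band
  records
}

#' Build the phenotype-correlated interaction network
#'
#' Restricts the interaction table to edges between passing candidates with
#' combined score at or above the minimum, drops candidates left without
#' any interaction, and annotates each surviving node with its z-score per
#' knock-out contrast (the red/blue node-coloring scale) and a
#' functional-category label from the KEGO map when available.
#'
#' @param candidates data.frame from \code{\link{selectCandidates}} (only
#'   rows with \code{passes} are used).
#' @param interactions data.frame with columns a, b, score
#'   (\code{\link{readInteractionTable}}).
#' @param zMatrix protein x contrast z matrix for node annotation.
#' @param minScore combined-score floor; default 0.4.
#' @param kegoMap optional data.frame (entity, kego, category) supplying the
#'   category label.
#' @return a \linkS4class{PhenotypeNetwork}.
#' @export
buildNetwork <- function(candidates, interactions, zMatrix, minScore = 0.4,
                         kegoMap = NULL) {
  pass <- candidates$protein[candidates$passes]
  if (!length(pass)) stop("no candidates passed the correlation filters")
  e <- interactions[interactions$a %in% pass & interactions$b %in% pass &
                      interactions$score >= minScore, , drop = FALSE]
  if (!nrow(e))
    stop("empty network: no candidate-candidate edge at score >= ", minScore,
         "; consider relaxing thresholds")
  nodes <- sort(unique(c(e$a, e$b)))
  nd <- data.frame(node = nodes, stringsAsFactors = FALSE)
  nd$category <- if (!is.null(kegoMap))
    kegoMap$category[match(nodes, kegoMap$entity)] else NA_character_
  zsub <- zMatrix[match(nodes, rownames(zMatrix)), , drop = FALSE]
  colnames(zsub) <- paste0("z.", colnames(zsub))
  nd <- cbind(nd, as.data.frame(zsub, row.names = NULL))
  rownames(e) <- NULL
  new("PhenotypeNetwork", nodes = nd,
      edges = e[, c("a", "b", "score")], minScore = minScore)
}
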