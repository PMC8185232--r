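#' Match detected metabolites to KEGO reactions
#'
#' One triad skeleton is formed per (metabolite, KEGO, role) where the
#' metabolite is the substrate or product of a reaction whose KEGO enzyme
#' family was detected in \emph{both} the transcript and the protein KEGO
#' tables. Reversible reactions give role \code{"reversible"} to each
#' detected participant; unidirectional reactions give \code{"substrate"} or
#' \code{"product"}.
#'
#' @param metabolites character; detected metabolite ids.
#' @param reactions reaction data.frame (kego, substrate, product,
#'   direction).
#' @param kegosTranscript,kegosProtein character; KEGO ids detected in each
#'   layer.
#' @return data.frame with columns metabolite, kego, role (possibly empty).
#' @export
matchReactions <- function(metabolites, reactions, kegosTranscript,
                           kegosProtein) {
  detected <- intersect(kegosTranscript, kegosProtein)
  rx <- reactions[reactions$kego %in% detected, , drop = FALSE]
  rows <- list()
  if (nrow(rx)) {
    sub <- rx[rx$substrate %in% metabolites, , drop = FALSE]
    prod <- rx[rx$product %in% metabolites, , drop = FALSE]
    rows$s <- data.frame(metabolite = sub$substrate, kego = sub$kego,
                         role = ifelse(sub$direction == "reversible",
                                       "reversible", "substrate"),
                         stringsAsFactors = FALSE)
    rows$p <- data.frame(metabolite = prod$product, kego = prod$kego,
                         role = ifelse(prod$direction == "reversible",
                                       "reversible", "product"),
                         stringsAsFactors = FALSE)
  }
  out <- unique(do.call(rbind, rows))
  if (is.null(out) || !nrow(out)) {
    message("no metabolite-KEGO reaction matches")
    return(data.frame(metabolite = character(), kego = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(out$metabolite, out$kego, out$role), , drop = FALSE]
}

#' Classify a reaction triad by the signs of its mean z-scores
#'
#' Cluster 1: transcripts, metabolites and proteins move together (both
#' all-up and all-down). Cluster 2: transcripts oppose metabolites and
#' proteins, which move together. Cluster 3: transcripts and metabolites
#' move together, proteins oppose. Cluster 4: transcripts and proteins move
#' together, metabolites oppose. Any exactly-zero mean gives
#' \code{"unclassified"}.
#'
#' @param meanZt,meanZm,meanZp numeric; mean z across knock-out contrasts for
#'   the transcript, metabolite and protein layer (vectorized).
#' @return character vector in \code{c("1","2","3","4","unclassified")}.
#' @examples
#' assignCluster(0.8, 1.2, 0.3)    # "1"
#' assignCluster(-0.5, 0.9, 0.4)   # "2"
#' @export
assignCluster <- function(meanZt, meanZm, meanZp) {
  st <- sign(meanZt); sm <- sign(meanZm); sp <- sign(meanZp)
  out <- rep("unclassified", length(st))
  ok <- is.finite(st) & is.finite(sm) & is.finite(sp) &
    st != 0 & sm != 0 & sp != 0
  same <- function(a, b) a == b
  out[ok & same(st, sm) & same(sm, sp)] <- "1"
  out[ok & !same(st, sm) & same(sm, sp)] <- "2"
  out[ok & same(st, sm) & !same(sm, sp)] <- "3"
  out[ok & same(st, sp) & !same(sm, sp) & !same(st, sm)] <- "4"
  out
}

.pearsonAcross <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warning("zero-variance profile: correlation set missing")
    return(NA_real_)
  }
  cor(x[ok], y[ok])
}

#' Assemble full reaction triads with profiles, correlations and clusters
#'
#' Attaches per-layer z-profiles across the knock-out contrasts to each
#' (metabolite, KEGO, role) skeleton, computes the mean z per layer, the
#' cluster assignment, and the three Pearson profile correlations r_tm
#' (transcript vs metabolite), r_pm (protein vs metabolite) and r_tp
#' (transcript vs protein) over pairwise-complete contrasts (missing when
#' fewer than 3 are complete).
#'
#' @param skeletons data.frame from \code{\link{matchReactions}}.
#' @param transcriptZ,proteinZ KEGO x contrast z matrices
#'   (\code{\link{contrastMatrix}} of the KEGO-level fold changes).
#' @param metaboliteZ metabolite x contrast z matrix.
#' @return data.frame: skeleton columns + mean_z_t, mean_z_m, mean_z_p,
#'   cluster, r_tm, r_pm, r_tp, and the per-contrast metabolite z profile
#'   kept as a matrix attribute \code{"profiles"}.
#' @export
profileCorrelations <- function(skeletons, transcriptZ, proteinZ,
                                metaboliteZ) {
  cons <- Reduce(intersect, list(colnames(transcriptZ), colnames(proteinZ),
                                 colnames(metaboliteZ)))
  if (length(cons) < 3L)
    stop("need at least 3 shared knock-out contrasts across the three layers")
  n <- nrow(skeletons)
  out <- skeletons
  out$mean_z_t <- out$mean_z_m <- out$mean_z_p <- NA_real_
  out$r_tm <- out$r_pm <- out$r_tp <- NA_real_
  for (i in seq_len(n)) {
    k <- skeletons$kego[i]; mmet <- skeletons$metabolite[i]
    tv <- if (k %in% rownames(transcriptZ)) transcriptZ[k, cons] else rep(NA_real_, length(cons))
    pv <- if (k %in% rownames(proteinZ)) proteinZ[k, cons] else rep(NA_real_, length(cons))
    mv <- if (mmet %in% rownames(metaboliteZ)) metaboliteZ[mmet, cons] else rep(NA_real_, length(cons))
    out$mean_z_t[i] <- if (all(is.na(tv))) NA_real_ else mean(tv, na.rm = TRUE)
    out$mean_z_p[i] <- if (all(is.na(pv))) NA_real_ else mean(pv, na.rm = TRUE)
    out$mean_z_m[i] <- if (all(is.na(mv))) NA_real_ else mean(mv, na.rm = TRUE)
    out$r_tm[i] <- .pearsonAcross(tv, mv)
    out$r_pm[i] <- .pearsonAcross(pv, mv)
    out$r_tp[i] <- .pearsonAcross(tv, pv)
  }
  out$cluster <- assignCluster(out$mean_z_t, out$mean_z_m, out$mean_z_p)
  out
}

#' Flag and order triads for the heatmap table
#'
#' Per metabolite: the green square (\code{most_abundant_kego}) marks the
#' KEGO with the highest mean abundance in the chosen layer; the blue circle
#' (\code{best_transcript_corr}) and orange circle
#' (\code{best_protein_corr}) mark the KEGOs with maximal r_tm and r_pm; the
#' grey circle (\code{single_reaction}) marks metabolites participating in
#' exactly one triad. Ties are broken by lexicographic KEGO id. Rows are
#' ordered by cluster, then role (substrate, product, reversible), then
#' descending mean metabolite z.
#'
#' @param triads data.frame from \code{\link{profileCorrelations}}.
#' @param kegoAbundance log2 kego-level \linkS4class{OmicsMatrix} of the
#'   abundance layer (protein by default upstream).
#' @return the triad table with four logical flag columns, ordered.
#' @export
flagAndOrder <- function(triads, kegoAbundance) {
  stopifnot(nrow(triads) > 0L)
  meanAb <- rowMeans(abundances(kegoAbundance), na.rm = TRUE)
  triads$single_reaction <- FALSE
  triads$most_abundant_kego <- FALSE
  triads$best_transcript_corr <- FALSE
  triads$best_protein_corr <- FALSE
  argmaxKego <- function(score, kego) {
    if (all(is.na(score))) return(kego[order(kego)][1L])
    top <- which(score == max(score, na.rm = TRUE))
    kego[top][order(kego[top])][1L]
  }
  for (mmet in unique(triads$metabolite)) {
    idx <- which(triads$metabolite == mmet)
    triads$single_reaction[idx] <- length(idx) == 1L
    ab <- meanAb[match(triads$kego[idx], names(meanAb))]
    triads$most_abundant_kego[idx[match(argmaxKego(ab, triads$kego[idx]),
                                        triads$kego[idx])]] <- TRUE
    triads$best_transcript_corr[idx[match(argmaxKego(triads$r_tm[idx],
                                                     triads$kego[idx]),
                                          triads$kego[idx])]] <- TRUE
    triads$best_protein_corr[idx[match(argmaxKego(triads$r_pm[idx],
                                                  triads$kego[idx]),
                                       triads$kego[idx])]] <- TRUE
  }
  roleOrd <- match(triads$role, c("substrate", "product", "reversible"))
  clusterOrd <- match(triads$cluster, c("1", "2", "3", "4", "unclassified"))
  out <- triads[order(clusterOrd, roleOrd, -triads$mean_z_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag proportions per reaction type and per cluster
#'
#' For each role and each cluster: the fraction of triads carrying each of
#' the four flags, and the joint fraction that are simultaneously the most
#' abundant KEGO and the best protein-correlated KEGO for their metabolite.
#' Empty groups are absent rather than zero-divided.
#'
#' @param triads flagged triad table from \code{\link{flagAndOrder}}.
#' @return data.frame with columns group_by, group, n and the five
#'   proportions.
#' @export
summarizeFlagDistribution <- function(triads) {
  stopifnot(nrow(triads) > 0L)
  summarize <- function(groupBy) {
    grp <- split(seq_len(nrow(triads)), triads[[groupBy]])
    do.call(rbind, lapply(names(grp), function(g) {
      idx <- grp[[g]]
      data.frame(group_by = groupBy, group = g, n = length(idx),
                 prop_single = mean(triads$single_reaction[idx]),
                 prop_most_abundant = mean(triads$most_abundant_kego[idx]),
                 prop_best_transcript = mean(triads$best_transcript_corr[idx]),
                 prop_best_protein = mean(triads$best_protein_corr[idx]),
                 prop_joint = mean(triads$most_abundant_kego[idx] &
                                     triads$best_protein_corr[idx]),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(summarize("role"), summarize("cluster"))
  rownames(out) <- NULL
  out
}
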