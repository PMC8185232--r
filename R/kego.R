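#' Collapse an abundance table into KEGO (KEGG Orthology) families
#'
#' Sums member linear values per KEGO family per sample -- protein KEGOs
#' from the unique-peptide linear table, transcript KEGOs from raw counts --
#' then converts to log2. An entity mapping to several KEGOs contributes its
#' full value to each; unmapped entities are dropped and counted in a
#' message.
#'
#' @param m linear-scale \linkS4class{OmicsMatrix} (transcript counts or the
#'   unique-peptide protein table).
#' @param kegoMap data.frame with columns entity, kego and optional category.
#' @return kego-level log2 \linkS4class{OmicsMatrix}; \code{rowData()$category}
#'   carries the functional-category label.
#' @export
collapseToKego <- function(m, kegoMap) {
  stopifnot(is(m, "OmicsMatrix"))
  if (isLog2(m))
    stop("collapseToKego needs linear-scale values; un-log first")
  map <- unique(kegoMap[, c("entity", "kego")])
  map <- map[map$entity %in% rownames(m), , drop = FALSE]
  if (!nrow(map)) stop("no entities of the matrix are covered by the KEGO map")
  nDropped <- length(setdiff(rownames(m), map$entity))
  if (nDropped)
    message(sprintf("%d unmapped entities dropped in KEGO collapse", nDropped))
  v <- abundances(m)[map$entity, , drop = FALSE]
  obs <- rowsum((!is.na(v)) + 0, map$kego)
  s <- rowsum(ifelse(is.na(v), 0, v), map$kego)
  s[obs == 0] <- NA_real_
  out <- OmicsMatrix(log2(ifelse(s == 0, NA, s)), level = "kego",
                     isLog2 = TRUE, colData = colData(m))
  if ("category" %in% names(kegoMap)) {
    cat <- kegoMap$category[match(rownames(out), kegoMap$kego)]
    rowData(out)$category <- cat
  }
  out
}

#' Transcript/protein overlap at gene and KEGO level
#'
#' Counts identifiers detected in both layers, in transcripts only and in
#' proteins only; repeats the comparison after mapping both sets to KEGO
#' families; and reports per-KEGG-category fractions of the KEGO-level
#' overlap.
#'
#' @param transcriptIds,proteinIds character vectors of detected ids.
#' @param kegoMap data.frame with columns entity, kego, category.
#' @return list with elements \code{gene} and \code{kego} (each named
#'   numeric: overlap, transcript_only, protein_only) and \code{categories}
#'   (data.frame of per-category overlap fractions).
#' @export
overlapSummary <- function(transcriptIds, proteinIds, kegoMap) {
  setCounts <- function(t, p)
    c(overlap = length(intersect(t, p)),
      transcript_only = length(setdiff(t, p)),
      protein_only = length(setdiff(p, t)))
  toKego <- function(ids)
    unique(kegoMap$kego[kegoMap$entity %in% ids])
  tK <- toKego(transcriptIds); pK <- toKego(proteinIds)
  catOf <- kegoMap$category[match(union(tK, pK), kegoMap$kego)]
  shared <- intersect(tK, pK)
  cats <- sort(unique(catOf[!is.na(catOf)]))
  catTab <- do.call(rbind, lapply(cats, function(cc) {
    members <- union(tK, pK)[!is.na(catOf) & catOf == cc]
    data.frame(category = cc, n_total = length(members),
               n_overlap = length(intersect(members, shared)),
               fraction = if (length(members))
                 length(intersect(members, shared)) / length(members) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(gene = setCounts(transcriptIds, proteinIds),
       kego = setCounts(tK, pK),
       categories = if (is.null(catTab))
         data.frame(category = character(), n_total = integer(),
                    n_overlap = integer(), fraction = numeric()) else catTab)
}

#' Pearson correlation between every pair of fold-change tables
#'
#' Takes a named list of log2-ratio profiles (named numeric vectors, or
#' entity x contrast matrices with matching contrast columns) and returns
#' the Pearson correlation over the shared, pairwise-complete entities for
#' every pair. Pairs sharing fewer than 3 entities get a missing cell with a
#' warning.
#'
#' @param tables named list of named numeric vectors or matrices.
#' @return symmetric correlation matrix.
#' @export
pairwiseProfileCorrelation <- function(tables) {
  stopifnot(length(tables) >= 2L)
  asMat <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 1L,
                                    dimnames = list(names(x), "value"))
  }
  tables <- lapply(tables, asMat)
  k <- length(tables)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("table", seq_len(k))
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(out) <- 1
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- tables[[i]]; b <- tables[[j]]
    ents <- intersect(rownames(a), rownames(b))
    cols <- intersect(colnames(a), colnames(b))
    if (length(ents) < 3L || !length(cols)) {
      warning(sprintf("pair (%s, %s): fewer than 3 shared entities", nm[i], nm[j]))
      next
    }
    x <- as.vector(a[ents, cols]); y <- as.vector(b[ents, cols])
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      warning(sprintf("pair (%s, %s): fewer than 3 complete observations", nm[i], nm[j]))
      next
    }
    out[i, j] <- out[j, i] <- cor(x[ok], y[ok])
  }
  out
}
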