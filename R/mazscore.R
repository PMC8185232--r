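#' @importFrom stats pnorm p.adjust mad cor complete.cases rnbinom rlnorm
#'   rnorm runif
NULL

#' Build M and A values for one knock-out versus wild-type comparison
#'
#' Replicates are averaged on the log2 scale on each side; per entity,
#' M = mean(ko) - mean(wt) (the log2 fold change) and A = (mean(ko) +
#' mean(wt)) / 2 (the average log2 abundance of the two means). Entities
#' with no observed replicate on either side are excluded and counted in a
#' message.
#'
#' @param wt,ko numeric matrices (entities x replicates, log2 scale) with
#'   rownames; entities are matched on the intersection of rownames.
#' @return data.frame with columns entity, M, A.
#' @export
makeMA <- function(wt, ko) {
  common <- intersect(rownames(wt), rownames(ko))
  if (!length(common)) stop("no shared entities between wt and ko")
  wtMean <- rowMeans(wt[common, , drop = FALSE], na.rm = TRUE)
  koMean <- rowMeans(ko[common, , drop = FALSE], na.rm = TRUE)
  ok <- is.finite(wtMean) & is.finite(koMean)
  if (any(!ok))
    message(sprintf("%d entities missing on one side excluded", sum(!ok)))
  data.frame(entity = common[ok],
             M = koMean[ok] - wtMean[ok],
             A = (koMean[ok] + wtMean[ok]) / 2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Abundance-localized z-scores via a ranked sliding window
#'
#' Records are ranked by A (average abundance); each record's window is its
#' \code{w} rank-nearest neighbours, where \code{w = max(3,
#' round(windowFrac * n))}, clamped to full width at the extremes so edge
#' windows never shrink. The z-score standardizes the log2 fold change by
#' the local fold-change distribution:
#' \code{z = (M - median(window M)) / spread(window M)}, with the spread the
#' sample standard deviation by default (median absolute deviation
#' optionally). Ties in A are broken by entity id for determinism. Windows
#' with zero spread yield missing z with one summary warning.
#'
#' @param records data.frame with columns entity, M, A (from
#'   \code{\link{makeMA}}).
#' @param windowFrac window width as a fraction of n, in (0, 1]; default 0.10.
#' @param spread \code{"sd"} or \code{"mad"}.
#' @return the input data.frame with a \code{z} column, input order
#'   preserved.
#' @export
windowedZ <- function(records, windowFrac = 0.10, spread = c("sd", "mad")) {
  spread <- match.arg(spread)
  n <- nrow(records)
  stopifnot(windowFrac > 0, windowFrac <= 1)
  ord <- order(records$A, records$entity)
  M <- records$M[ord]
  w <- max(3L, min(n, as.integer(round(windowFrac * n))))
  if (n < w) stop("need at least ", w, " records")
  half <- (w - 1L) %/% 2L
  starts <- pmin(pmax(seq_len(n) - half, 1L), n - w + 1L)
  cs <- c(0, cumsum(M)); cs2 <- c(0, cumsum(M^2))
  z <- rep(NA_real_, n)
  nFlat <- 0L
  for (i in seq_len(n)) {
    a <- starts[i]; b <- a + w - 1L
    win <- M[a:b]
    ctr <- median(win)
    s <- if (spread == "sd") {
      sw <- cs[b + 1L] - cs[a]
      sq <- cs2[b + 1L] - cs2[a]
      v <- (sq - sw^2 / w) / (w - 1L)
      # guard against cancellation noise masquerading as nonzero spread
      if (v <= 1e-12 * max(sq / (w - 1L), .Machine$double.xmin)) 0 else sqrt(v)
    } else mad(win)
    if (s > 0) z[i] <- (M[i] - ctr) / s else nFlat <- nFlat + 1L
  }
  if (nFlat > 0L)
    warning(sprintf("%d record(s) in zero-spread windows: z set missing", nFlat))
  records$z <- NA_real_
  records$z[ord] <- z
  records
}

#' Normal-tail p-value for a z-score
#'
#' Two-sided by default: \code{p = 2 * (1 - pnorm(|z|))}, so z = 0 gives
#' p = 1. The one-sided upper-tail form \code{1 - pnorm(|z|)} is available.
#'
#' @param z numeric z-scores (NA propagates).
#' @param twoSided logical(1).
#' @return p-values in [0, 1].
#' @export
pFromZ <- function(z, twoSided = TRUE) {
  p <- pnorm(-abs(z))
  if (twoSided) pmin(2 * p, 1) else p
}

.sampleAnnotation <- function(x, design) {
  cd <- as.data.frame(colData(x))
  if (all(c("line", "tissue") %in% names(cd)))
    return(data.frame(sample = colnames(x), line = cd$line,
                      tissue = cd$tissue, stringsAsFactors = FALSE))
  st <- sampleTable(design)
  hit <- match(colnames(x), st$sample)
  if (!anyNA(hit))
    return(st[hit, c("sample", "line", "tissue")])
  # fall back to the <line>.<tissue>.<rep> sample-id convention
  m <- regmatches(colnames(x),
                  regexec("^(.*)\\.([^.]+)\\.[^.]+$", colnames(x)))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("cannot infer line/tissue for sample(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  data.frame(sample = colnames(x),
             line = vapply(m, `[`, character(1), 2L),
             tissue = vapply(m, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Fold-change records with windowed z and p for every contrast
#'
#' For each knock-out line and tissue, compares against the wild type of the
#' same tissue: replicate columns are averaged, M/A computed
#' (\code{\link{makeMA}}), z-scores localized by abundance within each
#' contrast (\code{\link{windowedZ}}; optionally all contrasts pooled into
#' one ranked dataset), and two-sided normal p-values attached along with a
#' Benjamini-Hochberg adjusted column.
#'
#' @param x a log2 \linkS4class{OmicsMatrix} whose columns are replicate
#'   samples; line/tissue are taken from \code{colData(x)} or from
#'   \code{design}.
#' @param design a \linkS4class{StudyDesign}.
#' @param windowFrac,spread passed to \code{\link{windowedZ}}.
#' @param poolContrasts rank all contrasts as one dataset (default FALSE:
#'   per contrast within tissue).
#' @param twoSided passed to \code{\link{pFromZ}}.
#' @return data.frame with columns entity, line, tissue, contrast, M, A, z,
#'   p, p_bh.
#' @export
foldChanges <- function(x, design, windowFrac = 0.10, spread = "sd",
                        poolContrasts = FALSE, twoSided = TRUE) {
  stopifnot(isLog2(x))
  ann <- .sampleAnnotation(x, design)
  wtLab <- wildType(design)
  v <- abundances(x)
  recs <- list()
  for (tis in unique(ann$tissue)) {
    wtCols <- ann$sample[ann$line == wtLab & ann$tissue == tis]
    if (!length(wtCols)) next
    for (ln in setdiff(unique(ann$line[ann$tissue == tis]), wtLab)) {
      koCols <- ann$sample[ann$line == ln & ann$tissue == tis]
      ma <- makeMA(v[, wtCols, drop = FALSE], v[, koCols, drop = FALSE])
      if (!nrow(ma)) next
      ma$line <- ln; ma$tissue <- tis
      ma$contrast <- paste(ln, tis, sep = ".")
      recs[[ma$contrast[1L]]] <- ma
    }
  }
  if (!length(recs)) stop("no knock-out contrasts could be formed")
  if (poolContrasts) {
    all <- do.call(rbind, recs)
    all <- windowedZ(all, windowFrac, spread)
  } else {
    all <- do.call(rbind, lapply(recs, windowedZ,
                                 windowFrac = windowFrac, spread = spread))
  }
  all$p <- pFromZ(all$z, twoSided = twoSided)
  all$p_bh <- p.adjust(all$p, method = "BH")
  rownames(all) <- NULL
  all[, c("entity", "line", "tissue", "contrast", "M", "A", "z", "p", "p_bh")]
}

#' Entity-by-contrast matrix from fold-change records
#'
#' Reshapes the long record table into an entities x contrasts matrix of the
#' requested statistic.
#'
#' @param records output of \code{\link{foldChanges}}.
#' @param value which column to spread (\code{"z"} or \code{"M"}).
#' @param tissue optional tissue filter.
#' @return numeric matrix entities x contrasts (contrast = line when a
#'   single tissue is selected).
#' @export
contrastMatrix <- function(records, value = c("z", "M"), tissue = NULL) {
  value <- match.arg(value)
  if (!is.null(tissue)) {
    records <- records[records$tissue %in% tissue, , drop = FALSE]
    records$contrast <- records$line
  }
  ents <- sort(unique(records$entity))
  cons <- unique(records$contrast)
  m <- matrix(NA_real_, length(ents), length(cons),
              dimnames = list(ents, cons))
  m[cbind(match(records$entity, ents), match(records$contrast, cons))] <-
    records[[value]]
  m
}
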