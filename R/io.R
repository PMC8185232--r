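#' @importFrom utils read.delim write.table modifyList
NULL

.MISSING_TOKEN <- "NA"

#' Read an abundance table from TSV
#'
#' All pipeline tables are tab-separated with a header row and the entity id
#' in column 1. The literal token \code{"NA"} and empty cells are treated as
#' missing.
#'
#' @param path TSV file path.
#' @param level omics level tag for the resulting matrix.
#' @param isLog2 logical(1); whether the stored values are log2.
#' @return an \linkS4class{OmicsMatrix}.
#' @export
readOmicsTable <- function(path, level, isLog2 = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                  na.strings = c(.MISSING_TOKEN, ""),
                  stringsAsFactors = FALSE)
  if (ncol(d) < 2L)
    stop("schema error in ", path, ": need an entity id column plus >= 1 sample column")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids))
    stop("validation error in ", path, ": duplicate entity id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- d[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("schema error in ", path, ": non-numeric column(s): ",
         paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!isLog2 && any(m < 0, na.rm = TRUE)) {
    j <- which(colSums(m < 0, na.rm = TRUE) > 0)[1L]
    stop("validation error in ", path, ": negative linear value in column ",
         colnames(m)[j])
  }
  message(sprintf("read %s: %d entities x %d samples", basename(path),
                  nrow(m), ncol(m)))
  OmicsMatrix(m, level = level, isLog2 = isLog2)
}

#' Write an OmicsMatrix to TSV
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @param path output TSV path; missing cells are written as \code{"NA"}.
#' @param idColumn name for the entity id column (default the omics level).
#' @export
writeOmicsTable <- function(x, path, idColumn = omicsLevel(x)) {
  d <- data.frame(id = rownames(x), abundances(x), check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- idColumn
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = .MISSING_TOKEN)
  invisible(path)
}

#' Normalize metabolite abundances by internal standard and tissue weight
#'
#' Divides each sample column by that sample's internal-standard level
#' (e.g. 13C ribitol for primary metabolites, naringenin for secondary)
#' times its original tissue weight. Missing cells stay missing.
#'
#' @param m metabolite-level \linkS4class{OmicsMatrix}, linear scale.
#' @param standard named positive numeric, internal-standard value per sample.
#' @param weight named positive numeric, tissue weight per sample; defaults
#'   to 1 for every sample (standard-only normalization).
#' @return the normalized \linkS4class{OmicsMatrix}.
#' @export
normalizeByStandard <- function(m, standard, weight = NULL) {
  stopifnot(is(m, "OmicsMatrix"), !isLog2(m))
  s <- colnames(m)
  if (is.null(weight)) weight <- setNames(rep(1, length(s)), s)
  miss <- setdiff(s, names(standard))
  if (length(miss))
    stop("no internal-standard value for sample(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(s, names(weight))
  if (length(miss))
    stop("no tissue weight for sample(s): ", paste(miss, collapse = ", "))
  std <- standard[s]; wt <- weight[s]
  bad <- which(!(std > 0) | !(wt > 0))
  if (length(bad))
    stop("non-positive standard or weight for sample(s): ",
         paste(s[bad], collapse = ", "))
  v <- sweep(abundances(m), 2L, std * wt, "/")
  OmicsMatrix(v, level = omicsLevel(m), isLog2 = FALSE,
              colData = colData(m))
}

#' Read a peptide-to-protein map
#'
#' Two-column TSV (peptide, protein accession); peptides mapping to more than
#' one accession occupy one row per accession.
#'
#' @param path TSV path.
#' @return data.frame with columns peptide, protein.
#' @export
readPeptideMap <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:2] <- c("peptide", "protein")
  d
}

#' Read a KEGO (KEGG Orthology) map
#'
#' TSV with columns entity, kego, and an optional functional-category label.
#'
#' @param path TSV path.
#' @return data.frame with columns entity, kego, category.
#' @export
readKegoMap <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:2] <- c("entity", "kego")
  if (ncol(d) < 3L) d$category <- NA_character_ else names(d)[3L] <- "category"
  d[, c("entity", "kego", "category")]
}

#' Read a KEGO reaction table
#'
#' TSV with columns kego, substrate, product, direction
#' (\code{unidirectional} or \code{reversible}).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readReactionTable <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:4] <- c("kego", "substrate", "product", "direction")
  validateReactionTable(d)
}

validateReactionTable <- function(d) {
  if (any(d$substrate == d$product))
    stop("reaction with identical substrate and product")
  if (anyDuplicated(d[, c("kego", "substrate", "product")]))
    stop("duplicate (kego, substrate, product) reaction rows")
  if (!all(d$direction %in% c("unidirectional", "reversible")))
    stop("direction must be 'unidirectional' or 'reversible'")
  d
}

#' Read a per-line lignin phenotype table
#'
#' TSV with columns line and G+S monomer level (relative units).
#'
#' @param path TSV path.
#' @return named numeric vector of lignin levels.
#' @export
readLigninProfile <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  v <- as.numeric(d[[2L]])
  if (any(!is.finite(v)) || any(v <= 0))
    stop("lignin levels must be positive numbers")
  setNames(v, as.character(d[[1L]]))
}

#' Read a STRING-style protein interaction table
#'
#' TSV with columns protein a, protein b, combined score, and an optional
#' evidence label. Scores on the STRING 0-999 integer scale are detected and
#' rescaled to [0, 1].
#'
#' @param path TSV path.
#' @return data.frame with columns a, b, score, evidence.
#' @export
readInteractionTable <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:3] <- c("a", "b", "score")
  if (ncol(d) < 4L) d$evidence <- NA_character_ else names(d)[4L] <- "evidence"
  if (any(d$score > 1)) d$score <- d$score / 999   # STRING integer export
  validateInteractionTable(d[, c("a", "b", "score", "evidence")])
}

validateInteractionTable <- function(d) {
  if (any(d$score < 0 | d$score > 1))
    stop("combined_score must lie in [0, 1]")
  if (any(d$a == d$b)) stop("self-interaction rows are not allowed")
  key <- paste(pmin(d$a, d$b), pmax(d$a, d$b))
  if (anyDuplicated(key)) stop("duplicate unordered interaction pairs")
  d
}

#' Read spectrum-level iTRAQ reporter-ion reports
#'
#' TSV dialect: spectrum, peptide, proteins (";"-separated accessions), plex,
#' base_peak, then eight reporter-ion intensity columns (channels 113-121 in
#' order).
#'
#' @param path TSV path.
#' @return data.frame of spectrum reports.
#' @export
readSpectrumReports <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) != 13L)
    stop("schema error in ", path,
         ": expected 13 columns (5 annotation + 8 reporter channels)")
  names(d) <- c("spectrum", "peptide", "proteins", "plex", "base_peak",
                paste0("ri", 1:8))
  if (any(d$base_peak <= 0)) stop("base_peak_intensity must be > 0")
  d
}

#' @rdname readSpectrumReports
#' @param spectra spectrum-report data.frame.
#' @export
writeSpectrumReports <- function(spectra, path) {
  write.table(spectra, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = .MISSING_TOKEN)
  invisible(path)
}

#' Write a PhenotypeNetwork as SIF plus node attributes
#'
#' Writes \code{<prefix>.sif} (\code{nodeA<tab>pp<tab>nodeB}, one edge per
#' line) and \code{<prefix>.nodes.tsv} (node id, z-score per contrast,
#' functional category), the pair of files a Cytoscape session consumes.
#'
#' @param net a \linkS4class{PhenotypeNetwork}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeNetworkFiles <- function(net, prefix) {
  if (nrow(networkEdges(net)) == 0L)
    stop("empty network: no edges to write; consider relaxing rho/score thresholds")
  sif <- file.path(paste0(prefix, ".sif"))
  attrs <- file.path(paste0(prefix, ".nodes.tsv"))
  e <- networkEdges(net)
  writeLines(sprintf("%s\tpp\t%s", e$a, e$b), sif)
  write.table(networkNodes(net), attrs, sep = "\t", quote = FALSE,
              row.names = FALSE, na = .MISSING_TOKEN)
  invisible(c(sif = sif, nodes = attrs))
}

#' @rdname writeNetworkFiles
#' @return \code{readNetworkFiles}: list with \code{edges} (columns a, b) and
#'   \code{nodes} (the attribute table).
#' @export
readNetworkFiles <- function(prefix) {
  sif <- read.delim(paste0(prefix, ".sif"), header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  names(sif) <- c("a", "relation", "b")
  nodes <- read.delim(paste0(prefix, ".nodes.tsv"), header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      na.strings = c(.MISSING_TOKEN, ""))
  list(edges = sif[, c("a", "b")], nodes = nodes)
}
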