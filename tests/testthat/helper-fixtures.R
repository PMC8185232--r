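# small in-code fixtures shared across test files

# two-line, one-tissue, two-replicate design: 4 samples in one 8-plex
tinyDesign <- function() studyDesign(c("WT", "ko1"), "leaf", 2L)

# spectrum-report rows built by hand; reporters already sum to base_peak
# unless stated otherwise
makeSpectrum <- function(id, peptide, proteins, plex, base, reporters) {
  d <- data.frame(spectrum = id, peptide = peptide, proteins = proteins,
                  plex = plex, base_peak = base, stringsAsFactors = FALSE)
  ri <- matrix(reporters, nrow = 1, dimnames = list(NULL, paste0("ri", 1:8)))
  cbind(d, as.data.frame(ri))
}

# peptide matrix for a hand-built single- or multi-plex layout
peptideMatrix <- function(values, plex, reference, shared = NULL) {
  om <- OmicsMatrix(values, level = "peptide", isLog2 = TRUE,
                    colData = S4Vectors::DataFrame(
                      plex = plex, reference = reference,
                      row.names = colnames(values)))
  SummarizedExperiment::rowData(om)$shared <-
    if (is.null(shared)) rep(FALSE, nrow(values)) else shared
  om
}

# brute-force Spearman: rank with average ties, then textbook Pearson sums
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

pearsonOracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
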