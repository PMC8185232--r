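test_that("base-peak intensity is distributed by reporter share", {
  expect_equal(channelIntensities(1000, rep(1, 8)), rep(125, 8))
  # reporters sum to 800, so shares are reporters/800 of base 800
  out <- channelIntensities(800, c(300, 100, 100, 100, 100, 50, 25, 25))
  expect_equal(out[1], 300)
  expect_equal(sum(out), 800)
  out <- channelIntensities(500, c(0, 0, 7, 0, 0, 0, 0, 0))
  expect_equal(out, c(0, 0, 500, 0, 0, 0, 0, 0))
  expect_warning(res <- channelIntensities(500, rep(0, 8)), "skipped")
  expect_true(all(is.na(res)))
})

test_that("spectra of one peptide in one plex are summed before log2", {
  d <- tinyDesign()
  sp <- rbind(
    makeSpectrum("s1", "AAA", "P1", "plex01", 800, c(100, 100, 100, 100, 100, 100, 100, 100)),
    makeSpectrum("s2", "AAA", "P1", "plex01", 2400, c(300, 300, 300, 300, 300, 300, 300, 300)),
    makeSpectrum("s3", "BBB", "P1;P2", "plex01", 80, rep(10, 8)))
  pm <- suppressMessages(
    aggregatePeptides(sp, data.frame(peptide = c("AAA", "BBB", "BBB"),
                                     protein = c("P1", "P1", "P2")), d))
  # channel 1 carried 100 + 300 = 400 linear
  expect_equal(unname(abundances(pm)["AAA", "ref.plex01"]), log2(400),
               tolerance = 1e-12)
  expect_equal(unname(abundances(pm)["BBB", 2]), log2(10), tolerance = 1e-12)
  expect_identical(unname(SummarizedExperiment::rowData(pm)$shared),
                   c(FALSE, TRUE))
})

test_that("unmapped peptides are rejected, all-zero spectra skipped", {
  d <- tinyDesign()
  sp <- rbind(
    makeSpectrum("s1", "AAA", "P1", "plex01", 800, rep(100, 8)),
    makeSpectrum("s2", "ZZZ", "P9", "plex01", 800, rep(100, 8)),
    makeSpectrum("s3", "AAA", "P1", "plex01", 500, rep(0, 8)))
  expect_warning(
    pm <- suppressMessages(
      aggregatePeptides(sp, data.frame(peptide = "AAA", protein = "P1"), d)),
    "all-zero")
  expect_identical(S4Vectors::metadata(pm)$rejects, "ZZZ")
  expect_identical(rownames(pm), "AAA")
})

test_that("reference alignment anchors every peptide to its cross-plex mean", {
  cols <- c("ref.p1", "a1", "ref.p2", "b1")
  v <- matrix(c(5, 6, 7, 9,        # pep1: refs 5 and 7 -> shifts +1 / -1
                4, 4, 4, 8),       # pep2: refs 4 and 4 -> no shift
              2, 4, byrow = TRUE, dimnames = list(c("pep1", "pep2"), cols))
  pm <- peptideMatrix(v, plex = c("p1", "p1", "p2", "p2"),
                      reference = c(TRUE, FALSE, TRUE, FALSE))
  out <- alignReferencePool(pm)
  a <- abundances(out)
  expect_equal(unname(a["pep1", ]), c(6, 7, 6, 8))
  expect_equal(unname(a["pep2", ]), c(4, 4, 4, 8))
  # single-plex peptide rows are unshifted
  v2 <- v; v2["pep1", c("ref.p2", "b1")] <- NA
  pm2 <- peptideMatrix(v2, plex = c("p1", "p1", "p2", "p2"),
                       reference = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(abundances(alignReferencePool(pm2))["pep1", 1:2]),
               c(5, 6))
  # a plex row without its reference value is dropped with a warning
  v3 <- v; v3["pep1", "ref.p2"] <- NA
  pm3 <- peptideMatrix(v3, plex = c("p1", "p1", "p2", "p2"),
                       reference = c(TRUE, FALSE, TRUE, FALSE))
  expect_warning(out3 <- alignReferencePool(pm3), "lacked a reference")
  expect_true(is.na(abundances(out3)["pep1", "b1"]))
})

test_that("after alignment reference values are identical across plexes", {
  set.seed(42)
  nPep <- 50
  cols <- c("ref.p1", "a1", "a2", "ref.p2", "b1", "b2", "ref.p3", "c1")
  v <- matrix(rnorm(nPep * 8, 8, 2), nPep,
              dimnames = list(sprintf("pep%02d", 1:nPep), cols))
  v[sample(length(v), 40)] <- NA
  v[, "ref.p1"] <- rnorm(nPep, 8)   # keep every reference observed
  v[, "ref.p2"] <- rnorm(nPep, 9)
  v[, "ref.p3"] <- rnorm(nPep, 7)
  pm <- peptideMatrix(v, plex = rep(c("p1", "p2", "p3"), c(3, 3, 2)),
                      reference = cols %in% c("ref.p1", "ref.p2", "ref.p3"))
  a <- abundances(alignReferencePool(pm))
  refs <- a[, c("ref.p1", "ref.p2", "ref.p3")]
  ranges <- apply(refs, 1, function(r) diff(range(r, na.rm = TRUE)))
  expect_lt(max(ranges), 1e-9)
})

test_that("column centering zeroes every column mean and is idempotent", {
  v <- matrix(c(1, 2, 3, 4, NA, 6), 3, 2,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  pm <- peptideMatrix(v, plex = c("p1", "p1"), reference = c(TRUE, FALSE))
  out <- centerColumns(pm)
  expect_equal(unname(abundances(out)[, "s1"]), c(-1, 0, 1))
  # column 2 mean over observed cells only
  expect_equal(unname(abundances(out)[, "s2"]), c(-1, NA, 1))
  expect_equal(abundances(centerColumns(out)), abundances(out),
               tolerance = 1e-12)
  expect_lt(max(abs(colMeans(abundances(out), na.rm = TRUE))), 1e-9)
})

test_that("protein rollup sums peptides and applies the unique-preference rule", {
  cols <- c("ref.p1", "s1")
  mk <- function(v, peps) peptideMatrix(
    matrix(v, length(peps), 2, byrow = TRUE,
           dimnames = list(peps, cols)),
    plex = c("p1", "p1"), reference = c(TRUE, FALSE))
  # two unique peptides at linear 4 and 6 -> protein 10
  pm <- mk(c(log2(4), log2(4), log2(6), log2(6)), c("u1", "u2"))
  map <- data.frame(peptide = c("u1", "u2"), protein = "P1")
  out <- rollupProteins(pm, map, keepReference = TRUE)
  expect_equal(unname(abundances(out)["P1", "s1"]), log2(10),
               tolerance = 1e-12)
  expect_identical(unname(SummarizedExperiment::rowData(out)$provenance),
                   "unique-rollup")

  # unique rollup missing one channel -> complete shared rollup wins
  v <- matrix(c(NA, log2(4), log2(8), log2(8)), 2, 2, byrow = TRUE,
              dimnames = list(c("u1", "sh1"), cols))
  pm <- peptideMatrix(v, plex = c("p1", "p1"), reference = c(TRUE, FALSE))
  map <- data.frame(peptide = c("u1", "sh1", "sh1"),
                    protein = c("P1", "P1", "P2"))
  out <- rollupProteins(pm, map, keepReference = TRUE)
  expect_identical(
    unname(SummarizedExperiment::rowData(out)$provenance[
      rownames(out) == "P1"]), "shared-rollup")
  expect_equal(unname(abundances(out)["P1", "s1"]), log2(8))

  # unique rollup complete in all channels -> unique wins over shared
  v <- matrix(c(log2(4), log2(4), log2(8), log2(8)), 2, 2, byrow = TRUE,
              dimnames = list(c("u1", "sh1"), cols))
  pm <- peptideMatrix(v, plex = c("p1", "p1"), reference = c(TRUE, FALSE))
  out <- rollupProteins(pm, map, keepReference = TRUE)
  expect_identical(
    unname(SummarizedExperiment::rowData(out)$provenance[
      rownames(out) == "P1"]), "unique-rollup")
  expect_equal(unname(abundances(out)["P1", "s1"]), log2(4))
})

test_that("proteins sharing all peptides are reported as one ';' group", {
  cols <- c("ref.p1", "s1")
  v <- matrix(log2(c(3, 3, 5, 5)), 2, 2, byrow = TRUE,
              dimnames = list(c("sh1", "sh2"), cols))
  pm <- peptideMatrix(v, plex = c("p1", "p1"), reference = c(TRUE, FALSE))
  map <- data.frame(peptide = c("sh1", "sh1", "sh2", "sh2"),
                    protein = c("PA", "PB", "PA", "PB"))
  out <- rollupProteins(pm, map, keepReference = TRUE)
  expect_identical(rownames(out), "PA;PB")
  # within the group the peptides are unique -> summed as unique rollup
  expect_equal(unname(abundances(out)[1, "s1"]), log2(8))
  expect_identical(unname(SummarizedExperiment::rowData(out)$provenance),
                   "unique-rollup")
})

test_that("noise floor removes strictly-below cells and empty entities", {
  v <- matrix(c(1.9, 2.0, 2.1, 1.0, 1.0, 1.0, 8.0, 8.0, 8.0), 3, 3,
              byrow = TRUE,
              dimnames = list(c("keepish", "allnoise", "high"),
                              c("s1", "s2", "s3")))
  m <- OmicsMatrix(v, level = "protein", isLog2 = TRUE)
  out <- dropNoiseFloor(m, 2.0)
  expect_identical(rownames(out), c("keepish", "high"))
  expect_true(is.na(abundances(out)["keepish", "s1"]))
  expect_equal(unname(abundances(out)["keepish", c("s2", "s3")]), c(2.0, 2.1))
})

test_that("single-plex pipeline with balanced columns preserves contrasts", {
  # additive reference alignment and centering must not distort
  # between-sample log2 differences when columns are equally loaded
  set.seed(7)
  nPep <- 20
  base <- rnorm(nPep, 10, 1)
  dev <- matrix(rnorm(nPep * 3, 0, 0.5), nPep, 3)
  dev <- sweep(dev, 2, colMeans(dev))           # equal (zero) column means
  v <- cbind(ref = base, base + dev)
  colnames(v) <- c("ref.p1", "s1", "s2", "s3")
  rownames(v) <- sprintf("pep%02d", 1:nPep)
  pm <- peptideMatrix(v, plex = rep("p1", 4),
                      reference = c(TRUE, FALSE, FALSE, FALSE))
  out <- abundances(centerColumns(alignReferencePool(pm)))
  for (pair in list(c("s1", "s2"), c("s2", "s3")))
    expect_equal(out[, pair[1]] - out[, pair[2]],
                 v[, pair[1]] - v[, pair[2]], tolerance = 1e-9)
})

test_that("conservation: all-unique proteins equal their peptide sums", {
  d <- studyDesign(c("WT", "ko1", "ko2"), "leaf", 2L)
  s <- generateStudy(design = d,
                     params = list(nProteins = 40, nTranscripts = 120,
                                   nMetabolites = 10, fracShared = 0.25,
                                   nPlanted = 5, nDecoyEdges = 50),
                     seed = 11)
  pm <- suppressMessages(aggregatePeptides(s@spectra, s@pepMap, d))
  pm <- centerColumns(alignReferencePool(pm))
  prot <- rollupProteins(pm, s@pepMap, keepReference = TRUE)
  lin <- 2^abundances(pm)
  nOwners <- table(s@pepMap$peptide)
  uniqueOnly <- vapply(split(s@pepMap$peptide, s@pepMap$protein),
                       function(p) all(nOwners[p] == 1L), logical(1))
  checked <- 0L
  for (pr in names(uniqueOnly)[uniqueOnly]) {
    if (!pr %in% rownames(prot)) next
    peps <- intersect(s@pepMap$peptide[s@pepMap$protein == pr],
                      rownames(lin))
    expected <- colSums(lin[peps, , drop = FALSE], na.rm = TRUE)
    got <- 2^abundances(prot)[pr, ]
    ok <- !is.na(got)
    expect_lt(max(abs(got[ok] - expected[ok])), 1e-9)
    checked <- checked + 1L
  }
  expect_gte(checked, 8L)
})
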