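test_that("Spearman correlation to lignin handles monotone and tied cases", {
  lig <- c(ko1 = 10, ko2 = 20, ko3 = 30, ko4 = 40)
  prof <- rbind(up = c(1, 2, 3, 4), down = c(4, 3, 2, 1),
                mixed = c(2, 1, 4, 3))
  colnames(prof) <- names(lig)
  rec <- spearmanToLignin(prof, lig)
  expect_equal(rec$rho[rec$protein == "up"], 1.0)
  expect_equal(rec$rho[rec$protein == "down"], -1.0)
  # ranks (2,1,4,3) vs (1,2,3,4): sum d^2 = 4 -> rho = 1 - 24/60 = 0.6
  expect_equal(rec$rho[rec$protein == "mixed"], 0.6, tolerance = 1e-12)
  flat <- rbind(flat = rep(1, 4)); colnames(flat) <- names(lig)
  expect_warning(rec2 <- spearmanToLignin(flat, lig), "constant")
  expect_true(is.na(rec2$rho))
  expect_error(spearmanToLignin(prof[, 1:3], lig[1:3]), "at least 4")
})

test_that("rank correlation matches a brute-force rank-then-Pearson oracle", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (runif(1) < 0.3) x[sample(n, 1)] <- x[sample(n, 1)]  # force ties
    lig <- setNames(y, paste0("l", 1:n))
    prof <- matrix(x, 1, dimnames = list("p", names(lig)))
    got <- spearmanToLignin(prof, lig)$rho
    expect_equal(got, spearmanOracle(x, y), tolerance = 1e-12)
  }
})

test_that("candidate selection applies |rho| and adt1-band thresholds", {
  rec <- data.frame(protein = c("a", "b", "c", "d"),
                    rho = c(0.90, 0.90, -0.90, 0.84),
                    n_lines = 8, stringsAsFactors = FALSE)
  z <- c(a = 0.2, b = 0.8, c = 0.1, d = 0.0)
  out <- selectCandidates(rec, z, rhoCut = 0.85, adt1Band = 0.5)
  expect_identical(out$passes, c(TRUE, FALSE, TRUE, FALSE))
  # inclusive boundary keeps rho exactly at the cutoff
  rec$rho <- c(0.85, 0.85, -0.85, 0.84)
  out <- selectCandidates(rec, z, rhoCut = 0.85, adt1Band = 0.5)
  expect_true(out$passes[1])
  out <- selectCandidates(rec, z, rhoCut = 0.85, adt1Band = 0.5,
                          inclusive = FALSE)
  expect_false(out$passes[1])
  # lowering the cutoff never removes a passing candidate
  loose <- selectCandidates(rec, z, rhoCut = 0.5, adt1Band = 0.5)
  expect_true(all(loose$passes[out$passes]))
})

test_that("network keeps only qualifying candidate-candidate edges", {
  cand <- data.frame(protein = c("A", "B", "C", "D"),
                     rho = 0.9, n_lines = 8, adt1_z = 0,
                     passes = c(TRUE, TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  ints <- data.frame(a = c("A", "A", "B", "C"),
                     b = c("B", "C", "D", "D"),
                     score = c(0.9, 0.39, 0.95, 0.8),
                     stringsAsFactors = FALSE)
  z <- matrix(c(1, -1, 0.5, 0), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "ko1"))
  net <- buildNetwork(cand, ints, z, minScore = 0.4)
  # B-D and C-D touch the failing candidate D; A-C is below score
  expect_equal(nrow(networkEdges(net)), 1)
  expect_setequal(networkNodes(net)$node, c("A", "B"))
  expect_equal(networkNodes(net)$z.ko1, c(1, -1))
  # raising the score floor never adds an edge
  expect_error(buildNetwork(cand, ints, z, minScore = 0.95),
               "empty network")
  cand$passes <- FALSE
  expect_error(buildNetwork(cand, ints, z), "no candidates")
})

test_that("isolated candidates are dropped from the network", {
  cand <- data.frame(protein = c("A", "B", "C"), rho = 0.9, n_lines = 8,
                     adt1_z = 0, passes = TRUE, stringsAsFactors = FALSE)
  ints <- data.frame(a = "A", b = "B", score = 0.9,
                     stringsAsFactors = FALSE)
  z <- matrix(0, 3, 1, dimnames = list(c("A", "B", "C"), "ko1"))
  net <- buildNetwork(cand, ints, z)
  expect_false("C" %in% networkNodes(net)$node)
  deg <- table(c(networkEdges(net)$a, networkEdges(net)$b))
  expect_true(all(networkNodes(net)$node %in% names(deg)))
})

test_that("planted lignin-tracking proteins are recovered from the study", {
  s <- generateStudy(seed = 1)
  d <- s@design
  pm <- suppressMessages(aggregatePeptides(s@spectra, s@pepMap, d))
  pmA <- alignReferencePool(pm)
  prot <- rollupProteins(centerColumns(pmA), s@pepMap)
  ul <- uniquePeptideLinear(pmA, s@pepMap)
  pf <- dropNoiseFloor(shiftToAbundanceScale(prot, ul), 2)
  fc <- suppressMessages(foldChanges(pf, d))
  mProt <- contrastMatrix(fc, "M", tissue = "stem")
  zProt <- contrastMatrix(fc, "z", tissue = "stem")
  rec <- spearmanToLignin(mProt, s@lignin)
  cand <- selectCandidates(rec, setNames(zProt[, "adt1"], rownames(zProt)))
  planted <- s@truth$plantedProteins
  tp <- sum(cand$protein[cand$passes] %in% planted)
  sens <- tp / length(planted)
  fdp <- (sum(cand$passes) - tp) / max(1, sum(cand$passes))
  expect_gte(sens, 0.90)
  expect_lte(fdp, 0.10)
})
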