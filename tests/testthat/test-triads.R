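test_that("all eight nonzero sign triples map to exactly two per cluster", {
  signs <- expand.grid(t = c(-1, 1), m = c(-1, 1), p = c(-1, 1))
  cl <- assignCluster(signs$t, signs$m, signs$p)
  expect_setequal(unique(cl), c("1", "2", "3", "4"))
  expect_equal(as.integer(table(cl)), rep(2L, 4))
  # the Fig-style definitions, one representative each
  expect_identical(assignCluster(0.8, 1.2, 0.3), "1")
  expect_identical(assignCluster(-0.8, -1.2, -0.3), "1")
  expect_identical(assignCluster(-0.5, 0.9, 0.4), "2")
  expect_identical(assignCluster(0.5, 0.9, -0.4), "3")
  expect_identical(assignCluster(-0.5, 0.9, -0.4), "4")
  expect_identical(assignCluster(0, 1, 1), "unclassified")
  expect_identical(assignCluster(1, 0, 1), "unclassified")
  expect_identical(assignCluster(1, 1, 0), "unclassified")
})

test_that("reaction matching requires KEGO detection in both layers", {
  rx <- data.frame(kego = c("K1", "K2", "K3"),
                   substrate = c("m1", "m1", "m2"),
                   product = c("m2", "m3", "m3"),
                   direction = c("unidirectional", "unidirectional",
                                 "reversible"),
                   stringsAsFactors = FALSE)
  sk <- matchReactions(c("m1", "m2", "m3"), rx,
                       kegosTranscript = c("K1", "K2", "K3"),
                       kegosProtein = c("K1", "K3"))
  # K2 only in transcripts -> no triad
  expect_false("K2" %in% sk$kego)
  expect_identical(sk$role[sk$kego == "K1" & sk$metabolite == "m1"],
                   "substrate")
  expect_identical(sk$role[sk$kego == "K1" & sk$metabolite == "m2"],
                   "product")
  expect_setequal(sk$role[sk$kego == "K3"], "reversible")
  empty <- suppressMessages(
    matchReactions("zz", rx, "K1", "K1"))
  expect_equal(nrow(empty), 0)
})

test_that("profile correlations across contrasts follow Pearson", {
  cons <- paste0("ko", 1:4)
  tz <- matrix(c(1, 2, 3, 4), 1, dimnames = list("K1", cons))
  pz <- matrix(c(-1, -2, -3, -4), 1, dimnames = list("K1", cons))
  mz <- matrix(c(2, 1, 4, 3), 1, dimnames = list("m1", cons))
  sk <- data.frame(metabolite = "m1", kego = "K1", role = "substrate",
                   stringsAsFactors = FALSE)
  out <- profileCorrelations(sk, tz, pz, mz)
  expect_equal(out$r_tm, 0.6, tolerance = 1e-12)
  expect_equal(out$r_tp, -1.0)
  expect_equal(out$r_pm, -0.6, tolerance = 1e-12)
  expect_identical(out$cluster,
                   assignCluster(mean(tz), mean(mz), mean(pz)))
  # identical profiles correlate perfectly
  out2 <- profileCorrelations(sk, tz, pz, matrix(c(1, 2, 3, 4), 1,
                                                 dimnames = list("m1", cons)))
  expect_equal(out2$r_tm, 1.0)
  # fewer than 3 complete contrasts -> missing r
  mz3 <- mz; mz3[1, 1:2] <- NA
  expect_true(is.na(profileCorrelations(sk, tz, pz, mz3)$r_tm))
  # zero-variance profile warns and yields missing
  flat <- matrix(rep(1, 4), 1, dimnames = list("m1", cons))
  # both r_tm and r_pm hit the flat metabolite profile
  expect_warning(expect_warning(
    out4 <- profileCorrelations(sk, tz, pz, flat), "zero-variance"),
    "zero-variance")
  expect_true(is.na(out4$r_tm))
})

test_that("flags mark argmax KEGOs once per metabolite and rows are ordered", {
  cons <- paste0("ko", 1:4)
  sk <- data.frame(metabolite = c("m1", "m1", "m2"),
                   kego = c("K1", "K2", "K3"),
                   role = c("substrate", "substrate", "product"),
                   stringsAsFactors = FALSE)
  tz <- matrix(c(1, 2, 3, 4,  4, 3, 2, 1,  1, 2, 3, 4), 3, byrow = TRUE,
               dimnames = list(c("K1", "K2", "K3"), cons))
  pz <- matrix(c(2, 3, 4, 5,  5, 4, 3, 2,  1, 2, 3, 4), 3, byrow = TRUE,
               dimnames = list(c("K1", "K2", "K3"), cons))
  mz <- matrix(c(1.1, 2, 3, 4.2,  -1, -2, -2, -3), 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), cons))
  tr <- profileCorrelations(sk, tz, pz, mz)
  ab <- OmicsMatrix(matrix(c(8.1, 6.4, 5.0), 3, 2,
                           dimnames = list(c("K1", "K2", "K3"),
                                           c("s1", "s2"))),
                    level = "kego", isLog2 = TRUE)
  out <- flagAndOrder(tr, ab)
  # green square on the higher-abundance K1 (8.1 > 6.4)
  expect_true(out$most_abundant_kego[out$kego == "K1"])
  expect_false(out$most_abundant_kego[out$kego == "K2"])
  # orange and blue circles on the best-correlated K1 (r = 1 vs -1)
  expect_true(out$best_protein_corr[out$kego == "K1"])
  expect_true(out$best_transcript_corr[out$kego == "K1"])
  # single-triad metabolite carries every flag
  m2row <- out[out$metabolite == "m2", ]
  expect_true(all(unlist(m2row[, c("single_reaction", "most_abundant_kego",
                                   "best_transcript_corr",
                                   "best_protein_corr")])))
  # each flag appears exactly once per metabolite
  for (flag in c("most_abundant_kego", "best_transcript_corr",
                 "best_protein_corr"))
    expect_equal(as.integer(tapply(out[[flag]], out$metabolite, sum)),
                 c(1L, 1L))
  expect_identical(out$cluster, sort(out$cluster))
})

test_that("flag proportions summarize per role and cluster", {
  tr <- data.frame(
    metabolite = c("m1", "m2", "m3"),
    kego = c("K1", "K2", "K3"),
    role = c("substrate", "substrate", "product"),
    cluster = c("1", "1", "2"),
    mean_z_m = c(1, 0.5, -1),
    single_reaction = TRUE, most_abundant_kego = TRUE,
    best_transcript_corr = TRUE, best_protein_corr = TRUE,
    stringsAsFactors = FALSE)
  out <- summarizeFlagDistribution(tr)
  # every metabolite single-reaction: joint proportion is forced to 1
  expect_true(all(out$prop_joint == 1))
  expect_setequal(out$group[out$group_by == "role"],
                  c("substrate", "product"))
  # no row for clusters absent from the data
  expect_false("3" %in% out$group[out$group_by == "cluster"])
})

test_that("joint flag proportion approaches 1/k under independence", {
  # abundance rank and correlation rank independent across k = 3 KEGOs
  set.seed(31)
  bench <- generateTriadBenchmark(nMetabolites = 300, kegosPerMetabolite = 3,
                                  noiseSd = 3, seed = 31)  # noise >> signal
  tr <- profileCorrelations(bench$skeletons, bench$transcriptZ,
                            bench$proteinZ, bench$metaboliteZ)
  ab <- OmicsMatrix(matrix(rnorm(nrow(bench$proteinZ), 8, 1),
                           dimnames = list(rownames(bench$proteinZ), "s1"),
                           ncol = 1), level = "kego", isLog2 = TRUE)
  out <- flagAndOrder(tr, ab)
  joint <- mean(tapply(out$most_abundant_kego & out$best_protein_corr,
                       out$metabolite, any))
  p <- 1 / 3
  se <- sqrt(p * (1 - p) / 300)
  expect_lt(abs(joint - p), 4 * se)
})

test_that("best-protein-correlation flag recovers the producing KEGO", {
  bench <- generateTriadBenchmark(nMetabolites = 100, kegosPerMetabolite = 3,
                                  noiseSd = 0.1, seed = 1)
  tr <- profileCorrelations(bench$skeletons, bench$transcriptZ,
                            bench$proteinZ, bench$metaboliteZ)
  set.seed(2)
  ab <- OmicsMatrix(matrix(rnorm(nrow(bench$proteinZ), 8, 1),
                           dimnames = list(rownames(bench$proteinZ), "s1"),
                           ncol = 1), level = "kego", isLog2 = TRUE)
  out <- flagAndOrder(tr, ab)
  hit <- out$kego[out$best_protein_corr]
  names(hit) <- out$metabolite[out$best_protein_corr]
  recovered <- mean(hit[names(bench$producer)] == bench$producer)
  expect_gte(recovered, 0.90)
})
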