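#' @importFrom tools md5sum
#' @importFrom utils combn packageVersion
NULL

.writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = .MISSING_TOKEN)
  path
}

.adt1Line <- function(design, lignin) {
  lines <- studyLines(design)
  if ("adt1" %in% lines) return("adt1")
  ko <- setdiff(lines, wildType(design))
  ko[which.max(lignin[ko])]     # the knock-out closest to wild-type lignin
}

.netTissue <- function(design) {
  t <- studyTissues(design)
  if ("stem" %in% t) "stem" else t[1L]
}

#' Run the full multi-omics pipeline on a synthetic study
#'
#' Orchestrates simulate, rollup, zscore, kego, integrate and network as one
#' reproducible run: generates the seeded study, rolls spectra up to
#' proteins, computes abundance-localized z-scores for every layer,
#' collapses to KEGO families with a transcript/protein correlation and
#' overlap summary, builds the flagged reaction-triad table, assembles the
#' lignin-correlated protein network, and writes every intermediate table
#' under \code{outDir} plus a deterministic \code{manifest.yaml} of md5
#' checksums (stage wall-times go to a separate \code{timings.tsv} so the
#' manifest is reproducible byte for byte). Any stage failure aborts with
#' the stage name.
#'
#' @param config configuration list from \code{\link{loadConfig}} (or a YAML
#'   path).
#' @param seed integer; seeds every source of randomness.
#' @param outDir output directory (created if needed).
#' @param design optional \linkS4class{StudyDesign}; defaults to the
#'   nine-line two-tissue design with the configured replicate count.
#' @param inputs optional named list of real-data table paths (names
#'   \code{spectra}, \code{pepmap}, \code{transcripts}, \code{metabolites},
#'   \code{standards}, \code{kego_map}, \code{reactions}, \code{lignin},
#'   \code{interactions}); when given, tables are read instead of simulated
#'   and a missing entry aborts naming it.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultConfig(), seed = 1L,
                        outDir = "results", design = NULL, inputs = NULL) {
  if (is.character(config)) config <- loadConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design))
    design <- defaultStudyDesign(replicates = config$simulation$proteomeReplicates)
  if (!is.null(inputs)) {
    need <- c("spectra", "pepmap", "transcripts", "metabolites", "standards",
              "kego_map", "reactions", "lignin", "interactions")
    missing <- setdiff(need, names(inputs))
    if (length(missing))
      stop("real-data mode: missing input table(s): ",
           paste(missing, collapse = ", "))
  }
  stages <- list(); timings <- list()
  out <- function(f) file.path(outDir, f)
  runStage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    stages[[name]] <<- res      # character vector of files written
    res
  }

  ## stage 1: simulate (or load real-data tables) --------------------------
  study <- NULL
  if (!is.null(inputs)) {
    runStage("load", function() {
      std <- read.delim(inputs$standards, stringsAsFactors = FALSE)
      study <<- new("SyntheticStudy", design = design,
        spectra = readSpectrumReports(inputs$spectra),
        transcripts = readOmicsTable(inputs$transcripts, "transcript"),
        metabolites = readOmicsTable(inputs$metabolites, "metabolite"),
        metaboliteStandard = setNames(std$standard, std$sample),
        tissueWeight = setNames(std$weight, std$sample),
        pepMap = readPeptideMap(inputs$pepmap),
        kegoMap = readKegoMap(inputs$kego_map),
        reactions = readReactionTable(inputs$reactions),
        lignin = readLigninProfile(inputs$lignin),
        interactions = readInteractionTable(inputs$interactions),
        truth = list())
      unname(unlist(inputs))
    })
  } else runStage("simulate", function() {
    study <<- generateStudy(design = design,
                            params = config$simulation, seed = seed)
    files <- c(
      writeSpectrumReports(study@spectra, out("spectra.tsv")),
      writeOmicsTable(study@transcripts, out("transcripts.tsv"), "gene"),
      writeOmicsTable(study@metabolites, out("metabolites.tsv"), "metabolite"),
      .writeTsv(data.frame(sample = names(study@metaboliteStandard),
                           standard = study@metaboliteStandard,
                           weight = study@tissueWeight),
                out("metabolite_standards.tsv")),
      .writeTsv(study@pepMap, out("pepmap.tsv")),
      .writeTsv(study@kegoMap, out("kego_map.tsv")),
      .writeTsv(study@reactions, out("reactions.tsv")),
      .writeTsv(data.frame(line = names(study@lignin),
                           gs_level = study@lignin),
                out("lignin.tsv")),
      .writeTsv(study@interactions, out("interactions.tsv")))
    tr <- study@truth
    yaml::write_yaml(list(seed = tr$seed,
                          planted_proteins = tr$plantedProteins,
                          producer_kego = as.list(tr$producerKego),
                          lignin = as.list(tr$lignin),
                          params = tr$params),
                     out("truth.yaml"))
    c(files, out("truth.yaml"))
  })

  ## stage 2: rollup -------------------------------------------------------
  proteinsLog2 <- NULL; uniqueLinear <- NULL
  runStage("rollup", function() {
    pmAligned <- alignReferencePool(
      aggregatePeptides(study@spectra, study@pepMap, design))
    pm <- centerColumns(pmAligned)
    proteinsLog2 <<- rollupProteins(pm, study@pepMap)
    # abundance anchor and KEGO input come from the aligned (uncentered)
    # peptide signal: centering removes the abundance scale by design
    uniqueLinear <<- uniquePeptideLinear(pmAligned, study@pepMap)
    rej <- S4Vectors::metadata(pm)$rejects
    files <- c(writeOmicsTable(proteinsLog2, out("proteins.tsv")),
               writeOmicsTable(uniqueLinear, out("proteins_unique_linear.tsv")))
    if (length(rej))
      files <- c(files, .writeTsv(data.frame(peptide = rej),
                                  out("rollup.rejects.tsv")))
    files
  })

  ## stage 3: zscore (protein, transcript, metabolite) ---------------------
  zTabs <- list()
  runStage("zscore", function() {
    files <- character()
    protFloor <- dropNoiseFloor(shiftToAbundanceScale(proteinsLog2,
                                                      uniqueLinear),
                                config$noise_floor)
    zTabs$protein <<- foldChanges(protFloor, design,
                                  windowFrac = config$window_frac,
                                  spread = config$window_spread,
                                  poolContrasts = config$pool_contrasts,
                                  twoSided = config$two_sided_p)
    tLog <- OmicsMatrix(log2(abundances(study@transcripts) +
                               config$pseudocount),
                        level = "transcript", isLog2 = TRUE,
                        colData = colData(study@transcripts))
    zTabs$transcript <<- foldChanges(tLog, design,
                                     windowFrac = config$window_frac,
                                     spread = config$window_spread,
                                     poolContrasts = config$pool_contrasts,
                                     twoSided = config$two_sided_p)
    mNorm <- normalizeByStandard(study@metabolites,
                                 study@metaboliteStandard,
                                 study@tissueWeight)
    mLog <- OmicsMatrix(log2(abundances(mNorm)), level = "metabolite",
                        isLog2 = TRUE, colData = colData(mNorm))
    zTabs$metabolite <<- foldChanges(mLog, design,
                                     windowFrac = config$window_frac,
                                     spread = config$window_spread,
                                     poolContrasts = config$pool_contrasts,
                                     twoSided = config$two_sided_p)
    for (nm in names(zTabs))
      files <- c(files, .writeTsv(zTabs[[nm]], out(paste0(nm, ".z.tsv"))))
    files
  })

  ## stage 4: kego collapse + Fig2-style summary ---------------------------
  kegoZ <- list(); kegoTabs <- list()
  runStage("kego", function() {
    kegoTabs$transcript <<- collapseToKego(study@transcripts, study@kegoMap)
    kegoTabs$protein <<- collapseToKego(uniqueLinear, study@kegoMap)
    for (nm in names(kegoTabs)) {
      kegoZ[[nm]] <<- foldChanges(kegoTabs[[nm]], design,
                                  windowFrac = config$window_frac,
                                  spread = config$window_spread,
                                  poolContrasts = config$pool_contrasts,
                                  twoSided = config$two_sided_p)
    }
    corr <- crossLayerCorrelation(zTabs$transcript, zTabs$protein,
                                  kegoZ$transcript, kegoZ$protein)
    ov <- overlapSummary(rownames(study@transcripts),
                         rownames(uniqueLinear), study@kegoMap)
    files <- c(
      writeOmicsTable(kegoTabs$transcript, out("transcript.kego.tsv")),
      writeOmicsTable(kegoTabs$protein, out("protein.kego.tsv")),
      .writeTsv(kegoZ$transcript, out("transcript.kego.z.tsv")),
      .writeTsv(kegoZ$protein, out("protein.kego.z.tsv")),
      .writeTsv(corr, out("fig2_correlations.tsv")),
      .writeTsv(data.frame(level = c("gene", "kego"),
                           overlap = c(ov$gene["overlap"], ov$kego["overlap"]),
                           transcript_only = c(ov$gene["transcript_only"],
                                               ov$kego["transcript_only"]),
                           protein_only = c(ov$gene["protein_only"],
                                            ov$kego["protein_only"])),
                out("fig2_overlap.tsv")))
    files
  })

  ## stage 5: integrate (reaction triads) ----------------------------------
  triads <- NULL
  runStage("integrate", function() {
    perTissue <- lapply(studyTissues(design), function(tis) {
      tz <- contrastMatrix(kegoZ$transcript, "z", tissue = tis)
      pz <- contrastMatrix(kegoZ$protein, "z", tissue = tis)
      mz <- contrastMatrix(zTabs$metabolite, "z", tissue = tis)
      sk <- matchReactions(rownames(mz), study@reactions,
                           rownames(tz), rownames(pz))
      if (!nrow(sk)) return(NULL)
      tr <- profileCorrelations(sk, tz, pz, mz)
      tr <- flagAndOrder(tr, kegoTabs$protein)
      tr$tissue <- tis
      tr
    })
    triads <<- do.call(rbind, perTissue)
    if (is.null(triads) || !nrow(triads))
      stop("no reaction triads could be formed")
    flagSummary <- summarizeFlagDistribution(triads)
    c(.writeTsv(triads, out("triads.tsv")),
      .writeTsv(flagSummary, out("fig4_flag_summary.tsv")))
  })

  ## stage 6: network ------------------------------------------------------
  runStage("network", function() {
    tis <- .netTissue(design)
    mProt <- contrastMatrix(zTabs$protein, "M", tissue = tis)
    zProt <- contrastMatrix(zTabs$protein, "z", tissue = tis)
    rec <- spearmanToLignin(mProt, study@lignin)
    a1 <- .adt1Line(design, study@lignin)
    adt1Z <- setNames(zProt[, a1], rownames(zProt))
    cand <- selectCandidates(rec, adt1Z, rhoCut = config$rho_cutoff,
                             adt1Band = config$adt1_z_band,
                             inclusive = config$inclusive_rho)
    net <- buildNetwork(cand, study@interactions, zProt,
                        minScore = config$min_interaction_score,
                        kegoMap = study@kegoMap)
    files <- writeNetworkFiles(net, out("network"))
    c(unname(files), .writeTsv(cand, out("candidates.tsv")))
  })

  ## manifest ---------------------------------------------------------------
  cfgDump <- yaml::as.yaml(config[setdiff(names(config), "simulation")])
  simDump <- yaml::as.yaml(config$simulation[
    order(names(config$simulation))])
  manifest <- list(
    tool = "kegomics", version = as.character(packageVersion("kegomics")),
    seed = as.integer(seed),
    config_hash = unname(md5sum(.tempWrite(paste0(cfgDump, simDump)))),
    stages = lapply(names(stages), function(nm) {
      files <- stages[[nm]]
      list(name = nm,
           outputs = lapply(files, function(f)
             list(file = basename(f), md5 = unname(md5sum(f)))))
    }))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  .writeTsv(data.frame(stage = names(timings),
                       seconds = round(unlist(timings), 3)),
            file.path(outDir, "timings.tsv"))
  message(sprintf("pipeline complete: %d stages -> %s", length(stages),
                  outDir))
  invisible(manifest)
}

.tempWrite <- function(txt) {
  f <- tempfile(fileext = ".yaml")
  writeLines(txt, f)
  f
}

#' Shift centered protein log2 values back onto the abundance scale
#'
#' Column centering places protein log2 values around zero; the noise-floor
#' filter and the A axis of the MA plot need values on the abundance scale.
#' Each protein row is shifted by the difference between its mean log2
#' abundance in the unique-peptide linear table and its mean centered value,
#' preserving all within-row (between-sample) contrasts exactly.
#'
#' @param centered protein-level log2 \linkS4class{OmicsMatrix} (centered).
#' @param uniqueLinear linear protein table from
#'   \code{\link{uniquePeptideLinear}}.
#' @return shifted log2 \linkS4class{OmicsMatrix}.
#' @export
shiftToAbundanceScale <- function(centered, uniqueLinear) {
  v <- abundances(centered)
  ref <- log2(abundances(uniqueLinear))
  common <- intersect(rownames(v), rownames(ref))
  shift <- rowMeans(ref[common, , drop = FALSE], na.rm = TRUE) -
    rowMeans(v[common, , drop = FALSE], na.rm = TRUE)
  v2 <- v
  v2[common, ] <- v[common, , drop = FALSE] + shift
  keepRest <- setdiff(rownames(v), common)
  if (length(keepRest)) {
    grand <- mean(ref, na.rm = TRUE)
    v2[keepRest, ] <- v[keepRest, , drop = FALSE] + grand
  }
  OmicsMatrix(v2, level = "protein", isLog2 = TRUE,
              colData = colData(centered))
}

#' Transcript/protein correlation before and after KEGO collapse
#'
#' For each knock-out contrast present in both layers, the Pearson
#' correlation between transcript and protein log2 fold changes over shared
#' entities, at gene level and at KEGO level, plus the means across
#' contrasts.
#'
#' @param tZ,pZ entity-level fold-change tables (\code{\link{foldChanges}}).
#' @param tKegoZ,pKegoZ KEGO-level fold-change tables.
#' @return data.frame with columns contrast, r_entity, r_kego.
#' @export
crossLayerCorrelation <- function(tZ, pZ, tKegoZ, pKegoZ) {
  corOne <- function(a, b, con) {
    ai <- a[a$contrast == con, ]; bi <- b[b$contrast == con, ]
    shared <- intersect(ai$entity, bi$entity)
    if (length(shared) < 3L) return(NA_real_)
    cor(ai$M[match(shared, ai$entity)], bi$M[match(shared, bi$entity)],
        use = "complete.obs")
  }
  cons <- intersect(unique(tZ$contrast), unique(pZ$contrast))
  data.frame(contrast = cons,
             r_entity = vapply(cons, function(cc) corOne(tZ, pZ, cc),
                               numeric(1)),
             r_kego = vapply(cons, function(cc) corOne(tKegoZ, pKegoZ, cc),
                             numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
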