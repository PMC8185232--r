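#' Abundance-dependent measurement noise
#'
#' Standard deviation of log2 measurement noise as a monotone non-increasing
#' function of log2 abundance A: high-abundance signals are measured more
#' precisely. Spans a 4-fold range (0.5 at A = 4 down to 0.125 at A = 12,
#' clamped outside).
#'
#' @param A numeric; log2 abundance.
#' @return numeric; noise standard deviation (log2 units).
#' @export
defaultSigmaFn <- function(A) {
  pmin(0.5, pmax(0.125, 0.5 * 2^(-(A - 4) / 4)))
}

#' Generate true-null MA pairs with abundance-dependent variance
#'
#' Draws n entities with log2 abundance uniform on \code{aRange} and, for
#' each, a wild-type and a knock-out measurement with identical means and
#' noise sd \code{sigmaFn(A)} -- a true-null fold-change set whose variance
#' shrinks with abundance, the regime the sliding-window z-score is designed
#' to standardize.
#'
#' @param n number of entity pairs (>= 100).
#' @param sigmaFn positive function of log2 abundance.
#' @param seed integer RNG seed.
#' @param aRange log2 abundance range (default 4 to 12).
#' @return data.frame with columns entity, trueA, wt, ko.
#' @export
generateNullMAPairs <- function(n, sigmaFn = defaultSigmaFn, seed = 1L,
                                aRange = c(4, 12)) {
  stopifnot(n >= 100L)
  set.seed(seed)
  A <- runif(n, aRange[1L], aRange[2L])
  s <- sigmaFn(A)
  stopifnot(all(s > 0))
  data.frame(entity = sprintf("e%05d", seq_len(n)), trueA = A,
             wt = A + rnorm(n, 0, s), ko = A + rnorm(n, 0, s),
             stringsAsFactors = FALSE)
}

.syntheticLignin <- function(lines) {
  def <- defaultLigninLevels()
  if (all(lines %in% names(def))) return(def[lines])
  n <- length(lines)
  lv <- c(100, seq(95, 30, length.out = n - 1L))
  setNames(lv, lines)
}

#' Default synthetic-study parameters
#'
#' The generator's defaults define the emulated study: 500 proteins with 3
#' peptides each (20\% shared between two proteins), 2000 transcripts, 100
#' metabolites, KEGO families of 3 genes, 20 planted lignin-tracking
#' proteins whose per-line log2 effects are an affine function of the lignin
#' vector plus Gaussian noise of sd 0.05, and 9 metabolome replicates per
#' line and tissue.
#'
#' @return named list of generator parameters.
#' @export
defaultStudyParams <- function() {
  c(defaultConfig()$simulation,
    list(pepObsProb = 1.0, refNoiseSd = 0.05, nbDispersion = 10,
         plantedEdgeProb = 0.35, nDecoyEdges = 800L,
         sigmaFn = defaultSigmaFn))
}

#' Generate a seeded synthetic multi-omics study with known ground truth
#'
#' Emulates the knock-out study design end to end: 8-plex iTRAQ spectrum
#' reports with one pooled-reference channel per plex (the reference value
#' is the mean of the line channel values plus a small noise term),
#' negative-binomial transcript counts, log-normal metabolite abundances
#' carrying internal-standard and tissue-weight factors, gene-to-KEGO and
#' peptide-to-protein maps, a substrate/product reaction table, the per-line
#' lignin G+S vector, and a STRING-style interaction table containing
#' planted edges among the lignin-tracking set (score >= 0.7) plus random
#' decoys. Effects are planted at KEGO level and shared between the
#' transcript and protein members of a family; the planted lignin-tracking
#' proteins get log2 effects affine in the lignin vector. Deterministic for
#' a fixed seed.
#'
#' @param design a \linkS4class{StudyDesign};
#'   default \code{\link{defaultStudyDesign}()}.
#' @param params named list as in \code{\link{defaultStudyParams}} (partial
#'   lists are merged over the defaults).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticStudy}.
#' @export
generateStudy <- function(design = defaultStudyDesign(),
                          params = list(), seed = 1L) {
  p <- modifyList(defaultStudyParams(), params)
  if (p$fracShared >= 1 && p$nProteins < 2L)
    stop("infeasible parameters: cannot share peptides with a single protein")
  set.seed(seed)
  st <- sampleTable(design)
  lines <- studyLines(design); wt <- wildType(design)
  ko <- setdiff(lines, wt)
  tissues <- studyTissues(design)
  lignin <- .syntheticLignin(lines)

  nP <- p$nProteins; nT <- max(p$nTranscripts, nP)
  genes <- sprintf("G%04d", seq_len(nT))
  proteins <- genes[seq_len(nP)]

  ## KEGO map over the first genesPerKego * nKegos genes
  nKego <- nT %/% p$genesPerKego
  kegoIds <- sprintf("K%05d", seq_len(nKego))
  mappedGenes <- genes[seq_len(nKego * p$genesPerKego)]
  cats <- c("ribosome", "spliceosome", "RNA transport",
            "amino acid metabolism", "carbohydrate metabolism",
            "lipid metabolism", "phenylpropanoid biosynthesis")
  kegoCat <- sample(cats, nKego, replace = TRUE)
  kegoMap <- data.frame(
    entity = mappedGenes,
    kego = rep(kegoIds, each = p$genesPerKego),
    category = rep(kegoCat, each = p$genesPerKego),
    stringsAsFactors = FALSE)

  ## planted lignin-tracking proteins: effects affine in the lignin vector
  planted <- sort(sample(proteins, p$nPlanted))
  ligninDef <- (lignin - lignin[wt]) / diff(range(lignin))  # 0 at WT, -1 at min
  beta <- runif(p$nPlanted, 1.5, 2.5) *
    rep_len(c(1, -1), p$nPlanted)

  ## KEGO-level effects shared by member transcripts and proteins
  kegoEff <- matrix(rnorm(nKego * length(lines), 0, 0.5), nKego,
                    dimnames = list(kegoIds, lines))
  kegoEff[, wt] <- 0
  geneKego <- setNames(kegoMap$kego, kegoMap$entity)
  layerEffect <- function(entitySd) {
    eff <- matrix(rnorm(nT * length(lines), 0, 0.5), nT,
                  dimnames = list(genes, lines))
    mapped <- names(geneKego)
    eff[mapped, ] <- kegoEff[geneKego[mapped], ] +
      matrix(rnorm(length(mapped) * length(lines), 0, entitySd),
             length(mapped))
    eff[, wt] <- 0
    eff
  }
  tEff <- layerEffect(0.25)
  pEff <- layerEffect(0.25)
  if (p$nPlanted > 0L) {
    pEff[planted, ] <- outer(beta, ligninDef[lines]) +
      matrix(rnorm(p$nPlanted * length(lines), 0, p$plantedNoiseSd),
             p$nPlanted)
    pEff[planted, wt] <- 0
  }

  ## ---- proteome: peptides, spectra ----
  npp <- p$peptidesPerProtein
  pepIds <- sprintf("PEP%05d", seq_len(nP * npp))
  pepOwner <- rep(proteins, each = npp)
  pepMap <- data.frame(peptide = pepIds, protein = pepOwner,
                       stringsAsFactors = FALSE)
  nShared <- round(p$fracShared * length(pepIds))
  if (nShared > 0 && nP >= 2L) {
    sharedPep <- sample(pepIds, nShared)
    other <- vapply(pepOwner[match(sharedPep, pepIds)], function(pr)
      sample(setdiff(proteins, pr), 1L), character(1))
    pepMap <- rbind(pepMap, data.frame(peptide = sharedPep, protein = other,
                                       stringsAsFactors = FALSE))
  }
  pepMap <- pepMap[order(pepMap$peptide, pepMap$protein), ]
  rownames(pepMap) <- NULL

  protBase <- setNames(rnorm(nP, 12, 2), proteins)
  pepOffset <- setNames(rnorm(length(pepIds), 0, 0.3), pepIds)
  tissueOff <- matrix(rnorm(nP * length(tissues), 0, 0.2), nP,
                      dimnames = list(proteins, tissues))
  tissueOff[, 1L] <- 0

  # true log2 abundance of each peptide in each sample; a shared peptide's
  # signal is the linear sum over the proteins carrying it
  ownerList <- split(pepMap$protein, pepMap$peptide)
  pepNames <- names(ownerList)
  trueMat <- matrix(0, length(pepNames), nrow(st),
                    dimnames = list(pepNames, st$sample))
  base1 <- protBase - log2(npp)
  for (j in seq_len(nrow(st))) {
    effj <- pEff[proteins, st$line[j]] + tissueOff[proteins, st$tissue[j]]
    linProt <- 2^(base1 + effj)
    pepLin <- vapply(ownerList, function(ow) sum(linProt[ow]), numeric(1))
    trueMat[, j] <- log2(pepLin) + pepOffset[pepNames]
  }

  pa <- plexTable(design)
  spectra <- list()
  for (plex in unique(pa$plex)) {
    sub <- pa[pa$plex == plex, ]
    observed <- pepNames[runif(length(pepNames)) < p$pepObsProb]
    if (!length(observed)) next
    chanLog2 <- matrix(NA_real_, length(observed), 8L)
    for (r in seq_len(nrow(sub))) {
      ch <- sub$channel[r]
      if (sub$reference[r]) {
        chanLog2[, ch] <- rowMeans(trueMat[observed, , drop = FALSE]) +
          rnorm(length(observed), 0, p$refNoiseSd)
      } else if (!is.na(sub$sample[r])) {
        mu <- trueMat[observed, sub$sample[r]]
        chanLog2[, ch] <- mu + rnorm(length(observed), 0, p$sigmaFn(mu))
      }
    }
    chanLin <- 2^chanLog2
    chanLin[is.na(chanLin)] <- 0
    basePeak <- rowSums(chanLin)
    prots <- vapply(ownerList[observed], paste, character(1), collapse = ";")
    spectra[[plex]] <- data.frame(
      spectrum = sprintf("%s.s%05d", plex, seq_along(observed)),
      peptide = observed, proteins = unname(prots), plex = plex,
      base_peak = basePeak,
      stringsAsFactors = FALSE)
    colnames(chanLin) <- paste0("ri", 1:8)
    spectra[[plex]] <- cbind(spectra[[plex]], as.data.frame(chanLin))
  }
  spectra <- do.call(rbind, spectra)
  rownames(spectra) <- NULL

  ## ---- transcriptome: negative-binomial counts ----
  tBase <- setNames(rlnorm(nT, log(200), 1.2), genes)
  counts <- matrix(0L, nT, nrow(st), dimnames = list(genes, st$sample))
  for (j in seq_len(nrow(st))) {
    mu <- tBase * 2^(tEff[, st$line[j]])
    counts[, j] <- rnbinom(nT, size = p$nbDispersion, mu = mu)
  }
  transcripts <- OmicsMatrix(counts, level = "transcript", isLog2 = FALSE,
                             colData = S4Vectors::DataFrame(
                               line = st$line, tissue = st$tissue,
                               replicate = st$replicate,
                               row.names = st$sample))

  ## ---- metabolome: reactions + log-normal abundances ----
  nM <- p$nMetabolites
  mets <- sprintf("met%03d", seq_len(nM))
  kPerMet <- pmin(3L, nKego)
  producer <- setNames(character(nM), mets)
  rxn <- list()
  for (i in seq_len(nM)) {
    cand <- sample(kegoIds, kPerMet)
    producer[mets[i]] <- cand[1L]
    sub <- sample(setdiff(mets, mets[i]), 1L)
    rxn[[i]] <- data.frame(
      kego = cand, substrate = sub, product = mets[i],
      direction = ifelse(runif(kPerMet) < 0.2, "reversible",
                         "unidirectional"),
      stringsAsFactors = FALSE)
  }
  reactions <- unique(do.call(rbind, rxn))
  rownames(reactions) <- NULL

  mRep <- p$metabolomeReplicates
  mSamp <- expand.grid(replicate = seq_len(mRep), line = lines,
                       tissue = tissues, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  mSamp$sample <- sprintf("%s.%s.m%d", mSamp$line, mSamp$tissue,
                          mSamp$replicate)
  mBase <- setNames(rnorm(nM, 8, 1.2), mets)
  # metabolite effects track the producing KEGO's (protein-layer) effect
  mEff <- kegoEff[producer[mets], lines, drop = FALSE] +
    matrix(rnorm(nM * length(lines), 0, 0.3), nM)
  dimnames(mEff) <- list(mets, lines)
  mEff[, wt] <- 0
  standard <- setNames(rlnorm(nrow(mSamp), 0, 0.1), mSamp$sample)
  weight <- setNames(runif(nrow(mSamp), 40, 60), mSamp$sample)
  mVal <- matrix(0, nM, nrow(mSamp), dimnames = list(mets, mSamp$sample))
  for (j in seq_len(nrow(mSamp))) {
    mu <- mBase + mEff[, mSamp$line[j]]
    mVal[, j] <- 2^(mu + rnorm(nM, 0, 0.25)) * standard[j] * weight[j]
  }
  metabolites <- OmicsMatrix(mVal, level = "metabolite", isLog2 = FALSE,
                             colData = S4Vectors::DataFrame(
                               line = mSamp$line, tissue = mSamp$tissue,
                               replicate = mSamp$replicate,
                               row.names = mSamp$sample))

  ## ---- interaction table: planted edges + decoys ----
  edges <- list()
  if (length(planted) >= 2L) {
    ring <- data.frame(a = planted,
                       b = planted[c(2:length(planted), 1L)],
                       stringsAsFactors = FALSE)
    pairs <- t(combn(planted, 2L))
    keep <- runif(nrow(pairs)) < p$plantedEdgeProb
    extra <- data.frame(a = pairs[keep, 1L], b = pairs[keep, 2L],
                        stringsAsFactors = FALSE)
    pl <- rbind(ring, extra)
    pl$score <- runif(nrow(pl), 0.7, 0.95)
    pl$evidence <- "planted"
    edges$planted <- pl
  }
  da <- sample(proteins, p$nDecoyEdges, replace = TRUE)
  db <- sample(proteins, p$nDecoyEdges, replace = TRUE)
  keep <- da != db
  decoy <- data.frame(a = da[keep], b = db[keep],
                      score = runif(sum(keep), 0.05, 0.9),
                      evidence = "decoy", stringsAsFactors = FALSE)
  edges$decoy <- decoy
  interactions <- do.call(rbind, edges)
  key <- paste(pmin(interactions$a, interactions$b),
               pmax(interactions$a, interactions$b))
  interactions <- interactions[!duplicated(key), ]
  rownames(interactions) <- NULL

  truth <- list(plantedProteins = planted, beta = setNames(beta, planted),
                lignin = lignin, ligninDeficit = ligninDef,
                proteinEffects = pEff, transcriptEffects = tEff,
                kegoEffects = kegoEff, producerKego = producer,
                proteinBase = protBase, transcriptBase = tBase,
                metaboliteBase = mBase, metaboliteEffects = mEff,
                pepTrueLog2 = trueMat, seed = seed, params = p[
                  setdiff(names(p), "sigmaFn")])

  new("SyntheticStudy", design = design, spectra = spectra,
      transcripts = transcripts, metabolites = metabolites,
      metaboliteStandard = standard, tissueWeight = weight,
      pepMap = pepMap, kegoMap = kegoMap, reactions = reactions,
      lignin = lignin, interactions = interactions, truth = truth)
}

#' Synthetic benchmark for producing-KEGO recovery
#'
#' Builds z-profiles across knock-out contrasts for a set of metabolites,
#' each with k candidate KEGO families detected in both the transcript and
#' protein layers; the metabolite profile equals its true producing KEGO's
#' protein profile plus Gaussian noise. Used to measure how often the
#' best-protein-correlation flag recovers the generating enzyme family.
#'
#' @param nMetabolites number of metabolites (>= 1).
#' @param kegosPerMetabolite candidate KEGOs per metabolite.
#' @param noiseSd sd of the noise added to the producing profile.
#' @param nContrasts number of knock-out contrasts.
#' @param seed integer RNG seed.
#' @return list with skeletons, transcriptZ, proteinZ, metaboliteZ matrices
#'   and the named \code{producer} truth vector.
#' @export
generateTriadBenchmark <- function(nMetabolites = 100L,
                                   kegosPerMetabolite = 3L,
                                   noiseSd = 0.1, nContrasts = 8L,
                                   seed = 1L) {
  set.seed(seed)
  nK <- nMetabolites * kegosPerMetabolite
  kegos <- sprintf("K%05d", seq_len(nK))
  mets <- sprintf("met%03d", seq_len(nMetabolites))
  cons <- sprintf("ko%d", seq_len(nContrasts))
  proteinZ <- matrix(rnorm(nK * nContrasts), nK,
                     dimnames = list(kegos, cons))
  transcriptZ <- matrix(rnorm(nK * nContrasts), nK,
                        dimnames = list(kegos, cons))
  producer <- setNames(kegos[(seq_len(nMetabolites) - 1L) *
                               kegosPerMetabolite + 1L], mets)
  metaboliteZ <- proteinZ[producer, , drop = FALSE] +
    matrix(rnorm(nMetabolites * nContrasts, 0, noiseSd), nMetabolites)
  rownames(metaboliteZ) <- mets
  skeletons <- data.frame(
    metabolite = rep(mets, each = kegosPerMetabolite),
    kego = kegos, role = "product", stringsAsFactors = FALSE)
  list(skeletons = skeletons, transcriptZ = transcriptZ,
       proteinZ = proteinZ, metaboliteZ = metaboliteZ, producer = producer)
}
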