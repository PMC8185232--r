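#' Pipeline configuration defaults
#'
#' One place for every tunable threshold. Defaults:
#' \itemize{
#'   \item \code{window_frac} 0.10 — sliding-window width as a fraction of
#'     the ranked MA data.
#'   \item \code{noise_floor} 2.0 — log2 protein values below this are
#'     treated as noise and removed.
#'   \item \code{rho_cutoff} 0.85 — Spearman |rho| threshold to the lignin
#'     G+S vector.
#'   \item \code{adt1_z_band} 0.5 — candidates must satisfy |z| <= band in
#'     the adt1-vs-WT stem contrast.
#'   \item \code{min_interaction_score} 0.4 — STRING combined-score floor.
#'   \item \code{pseudocount} 1 — added to transcript counts before log2.
#'   \item \code{pool_contrasts} FALSE — rank A per contrast rather than
#'     pooling all contrasts into one dataset.
#'   \item \code{window_spread} "sd" — window spread statistic ("sd" or
#'     "mad").
#'   \item \code{two_sided_p} TRUE — two-sided normal tail p-values.
#'   \item \code{inclusive_rho} TRUE — |rho| >= cutoff rather than strictly
#'     greater.
#'   \item \code{abundance_layer} "protein" — layer defining the
#'     most-abundant-KEGO flag.
#' }
#' plus a \code{simulation} block holding the synthetic-study parameters
#' (see \code{\link{generateStudy}}).
#'
#' @return named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    window_frac = 0.10,
    noise_floor = 2.0,
    rho_cutoff = 0.85,
    adt1_z_band = 0.5,
    min_interaction_score = 0.4,
    pseudocount = 1,
    pool_contrasts = FALSE,
    window_spread = "sd",
    two_sided_p = TRUE,
    inclusive_rho = TRUE,
    abundance_layer = "protein",
    simulation = list(
      nProteins = 500L, peptidesPerProtein = 3L, fracShared = 0.2,
      nTranscripts = 2000L, nMetabolites = 100L, genesPerKego = 3L,
      nPlanted = 20L, plantedNoiseSd = 0.05,
      proteomeReplicates = 3L, metabolomeReplicates = 9L
    )
  )
}

#' Load and validate a YAML configuration
#'
#' Reads a single-document YAML file and merges it over
#' \code{\link{defaultConfig}}. Unknown keys are rejected so typos surface
#' immediately.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return named list of configuration values.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(user$simulation)) {
    unknown <- setdiff(names(user$simulation), names(cfg$simulation))
    if (length(unknown))
      stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
    cfg$simulation <- modifyList(cfg$simulation, user$simulation)
    user$simulation <- NULL
  }
  cfg <- modifyList(cfg, user)
  stopifnot(cfg$window_frac > 0, cfg$window_frac <= 1,
            cfg$rho_cutoff > 0, cfg$rho_cutoff <= 1,
            cfg$adt1_z_band >= 0, cfg$min_interaction_score >= 0,
            cfg$window_spread %in% c("sd", "mad"),
            cfg$abundance_layer %in% c("protein", "transcript"))
  cfg
}
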