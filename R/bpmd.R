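# Aggregation of repeated short biased-simulation trials into the pose
# stability scores used to compare the docked and MD-relaxed poses.

#' One metadynamics trial result
#'
#' @param rmsd numeric vector: ligand RMSD from the starting pose, per
#'   frame (Angstrom, all >= 0).
#' @param persistence named numeric vector of per-interaction persistence
#'   fractions in \[0, 1\].
#' @return a trial-result list consumed by the aggregators.
#' @export
trialResult <- function(rmsd, persistence = numeric()) {
  stopifnot(is.numeric(rmsd), length(rmsd) >= 1, all(rmsd >= 0),
            all(persistence >= 0 & persistence <= 1))
  structure(list(rmsd = rmsd, persistence = persistence),
            class = "trialResult")
}

#' PoseScore: mean over trials of the time-averaged ligand RMSD
#'
#' The averaging window defaults to the full series; a window
#' (`c(from, to)` frame indices) restricts it.
#'
#' @param trials list of [trialResult()] objects.
#' @param window optional integer pair restricting the time average.
#' @return PoseScore in Angstrom.
#' @export
poseScore <- function(trials, window = NULL) {
  if (!length(trials)) stop("poseScore requires at least one trial")
  mean(vapply(trials, function(tr) {
    r <- tr$rmsd
    if (!is.null(window)) r <- r[window[1]:min(window[2], length(r))]
    mean(r)
  }, numeric(1)))
}

#' PersScore: mean over trials of the mean per-interaction persistence
#'
#' Persistence is measured for the contacts defined at the starting pose
#' (frame 0); interactions absent from a trial contribute nothing to that
#' trial's mean.
#'
#' @param trials list of [trialResult()] objects, each with at least one
#'   interaction.
#' @return PersScore fraction in \[0, 1\].
#' @export
persScore <- function(trials) {
  if (!length(trials)) stop("persScore requires at least one trial")
  vals <- vapply(trials, function(tr) {
    if (!length(tr$persistence))
      stop("persScore requires at least one interaction per trial")
    mean(tr$persistence)
  }, numeric(1))
  mean(vals)
}

#' CompScore: composite pose-stability score
#'
#' `compScore = poseScore - weight * persScore` with the conventional
#' weight of 5: strictly increasing in PoseScore and strictly decreasing
#' in PersScore, so increasingly negative values indicate better
#' stability.
#'
#' @param poseScore PoseScore (Angstrom).
#' @param persScore PersScore (fraction).
#' @param weight PersScore weight (default 5).
#' @return composite score.
#' @examples
#' compScore(3.226, 0.712)  # -0.334
#' compScore(1.747, 0.679)  # -1.648
#' @export
compScore <- function(poseScore, persScore, weight = 5) {
  stopifnot(is.finite(poseScore), is.finite(persScore))
  poseScore - weight * persScore
}

#' Aggregate trials into a full BPMD result
#'
#' @param trials list of [trialResult()] objects.
#' @param weight CompScore weight.
#' @param poseThreshold PoseScore below/at which the pose counts as
#'   stable (Angstrom, default 2).
#' @param persThreshold PersScore at/above which the contact network
#'   counts as maintained (default 0.6).
#' @param window optional PoseScore averaging window.
#' @return a [BPMDResult-class].
#' @export
bpmdScore <- function(trials, weight = 5, poseThreshold = 2,
                      persThreshold = 0.6, window = NULL) {
  ps <- poseScore(trials, window)
  pr <- persScore(trials)
  new("BPMDResult", poseScore = ps, persScore = pr,
      compScore = compScore(ps, pr, weight),
      poseStable = ps <= poseThreshold,
      contactsMaintained = pr >= persThreshold,
      weight = weight)
}

setMethod("show", "BPMDResult", function(object) {
  cat(sprintf(
    "BPMDResult: PoseScore %.3f A (%s), PersScore %.3f (%s), CompScore %.3f\n",
    object@poseScore,
    if (object@poseStable) "stable" else "not stable",
    object@persScore,
    if (object@contactsMaintained) "contacts maintained" else
      "contacts lost",
    object@compScore))
})

#' Read trials from a JSON manifest
#'
#' The manifest is a JSON array of objects with keys `rmsd_file` (CSV
#' `frame,value`) and `persistence_file` (CSV `interaction,fraction`);
#' paths are resolved relative to the manifest.
#'
#' @param path manifest file.
#' @return list of [trialResult()] objects.
#' @export
readTrials <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    r <- utils::read.csv(file.path(base, man$rmsd_file[i]))
    p <- utils::read.csv(file.path(base, man$persistence_file[i]))
    trialResult(r$value, stats::setNames(p$fraction, p$interaction))
  })
}

#' Write a BPMD result
#'
#' JSON object plus a one-line CSV summary
#' (`pose_score,pers_score,comp_score,pose_stable,contacts_maintained`).
#'
#' @param result a [BPMDResult-class].
#' @param path output path without extension; `.json` and `.csv` are
#'   appended.
#' @return invisibly, the two file paths.
#' @export
writeBPMD <- function(result, path) {
  obj <- list(pose_score = result@poseScore, pers_score = result@persScore,
              comp_score = result@compScore,
              pose_stable = result@poseStable,
              contacts_maintained = result@contactsMaintained)
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(as.data.frame(obj), paste0(path, ".csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(c(paste0(path, ".json"), paste0(path, ".csv")))
}
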