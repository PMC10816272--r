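# The end-to-end comparative screening funnel: curation -> pharmacophore
# -> target docking -> pose filter -> anti-target docking -> comparative
# elimination -> alerts -> ranking, with a telescoping audit report.

#' Default funnel configuration
#'
#' Stage order is fixed: substructure, state selection, rule of five,
#' pharmacophore, target docking, pose filter, anti-target docking +
#' comparative elimination, alerts, ranking.  Exactly one receptor is the
#' target; each anti-target carries an elimination rule --
#' `remove_if_bidentate`, or `remove_if_bidentate_or_monodentate` for
#' receptors (HDAC6-style) where even monodentate chelation disqualifies
#' a ligand.
#'
#' @param target target receptor label.
#' @param antitargetRules named character vector: anti-target label ->
#'   elimination rule.
#' @param cutoff chelation contact cutoff (Angstrom).
#' @param maxConformers pharmacophore conformer cap.
#' @param topK ranking truncation (`Inf` keeps all).
#' @return configuration list consumed by [runFunnel()].
#' @export
defaultFunnelConfig <- function(target = "HDAC11",
                                antitargetRules = c(
                                  HDAC1 = "remove_if_bidentate",
                                  HDAC6 = "remove_if_bidentate_or_monodentate",
                                  HDAC8 = "remove_if_bidentate"),
                                cutoff = 2.6, maxConformers = 50L,
                                topK = Inf) {
  list(target = target,
       antitargetRules = antitargetRules,
       substructurePattern = benzohydroxamateSmarts(),
       statePattern = hydroxamateAnionSmarts(),
       ro5 = list(strict = TRUE,
                  thresholds = list(mw = 500, logp = 5, hbd = 5, hba = 10)),
       cutoff = cutoff,
       maxConformers = maxConformers,
       topK = topK)
}

#' Read a funnel configuration from YAML
#'
#' Unspecified keys fall back to [defaultFunnelConfig()] values.  An
#' `hypothesis` key holding a file path is loaded with [readHypothesis()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readFunnelConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultFunnelConfig()
  if (!is.null(user$antitargets)) {
    cfg$antitargetRules <- vapply(user$antitargets, identity, character(1))
    user$antitargets <- NULL
  }
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  if (is.character(cfg$hypothesis))
    cfg$hypothesis <- readHypothesis(cfg$hypothesis)
  if (!is.null(cfg$alerts) && is.character(cfg$alerts) &&
      file.exists(cfg$alerts[1]))
    cfg$alerts <- defaultAlerts(cfg$alerts)
  cfg
}

.validRules <- c("remove_if_bidentate", "remove_if_bidentate_or_monodentate")

#' Comparative anti-target elimination
#'
#' A ligand that passed the target pose filter is removed iff any
#' anti-target chelation assessment triggers that receptor's rule:
#' `remove_if_bidentate` removes bidentate chelators,
#' `remove_if_bidentate_or_monodentate` removes both chelation modes.
#' Ids absent from an anti-target's table (docking failed there) are never
#' removed by that receptor.
#'
#' @param targetPass character vector of ids bidentate in the target.
#' @param antitargetAssessments named list: receptor -> data.frame with
#'   columns `id`, `class` (or a named character vector id -> class).
#' @param rules named character vector: receptor -> rule.
#' @return list with `kept` (surviving ids, input order) and `log`
#'   (data.frame `id`, `stage`, `reason`).
#' @export
comparativeEliminate <- function(targetPass, antitargetAssessments, rules) {
  if (!all(rules %in% .validRules))
    stop("unknown elimination rule(s): ",
         paste(setdiff(rules, .validRules), collapse = ", "))
  missing <- setdiff(names(rules), names(antitargetAssessments))
  if (length(missing))
    stop("elimination rule references unknown receptor(s): ",
         paste(missing, collapse = ", "))
  reason <- stats::setNames(rep(NA_character_, length(targetPass)),
                            targetPass)
  for (rec in names(rules)) {
    tab <- antitargetAssessments[[rec]]
    cls <- if (is.data.frame(tab)) {
      stats::setNames(tab$class, tab$id)
    } else tab
    bad <- switch(rules[[rec]],
      remove_if_bidentate = names(cls)[cls == "bidentate"],
      remove_if_bidentate_or_monodentate =
        names(cls)[cls %in% c("bidentate", "monodentate")])
    hit <- intersect(targetPass, bad)
    newHit <- hit[is.na(reason[hit])]
    reason[newHit] <- paste0(cls[newHit], " chelation in ", rec)
  }
  keptIds <- targetPass[is.na(reason[targetPass])]
  removedIds <- targetPass[!is.na(reason[targetPass])]
  log <- data.frame(id = removedIds,
                    stage = rep("comparative", length(removedIds)),
                    reason = unname(reason[removedIds]),
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(kept = keptIds, log = log)
}

#' Rank survivors by externally supplied binding scores
#'
#' Ascending by score (most negative binding energy first); ties are
#' broken by lexicographic id order for reproducibility.  Binding energies
#' (e.g. MM-GBSA) are consumed, never computed here.
#'
#' @param ids character vector of survivor ids.
#' @param scores named numeric vector (id -> score, lower is better) or
#'   data.frame with columns `id`, `score`.
#' @param topK truncation; `Inf` keeps all.
#' @return data.frame with columns `id`, `score`, `rank`.
#' @export
rankHits <- function(ids, scores, topK = Inf) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score, scores$id)
  missing <- setdiff(ids, names(scores))
  if (length(missing))
    stop("missing scores for: ", paste(missing, collapse = ", "))
  s <- scores[ids]
  if (any(!is.finite(s))) stop("scores must be finite")
  ord <- order(s, ids, method = "radix")
  out <- data.frame(id = ids[ord], score = unname(s[ord]),
                    stringsAsFactors = FALSE)
  if (is.finite(topK)) out <- utils::head(out, topK)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the complete comparative screening funnel
#'
#' Executes the fixed stage order on a ligand library, docking via the
#' supplied backend (`function(molecule, receptor) -> DockedPose` or
#' `NULL` when docking fails), and returns a full audit report whose
#' per-stage counts telescope.  Deterministic for a deterministic backend.
#'
#' @param lib a [MoleculeLibrary-class].
#' @param config configuration list (see [defaultFunnelConfig()]); must
#'   contain an `hypothesis` entry ([PharmacophoreHypothesis-class]).
#' @param receptors named list of [ReceptorContext-class]; must contain
#'   the target and every anti-target named in the rules.
#' @param backend docking backend function.
#' @param scores binding scores for ranking (named vector or data.frame);
#'   every comparative/alert survivor must have one.
#' @param alerts alert set for the REOS stage (default [defaultAlerts()]).
#' @return a [FunnelReport-class].
#' @export
runFunnel <- function(lib, config, receptors, backend, scores,
                      alerts = defaultAlerts()) {
  if (is.null(config$target) || !config$target %in% names(receptors))
    stop("configuration error [setup]: target receptor '", config$target,
         "' not among supplied receptors")
  rules <- config$antitargetRules
  if (length(setdiff(names(rules), names(receptors))))
    stop("configuration error [setup]: rule references unknown receptor(s): ",
         paste(setdiff(names(rules), names(receptors)), collapse = ", "))
  if (is.null(config$hypothesis) ||
      !is(config$hypothesis, "PharmacophoreHypothesis"))
    stop("configuration error [pharmacophore]: config$hypothesis must be a PharmacophoreHypothesis")

  stages <- data.frame(stage = character(), nIn = integer(),
                       nOut = integer(), stringsAsFactors = FALSE)
  survivors <- list()
  removals <- data.frame(id = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)
  note <- function(stage, nIn, keptLib, log) {
    stages <<- rbind(stages, data.frame(stage = stage, nIn = nIn,
                                        nOut = length(keptLib)))
    survivors[[stage]] <<- molIds(keptLib)
    removals <<- rbind(removals, log)
  }

  cur <- lib

  res <- substructureFilter(cur, config$substructurePattern)
  note("substructure", length(cur), kept(res), removalLog(res))
  cur <- kept(res)

  res <- selectHydroxamateState(cur, config$statePattern)
  note("state", length(cur), kept(res), removalLog(res))
  cur <- kept(res)

  res <- lipinskiFilter(cur, thresholds = config$ro5$thresholds,
                        strict = isTRUE(config$ro5$strict))
  note("rule_of_five", length(cur), kept(res), removalLog(res))
  cur <- kept(res)

  res <- screenPharmacophore(cur, config$hypothesis,
                             maxConformers = config$maxConformers)
  note("pharmacophore", length(cur), kept(res), removalLog(res))
  matches <- attr(res, "matches")
  cur <- kept(res)

  # docking into the target: one top pose per ligand, via the backend
  target <- receptors[[config$target]]
  poses <- list()
  docked <- logical(length(cur))
  for (i in seq_len(length(cur))) {
    p <- backend(cur[[i]], target)
    if (!is.null(p)) {
      docked[i] <- TRUE
      poses[[molIds(cur)[i]]] <- p
    }
  }
  resLib <- cur[which(docked)]
  failedIds <- molIds(cur)[!docked]
  note("docking_target", length(cur), resLib,
       data.frame(id = failedIds,
                  stage = rep("docking_target", length(failedIds)),
                  reason = rep("docking failed", length(failedIds)),
                  stringsAsFactors = FALSE))
  cur <- resLib

  # pose filter: keep bidentate chelators of the target zinc
  assessTarget <- lapply(poses[molIds(cur)], assessChelation,
                         receptor = target, cutoff = config$cutoff)
  keep <- vapply(assessTarget, function(a) a@cls == "bidentate", logical(1))
  res <- .filterResult(cur, keep, "pose_filter",
                       paste0(vapply(assessTarget, function(a) a@cls,
                                     character(1)),
                              " chelation in target")[!keep])
  note("pose_filter", length(cur), kept(res), removalLog(res))
  cur <- kept(res)

  # anti-target docking + chelation assessment
  anti <- list()
  for (rec in names(rules)) {
    receptor <- receptors[[rec]]
    tab <- list()
    for (i in seq_len(length(cur))) {
      p <- backend(cur[[i]], receptor)
      if (is.null(p)) next   # failed docking: absence is not removal
      a <- assessChelation(p, receptor, cutoff = config$cutoff)
      tab[[length(tab) + 1L]] <- data.frame(
        id = molIds(cur)[i], class = a@cls, stringsAsFactors = FALSE)
    }
    anti[[rec]] <- if (length(tab)) do.call(rbind, tab) else
      data.frame(id = character(), class = character())
  }
  cmp <- comparativeEliminate(molIds(cur), anti, rules)
  res <- .filterResult(cur, molIds(cur) %in% cmp$kept, "comparative",
                       cmp$log$reason[match(
                         molIds(cur)[!molIds(cur) %in% cmp$kept],
                         cmp$log$id)])
  note("comparative", length(cur), kept(res), removalLog(res))
  cur <- kept(res)

  res <- reosFilter(cur, alerts)
  note("alerts", length(cur), kept(res), removalLog(res))
  cur <- kept(res)

  ranking <- rankHits(molIds(cur), scores, topK = config$topK)
  note("ranking", length(cur), cur[ranking$id],
       data.frame(id = character(), stage = character(),
                  reason = character(), stringsAsFactors = FALSE))

  report <- new("FunnelReport", stages = stages, survivors = survivors,
                removals = removals, ranking = ranking)
  attr(report, "matches") <- matches
  attr(report, "poses") <- poses
  attr(report, "antitargetAssessments") <- anti
  report
}

#' @describeIn stageCounts stage count table of a funnel run.
#' @export
setMethod("stageCounts", "FunnelReport", function(x) x@stages)

#' @describeIn stageSurvivors survivor id sets per stage.
#' @export
setMethod("stageSurvivors", "FunnelReport", function(x) x@survivors)

#' @describeIn removalLog removal log of a funnel run.
#' @export
setMethod("removalLog", "FunnelReport", function(x) x@removals)

#' @describeIn rankingOf final ranking table.
#' @export
setMethod("rankingOf", "FunnelReport", function(x) x@ranking)

setMethod("show", "FunnelReport", function(object) {
  cat("FunnelReport\n")
  s <- object@stages
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %5d -> %5d\n", s$stage[i], s$nIn[i], s$nOut[i]))
  if (nrow(object@ranking)) {
    cat("  top ranked:",
        paste(utils::head(object@ranking$id, 5), collapse = ", "), "\n")
  }
})

#' Write a funnel report to disk
#'
#' Produces a machine-readable `report.json` (stages, counts, survivor
#' sets, ranking) plus human-readable CSVs: `removals.csv`
#' (`id,stage,reason`), `ranking.csv`, and one survivor list per stage.
#'
#' @param report a [FunnelReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFunnelReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- list(stages = report@stages, survivors = report@survivors,
              ranking = report@ranking)
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report@removals, file.path(dir, "removals.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report@ranking, file.path(dir, "ranking.csv"),
                   row.names = FALSE, quote = FALSE)
  for (stage in names(report@survivors)) {
    writeLines(report@survivors[[stage]],
               file.path(dir, paste0("survivors_", stage, ".txt")))
  }
  invisible(dir)
}
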