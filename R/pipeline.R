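## ---- end-to-end docking pipeline --------------------------------------
##
## sample with the empirical score -> minimize -> optionally CNN-rescore ->
## rank -> write SDF + JSON summary. Rescoring never touches coordinates;
## it only reorders poses and attaches CNNscore/CNNaffinity tags.

.inputError <- function(...) stop(errorCondition(paste0(...),
  class = c("minidock_input_error", "error")))
.samplingError <- function(...) stop(errorCondition(paste0(...),
  class = c("minidock_sampling_error", "error")))
.scoringError <- function(...) stop(errorCondition(paste0(...),
  class = c("minidock_scoring_error", "error")))

#' Docking job configuration
#'
#' @param receptor path to a receptor PDB or a \linkS4class{TypedMolecule}
#' @param ligand path to a ligand SDF or a \linkS4class{TypedMolecule}
#'   (or list thereof)
#' @param boxCenter,boxSize explicit search box (Angstrom); give either
#'   these or \code{autoboxLigand}, not both
#' @param autoboxLigand reference ligand (path or molecule): box = its
#'   extents + 4 Angstrom margin per side
#' @param cnn \code{"ensemble"} (3 members), \code{"fast"} (single
#'   distilled default2018-family student) or \code{"none"}
#' @param cnnScoring \code{"rescore"} (default) or \code{"none"};
#'   \code{"refinement"} is accepted but maps to rescore with a warning
#' @param cnnModels optional list of trained "CNNModel"s (overrides the
#'   synthetic-trained default scorers), plus attribute "gridSpec"
#' @param sampler a \code{\link{samplerConfig}}
#' @param covalent optional \code{\link{covalentSpec}}
#' @param out output SDF path (summary JSON lands next to it)
#' @param seed master seed: sampler and scorer training seeds derive from it
#' @param verbosity 0 quiet, 1 progress
#' @return list of class "JobConfig"
#' @export
jobConfig <- function(receptor, ligand, boxCenter = NULL, boxSize = NULL,
                      autoboxLigand = NULL, cnn = c("ensemble", "fast", "none"),
                      cnnScoring = c("rescore", "none", "refinement"),
                      cnnModels = NULL, sampler = samplerConfig(),
                      covalent = NULL, out = NULL, seed = 0L, verbosity = 0L) {
  cnn <- match.arg(cnn)
  cnnScoring <- match.arg(cnnScoring)
  if (cnnScoring == "refinement") {
    warning("cnn_scoring=refinement is not supported; falling back to rescore")
    cnnScoring <- "rescore"
  }
  haveExplicit <- !is.null(boxCenter) || !is.null(boxSize)
  if (haveExplicit && !is.null(autoboxLigand))
    .inputError("give either an explicit box or autoboxLigand, not both")
  if (haveExplicit && (is.null(boxCenter) || is.null(boxSize)))
    .inputError("explicit box needs both boxCenter and boxSize")
  if (!haveExplicit && is.null(autoboxLigand) && is.null(covalent))
    .inputError("no box specification (boxCenter/boxSize or autoboxLigand)")
  sampler$seed <- as.integer(seed)
  structure(list(receptor = receptor, ligand = ligand, boxCenter = boxCenter,
                 boxSize = boxSize, autoboxLigand = autoboxLigand, cnn = cnn,
                 cnnScoring = cnnScoring, cnnModels = cnnModels,
                 sampler = sampler, covalent = covalent, out = out,
                 seed = as.integer(seed), verbosity = verbosity),
            class = "JobConfig")
}

.loadReceptor <- function(x) {
  if (is(x, "TypedMolecule")) return(x)
  tryCatch(readReceptor(x), error = function(e)
    .inputError("receptor: ", conditionMessage(e)))
}

.loadLigands <- function(x) {
  if (is(x, "TypedMolecule")) return(list(x))
  if (is.list(x)) return(x)
  tryCatch(readLigands(x), error = function(e)
    .inputError("ligand: ", conditionMessage(e)))
}

.resolveBox <- function(config) {
  if (!is.null(config$boxCenter))
    return(list(center = as.numeric(config$boxCenter),
                size = as.numeric(rep_len(config$boxSize, 3))))
  ref <- config$autoboxLigand
  if (is.character(ref)) ref <- .loadLigands(ref)[[1]]
  X <- coords(ref)
  lo <- apply(X, 2, min) - 4
  hi <- apply(X, 2, max) + 4
  list(center = (lo + hi) / 2, size = hi - lo)
}

#' Default grid specification for CNN rescoring
#'
#' Desk-scale rescoring grid: coarse channels, 8 points of 1.25 Angstrom
#' (a 10 Angstrom cube around the box center).
#' @export
rescoreGridSpec <- function() gridSpec(resolution = 1.25, points = 8L,
                                       channels = "coarse")

#' Synthetic-trained CNN scorers for the pipeline
#'
#' Builds the scorer set behind \code{--cnn}: \code{"ensemble"} is three
#' members mirroring the release structure (one dense teacher-trained
#' model, one distilled dense student, one distilled default2018 student);
#' \code{"fast"} is the single distilled default2018-family student. All
#' members are trained on synthetic pose-labeled grids - this exercises
#' the full scoring pathway at desk scale, it does not claim real-data
#' accuracy.
#'
#' @param mode "ensemble" or "fast"
#' @param seed training seed
#' @param spec grid spec the scorers consume (must match rescoring)
#' @param nTrain training-set size
#' @return list of "CNNModel"s with attr "gridSpec"
#' @export
defaultCnnScorers <- function(mode = c("ensemble", "fast"), seed = 0L,
                              spec = rescoreGridSpec(), nTrain = 96L) {
  mode <- match.arg(mode)
  ds <- makeGridDataset(nTrain, seed = seed + 1000L, spec = spec)
  C <- spec$nchannels; np <- spec$points
  denseSpec <- modelSpec("dense", width = 4L, inChannels = C, npts = np,
                         seed = seed + 1L)
  d18Spec <- modelSpec("default2018", width = 8L, inChannels = C, npts = np,
                       seed = seed + 2L)
  teachers <- lapply(1:2, function(k)
    trainModel(modelSpec("dense", width = 4L, inChannels = C, npts = np,
                         seed = seed + 10L + k),
               ds, epochs = 8L, lr = 0.02, shuffleSeed = seed + 20L + k)$model)
  fastStudent <- distillStudent(teachers, ds, d18Spec,
    distillConfig(epochs = 8L, lr = 0.02, seed = seed + 3L))$model
  if (mode == "fast") {
    out <- list(fastStudent)
  } else {
    denseModel <- trainModel(denseSpec, ds, epochs = 8L, lr = 0.02,
                             shuffleSeed = seed + 30L)$model
    denseStudent <- distillStudent(teachers, ds, denseSpec,
      distillConfig(epochs = 8L, lr = 0.02, seed = seed + 4L))$model
    out <- list(denseModel, denseStudent, fastStudent)
  }
  attr(out, "gridSpec") <- spec
  out
}

.rescorePoses <- function(poses, receptor, ligand, models, box) {
  spec <- attr(models, "gridSpec") %||% rescoreGridSpec()
  lapply(poses, function(p) {
    g <- tryCatch(
      suppressWarnings(voxelize(receptor, ligand, p, spec,
                                center = box$center)),
      error = function(e) .scoringError("voxelization: ", conditionMessage(e)))
    sc <- ensembleScore(models, g)
    p@cnnScore <- sc$poseScore
    p@cnnAffinity <- sc$affinity
    p
  })
}

#' Run a docking job
#'
#' The full workflow: Monte Carlo sampling with per-step minimization
#' against the empirical score, pose pooling and diversity filtering, then
#' (unless \code{cnn = "none"}) CNN rescoring and re-ranking by descending
#' CNNscore. Coordinates are never changed after sampling. Deterministic
#' for a fixed seed; identical configs produce byte-identical SDF output.
#'
#' @param config a \code{\link{jobConfig}}
#' @return invisibly, a list: \code{poses} (ranked), \code{summary}
#'   (written as JSON when \code{config$out} is set, next to the SDF)
#' @export
runJob <- function(config) {
  stopifnot(inherits(config, "JobConfig"))
  receptor <- .loadReceptor(config$receptor)
  ligands <- .loadLigands(config$ligand)
  ligand <- ligands[[1]]
  if (length(ligands) > 1)
    warning("multiple ligand records: docking the first (use runScreen for libraries)")

  covalentMode <- !is.null(config$covalent)
  if (covalentMode) {
    config$sampler$covalentMode <- TRUE
    res <- covalentDock(receptor, ligand, config$covalent, config$sampler)
    poses <- res$poses
    scoreMol <- res$pairings[[1]]$construct
    scoreRec <- res$pairings[[1]]$restReceptor
    box <- list(center = colMeans(coords(scoreMol)), size = c(24, 24, 24))
  } else {
    box <- .resolveBox(config)
    poses <- tryCatch(
      runDocking(receptor, ligand, box, config = config$sampler),
      error = function(e) .samplingError(conditionMessage(e)))
    scoreMol <- ligand
    scoreRec <- receptor
  }
  if (length(poses) == 0) warning("docking produced no poses")

  if (config$cnn != "none" && config$cnnScoring == "rescore" &&
      length(poses)) {
    models <- config$cnnModels %||%
      defaultCnnScorers(if (config$cnn == "fast") "fast" else "ensemble",
                        seed = config$seed)
    if (covalentMode) {
      ## score each pairing's construct against its own environment
      poses <- unlist(lapply(res$pairings, function(pr)
        .rescorePoses(pr$poses, pr$restReceptor, pr$construct, models, box)),
        recursive = FALSE)
    } else {
      poses <- .rescorePoses(poses, scoreRec, scoreMol, models, box)
    }
    poses <- poses[order(-vapply(poses, function(p) p@cnnScore, numeric(1)))]
  }

  summary <- list(
    nPoses = length(poses), seed = config$seed, cnn = config$cnn,
    cnnScoring = config$cnnScoring, covalent = covalentMode,
    box = box,
    scores = lapply(poses, function(p) list(
      minimizedAffinity = p@empiricalScore, CNNscore = p@cnnScore,
      CNNaffinity = p@cnnAffinity,
      covalent_pairing = p@provenance$covalent_pairing)))
  if (!is.null(config$out)) {
    ok <- FALSE
    on.exit(if (!ok && file.exists(config$out)) unlink(config$out))
    writePoses(scoreMol, poses, config$out,
               title = if (covalentMode) "covalent_pose" else "pose")
    jsonlite::write_json(summary, sub("\\.sdf$", ".json", config$out),
                         auto_unbox = TRUE, digits = NA, null = "null")
    ok <- TRUE
  }
  invisible(list(poses = poses, summary = summary, molecule = scoreMol,
                 box = box))
}

#' Screen a ligand library
#'
#' Docks every record of a multi-ligand SDF (or list of molecules) and
#' reports each compound's best pose score: best CNNscore under CNN
#' rescoring, otherwise the negated empirical score, so higher is always
#' better. Per-record failures are logged as warnings and skipped.
#'
#' @param config a \code{\link{jobConfig}}; its \code{ligand} field is the
#'   library
#' @return data.frame: id, score (one row per successfully docked record)
#' @export
runScreen <- function(config) {
  receptor <- .loadReceptor(config$receptor)
  ligands <- .loadLigands(config$ligand)
  if (length(ligands) == 0) {
    warning("empty ligand library")
    return(data.frame(id = character(0), score = numeric(0)))
  }
  if (is.null(names(ligands)) || any(!nzchar(names(ligands))))
    names(ligands) <- paste0("ligand_", seq_along(ligands))
  models <- NULL
  if (config$cnn != "none")
    models <- config$cnnModels %||%
      defaultCnnScorers(if (config$cnn == "fast") "fast" else "ensemble",
                        seed = config$seed)
  box <- .resolveBox(config)
  rows <- lapply(seq_along(ligands), function(i) {
    lig <- ligands[[i]]
    res <- tryCatch({
      cfg <- config
      cfg$ligand <- lig
      cfg$cnnModels <- models
      cfg$out <- NULL
      cfg$seed <- config$seed + i
      cfg$sampler$seed <- cfg$seed
      out <- runJob(cfg)
      if (length(out$poses) == 0) return(NULL)
      best <- out$poses[[1]]
      score <- if (config$cnn != "none") best@cnnScore else -best@empiricalScore
      data.frame(id = names(ligands)[i], score = score)
    }, error = function(e) {
      warning("record ", names(ligands)[i], " failed: ", conditionMessage(e))
      NULL
    })
    res
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(data.frame(id = character(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
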