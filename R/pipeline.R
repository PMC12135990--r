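## Staged project pipeline: each stage reads its prerequisites' artifacts
## from the project directory and writes its own (CSV/PDB for humans, an
## .rds state file for resume), so a project can be resumed or partially
## rerun; identical config and seed reproduce identical outputs.

.stages <- c("load-saxs", "load-structure", "flex", "mc", "reduce",
             "profiles", "select", "final")

#' Assemble and validate a project configuration
#'
#' @param projectName project identifier (directory name).
#' @param dir parent directory for projects.
#' @param structureFile path to the starting structure (PDB/mmCIF).
#' @param iqFile,prFile experimental I(q) and P(r) text files.
#' @param qUnit,rUnit input units (see [readScatteringCurve()]).
#' @param flexThreshold,flexMinRun auto-detection parameters; ignored when
#'   \code{manualRegions} is given as a 2-column start/end matrix.
#' @param manualRegions optional matrix/data.frame of manual region bounds.
#' @param alignRange \code{c(start, end)} residue range for superposition.
#' @param trialAttempts,maxAngle,returnAfterFails,overlapBasis Monte Carlo
#'   parameters (see [mcConfig()]).
#' @param stride,offset pool reduction (see [reducePool()]).
#' @param adjacentK adjacent-frame augmentation depth (see
#'   [augmentAdjacent()]).
#' @param useSdWeighting use 1/SD weights for the I(q) NNLS fits.
#' @param calculator I(q) calculator: \code{"debye"} (internal) or a
#'   \code{function(structure, qGrid) -> ScatteringCurve} plug-in.
#' @param qGridN points of the calculator grid before interpolation.
#' @param seed seed for every random draw in the project.
#' @return A validated config list of class \code{saxsens_config}.
#' @export
projectConfig <- function(projectName, dir = tempdir(), structureFile,
                          iqFile, prFile,
                          qUnit = "inv_angstrom", rUnit = "angstrom",
                          flexThreshold = 60, flexMinRun = 5,
                          manualRegions = NULL, alignRange,
                          trialAttempts = 50000, maxAngle = 30,
                          returnAfterFails = 20, overlapBasis = "heavy",
                          stride = 10, offset = 0, adjacentK = 0,
                          useSdWeighting = TRUE, calculator = "debye",
                          qGridN = 201, seed = 1) {
  if (!nzchar(projectName)) stop("projectName must be non-empty")
  cfg <- list(projectName = projectName, dir = file.path(dir, projectName),
              structureFile = structureFile, iqFile = iqFile,
              prFile = prFile, qUnit = qUnit, rUnit = rUnit,
              flexThreshold = flexThreshold, flexMinRun = flexMinRun,
              manualRegions = manualRegions, alignRange = alignRange,
              trialAttempts = trialAttempts, maxAngle = maxAngle,
              returnAfterFails = returnAfterFails,
              overlapBasis = overlapBasis, stride = stride,
              offset = offset, adjacentK = adjacentK,
              useSdWeighting = useSdWeighting, calculator = calculator,
              qGridN = qGridN, seed = seed)
  class(cfg) <- "saxsens_config"
  cfg
}

.state_file <- function(cfg, stage) file.path(cfg$dir, paste0(stage, ".rds"))

.need_stage <- function(cfg, stage) {
  f <- .state_file(cfg, stage)
  if (!file.exists(f))
    stop("stage '", stage, "' has not been run yet; run it first")
  readRDS(f)
}

.log_line <- function(cfg, stage, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...,
      "\n", sep = "", file = file.path(cfg$dir, "project.log"),
      append = TRUE)
}

#' Run one pipeline stage
#'
#' Stages, in order: \code{load-saxs} (read + unit-convert the experimental
#' curves), \code{load-structure} (read the structure, derive mass/Rg and
#' the starting-model P(r) and I(q) comparison), \code{flex} (flexible
#' regions, auto or manual), \code{mc} (Monte Carlo pool), \code{reduce}
#' (stride/offset reduction with Rg-histogram diagnostic), \code{profiles}
#' (per-model P(r)/I(q) + NNLS preselection), \code{select}
#' (adjacent-frame augmentation + final NNLS), \code{final} (report).
#' Each stage writes its artifacts under the project directory and a state
#' file supporting resume; a missing prerequisite is an error naming the
#' stage to run first.
#'
#' @param cfg a config from [projectConfig()].
#' @param stage one of the stage names above.
#' @return The stage's state (invisibly), also saved on disk.
#' @export
runStage <- function(cfg, stage) {
  stage <- match.arg(stage, .stages)
  dir.create(cfg$dir, showWarnings = FALSE, recursive = TRUE)
  state <- switch(stage,
    "load-saxs" = .stage_load_saxs(cfg),
    "load-structure" = .stage_load_structure(cfg),
    "flex" = .stage_flex(cfg),
    "mc" = .stage_mc(cfg),
    "reduce" = .stage_reduce(cfg),
    "profiles" = .stage_profiles(cfg),
    "select" = .stage_select(cfg),
    "final" = .stage_final(cfg))
  saveRDS(state, .state_file(cfg, stage))
  invisible(state)
}

#' Run all stages in order
#' @param cfg a config from [projectConfig()].
#' @return The final report (see [finalReport()]), invisibly.
#' @export
runPipeline <- function(cfg) {
  for (s in .stages) runStage(cfg, s)
  invisible(.need_stage(cfg, "final"))
}

.stage_load_saxs <- function(cfg) {
  iq <- readScatteringCurve(cfg$iqFile, cfg$qUnit)
  pr <- readPofR(cfg$prFile, cfg$rUnit)
  writeCurvesCSV(list(iq), "I_exp", file.path(cfg$dir, "iq_exp.csv"))
  writeCurvesCSV(list(pr), "P_exp", file.path(cfg$dir, "pr_exp.csv"))
  .log_line(cfg, "load-saxs", "I(q): ", length(iq@q), " points; P(r): ",
            length(pr@r), " bins")
  list(iq = iq, pr = pr)
}

.stage_load_structure <- function(cfg) {
  saxs <- .need_stage(cfg, "load-saxs")
  s <- readStructure(cfg$structureFile)
  pr0 <- computePr(s)
  ## the internal Debye calculator can evaluate on the experimental grid
  ## directly; external calculators get their own grid and are linearly
  ## interpolated onto the experimental q values
  qgrid <- if (is.function(cfg$calculator))
    seq(max(min(saxs$iq@q) * 0.5, 1e-4), max(saxs$iq@q),
        length.out = cfg$qGridN)
  else saxs$iq@q
  iq0 <- .calc_iq(cfg, s, qgrid)
  iq0i <- interpolateToGrid(iq0, saxs$iq@q)
  fit_iq <- scaleAndChi2(iq0i, saxs$iq)
  pr0_grid <- .pr_on_grid(pr0, saxs$pr@r)
  fit_pr <- .pr_rmsd(pr0_grid, saxs$pr)
  .log_line(cfg, "load-structure", nAtoms(s), " atoms, ", nResidues(s),
            " residues, mass ", round(molecularMass(s), 1), " Da, Rg ",
            round(rgFromCoords(s), 2), " A; I(q) nchi2 ",
            signif(fit_iq$nchi2, 4))
  list(structure = s, rg = rgFromCoords(s), mass = molecularMass(s),
       pr = pr0, iq = iq0, iq_interp = iq0i, fit_iq = fit_iq,
       fit_pr = fit_pr, qgrid = qgrid)
}

.calc_iq <- function(cfg, s, qgrid) {
  if (is.function(cfg$calculator)) cfg$calculator(s, qgrid)
  else computeIqDebye(s, qgrid)
}

## put a computed P(r) onto the experimental r grid (same bin width
## required; shorter/longer tails zero-padded or truncated with a check)
.pr_on_grid <- function(pr, r_target) {
  dr_s <- if (length(pr@r) > 1) pr@r[2] - pr@r[1] else 1
  dr_t <- if (length(r_target) > 1) r_target[2] - r_target[1] else 1
  if (abs(dr_s - dr_t) > 1e-6)
    stop("P(r) bin widths differ (", dr_s, " vs ", dr_t, ")")
  p <- numeric(length(r_target))
  n <- min(length(pr@p), length(p))
  p[seq_len(n)] <- pr@p[seq_len(n)]
  if (length(pr@p) > length(p) && any(pr@p[-seq_len(n)] > 0))
    warning("computed P(r) extends beyond the experimental Dmax; tail cut")
  p
}

.pr_rmsd <- function(p_calc, pr_exp) {
  ## experimental P(r) is on its own scale: scale calc to exp (unweighted)
  cc <- sum(pr_exp@p * p_calc) / sum(p_calc^2)
  list(scale = cc, rmsd = sqrt(mean((pr_exp@p - cc * p_calc)^2)))
}

.stage_flex <- function(cfg) {
  st <- .need_stage(cfg, "load-structure")
  s <- st$structure
  regions <- if (!is.null(cfg$manualRegions)) {
    mr <- as.matrix(cfg$manualRegions)
    manualRegions(mr[, 1], mr[, 2], nResidues(s))
  } else {
    detectFlexibleRegions(confidence(s), cfg$flexThreshold, cfg$flexMinRun)
  }
  if (!length(regions))
    stop("no flexible regions found; lower the threshold or supply ",
         "manual regions")
  validateAlignmentRange(regions, cfg$alignRange, nResidues(s))
  df <- data.frame(start = start(regions), end = end(regions))
  write.csv(df, file.path(cfg$dir, "flexible_regions.csv"),
            row.names = FALSE)
  .log_line(cfg, "flex", nrow(df), " region(s): ",
            paste(df$start, df$end, sep = "-", collapse = ", "))
  list(regions = regions)
}

.stage_mc <- function(cfg) {
  st <- .need_stage(cfg, "load-structure")
  fx <- .need_stage(cfg, "flex")
  config <- mcConfig(alignRange = cfg$alignRange,
                     trialAttempts = cfg$trialAttempts,
                     maxAngle = cfg$maxAngle,
                     returnAfterFails = cfg$returnAfterFails,
                     overlapBasis = cfg$overlapBasis, seed = cfg$seed)
  pool <- runMC(st$structure, fx$regions, config)
  write.csv(data.frame(trial = seq_along(acceptanceLog(pool)),
                       accepted = as.integer(acceptanceLog(pool))),
            file.path(cfg$dir, "acceptance_log.csv"), row.names = FALSE)
  write.csv(data.frame(model = modelNumbers(pool), rg = poolRg(pool)),
            file.path(cfg$dir, "rg_vs_frame.csv"), row.names = FALSE)
  .log_line(cfg, "mc", sum(acceptanceLog(pool)), " accepted of ",
            length(acceptanceLog(pool)), " trials")
  list(pool = pool)
}

.stage_reduce <- function(cfg) {
  mc <- .need_stage(cfg, "mc")
  reduced <- reducePool(mc$pool, stride = cfg$stride, offset = cfg$offset)
  cmp <- rgHistogramCompare(poolRg(mc$pool), poolRg(reduced))
  write.csv(data.frame(bin_left = head(cmp$breaks, -1),
                       full = cmp$histFull, reduced = cmp$histReduced),
            file.path(cfg$dir, "rg_histograms.csv"), row.names = FALSE)
  writeMultimodelPDB(reduced, file.path(cfg$dir, "reduced_pool.pdb"))
  .log_line(cfg, "reduce", nFrames(reduced), " of ", nFrames(mc$pool),
            " frames kept (stride ", cfg$stride, ", offset ", cfg$offset,
            "); Rg-histogram TV distance ", signif(cmp$tvDistance, 3))
  list(reduced = reduced, tvDistance = cmp$tvDistance)
}

.stage_profiles <- function(cfg) {
  saxs <- .need_stage(cfg, "load-saxs")
  st <- .need_stage(cfg, "load-structure")
  rd <- .need_stage(cfg, "reduce")
  pool <- rd$reduced
  nq <- length(saxs$iq@q)
  iq_cols <- matrix(NA_real_, nq, nFrames(pool))
  pr_cols <- matrix(0, length(saxs$pr@r), nFrames(pool))
  for (k in seq_len(nFrames(pool))) {
    fr <- getFrame(pool, k)
    iq_cols[, k] <- interpolateToGrid(.calc_iq(cfg, fr, st$qgrid),
                                      saxs$iq@q)@intensity
    pr_cols[, k] <- .pr_on_grid(computePr(fr), saxs$pr@r)
  }
  colnames(iq_cols) <- colnames(pr_cols) <- modelNumbers(pool)
  fit_iq <- nnlsSelect(iq_cols, saxs$iq,
                       useSdWeighting = cfg$useSdWeighting,
                       rg = poolRg(pool))
  fit_pr <- nnlsSelect(pr_cols, saxs$pr, useSdWeighting = FALSE,
                       rg = poolRg(pool))
  fits <- list(iq = fit_iq, pr = fit_pr)
  if (length(saxs$pr@sd))
    fits$pr_sd <- nnlsSelect(pr_cols, saxs$pr, useSdWeighting = TRUE,
                             rg = poolRg(pool))
  preselected <- sort(unique(unlist(lapply(fits, modelNumbers))))
  utils::write.csv(cbind(q = saxs$iq@q, iq_cols),
                   file.path(cfg$dir, "iq_models.csv"), row.names = FALSE)
  utils::write.csv(cbind(r = saxs$pr@r, pr_cols),
                   file.path(cfg$dir, "pr_models.csv"), row.names = FALSE)
  .log_line(cfg, "profiles", ncol(iq_cols), " models profiled; ",
            length(preselected), " preselected (I(q): ",
            length(modelNumbers(fit_iq)), ", P(r): ",
            length(modelNumbers(fit_pr)), ")")
  list(iqProfiles = iq_cols, prProfiles = pr_cols, fits = fits,
       preselected = preselected)
}

.stage_select <- function(cfg) {
  saxs <- .need_stage(cfg, "load-saxs")
  st <- .need_stage(cfg, "load-structure")
  mc <- .need_stage(cfg, "mc")
  pf <- .need_stage(cfg, "profiles")
  pool <- mc$pool
  ## preselected model numbers -> positions in the accepted pool, then
  ## augment with adjacent accepted frames in original pool ordering
  pre_pos <- match(pf$preselected, modelNumbers(pool))
  aug_pos <- if (cfg$adjacentK > 0)
    augmentAdjacent(pre_pos, cfg$adjacentK, cfg$stride, nFrames(pool))
  else sort(unique(pre_pos))
  sel_models <- modelNumbers(pool)[aug_pos]
  nq <- length(saxs$iq@q)
  iq_cols <- matrix(NA_real_, nq, length(aug_pos))
  for (k in seq_along(aug_pos)) {
    fr <- getFrame(pool, aug_pos[k])
    iq_cols[, k] <- interpolateToGrid(.calc_iq(cfg, fr, st$qgrid),
                                      saxs$iq@q)@intensity
  }
  colnames(iq_cols) <- sel_models
  fit <- nnlsSelect(iq_cols, saxs$iq, useSdWeighting = cfg$useSdWeighting,
                    rg = poolRg(pool)[aug_pos])
  keep_pos <- aug_pos[match(modelNumbers(fit), sel_models)]
  sel_pool <- new("ConformerPool", template = pool@template,
                  coords = pool@coords[, , keep_pos, drop = FALSE],
                  modelNumbers = modelNumbers(pool)[keep_pos],
                  rg = poolRg(pool)[keep_pos],
                  acceptanceLog = logical())
  writeMultimodelPDB(sel_pool, file.path(cfg$dir, "selected_models.pdb"))
  recon <- reconstructCurve(iq_cols[, match(modelNumbers(fit), sel_models),
                                    drop = FALSE],
                            fitWeights(fit), saxs$iq@q)
  writeCurvesCSV(list(saxs$iq, recon), c("I_exp", "I_ensemble"),
                 file.path(cfg$dir, "iq_reconstructed.csv"))
  pr_pos <- match(modelNumbers(fit), colnames(pf$prProfiles))
  pr_part <- .selected_pr(cfg, pool, keep_pos, saxs$pr@r, pf, pr_pos)
  rec_pr <- reconstructPr(pr_part, percents(fit), saxs$pr)
  .log_line(cfg, "select", length(modelNumbers(fit)),
            " models selected, nchi2 ", signif(nChi2(fit), 4))
  list(fit = fit, selectedPool = sel_pool, reconstructed = recon,
       compositePr = rec_pr)
}

## P(r) columns for the finally selected models: reuse the profiles-stage
## columns where available, compute the augmented extras fresh
.selected_pr <- function(cfg, pool, keep_pos, r_grid, pf, pr_pos) {
  out <- matrix(0, length(r_grid), length(keep_pos))
  for (k in seq_along(keep_pos)) {
    if (!is.na(pr_pos[k])) out[, k] <- pf$prProfiles[, pr_pos[k]]
    else out[, k] <- .pr_on_grid(computePr(getFrame(pool, keep_pos[k])),
                                 r_grid)
  }
  out
}

.stage_final <- function(cfg) {
  report <- finalReport(cfg)
  writeLines(report$text, file.path(cfg$dir, "final_report.txt"))
  write.csv(report$models, file.path(cfg$dir, "final_models.csv"),
            row.names = FALSE)
  report
}

#' Assemble the end-of-pipeline report
#'
#' Per-model number/percent/Rg table, the starting-structure versus
#' ensemble fit quality, and the three reference Rg values: starting
#' structure, weighted ensemble, and from the experimentally derived P(r).
#'
#' @param cfg a config whose \code{select} stage has completed.
#' @return list with \code{models} (data.frame), \code{summary} (named
#'   numerics) and \code{text} (formatted lines).
#' @export
finalReport <- function(cfg) {
  saxs <- .need_stage(cfg, "load-saxs")
  st <- .need_stage(cfg, "load-structure")
  sel <- .need_stage(cfg, "select")
  fit <- sel$fit
  models <- data.frame(model = modelNumbers(fit),
                       percent = round(percents(fit), 4),
                       rg = round(poolRg(sel$selectedPool), 4))
  summary <- c(start_nchi2 = st$fit_iq$nchi2,
               ensemble_nchi2 = nChi2(fit),
               start_pr_rmsd = st$fit_pr$rmsd,
               ensemble_pr_rmsd = sel$compositePr$rmsd,
               rg_start = st$rg,
               rg_ensemble = fit@weightedRg,
               rg_from_exp_pr = rgFromPr(saxs$pr))
  text <- c(
    sprintf("project: %s", cfg$projectName),
    sprintf("selected models: %d (percents total %.1f)",
            nrow(models), sum(models$percent)),
    sprintf("  model %6d  %7.3f %%  Rg %7.3f A",
            models$model, models$percent, models$rg),
    sprintf("I(q) nchi2: starting %.6g, ensemble %.6g",
            summary["start_nchi2"], summary["ensemble_nchi2"]),
    sprintf("P(r) rmsd: starting %.6g, ensemble composite %.6g",
            summary["start_pr_rmsd"], summary["ensemble_pr_rmsd"]),
    sprintf("Rg (A): starting %.3f, weighted ensemble %.3f, from experimental P(r) %.3f",
            summary["rg_start"], summary["rg_ensemble"],
            summary["rg_from_exp_pr"]))
  list(models = models, summary = summary, text = text)
}
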