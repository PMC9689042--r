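## End-to-end orchestration: simulate -> extract -> compare -> train /
## evaluate -> report, plus round-tripping cohorts through PNG + CSV so
## real B-mode exports can replace the simulator.

.KNOWN_CLASSIFIERS <- c("logistic", "naive_bayes", "mlp")
.KNOWN_SCHEMES <- c("loo", "kfold", "split50", "split60", "split70",
                    "split80")

#' Configure a pipeline run
#'
#' Validates and assembles all settings of one reproducible run. Scheme
#' labels: \code{"loo"}, \code{"kfold"} (10-fold) and
#' \code{"splitNN"} for a NN\% training percentage split.
#'
#' @param sim a \linkS4class{SimulationConfig}.
#' @param nEarly,nAdvanced,imagesPerSubject cohort layout.
#' @param levels,distance,directions texture extraction parameters.
#' @param alpha feature-screen significance level.
#' @param classifiers subset of "logistic", "naive_bayes", "mlp".
#' @param schemes subset of the known scheme labels.
#' @param nTrials trials per percentage split (cross-validation schemes
#'   run once).
#' @param seed master seed; every stage seed derives from it.
#' @param outDir output directory, created on run.
#' @param calibrate run \code{\link{calibrateGenerator}} first.
#' @param writeImages write the cohort as PNG files.
#' @return A validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simulationConfig(), nEarly = 100,
                           nAdvanced = 100, imagesPerSubject = 5,
                           levels = 32, distance = 1,
                           directions = c(0, 45, 90, 135), alpha = 0.05,
                           classifiers = .KNOWN_CLASSIFIERS,
                           schemes = .KNOWN_SCHEMES, nTrials = 5,
                           seed = 7, outDir = tempfile("liverqus_run_"),
                           calibrate = TRUE, writeImages = FALSE) {
  bad <- setdiff(classifiers, .KNOWN_CLASSIFIERS)
  if (length(bad))
    stop("unknown classifier(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(.KNOWN_CLASSIFIERS, collapse = ", "), ")")
  bad <- setdiff(schemes, .KNOWN_SCHEMES)
  if (length(bad))
    stop("unknown scheme(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(.KNOWN_SCHEMES, collapse = ", "), ")")
  new("PipelineConfig", sim = sim, nEarly = as.integer(nEarly),
      nAdvanced = as.integer(nAdvanced),
      imagesPerSubject = as.integer(imagesPerSubject),
      levels = as.integer(levels), distance = as.integer(distance),
      directions = as.numeric(directions), alpha = alpha,
      classifiers = classifiers, schemes = schemes,
      nTrials = as.integer(nTrials), seed = as.integer(seed),
      outDir = outDir, calibrate = calibrate, writeImages = writeImages)
}

## stable fingerprint of a config: serialize its fields to text, md5 it
.configHash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  s <- config@sim
  fields <- c(
    vapply(slotNames(s), function(x) paste(format(slot(s, x),
      digits = 15), collapse = ","), character(1)),
    vapply(setdiff(slotNames(config), "sim"), function(x)
      paste(format(slot(config, x), digits = 15), collapse = ","),
      character(1)))
  writeLines(paste(names(fields), fields, sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

.runStage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, extracts the 16-feature table, screens
#' features by Welch t-test, evaluates every requested classifier under
#' every requested sampling scheme, and writes a report bundle into the
#' configured output directory: \code{manifest.csv}, \code{rois.csv},
#' \code{features.csv}, \code{group_comparison.csv},
#' \code{normalized_means.csv}, \code{feature_performance.csv},
#' \code{trial_summaries.csv}, one \code{models/*.json} per classifier
#' (fitted on the full cohort), and \code{run_log.txt} with the config
#' hash, seed, counts and achieved calibration moments. Re-running with
#' an identical config reproduces identical CSVs. A failure leaves a
#' \code{INCOMPLETE} marker naming the failed stage.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param cohort optional pre-built cohort (list of image/ROI pairs);
#'   when given, simulation and calibration are skipped.
#' @return Invisibly, a list with the cohort, feature table, comparison,
#'   trial summaries and output paths.
#' @export
runPipeline <- function(config, cohort = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config@sim)
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config@outDir, "INCOMPLETE")
  writeLines("stage: start", marker)
  seeds <- .subSeeds(config@seed, 4L)
  logLines <- c(sprintf("liverQUS pipeline  config_hash=%s  seed=%d",
                        .configHash(config), config@seed))

  sim <- config@sim
  if (is.null(cohort)) {
    if (config@calibrate) {
      writeLines("stage: calibrate", marker)
      sim <- .runStage("calibrate", logLines,
                       calibrateGenerator(sim, seed = seeds[1]))
      a <- sim@achieved
      logLines <- c(logLines, sprintf(
        "calibration: %d iteration(s); achieved EI/HT %0.2f/%0.2f (early) %0.2f/%0.2f (advanced)",
        a$iterations, a$earlyEcho, a$earlyHet, a$advancedEcho,
        a$advancedHet))
    }
    writeLines("stage: simulate", marker)
    cohort <- .runStage("simulate", logLines,
      generateCohort(sim, config@nEarly, config@nAdvanced,
                     config@imagesPerSubject, seed = seeds[2]))
  }
  logLines <- c(logLines, sprintf("cohort: %d image(s), %d ROI(s)",
    length(cohort), sum(vapply(cohort, function(e) nrow(e$rois@rois),
                               integer(1)))))
  writeLines("stage: write_cohort", marker)
  .runStage("write_cohort", logLines,
            writeCohort(cohort, config@outDir,
                        writeImages = config@writeImages))

  writeLines("stage: extract", marker)
  ft <- .runStage("extract", logLines,
    extractFeatureTable(cohort, levels = config@levels,
                        distance = config@distance,
                        directions = config@directions))
  writeFeatureTable(ft, file.path(config@outDir, "features.csv"))

  writeLines("stage: compare", marker)
  cmp <- .runStage("compare", logLines, groupCompare(ft, config@alpha))
  writeGroupComparison(cmp, file.path(config@outDir,
                                      "group_comparison.csv"))
  selected <- .runStage("compare", logLines, selectFeatures(cmp))
  logLines <- c(logLines, sprintf("selected %d/%d features at alpha=%s: %s",
    length(selected), nrow(cmp), format(config@alpha),
    paste(.FEATURE_ABBREV[selected], collapse = " ")))
  ngm <- normalizedGroupMeans(ft)
  utils::write.csv(as.data.frame(ngm),
                   file.path(config@outDir, "normalized_means.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(featurePerformance(ft)),
                   file.path(config@outDir, "feature_performance.csv"),
                   row.names = FALSE)

  writeLines("stage: evaluate", marker)
  rows <- list()
  summaries <- list()
  for (cl in config@classifiers) {
    for (sch in config@schemes) {
      args <- .parseScheme(sch)
      ts <- .runStage("evaluate", logLines,
        runTrials(ft, selected, cl, args$scheme, k = args$k,
                  trainFraction = args$trainFraction,
                  nTrials = if (args$scheme == "percentage")
                    config@nTrials else 1L,
                  baseSeed = seeds[3]))
      summaries[[paste(cl, sch, sep = ".")]] <- ts
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = ts@scheme, classifier = cl,
        trial_aucs = paste(sprintf("%.4f", ts@aucs), collapse = ";"),
        mean_auc = .roundHalfUp(ts@meanAuc, 2),
        sd_auc = ifelse(is.na(ts@sdAuc), NA, .roundHalfUp(ts@sdAuc, 2)),
        cv_percent = ts@cvPercent)
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(config@outDir, "trial_summaries.csv"),
                   row.names = FALSE)

  writeLines("stage: models", marker)
  dir.create(file.path(config@outDir, "models"), showWarnings = FALSE)
  mlpSeed <- seeds[4]
  for (cl in config@classifiers) {
    fit <- .runStage("models", logLines,
                     .fitModel(cl, ft, selected, seed = mlpSeed))
    writeModel(fit, file.path(config@outDir, "models",
                              paste0(cl, ".json")))
  }

  writeLines(logLines, file.path(config@outDir, "run_log.txt"))
  unlink(marker)
  invisible(list(cohort = cohort, features = ft, comparison = cmp,
                 selected = selected, summaries = summaries,
                 outDir = config@outDir))
}

.parseScheme <- function(s) {
  if (s == "loo") return(list(scheme = "loo", k = NA, trainFraction = NA))
  if (s == "kfold") return(list(scheme = "kfold", k = 10,
                                trainFraction = NA))
  frac <- as.numeric(sub("split", "", s)) / 100
  list(scheme = "percentage", k = NA, trainFraction = frac)
}

## ----- cohort I/O ----------------------------------------------------------

#' Write a cohort as PNG images plus manifest and ROI CSVs
#'
#' \code{manifest.csv} holds image_id, subject_id, label and the image
#' path (empty when images are not written); \code{rois.csv} holds one
#' row per ROI with 0-based half-open pixel coordinates.
#'
#' @param cohort list of \code{list(image, rois)}.
#' @param dir output directory.
#' @param writeImages write the 8-bit grayscale PNGs (default TRUE).
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir, writeImages = TRUE) {
  .cohortCheck(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (writeImages)
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
  man <- do.call(rbind, lapply(cohort, function(e) {
    path <- ""
    if (writeImages) {
      path <- file.path("images", paste0(e$image@acquisitionId, ".png"))
      png::writePNG(e$image@pixels / 255, file.path(dir, path))
    }
    data.frame(image_id = e$image@acquisitionId,
               subject_id = e$image@subjectId,
               label = e$image@label, path = path)
  }))
  rois <- do.call(rbind, lapply(cohort, function(e)
    cbind(image_id = e$image@acquisitionId, e$rois@rois)))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(rois, file.path(dir, "rois.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Load an external cohort from a manifest
#'
#' Reads a \code{manifest.csv}-style table (image_id, subject_id, label,
#' path) of 8-bit grayscale PNG (or TIFF) images and an optional ROI CSV
#' (image_id, x0, y0, x1, y1; 0-based half-open). Images that are not
#' 8-bit grayscale, missing files and out-of-bounds ROIs are rejected
#' row by row; the remaining rows are loaded and the rejections reported
#' in the \code{"errors"} attribute and as a warning.
#'
#' @param manifest path to the manifest CSV.
#' @param roiCsv optional path to the ROI CSV; images without (valid)
#'   ROIs get a default grid.
#' @param nRois,roiSize default-grid parameters for images without ROIs.
#' @return Cohort list in the same form \code{\link{generateCohort}}
#'   produces, with per-row error messages in \code{attr(, "errors")}.
#' @export
loadExternalCohort <- function(manifest, roiCsv = NULL, nRois = 5,
                               roiSize = 64) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "subject_id", "label", "path") %in%
                names(man)))
  base <- dirname(manifest)
  roiTab <- if (!is.null(roiCsv)) utils::read.csv(roiCsv) else NULL
  errors <- character(0)
  out <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    res <- tryCatch({
      fp <- if (file.exists(row$path)) row$path
            else file.path(base, row$path)
      if (!file.exists(fp)) stop("file not found: ", row$path)
      a <- if (grepl("\\.tiff?$", fp, ignore.case = TRUE)) {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("TIFF support needs the 'tiff' package")
        tiff::readTIFF(fp)
      } else png::readPNG(fp)
      if (length(dim(a)) == 3L) {
        if (dim(a)[3] > 1L)
          stop("RGB/multichannel image; convert to 8-bit grayscale first")
        a <- a[, , 1]
      }
      px <- a * 255
      if (max(abs(px - round(px))) > 1e-6)
        stop("not an 8-bit image (gray levels are not integers on 0..255)")
      img <- LiverImage(round(px), label = row$label,
                        subjectId = row$subject_id,
                        acquisitionId = row$image_id)
      rois <- NULL
      if (!is.null(roiTab)) {
        sub <- roiTab[roiTab$image_id == row$image_id, , drop = FALSE]
        if (nrow(sub)) {
          ok <- sub$x0 >= 0 & sub$y0 >= 0 & sub$x1 <= ncol(px) &
            sub$y1 <= nrow(px) & sub$x1 > sub$x0 & sub$y1 > sub$y0
          if (any(!ok))
            errors <- c(errors, sprintf(
              "%s: dropped %d out-of-bounds ROI(s)", row$image_id,
              sum(!ok)))
          if (any(ok))
            rois <- ROISet(row$image_id, sub[ok, c("x0", "y0", "x1", "y1")])
        }
      }
      if (is.null(rois))
        rois <- defaultRoiGrid(img, nRois, roiSize)
      list(image = img, rois = rois)
    }, error = function(e)
      structure(conditionMessage(e), class = "rowError"))
    if (inherits(res, "rowError")) {
      errors <- c(errors, sprintf("%s: %s", row$image_id, res))
    } else {
      out[[length(out) + 1L]] <- res
    }
  }
  if (length(errors))
    warning(sprintf("%d manifest row issue(s); see attr(, 'errors')",
                    length(errors)))
  attr(out, "errors") <- errors
  out
}
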